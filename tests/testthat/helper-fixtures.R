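# shared fixture builders (all data generated in code)

# a tiny valid plate with arbitrary values
tiny_plate <- function(wells = c("A01", "A02"), times = c(13, 13.5, 14),
                       values = NULL, plate_id = "p1") {
  if (is.null(values)) {
    values <- matrix(seq_len(length(wells) * length(times)),
                     nrow = length(wells))
  }
  plate_timeseries(plate_id, wells, times, values)
}

# write lines to a temp csv and return the path
tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# a library-shaped annotation: n_racks racks, n_samples sample wells each,
# plus a negative control, written as a data.frame
library_annotation <- function(n_racks = 11, n_samples = 80) {
  do.call(rbind, lapply(seq_len(n_racks), function(r) {
    wells <- all_wells()[seq_len(n_samples + 1)]
    data.frame(rack = r, well = wells,
               gene_symbol = c(sprintf("G%02d_%03d", r, seq_len(n_samples)),
                               "siAllStars"),
               role = c(rep("sample", n_samples), "negative_control"),
               stringsAsFactors = FALSE)
  }))
}

# brute-force transient-hit oracle: enumerate every interval, keep those
# whose points all lie beyond the cut and whose duration (points * dt)
# reaches the window; completely independent of the rle-based detector
oracle_transient <- function(z, times, alpha, window_h) {
  dt <- diff(times)[1]
  cut <- qnorm(1 - alpha / 2)
  n <- length(z)
  member <- rep(FALSE, n)
  for (sgn in c(1, -1)) {
    sig <- !is.na(z) & sgn * z >= cut
    for (i in seq_len(n)) {
      if (!sig[i]) next
      j <- i
      while (j <= n && sig[j]) {
        if ((j - i + 1) * dt >= window_h - 1e-9) member[i:j] <- TRUE
        j <- j + 1
      }
    }
  }
  if (!any(member)) return(NULL)
  idx <- which(member)
  best <- idx[which.max(abs(z[idx]))]
  list(hit = TRUE,
       direction = if (z[best] < 0) "inhibitor" else "activator",
       peak_time_h = times[best],
       peak_z = z[best])
}

# a z-curve generator mixing pure noise with injected excursions
random_z_curve <- function(n = 91, p_excursion = 0.4) {
  z <- rnorm(n)
  if (runif(1) < p_excursion) {
    len <- sample(1:12, 1)
    start <- sample(seq_len(n - len + 1), 1)
    amp <- runif(1, 2, 4) * sample(c(-1, 1), 1)
    z[start:(start + len - 1)] <- z[start:(start + len - 1)] * 0.2 + amp
  }
  z
}

# small screen simulation shared across tests (2 racks, cached per session)
small_null_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_screen(sim_config(seed = 7), null_library(176))
    }
    cache
  }
})
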