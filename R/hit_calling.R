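#' Two-sided normal z cut-off for a significance level
#'
#' `alpha = 0.05` gives 1.96 (to 2 dp): the magnitude beyond which a
#' standard-normal score is in the outer `alpha` fraction (split over both
#' tails for `sidedness = "two"`).
#'
#' @param alpha significance level in (0, 1).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return positive z cut-off.
#' @examples
#' z_threshold(0.05)  # 1.959964
#' @export
z_threshold <- function(alpha, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  if (sidedness == "two") stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
}

#' Constant proliferation modulators
#'
#' Selects genes whose summarized average-CIGR z-score magnitude reaches
#' the two-sided cut-off for `alpha` (inclusive: `|z| >= cut`). Negative z
#' means lower growth than the sample population (inhibitor of
#' proliferation once the gene is knocked down), positive means activator.
#' Output is ranked by `|z|` descending.
#'
#' @param z named numeric vector of per-gene z-scores.
#' @param alpha significance level (default 0.05, i.e. the top ~5% under a
#'   standard-normal null).
#' @return data.frame `gene`, `zscore`, `direction`, ranked by `|z|`.
#' @export
constant_hits <- function(z, alpha = 0.05) {
  if (anyNA(z)) stop("z contains NA; summarize/complete first")
  cut <- z_threshold(alpha)
  sel <- abs(z) >= cut
  genes <- if (!is.null(names(z))) names(z) else as.character(seq_along(z))
  out <- data.frame(gene = genes[sel], zscore = unname(z[sel]),
                    direction = ifelse(z[sel] < 0, "inhibitor", "activator"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$zscore)), , drop = FALSE]
}

#' Transient-hit detection by thresholded run length (flooding watershed)
#'
#' Raises the "water level" to the two-sided cut-off for `alpha` and keeps
#' the maximal runs of consecutive grid points where the z-curve stays
#' beyond it (`z >= +cut` for activators, `z <= -cut` for inhibitors). A
#' run of `k` points counts as duration `k * dt` (3 half-hour points = 1.5
#' hours). The gene is a transient hit if any run lasts at least
#' `window_h`; runs shorter than the window eliminate too-transient spikes.
#' The peak is the maximum `|z|` over qualifying runs (earliest time on
#' ties); if both directions qualify, the direction of the global maximum
#' `|z|` wins, though both directions' intervals are retained.
#'
#' @param z numeric z-score curve (one gene/well).
#' @param times grid time vector (uniform step).
#' @param alpha significance level (default 0.05).
#' @param window_h minimum duration in hours a run must last (default 3);
#'   must be at least the grid step.
#' @return `NULL` if no hit, else a list of class `transient_hit` with
#'   `direction`, `intervals` (matrix `start_h`/`end_h`/`direction` rows for
#'   qualifying runs of either direction), `peak_time_h`, `peak_z`,
#'   `peak_class`.
#' @export
watershed_transient_hits <- function(z, times, alpha = 0.05, window_h = 3) {
  dt <- grid_step(times)
  if (is.na(dt)) stop("times must be a uniform grid")
  if (window_h < dt - 1e-9) stop("window_h must be >= the grid step ", dt)
  cut <- z_threshold(alpha)
  runs_of <- function(sig) {
    sig[is.na(sig)] <- FALSE
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths * dt >= window_h - 1e-9
    cbind(start = starts[keep], end = ends[keep])
  }
  up <- runs_of(z >= cut)
  dn <- runs_of(z <= -cut)
  if (nrow(up) + nrow(dn) == 0) return(NULL)
  seg <- function(runs, dir) {
    if (!nrow(runs)) return(NULL)
    data.frame(start_h = times[runs[, "start"]], end_h = times[runs[, "end"]],
               direction = dir, stringsAsFactors = FALSE)
  }
  intervals <- rbind(seg(up, "activator"), seg(dn, "inhibitor"))
  # peak over qualifying run points only
  idx <- integer(0)
  for (k in seq_len(nrow(up))) idx <- c(idx, up[k, 1]:up[k, 2])
  for (k in seq_len(nrow(dn))) idx <- c(idx, dn[k, 1]:dn[k, 2])
  idx <- sort(unique(idx))
  best <- idx[which.max(abs(z[idx]))]          # which.max -> earliest tie
  peak_z <- z[best]
  list_out <- structure(list(
    direction = if (peak_z < 0) "inhibitor" else "activator",
    intervals = intervals,
    peak_time_h = times[best],
    peak_z = peak_z,
    peak_class = classify_peak_time(times[best])),
    class = "transient_hit")
  list_out
}

#' Classify a peak time into kinetic phases
#'
#' Early effectors reach their maximum knockdown effect before 30 h post
#' transfection, intermediate in [30, 45) h, late from 45 h on (half-open
#' bins; boundary membership at 30 and 45 is assigned upward).
#'
#' @param peak_time_h hours post transfection (vectorized).
#' @return character vector `"early"`, `"intermediate"` or `"late"`.
#' @examples
#' classify_peak_time(c(25, 32, 50))
#' @export
classify_peak_time <- function(peak_time_h) {
  ifelse(peak_time_h < 30, "early",
         ifelse(peak_time_h < 45, "intermediate", "late"))
}

#' Transient hits for every row of a z-score matrix
#'
#' Applies [watershed_transient_hits()] to each well/gene row and collects
#' the calls into a hit table.
#'
#' @param zmat a [timeseries_zscore()] result (or plain matrix with
#'   `times`).
#' @param times grid times if `zmat` is a plain matrix.
#' @param alpha,window_h as in [watershed_transient_hits()].
#' @return data.frame with one row per significant interval, columns
#'   `gene`, `direction`, `zscore` (peak z), `peak_time_h`, `peak_class`,
#'   `interval_start_h`, `interval_end_h`. Zero rows if no hits.
#' @export
transient_hits <- function(zmat, times = NULL, alpha = 0.05, window_h = 3) {
  if (inherits(zmat, "plate_timeseries")) {
    times <- zmat$times
    m <- zmat$values
  } else m <- as.matrix(zmat)
  genes <- rownames(m)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(m)))
  out <- list()
  for (i in seq_len(nrow(m))) {
    h <- watershed_transient_hits(m[i, ], times, alpha, window_h)
    if (is.null(h)) next
    out[[length(out) + 1L]] <- data.frame(
      gene = genes[i], direction = h$direction, zscore = h$peak_z,
      peak_time_h = h$peak_time_h, peak_class = h$peak_class,
      interval_start_h = h$intervals$start_h,
      interval_end_h = h$intervals$end_h,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(), direction = character(),
                      zscore = numeric(), peak_time_h = numeric(),
                      peak_class = character(), interval_start_h = numeric(),
                      interval_end_h = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Parameter sweep of the transient-hit detector
#'
#' Counts transient hits over a grid of significance levels and minimum
#' time windows. Stricter levels (smaller `alpha`) and longer windows can
#' only lose hits; the monotonicity is checked after counting and any
#' violation is reported via warning (none are expected).
#'
#' @param zmat z-score matrix (rows = genes) or [timeseries_zscore()]
#'   result.
#' @param times grid times if `zmat` is a plain matrix.
#' @param alphas significance levels (default 0.01, 0.05, 0.10).
#' @param windows_h minimum windows in hours (default eight values spanning
#'   1.5-6 h).
#' @return object of class `sweep_result`: list with `alphas`, `windows_h`,
#'   and count matrices `total`, `inhibitor`, `activator`
#'   (alpha x window).
#' @export
sweep_hits <- function(zmat, times = NULL,
                       alphas = c(0.01, 0.05, 0.10),
                       windows_h = c(1.5, 2, 2.5, 3, 3.5, 4, 5, 6)) {
  if (inherits(zmat, "plate_timeseries")) {
    times <- zmat$times
    m <- zmat$values
  } else m <- as.matrix(zmat)
  dims <- list(alpha = format(alphas), window_h = format(windows_h))
  tot <- inh <- act <- matrix(0L, length(alphas), length(windows_h),
                              dimnames = dims)
  for (a in seq_along(alphas)) for (w in seq_along(windows_h)) {
    if (nrow(m)) {
      hits <- transient_hits(m, times, alphas[a], windows_h[w])
      per_gene <- unique(hits[, c("gene", "direction")])
      tot[a, w] <- nrow(per_gene)
      inh[a, w] <- sum(per_gene$direction == "inhibitor")
      act[a, w] <- sum(per_gene$direction == "activator")
    }
  }
  res <- structure(list(alphas = alphas, windows_h = windows_h,
                        total = tot, inhibitor = inh, activator = act),
                   class = "sweep_result")
  v <- sweep_monotonicity_violations(res)
  if (nrow(v)) warning("sweep monotonicity violated in ", nrow(v), " cell(s)")
  res
}

#' @rdname sweep_hits
#' @param x a `sweep_result`.
#' @return `sweep_monotonicity_violations()` returns a data.frame of cells
#'   where the count increased under a stricter setting (empty when the
#'   expected monotonicity holds).
#' @export
sweep_monotonicity_violations <- function(x) {
  stopifnot(inherits(x, "sweep_result"))
  out <- data.frame(axis = character(), i = integer(), j = integer())
  cnt <- x$total
  o <- order(x$alphas, decreasing = TRUE)  # lenient -> strict
  cnt_a <- cnt[o, , drop = FALSE]
  for (i in seq_len(nrow(cnt_a) - 1)) for (j in seq_len(ncol(cnt_a))) {
    if (cnt_a[i + 1, j] > cnt_a[i, j]) {
      out <- rbind(out, data.frame(axis = "alpha", i = i + 1L, j = j))
    }
  }
  for (i in seq_len(nrow(cnt))) for (j in seq_len(ncol(cnt) - 1)) {
    if (cnt[i, j + 1] > cnt[i, j]) {
      out <- rbind(out, data.frame(axis = "window", i = i, j = j + 1L))
    }
  }
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result: ", length(x$alphas), " alphas x ", length(x$windows_h),
      " windows (", length(x$total), " cells)\n", sep = "")
  cat("total hit counts:\n")
  print(x$total)
  invisible(x)
}

#' Display order for a transient-hit heatmap
#'
#' Inhibitors first, then activators; within each direction ascending peak
#' time; stable (ties keep input order). Returns a permutation of row
#' indices.
#'
#' @param hits data.frame with columns `direction` and `peak_time_h` (one
#'   row per hit).
#' @return integer permutation of `seq_len(nrow(hits))`.
#' @export
heatmap_order <- function(hits) {
  stopifnot(all(c("direction", "peak_time_h") %in% names(hits)))
  dir_rank <- ifelse(hits$direction == "inhibitor", 0L, 1L)
  order(dir_rank, hits$peak_time_h)  # order() is stable
}
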