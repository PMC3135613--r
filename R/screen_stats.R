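#' Z-factor assay-quality statistic
#'
#' `Z = 1 - 3 (sd_p + sd_n) / |mu_p - mu_n|` for a positive/negative control
#' pair (the classic screening-window coefficient). Bounded above by 1;
#' values >= 0 indicate controls separated well enough for screening.
#'
#' @param mu_p,sigma_p mean and standard deviation of the positive control.
#' @param mu_n,sigma_n mean and standard deviation of the negative control.
#' @return the Z-factor (scalar, or vector if inputs are vectors).
#' @examples
#' zfactor(1, 0.2, 0, 0.1)  # 0.1
#' @export
zfactor <- function(mu_p, sigma_p, mu_n, sigma_n) {
  if (any(sigma_p < 0, na.rm = TRUE) || any(sigma_n < 0, na.rm = TRUE)) {
    stop("standard deviations must be >= 0")
  }
  sep <- abs(mu_p - mu_n)
  if (length(sep) == 1L && !is.na(sep) && sep == 0) {
    stop("undefined separation: mu_p equals mu_n")
  }
  z <- 1 - 3 * (sigma_p + sigma_n) / sep
  z[!is.na(sep) & sep == 0] <- NA_real_
  z
}

#' Time-dependent Z-factor
#'
#' Extends the Z-factor into the time domain: at each time point the means
#' and n-1 standard deviations of the replicate CIGR curves of one
#' positive-control siRNA and the negative control are plugged into
#' [zfactor()]. Time points with zero separation yield `NA` rather than an
#' error so 91-point curves stay reportable.
#'
#' @param pos,neg numeric matrices, replicates x time points, on a common
#'   grid (rows are replicate wells' CIGR traces).
#' @param times optional time vector for the columns.
#' @return object of class `zfactor_curve`: list with `times`, `values`.
#' @export
time_dependent_zfactor <- function(pos, neg, times = NULL) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (ncol(pos) != ncol(neg)) stop("pos and neg must share the time grid")
  if (nrow(pos) < 2 || nrow(neg) < 2) stop("need >= 2 replicates per group")
  mu_p <- colMeans(pos, na.rm = TRUE); sd_p <- apply(pos, 2, stats::sd, na.rm = TRUE)
  mu_n <- colMeans(neg, na.rm = TRUE); sd_n <- apply(neg, 2, stats::sd, na.rm = TRUE)
  sep <- abs(mu_p - mu_n)
  z <- ifelse(sep > 0, 1 - 3 * (sd_p + sd_n) / sep, NA_real_)
  if (is.null(times)) times <- seq_len(ncol(pos))
  structure(list(times = times, values = z), class = "zfactor_curve")
}

#' @export
print.zfactor_curve <- function(x, ...) {
  fin <- is.finite(x$values)
  cat("zfactor_curve: ", length(x$values), " time points; ",
      sum(x$values >= 0, na.rm = TRUE), " with Z >= 0; max Z = ",
      if (any(fin)) format(max(x$values[fin]), digits = 3) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.zfactor_curve <- function(x, ylim = c(-2, 1), ...) {
  graphics::plot(x$times, pmax(x$values, ylim[1]), type = "l",
                 xlab = "hours post transfection", ylab = "Z-factor",
                 ylim = ylim, ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Widest contiguous window with Z-factor above a floor
#'
#' Helper for assessing an assay: length in hours of the longest run of
#' consecutive time points with `Z(t) >= floor`.
#'
#' @param curve a [time_dependent_zfactor()] result.
#' @param floor threshold (default 0).
#' @return window length in hours (0 if none).
#' @export
zfactor_window <- function(curve, floor = 0) {
  stopifnot(inherits(curve, "zfactor_curve"))
  ok <- !is.na(curve$values) & curve$values >= floor
  if (!any(ok)) return(0)
  r <- rle(ok)
  dt <- grid_step(curve$times)
  if (is.na(dt)) dt <- mean(diff(curve$times))
  max(r$lengths[r$values]) * dt
}

#' Plate-wise z-score normalization
#'
#' Centers and scales per-well scalars by the mean and n-1 standard
#' deviation of a reference population (by default the sample wells of the
#' plate, controls excluded from the reference but scored against it).
#' Removes additive plate/batch effects such as an incubator gas-supply
#' change mid-screen.
#'
#' @param values named numeric vector of per-well scalars (e.g. average
#'   CIGR).
#' @param reference indices or names of the reference wells; default all.
#' @return z-scores for all wells (same names/order as `values`).
#' @examples
#' plate_zscore(c(0, 2))  # -0.7071 +0.7071
#' @export
plate_zscore <- function(values, reference = NULL) {
  if (is.null(reference)) reference <- seq_along(values)
  ref <- values[reference]
  ref <- ref[!is.na(ref)]
  if (length(ref) < 2) stop("reference population must have >= 2 wells")
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("zero reference variance")
  (values - mean(ref)) / s
}

#' Time-series z-score normalization
#'
#' Per-time-point z-scores of a CIGR matrix against the plate's sample
#' wells: at each time point every well is centered and scaled by the mean
#' and n-1 standard deviation of the reference (sample) wells at that time
#' point. Time points where the reference variance is zero come back `NA`.
#'
#' @param cigr a [cigr_transform()] result (or any
#'   [plate_timeseries()]-shaped matrix object).
#' @param reference indices or well names of the reference population;
#'   default all wells.
#' @return object like `cigr` with z-scores in `$values` and class
#'   `zscore_matrix` prepended.
#' @export
timeseries_zscore <- function(cigr, reference = NULL) {
  stopifnot(inherits(cigr, "plate_timeseries"))
  v <- cigr$values
  if (is.null(reference)) reference <- seq_len(nrow(v))
  if (is.character(reference)) reference <- match(reference, cigr$wells)
  if (anyNA(reference)) stop("unknown reference well(s)")
  if (length(reference) < 2) stop("reference population must have >= 2 wells")
  m <- colMeans(v[reference, , drop = FALSE], na.rm = TRUE)
  s <- apply(v[reference, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  z <- sweep(sweep(v, 2, m, "-"), 2, s, "/")
  z[, !is.finite(s) | s == 0] <- NA_real_
  out <- cigr
  out$values <- z
  class(out) <- unique(c("zscore_matrix", class(cigr)))
  attr(out, "reference") <- reference
  out
}

#' Signed root-mean-square replicate summary
#'
#' Combines replicate z-scores into one value of magnitude
#' `sqrt(mean(z^2))`. By default the sign of the replicate mean is attached
#' so inhibitors (negative) and activators (positive) stay distinguishable;
#' `signed = FALSE` returns the plain RMS.
#'
#' @param z numeric vector of replicate z-scores (`NA` dropped).
#' @param signed attach `sign(mean(z))` (default `TRUE`).
#' @return scalar summary.
#' @examples
#' rms_summarize(c(3, 4))    # 3.5355
#' rms_summarize(c(-3, -4))  # -3.5355
#' @export
rms_summarize <- function(z, signed = TRUE) {
  z <- z[!is.na(z)]
  if (!length(z)) stop("no replicate values")
  m <- sqrt(mean(z^2))
  if (signed) sign(mean(z)) * m else m
}

#' Stouffer replicate combination
#'
#' `sum(z) / sqrt(n)`: preserves sign and, for independent standard-normal
#' replicates, is itself standard normal — so a fixed normal cut-off keeps
#' its nominal false-positive rate after combination.
#'
#' @param z numeric vector of replicate z-scores (`NA` dropped).
#' @return scalar combined z.
#' @export
stouffer_summarize <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) stop("no replicate values")
  sum(z) / sqrt(length(z))
}

#' Population summary of a wells-by-time matrix
#'
#' Per-time-point mean and standard deviation over wells, plus an ordinary
#' least-squares quadratic trend `mean(t) ~ a + b t + c t^2` fitted to the
#' per-time means (descriptive, unweighted). With fewer than 3 time points
#' the trend is omitted.
#'
#' @param x a [plate_timeseries()]/[cigr_transform()] object or a plain
#'   matrix (wells x time).
#' @param times time vector if `x` is a plain matrix.
#' @return list with `times`, `mean`, `sd`, and `trend` (named coefficients
#'   `a`, `b`, `c`, or `NULL`).
#' @export
population_summary <- function(x, times = NULL) {
  if (inherits(x, "plate_timeseries")) {
    times <- x$times
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(times)) times <- seq_len(ncol(x))
  m <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2, stats::sd, na.rm = TRUE)
  trend <- NULL
  if (length(times) >= 3) {
    fit <- stats::lm(m ~ times + I(times^2))
    trend <- stats::setNames(stats::coef(fit), c("a", "b", "c"))
  }
  list(times = times, mean = m, sd = s, trend = trend)
}

#' Dominant oscillation period of a time series
#'
#' Least-squares grid search for a damped sinusoid: after removing a
#' quadratic trend, the series is regressed on
#' `exp(-t/tau) * {cos, sin}` over a grid of candidate periods and
#' envelope time constants `tau` (including an undamped envelope); the
#' period of the minimum residual sum of squares is returned. Suited to
#' short records (a few cycles) where raw periodogram bins are far too
#' coarse for hour-level resolution.
#'
#' @param times time vector (hours).
#' @param x series values (e.g. population-mean CIGR).
#' @param period_range candidate period range in hours.
#' @param resolution_h grid resolution of the period search (default
#'   0.05 h).
#' @param damping_grid_h candidate envelope time constants in hours
#'   (`Inf` = undamped).
#' @return estimated period in hours.
#' @export
estimate_period <- function(times, x, period_range = c(8, 30),
                            resolution_h = 0.05,
                            damping_grid_h = c(10, 15, 20, 30, 50, Inf)) {
  ok <- is.finite(x)
  times <- times[ok]; x <- x[ok]
  detr <- stats::resid(stats::lm(x ~ times + I(times^2)))
  periods <- seq(period_range[1], period_range[2], by = resolution_h)
  t0 <- times - min(times)
  best_p <- NA_real_; best_rss <- Inf
  for (tau in damping_grid_h) {
    env <- if (is.finite(tau)) exp(-t0 / tau) else rep(1, length(t0))
    for (p in periods) {
      w <- 2 * pi / p
      X <- cbind(1, env * cos(w * times), env * sin(w * times))
      rss <- sum(stats::lm.fit(X, detr)$residuals^2)
      if (rss < best_rss) {
        best_rss <- rss; best_p <- p
      }
    }
  }
  best_p
}

#' End-point comparison for a viability screen
#'
#' Paired t-test of natural-log-transformed treated intensities against
#' matched non-targeting-control intensities, per siRNA, with
#' Benjamini-Hochberg step-up q-values over the tested set.
#'
#' @param treated numeric matrix, siRNAs x replicates, raw intensities
#'   (> 0).
#' @param control matching matrix of control intensities (same dimensions),
#'   or a single replicate-length vector recycled for every siRNA.
#' @return data.frame with columns `t`, `p`, `q` (one row per siRNA,
#'   rownames kept).
#' @export
endpoint_compare <- function(treated, control) {
  treated <- as.matrix(treated)
  if (is.null(dim(control))) {
    control <- matrix(control, nrow(treated), length(control), byrow = TRUE)
  }
  control <- as.matrix(control)
  if (!all(dim(treated) == dim(control))) {
    stop("treated and control must have matching dimensions")
  }
  if (ncol(treated) < 2) stop("need >= 2 paired replicates")
  if (any(treated <= 0) || any(control <= 0)) {
    stop("intensities must be positive before log transformation")
  }
  d <- log(treated) - log(control)
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degen <- sdd == 0 & md == 0       # identical pairs: no evidence
  tstat[degen] <- 0
  p[degen] <- 1
  data.frame(t = tstat, p = p, q = stats::p.adjust(p, method = "BH"),
             row.names = rownames(treated))
}

#' Normality diagnostic
#'
#' Shapiro-Wilk test plus the quantile pairs for a QQ plot, used before
#' trusting z-score normalization of per-plate distributions.
#'
#' @param values numeric vector, 3 <= n <= 5000 after `NA` removal.
#' @return list with `W`, `p`, and `qq` (data.frame `theoretical`,
#'   `sample`).
#' @export
normality_diagnostic <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("need 3 <= n <= 5000 values (got ", n, ")")
  if (stats::sd(values) == 0) stop("constant input: W undefined")
  sw <- stats::shapiro.test(values)
  qq <- stats::qqnorm(values, plot.it = FALSE)
  list(W = unname(sw$statistic), p = sw$p.value,
       qq = data.frame(theoretical = sort(qq$x), sample = sort(qq$y)))
}
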