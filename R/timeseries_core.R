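#' Uniform analysis grid
#'
#' The screen's analysis domain is a uniform time grid; the default mirrors
#' a kinome screen recorded every 30 minutes from 13 h to 58 h post
#' transfection, i.e. 91 points.
#'
#' @param start_h,end_h grid limits in hours post transfection.
#' @param step_h grid step in hours (default 0.5 = 30 minutes).
#' @return object of class `uniform_grid` with elements `start_h`, `end_h`,
#'   `step_h` and the point vector `times`.
#' @examples
#' length(uniform_grid()$times)  # 91
#' @export
uniform_grid <- function(start_h = 13, end_h = 58, step_h = 0.5) {
  if (!(start_h < end_h)) stop("start_h must be < end_h")
  if (step_h <= 0) stop("step_h must be > 0")
  n <- floor((end_h - start_h) / step_h + 1e-9) + 1L
  structure(list(start_h = start_h, end_h = end_h, step_h = step_h,
                 times = start_h + step_h * (seq_len(n) - 1L)),
            class = "uniform_grid")
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat("uniform_grid: ", x$start_h, "-", x$end_h, " h, step ", x$step_h,
      " h (", length(x$times), " points)\n", sep = "")
  invisible(x)
}

#' Interpolate recorded traces onto a uniform grid
#'
#' Each well's recorded readings are interpolated by a cubic spline
#' (classic FMM interpolating spline, exact at the recorded points and on
#' cubic polynomials) and evaluated at every grid point. No extrapolation:
#' the recorded times of every well must span the grid. Missing readings
#' are dropped from that well's fit; wells with more than `max_missing`
#' missing fraction raise an error (flag and drop them beforehand).
#'
#' @param series a [plate_timeseries()] (possibly irregular times).
#' @param grid a [uniform_grid()].
#' @param max_missing maximum tolerated fraction of missing readings per
#'   well (default 0.2).
#' @return a [plate_timeseries()] on `grid$times`.
#' @examples
#' s <- plate_timeseries("p", "A01", c(0, 1, 2.5, 4), matrix(c(1, 2, 3, 5), 1))
#' interpolate_to_grid(s, uniform_grid(0, 4, 1))
#' @export
interpolate_to_grid <- function(series, grid, max_missing = 0.2) {
  stopifnot(inherits(series, "plate_timeseries"),
            inherits(grid, "uniform_grid"))
  gt <- grid$times
  out <- matrix(NA_real_, length(series$wells), length(gt),
                dimnames = list(series$wells, NULL))
  for (i in seq_along(series$wells)) {
    ok <- !is.na(series$values[i, ])
    frac_missing <- 1 - mean(ok)
    if (frac_missing > max_missing) {
      stop("well ", series$wells[i], ": ",
           round(100 * frac_missing), "% readings missing (> ",
           round(100 * max_missing), "% tolerated)")
    }
    if (sum(ok) < 4) {
      stop("well ", series$wells[i], ": fewer than 4 recorded points")
    }
    tt <- series$times[ok]
    if (min(tt) > gt[1] + 1e-9 || max(tt) < gt[length(gt)] - 1e-9) {
      stop("well ", series$wells[i], ": recorded times [",
           format(min(tt)), ", ", format(max(tt)),
           "] do not span the grid [", gt[1], ", ", gt[length(gt)],
           "]; extrapolation is not performed")
    }
    out[i, ] <- stats::spline(tt, series$values[i, ok], xout = gt,
                              method = "fmm")$y
  }
  out[out < 0 & out > -1e-9] <- 0  # clamp tiny negative spline overshoot
  plate_timeseries(series$plate_id, series$wells, gt, pmax(out, 0))
}

#' Normalize cell index to a reference time point
#'
#' Divides every well's trace by its own reading at `t0_h`, the
#' manufacturer's "normalized cell index": the column at `t0_h` becomes
#' exactly 1 for every well. `t0_h` must be one of the recorded time points
#' and the reading there must be positive.
#'
#' @param series a [plate_timeseries()].
#' @param t0_h normalization time point in hours (default 8, the reference
#'   used when traces are recorded from shortly after transfection).
#' @return a [plate_timeseries()] of normalized cell index with attribute
#'   `t0_h`.
#' @examples
#' s <- plate_timeseries("p", "A01", c(8, 9, 10), matrix(c(2, 4, 6), 1))
#' normalize_ci(s, 8)$values  # 1 2 3
#' @export
normalize_ci <- function(series, t0_h = 8) {
  stopifnot(inherits(series, "plate_timeseries"))
  j <- which(abs(series$times - t0_h) < 1e-9)
  if (length(j) != 1L) {
    stop("t0_h = ", t0_h, " is not a recorded time point")
  }
  ref <- series$values[, j]
  bad <- is.na(ref) | ref <= 0
  if (any(bad)) {
    stop("cell index at t0 missing or non-positive for well(s): ",
         paste(series$wells[bad], collapse = ", "))
  }
  out <- plate_timeseries(series$plate_id, series$wells, series$times,
                          series$values / ref)
  attr(out, "t0_h") <- t0_h
  out
}

#' Cell-index growth rate (CIGR) transform
#'
#' The point-wise first derivative of the cell-index trace on a uniform
#' grid: `CIGR(t_i) = (CI(t_{i+1}) - CI(t_i)) / dt`, assigned to the left
#' endpoint, units cell-index per hour. Positive values mean the well is
#' growing, negative in recession, zero constant. With `raw_diff = TRUE`
#' the undivided successive differences are returned instead (the output of
#' a plain `diff()` on the trace).
#'
#' The transform is a left inverse of discrete integration:
#' `CI(t_1) + dt * cumsum(CIGR)` reconstructs the trace.
#'
#' @param series a [plate_timeseries()] on a uniform grid (interpolate
#'   first if needed); normalized or raw cell index.
#' @param raw_diff if `TRUE`, do not divide by the grid step.
#' @return a [plate_timeseries()] with class `cigr_matrix` prepended; one
#'   fewer time point than the input.
#' @examples
#' s <- plate_timeseries("p", "A01", c(0, 0.5, 1), matrix(c(1, 1.5, 2.5), 1))
#' cigr_transform(s)$values  # 1 2
#' @export
cigr_transform <- function(series, raw_diff = FALSE) {
  stopifnot(inherits(series, "plate_timeseries"))
  if (length(series$times) < 2) stop("need at least 2 time points")
  dt <- grid_step(series$times)
  if (is.na(dt)) stop("times are not a uniform grid; interpolate first")
  d <- t(apply(series$values, 1, diff))
  if (length(series$wells) == 1L) d <- matrix(d, nrow = 1)
  if (!raw_diff) d <- d / dt
  out <- structure(list(plate_id = series$plate_id, wells = series$wells,
                        times = series$times[-length(series$times)],
                        values = d),
                   class = c("cigr_matrix", "plate_timeseries"))
  dimnames(out$values) <- list(out$wells, NULL)
  attr(out, "step_h") <- dt
  attr(out, "raw_diff") <- raw_diff
  out
}

#' Average cell-index growth rate
#'
#' The arithmetic mean of a well's CIGR over a time domain. Over the full
#' domain this telescopes to `(CI(t_N) - CI(t_1)) / (t_N - t_1)`, i.e. the
#' integral of growth over the window, making it comparable to an end-point
#' readout.
#'
#' @param cigr a [cigr_transform()] result.
#' @param domain optional `c(start_h, end_h)`; CIGR points with left
#'   endpoint inside `[start_h, end_h]` are averaged. Default: all.
#' @param na.rm drop missing CIGR values (default `TRUE`).
#' @return named numeric vector, one mean growth rate per well.
#' @export
average_cigr <- function(cigr, domain = NULL, na.rm = TRUE) {
  stopifnot(inherits(cigr, "cigr_matrix"))
  keep <- rep(TRUE, length(cigr$times))
  if (!is.null(domain)) {
    stopifnot(length(domain) == 2, domain[1] <= domain[2])
    keep <- cigr$times >= domain[1] - 1e-9 & cigr$times <= domain[2] + 1e-9
    if (!any(keep)) stop("empty domain: no CIGR points in [",
                         domain[1], ", ", domain[2], "]")
  }
  rowMeans(cigr$values[, keep, drop = FALSE], na.rm = na.rm)
}
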