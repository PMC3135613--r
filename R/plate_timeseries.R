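#' Per-well cell-index time series for one plate
#'
#' The central container of the package: a wells-by-times matrix of
#' non-negative cell-index readings with hours-post-transfection time stamps.
#' Missing readings are `NA`; they are carried, never silently imputed.
#'
#' @param plate_id single string identifying the plate (e.g. `"R01_rep1"`).
#' @param wells character vector of well ids (`"A01"` style).
#' @param times strictly increasing numeric vector, hours post transfection.
#' @param values numeric matrix, `length(wells)` rows by `length(times)`
#'   columns; non-negative where not `NA`.
#' @return an object of class `plate_timeseries`.
#' @seealso [read_plate_timeseries()], [interpolate_to_grid()],
#'   [cigr_transform()]
#' @export
plate_timeseries <- function(plate_id, wells, times, values) {
  wells <- as.character(wells)
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(plate_id) != 1L) stop("plate_id must be a single string")
  bad <- wells[!is_valid_well(wells)]
  if (length(bad)) stop("invalid well id(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(wells)) stop("duplicate well ids")
  if (any(is.na(times))) stop("times must not contain NA")
  if (any(times < 0)) stop("negative times (hours post transfection) not allowed")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (nrow(values) != length(wells) || ncol(values) != length(times)) {
    stop("values must be a ", length(wells), " x ", length(times), " matrix")
  }
  if (any(values < 0, na.rm = TRUE)) stop("cell index values must be >= 0")
  storage.mode(values) <- "double"
  dimnames(values) <- list(wells, NULL)
  structure(list(plate_id = as.character(plate_id), wells = wells,
                 times = times, values = values),
            class = "plate_timeseries")
}

#' @export
print.plate_timeseries <- function(x, ...) {
  cat("plate_timeseries '", x$plate_id, "': ", length(x$wells), " wells, ",
      length(x$times), " time points (", format(min(x$times)), "-",
      format(max(x$times)), " h)", sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(", ", nmiss, " missing readings", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`==.plate_timeseries` <- function(e1, e2) {
  isTRUE(all.equal(unclass(e1), unclass(e2), tolerance = 0))
}

# is the time axis uniform? returns the step or NA
grid_step <- function(times, tol = 1e-8) {
  if (length(times) < 2) return(NA_real_)
  d <- diff(times)
  if (max(d) - min(d) > tol * max(abs(d), 1)) return(NA_real_)
  mean(d)
}
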