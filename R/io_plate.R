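#' Read a plate time series from CSV
#'
#' Two plain-text layouts are supported. Wide: first column `well`, remaining
#' column headers are numeric time stamps in hours; one row per well. Long
#' (tidy): columns `plate`, `well`, `time_h`, `ci`; one row per reading.
#' Empty cells are read as missing (`NA`), never as zero. Both layouts
#' decode to identical [plate_timeseries()] objects.
#'
#' @param path path to a CSV file (UTF-8, `.` decimal point).
#' @param layout `"wide"` or `"long"`.
#' @param plate_id plate identifier to attach when the wide layout (which
#'   carries none) is read; defaults to the file name without extension.
#' @return a [plate_timeseries()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("well,13,13.5", "A01,1.0,1.2", "A02,0.9,1.1"), f)
#' read_plate_timeseries(f, layout = "wide")
#' @export
read_plate_timeseries <- function(path, layout = c("wide", "long"),
                                  plate_id = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (layout == "wide") {
    if (ncol(df) < 2 || tolower(names(df)[1]) != "well") {
      stop("wide layout requires a first column 'well' and >= 1 time column")
    }
    times <- suppressWarnings(as.numeric(names(df)[-1]))
    if (any(is.na(times))) {
      stop("non-numeric time header(s): ",
           paste(names(df)[-1][is.na(times)], collapse = ", "))
    }
    if (anyDuplicated(times)) stop("duplicate time stamps in header")
    if (length(times) > 1 && any(diff(times) <= 0)) {
      stop("time header must be strictly increasing")
    }
    wells <- as.character(df[[1]])
    bad <- wells[!is_valid_well(wells)]
    if (length(bad)) stop("invalid well id(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(wells)) {
      stop("duplicate well row(s): ",
           paste(unique(wells[duplicated(wells)]), collapse = ", "))
    }
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
    plate_timeseries(plate_id, wells, times, vals)
  } else {
    need <- c("plate", "well", "time_h", "ci")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("long layout missing column(s): ",
                           paste(miss, collapse = ", "))
    plates <- unique(df$plate)
    if (length(plates) != 1L) {
      stop("long file must contain exactly one plate (found ",
           length(plates), "); split multi-plate files first")
    }
    bad <- df$well[!is_valid_well(df$well)]
    if (length(bad)) stop("invalid well id(s): ",
                          paste(unique(bad), collapse = ", "))
    if (anyDuplicated(df[, c("well", "time_h")])) {
      stop("duplicate (well, time) pair(s)")
    }
    times <- sort(unique(as.numeric(df$time_h)))
    wells <- unique(as.character(df$well))
    vals <- matrix(NA_real_, length(wells), length(times),
                   dimnames = list(wells, NULL))
    i <- match(df$well, wells)
    j <- match(df$time_h, times)
    vals[cbind(i, j)] <- as.numeric(df$ci)
    plate_timeseries(as.character(plates), wells, times, vals)
  }
}

#' Write a plate time series to CSV
#'
#' Inverse of [read_plate_timeseries()]; missing readings are written as
#' empty cells and survive a round trip as missing.
#'
#' @param series a [plate_timeseries()].
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_plate_timeseries <- function(series, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(series, "plate_timeseries"))
  if (layout == "wide") {
    df <- data.frame(well = series$wells, series$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("well", format(series$times, trim = TRUE, digits = 15))
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    df <- data.frame(
      plate = series$plate_id,
      well = rep(series$wells, times = length(series$times)),
      time_h = rep(series$times, each = length(series$wells)),
      ci = as.vector(series$values),
      stringsAsFactors = FALSE)
    df <- df[!is.na(df$ci), , drop = FALSE]  # long form omits missing cells
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a plate-layout annotation table
#'
#' CSV with one row per (rack, well): required columns `rack`, `well`,
#' `gene_symbol`, `role`; optional `catalog_number` and `replicate`. Roles
#' are `sample`, `negative_control` or `positive_control`. Every rack must
#' carry at least one negative-control well.
#'
#' @param path CSV path.
#' @return data.frame of class `well_annotation` with columns `rack`,
#'   `well`, `catalog_number`, `gene_symbol`, `role`, `replicate`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_annotation(df)
}

#' @rdname read_annotation
#' @param df a data.frame shaped as described above (already in memory).
#' @export
validate_annotation <- function(df) {
  need <- c("rack", "well", "gene_symbol", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"catalog_number" %in% names(df)) df$catalog_number <- NA_character_
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  bad <- df$well[!is_valid_well(df$well)]
  if (length(bad)) stop("invalid well id(s): ",
                        paste(unique(bad), collapse = ", "))
  roles <- c("sample", "negative_control", "positive_control")
  badrole <- setdiff(unique(df$role), roles)
  if (length(badrole)) stop("invalid role(s): ",
                            paste(badrole, collapse = ", "),
                            " (expected ", paste(roles, collapse = "/"), ")")
  if (anyDuplicated(df[, c("rack", "well")])) {
    d <- df[duplicated(df[, c("rack", "well")]), c("rack", "well")]
    stop("duplicate (rack, well): ",
         paste(paste(d$rack, d$well, sep = "/"), collapse = ", "))
  }
  if (any(df$replicate < 1)) stop("replicate must be >= 1")
  nneg <- tapply(df$role == "negative_control", df$rack, sum)
  if (any(nneg == 0)) {
    stop("rack(s) without a negative control well: ",
         paste(names(nneg)[nneg == 0], collapse = ", "))
  }
  df <- df[, c("rack", "well", "catalog_number", "gene_symbol",
               "role", "replicate")]
  class(df) <- c("well_annotation", "data.frame")
  df
}

#' Write / read a hit table
#'
#' Serializes hit calls to the plain CSV used for screen reports, columns
#' `rack`, `well`, `gene_symbol`, `direction`, `zscore`, `peak_time_h`,
#' `peak_class`, `interval_start_h`, `interval_end_h` (a hit with several
#' significant intervals occupies several rows sharing its peak fields).
#' `read_hits_table()` restores the data.frame; a write/read round trip is
#' the identity.
#'
#' @param hits data.frame with the columns above (as produced by
#'   [transient_hits()] or [constant_hits()]; missing columns are filled
#'   with `NA`). An empty data.frame yields a header-only file.
#' @param path CSV path.
#' @return `write_hits_table()` returns `path` invisibly;
#'   `read_hits_table()` returns the data.frame.
#' @export
write_hits_table <- function(hits, path) {
  cols <- c("rack", "well", "gene_symbol", "direction", "zscore",
            "peak_time_h", "peak_class", "interval_start_h", "interval_end_h")
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  for (cc in setdiff(cols, names(hits))) hits[[cc]] <- rep(NA, nrow(hits))
  hits <- hits[, cols, drop = FALSE]
  utils::write.csv(hits, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hits_table
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(rack = "character",
                                       well = "character",
                                       gene_symbol = "character",
                                       direction = "character",
                                       peak_class = "character"))
  df
}
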