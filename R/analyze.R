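#' Analyze an impedance screen
#'
#' The full analysis chain of the package, from raw per-well cell-index
#' traces to hit tables: per plate, traces are spline-interpolated onto a
#' uniform half-hour grid spanning the normalization time point to the end
#' of the analysis domain, normalized to the cell index at `t0_h`,
#' transformed to cell-index growth rates (CIGR), and restricted to the
#' analysis domain; the average CIGR of every well is z-scored against the
#' plate's sample wells (controls are scored but excluded from the
#' reference), replicate plate copies are combined per gene, and constant
#' modulators are selected at `|z| >= z_threshold(alpha)`. Time-series
#' z-scores are computed per plate and time point the same way and fed to
#' the run-length transient-hit detector. Time-dependent Z-factor curves
#' are computed per positive-control gene against the negative control,
#' pooling control wells across plates.
#'
#' @param x either a [simulate_screen()] result, or a list with elements
#'   `plates` (named list of [plate_timeseries()]), `plate_map`
#'   (data.frame `plate_id`, `rack`, `replicate`) and `annotation`
#'   (as from [read_annotation()]).
#' @param grid analysis [uniform_grid()] (default 13-58 h, 30-min step).
#' @param t0_h normalization time point (default 8 h; must be covered by
#'   the recorded traces).
#' @param alpha significance level for hit calling (default 0.05).
#' @param window_h minimum significant window for transient hits (default
#'   3 h).
#' @param combine replicate-combination rule for z-scores: `"stouffer"`
#'   (`sum(z)/sqrt(n)`; standard normal under the null, so the fixed
#'   threshold keeps its nominal rate — the default), `"rms"` (signed
#'   root-mean-square) or `"mean"`.
#' @param raw_diff pass `TRUE` to use undivided successive differences as
#'   the growth-rate measure (see [cigr_transform()]).
#' @param max_missing wells with a larger fraction of missing readings are
#'   excluded from plate statistics (default 0.2); excluded wells are
#'   listed in the result.
#' @return object of class `screen_analysis`; see Details.
#' @details The returned object contains `gene_z` (combined per-gene
#'   z-scores of average CIGR, sample genes), `control_z` (same for control
#'   genes), `constant_hits`, `transient_hits`, `gene_zmat` (gene x time
#'   combined z matrix), `zfactor_curves` (per positive control),
#'   `population` ([population_summary()] over all sample-well CIGR),
#'   `cigr` (named list of per-plate CIGR objects), `excluded_wells`, and
#'   the call parameters.
#' @export
analyze_screen <- function(x, grid = uniform_grid(), t0_h = 8,
                           alpha = 0.05, window_h = 3,
                           combine = c("stouffer", "rms", "mean"),
                           raw_diff = FALSE, max_missing = 0.2) {
  combine <- match.arg(combine)
  plates <- x$plates
  plate_map <- x$plate_map
  ann <- x$annotation
  if (is.null(plates) || is.null(plate_map) || is.null(ann)) {
    stop("x must carry plates, plate_map and annotation")
  }
  comb_fun <- switch(combine,
                     stouffer = stouffer_summarize,
                     rms = rms_summarize,
                     mean = function(z) mean(z, na.rm = TRUE))
  # interpolation grid runs from t0 so normalization hits a grid point
  igrid <- uniform_grid(min(t0_h, grid$start_h), grid$end_h, grid$step_h)

  per_plate <- list()
  excluded <- character(0)
  for (pid in names(plates)) {
    pl <- plates[[pid]]
    rack <- plate_map$rack[match(pid, plate_map$plate_id)]
    if (is.na(rack)) stop("plate ", pid, " missing from plate_map")
    a <- ann[ann$rack == rack, , drop = FALSE]
    unk <- setdiff(pl$wells, a$well)
    if (length(unk)) {
      stop("plate ", pid, ": no annotation for well(s) ",
           paste(unk, collapse = ", "))
    }
    frac_missing <- rowMeans(is.na(pl$values))
    drop <- frac_missing > max_missing
    if (any(drop)) {
      excluded <- c(excluded, paste0(pid, "/", pl$wells[drop]))
      pl <- plate_timeseries(pl$plate_id, pl$wells[!drop], pl$times,
                             pl$values[!drop, , drop = FALSE])
    }
    u <- interpolate_to_grid(pl, igrid, max_missing = 1)
    nci <- normalize_ci(u, t0_h)
    cig <- cigr_transform(nci, raw_diff = raw_diff)
    keep <- cig$times >= grid$start_h - 1e-9 & cig$times <= grid$end_h + 1e-9
    cig$times <- cig$times[keep]
    cig$values <- cig$values[, keep, drop = FALSE]
    roles <- a$role[match(cig$wells, a$well)]
    genes <- a$gene_symbol[match(cig$wells, a$well)]
    avg <- average_cigr(cig)
    ref <- which(roles == "sample")
    zavg <- plate_zscore(avg, reference = ref)
    zts <- timeseries_zscore(cig, reference = ref)
    per_plate[[pid]] <- list(cigr = cig, roles = roles, genes = genes,
                             avg_cigr = avg, z_avg = zavg, z_ts = zts,
                             rack = rack)
  }

  # combine replicate plate copies per gene (scalar z and per-time z)
  all_genes <- unique(unlist(lapply(per_plate, `[[`, "genes")))
  ntime <- length(per_plate[[1]]$cigr$times)
  gene_z <- numeric(0)
  gene_role <- character(0)
  gene_zmat <- matrix(NA_real_, 0, ntime)
  for (g in all_genes) {
    zs <- numeric(0)
    rows <- NULL
    role_g <- NA_character_
    for (pp in per_plate) {
      j <- which(pp$genes == g)
      if (!length(j)) next
      role_g <- pp$roles[j[1]]
      zs <- c(zs, pp$z_avg[j])
      rows <- rbind(rows, pp$z_ts$values[j, , drop = FALSE])
    }
    gene_z[g] <- comb_fun(zs)
    gene_role[g] <- role_g
    gene_zmat <- rbind(gene_zmat, apply(rows, 2, comb_fun))
  }
  rownames(gene_zmat) <- all_genes
  samp <- gene_role == "sample"

  const <- constant_hits(gene_z[samp], alpha = alpha)
  trans <- transient_hits(gene_zmat[samp, , drop = FALSE],
                          per_plate[[1]]$cigr$times,
                          alpha = alpha, window_h = window_h)

  # control CIGR pooled across plates for Z-factor curves
  ctrl_rows <- function(role_or_gene) {
    do.call(rbind, lapply(per_plate, function(pp) {
      j <- which(pp$genes == role_or_gene)
      pp$cigr$values[j, , drop = FALSE]
    }))
  }
  neg_genes <- unique(unlist(lapply(per_plate, function(pp)
    pp$genes[pp$roles == "negative_control"])))
  pos_genes <- unique(unlist(lapply(per_plate, function(pp)
    pp$genes[pp$roles == "positive_control"])))
  neg_mat <- do.call(rbind, lapply(neg_genes, ctrl_rows))
  times <- per_plate[[1]]$cigr$times
  zf <- lapply(pos_genes, function(g)
    time_dependent_zfactor(ctrl_rows(g), neg_mat, times = times))
  names(zf) <- pos_genes

  samp_cigr <- do.call(rbind, lapply(per_plate, function(pp)
    pp$cigr$values[pp$roles == "sample", , drop = FALSE]))
  pop <- population_summary(samp_cigr, times)

  structure(list(gene_z = gene_z[samp], control_z = gene_z[!samp],
                 gene_zmat = gene_zmat,
                 constant_hits = const, transient_hits = trans,
                 zfactor_curves = zf, population = pop,
                 per_plate = per_plate, times = times,
                 annotation = ann, excluded_wells = excluded,
                 params = list(grid = grid, t0_h = t0_h, alpha = alpha,
                               window_h = window_h, combine = combine,
                               raw_diff = raw_diff)),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("screen_analysis: ", length(x$gene_z), " genes on ",
      length(x$per_plate), " plates\n", sep = "")
  cat("  constant hits (alpha=", x$params$alpha, "): ",
      nrow(x$constant_hits), " (",
      sum(x$constant_hits$direction == "inhibitor"), " inhibitors, ",
      sum(x$constant_hits$direction == "activator"), " activators)\n",
      sep = "")
  tg <- unique(x$transient_hits[, c("gene", "direction")])
  cat("  transient hits (window ", x$params$window_h, " h): ", nrow(tg),
      " genes\n", sep = "")
  if (length(x$excluded_wells)) {
    cat("  excluded wells (> missing threshold): ",
        length(x$excluded_wells), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.screen_analysis <- function(object, ...) {
  zf <- vapply(object$zfactor_curves, zfactor_window, numeric(1))
  out <- list(n_genes = length(object$gene_z),
              n_plates = length(object$per_plate),
              constant_hits = nrow(object$constant_hits),
              transient_genes = nrow(unique(
                object$transient_hits[, c("gene", "direction")])),
              zfactor_window_h = zf,
              trend = object$population$trend)
  class(out) <- "summary.screen_analysis"
  out
}

#' @export
print.summary.screen_analysis <- function(x, ...) {
  cat("Screen of", x$n_genes, "genes on", x$n_plates, "plates\n")
  cat("Constant hits:", x$constant_hits,
      "| transient hit genes:", x$transient_genes, "\n")
  cat("Z-factor >= 0 window (h) per positive control:\n")
  print(round(x$zfactor_window_h, 1))
  if (!is.null(x$trend)) {
    cat("Population CIGR quadratic trend (a + b t + c t^2):\n")
    print(signif(x$trend, 3))
  }
  invisible(x)
}

#' @export
plot.screen_analysis <- function(x, which = c("population", "zfactor"), ...) {
  which <- match.arg(which)
  if (which == "population") {
    p <- x$population
    graphics::plot(p$times, p$mean, ylim = range(p$mean - p$sd, p$mean + p$sd),
                   xlab = "hours post transfection",
                   ylab = "population CIGR (1/h)", pch = 16, cex = 0.5, ...)
    graphics::arrows(p$times, p$mean - p$sd, p$times, p$mean + p$sd,
                     angle = 90, code = 3, length = 0.01, col = "grey70")
    if (!is.null(p$trend)) {
      graphics::curve(p$trend["a"] + p$trend["b"] * x + p$trend["c"] * x^2,
                      add = TRUE, lty = 2)
    }
  } else {
    zf <- x$zfactor_curves
    graphics::plot(NULL, xlim = range(x$times), ylim = c(-2, 1),
                   xlab = "hours post transfection", ylab = "Z-factor", ...)
    for (i in seq_along(zf)) {
      graphics::lines(zf[[i]]$times, pmax(zf[[i]]$values, -2), col = i)
    }
    graphics::abline(h = 0, lty = 2, col = "grey50")
    graphics::legend("bottomright", legend = names(zf), col = seq_along(zf),
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Run the full pipeline on CSV inputs and write a results bundle
#'
#' Thin orchestration over [analyze_screen()] for command-line use: reads
#' plate time-series CSVs and the annotation table, analyzes, and writes
#' normalized CI, CIGR and z-score matrices, Z-factor curves, hit tables,
#' the sweep grid and a run manifest into `out_dir`.
#'
#' @param plate_files character vector of plate CSV paths (wide or long
#'   layout).
#' @param annotation_file annotation CSV path.
#' @param plate_map data.frame `plate_id`, `rack`, `replicate`; default
#'   parses ids of the form `"R<rack>_rep<k>"` from the file names.
#' @param out_dir output directory (created if needed).
#' @param layout plate CSV layout.
#' @param ... passed to [analyze_screen()] (`grid`, `t0_h`, `alpha`,
#'   `window_h`, `combine`, ...).
#' @return the [analyze_screen()] result, invisibly.
#' @export
run_pipeline <- function(plate_files, annotation_file, plate_map = NULL,
                         out_dir = "screen_results",
                         layout = c("wide", "long"), ...) {
  layout <- match.arg(layout)
  plates <- lapply(plate_files, read_plate_timeseries, layout = layout)
  names(plates) <- vapply(plates, `[[`, "", "plate_id")
  if (is.null(plate_map)) {
    m <- regmatches(names(plates),
                    regexec("^R(\\d+)_rep(\\d+)$", names(plates)))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad)) {
      stop("cannot parse rack/replicate from plate id(s) ",
           paste(names(plates)[bad], collapse = ", "),
           "; supply plate_map explicitly")
    }
    plate_map <- data.frame(
      plate_id = names(plates),
      rack = as.integer(vapply(m, `[[`, "", 2)),
      replicate = as.integer(vapply(m, `[[`, "", 3)),
      stringsAsFactors = FALSE)
  }
  ann <- read_annotation(annotation_file)
  an <- analyze_screen(list(plates = plates, plate_map = plate_map,
                            annotation = ann), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(an$per_plate)) {
    pp <- an$per_plate[[pid]]
    write_plate_timeseries(pp$cigr, file.path(out_dir,
                                              paste0("cigr_", pid, ".csv")))
    write_plate_timeseries(pp$z_ts, file.path(out_dir,
                                              paste0("zscore_", pid, ".csv")))
  }
  for (g in names(an$zfactor_curves)) {
    utils::write.csv(data.frame(time_h = an$zfactor_curves[[g]]$times,
                                zfactor = an$zfactor_curves[[g]]$values),
                     file.path(out_dir, paste0("zfactor_", g, ".csv")),
                     row.names = FALSE)
  }
  ch <- an$constant_hits
  ann_idx <- match(ch$gene, ann$gene_symbol)
  write_hits_table(data.frame(rack = ann$rack[ann_idx],
                              well = ann$well[ann_idx],
                              gene_symbol = ch$gene,
                              direction = ch$direction, zscore = ch$zscore,
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "constant_hits.csv"))
  th <- an$transient_hits
  ann_idx <- match(th$gene, ann$gene_symbol)
  write_hits_table(data.frame(rack = ann$rack[ann_idx],
                              well = ann$well[ann_idx],
                              gene_symbol = th$gene,
                              direction = th$direction, zscore = th$zscore,
                              peak_time_h = th$peak_time_h,
                              peak_class = th$peak_class,
                              interval_start_h = th$interval_start_h,
                              interval_end_h = th$interval_end_h,
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "transient_hits.csv"))
  sw <- sweep_hits(an$gene_zmat, an$times)
  swdf <- data.frame(alpha = rep(sw$alphas, times = length(sw$windows_h)),
                     window_h = rep(sw$windows_h, each = length(sw$alphas)),
                     total = as.vector(sw$total),
                     inhibitor = as.vector(sw$inhibitor),
                     activator = as.vector(sw$activator))
  utils::write.csv(swdf, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  manifest <- c(
    package = "cigrscreen",
    version = as.character(utils::packageVersion("cigrscreen")),
    grid_start_h = an$params$grid$start_h, grid_end_h = an$params$grid$end_h,
    grid_step_h = an$params$grid$step_h, t0_h = an$params$t0_h,
    alpha = an$params$alpha, window_h = an$params$window_h,
    combine = an$params$combine, layout = layout,
    annotation_file = annotation_file,
    plate_files = paste(plate_files, collapse = ";"))
  write.dcf(as.data.frame(t(manifest)),
            file.path(out_dir, "manifest.dcf"))
  invisible(an)
}

#' Reproduce published screen summary counts from supplementary tables
#'
#' Given a directory holding the screen's supplementary tables exported as
#' CSV (`table_s5.csv` with columns `GeneSymbol` and `Zscore`;
#' `table_s4.csv` as a wide CIGR matrix with `Rack`, `Well`, `GeneSymbol`
#' and time columns; `table_s1.csv` with a `Rack` column), recomputes the
#' headline counts: constant hits at `|z| >= 1.96` split by direction,
#' per-gene peak times of plate-wise time-series z-scores for selected
#' genes, and the number of library entries on racks 1-10. The tables are
#' not shipped with the package; without them this function stops.
#'
#' @param dir directory containing the CSV exports.
#' @param genes genes whose peak times to report (default CDC20, CHEK1).
#' @return list with `n_hits`, `n_inhibitors`, `n_activators`,
#'   `peak_times_h` (named), `n_rack_1_10`.
#' @export
reproduce_supplementary_counts <- function(dir,
                                           genes = c("CDC20", "CHEK1")) {
  need <- file.path(dir, c("table_s5.csv", "table_s4.csv", "table_s1.csv"))
  if (!all(file.exists(need))) {
    stop("supplementary tables not found under ", dir,
         " (expected table_s1.csv, table_s4.csv, table_s5.csv)")
  }
  s5 <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  hits <- constant_hits(stats::setNames(s5$Zscore, s5$GeneSymbol),
                        alpha = 0.05)
  s4 <- utils::read.csv(need[2], stringsAsFactors = FALSE, check.names = FALSE)
  timecols <- !is.na(suppressWarnings(as.numeric(names(s4))))
  times <- as.numeric(names(s4)[timecols])
  peak <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (rk in unique(s4$Rack)) {
    sub <- s4[s4$Rack == rk, , drop = FALSE]
    m <- as.matrix(sub[, timecols, drop = FALSE])
    rownames(m) <- sub$GeneSymbol
    obj <- structure(list(plate_id = as.character(rk),
                          wells = sub$Well, times = times, values = m),
                     class = c("cigr_matrix", "plate_timeseries"))
    z <- timeseries_zscore(obj)
    for (g in genes) {
      j <- which(sub$GeneSymbol == g)
      if (length(j)) {
        zz <- colMeans(z$values[j, , drop = FALSE], na.rm = TRUE)
        peak[g] <- times[which.max(abs(zz))]
      }
    }
  }
  s1 <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  list(n_hits = nrow(hits),
       n_inhibitors = sum(hits$direction == "inhibitor"),
       n_activators = sum(hits$direction == "activator"),
       peak_times_h = peak,
       n_rack_1_10 = sum(s1$Rack %in% 1:10))
}
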