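# Synthetic impedance screens.
#
# The generative model: cells grow logistically with a time-varying rate
#   r(t) = g * lag(t) * (1 + A exp(-t/tau) cos(2 pi t / P + phi)) * e(t) * b
# (g baseline rate, lag() a smooth post-transfection lag ramp, damped
# oscillation from partial cell-cycle synchronization, e(t) the knockdown
# effect on the growth rate, b a batch factor). With r(t) given, the
# logistic ODE dN/dt = r(t) N (1 - N/K) has the closed form
#   N(t) = K / (1 + (K/N0 - 1) exp(-R(t))),  R(t) = int_0^t r(s) ds,
# evaluated here by trapezoidal accumulation on a fine internal grid.
# Cell index is ci_per_cell * N; the measured trace adds independent
# Gaussian noise to each successive increment (a random walk), so CI
# variance grows over time while CIGR noise stays stationary.

#' Knockdown effect profile
#'
#' Describes how an siRNA knockdown modulates the instantaneous growth
#' rate: direction, fractional magnitude, onset and ramp-in time, and shape
#' (`sustained` stays on once ramped in; `transient` decays again after
#' `transient_duration_h`; `biphasic` follows the transient phase with an
#' opposite-direction rebound at half magnitude).
#'
#' @param direction `"inhibitor"`, `"activator"` or `"none"`.
#' @param magnitude fractional change of growth rate at full effect
#'   (>= 0; 1 for an inhibitor stalls growth completely).
#' @param onset_h hours post transfection at which the effect starts
#'   ramping in.
#' @param ramp_h hours over which the effect ramps to (most of) full
#'   strength.
#' @param shape `"sustained"`, `"transient"` or `"biphasic"`.
#' @param transient_duration_h duration of the first phase for
#'   transient/biphasic shapes.
#' @return object of class `effect_profile`.
#' @export
effect_profile <- function(direction = c("none", "inhibitor", "activator"),
                           magnitude = 0, onset_h = 20, ramp_h = 6,
                           shape = c("sustained", "transient", "biphasic"),
                           transient_duration_h = 12) {
  direction <- match.arg(direction)
  shape <- match.arg(shape)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (onset_h < 0) stop("onset_h must be >= 0")
  if (ramp_h <= 0) stop("ramp_h must be > 0")
  structure(list(direction = direction, magnitude = magnitude,
                 onset_h = onset_h, ramp_h = ramp_h, shape = shape,
                 transient_duration_h = transient_duration_h),
            class = "effect_profile")
}

# multiplicative growth-rate modifier e(t) of an effect profile
effect_modifier <- function(effect, t) {
  if (effect$direction == "none" || effect$magnitude == 0) {
    return(rep(1, length(t)))
  }
  up <- stats::plogis((t - effect$onset_h) / (effect$ramp_h / 4))
  env <- switch(effect$shape,
    sustained = up,
    transient = up * (1 - stats::plogis(
      (t - effect$onset_h - effect$transient_duration_h) /
        (effect$ramp_h / 4))),
    biphasic = {
      off <- stats::plogis((t - effect$onset_h - effect$transient_duration_h) /
                             (effect$ramp_h / 4))
      up * (1 - off) - 0.5 * off
    })
  s <- if (effect$direction == "inhibitor") -1 else 1
  pmax(1 + s * effect$magnitude * env, 0)
}

#' Simulator configuration
#'
#' Defaults encode the study conditions the generator emulates: two
#' biological replicates per siRNA, 96-well plates with per-plate controls,
#' a ~30 h post-transfection lag, a damped oscillation with ~17 h period
#' (partial synchronization: common phase with small per-plate jitter), a
#' random-walk measurement noise that makes CI variance grow over time
#' while CIGR noise stays stationary, and an abrupt batch shift (growth
#' conditions change) from rack 7 onward.
#'
#' @param seed integer master seed; all per-plate and per-well randomness
#'   derives from it, so a fixed seed gives identical output regardless of
#'   evaluation order.
#' @param replicates plate copies per rack (default 2).
#' @param n0 seeded cells per well (default 10000).
#' @param n0_cv,rate_cv well-to-well coefficients of variation of seeding
#'   and growth rate.
#' @param growth_rate_per_h baseline exponential growth rate (1/h).
#' @param carrying_capacity logistic saturation (cells).
#' @param lag_h center of the post-transfection lag ramp (h); `0` disables
#'   the lag (seeding-density experiments without transfection).
#' @param lag_scale_h steepness scale of the lag ramp.
#' @param lag_base growth-rate fraction before the lag midpoint (cells do
#'   grow during the lag, just slower; the ramp rises from this fraction
#'   to 1).
#' @param osc_period_h,osc_amplitude,osc_damping_h damped oscillation of
#'   the growth rate.
#' @param phase_jitter_sd per-plate phase jitter (radians) around the
#'   common transfection-synchronized phase.
#' @param ci_per_cell impedance (cell-index) units per attached cell.
#' @param increment_noise_sd sd of the Gaussian noise added to each
#'   successive measured CI increment.
#' @param noise `"increment"` (random walk on CI, the default mechanism) or
#'   `"white"` (independent noise on each CI reading, for contrast tests).
#' @param plate_shift fractional growth-rate increase applied from
#'   `shift_from_rack` onward (batch effect).
#' @param shift_from_rack first rack index affected by the shift.
#' @param measure_times measurement time stamps (hours post transfection);
#'   default every 15 min from 5 h to 33 h then hourly to 60 h, mirroring a
#'   two-cadence recording schedule.
#' @param grid analysis [uniform_grid()] (default 13-58 h, 0.5 h step).
#' @param t0_h cell-index normalization time point (default 8 h).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, replicates = 2L, n0 = 10000,
                       n0_cv = 0.05, rate_cv = 0.005,
                       growth_rate_per_h = 0.05,
                       carrying_capacity = 5e6,
                       lag_h = 30, lag_scale_h = 4, lag_base = 0.3,
                       osc_period_h = 17, osc_amplitude = 0.3,
                       osc_damping_h = 30, phase_jitter_sd = 0.3,
                       ci_per_cell = 1e-4,
                       increment_noise_sd = 0.002,
                       noise = c("increment", "white"),
                       plate_shift = 0.15, shift_from_rack = 7L,
                       measure_times = c(seq(5, 33, by = 0.25),
                                         seq(34, 60, by = 1)),
                       grid = uniform_grid(), t0_h = 8) {
  noise <- match.arg(noise)
  stopifnot(growth_rate_per_h > 0, carrying_capacity > 0,
            osc_period_h > 0, osc_damping_h > 0, ci_per_cell > 0,
            n0 > 0, replicates >= 1, increment_noise_sd >= 0,
            osc_amplitude >= 0, lag_h >= 0)
  structure(list(seed = as.integer(seed), replicates = as.integer(replicates),
                 n0 = n0, n0_cv = n0_cv, rate_cv = rate_cv,
                 growth_rate_per_h = growth_rate_per_h,
                 carrying_capacity = carrying_capacity,
                 lag_h = lag_h, lag_scale_h = lag_scale_h,
                 lag_base = lag_base,
                 osc_period_h = osc_period_h, osc_amplitude = osc_amplitude,
                 osc_damping_h = osc_damping_h,
                 phase_jitter_sd = phase_jitter_sd,
                 ci_per_cell = ci_per_cell,
                 increment_noise_sd = increment_noise_sd, noise = noise,
                 plate_shift = plate_shift,
                 shift_from_rack = as.integer(shift_from_rack),
                 measure_times = measure_times, grid = grid, t0_h = t0_h),
            class = "sim_config")
}

# evaluate expr with a local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  expr
}

#' Simulate one well's cell-index trace
#'
#' @param config a [sim_config()].
#' @param effect an [effect_profile()].
#' @param seed per-well seed (derive from the master seed; two calls with
#'   the same seed are identical).
#' @param phase oscillation phase of the well's plate (radians).
#' @param rate_factor multiplicative batch factor on the growth rate
#'   (1 = no batch effect).
#' @return list with `times` (the config's measurement times) and `ci`.
#' @export
simulate_well <- function(config, effect = effect_profile(), seed = 1L,
                          phase = 0, rate_factor = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "effect_profile"))
  with_seed(seed, {
    tm <- config$measure_times
    n0 <- config$n0 * exp(stats::rnorm(1, 0, config$n0_cv))
    g <- config$growth_rate_per_h * rate_factor *
      exp(stats::rnorm(1, 0, config$rate_cv))
    tfine <- seq(0, max(tm), by = 0.1)
    lag <- if (config$lag_h > 0) {
      config$lag_base + (1 - config$lag_base) *
        stats::plogis((tfine - config$lag_h) / config$lag_scale_h)
    } else 1
    osc <- 1 + config$osc_amplitude * exp(-tfine / config$osc_damping_h) *
      cos(2 * pi * tfine / config$osc_period_h + phase)
    r <- g * lag * osc * effect_modifier(effect, tfine)
    R <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * diff(tfine)))
    Rm <- stats::approx(tfine, R, xout = tm)$y
    K <- config$carrying_capacity
    N <- K / (1 + (K / n0 - 1) * exp(-Rm))
    ci <- config$ci_per_cell * N
    if (config$increment_noise_sd > 0) {
      eps <- stats::rnorm(length(tm) - 1, 0, config$increment_noise_sd)
      ci <- if (config$noise == "increment") {
        ci + c(0, cumsum(eps))                    # random walk on increments
      } else {
        ci + c(0, eps)                            # white noise on readings
      }
    }
    list(times = tm, ci = pmax(ci, 0))
  })
}

# fixed control panel occupying column 12 of every plate
control_panel <- function() {
  data.frame(
    well = c("A12", "B12", "C12", "D12", "E12", "F12", "G12", "H12"),
    gene_symbol = c("siAllStars", "siAllStars", "PLK1", "PLK1",
                    "WEE1", "WEE1", "COPB2", "COPB2"),
    role = rep(c("negative_control", "positive_control", "positive_control",
                 "positive_control"), each = 2),
    stringsAsFactors = FALSE)
}

# effect profiles of the control genes: strong proliferation inhibitors
# with gene-specific kinetics (COPB2 manifests later than PLK1/WEE1)
control_effects <- function() {
  list(siAllStars = effect_profile("none"),
       PLK1 = effect_profile("inhibitor", magnitude = 0.95, onset_h = 12,
                             ramp_h = 6),
       WEE1 = effect_profile("inhibitor", magnitude = 0.9, onset_h = 10,
                             ramp_h = 6),
       COPB2 = effect_profile("inhibitor", magnitude = 1.0, onset_h = 22,
                              ramp_h = 10))
}

#' siRNA libraries for simulated screens
#'
#' `null_library()` builds a library of `n` genes with no effect (type-I
#' calibration); `example_library()` mixes null genes with configurable
#' numbers of early-onset inhibitors and late-onset activators.
#'
#' @param n number of genes (default 859: a kinome-plus-cell-cycle-sized
#'   library).
#' @return data.frame with columns `gene`, `direction`, `magnitude`,
#'   `onset_h`, `ramp_h`, `shape`, `transient_duration_h`.
#' @export
null_library <- function(n = 859) {
  data.frame(gene = sprintf("GENE%04d", seq_len(n)),
             direction = "none", magnitude = 0, onset_h = 20, ramp_h = 6,
             shape = "sustained", transient_duration_h = 12,
             stringsAsFactors = FALSE)
}

#' @rdname null_library
#' @param n_inhibitors,n_activators numbers of true effect genes.
#' @param inhibitor_onset_h,activator_onset_h effect onsets (inhibitors
#'   earlier by default, as observed for mitotic regulators).
#' @param magnitude effect magnitude of the true modulators.
#' @param shape effect shape for the true modulators.
#' @export
example_library <- function(n = 859, n_inhibitors = 15, n_activators = 15,
                            inhibitor_onset_h = 16, activator_onset_h = 32,
                            magnitude = 0.6, shape = "transient") {
  lib <- null_library(n)
  stopifnot(n_inhibitors + n_activators <= n)
  ii <- seq_len(n_inhibitors)
  ia <- n_inhibitors + seq_len(n_activators)
  lib$direction[ii] <- "inhibitor"
  lib$onset_h[ii] <- inhibitor_onset_h
  lib$direction[ia] <- "activator"
  lib$onset_h[ia] <- activator_onset_h
  lib$magnitude[c(ii, ia)] <- magnitude
  lib$shape[c(ii, ia)] <- shape
  lib
}

lib_row_effect <- function(row) {
  effect_profile(row$direction, row$magnitude, row$onset_h, row$ramp_h,
                 row$shape, row$transient_duration_h)
}

#' Simulate a multi-plate impedance screen
#'
#' Distributes the library over 96-well racks (88 sample wells per rack,
#' column 12 holds duplicate negative and positive control wells), screens
#' each rack in `config$replicates` plate copies, applies the batch shift
#' from `config$shift_from_rack` onward, and returns the plate traces with
#' the matching annotation table. Per-well seeds are derived from the
#' master seed, so output is deterministic and independent of evaluation
#' order.
#'
#' @param config a [sim_config()].
#' @param library a library data.frame ([null_library()] /
#'   [example_library()]).
#' @return object of class `sim_screen`: list with `plates` (named list of
#'   [plate_timeseries()]), `plate_map` (data.frame `plate_id`, `rack`,
#'   `replicate`), `annotation` ([read_annotation()]-shaped), `library`,
#'   `config`.
#' @export
simulate_screen <- function(config = sim_config(), library = null_library()) {
  stopifnot(inherits(config, "sim_config"))
  per_rack <- 80L   # 80 sample wells + 8 control wells per 96-well rack
  n_racks <- ceiling(nrow(library) / per_rack)
  sample_wells <- setdiff(all_wells(), control_panel()$well)
  ce <- control_effects()
  cp <- control_panel()

  ann <- list()
  plates <- list()
  plate_map <- list()
  gene_idx <- 0L
  for (rack in seq_len(n_racks)) {
    n_here <- min(per_rack, nrow(library) - gene_idx)
    rows <- library[gene_idx + seq_len(n_here), , drop = FALSE]
    gene_idx <- gene_idx + n_here
    wells <- c(sample_wells[seq_len(n_here)], cp$well)
    genes <- c(rows$gene, cp$gene_symbol)
    roles <- c(rep("sample", n_here), cp$role)
    ann[[rack]] <- data.frame(rack = rack, well = wells,
                              catalog_number = NA_character_,
                              gene_symbol = genes, role = roles,
                              replicate = 1L, stringsAsFactors = FALSE)
    effects <- c(lapply(seq_len(n_here), function(i) lib_row_effect(rows[i, ])),
                 lapply(cp$gene_symbol, function(g) ce[[g]]))
    rate_factor <- if (rack >= config$shift_from_rack) {
      1 + config$plate_shift
    } else 1
    for (rep_i in seq_len(config$replicates)) {
      plate_id <- sprintf("R%02d_rep%d", rack, rep_i)
      pseed <- (config$seed * 7907L + rack * 211L + rep_i * 13L) %% 2147483647L
      phase <- with_seed(pseed,
                         stats::rnorm(1, 0, config$phase_jitter_sd))
      vals <- matrix(NA_real_, length(wells), length(config$measure_times))
      for (w in seq_along(wells)) {
        # seed keyed by the well's plate position: a well's trace does not
        # depend on how much of the library surrounds it
        wseed <- (pseed + 1009L * match(wells[w], all_wells())) %% 2147483647L
        tr <- simulate_well(config, effects[[w]], seed = wseed,
                            phase = phase, rate_factor = rate_factor)
        vals[w, ] <- tr$ci
      }
      plates[[plate_id]] <- plate_timeseries(plate_id, wells,
                                             config$measure_times, vals)
      plate_map[[length(plate_map) + 1L]] <-
        data.frame(plate_id = plate_id, rack = rack, replicate = rep_i,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(plates = plates,
                 plate_map = do.call(rbind, plate_map),
                 annotation = validate_annotation(do.call(rbind, ann)),
                 library = library, config = config),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("sim_screen: ", nrow(x$library), " genes on ",
      length(unique(x$plate_map$rack)), " racks x ",
      x$config$replicates, " replicates = ", length(x$plates),
      " plates (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Parameter-recovery diagnostics for a simulated screen
#'
#' Runs the analysis pipeline on the simulated screen and checks that the
#' generator's parameters are recoverable: the oscillation period from the
#' population-mean CIGR, the linearity of the noiseless maximum CIGR in the
#' seeded cell number, and (when the library contains effect genes) the
#' inhibitor-vs-activator peak-time ordering.
#'
#' @param screen a [simulate_screen()] result.
#' @param n0_grid seeding densities for the linearity check.
#' @param alpha,window_h transient-hit parameters for the peak-time check.
#' @return list with `period_h` (estimate), `configured_period_h`,
#'   `n0_linearity` (list `n0`, `max_cigr`, `r_squared`), and `peak_times`
#'   (`NULL` for an all-null library, else list with per-direction means
#'   and the one-sided t-test p-value for inhibitors peaking earlier).
#' @export
recover_parameters <- function(screen, n0_grid = c(3000, 10000, 30000),
                               alpha = 0.05, window_h = 3) {
  stopifnot(inherits(screen, "sim_screen"))
  an <- analyze_screen(screen, alpha = alpha, window_h = window_h)

  period <- estimate_period(an$population$times, an$population$mean)

  # noiseless seeding-density runs: no transfection lag, no effect
  cfg <- screen$config
  cfg$increment_noise_sd <- 0
  cfg$n0_cv <- 0; cfg$rate_cv <- 0
  cfg$lag_h <- 0
  # maximum CIGR within the common exponential phase: the comparison
  # window ends where the densest seeding reaches 2% of the carrying
  # capacity, so every density is still in (near-)exponential growth there
  traces <- lapply(n0_grid, function(n0) {
    cfg$n0 <- n0
    simulate_well(cfg, effect_profile(), seed = 1L, phase = 0)
  })
  t_end <- min(vapply(traces, function(tr) {
    sat <- which(tr$ci / cfg$ci_per_cell >= 0.02 * cfg$carrying_capacity)
    if (length(sat)) tr$times[min(sat)] else max(tr$times)
  }, numeric(1)))
  maxc <- vapply(traces, function(tr) {
    keep <- tr$times[-1] <= t_end
    max((diff(tr$ci) / diff(tr$times))[keep])
  }, numeric(1))
  r2 <- summary(stats::lm(maxc ~ n0_grid))$r.squared

  peak <- NULL
  truth <- screen$library
  if (any(truth$direction != "none") && nrow(an$transient_hits)) {
    hits <- unique(an$transient_hits[, c("gene", "direction", "peak_time_h")])
    hits <- hits[hits$gene %in% truth$gene[truth$direction != "none"], ]
    ti <- hits$peak_time_h[hits$direction == "inhibitor"]
    ta <- hits$peak_time_h[hits$direction == "activator"]
    if (length(ti) >= 2 && length(ta) >= 2) {
      tt <- stats::t.test(ti, ta, alternative = "less")
      peak <- list(mean_inhibitor_h = mean(ti), mean_activator_h = mean(ta),
                   p_value = tt$p.value, n_inhibitor = length(ti),
                   n_activator = length(ta))
    }
  }
  list(period_h = period, configured_period_h = screen$config$osc_period_h,
       n0_linearity = list(n0 = n0_grid, max_cigr = maxc, r_squared = r2),
       peak_times = peak)
}
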