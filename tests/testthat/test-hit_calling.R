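test_that("z cut-offs match the normal quantiles for the usual levels", {
  expect_equal(round(z_threshold(0.05), 2), 1.96)
  expect_equal(round(z_threshold(0.10), 2), 1.64)
  expect_equal(round(z_threshold(0.01), 2), 2.58)
  expect_equal(z_threshold(0.05, "one"), qnorm(0.95))
  expect_error(z_threshold(1), "alpha")
  expect_error(z_threshold(0), "alpha")
})

test_that("constant-hit selection is inclusive, signed and ranked", {
  # construct a screen-sized z vector with exactly 45 of 859 beyond the cut
  set.seed(4)
  z <- c(runif(814, -1.9, 1.9), runif(20, -5, -2), runif(25, 2, 5))
  names(z) <- sprintf("G%03d", seq_along(z))
  z <- sample(z)
  h <- constant_hits(z, alpha = 0.05)
  expect_equal(nrow(h), 45)
  expect_equal(sum(h$direction == "inhibitor"), 20)
  expect_equal(sum(h$direction == "activator"), 25)
  expect_true(all(diff(abs(h$zscore)) <= 1e-12))
  # boundary value included
  hb <- constant_hits(c(a = qnorm(0.975)), alpha = 0.05)
  expect_equal(nrow(hb), 1)
  # all sub-threshold -> empty
  expect_equal(nrow(constant_hits(c(a = 0.5, b = -0.9))), 0)
})

test_that("run-length detection honors the minimum window", {
  tt <- seq(13, 58, 0.5)
  z <- rep(0, length(tt))
  z[20:25] <- 2.5               # six consecutive points = 3 h
  expect_false(is.null(watershed_transient_hits(z, tt, 0.05, 3)))
  z5 <- rep(0, length(tt)); z5[20:24] <- 2.5   # five points = 2.5 h
  expect_null(watershed_transient_hits(z5, tt, 0.05, 3))
  # a single spike never qualifies at a 1.5 h window
  zs <- rep(0, length(tt)); zs[40] <- 8
  expect_null(watershed_transient_hits(zs, tt, 0.05, 1.5))
  # everything below the cut -> no hit
  expect_null(watershed_transient_hits(rnorm(length(tt), 0, 0.3), tt, 0.05, 3))
  expect_error(watershed_transient_hits(z, tt, 0.05, 0.25), "grid step")
})

test_that("hits carry direction, intervals and the earliest-tie peak", {
  tt <- seq(13, 58, 0.5)
  z <- rep(0, length(tt))
  z[11:20] <- -3                # inhibitor run, constant -> tie at peak
  z[51:60] <- 2.2               # weaker activator run
  h <- watershed_transient_hits(z, tt, 0.05, 3)
  expect_equal(h$direction, "inhibitor")
  expect_equal(h$peak_z, -3)
  expect_equal(h$peak_time_h, tt[11])             # earliest tie
  expect_equal(nrow(h$intervals), 2)              # both directions retained
  expect_setequal(h$intervals$direction, c("inhibitor", "activator"))
})

test_that("the detector agrees with a brute-force interval oracle", {
  set.seed(77)
  tt <- seq(13, 58, 0.5)
  n_mismatch <- 0
  for (k in 1:1000) {
    z <- random_z_curve(length(tt))
    for (w in c(1.5, 3, 6)) {
      got <- watershed_transient_hits(z, tt, 0.05, w)
      want <- oracle_transient(z, tt, 0.05, w)
      if (is.null(want)) {
        if (!is.null(got)) n_mismatch <- n_mismatch + 1
      } else {
        if (is.null(got) ||
            got$direction != want$direction ||
            abs(got$peak_time_h - want$peak_time_h) > 1e-9 ||
            abs(got$peak_z - want$peak_z) > 1e-9) {
          n_mismatch <- n_mismatch + 1
        }
      }
    }
  }
  expect_equal(n_mismatch, 0)
  # and across the full default (alpha x window) grid on a smaller batch
  for (k in 1:100) {
    z <- random_z_curve(length(tt))
    for (a in c(0.01, 0.05, 0.10)) for (w in c(1.5, 2.5, 4, 6)) {
      got <- watershed_transient_hits(z, tt, a, w)
      want <- oracle_transient(z, tt, a, w)
      expect_identical(is.null(got), is.null(want))
    }
  }
})

test_that("peak times bin into early/intermediate/late kinetic classes", {
  expect_equal(classify_peak_time(c(25, 32, 50)),
               c("early", "intermediate", "late"))
  expect_equal(classify_peak_time(c(30, 45)), c("intermediate", "late"))
  expect_equal(classify_peak_time(29.999), "early")
})

test_that("the parameter sweep spans 24 cells and is monotone", {
  tt <- seq(13, 58, 0.5)
  set.seed(15)
  m <- t(replicate(60, random_z_curve(length(tt), p_excursion = 0.7)))
  sw <- sweep_hits(m, tt)
  expect_s3_class(sw, "sweep_result")
  expect_equal(length(sw$total), 24)
  expect_equal(dim(sw$total), c(3, 8))
  expect_equal(sw$total, sw$inhibitor + sw$activator)
  expect_equal(nrow(sweep_monotonicity_violations(sw)), 0)
  # monotone for random instances too
  for (k in 1:5) {
    m2 <- t(replicate(25, random_z_curve(length(tt), p_excursion = 0.8)))
    expect_equal(nrow(sweep_monotonicity_violations(sweep_hits(m2, tt))), 0)
  }
  # empty matrix -> all-zero grid
  sw0 <- sweep_hits(matrix(numeric(0), 0, length(tt)), tt)
  expect_true(all(sw0$total == 0))
})

test_that("a whole-domain constant hit is a transient hit at any window", {
  tt <- seq(13, 58, 0.5)
  z <- rep(2.5, length(tt))
  for (w in c(1.5, 3, 6, 40)) {
    expect_false(is.null(watershed_transient_hits(z, tt, 0.05, w)))
  }
})

test_that("heatmap ordering is inhibitors-first, by peak time, stable", {
  hits <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    direction = c("activator", "inhibitor", "activator", "inhibitor",
                  "inhibitor"),
    peak_time_h = c(20, 35, 20, 15, 35))
  o <- heatmap_order(hits)
  expect_setequal(o, 1:5)                      # a permutation
  expect_equal(hits$gene[o], c("d", "b", "e", "a", "c"))
})
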