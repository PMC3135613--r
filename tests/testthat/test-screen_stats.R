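test_that("the Z-factor reproduces hand-computed values and its bounds", {
  expect_equal(zfactor(1, 0.2, 0, 0.1), 0.1)
  expect_equal(zfactor(1, 0, 0, 0), 1.0)    # perfect assay limit
  expect_error(zfactor(1, 0.1, 1, 0.1), "separation")
  expect_error(zfactor(1, -0.1, 0, 0.1), ">= 0")
  # symmetric in which group is called positive
  expect_equal(zfactor(1, 0.2, 0, 0.1), zfactor(0, 0.1, 1, 0.2))
  # strictly decreasing in either spread
  expect_lt(zfactor(1, 0.25, 0, 0.1), zfactor(1, 0.2, 0, 0.1))
  expect_lt(zfactor(1, 0.2, 0, 0.15), zfactor(1, 0.2, 0, 0.1))
})

test_that("time-dependent Z-factor reduces to the scalar on constant curves", {
  pos <- rbind(rep(1, 10), rep(1.2, 10), rep(0.8, 10))
  neg <- rbind(rep(3, 10), rep(3.3, 10), rep(2.7, 10))
  zc <- time_dependent_zfactor(pos, neg, times = 1:10)
  expect_s3_class(zc, "zfactor_curve")
  expect_equal(zc$values,
               rep(zfactor(1, sd(c(1, 1.2, 0.8)), 3, sd(c(3, 3.3, 2.7))), 10))
  expect_true(all(zc$values <= 1, na.rm = TRUE))
  # degenerate time point (equal means) -> NA, not an error
  pos2 <- rbind(c(1, 3), c(1, 3)); neg2 <- rbind(c(1, 0), c(1, 0))
  expect_true(is.na(time_dependent_zfactor(pos2, neg2)$values[1]))
  expect_false(is.na(time_dependent_zfactor(pos2, neg2)$values[2]))
  expect_error(time_dependent_zfactor(pos[1, , drop = FALSE], neg),
               "2 replicates")
})

test_that("plate z-scores center and scale by the reference population", {
  z <- plate_zscore(c(1, 2, 3, 4, 5))
  expect_equal(unname(z[3]), 0)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(unname(plate_zscore(c(0, 2))),
               c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_error(plate_zscore(c(1, 1, 1)), "zero reference variance")
  # affine equivariance: shifting/scaling all inputs leaves z unchanged
  x <- rnorm(20)
  expect_equal(plate_zscore(3 * x + 7), plate_zscore(x), tolerance = 1e-12)
  # controls scored against a sample-only reference
  z2 <- plate_zscore(c(10, 1, 2, 3), reference = 2:4)
  expect_equal(unname(z2[1]), (10 - 2) / 1)
})

test_that("time-series z-scores normalize each time point by the samples", {
  set.seed(5)
  v <- matrix(rnorm(50, 10, 2), 10, 5)
  cg <- structure(list(plate_id = "p", wells = sprintf("A%02d", 1:10),
                       times = seq(13, 15, 0.5), values = v),
                  class = c("cigr_matrix", "plate_timeseries"))
  zs <- timeseries_zscore(cg, reference = 1:8)
  ref <- zs$values[1:8, ]
  expect_equal(colMeans(ref), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(ref, 2, sd), rep(1, 5), tolerance = 1e-9)
  # a well equal to the per-time reference mean scores zero everywhere
  v2 <- rbind(v, colMeans(v[1:8, ]))
  cg2 <- cg; cg2$values <- v2; cg2$wells <- c(cg$wells, "B01")
  expect_equal(timeseries_zscore(cg2, reference = 1:8)$values[11, ],
               rep(0, 5), tolerance = 1e-9)
  # shifting one well by +2 reference sd at one time point moves its z by 2
  v3 <- v
  v3[9, 3] <- v[9, 3] + 2 * sd(v[1:8, 3])
  cg3 <- cg; cg3$values <- v3
  expect_equal(timeseries_zscore(cg3, reference = 1:8)$values[9, 3] -
                 zs$values[9, 3], 2, tolerance = 1e-9)
  # zero reference variance at a time point -> NA there
  v4 <- v; v4[1:8, 2] <- 1
  cg4 <- cg; cg4$values <- v4
  expect_true(all(is.na(timeseries_zscore(cg4, reference = 1:8)$values[, 2])))
})

test_that("replicate summaries behave as signed RMS and Stouffer", {
  expect_equal(rms_summarize(c(3, 4)), sqrt(12.5), tolerance = 1e-9)
  expect_equal(rms_summarize(c(3, 4)), 3.5355, tolerance = 1e-4)
  expect_equal(rms_summarize(c(-3, -4)), -3.5355, tolerance = 1e-4)
  expect_equal(rms_summarize(5), 5)
  expect_equal(rms_summarize(c(-3, 4), signed = FALSE), sqrt(12.5))
  expect_error(rms_summarize(numeric(0)), "no replicate")
  # Jensen: RMS magnitude is at least the absolute mean
  set.seed(8)
  for (i in 1:25) {
    z <- rnorm(sample(1:5, 1))
    expect_gte(abs(rms_summarize(z)) + 1e-12, abs(mean(z)))
  }
  expect_equal(stouffer_summarize(c(3, 4)), 7 / sqrt(2))
  expect_equal(stouffer_summarize(-2), -2)
})

test_that("population summary recovers an exact quadratic trend", {
  tt <- seq(13, 58, 0.5)
  m <- 1 + 2 * tt - 0.1 * tt^2
  x <- rbind(m, m, m)   # constant over wells: sd 0, means exact
  ps <- population_summary(x, tt)
  expect_equal(unname(ps$trend), c(1, 2, -0.1), tolerance = 1e-9)
  expect_equal(ps$sd, rep(0, length(tt)))
  cst <- matrix(4, 5, 10)
  ps2 <- population_summary(cst, 1:10)
  expect_equal(unname(ps2$trend[2:3]), c(0, 0), tolerance = 1e-9)
})

test_that("the period estimator resolves a damped oscillation to the hour", {
  tt <- seq(13, 57.5, 0.5)
  for (p_true in c(14, 17, 20)) {
    x <- 0.1 + 0.004 * tt +
      0.05 * exp(-tt / 30) * cos(2 * pi * tt / p_true + 0.6)
    expect_lt(abs(estimate_period(tt, x) - p_true), 1)
  }
})

test_that("end-point comparison matches paired t statistics and BH step-up", {
  # identical treated/control -> t = 0, p = 1
  m <- matrix(c(100, 110, 120), 1)
  r <- endpoint_compare(m, m)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # hand BH on p = (0.01, 0.02, 0.04) -> q = (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  # independent oracle: stats::t.test on the log-ratios
  set.seed(13)
  tr <- matrix(runif(9, 80, 120), 3)
  ct <- matrix(runif(9, 90, 110), 3)
  r2 <- endpoint_compare(tr, ct)
  for (i in 1:3) {
    o <- t.test(log(tr[i, ]), log(ct[i, ]), paired = TRUE)
    expect_equal(r2$t[i], unname(o$statistic), tolerance = 1e-9)
    expect_equal(r2$p[i], o$p.value, tolerance = 1e-9)
  }
  # q-values are monotone in ranked p and never below p
  expect_true(all(r2$q >= r2$p - 1e-12))
  o <- order(r2$p)
  expect_true(all(diff(r2$q[o]) >= -1e-12))
  expect_error(endpoint_compare(matrix(c(-1, 2), 1), matrix(c(1, 2), 1)),
               "positive")
  expect_error(endpoint_compare(matrix(1, 1, 1), matrix(1, 1, 1)),
               "2 paired")
})

test_that("the normality diagnostic calibrates on normal and flags skewed data", {
  set.seed(21)
  expect_gt(normality_diagnostic(rnorm(200))$p, 0.01)
  expect_lt(normality_diagnostic(rexp(200))$p, 0.01)
  d <- normality_diagnostic(rnorm(50))
  expect_equal(nrow(d$qq), 50)
  expect_error(normality_diagnostic(rep(1, 10)), "constant")
  expect_error(normality_diagnostic(c(1, 2)), "n <= 5000")
})
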