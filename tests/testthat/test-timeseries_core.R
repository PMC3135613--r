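test_that("the default analysis grid has 91 half-hour points over 13-58 h", {
  g <- uniform_grid()
  expect_length(g$times, 91)
  expect_equal(g$times[1], 13)
  expect_equal(g$times[91], 58)
  expect_error(uniform_grid(10, 10), "start_h")
  expect_error(uniform_grid(10, 20, 0), "step_h")
})

test_that("cubic traces are reproduced exactly by the interpolating spline", {
  p <- function(t) t^3 - 2 * t
  tt <- c(0, 0.7, 1.1, 2.3, 3.1, 4.2, 5.0)
  s <- plate_timeseries("p", "A01", tt, matrix(p(tt) + 20, 1))  # shift >= 0
  g <- uniform_grid(0, 5, 0.25)
  out <- interpolate_to_grid(s, g)
  expect_equal(out$values[1, ], p(g$times) + 20, tolerance = 1e-9)
})

test_that("interpolation at the knots is the identity", {
  g <- uniform_grid(13, 16, 0.5)
  s <- tiny_plate(times = g$times,
                  values = matrix(runif(2 * 7, 1, 2), 2))
  out <- interpolate_to_grid(s, g)
  expect_equal(out$values, s$values, tolerance = 1e-12)
})

test_that("interpolation refuses extrapolation and sparse wells", {
  s <- tiny_plate(wells = "A05", times = c(14, 15, 16, 17),
                  values = matrix(1:4, 1))
  expect_error(interpolate_to_grid(s, uniform_grid(13, 17, 1)), "A05")
  s2 <- tiny_plate(wells = "B02", times = c(13, 15, 17),
                   values = matrix(1:3, 1))
  expect_error(interpolate_to_grid(s2, uniform_grid(13, 17, 1)),
               "fewer than 4")
})

test_that("cell-index normalization divides by the reference reading", {
  s <- plate_timeseries("p", "A01", c(8, 9, 10), matrix(c(2, 4, 6), 1))
  n <- normalize_ci(s, 8)
  expect_equal(n$values[1, ], c(1, 2, 3))
  # the t0 column is exactly 1 for every well, any input
  s2 <- tiny_plate(times = c(8, 9, 10), values = matrix(runif(6, 1, 5), 2))
  expect_equal(normalize_ci(s2, 8)$values[, 1], c(A01 = 1, A02 = 1))
  # normalizing an already-normalized matrix at the same t0 is the identity
  n2 <- normalize_ci(normalize_ci(s2, 8), 8)
  expect_equal(n2$values, normalize_ci(s2, 8)$values)
})

test_that("normalization rejects zero/missing reference readings", {
  s <- plate_timeseries("p", c("A01", "A02"), c(8, 9),
                        matrix(c(0, 1, 2, 3), 2))
  expect_error(normalize_ci(s, 8), "A01")
  expect_error(normalize_ci(tiny_plate(times = c(9, 10)), 8),
               "not a recorded time point")
})

test_that("CIGR is the forward difference over the grid step", {
  s <- plate_timeseries("p", "A01", c(0, 0.5, 1), matrix(c(1, 1.5, 2.5), 1))
  expect_equal(cigr_transform(s)$values[1, ], c(1, 2))
  expect_equal(cigr_transform(s, raw_diff = TRUE)$values[1, ], c(0.5, 1.0))
  # constant trace -> all zeros
  cst <- plate_timeseries("p", "A01", 0:4, matrix(rep(2, 5), 1))
  expect_equal(cigr_transform(cst)$values[1, ], rep(0, 4))
  # non-uniform grid is refused
  bad <- plate_timeseries("p", "A01", c(0, 1, 3), matrix(1:3, 1))
  expect_error(cigr_transform(bad), "uniform")
})

test_that("CIGR is a left inverse of discrete integration", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:91, 1)
    dt <- sample(c(0.25, 0.5, 1), 1)
    ci <- cumsum(runif(n, 0, 0.3)) + 1
    s <- plate_timeseries("p", "A01", dt * (0:(n - 1)), matrix(ci, 1))
    cg <- cigr_transform(s)
    rec <- ci[1] + dt * cumsum(cg$values[1, ])
    expect_equal(rec, ci[-1], tolerance = 1e-9)
  }
})

test_that("differencing commutes with per-well normalization", {
  set.seed(3)
  s <- tiny_plate(times = seq(8, 12, 0.5),
                  values = matrix(runif(18, 1, 4), 2))
  a <- cigr_transform(normalize_ci(s, 8))$values
  b <- cigr_transform(s)$values / s$values[, 1]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("average CIGR telescopes to the end-point slope", {
  set.seed(9)
  n <- 41; dt <- 0.5
  ci <- cumsum(runif(n, 0, 0.2)) + 1
  s <- plate_timeseries("p", "A01", 13 + dt * (0:(n - 1)), matrix(ci, 1))
  cg <- cigr_transform(s)
  expect_equal(unname(average_cigr(cg)),
               (ci[n] - ci[1]) / (s$times[n] - s$times[1]),
               tolerance = 1e-12)
  # constant CIGR = c -> c; single-point domain -> that point
  expect_equal(unname(average_cigr(cigr_transform(
    plate_timeseries("p", "A01", 0:3, matrix(c(1, 2, 3, 4), 1))))), 1)
  expect_equal(unname(average_cigr(cg, domain = c(13, 13))),
               unname(cg$values[1, 1]))
  expect_error(average_cigr(cg, domain = c(60, 61)), "empty domain")
})

test_that("average CIGR is stable under grid refinement of a smooth trace", {
  f <- function(t) 5 + 0.3 * t + 0.02 * t^2   # smooth positive trace
  for (dt in c(1, 0.5)) {
    tt <- seq(10, 30, dt)
    s <- plate_timeseries("p", "A01", tt, matrix(f(tt), 1))
    a <- average_cigr(cigr_transform(s))
    if (dt == 1) coarse <- a else fine <- a
  }
  expect_lt(abs(fine - coarse) / abs(coarse), 1e-3)
})
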