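test_that("baseline subtraction re-references curves to their resting level", {
  tt <- seq(-5, 10, by = 0.5)
  ## constant trajectory -> identically zero
  d <- deltaCurve(tt, rep(3.7, length(tt)))
  expect_true(all(d$delta == 0))
  ## step of +5 at t = 0 -> delta = 5 for t > 0
  x <- ifelse(tt > 0, 8, 3)
  d <- deltaCurve(tt, x)
  expect_true(all(d$delta[d$time > 0] == 5))
  expect_true(all(d$delta[d$time <= 0] == 0))
  expect_error(deltaCurve(tt, x, baselineWindow = c(-20, -10)), "empty")
  expect_error(deltaCurve(tt, x, baselineWindow = c(0, 5)), "precede")
})

test_that("metrics of a triangular response follow the geometry", {
  tt <- seq(-1, 2, by = 0.001)
  x <- pmax(0, 1 - abs(tt - 1))
  m <- computeMetrics(tt, x)
  expect_equal(m$deltaAUC, 1, tolerance = 1e-5)
  expect_equal(m$deltaPeak, 1)
  expect_equal(m$tPeak, 1)
  ## 10% level crossed on the falling edge at t = 1.9
  expect_equal(m$lifetime, 0.9, tolerance = 1e-3)
  expect_false(m$censored)
  expect_true(m$responder)
})

test_that("exponential decay lifetime equals ln(10)/lambda", {
  lam <- 0.05
  tt <- seq(0, 120, by = 0.05)
  m <- computeMetrics(tt, 2 * exp(-lam * tt))
  expect_equal(m$lifetime, log(10) / lam, tolerance = 1e-3)
})

test_that("a flat response is a non-responder with undefined lifetime", {
  tt <- seq(-2, 10, by = 0.1)
  m <- computeMetrics(tt, rep(0, length(tt)))
  expect_false(m$responder)
  expect_true(is.na(m$lifetime))
  expect_equal(m$deltaPeak, 0)
})

test_that("metrics are stable under time-grid refinement", {
  f <- function(t) 3 * (1 - exp(-0.2 * t)) * exp(-0.02 * t)
  coarse <- seq(0, 200, by = 0.2)
  fine <- seq(0, 200, by = 0.1)
  m1 <- computeMetrics(coarse, f(coarse))
  m2 <- computeMetrics(fine, f(fine))
  expect_lt(abs(m1$deltaAUC - m2$deltaAUC) / m2$deltaAUC, 0.01)
  expect_lt(abs(m1$lifetime - m2$lifetime) / m2$lifetime, 0.01)
})

test_that("the leaky-integrator fitter recovers noiseless parameters", {
  tt <- seq(0, 60, by = 0.1)
  for (par in list(c(5, 0.03), c(0.36, 0.045), c(7.24, 0.025))) {
    x <- par[1] * (1 - exp(-par[2] * tt))
    f <- fitLeakyIntegrator(tt, x)
    expect_equal(leakCapacity(f), par[1], tolerance = 1e-6)
    expect_equal(leakRate(f), par[2], tolerance = 1e-6)
    expect_gt(fitR2(f), 1 - 1e-8)
  }
})

test_that("the fitter recovers parameters from noisy curves within 3 SE", {
  tt <- seq(0, 60, by = 0.1)
  set.seed(11)
  grid <- expand.grid(k = c(0.3, 2, 10), a = c(0.01, 0.05, 0.1))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; a <- grid$a[i]
    x <- k * (1 - exp(-a * tt)) + rnorm(length(tt), sd = 0.05 * k)
    f <- fitLeakyIntegrator(tt, x)
    se <- sqrt(diag(f@cov))
    expect_lt(abs(leakCapacity(f) - k), 3 * se[1] + 0.05 * k)
    expect_lt(abs(leakRate(f) - a), 3 * se[2] + 0.05 * a)
  }
})

test_that("pulse ratios flag sub-linear integration", {
  m1 <- list(deltaAUC = 4, deltaPeak = 1.5)
  expect_equal(pulseRatio(m1, m1)$aucRatio, 1)
  expect_equal(pulseRatio(m1, m1)$peakRatio, 1)
  r <- pulseRatio(list(deltaAUC = 30, deltaPeak = 6),
                  list(deltaAUC = 4, deltaPeak = 1.5))
  expect_equal(r$aucRatio, 7.5)
  expect_equal(r$peakRatio, 4)
  expect_true(r$subLinear)
  rz <- pulseRatio(m1, list(deltaAUC = 0, deltaPeak = 0))
  expect_true(is.na(rz$peakRatio))
})

test_that("ensemble averaging respects the responder policy", {
  tt <- seq(-5, 10, by = 0.5)
  mk <- function(x, events) {
    new("Trajectory", time = tt,
        values = matrix(x, ncol = 1, dimnames = list(NULL, "pSub")),
        protocol = NULL,
        meta = list(model = "ssa", phosphoEvents = events, peakCa = 10))
  }
  up <- ifelse(tt > 0, 2, 0)
  trajs <- list(mk(up, 5), mk(up, 5), mk(rep(0, length(tt)), 0))
  allAvg <- ensembleAverage(trajs, responderPolicy = "all")
  expect_equal(allAvg$responders, 2)
  expect_equal(max(allAvg$mean), 2 * 2 / 3)
  respAvg <- ensembleAverage(trajs, responderPolicy = "responders")
  expect_equal(max(respAvg$mean), 2)
  ## identical members average to themselves
  same <- ensembleAverage(list(mk(up, 1), mk(up, 1)))
  expect_equal(same$mean, deltaCurve(tt, up)$delta)
  ## no responders under responder-only policy is an error
  expect_error(ensembleAverage(list(mk(rep(0, length(tt)), 0)),
                               responderPolicy = "responders"),
               "no responders")
})
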