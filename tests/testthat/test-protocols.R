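test_that("pulse trains place onsets at the requested frequency", {
  p <- makePulseTrain(10, 0.5, A = 5000)
  expect_equal(p@onsets, seq(0, 18, by = 2))
  p1 <- makePulseTrain(1, 0.5, A = 5000)
  expect_length(p1@onsets, 1L)
  p30 <- makePulseTrain(30, 0.5, A = 5000)
  expect_equal(max(p30@onsets), 58)
  expect_error(makePulseTrain(0, 0.5, A = 1), ">= 1")
  expect_error(makePulseTrain(5, -1, A = 1), "positive")
})

test_that("pulse shape peak matches the calculus solution", {
  pk <- pulseShapePeak(1, 1, 1)
  expect_equal(pk$tPeak, 1)
  expect_equal(pk$peakRate, exp(-1))
  ## scaling the amplitude scales the peak linearly
  expect_equal(pulseShapePeak(7, 1, 1)$peakRate, 7 * exp(-1))
  ## numerical maximum of the envelope agrees
  p <- makePulseTrain(1, 0.5, A = 3, tauR = 0.004, tauF = 0.02)
  tt <- seq(0, 0.3, by = 1e-5)
  expect_equal(max(influxEnvelope(p, tt)),
               pulseShapePeak(3, 0.004, 0.02)$peakRate, tolerance = 1e-5)
  expect_equal(tt[which.max(influxEnvelope(p, tt))], 0.02, tolerance = 1e-3)
})

test_that("the influx envelope integrates to the closed form", {
  p <- makePulseTrain(1, 0.5, A = 1000, tauR = 0.005, tauF = 0.015)
  q <- integrate(function(t) influxEnvelope(p, t), 0, 5,
                 rel.tol = 1e-10)$value
  expect_equal(q, pulseIntegral(p), tolerance = 1e-6)
  ## non-negative and continuous at the onset
  expect_true(all(influxEnvelope(p, seq(-0.1, 0.5, by = 1e-3)) >= 0))
})

test_that("the thinning bound dominates the envelope everywhere", {
  p <- makePulseTrain(30, 0.5, A = 12000)
  tt <- seq(-1, 62, by = 0.001)
  expect_true(all(influxEnvelope(p, tt) <= influxBound(p) + 1e-9))
  expect_identical(influxBound(clampProtocol(0.1)), 0)
})

test_that("protocols round-trip through JSON", {
  p <- makePulseTrain(10, 0.5, A = 1234.5, tauR = 0.004, tauF = 0.018,
                      ke = 800, baseline = 0.12)
  q <- protocolFromJSON(protocolToJSON(p))
  for (sl in c("baseline", "onsets", "A", "tauR", "tauF", "ke", "mode"))
    expect_equal(slot(q, sl), slot(p, sl))
})

test_that("protocol validity rejects malformed inputs", {
  expect_error(new("PulseProtocol", baseline = 0.1, onsets = c(2, 1),
                   A = 1, tauR = 0.005, tauF = 0.015, ke = 100,
                   mode = "pulse"), "increasing")
  expect_error(new("PulseProtocol", baseline = 0.1, onsets = numeric(0),
                   A = 1, tauR = -1, tauF = 0.015, ke = 100,
                   mode = "pulse"), "tauR")
})

test_that("calibration reproduces a requested sub-baseline target trivially", {
  ## target at baseline requires no pulse at all
  cal <- calibratePulse(0.1, list(CaM = 5), baseline = 0.1)
  expect_equal(cal$A, 0)
  expect_equal(cal$achievedPeak, 0.1)
})

test_that("calibration hits the target peak and is deterministic", {
  ## small CaM-only context keeps the network tiny
  ctx <- list(CaM = 5)
  cal1 <- calibratePulse(5, ctx, tolerance = 0.01)
  expect_equal(cal1$achievedPeak, 5, tolerance = 0.02)
  ctx$network <- cal1$network; ctx$equilibrium <- cal1$equilibrium
  cal2 <- calibratePulse(5, ctx, tolerance = 0.01)
  expect_identical(cal1$A, cal2$A)
  ## the calibrated pulse is part of any sweep containing its target
  sweep <- amplitudeSweep(c(5, 8), ctx, tolerance = 0.01)
  expect_identical(sweep[[1]]$A, cal1$A)
  expect_gt(sweep[[2]]$A, sweep[[1]]$A)
})
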