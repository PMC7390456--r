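test_that("initial state lays out complete holoenzymes and agent counts", {
  set.seed(1)
  st <- buildInitialState(list(CaM = 30, Ng = 20, CaMKII = 80, PP1 = 1.25))
  expect_identical(st$nHolo, 63L)
  expect_length(st$subP, 756L)
  expect_length(st$camC, 282L)
  expect_identical(st$freeNg + sum(st$camNg), 188L)
  expect_identical(st$freePP1, concToCount(1.25))
  expect_identical(st$nCa, 1L)  # 100 nM is about one free ion
  ## occupancy marginals from a supplied equilibrium
  eq <- equilibrate(camCaNgNet(), list(CaM = 30, Ng = 20), targetFreeCa = 0.1)
  set.seed(2)
  st2 <- buildInitialState(list(CaM = 30, Ng = 20), eq)
  expect_equal(sum(st2$camNg), round(282 * 19.62 / 30), tolerance = 0.02)
  expect_error(buildInitialState(list(CaM = -1)), "non-negative")
})

test_that("identical seeds reproduce stochastic trajectories exactly", {
  proto <- makePulseTrain(2, 0.5, A = 9000)
  cfg <- list(CaM = 30, Ng = 20, CaMKII = 80, PP1 = 1.25)
  e1 <- runEnsemble(cfg, proto, nRuns = 2, baseSeed = 99, tEnd = 4,
                    recordDt = 0.1, tBurn = 2)
  e2 <- runEnsemble(cfg, proto, nRuns = 2, baseSeed = 99, tEnd = 4,
                    recordDt = 0.1, tBurn = 2)
  expect_identical(e1[[1]]@values, e2[[1]]@values)
  expect_identical(e1[[2]]@values, e2[[2]]@values)
  expect_identical(e1[[1]]@meta$nEvents, e2[[1]]@meta$nEvents)
  ## different run seeds give different trajectories
  expect_false(identical(e1[[1]]@values, e1[[2]]@values))
})

test_that("conservation and state-consistency audit passes during a spike", {
  set.seed(5)
  st <- buildInitialState(list(CaM = 30, Ng = 20, CaMKII = 80, PP1 = 1.25))
  proto <- makePulseTrain(2, 0.5, A = 9646)
  tr <- ssaRun(st, proto, tEnd = 5, recordDt = 0.1, tBurn = 5, audit = TRUE)
  ## the audit (every 2^16 events) raises on any drift; additionally check
  ## the recorded observables respect molecule totals at all times
  camTotal <- 282 / st$ctx@molPerUM
  held <- trajObservable(tr, "camNg") + trajObservable(tr, "freeCaM") +
    trajObservable(tr, "camBound")
  expect_true(all(abs(held - camTotal) < 1e-9))
  expect_true(all(trajObservable(tr, "pSub") >= 0))
  expect_true(all(trajObservable(tr, "camBoundU") <=
                    trajObservable(tr, "camBound") + 1e-12))
  expect_gte(tr@meta$phosphoEvents, 0)
})

test_that("subunits never change state without calmodulin present", {
  set.seed(3)
  st <- buildInitialState(list(CaM = 0, Ng = 0, CaMKII = 80, PP1 = 1.25))
  proto <- makePulseTrain(1, 0.5, A = 9000)
  tr <- ssaRun(st, proto, tEnd = 3, recordDt = 0.1, tBurn = 1, audit = TRUE)
  expect_true(all(trajObservable(tr, "pSub") == 0))
  expect_true(all(trajObservable(tr, "camBound") == 0))
  expect_equal(tr@meta$phosphoEvents, 0)
})

test_that("stochastic spike responses carry responder metadata", {
  cal <- list(A = 11040)   # amplitude calibrated for CaM 30, no Ng
  proto <- makePulseTrain(1, 0.5, A = cal$A)
  trajs <- runEnsemble(list(CaM = 30, Ng = 0, CaMKII = 80, PP1 = 1.25),
                       proto, nRuns = 6, baseSeed = 4, tEnd = 20,
                       recordDt = 0.1, tBurn = 10)
  peaks <- vapply(trajs, function(tr) tr@meta$peakCa, numeric(1))
  expect_true(all(peaks > 3) && all(peaks < 30))
  ev <- vapply(trajs, function(tr) tr@meta$phosphoEvents, numeric(1))
  expect_true(all(ev >= 0))
})
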