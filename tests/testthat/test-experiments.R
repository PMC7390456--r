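test_that("configuration parsing fills defaults and validates fields", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines("", tmp)
  cfg <- parseConfig(tmp)
  expect_equal(cfg$CaMKII, 80)
  expect_equal(cfg$V, 0.0156)
  expect_equal(cfg$PP1, 1.25)
  expect_equal(cfg$model, "holoenzyme_ssa")
  expect_s4_class(cfg$rates, "RateTable")
  expect_error(parseConfig(list(CaM = -1)), "non-negative")
  expect_error(parseConfig(list(model = "nope")), "model")
  ## overriding a published rate is logged
  expect_message(cfg2 <- parseConfig(list(rateOverrides = list(konNg = 6))),
                 "override")
  expect_equal(rateValue(cfg2$rates, "konNg"), 6)
})

test_that("unknown experiment presets are rejected", {
  expect_error(runExperiment("frobnicate"), "unknown experiment")
})

test_that("the CaM-only control scan shows the Ng crossover for multi-Ca CaM", {
  ## with CaMKII absent the competition between Ng and Ca2+ for CaM remains
  out <- runExperiment("no-camkii-control",
                       list(camGrid = c(2, 5, 15, 40, 120, 400)))
  expect_named(out, c("withoutNg", "withNg"))
  d0 <- out$withoutNg; d1 <- out$withNg
  ## 1-Ca CaM is consistently more abundant without Ng
  expect_true(all(d0$maxRelCa1 >= d1$maxRelCa1))
  ## 4-Ca CaM: without Ng wins at the lowest CaM, with Ng wins in the
  ## mid-range (the curves cross), and the forms die out at high CaM
  diff4 <- d1$maxRelCa4 - d0$maxRelCa4
  expect_lt(diff4[1], 0)
  expect_true(any(diff4 > 0))
  expect_lt(max(d0$maxRelCa4[d0$cam >= 100]), 1e-3)
})
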