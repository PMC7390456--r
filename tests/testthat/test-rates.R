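test_that("rate table defaults match the published constants", {
  rt <- loadRateTable()
  expect_equal(rateValue(rt, "konNg"), 5)
  expect_equal(rateValue(rt, "koffNg"), 1)
  expect_equal(rateValue(rt, "kcat"), 0.41)
  expect_equal(rateValue(rt, "Km"), 11)
  expect_equal(rateValue(rt, "kon1C"), 4)
  expect_equal(rateValue(rt, "koff1N"), 2660)
  expect_equal(rateValue(rt, "konCaM0"), 0.0038)
  expect_equal(rateValue(rt, "kpCaM4"), 0.96)
  expect_equal(rateValue(rt, "kponCaM1C"), 19.7)
  expect_equal(rateValue(rt, "kpoffCaM"), 0.07)
  ## every on-rate pairs with an off-rate; the 8 phosphorylation rates and
  ## kcat are irreversible
  on <- grep("^k(p?)on", rateNames(rt), value = TRUE)
  for (nm in setdiff(on, "kponCaM0")) {
    off <- sub("^kon", "koff", sub("^kpon", "kpoff", nm))
    if (!off %in% rateNames(rt)) off <- "kpoffCaM"
    expect_true(off %in% rateNames(rt) || nm == "konPP1", info = nm)
  }
  expect_false("kpCaM0" %in% rateNames(rt))
})

test_that("rate overrides are validated and logged", {
  expect_message(rt <- loadRateTable(list(konNg = 7)), "override")
  expect_equal(rateValue(rt, "konNg"), 7)
  expect_identical(rt@overrides, "konNg")
  expect_error(loadRateTable(list(noSuchRate = 1)), "unknown rate")
  expect_error(loadRateTable(list(konNg = -1)), "positive")
  expect_error(loadRateTable(list(konNg = 0)), "positive")
})

test_that("rate table round-trips through its plain-text form exactly", {
  rt <- defaultRateTable()
  tmp <- tempfile(fileext = ".tsv")
  write.table(rt@table, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  rt2 <- loadRateTable(file = tmp)
  expect_identical(rt2@rates, rt@rates)
})

test_that("concentration/count conversion reproduces the compartment counts", {
  expect_identical(concToCount(80), 752L)
  expect_identical(round(concToCount(80) / 12), 63)
  expect_identical(concToCount(0), 0L)
  expect_identical(concToCount(20), 188L)
  expect_identical(concToCount(30), 282L)
  expect_error(concToCount(-1), "non-negative")
  ## monotone non-decreasing in concentration
  grid <- seq(0, 100, by = 0.37)
  expect_true(all(diff(concToCount(grid)) >= 0))
})

test_that("bimolecular rates convert to per-pair propensities by 1/(NA*V)", {
  ctx <- volumeContext()
  expect_equal(ctx@molPerUM, 6.022e23 * 0.0156e-15 * 1e-6)
  expect_equal(bimolecularToPropensity(50), 50 / ctx@molPerUM)
  expect_equal(bimolecularToPropensity(4), 4 / ctx@molPerUM, tolerance = 1e-12)
  ## doubling the volume halves the per-pair rate
  expect_equal(bimolecularToPropensity(50, volumeContext(2 * 0.0156)),
               bimolecularToPropensity(50) / 2)
  expect_error(bimolecularToPropensity(0), "positive")
})

test_that("PP1 unbinding rate is consistent with the Michaelis constant", {
  rt <- defaultRateTable()
  koff <- pp1OffRate(rt)
  expect_equal((koff + rateValue(rt, "kcat")) / rateValue(rt, "konPP1"),
               rateValue(rt, "Km"))
})
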