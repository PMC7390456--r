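test_that("rule set variants differ only by the monomer pairing rules", {
  withDimer <- buildRuleSet(TRUE)
  without <- buildRuleSet(FALSE)
  nm1 <- vapply(withDimer, function(r) r@name, character(1))
  nm0 <- vapply(without, function(r) r@name, character(1))
  expect_true("CaM-bound monomer pairing" %in% nm1)
  expect_false("CaM-bound monomer pairing" %in% nm0)
  expect_setequal(setdiff(nm1, nm0),
                  c("CaM-bound monomer pairing", "monomer pair dissociation",
                    "phosphorylation within a pair"))
})

test_that("Ca-binding rules close into the 9-state CaM network", {
  net <- camCaNet()
  ## 3x3 lobe states + free Ca; 12 reversible transitions
  expect_identical(nSpecies(net), 10L)
  expect_identical(nReactions(net), 24L)
  ## the on-rate of each transition is set by (lobe, current count) alone
  rx <- net@reactions
  sp <- speciesNames(net)
  for (i in which(grepl("^kon", rx$rateName))) {
    from <- sp[c(rx$r1[i], rx$r2[i])]
    cam <- grep("^CaM", from, value = TRUE)
    st <- as.integer(regmatches(cam, regexec("CaM_(\\d)C(\\d)N", cam))[[1]][2:3])
    to <- as.integer(regmatches(sp[rx$p1[i]],
                                regexec("CaM_(\\d)C(\\d)N", sp[rx$p1[i]]))[[1]][2:3])
    expected <- if (to[1] > st[1]) paste0("kon", st[1] + 1, "C")
                else paste0("kon", st[2] + 1, "N")
    expect_identical(rx$rateName[i], expected)
  }
})

test_that("adding Ng extends the network by the sequestered complex only", {
  n0 <- camCaNet(); n1 <- camCaNgNet()
  expect_identical(nSpecies(n1), nSpecies(n0) + 2L)  # Ng and CaM.Ng
  expect_identical(nReactions(n1), nReactions(n0) + 2L)
  ## only Ca-free CaM matches the Ng rule
  rx <- n1@reactions
  i <- which(rx$rateName == "konNg")
  expect_length(i, 1L)
  expect_setequal(speciesNames(n1)[c(rx$r1[i], rx$r2[i])],
                  c("Ng", "CaM_0C0N"))
})

test_that("network generation is deterministic", {
  a <- generateNetwork(buildRuleSet(FALSE), c("Ca", "CaM_0C0N", "Ng"))
  b <- generateNetwork(buildRuleSet(FALSE), c("Ca", "CaM_0C0N", "Ng"))
  expect_identical(speciesNames(a), speciesNames(b))
  expect_identical(a@reactions, b@reactions)
})

test_that("conservation groups are exact left null vectors of the stoichiometry", {
  net <- monomerNet()
  cg <- conservationGroups(net)
  for (nm in names(cg)) {
    resid <- as.vector(Matrix::t(net@stoich) %*% cg[[nm]])
    expect_identical(max(abs(resid)), 0, info = nm)
  }
})

test_that("every phosphorylation reaction's substrate CaM carries calcium", {
  net <- monomerNet()
  rx <- net@reactions
  sp <- speciesNames(net)
  ip <- which(grepl("^kpCaM", rx$rateName))
  expect_gt(length(ip), 0)
  for (i in ip) {
    ## the rate is indexed by the substrate member's CaM state; the reactant
    ## dimer must contain an unphosphorylated member whose CaM has >= 1 Ca
    members <- regmatches(sp[rx$r1[i]],
                          gregexec("([PU])_(\\d)C(\\d)N", sp[rx$r1[i]]))[[1]]
    uCa <- as.integer(members[3, members[2, ] == "U"]) +
      as.integer(members[4, members[2, ] == "U"])
    expect_true(any(uCa >= 1), info = sp[rx$r1[i]])
    expect_false(rx$rateName[i] == "kpCaM0")
  }
})

test_that("mass-action derivatives follow the rate law and conservation", {
  net <- camCaNgNet()
  rhs <- massActionRHS(net)
  sp <- speciesNames(net)
  y <- setNames(numeric(length(sp)), sp)
  ## toy state: 1 uM CaM(0C0N), 1 uM Ng -> d[CaM.Ng]/dt = konNg * 1 * 1
  y["CaM_0C0N"] <- 1; y["Ng"] <- 1
  dy <- rhs(0, y)
  expect_equal(dy[match("CaM.Ng", sp)], 5)
  ## total CaM is flat with influx off
  info <- net@speciesInfo
  expect_equal(sum(dy * info$nCaM), 0)
  ## single reversible reaction at its equilibrium point: Kd = 0.2 uM
  y2 <- setNames(numeric(length(sp)), sp)
  y2["CaM_0C0N"] <- 0.2; y2["Ng"] <- 1; y2["CaM.Ng"] <- 1
  expect_equal(max(abs(rhs(0, y2))), 0)
})

test_that("clamped equilibrium matches the sequential-binding closed form", {
  net <- camCaNet()
  ca <- 1
  eq <- equilibrate(net, list(CaM = 10), targetFreeCa = ca, tol = 1e-10)
  w <- camStateWeights(ca)
  expected <- 10 * as.vector(w) / sum(w)
  labs <- as.vector(outer(0:2, 0:2,
                          function(c, n) sprintf("CaM_%dC%dN", c, n)))
  got <- eq@concentrations[labs]
  expect_equal(unname(got), expected, tolerance = 1e-8)
})

test_that("equilibrate without Ng leaves no sequestered complex", {
  net <- camCaNgNet()
  eq <- equilibrate(net, list(CaM = 10, Ng = 0), targetFreeCa = 0.1)
  expect_equal(unname(eq@concentrations["CaM.Ng"]), 0)
})

test_that("a zero-amplitude protocol leaves the steady state unchanged", {
  net <- camCaNgNet()
  eq <- equilibrate(net, list(CaM = 10, Ng = 5), targetFreeCa = 0.1,
                    tol = 1e-10)
  proto <- makePulseTrain(1, 0.5, A = 1e-12)
  tr <- simulateODE(net, eq, proto, seq(0, 10, by = 0.5))
  for (j in seq_len(ncol(tr@values))) {
    ref <- tr@values[1, j]
    if (ref > 1e-8)
      expect_lt(max(abs(tr@values[, j] - ref)) / ref, 1e-6)
  }
})
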