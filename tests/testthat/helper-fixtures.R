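## Shared fixtures: networks are deterministic to build, so construct them
## once per test session.

.rt <- defaultRateTable()

camCaNet <- function() {
  if (is.null(.fixtures$camCa))
    .fixtures$camCa <- generateNetwork(buildRuleSet(FALSE),
                                       c("Ca", "CaM_0C0N"), .rt)
  .fixtures$camCa
}

camCaNgNet <- function() {
  if (is.null(.fixtures$camCaNg))
    .fixtures$camCaNg <- generateNetwork(buildRuleSet(FALSE),
                                         c("Ca", "CaM_0C0N", "Ng"), .rt)
  .fixtures$camCaNg
}

monomerNet <- function() {
  if (is.null(.fixtures$monomer))
    .fixtures$monomer <- generateNetwork(
      buildRuleSet(TRUE), c("Ca", "CaM_0C0N", "Ng", "K", "PP1"), .rt)
  .fixtures$monomer
}

.fixtures <- new.env()

## closed-form sequential-binding weights of the 9 free-CaM states at a
## given free Ca (products of stepwise association constants); independent
## oracle for the Ca/CaM equilibrium
camStateWeights <- function(ca, rt = .rt) {
  kC <- rateValue(rt, c("kon1C", "kon2C")) / rateValue(rt, c("koff1C", "koff2C"))
  kN <- rateValue(rt, c("kon1N", "kon2N")) / rateValue(rt, c("koff1N", "koff2N"))
  w <- matrix(0, 3, 3, dimnames = list(paste0(0:2, "C"), paste0(0:2, "N")))
  for (c in 0:2)
    for (n in 0:2)
      w[c + 1, n + 1] <- prod(c(1, kC * ca)[seq_len(c + 1)]) *
        prod(c(1, kN * ca)[seq_len(n + 1)])
  w / w[1, 1]
}

## independent oracle for the CaM/Ng/Ca equilibrium: with free Ca clamped,
## free-CaM states are proportional to camStateWeights; solve the scalar
## binding balance for the Ng-bound pool
camNgEquilibriumOracle <- function(camTot, ngTot, ca, rt = .rt) {
  Z <- sum(camStateWeights(ca, rt))
  Kd <- rateValue(rt, "koffNg") / rateValue(rt, "konNg")
  ## b = [CaM.Ng]; free CaM(0,0) = (camTot - b)/Z; (camTot-b)/Z*(ngTot-b) = Kd*b
  roots <- Re(polyroot(c(camTot * ngTot, -(camTot + ngTot + Kd * Z), 1)))
  min(roots[roots > 0 & roots < min(camTot, ngTot)])
}
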