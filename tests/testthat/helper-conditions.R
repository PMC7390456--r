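## Cached per-condition equilibria and calibrated single-pulse amplitudes on
## the shared monomer network (deterministic, so safe to reuse).

conditionCal <- function(cam, ng) {
  key <- sprintf("cal_%g_%g", cam, ng)
  if (is.null(.fixtures[[key]])) {
    net <- monomerNet()
    eq <- equilibrate(net, list(CaM = cam, Ng = ng, CaMKII = 80, PP1 = 1.25),
                      targetFreeCa = 0.1, tol = 1e-7)
    .fixtures[[key]] <- calibratePulse(10, list(CaM = cam, Ng = ng,
                                                CaMKII = 80, PP1 = 1.25,
                                                network = net,
                                                equilibrium = eq))
  }
  .fixtures[[key]]
}

## a train ensemble for a condition, averaged over all runs
trainEnsemble <- function(cam, ng, nPulses, nRuns, baseSeed, tEnd) {
  cal <- conditionCal(cam, ng)
  proto <- makePulseTrain(nPulses, 0.5, A = cal$A)
  runEnsemble(list(CaM = cam, Ng = ng, CaMKII = 80, PP1 = 1.25), proto,
              nRuns = nRuns, baseSeed = baseSeed, tEnd = tEnd,
              recordDt = 0.1, tBurn = 10)
}

## cached single-spike ensemble averages (all-runs policy)
singleSpikeAvg <- function(cam, ng) {
  key <- sprintf("spike_%g_%g", cam, ng)
  if (is.null(.fixtures[[key]])) {
    trajs <- trainEnsemble(cam, ng, nPulses = 1, nRuns = 30, baseSeed = 10,
                           tEnd = 40)
    .fixtures[[key]] <- ensembleAverage(trajs, responderPolicy = "all")
  }
  .fixtures[[key]]
}
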