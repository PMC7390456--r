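## Network-free stochastic simulation of dodecameric holoenzymes.

#' Build the initial agent state for a stochastic run
#'
#' Converts the configured concentrations to discrete molecule counts in the
#' compartment volume and lays out the agents: holoenzymes as two stacked
#' rings of six subunits each (all unphosphorylated and CaM-free unless
#' \code{allPhospho}), CaM molecules with lobe occupancies and Ng bonds
#' sampled from the deterministic baseline equilibrium marginals when one is
#' supplied, free Ng, free PP1 and an integer free-calcium pool. The state
#' is finished by an in-simulation burn-in at baseline (see
#' \code{\link{ssaRun}}). Sampling uses R's RNG, so seed with
#' \code{set.seed()} for reproducibility.
#'
#' An 80 uM CaMKII total corresponds to 752 monomers in the 0.0156 um^3
#' compartment; as 752 is not divisible by 12 the model instantiates the
#' rounded 63 complete holoenzymes (756 subunits).
#'
#' @param config list: totals in uM (\code{CaM}, \code{Ng}, \code{CaMKII}
#'   default 80, \code{PP1} default 1.25), \code{V} (um^3, default 0.0156),
#'   \code{baselineCa} (uM, default 0.1), optional \code{rates}
#'   (\linkS4class{RateTable}).
#' @param equilibrium optional \linkS4class{SteadyState} of a network
#'   containing the baseline CaM/Ng/Ca equilibrium, used for the occupancy
#'   marginals.
#' @param allPhospho start with every subunit phosphorylated (used by the
#'   bistability check).
#' @return list of agent vectors and counts consumed by \code{\link{ssaRun}}.
#' @export
buildInitialState <- function(config, equilibrium = NULL,
                              allPhospho = FALSE) {
  cfg <- modifyList(list(CaM = 30, Ng = 0, CaMKII = 80, PP1 = 1.25,
                         V = 0.0156, baselineCa = 0.1), config)
  if (any(unlist(cfg[c("CaM", "Ng", "CaMKII", "PP1")]) < 0))
    stop("concentrations must be non-negative")
  ctx <- volumeContext(cfg$V)
  nCaM <- concToCount(cfg$CaM, ctx)
  nNgTot <- concToCount(cfg$Ng, ctx)
  nHolo <- as.integer(round(concToCount(cfg$CaMKII, ctx) / 12))
  nSub <- 12L * nHolo
  nPP1 <- concToCount(cfg$PP1, ctx)
  nCa <- concToCount(cfg$baselineCa, ctx)

  camC <- integer(nCaM); camN <- integer(nCaM); camNg <- integer(nCaM)
  if (nCaM > 0 && !is.null(equilibrium)) {
    conc <- equilibrium@concentrations
    pNg <- (conc["CaM.Ng"] %|na|% 0) / max(cfg$CaM, 1e-12)
    nBoundNg <- min(nNgTot, round(nCaM * pNg))
    if (nBoundNg > 0) camNg[seq_len(nBoundNg)] <- 1L
    freeIdx <- which(camNg == 0L)
    states <- expand.grid(c = 0:2, n = 0:2)
    w <- vapply(seq_len(nrow(states)), function(i) {
      lab <- sprintf("CaM_%dC%dN", states$c[i], states$n[i])
      conc[lab] %|na|% 0
    }, numeric(1))
    if (sum(w) > 0 && length(freeIdx)) {
      draw <- as.vector(rmultinom(1, length(freeIdx), w))
      k <- 0L
      for (i in seq_len(nrow(states))) {
        if (draw[i] > 0) {
          sel <- freeIdx[k + seq_len(draw[i])]
          camC[sel] <- states$c[i]; camN[sel] <- states$n[i]
          k <- k + draw[i]
        }
      }
    }
  }
  list(camC = camC, camN = camN, camNg = camNg,
       camSub = rep(-1L, nCaM),
       subP = rep(if (allPhospho) 1L else 0L, nSub),
       subCam = rep(-1L, nSub), subPP1 = rep(0L, nSub),
       freeNg = nNgTot - sum(camNg), freePP1 = nPP1, nCa = nCa,
       ctx = ctx, config = cfg, nHolo = nHolo)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else unname(a)

#' Run the stochastic holoenzyme simulator
#'
#' Exact stochastic simulation of the agent state under a calcium protocol.
#' Constant-rate channels are simulated exactly; the time-inhomogeneous
#' pulse-influx channel is thinned against the analytic envelope bound. The
#' run starts \code{tBurn} seconds before the protocol (burn-in at baseline)
#' and records observables every \code{recordDt} from \code{recordStart}
#' (negative = include pre-pulse baseline) to \code{tEnd}. Identical
#' (state, protocol, seed) give identical trajectories.
#'
#' @param state agent state from \code{\link{buildInitialState}}.
#' @param protocol a \linkS4class{PulseProtocol}; in clamp mode the free
#'   calcium count is held fixed at the clamp level.
#' @param tEnd end of the recording window (s, protocol starts at 0).
#' @param recordDt recording interval (s).
#' @param seed optional integer seed (set before burn-in).
#' @param tBurn burn-in duration before t = 0 (s).
#' @param recordStart first recorded time (s), not before -tBurn.
#' @param audit run the internal conservation/consistency audit while
#'   simulating (used by the tests; any violation is a fatal error).
#' @return A \linkS4class{Trajectory} with columns pSub, camBound,
#'   camBoundU, freeCa, camNg, freeCaM, pp1Bound (all uM); metadata holds
#'   the per-run peak free calcium (uM), phosphorylation event count during
#'   the protocol window and per-family event tallies.
#' @export
ssaRun <- function(state, protocol, tEnd, recordDt = 0.05, seed = NULL,
                   tBurn = 20, recordStart = -5, audit = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  rates <- state$config$rates %||% defaultRateTable()
  clamp <- protocol@mode == "clamp"
  nCa <- if (clamp) concToCount(protocol@baseline, state$ctx) else state$nCa
  res <- .ssaRunCpp(state$camC, state$camN, state$camNg, state$camSub,
                    state$subP, state$subCam, state$subPP1,
                    state$freeNg, state$freePP1, nCa,
                    rates@rates, state$ctx@molPerUM,
                    protocol@ke, protocol@baseline,
                    protocol@onsets, protocol@A, protocol@tauR,
                    protocol@tauF, influxBound(protocol),
                    -abs(tBurn), tEnd, max(recordStart, -abs(tBurn)),
                    recordDt, clamp, audit)
  new("Trajectory", time = res$time, values = res$obs, protocol = protocol,
      meta = list(model = "ssa", seed = seed, peakCa = res$peakCa,
                  phosphoEvents = res$phosphoEvents, nEvents = res$nEvents,
                  eventCounts = res$eventCounts, final = res$final,
                  config = state$config))
}

#' Run an ensemble of independent stochastic simulations
#'
#' Derives per-run seeds deterministically from \code{baseSeed}, prepares the
#' baseline CaM/Ng occupancy marginals once from the deterministic
#' equilibrium of the condition, and runs \code{nRuns} independent
#' trajectories. Per-run metadata (seed, peak free calcium, phosphorylation
#' event count) is retained for the responder statistics.
#'
#' @param config condition as in \code{\link{buildInitialState}}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param nRuns number of runs (>= 1).
#' @param baseSeed integer base seed.
#' @param tEnd,recordDt,tBurn,recordStart,audit passed to \code{\link{ssaRun}}.
#' @param equilibrium optional precomputed baseline \linkS4class{SteadyState}.
#' @param allPhospho start fully phosphorylated (bistability check).
#' @return list of \linkS4class{Trajectory}.
#' @export
runEnsemble <- function(config, protocol, nRuns, baseSeed, tEnd,
                        recordDt = 0.05, tBurn = 20, recordStart = -5,
                        audit = FALSE, equilibrium = NULL,
                        allPhospho = FALSE) {
  stopifnot(nRuns >= 1)
  set.seed(baseSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, nRuns)
  if (is.null(equilibrium) && (config$CaM %||% 0) > 0) {
    seedsLab <- c("Ca", "CaM_0C0N")
    if ((config$Ng %||% 0) > 0) seedsLab <- c(seedsLab, "Ng")
    net <- generateNetwork(buildRuleSet(FALSE), seedsLab,
                           config$rates %||% defaultRateTable())
    equilibrium <- equilibrate(net, list(CaM = config$CaM,
                                         Ng = config$Ng %||% 0),
                               targetFreeCa = config$baselineCa %||% 0.1)
  }
  lapply(seq_len(nRuns), function(i) {
    set.seed(seeds[i])
    st <- buildInitialState(config, equilibrium, allPhospho = allPhospho)
    tr <- ssaRun(st, protocol, tEnd, recordDt = recordDt, seed = NULL,
                 tBurn = tBurn, recordStart = recordStart, audit = audit)
    tr@meta$seed <- seeds[i]
    tr
  })
}
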