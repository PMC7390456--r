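## Named experiments and configuration handling.

.configDefaults <- function() list(
  model = "holoenzyme_ssa", CaM = 30, Ng = 0, CaMKII = 80, PP1 = 1.25,
  V = 0.0156, baselineCa = 0.1, nRuns = 30, baseSeed = 1L, recordDt = 0.05,
  tBurn = 20, rateOverrides = list())

#' Parse a simulation configuration file
#'
#' Reads a YAML configuration, fills defaults (80 uM CaMKII, 0.0156 um^3
#' volume, 100 nM baseline calcium, PP1 at the documented repository
#' default of 1.25 uM) and validates the fields. Rate overrides are applied
#' to the rate table and logged as deviations from the defaults.
#'
#' @param file path to a YAML file; an empty or missing body gives the full
#'   default configuration.
#' @return validated configuration list with a \code{rates}
#'   \linkS4class{RateTable} attached.
#' @export
parseConfig <- function(file) {
  raw <- if (is.character(file)) yaml::read_yaml(file) else file
  if (is.null(raw)) raw <- list()
  cfg <- modifyList(.configDefaults(), raw)
  if (!cfg$model %in% c("monomer_ode", "holoenzyme_ssa"))
    stop("config field 'model' must be monomer_ode or holoenzyme_ssa")
  for (f in c("CaM", "Ng", "CaMKII", "PP1")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("config field '", f, "' must be a non-negative concentration")
  }
  if (cfg$V <= 0) stop("config field 'V' must be positive")
  if (cfg$nRuns < 1) stop("config field 'nRuns' must be >= 1")
  cfg$rates <- loadRateTable(cfg$rateOverrides)
  cfg
}

#' Run a named experiment
#'
#' Presets reproducing the study's computational experiments end to end:
#' \describe{
#'   \item{dose-response}{monomer model, free Ca clamped at 10 uM, CaM grid
#'     with and without 20 uM Ng: Ca/CaM species maxima, phospho-monomer
#'     per CaM species and steady-state total phosphorylation.}
#'   \item{spike-sweep}{monomer model: peak phosphorylation increase versus
#'     calibrated single-spike amplitude, with and without Ng.}
#'   \item{single-spike}{holoenzyme ensembles, one ~10 uM spike; responder
#'     statistics and responder-averaged metrics.}
#'   \item{train-10 / train-30}{holoenzyme ensembles driven by 0.5 Hz pulse
#'     trains; train-30 also fits the leaky-integrator form.}
#'   \item{cam-binding-train}{CaM-bound (and unphosphorylated CaM-bound)
#'     subunit trajectories during a 30-pulse train at 50 uM CaM.}
#'   \item{bistability-check}{all subunits initially phosphorylated at
#'     100 nM free Ca; verifies relaxation to baseline (deterministic and
#'     stochastic variants).}
#'   \item{no-camkii-control}{dose-response scan with CaMKII removed.}
#' }
#'
#' @param name preset name.
#' @param config configuration list (see \code{\link{parseConfig}}); the
#'   presets consult \code{CaM}, \code{Ng}, \code{nRuns}, \code{baseSeed}
#'   and optional preset-specific fields (\code{camGrid}, \code{targets},
#'   \code{tEnd}).
#' @param outDir optional output directory; when given, trajectories,
#'   metrics and fits are written as CSV/JSON with the protocol and
#'   configuration echoed for provenance.
#' @return named list with the experiment's results.
#' @export
runExperiment <- function(name, config = list(), outDir = NULL) {
  cfg <- parseConfig(config)
  rules1 <- buildRuleSet(TRUE)
  out <- switch(name,
    "dose-response" = {
      camGrid <- cfg$camGrid %||% exp(seq(log(0.5), log(2000), length.out = 17))
      net <- generateNetwork(rules1, c("Ca", "CaM_0C0N", "Ng", "K", "PP1"),
                             cfg$rates)
      list(withoutNg = doseResponseScan(net, camGrid, FALSE,
                                        camkii = cfg$CaMKII, pp1 = cfg$PP1),
           withNg = doseResponseScan(net, camGrid, TRUE, ng = 20,
                                     camkii = cfg$CaMKII, pp1 = cfg$PP1))
    },
    "spike-sweep" = {
      targets <- cfg$targets %||% c(2, 5, 10, 20)
      res <- lapply(c(noNg = 0, withNg = 20), function(ng) {
        ctxList <- list(CaM = cfg$CaM, Ng = ng, CaMKII = cfg$CaMKII,
                        PP1 = cfg$PP1, rates = cfg$rates)
        cals <- amplitudeSweep(targets, ctxList)
        peaks <- vapply(cals, function(cal) {
          tGrid <- seq(0, cfg$tEnd %||% 200, by = 0.5)
          tr <- simulateODE(cal$network, cal$equilibrium, cal$protocol, tGrid)
          p <- trajObservable(tr, "totalP")
          max(p) - p[1]
        }, numeric(1))
        data.frame(targetPeakCa = targets,
                   achievedPeakCa = vapply(cals, `[[`, numeric(1),
                                           "achievedPeak"),
                   deltaPeakP = peaks)
      })
      res
    },
    "single-spike" = .spikeTrainExperiment(cfg, nPulses = 1,
                                           policy = "responders"),
    "train-10" = .spikeTrainExperiment(cfg, nPulses = 10, policy = "all"),
    "train-30" = .spikeTrainExperiment(cfg, nPulses = 30, policy = "all",
                                       fit = TRUE),
    "cam-binding-train" = {
      cfg$CaM <- cfg$CaM %||% 50
      .spikeTrainExperiment(cfg, nPulses = 30, policy = "all",
                            observable = "camBound")
    },
    "bistability-check" = .bistabilityCheck(cfg),
    "no-camkii-control" = {
      camGrid <- cfg$camGrid %||% exp(seq(log(0.5), log(2000), length.out = 17))
      net <- generateNetwork(buildRuleSet(FALSE), c("Ca", "CaM_0C0N", "Ng"),
                             cfg$rates)
      list(withoutNg = doseResponseScan(net, camGrid, FALSE, camkii = 0,
                                        pp1 = 0),
           withNg = doseResponseScan(net, camGrid, TRUE, camkii = 0,
                                     pp1 = 0))
    },
    stop("unknown experiment preset: ", name))
  if (!is.null(outDir)) .writeBundle(name, cfg, out, outDir)
  out
}

## shared machinery for the spike/train presets: calibrate, run the
## ensemble, average, compute metrics (and optionally the leaky fit)
.spikeTrainExperiment <- function(cfg, nPulses, policy, fit = FALSE,
                                  observable = "pSub") {
  ctxList <- list(CaM = cfg$CaM, Ng = cfg$Ng, CaMKII = cfg$CaMKII,
                  PP1 = cfg$PP1, rates = cfg$rates)
  cal <- calibratePulse(cfg$targetPeak %||% 10, ctxList)
  proto <- makePulseTrain(nPulses, 0.5, A = cal$A,
                          tauR = cal$protocol@tauR, tauF = cal$protocol@tauF,
                          ke = cal$protocol@ke, baseline = cal$protocol@baseline)
  tEnd <- cfg$tEnd %||% (if (nPulses == 1) 90 else nPulses / 0.5 + 30)
  trajs <- runEnsemble(list(CaM = cfg$CaM, Ng = cfg$Ng, CaMKII = cfg$CaMKII,
                            PP1 = cfg$PP1, V = cfg$V,
                            baselineCa = cfg$baselineCa, rates = cfg$rates),
                       proto, cfg$nRuns, cfg$baseSeed, tEnd,
                       recordDt = cfg$recordDt, tBurn = cfg$tBurn)
  avg <- ensembleAverage(trajs, observable = observable,
                         responderPolicy = policy)
  res <- list(protocol = proto, calibration = cal[c("A", "achievedPeak")],
              ensemble = avg,
              meanMetrics = computeMetrics(avg$time, avg$mean),
              meanPeakCa = mean(avg$perRun$peakCa),
              sdPeakCa = stats::sd(avg$perRun$peakCa))
  if (fit) {
    fitWin <- avg$time >= 0 & avg$time <= nPulses / 0.5
    res$leakyFit <- fitLeakyIntegrator(avg$time[fitWin], avg$mean[fitWin])
  }
  res
}

.bistabilityCheck <- function(cfg) {
  ## deterministic variant: monomer network, everything phosphorylated
  net <- generateNetwork(buildRuleSet(TRUE),
                         c("Ca", "CaM_0C0N", "Ng", "K", "PP1"), cfg$rates)
  y0 <- .initialState(net, list(CaM = cfg$CaM, Ng = cfg$Ng,
                                CaMKII = 0, PP1 = cfg$PP1),
                      cfg$baselineCa)
  y0["pK"] <- cfg$CaMKII
  proto <- clampProtocol(cfg$baselineCa)
  tGrid <- c(0, exp(seq(log(0.1), log(cfg$tEnd %||% 3000), length.out = 80)))
  trOde <- simulateODE(net, y0, proto, tGrid)
  pOde <- trajObservable(trOde, "totalP")
  ## reference baseline equilibrium (unperturbed)
  eq <- equilibrate(net, list(CaM = cfg$CaM, Ng = cfg$Ng, CaMKII = cfg$CaMKII,
                              PP1 = cfg$PP1), cfg$baselineCa)
  baseP <- sum(net@speciesInfo$nKP * eq@concentrations)
  ## stochastic variant
  trajs <- runEnsemble(list(CaM = cfg$CaM, Ng = cfg$Ng, CaMKII = cfg$CaMKII,
                            PP1 = cfg$PP1, V = cfg$V,
                            baselineCa = cfg$baselineCa, rates = cfg$rates),
                       clampProtocol(cfg$baselineCa),
                       cfg$nRuns, cfg$baseSeed, tEnd = cfg$tEndSSA %||% 600,
                       recordDt = 0.5, tBurn = 0, recordStart = 0,
                       allPhospho = TRUE)
  pEnd <- vapply(trajs, function(tr) tail(trajObservable(tr, "pSub"), 1),
                 numeric(1))
  list(odeTime = trajTime(trOde), odeTotalP = pOde,
       odeBaselineP = baseP, odeFinalP = tail(pOde, 1),
       ssaFinalP = pEnd, decayed = tail(pOde, 1) < 0.05 * cfg$CaMKII)
}

.writeBundle <- function(name, cfg, out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgOut <- cfg; cfgOut$rates <- NULL
  jsonlite::write_json(list(experiment = name, config = cfgOut),
                       file.path(outDir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(out)) {
    x <- out[[nm]]
    if (is.data.frame(x))
      write.csv(x, file.path(outDir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(NULL)
}
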