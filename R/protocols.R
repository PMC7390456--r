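## Synthetic calcium input programs: clamps, single spikes, 0.5 Hz trains,
## and per-condition amplitude calibration.

#' Free-calcium clamp protocol
#'
#' @param level clamped free Ca2+ (uM).
#' @return A \linkS4class{PulseProtocol} in clamp mode.
#' @export
clampProtocol <- function(level = 0.1) {
  new("PulseProtocol", baseline = level, onsets = numeric(0), A = 0,
      tauR = 0.005, tauF = 0.015, ke = 1000, mode = "clamp")
}

#' Build a calcium pulse train
#'
#' Pulses start at k/frequency for k = 0 .. n-1; each injects calcium at
#' rate A*((t-t0)/tauR)*exp(-(t-t0)/tauF) for t >= t0, and overlapping
#' pulses sum. A 0.5 Hz train of 10 or 30 pulses reproduces the
#' spike-train stimuli; n = 1 gives the single-spike protocol.
#'
#' @param nPulses number of pulses (>= 1).
#' @param frequencyHz pulse rate (Hz, > 0).
#' @param A influx amplitude (uM/s scale; calibrate with
#'   \code{\link{calibratePulse}}).
#' @param tauR,tauF rise and fall time constants (s).
#' @param ke first-order calcium efflux rate (s^-1).
#' @param baseline resting free Ca2+ (uM).
#' @param start onset of the first pulse (s).
#' @return A \linkS4class{PulseProtocol}.
#' @examples
#' p <- makePulseTrain(10, 0.5, A = 5000)
#' p@onsets   # 0, 2, 4, ..., 18
#' @export
makePulseTrain <- function(nPulses, frequencyHz, A, tauR = 0.005,
                           tauF = 0.015, ke = 1000, baseline = 0.1,
                           start = 0) {
  if (nPulses < 1) stop("nPulses must be >= 1")
  if (frequencyHz <= 0) stop("frequency must be positive")
  new("PulseProtocol", baseline = baseline,
      onsets = start + (seq_len(nPulses) - 1) / frequencyHz,
      A = A, tauR = tauR, tauF = tauF, ke = ke, mode = "pulse")
}

#' Pulse influx envelope
#'
#' The pulse-only calcium influx rate at time t (uM/s): the sum over pulses
#' of A*((t-t0)/tauR)*exp(-(t-t0)/tauF). The constant baseline influx
#' ke*baseline that balances efflux at rest is added by the simulators, not
#' here.
#'
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param t time(s), seconds.
#' @return influx rate(s), uM/s.
#' @export
influxEnvelope <- function(protocol, t) {
  if (protocol@mode == "clamp" || length(protocol@onsets) == 0)
    return(rep(0, length(t)))
  out <- numeric(length(t))
  for (t0 in protocol@onsets) {
    dt <- t - t0
    on <- dt >= 0
    out[on] <- out[on] +
      protocol@A * (dt[on] / protocol@tauR) * exp(-dt[on] / protocol@tauF)
  }
  out
}

#' Analytic peak of the pulse shape
#'
#' The envelope A*(t/tauR)*exp(-t/tauF) attains its maximum at t = tauF with
#' value A*(tauF/tauR)*exp(-1).
#'
#' @param A,tauR,tauF pulse parameters (positive).
#' @return list(tPeak, peakRate).
#' @export
pulseShapePeak <- function(A, tauR, tauF) {
  if (any(c(A, tauR, tauF) <= 0)) stop("pulse parameters must be positive")
  list(tPeak = tauF, peakRate = A * (tauF / tauR) * exp(-1))
}

#' Rigorous upper bound on the influx envelope
#'
#' Used as the thinning bound of the time-inhomogeneous influx channel in
#' the stochastic simulator: the contribution of the pulse active at t is
#' bounded by the single-pulse peak, and each earlier pulse k periods old is
#' bounded by its envelope value at age k periods (the envelope is
#' decreasing past tauF).
#'
#' @param protocol a \linkS4class{PulseProtocol}.
#' @return bound in uM/s (0 for clamp protocols).
#' @export
influxBound <- function(protocol) {
  if (protocol@mode == "clamp" || length(protocol@onsets) == 0) return(0)
  b <- pulseShapePeak(protocol@A, protocol@tauR, protocol@tauF)$peakRate
  if (length(protocol@onsets) > 1) {
    gap <- min(diff(protocol@onsets))
    ages <- gap * seq_len(length(protocol@onsets) - 1)
    ages <- pmax(ages, protocol@tauF)
    b <- b + sum(protocol@A * (ages / protocol@tauR) * exp(-ages / protocol@tauF))
  }
  b
}

#' Total calcium injected by one pulse
#'
#' Closed form of the envelope integral: A * tauF^2 / tauR (in uM).
#' @param protocol a \linkS4class{PulseProtocol}.
#' @return uM of calcium per pulse.
#' @export
pulseIntegral <- function(protocol)
  protocol@A * protocol@tauF^2 / protocol@tauR

#' @rdname PulseProtocol-class
#' @param object a PulseProtocol.
#' @export
setMethod("show", "PulseProtocol", function(object) {
  if (object@mode == "clamp")
    cat(sprintf("PulseProtocol: free Ca clamped at %g uM\n", object@baseline))
  else
    cat(sprintf(
      "PulseProtocol: %d pulse(s), A = %.4g uM/s, tauR = %g ms, tauF = %g ms, ke = %g /s, baseline %g uM\n",
      length(object@onsets), object@A, 1e3 * object@tauR, 1e3 * object@tauF,
      object@ke, object@baseline))
})

#' Serialise / restore a protocol (JSON)
#'
#' Protocols embed into output files for provenance.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @return JSON string (\code{protocolToJSON}) or protocol
#'   (\code{protocolFromJSON}).
#' @export
protocolToJSON <- function(protocol) {
  jsonlite::toJSON(list(baseline = protocol@baseline, onsets = protocol@onsets,
                        A = protocol@A, tauR = protocol@tauR,
                        tauF = protocol@tauF, ke = protocol@ke,
                        mode = protocol@mode),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname protocolToJSON
#' @param json JSON string from \code{protocolToJSON}.
#' @export
protocolFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("PulseProtocol", baseline = x$baseline,
      onsets = as.numeric(unlist(x$onsets)), A = x$A, tauR = x$tauR,
      tauF = x$tauF, ke = x$ke, mode = x$mode)
}

#' Calibrate the pulse amplitude to a target free-calcium peak
#'
#' Because calmodulin, neurogranin and CaMKII buffer incoming calcium, the
#' amplitude needed to reach a given free-Ca2+ peak depends on the
#' condition; calibration therefore runs the deterministic monomer network
#' for the condition's composition and solves for A by bisection (the peak
#' is monotone in A). The protocol shape constraints are the stated study
#' conditions: ~10 uM free-calcium peak, return to near baseline within
#' ~100 ms.
#'
#' @param targetPeak target peak free Ca2+ (uM).
#' @param context named list describing the condition: totals \code{CaM},
#'   \code{Ng}, \code{CaMKII}, \code{PP1} (uM), optionally \code{network}
#'   (monomer \linkS4class{ReactionNetwork}) and \code{equilibrium} (a
#'   \linkS4class{SteadyState}) to reuse across calls.
#' @param decayWindow required return window (s): free Ca must fall back to
#'   within twice the baseline inside this window after the pulse peak.
#' @param tolerance relative tolerance on the achieved peak.
#' @param tauR,tauF,ke,baseline protocol shape parameters.
#' @param Arange bisection bracket for A (uM/s).
#' @return list: protocol (single-pulse \linkS4class{PulseProtocol}),
#'   achievedPeak (uM), returnTime (s, time after onset at which free Ca is
#'   back within 2x baseline), nearBaselineTime (s, first time past the peak
#'   at which free Ca has fallen below 10% of the peak level), A,
#'   equilibrium, network.
#' @export
calibratePulse <- function(targetPeak = 10, context, decayWindow = 0.1,
                           tolerance = 0.01, tauR = 0.005, tauF = 0.015,
                           ke = 1000, baseline = 0.1,
                           Arange = c(1, 1e6)) {
  net <- context$network %||%
    generateNetwork(buildRuleSet(TRUE), .seedLabels(context),
                    context$rates %||% defaultRateTable())
  totals <- context[intersect(names(context), c("CaM", "Ng", "CaMKII", "PP1"))]
  eq <- context$equilibrium %||%
    equilibrate(net, totals, targetFreeCa = baseline, tol = 1e-7)
  if (targetPeak <= baseline * 1.0001)
    return(list(protocol = makePulseTrain(1, 0.5, A = 0, tauR = tauR,
                                          tauF = tauF, ke = ke,
                                          baseline = baseline),
                achievedPeak = baseline, returnTime = 0, A = 0,
                equilibrium = eq, network = net))
  tGrid <- seq(0, max(0.4, 4 * decayWindow), by = 0.002)
  peakOf <- function(A) {
    proto <- makePulseTrain(1, 0.5, A = A, tauR = tauR, tauF = tauF,
                            ke = ke, baseline = baseline)
    traj <- simulateODE(net, eq, proto, tGrid, rtol = 1e-7, atol = 1e-9)
    trajObservable(traj, "freeCa")
  }
  lo <- Arange[1]; hi <- Arange[2]
  if (max(peakOf(hi)) < targetPeak)
    stop("calibration failed: upper amplitude bound too small")
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    pk <- max(peakOf(mid))
    if (pk < targetPeak) lo <- mid else hi <- mid
    if (abs(pk - targetPeak) / targetPeak < tolerance) { hi <- mid; break }
  }
  A <- hi
  ## characterise the calibrated pulse on a longer horizon: the fast
  ## (efflux-limited) relaxation ends within the decay window, while slow
  ## release of buffer-bound calcium leaves a sub-uM tail that is reported,
  ## not enforced
  tLong <- seq(0, max(2, 4 * decayWindow), by = 0.002)
  proto <- makePulseTrain(1, 0.5, A = A, tauR = tauR, tauF = tauF,
                          ke = ke, baseline = baseline)
  trLong <- simulateODE(net, eq, proto, tLong, rtol = 1e-7, atol = 1e-9)
  ca <- trajObservable(trLong, "freeCa")
  achieved <- max(ca)
  iPk <- which.max(ca)
  back <- which(ca <= 2 * baseline & seq_along(ca) > iPk)
  returnTime <- if (length(back)) tLong[back[1]] else Inf
  nearIdx <- which(ca <= 0.1 * achieved & seq_along(ca) > iPk)
  nearTime <- if (length(nearIdx)) tLong[nearIdx[1]] else Inf
  list(protocol = proto, achievedPeak = achieved, returnTime = returnTime,
       nearBaselineTime = nearTime, A = A, equilibrium = eq, network = net)
}

.seedLabels <- function(context) {
  seeds <- c("Ca", "CaM_0C0N")
  if ((context$Ng %||% 0) > 0) seeds <- c(seeds, "Ng")
  if ((context$CaMKII %||% 0) > 0) seeds <- c(seeds, "K")
  if ((context$PP1 %||% 0) > 0) seeds <- c(seeds, "PP1")
  seeds
}

#' Calibrated protocols for a sweep of target peaks
#'
#' One calibrated single-pulse protocol per requested peak free calcium,
#' sharing the condition's network and equilibrium.
#'
#' @param targets positive target peaks (uM).
#' @param context condition description as in \code{\link{calibratePulse}}.
#' @param ... passed to \code{\link{calibratePulse}}.
#' @return list of calibration results.
#' @export
amplitudeSweep <- function(targets, context, ...) {
  if (any(targets <= 0)) stop("targets must be positive")
  first <- calibratePulse(targets[1], context, ...)
  context$network <- first$network
  context$equilibrium <- first$equilibrium
  c(list(first),
    lapply(targets[-1], function(tp) calibratePulse(tp, context, ...)))
}
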