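## Response metrics, responder statistics and the leaky-integrator fit.

#' Baseline-subtracted response curve
#'
#' Subtracts the time-average of the observable over a baseline window that
#' precedes the first pulse, so conditions with different resting
#' phosphorylation levels can be compared directly.
#'
#' @param time time vector (s), 0 at the first pulse onset.
#' @param values observable values along \code{time}.
#' @param baselineWindow two times (s) delimiting the baseline average;
#'   must precede 0 and contain at least one sample.
#' @return data.frame(time, delta) restricted to t >= baselineWindow start.
#' @export
deltaCurve <- function(time, values, baselineWindow = c(-5, 0)) {
  if (baselineWindow[2] > 0) stop("baseline window must precede the first pulse")
  inWin <- time >= baselineWindow[1] & time <= baselineWindow[2]
  if (!any(inWin)) stop("empty baseline window")
  data.frame(time = time, delta = values - mean(values[inWin]))
}

#' Response metrics of a baseline-subtracted curve
#'
#' Area under the curve by the trapezoid rule over t >= 0, the peak
#' increase, the peak time, and the lifetime: the time after the peak at
#' which the curve first attains 10% of the peak (linear interpolation
#' between samples; censored at the record end when the level is never
#' reached).
#'
#' @param time time vector (s).
#' @param delta baseline-subtracted observable.
#' @return list: deltaAUC, deltaPeak, tPeak, lifetime (NA when undefined),
#'   censored, responder.
#' @export
computeMetrics <- function(time, delta) {
  post <- time >= 0
  tt <- time[post]; x <- delta[post]
  auc <- sum(diff(tt) * (head(x, -1) + tail(x, -1)) / 2)
  pk <- max(x)
  if (pk <= 0)
    return(list(deltaAUC = auc, deltaPeak = 0, tPeak = NA_real_,
                lifetime = NA_real_, censored = FALSE, responder = FALSE))
  iPk <- which.max(x)
  tPk <- tt[iPk]
  thr <- 0.1 * pk
  lifetime <- NA_real_; censored <- TRUE
  if (iPk < length(x)) {
    below <- which(x[(iPk + 1):length(x)] <= thr)
    if (length(below)) {
      j <- iPk + below[1]          # first sample at/below threshold
      t1 <- tt[j - 1]; t2 <- tt[j]; x1 <- x[j - 1]; x2 <- x[j]
      tCross <- if (x1 == x2) t2 else t1 + (x1 - thr) / (x1 - x2) * (t2 - t1)
      lifetime <- tCross - tPk
      censored <- FALSE
    }
  }
  if (censored) lifetime <- max(tt) - tPk
  list(deltaAUC = auc, deltaPeak = pk, tPeak = tPk, lifetime = lifetime,
       censored = censored, responder = TRUE)
}

#' Ensemble mean response and per-run metrics
#'
#' Averages the baseline-subtracted curves of a trajectory ensemble. For
#' single-spike analyses the convention is to average responders only (runs
#' in which at least one phosphorylation event fired during the protocol);
#' for train analyses all runs are averaged. The responder fraction is
#' reported with an exact binomial confidence interval.
#'
#' @param trajectories list of \linkS4class{Trajectory} (stochastic runs).
#' @param observable observable name (default "pSub").
#' @param responderPolicy "all" or "responders".
#' @param baselineWindow passed to \code{\link{deltaCurve}}.
#' @param responderMinEvents minimum number of phosphorylation events for a
#'   run to count as a responder (default 1).
#' @return list: time, mean (mean delta curve), perRun (data.frame of
#'   metrics), responders, nRuns, responderFraction, responderCI, policy.
#' @export
ensembleAverage <- function(trajectories, observable = "pSub",
                            responderPolicy = c("all", "responders"),
                            baselineWindow = c(-5, 0),
                            responderMinEvents = 1) {
  responderPolicy <- match.arg(responderPolicy)
  stopifnot(length(trajectories) >= 1)
  time <- trajTime(trajectories[[1]])
  curves <- lapply(trajectories, function(tr)
    deltaCurve(trajTime(tr), trajObservable(tr, observable),
               baselineWindow)$delta)
  isResp <- vapply(trajectories, function(tr)
    (tr@meta$phosphoEvents %||% NA_real_) >= responderMinEvents, logical(1))
  perRun <- do.call(rbind, lapply(seq_along(curves), function(i) {
    m <- computeMetrics(time, curves[[i]])
    data.frame(run = i, seed = trajectories[[i]]@meta$seed %||% NA,
               responder = isResp[i],
               peakCa = trajectories[[i]]@meta$peakCa %||% NA_real_,
               deltaAUC = m$deltaAUC, deltaPeak = m$deltaPeak,
               tPeak = m$tPeak, lifetime = m$lifetime,
               censored = m$censored)
  }))
  use <- if (responderPolicy == "responders") which(isResp) else
    seq_along(curves)
  if (!length(use))
    stop("no responders among ", length(curves), " runs under policy '",
         responderPolicy, "'")
  meanCurve <- Reduce(`+`, curves[use]) / length(use)
  bt <- binom.test(sum(isResp), length(isResp))
  list(time = time, mean = meanCurve, perRun = perRun,
       responders = sum(isResp), nRuns = length(curves),
       responderFraction = unname(bt$estimate),
       responderCI = as.numeric(bt$conf.int), policy = responderPolicy)
}

#' Fit the leaky-integrator form to a mean response
#'
#' Nonlinear least squares of x(t) = k*(1 - exp(-a*t)) on t >= 0,
#' initialised at k0 = the late-curve level and a0 = 1/(time to half of k0).
#' The fitted capacity k is the asymptotic phosphorylation increase and a
#' the integration/leak rate of the equivalent leaky integrator.
#'
#' @param time time (s), starting near 0 at the first pulse onset.
#' @param x mean baseline-subtracted response.
#' @return A \linkS4class{LeakyFit}.
#' @export
fitLeakyIntegrator <- function(time, x) {
  post <- time >= 0
  tt <- time[post]; xx <- x[post]
  n <- length(tt)
  k0 <- max(mean(tail(xx, max(3, round(n / 10)))), 1e-6)
  tHalf <- tt[which(xx >= k0 / 2)[1]]
  a0 <- if (is.na(tHalf) || tHalf <= 0) 1 / (max(tt) / 3) else log(2) / tHalf
  fit <- minpack.lm::nlsLM(xx ~ k * (1 - exp(-a * tt)),
                           start = list(k = k0, a = a0),
                           lower = c(0, 1e-6), upper = c(Inf, Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (cf["a"] <= 0) stop("leaky-integrator fit failed: non-positive rate")
  res <- xx - predict(fit)
  r2 <- 1 - sum(res^2) / sum((xx - mean(xx))^2)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  new("LeakyFit", k = unname(cf["k"]), a = unname(cf["a"]), r2 = r2,
      cov = unname(vc), converged = fit$convInfo$isConv %||% TRUE)
}

#' @rdname LeakyFit-class
#' @param object a LeakyFit.
#' @export
setMethod("show", "LeakyFit", function(object) {
  cat(sprintf("LeakyFit: x(t) = k(1 - exp(-a t)), k = %.4g uM, a = %.4g /s, R^2 = %.4f\n",
              object@k, object@a, object@r2))
})

#' Accessors for LeakyFit
#' @param x a \linkS4class{LeakyFit}.
#' @export
leakCapacity <- function(x) x@k
#' @rdname leakCapacity
#' @export
leakRate <- function(x) x@a
#' @rdname leakCapacity
#' @export
fitR2 <- function(x) x@r2

#' Multi-pulse to single-pulse response ratios
#'
#' Element-wise ratios of AUC and peak metrics between a 10-pulse (or
#' n-pulse) and a 1-pulse condition; a ratio below the pulse-count multiple
#' flags sub-linear integration (leakage).
#'
#' @param metricsMulti,metricsSingle metric lists from
#'   \code{\link{computeMetrics}} (or rows of ensemble means) for the same
#'   condition.
#' @param nMulti pulse count of the multi-pulse protocol (default 10).
#' @return list: aucRatio, peakRatio, subLinear (logical or NA when a
#'   denominator is 0).
#' @export
pulseRatio <- function(metricsMulti, metricsSingle, nMulti = 10) {
  div <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b
  aucRatio <- div(metricsMulti$deltaAUC, metricsSingle$deltaAUC)
  peakRatio <- div(metricsMulti$deltaPeak, metricsSingle$deltaPeak)
  list(aucRatio = aucRatio, peakRatio = peakRatio,
       subLinear = if (is.na(peakRatio)) NA else peakRatio < nMulti)
}
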