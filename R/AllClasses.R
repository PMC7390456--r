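## S4 containers for the model objects.

#' RateTable: kinetic constants of the model
#'
#' Holds every kinetic constant of the signalling model (Ca2+ binding to the
#' two calmodulin lobes, CaM binding to (phospho-)CaMKII, Ca2+ binding to
#' CaMKII-bound CaM, monomer dimerisation, the eight substrate-indexed
#' autophosphorylation rates, Ng binding, and the PP1 Michaelis-Menten
#' constants), with units and row provenance. Defaults are read from the
#' versioned plain-text table shipped in \code{inst/extdata}.
#'
#' @slot rates named numeric vector of rate constants.
#' @slot table data.frame with columns name, value, unit, group, note.
#' @slot overrides character vector of names whose defaults were overridden.
#' @exportClass RateTable
setClass("RateTable",
  slots = c(rates = "numeric", table = "data.frame", overrides = "character"))

setValidity("RateTable", function(object) {
  r <- object@rates
  if (is.null(names(r)) || any(!nzchar(names(r)))) return("rates must be named")
  if (any(!is.finite(r)) || any(r <= 0)) return("all rate constants must be finite and > 0")
  if (any(duplicated(names(r)))) return("duplicated rate names")
  if (!all(object@overrides %in% names(r))) return("overrides must name existing rates")
  TRUE
})

#' VolumeContext: reaction volume and count conversion
#'
#' The fixed, well-mixed postsynaptic-density volume together with the derived
#' molecules-per-micromolar conversion factor (Avogadro's number times the
#' volume in litres times 1e-6).
#'
#' @slot V volume in cubic micrometres (default 0.0156).
#' @slot molPerUM derived molecules per micromolar of concentration.
#' @exportClass VolumeContext
setClass("VolumeContext", slots = c(V = "numeric", molPerUM = "numeric"))

setValidity("VolumeContext", function(object) {
  if (length(object@V) != 1L || !is.finite(object@V) || object@V <= 0)
    return("V must be a single positive number")
  if (object@molPerUM <= 0) return("molPerUM must be > 0")
  TRUE
})

#' Rule: one rule family of the kinetic model
#'
#' A rule names the partial reactant states it cares about and the
#' transformation it applies; fields it does not name are wildcards, so one
#' rule instantiates into many concrete reactions when the network is
#' generated.
#'
#' @slot name human-readable rule family name.
#' @slot arity 1L (unimolecular) or 2L (bimolecular).
#' @slot rateNames the RateTable entries this family draws on.
#' @slot guard description of the context guard (e.g. substrate CaM needs
#'   at least one bound Ca2+).
#' @slot apply matcher: for arity 1 a function(species) and for arity 2 a
#'   function(speciesA, speciesB), returning a (possibly empty) list of
#'   instantiated reactions.
#' @exportClass Rule
setClass("Rule",
  slots = c(name = "character", arity = "integer", rateNames = "character",
            guard = "character", apply = "function"))

#' ReactionNetwork: enumerated species and mass-action reactions
#'
#' The closure of the rule set over a seed species set: every reachable
#' species (canonically labelled, so each chemical species appears exactly
#' once) and every instantiated mass-action reaction, plus the stoichiometric
#' matrix and the conservation groups (total CaM, CaMKII, Ng, PP1, Ca).
#'
#' @slot species character vector of canonical species labels.
#' @slot speciesInfo data.frame of per-species composition counts used for
#'   observables and conservation groups.
#' @slot reactions data.frame with reactant/product indices (r1, r2, p1, p2;
#'   NA when absent), rate name, rate value and the mass-action symmetry
#'   factor.
#' @slot stoich sparse stoichiometric matrix (species x reactions).
#' @slot rateTable the RateTable the reaction rates trace to.
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  slots = c(species = "character", speciesInfo = "data.frame",
            reactions = "data.frame", stoich = "Matrix",
            rateTable = "RateTable"))

setValidity("ReactionNetwork", function(object) {
  if (nrow(object@speciesInfo) != length(object@species))
    return("speciesInfo must have one row per species")
  if (!all(dim(object@stoich) == c(length(object@species), nrow(object@reactions))))
    return("stoichiometric matrix dimensions do not match species/reactions")
  if (any(!is.finite(object@reactions$rateValue)) || any(object@reactions$rateValue < 0))
    return("reaction rate values must be finite and non-negative")
  TRUE
})

#' SteadyState: equilibrated network state
#'
#' Species concentrations at a steady state with free Ca2+ clamped at a
#' target value, together with the residual derivative norm and the total
#' calcium (free plus bound) the clamp implies.
#'
#' @slot concentrations named numeric vector (uM).
#' @slot residual maximum relative time-derivative at the reported state.
#' @slot totalCa total calcium concentration implied by the clamp (uM).
#' @slot freeCa the clamped free Ca2+ concentration (uM).
#' @exportClass SteadyState
setClass("SteadyState",
  slots = c(concentrations = "numeric", residual = "numeric",
            totalCa = "numeric", freeCa = "numeric"))

setValidity("SteadyState", function(object) {
  if (any(object@concentrations < -1e-8)) return("negative steady-state concentration")
  TRUE
})

#' PulseProtocol: a synthetic calcium input program
#'
#' Either a free-Ca2+ clamp or a train of influx pulses. Each pulse injects
#' calcium at rate A*((t-t0)/tauR)*exp(-(t-t0)/tauF) for t >= onset t0;
#' calcium leaves by first-order efflux at rate ke, and a constant baseline
#' influx ke*baseline holds the resting free Ca2+ near the baseline.
#'
#' @slot baseline resting (or clamped) free Ca2+ in uM, default 0.1.
#' @slot onsets strictly increasing pulse onset times (s); empty in clamp mode.
#' @slot A influx amplitude (uM/s scale).
#' @slot tauR rise time constant (s).
#' @slot tauF fall time constant (s).
#' @slot ke first-order efflux rate (s^-1).
#' @slot mode "clamp" or "pulse".
#' @exportClass PulseProtocol
setClass("PulseProtocol",
  slots = c(baseline = "numeric", onsets = "numeric", A = "numeric",
            tauR = "numeric", tauF = "numeric", ke = "numeric",
            mode = "character"))

setValidity("PulseProtocol", function(object) {
  if (!object@mode %in% c("clamp", "pulse")) return("mode must be 'clamp' or 'pulse'")
  if (object@mode == "clamp" && length(object@onsets))
    return("clamp protocols carry no pulses")
  if (length(object@onsets) > 1 && any(diff(object@onsets) <= 0))
    return("pulse onsets must be strictly increasing")
  if (object@tauR <= 0 || object@tauF <= 0) return("tauR and tauF must be > 0")
  if (object@baseline < 0 || object@A < 0 || object@ke < 0)
    return("baseline, A and ke must be non-negative")
  TRUE
})

#' Trajectory: recorded time course of a simulation
#'
#' Observables on a regular time grid, from either the deterministic network
#' ODE (one column per species, uM) or a stochastic holoenzyme run (summary
#' observables, uM). Metadata carries the protocol, seed, model kind and, for
#' stochastic runs, the per-run peak free calcium and phosphorylation event
#' count used by the responder statistics.
#'
#' @slot time numeric time grid (s), 0 at the first pulse onset.
#' @slot values numeric matrix, one row per time point.
#' @slot protocol the PulseProtocol that drove the run (or NULL).
#' @slot meta list: model, seed, peakCa, phosphoEvents, condition, ...
#' @exportClass Trajectory
setClass("Trajectory",
  slots = c(time = "numeric", values = "matrix", protocol = "ANY",
            meta = "list"))

setValidity("Trajectory", function(object) {
  if (nrow(object@values) != length(object@time))
    return("values must have one row per time point")
  TRUE
})

#' LeakyFit: saturating-exponential characterisation
#'
#' Nonlinear least-squares fit of x(t) = k*(1 - exp(-a*t)) to a mean
#' baseline-subtracted phosphorylation curve: capacity k (uM), rate a (s^-1),
#' coefficient of determination and the parameter covariance.
#'
#' @slot k asymptotic phosphorylation increase (uM).
#' @slot a integration/leak rate (s^-1).
#' @slot r2 coefficient of determination on the fitted grid.
#' @slot cov 2x2 covariance matrix of (k, a).
#' @slot converged logical.
#' @exportClass LeakyFit
setClass("LeakyFit",
  slots = c(k = "numeric", a = "numeric", r2 = "numeric", cov = "matrix",
            converged = "logical"))

setValidity("LeakyFit", function(object) {
  if (object@r2 > 1 + 1e-12) return("R^2 cannot exceed 1")
  TRUE
})
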