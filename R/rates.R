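## Rate table, unit/count conversions and accessors.

#' Load the kinetic rate table
#'
#' Reads the versioned plain-text rate table shipped with the package and
#' applies optional overrides. Defaults are the published stepwise constants:
#' the two Ca2+ sites within a lobe are treated as a count (0/1/2) and the
#' printed stepwise rates are used as-is, with no additional combinatorial
#' factor.
#'
#' @param overrides named numeric vector or list of rate values replacing the
#'   defaults. Unknown names or non-positive values are configuration errors.
#' @param file path to an alternative rate table (name/value/unit/group TSV).
#' @return A \linkS4class{RateTable}.
#' @examples
#' rt <- loadRateTable()
#' rateValue(rt, "konNg")   # 5 uM^-1 s^-1
#' rateValue(rt, "kcat")    # 0.41 s^-1
#' @export
loadRateTable <- function(overrides = list(),
                          file = system.file("extdata", "rate_table_v1.tsv",
                                             package = "CaMKIIsim")) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value", "unit", "group") %in% names(tab)))
  rates <- setNames(as.numeric(tab$value), tab$name)
  overrides <- unlist(overrides)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("rate overrides must be named")
    unknown <- setdiff(names(overrides), names(rates))
    if (length(unknown))
      stop("unknown rate name(s): ", paste(unknown, collapse = ", "))
    if (any(!is.finite(overrides)) || any(overrides <= 0))
      stop("rate constants must be finite and positive")
    rates[names(overrides)] <- overrides
    message("rate override(s) applied: ",
            paste0(names(overrides), "=", overrides, collapse = ", "))
  }
  new("RateTable", rates = rates, table = tab,
      overrides = as.character(names(overrides)))
}

#' @describeIn loadRateTable the unmodified default table.
#' @export
defaultRateTable <- function() loadRateTable()

#' Look up rate constants
#'
#' @param x a \linkS4class{RateTable}.
#' @param name rate name(s).
#' @return numeric value(s).
#' @export
rateValue <- function(x, name) {
  stopifnot(is(x, "RateTable"))
  missing <- setdiff(name, names(x@rates))
  if (length(missing)) stop("no such rate: ", paste(missing, collapse = ", "))
  unname(x@rates[name])
}

#' @rdname rateValue
#' @export
rateNames <- function(x) names(x@rates)

#' PP1 unbinding rate implied by the Michaelis constant
#'
#' PP1 acts through an explicit enzyme-substrate complex; the published
#' constants are Km and kcat only, so the dissociation rate is derived as
#' koffPP1 = konPP1 * Km - kcat, which makes (koffPP1 + kcat)/konPP1 = Km.
#'
#' @param rates a \linkS4class{RateTable}.
#' @return koffPP1 in s^-1.
#' @export
pp1OffRate <- function(rates) {
  k <- rateValue(rates, c("konPP1", "Km", "kcat"))
  off <- k[1] * k[2] - k[3]
  if (off <= 0) stop("konPP1 too small for the given Km and kcat")
  off
}

#' Volume context for concentration/count conversion
#'
#' @param V compartment volume in cubic micrometres; default is the simulated
#'   postsynaptic-density volume 0.0156 um^3.
#' @return A \linkS4class{VolumeContext}; its \code{molPerUM} slot is
#'   Avogadro's number x V(litres) x 1e-6, about 9.39 molecules per uM at the
#'   default volume.
#' @export
volumeContext <- function(V = 0.0156) {
  new("VolumeContext", V = V, molPerUM = 6.022e23 * V * 1e-15 * 1e-6)
}

#' Convert a concentration to a discrete molecule count
#'
#' @param conc concentration in uM (non-negative).
#' @param ctx a \linkS4class{VolumeContext}.
#' @return integer count, round-to-nearest of conc x molPerUM. At the default
#'   volume 80 uM gives 752 monomers, i.e. 63 dodecameric holoenzymes.
#' @export
concToCount <- function(conc, ctx = volumeContext()) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  as.integer(round(conc * ctx@molPerUM))
}

#' Convert a bimolecular rate to a stochastic per-pair propensity
#'
#' @param kon bimolecular rate in uM^-1 s^-1 (positive).
#' @param ctx a \linkS4class{VolumeContext}.
#' @return per-molecule-pair rate in s^-1: kon / molPerUM. Doubling the
#'   volume halves the per-pair rate.
#' @export
bimolecularToPropensity <- function(kon, ctx = volumeContext()) {
  if (any(kon <= 0)) stop("kon must be positive")
  kon / ctx@molPerUM
}

#' @export
setMethod("show", "RateTable", function(object) {
  cat("RateTable with", length(object@rates), "constants",
      sprintf("(%d group(s))\n", length(unique(object@table$group))))
  if (length(object@overrides))
    cat("  overridden:", paste(object@overrides, collapse = ", "), "\n")
  else cat("  all values at table defaults\n")
})

#' @export
setMethod("show", "VolumeContext", function(object) {
  cat(sprintf("VolumeContext: V = %g um^3, %0.4f molecules per uM\n",
              object@V, object@molPerUM))
})
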