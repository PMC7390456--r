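## Rule closure into a concrete reaction network, and deterministic
## (mass-action ODE) simulation of the monomer model.

#' Parse a canonical species label
#' @param lab character label (see \code{\link{buildRuleSet}} for the forms).
#' @return structured species.
#' @keywords internal
parseSpeciesLabel <- function(lab) {
  if (lab == "Ca") return(.spCa())
  if (lab == "Ng") return(.spNg())
  if (lab == "PP1") return(.spPP1())
  if (lab == "CaM.Ng") return(.spCaMNg())
  m <- regmatches(lab, regexec("^CaM_([0-2])C([0-2])N$", lab))[[1]]
  if (length(m)) return(.spCaM(as.integer(m[2]), as.integer(m[3])))
  m <- regmatches(lab, regexec("^(p?)K$", lab))[[1]]
  if (length(m)) return(.spK(as.integer(nzchar(m[2]))))
  m <- regmatches(lab, regexec("^(p?)K\\.CaM_([0-2])C([0-2])N$", lab))[[1]]
  if (length(m))
    return(.spK(as.integer(nzchar(m[2])), c(as.integer(m[3]), as.integer(m[4]))))
  if (lab == "PP1.pK") return(.spPP1K())
  m <- regmatches(lab, regexec("^PP1\\.pK\\.CaM_([0-2])C([0-2])N$", lab))[[1]]
  if (length(m)) return(.spPP1K(c(as.integer(m[2]), as.integer(m[3]))))
  m <- regmatches(lab, regexec(
    "^D\\(([PUQ])_([0-2])C([0-2])N\\|([PUQ])_([0-2])C([0-2])N\\)$", lab))[[1]]
  if (length(m))
    return(.spD(.mem(as.integer(m[2] %in% c("P", "Q")), as.integer(m[3]),
                     as.integer(m[4]), as.integer(m[2] == "Q")),
                .mem(as.integer(m[5] %in% c("P", "Q")), as.integer(m[6]),
                     as.integer(m[7]), as.integer(m[5] == "Q"))))
  stop("cannot parse species label: ", lab)
}

#' Generate the concrete reaction network from a rule set
#'
#' Applies the rules to the seed species iteratively to a fixpoint: every
#' reachable species is enumerated once (canonical labels), and every
#' instantiated mass-action reaction is recorded with its rate-table entry.
#' Identical instantiations arising from several embeddings of a rule into a
#' symmetric species are merged by summing their statistical factors, and a
#' bimolecular reaction between two copies of the same species carries the
#' usual factor 1/2.
#'
#' @param rules list of \linkS4class{Rule}, e.g. from \code{buildRuleSet()}.
#' @param seeds seed species: character labels or structured species. These
#'   are the unbound molecule kinds present in the configuration.
#' @param rateTable a \linkS4class{RateTable} the reactions draw rates from.
#' @param maxSpecies guard against runaway closure.
#' @return A \linkS4class{ReactionNetwork}. Ordering is deterministic
#'   (breadth-first from the seeds in the given order).
#' @examples
#' rules <- buildRuleSet(FALSE)
#' ## Ca/CaM subnetwork: 9 lobe-occupancy states, 12 reversible transitions
#' net <- generateNetwork(rules, c("Ca", "CaM_0C0N"))
#' @export
generateNetwork <- function(rules, seeds, rateTable = defaultRateTable(),
                            maxSpecies = 5000L) {
  structs <- lapply(seeds, function(s)
    if (is.character(s)) parseSpeciesLabel(s) else s)
  labels <- vapply(structs, speciesLabel, character(1))

  spEnv <- new.env(hash = TRUE, parent = emptyenv())
  spList <- list(); spOrder <- character(0)
  queue <- list()
  addSpecies <- function(sp) {
    lab <- speciesLabel(sp)
    if (!exists(lab, envir = spEnv, inherits = FALSE)) {
      assign(lab, sp, envir = spEnv)
      spList[[length(spList) + 1L]] <<- sp
      spOrder[length(spOrder) + 1L] <<- lab
      queue[[length(queue) + 1L]] <<- sp
      if (length(spOrder) > maxSpecies)
        stop("species cap exceeded (", maxSpecies,
             "): rule closure did not terminate; last species ", lab)
    }
    lab
  }
  for (sp in structs) addSpecies(sp)

  rxnEnv <- new.env(hash = TRUE, parent = emptyenv())
  rxns <- list()
  addReaction <- function(reactants, products, rateName, factor) {
    rLabs <- sort(vapply(reactants, speciesLabel, character(1)))
    pLabs <- sort(vapply(products, function(p) addSpecies(p), character(1)))
    key <- paste0(paste(rLabs, collapse = "+"), ">",
                  paste(pLabs, collapse = "+"), "@", rateName)
    if (exists(key, envir = rxnEnv, inherits = FALSE)) {
      i <- get(key, envir = rxnEnv)
      rxns[[i]]$factor <<- rxns[[i]]$factor + factor
    } else {
      rxns[[length(rxns) + 1L]] <<- list(reactants = rLabs, products = pLabs,
                                         rateName = rateName, factor = factor)
      assign(key, length(rxns), envir = rxnEnv)
    }
  }

  uniRules <- Filter(function(r) r@arity == 1L, rules)
  biRules <- Filter(function(r) r@arity == 2L, rules)

  processed <- list()
  while (length(queue)) {
    sp <- queue[[1L]]; queue[[1L]] <- NULL
    for (r in uniRules)
      for (rx in r@apply(sp))
        addReaction(list(sp), rx$products, rx$rateName, rx$factor)
    partners <- c(processed, list(sp))
    for (r in biRules)
      for (other in partners) {
        sym <- identical(speciesLabel(sp), speciesLabel(other))
        for (rx in r@apply(sp, other))
          addReaction(list(sp, other), rx$products, rx$rateName,
                      rx$factor * if (sym) 0.5 else 1)
      }
    processed[[length(processed) + 1L]] <- sp
  }

  idx <- setNames(seq_along(spOrder), spOrder)
  nR <- length(rxns)
  r1 <- r2 <- p1 <- p2 <- rep(NA_integer_, nR)
  rateName <- character(nR); factor <- numeric(nR)
  for (i in seq_len(nR)) {
    rr <- rxns[[i]]
    r1[i] <- idx[[rr$reactants[1]]]
    if (length(rr$reactants) > 1) r2[i] <- idx[[rr$reactants[2]]]
    p1[i] <- idx[[rr$products[1]]]
    if (length(rr$products) > 1) p2[i] <- idx[[rr$products[2]]]
    rateName[i] <- rr$rateName; factor[i] <- rr$factor
  }
  rateValue <- vapply(rateName, function(nm) {
    if (nm == "koffPP1") pp1OffRate(rateTable) else rateValue(rateTable, nm)
  }, numeric(1))

  ii <- c(r1, r2, p1, p2)
  jj <- rep(seq_len(nR), 4L)
  xx <- rep(c(-1, -1, 1, 1), each = nR)
  keep <- !is.na(ii)
  stoich <- sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                         dims = c(length(spOrder), nR))

  comp <- t(vapply(spList, speciesComposition, numeric(18)))
  info <- as.data.frame(comp)
  info$label <- spOrder
  info$type <- vapply(spList, `[[`, character(1), "type")

  new("ReactionNetwork", species = spOrder, speciesInfo = info,
      reactions = data.frame(r1 = r1, r2 = r2, p1 = p1, p2 = p2,
                             rateName = rateName, rateValue = unname(rateValue),
                             factor = factor, stringsAsFactors = FALSE),
      stoich = stoich, rateTable = rateTable)
}

#' @rdname ReactionNetwork-class
#' @param object a ReactionNetwork.
#' @export
setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", length(object@species), "species,",
      nrow(object@reactions), "reactions\n")
  tt <- table(object@speciesInfo$type)
  cat("  species by kind:",
      paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
})

#' Number of species / reactions
#' @param network a \linkS4class{ReactionNetwork}.
#' @export
nSpecies <- function(network) length(network@species)

#' @rdname nSpecies
#' @export
nReactions <- function(network) nrow(network@reactions)

#' @rdname nSpecies
#' @export
speciesNames <- function(network) network@species

#' Conservation groups of a network
#'
#' Returns the stoichiometry vectors of total CaM, CaMKII, Ng, PP1 and Ca
#' (free plus bound). Each is a left null vector of the stoichiometric matrix
#' (calcium only when influx/efflux are off), which is checked exactly.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @return named list of numeric vectors (one entry per species).
#' @export
conservationGroups <- function(network) {
  info <- network@speciesInfo
  list(CaM = info$nCaM, CaMKII = info$nK, Ng = info$nNg, PP1 = info$nPP1,
       Ca = info$caBound + info$freeCa)
}

## index of the free-Ca species (NA when absent)
.caIndex <- function(network) {
  i <- match("Ca", network@species)
  if (is.na(i)) stop("network has no free Ca species")
  i
}

#' Mass-action right-hand side of a network
#'
#' Builds the time-derivative function of the generated network under
#' mass-action kinetics, with optional calcium source/sink terms. Used
#' directly by the integrators; exposed for testing.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @return function(t, state, influxRate = 0, effluxRate = 0) returning the
#'   derivative vector (uM/s); influxRate is added to, and
#'   effluxRate * [Ca] subtracted from, the free-calcium derivative.
#' @export
massActionRHS <- function(network) {
  kf <- network@reactions$rateValue * network@reactions$factor
  i1 <- network@reactions$r1
  i2 <- network@reactions$r2
  hasR2 <- !is.na(i2)
  i2f <- ifelse(hasR2, i2, 1L)
  S <- network@stoich
  ca <- match("Ca", network@species)
  function(t, state, influxRate = 0, effluxRate = 0) {
    if (length(state) != length(network@species))
      stop("state length must equal species count")
    v <- kf * state[i1] * ifelse(hasR2, state[i2f], 1)
    dy <- as.vector(S %*% v)
    if (!is.na(ca)) dy[ca] <- dy[ca] + influxRate - effluxRate * state[ca]
    if (any(!is.finite(dy)))
      stop("non-finite derivative; state: ",
           paste(utils::head(signif(state, 4), 20), collapse = ","))
    dy
  }
}

## internal fast RHS + Jacobian factory for deSolve.
## mode "clamp": dCa/dt forced to 0.  mode "pulse": baseline influx
## ke*baseline, pulse envelope, first-order efflux ke*[Ca].
.odeFunctions <- function(network, mode = c("clamp", "pulse"),
                          protocol = NULL) {
  mode <- match.arg(mode)
  kf <- network@reactions$rateValue * network@reactions$factor
  i1 <- network@reactions$r1
  i2 <- network@reactions$r2
  hasR2 <- !is.na(i2)
  i2f <- ifelse(hasR2, i2, 1L)
  S <- network@stoich
  nS <- length(network@species)
  nR <- length(kf)
  ca <- match("Ca", network@species)
  jj <- rep(seq_len(nR), 2L)
  if (mode == "pulse") {
    stopifnot(!is.null(protocol))
    ke <- protocol@ke
    j0 <- ke * protocol@baseline
  }
  rhs <- function(t, y, parms) {
    one <- rep(1, length(hasR2)); one[hasR2] <- y[i2f[hasR2]]
    v <- kf * y[i1] * one
    dy <- as.vector(S %*% v)
    if (mode == "clamp") dy[ca] <- 0
    else dy[ca] <- dy[ca] + j0 + influxEnvelope(protocol, t) - ke * y[ca]
    list(dy)
  }
  jac <- function(t, y, parms) {
    one <- rep(1, length(hasR2)); one[hasR2] <- y[i2f[hasR2]]
    dv <- sparseMatrix(i = jj, j = c(i1, i2f),
                       x = c(kf * one, ifelse(hasR2, kf * y[i1], 0)),
                       dims = c(nR, nS))
    J <- as.matrix(S %*% dv)
    if (mode == "clamp") J[ca, ] <- 0
    else J[ca, ca] <- J[ca, ca] - ke
    J
  }
  list(rhs = rhs, jac = jac, caIndex = ca)
}

## initial state vector for a set of totals (uM)
.initialState <- function(network, totals, freeCa) {
  y <- setNames(numeric(length(network@species)), network@species)
  put <- function(lab, val) {
    if (val > 0) {
      if (!lab %in% network@species)
        stop("species ", lab, " not in network but total > 0")
      y[lab] <<- val
    }
  }
  put("Ca", freeCa)
  put("CaM_0C0N", totals$CaM %||% 0)
  put("Ng", totals$Ng %||% 0)
  put("K", totals$CaMKII %||% 0)
  put("PP1", totals$PP1 %||% 0)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equilibrate a network with free calcium clamped
#'
#' Finds the steady state of the deterministic network with free Ca2+ held at
#' a target concentration (an algebraic clamp: bound calcium evolves, the
#' free-calcium pool is treated as buffered). The total calcium the clamp
#' implies is reported, since it differs between conditions.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param totals named list of totals in uM: CaM, Ng, CaMKII, PP1 (absent
#'   entries default to 0).
#' @param targetFreeCa clamped free Ca2+ (uM), default 0.1 (resting spine).
#' @param tol convergence tolerance on the maximum relative derivative.
#' @param tMax integration horizon cap (s).
#' @return A \linkS4class{SteadyState}.
#' @export
equilibrate <- function(network, totals, targetFreeCa = 0.1, tol = 1e-8,
                        tMax = 50000) {
  if (any(unlist(totals) < 0)) stop("totals must be non-negative")
  fns <- .odeFunctions(network, "clamp")
  y <- .initialState(network, totals, targetFreeCa)
  rhsPlain <- massActionRHS(network)
  tEnd <- 50
  repeat {
    sol <- deSolve::lsoda(y, c(0, tEnd), fns$rhs, parms = NULL,
                          jacfunc = fns$jac, jactype = "fullusr",
                          rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    y[y < 0] <- 0
    y[fns$caIndex] <- targetFreeCa
    dy <- rhsPlain(0, y)
    dy[fns$caIndex] <- 0
    res <- max(abs(dy) / (1e-9 + abs(y)))
    if (res < tol || tEnd >= tMax) break
    tEnd <- tEnd * 10
  }
  if (res >= tol)
    warning(sprintf("equilibrate: residual %.3g above tolerance %.3g", res, tol))
  info <- network@speciesInfo
  new("SteadyState", concentrations = y, residual = res,
      totalCa = sum((info$caBound + info$freeCa) * y),
      freeCa = targetFreeCa)
}

#' @rdname SteadyState-class
#' @param object a SteadyState.
#' @export
setMethod("show", "SteadyState", function(object) {
  cat(sprintf("SteadyState: free Ca = %g uM (clamped), total Ca = %.4g uM, residual %.2e\n",
              object@freeCa, object@totalCa, object@residual))
  top <- sort(object@concentrations, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(6, sum(top > 0)))]
  for (nm in names(top)) cat(sprintf("  %-18s %.4g uM\n", nm, top[[nm]]))
})

#' Simulate the network deterministically
#'
#' Stiff-capable mass-action integration of a generated network driven by a
#' calcium protocol. In clamp mode free Ca2+ is held at the protocol
#' baseline; in pulse mode calcium enters via the pulse envelope plus a
#' constant baseline influx and leaves by first-order efflux.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param init a \linkS4class{SteadyState} or a named state vector (uM).
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param tGrid recording times (s).
#' @param rtol,atol integrator tolerances.
#' @return A \linkS4class{Trajectory} with one column per species.
#' @export
simulateODE <- function(network, init, protocol, tGrid,
                        rtol = 1e-8, atol = 1e-10) {
  y0 <- if (is(init, "SteadyState")) init@concentrations else init
  if (length(y0) != length(network@species))
    stop("initial state does not match network species")
  fns <- .odeFunctions(network, protocol@mode, protocol)
  if (protocol@mode == "clamp") y0[fns$caIndex] <- protocol@baseline
  ## the initial state corresponds to tGrid[1]
  sol <- deSolve::lsoda(y0, tGrid, fns$rhs, parms = NULL,
                        jacfunc = fns$jac, jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed near t = ", max(sol[, 1]))
  vals <- sol[, -1, drop = FALSE]
  vals[vals < 0 & vals > -atol * 100] <- 0
  new("Trajectory", time = sol[, 1], values = vals,
      protocol = protocol,
      meta = list(model = "ode", speciesInfo = network@speciesInfo))
}

#' Extract an observable from a trajectory
#'
#' For deterministic trajectories observables are computed from the species
#' composition table: \code{"freeCa"}, \code{"totalP"} (all phosphorylated
#' CaMKII units, with or without CaM), \code{"camNg"}, \code{"camCa0"} ..
#' \code{"camCa4"} (CaM units carrying 0..4 Ca2+ in any context),
#' \code{"pCamCa0"} .. \code{"pCamCa4"} (phosphorylated CaMKII bound to CaM
#' with 0..4 Ca2+), or any species label. For stochastic trajectories the
#' recorded columns (\code{"pSub"}, \code{"camBound"}, \code{"camBoundU"},
#' \code{"freeCa"}, \code{"camNg"}, \code{"freeCaM"}) are returned directly
#' in uM.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param name observable name.
#' @return numeric vector along \code{trajTime(traj)}.
#' @export
trajObservable <- function(traj, name) {
  if (identical(traj@meta$model, "ssa")) {
    if (!name %in% colnames(traj@values))
      stop("no such observable in stochastic trajectory: ", name)
    return(traj@values[, name])
  }
  info <- traj@meta$speciesInfo
  if (name %in% colnames(traj@values)) return(traj@values[, name])
  w <- switch(name,
    freeCa = info$freeCa,
    totalP = info$nKP,
    camNg = info$nNgBound,
    camBound = {  # CaM-bound CaMKII units
      info$camCa0 + info$camCa1 + info$camCa2 + info$camCa3 + info$camCa4 -
        (info$type == "CaM") * 1 - (info$type == "CaMNg") * 1
    },
    if (name %in% colnames(info)) info[[name]] else
      stop("unknown observable: ", name))
  as.vector(traj@values %*% w)
}

#' @rdname trajObservable
#' @export
trajTime <- function(traj) traj@time

#' @rdname Trajectory-class
#' @param object a Trajectory.
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (%s): %d time points over [%.3g, %.3g] s, %d column(s)\n",
              object@meta$model %||% "?", length(object@time),
              min(object@time), max(object@time), ncol(object@values)))
})

#' Dose-response scan over total calmodulin
#'
#' For each total CaM on the grid, runs the deterministic monomer model as a
#' closed system holding total calcium at \code{totalCa} (free calcium
#' evolves by mass conservation, so increasing CaM depletes free Ca2+ — the
#' competition regime in which Ng raises the multi-Ca CaM species), and
#' records (a) the maximum over time of total CaM carrying 1..4 Ca2+
#' relative to total CaM, (b) the steady-state phosphorylated monomer
#' concentration bound to each CaM Ca-load, and (c) the steady-state total
#' phosphorylated monomer concentration, which also counts phosphorylated
#' monomers that have released their CaM.
#'
#' @param network monomer-model \linkS4class{ReactionNetwork} (with
#'   dimerisation rule).
#' @param camGrid total CaM values (uM), positive.
#' @param withNg logical; when TRUE total Ng is \code{ng} (default 20 uM).
#' @param totalCa total calcium held in the compartment, default 10 uM.
#' @param camkii,ng,pp1 totals in uM.
#' @param tEnd integration horizon per point (s); the endpoint is used as the
#'   steady state.
#' @param nt number of recording points per run.
#' @return data.frame with one row per CaM value.
#' @export
doseResponseScan <- function(network, camGrid, withNg, totalCa = 10,
                             camkii = 80, ng = 20, pp1 = 1.25,
                             tEnd = 2000, nt = 120) {
  if (any(camGrid <= 0)) stop("camGrid must be positive")
  ## closed system: pulse mode with no pulses and no efflux
  proto <- new("PulseProtocol", baseline = 0, onsets = numeric(0), A = 0,
               tauR = 0.005, tauF = 0.015, ke = 0, mode = "pulse")
  out <- lapply(camGrid, function(cam) {
    y0 <- .initialState(network, list(CaM = cam, Ng = if (withNg) ng else 0,
                                      CaMKII = camkii, PP1 = pp1), totalCa)
    tGrid <- c(0, exp(seq(log(1e-3), log(tEnd), length.out = nt)))
    traj <- simulateODE(network, y0, proto, tGrid)
    rel <- vapply(1:4, function(j)
      max(trajObservable(traj, paste0("camCa", j))) / cam, numeric(1))
    ssPB <- vapply(1:4, function(j)
      utils::tail(trajObservable(traj, paste0("pCamCa", j)), 1), numeric(1))
    ssP <- utils::tail(trajObservable(traj, "totalP"), 1)
    c(cam = cam, maxRelCa1 = rel[1], maxRelCa2 = rel[2], maxRelCa3 = rel[3],
      maxRelCa4 = rel[4], ssPCa1 = ssPB[1], ssPCa2 = ssPB[2],
      ssPCa3 = ssPB[3], ssPCa4 = ssPB[4], ssTotalP = ssP)
  })
  as.data.frame(do.call(rbind, out))
}

#' Export a network as plain text
#'
#' Writes a human-readable reaction list (one reaction per line with rate
#' name and value) and a species/composition CSV.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param reactionsFile,speciesFile output paths.
#' @export
exportNetwork <- function(network, reactionsFile, speciesFile) {
  rx <- network@reactions
  sp <- network@species
  lines <- vapply(seq_len(nrow(rx)), function(i) {
    lhs <- paste(stats::na.omit(c(sp[rx$r1[i]], sp[rx$r2[i]])), collapse = " + ")
    rhs <- paste(stats::na.omit(c(sp[rx$p1[i]], sp[rx$p2[i]])), collapse = " + ")
    sprintf("%s -> %s  [%s = %g, factor %g]", lhs, rhs, rx$rateName[i],
            rx$rateValue[i], rx$factor[i])
  }, character(1))
  writeLines(lines, reactionsFile)
  write.csv(network@speciesInfo, speciesFile, row.names = FALSE)
  invisible(NULL)
}
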