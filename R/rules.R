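## Multistate species representation and the rule families of the model.
##
## Species are structured lists with canonical labels so that each chemical
## species appears exactly once in a generated network:
##   "Ca", "Ng", "PP1"                      free small species
##   "CaM_1C2N"                            free CaM, C-lobe/N-lobe Ca counts
##   "CaM.Ng"                               Ng-sequestered (Ca-free) CaM
##   "K", "pK"                              CaM-free monomer, (un)phosphorylated
##   "K.CaM_0C0N", "pK.CaM_2C1N"            CaM-bound monomer
##   "PP1.pK", "PP1.pK.CaM_1C0N"            PP1-substrate complexes
##   "D(P_2C2N|U_1C0N)"                     dimer of two CaM-bound monomers,
##                                          members sorted for canonical order

camStateLabel <- function(c, n) sprintf("%dC%dN", c, n)

.spCa   <- function() list(type = "Ca")
.spNg   <- function() list(type = "Ng")
.spPP1  <- function() list(type = "PP1")
.spCaM  <- function(c, n) list(type = "CaM", c = c, n = n)
.spCaMNg <- function() list(type = "CaMNg")
.spK    <- function(p, cam = NULL) list(type = "K", p = p, cam = cam)
.spPP1K <- function(cam = NULL) list(type = "PP1K", p = 1L, cam = cam)
.spD    <- function(m1, m2) {
  mm <- list(m1, m2)
  mm <- mm[order(vapply(mm, .memberLabel, character(1)))]
  list(type = "D", members = mm)
}
## member tokens: U unphosphorylated, P phosphorylated, Q phosphorylated
## with PP1 bound ("don't care, don't write": PP1 reaches a phosphorylated
## monomer whether or not it is paired)
.memberLabel <- function(m) {
  tag <- if (isTRUE(m$q == 1L)) "Q" else if (m$p) "P" else "U"
  sprintf("%s_%s", tag, camStateLabel(m$c, m$n))
}
.mem <- function(p, c, n, q = 0L) list(p = p, c = c, n = n, q = q)

#' Canonical label of a species structure
#' @param sp structured species (internal representation).
#' @return character label.
#' @keywords internal
speciesLabel <- function(sp) {
  switch(sp$type,
    Ca = "Ca", Ng = "Ng", PP1 = "PP1",
    CaM = sprintf("CaM_%s", camStateLabel(sp$c, sp$n)),
    CaMNg = "CaM.Ng",
    K = {
      base <- if (sp$p) "pK" else "K"
      if (is.null(sp$cam)) base
      else sprintf("%s.CaM_%s", base, camStateLabel(sp$cam[1], sp$cam[2]))
    },
    PP1K = {
      if (is.null(sp$cam)) "PP1.pK"
      else sprintf("PP1.pK.CaM_%s", camStateLabel(sp$cam[1], sp$cam[2]))
    },
    D = sprintf("D(%s|%s)", .memberLabel(sp$members[[1]]),
                .memberLabel(sp$members[[2]])),
    stop("unknown species type"))
}

## composition counters used for observables and conservation groups
speciesComposition <- function(sp) {
  z <- c(nCaM = 0, nK = 0, nKP = 0, nNg = 0, nNgBound = 0, nPP1 = 0,
         caBound = 0, camCa0 = 0, camCa1 = 0, camCa2 = 0, camCa3 = 0,
         camCa4 = 0, pCamCa0 = 0, pCamCa1 = 0, pCamCa2 = 0, pCamCa3 = 0,
         pCamCa4 = 0, freeCa = 0)
  addCam <- function(z, c, n, phosphoHost = FALSE) {
    tot <- c + n
    z["nCaM"] <- z["nCaM"] + 1
    z["caBound"] <- z["caBound"] + tot
    z[paste0("camCa", tot)] <- z[paste0("camCa", tot)] + 1
    if (phosphoHost) z[paste0("pCamCa", tot)] <- z[paste0("pCamCa", tot)] + 1
    z
  }
  switch(sp$type,
    Ca = { z["freeCa"] <- 1; z },
    Ng = { z["nNg"] <- 1; z },
    PP1 = { z["nPP1"] <- 1; z },
    CaM = addCam(z, sp$c, sp$n),
    CaMNg = { z["nNg"] <- 1; z["nNgBound"] <- 1; addCam(z, 0, 0) },
    K = {
      z["nK"] <- 1; z["nKP"] <- sp$p
      if (!is.null(sp$cam)) z <- addCam(z, sp$cam[1], sp$cam[2], sp$p == 1L)
      z
    },
    PP1K = {
      z["nPP1"] <- 1; z["nK"] <- 1; z["nKP"] <- 1
      if (!is.null(sp$cam)) z <- addCam(z, sp$cam[1], sp$cam[2], TRUE)
      z
    },
    D = {
      for (m in sp$members) {
        z["nK"] <- z["nK"] + 1; z["nKP"] <- z["nKP"] + m$p
        if (isTRUE(m$q == 1L)) z["nPP1"] <- z["nPP1"] + 1
        z <- addCam(z, m$c, m$n, m$p == 1L)
      }
      z
    })
}

.onRateFree <- c("kon1C", "kon2C")    # indexed by current count + 1
.offRateFreeC <- c("koff1C", "koff2C")
.onRateFreeN <- c("kon1N", "kon2N")
.offRateFreeN <- c("koff1N", "koff2N")
.onRateK <- c("konK1C", "konK2C"); .offRateKC <- c("koffK1C", "koffK2C")
.onRateKN <- c("konK1N", "konK2N"); .offRateKN <- c("koffK1N", "koffK2N")

camSuffix <- function(c, n) {
  if (c + n == 0) return("0")
  if (c + n == 4) return("4")
  paste0(if (c > 0) paste0(c, "C") else "", if (n > 0) paste0(n, "N") else "")
}
konCaMName  <- function(c, n) paste0("konCaM", camSuffix(c, n))
koffCaMName <- function(c, n) paste0("koffCaM", camSuffix(c, n))
kponCaMName <- function(c, n) paste0("kponCaM", camSuffix(c, n))
kpName      <- function(c, n) paste0("kpCaM", camSuffix(c, n))

.rx <- function(products, rateName, factor = 1)
  list(products = products, rateName = rateName, factor = factor)

## Ca2+ transitions on a CaM state (shared by free and CaMKII-bound contexts)
.caTransitionsOn <- function(c, n, onC, onN) {
  out <- list()
  if (c < 2) out[[length(out) + 1L]] <- list(c = c + 1L, n = n, rate = onC[c + 1L])
  if (n < 2) out[[length(out) + 1L]] <- list(c = c, n = n + 1L, rate = onN[n + 1L])
  out
}
.caTransitionsOff <- function(c, n, offC, offN) {
  out <- list()
  if (c > 0) out[[length(out) + 1L]] <- list(c = c - 1L, n = n, rate = offC[c])
  if (n > 0) out[[length(out) + 1L]] <- list(c = c, n = n - 1L, rate = offN[n])
  out
}

#' Build the rule families of the kinetic model
#'
#' Returns the rule set over multistate agents: Ca2+ exchange on free and
#' CaMKII-bound CaM (two lobes, sites within a lobe counted, not labelled),
#' mutually exclusive Ng sequestration of Ca-free CaM, CaM binding to
#' unphosphorylated and (with slow trapping-release kinetics) phosphorylated
#' CaMKII, neighbour/partner autophosphorylation guarded by the substrate's
#' CaM carrying at least one Ca2+, and PP1 dephosphorylation through an
#' explicit enzyme-substrate complex.
#'
#' @param includeMonomerDimerization if TRUE (monomer model) two CaM-bound
#'   monomers may pair reversibly at konCaMKII/koffCaMKII and phosphorylate
#'   each other inside the pair; if FALSE (holoenzyme model) the pairing rule
#'   is omitted because subunits are permanently linked, and phosphorylation
#'   instead requires an active ring neighbour.
#' @return list of \linkS4class{Rule} objects.
#' @export
buildRuleSet <- function(includeMonomerDimerization = TRUE) {
  rules <- list()
  add <- function(name, arity, rateNames, guard, apply)
    rules[[length(rules) + 1L]] <<- new("Rule", name = name,
      arity = as.integer(arity), rateNames = rateNames, guard = guard,
      apply = apply)

  ## 1. Ca2+ <-> free CaM
  add("Ca binding to free CaM", 2L,
      c(.onRateFree, .onRateFreeN), "CaM not Ng-bound, lobe not full",
      function(a, b) {
        if (a$type == "CaM" && b$type == "Ca") { tmp <- a; a <- b; b <- tmp }
        if (!(a$type == "Ca" && b$type == "CaM")) return(list())
        lapply(.caTransitionsOn(b$c, b$n, .onRateFree, .onRateFreeN),
               function(tr) .rx(list(.spCaM(tr$c, tr$n)), tr$rate))
      })
  add("Ca unbinding from free CaM", 1L,
      c(.offRateFreeC, .offRateFreeN), "lobe occupied",
      function(a) {
        if (a$type != "CaM") return(list())
        lapply(.caTransitionsOff(a$c, a$n, .offRateFreeC, .offRateFreeN),
               function(tr) .rx(list(.spCa(), .spCaM(tr$c, tr$n)), tr$rate))
      })

  ## 2. Ng <-> Ca-free CaM (mutually exclusive with Ca2+)
  add("Ng binding to CaM", 2L, "konNg", "CaM has zero Ca2+ bound",
      function(a, b) {
        if (a$type == "CaM" && b$type == "Ng") { tmp <- a; a <- b; b <- tmp }
        if (a$type == "Ng" && b$type == "CaM" && b$c == 0 && b$n == 0)
          list(.rx(list(.spCaMNg()), "konNg")) else list()
      })
  add("Ng unbinding from CaM", 1L, "koffNg", "",
      function(a) {
        if (a$type != "CaMNg") return(list())
        list(.rx(list(.spNg(), .spCaM(0L, 0L)), "koffNg"))
      })

  ## 3./7. CaM <-> CaMKII monomer (state-dependent on-rates; trapping release
  ##       at kpoffCaM when the host is phosphorylated)
  add("CaM binding to CaMKII", 2L,
      c(vapply(0:2, function(c) vapply(0:2, function(n) konCaMName(c, n),
        character(1)), character(3)),
        vapply(0:2, function(c) vapply(0:2, function(n) kponCaMName(c, n),
        character(1)), character(3))),
      "CaMKII CaM-binding site free",
      function(a, b) {
        if (b$type == "CaM") { tmp <- a; a <- b; b <- tmp }
        if (a$type != "CaM") return(list())
        if (b$type == "K" && is.null(b$cam)) {
          rn <- if (b$p) kponCaMName(a$c, a$n) else konCaMName(a$c, a$n)
          list(.rx(list(.spK(b$p, c(a$c, a$n))), rn))
        } else if (b$type == "PP1K" && is.null(b$cam)) {
          list(.rx(list(.spPP1K(c(a$c, a$n))), kponCaMName(a$c, a$n)))
        } else list()
      })
  add("CaM unbinding from CaMKII", 1L,
      c("kpoffCaM",
        vapply(0:2, function(c) vapply(0:2, function(n) koffCaMName(c, n),
        character(1)), character(3))),
      "monomer not dimerised",
      function(a) {
        if (a$type == "K" && !is.null(a$cam)) {
          rn <- if (a$p) "kpoffCaM" else koffCaMName(a$cam[1], a$cam[2])
          list(.rx(list(.spK(a$p), .spCaM(a$cam[1], a$cam[2])), rn))
        } else if (a$type == "PP1K" && !is.null(a$cam)) {
          list(.rx(list(.spPP1K(), .spCaM(a$cam[1], a$cam[2])), "kpoffCaM"))
        } else list()
      })

  ## 4. Ca2+ <-> CaMKII-bound CaM (monomers, PP1 complexes and dimer members)
  add("Ca binding to CaMKII-bound CaM", 2L, c(.onRateK, .onRateKN),
      "CaM bound to CaMKII, lobe not full",
      function(a, b) {
        if (b$type == "Ca") { tmp <- a; a <- b; b <- tmp }
        if (a$type != "Ca") return(list())
        if (b$type %in% c("K", "PP1K") && !is.null(b$cam)) {
          lapply(.caTransitionsOn(b$cam[1], b$cam[2], .onRateK, .onRateKN),
                 function(tr) {
                   p <- if (b$type == "K") .spK(b$p, c(tr$c, tr$n))
                        else .spPP1K(c(tr$c, tr$n))
                   .rx(list(p), tr$rate)
                 })
        } else if (b$type == "D") {
          out <- list()
          for (i in 1:2) {
            m <- b$members[[i]]
            for (tr in .caTransitionsOn(m$c, m$n, .onRateK, .onRateKN)) {
              m2 <- m; m2$c <- tr$c; m2$n <- tr$n
              out[[length(out) + 1L]] <-
                .rx(list(.spD(b$members[[3 - i]], m2)), tr$rate)
            }
          }
          out
        } else list()
      })
  add("Ca unbinding from CaMKII-bound CaM", 1L, c(.offRateKC, .offRateKN),
      "lobe occupied",
      function(a) {
        if (a$type %in% c("K", "PP1K") && !is.null(a$cam)) {
          lapply(.caTransitionsOff(a$cam[1], a$cam[2], .offRateKC, .offRateKN),
                 function(tr) {
                   p <- if (a$type == "K") .spK(a$p, c(tr$c, tr$n))
                        else .spPP1K(c(tr$c, tr$n))
                   .rx(list(.spCa(), p), tr$rate)
                 })
        } else if (a$type == "D") {
          out <- list()
          for (i in 1:2) {
            m <- a$members[[i]]
            for (tr in .caTransitionsOff(m$c, m$n, .offRateKC, .offRateKN)) {
              m2 <- m; m2$c <- tr$c; m2$n <- tr$n
              out[[length(out) + 1L]] <-
                .rx(list(.spCa(), .spD(a$members[[3 - i]], m2)), tr$rate)
            }
          }
          out
        } else list()
      })

  ## 5. monomer pairing (monomer model only)
  if (includeMonomerDimerization) {
    add("CaM-bound monomer pairing", 2L, "konCaMKII",
        "both partners CaM-bound (PP1-engaged phospho-monomers included)",
        function(a, b) {
          memOf <- function(x) {
            if (x$type == "K" && !is.null(x$cam))
              .mem(x$p, x$cam[1], x$cam[2], 0L)
            else if (x$type == "PP1K" && !is.null(x$cam))
              .mem(1L, x$cam[1], x$cam[2], 1L)
            else NULL
          }
          ma <- memOf(a); mb <- memOf(b)
          if (!is.null(ma) && !is.null(mb))
            list(.rx(list(.spD(ma, mb)), "konCaMKII"))
          else list()
        })
    add("monomer pair dissociation", 1L, "koffCaMKII", "",
        function(a) {
          if (a$type != "D") return(list())
          ms <- lapply(a$members, function(m) {
            if (isTRUE(m$q == 1L)) .spPP1K(c(m$c, m$n))
            else .spK(m$p, c(m$c, m$n))
          })
          list(.rx(ms, "koffCaMKII"))
        })
    ## 6. phosphorylation inside a pair: the substrate member must be
    ##    unphosphorylated with >= 1 Ca2+ on its CaM; the partner (kinase) is
    ##    active by virtue of being CaM-bound, whatever its Ca load.
    add("phosphorylation within a pair", 1L,
        vapply(seq_len(8), function(i) {
          states <- list(c(1,0), c(2,0), c(0,1), c(0,2), c(1,1), c(2,1),
                         c(1,2), c(2,2))[[i]]
          kpName(states[1], states[2])
        }, character(1)),
        "substrate unphosphorylated, substrate CaM has >= 1 Ca2+",
        function(a) {
          if (a$type != "D") return(list())
          out <- list()
          for (i in 1:2) {
            m <- a$members[[i]]
            if (m$p == 0L && (m$c + m$n) >= 1) {
              m2 <- m; m2$p <- 1L
              out[[length(out) + 1L]] <-
                .rx(list(.spD(a$members[[3 - i]], m2)), kpName(m$c, m$n))
            }
          }
          out
        })
  }

  ## 8. PP1 dephosphorylation via explicit enzyme-substrate complex
  add("PP1 binding to phosphorylated CaMKII", 2L, "konPP1",
      "substrate phosphorylated, PP1 site free",
      function(a, b) {
        if (b$type == "PP1") { tmp <- a; a <- b; b <- tmp }
        if (a$type != "PP1") return(list())
        if (b$type == "K" && b$p == 1L)
          return(list(.rx(list(.spPP1K(b$cam)), "konPP1")))
        if (b$type == "D") {
          out <- list()
          for (i in 1:2) {
            m <- b$members[[i]]
            if (m$p == 1L && !isTRUE(m$q == 1L)) {
              m2 <- m; m2$q <- 1L
              out[[length(out) + 1L]] <-
                .rx(list(.spD(b$members[[3 - i]], m2)), "konPP1")
            }
          }
          return(out)
        }
        list()
      })
  add("PP1 unbinding", 1L, "koffPP1", "",
      function(a) {
        if (a$type == "PP1K")
          return(list(.rx(list(.spPP1(), .spK(1L, a$cam)), "koffPP1")))
        if (a$type == "D") {
          out <- list()
          for (i in 1:2) {
            m <- a$members[[i]]
            if (isTRUE(m$q == 1L)) {
              m2 <- m; m2$q <- 0L
              out[[length(out) + 1L]] <-
                .rx(list(.spPP1(), .spD(a$members[[3 - i]], m2)), "koffPP1")
            }
          }
          return(out)
        }
        list()
      })
  add("PP1 catalysis", 1L, "kcat", "",
      function(a) {
        if (a$type == "PP1K")
          return(list(.rx(list(.spPP1(), .spK(0L, a$cam)), "kcat")))
        if (a$type == "D") {
          out <- list()
          for (i in 1:2) {
            m <- a$members[[i]]
            if (isTRUE(m$q == 1L)) {
              m2 <- m; m2$q <- 0L; m2$p <- 0L
              out[[length(out) + 1L]] <-
                .rx(list(.spPP1(), .spD(a$members[[3 - i]], m2)), "kcat")
            }
          }
          return(out)
        }
        list()
      })

  rules
}

#' @export
setMethod("show", "Rule", function(object) {
  cat(sprintf("Rule '%s' (%s)\n", object@name,
              if (object@arity == 1L) "unimolecular" else "bimolecular"))
  if (nzchar(object@guard)) cat("  guard:", object@guard, "\n")
  cat("  rates:", paste(unique(object@rateNames), collapse = ", "), "\n")
})
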