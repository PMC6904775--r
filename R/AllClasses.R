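#' @import methods
NULL

#' ReactionNetwork: a kinetic reaction network with parameter registry
#'
#' Container for a mass-action-free kinetic network: species (with initial
#' concentrations and a fluorination flag), reactions (stoichiometry given as
#' substrate/product id lists, a rate-law binding and a parameter-group key),
#' a parameter registry with sharing links and fixed-value flags, and the
#' NMR observable grouping.
#'
#' Parameter sharing is by reference through the registry: several reactions
#' may point at the same parameter group (e.g. the three
#' nucleoside-diphosphate kinase reactions of the 5-FU model), and single
#' parameters may be linked across groups. Changing a shared value through
#' [setParameter()] therefore changes every reaction bound to it.
#'
#' @slot species data.frame with columns id, initial (uM), fluorinated
#'   (logical), boundary (logical; boundary species are held constant)
#' @slot reactions data.frame with columns index, ec, name, rateLaw,
#'   paramGroup, hypothetical and list-columns substrates, products
#' @slot paramGroups named list of named numeric parameter vectors
#' @slot paramLinks data.frame(group, name, toGroup, toName) of single-value
#'   sharing links
#' @slot paramFixed data.frame(group, name) of parameters excluded from any
#'   fit
#' @slot observables named list of species-id sets (NMR-indistinguishable
#'   groups); the special group "totalF" is the union of all fluorinated
#'   species
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "data.frame",
                 paramGroups = "list", paramLinks = "data.frame",
                 paramFixed = "data.frame", observables = "list"))

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  sp <- object@species
  rx <- object@reactions
  if (!all(c("id", "initial", "fluorinated", "boundary") %in% names(sp)))
    msg <- c(msg, "species table lacks required columns")
  else {
    if (anyDuplicated(sp$id)) msg <- c(msg, "duplicated species ids")
    if (any(sp$initial < 0)) msg <- c(msg, "negative initial concentration")
  }
  if (nrow(rx)) {
    law <- rx$rateLaw
    if (!all(law %in% c("irr_mm", "rev_mm", "ping_pong")))
      msg <- c(msg, "unknown rate law")
    ids <- unlist(c(rx$substrates, rx$products))
    if (!all(ids %in% sp$id))
      msg <- c(msg, "reaction references unknown species")
    if (!all(rx$paramGroup %in% names(object@paramGroups)))
      msg <- c(msg, "reaction references unknown parameter group")
    need <- list(irr_mm = c("V", "Km"),
                 rev_mm = c("Vf", "Vr", "Kms", "Kmp"),
                 ping_pong = c("Keq", "Kia", "Kiq", "Kma", "Kmb",
                               "Kmp", "Kmq", "Vf", "Vr"))
    for (i in seq_len(nrow(rx))) {
      p <- try(resolveParams(object, rx$paramGroup[i]), silent = TRUE)
      if (inherits(p, "try-error") ||
          !all(need[[law[i]]] %in% names(p)))
        msg <- c(msg, sprintf("incomplete parameters for reaction %d",
                              rx$index[i]))
    }
  }
  ok <- vapply(object@observables, function(g) all(g %in% sp$id), logical(1))
  if (!all(ok)) msg <- c(msg, "observable group references unknown species")
  if (length(msg)) msg else TRUE
})

#' Trajectory: a simulated time course
#'
#' @slot times time grid in hours
#' @slot states matrix (time x species) of concentrations, uM
#' @slot fluxes matrix (time x reaction) of signed reaction rates, uM/h
#' @slot observables matrix (time x observable group) of group sums, uM
#' @slot atpMode ATP handling mode used ("forced" or "dynamic")
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", fluxes = "matrix",
                 observables = "matrix", atpMode = "character"))

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@states))
    "times and states disagree" else TRUE
})

#' FitResult: multi-start parameter estimation result
#'
#' Per free parameter the best-fit value (bfv), the mean over the retained
#' best attempts (avg), the sample standard deviation (stds) and the
#' |bfv - avg| / stds ratio (devStds, reported as 0 when stds is 0); plus the
#' attempt trace and the protocol used.
#'
#' @slot par data.frame(parameter, bfv, avg, stds, devStds)
#' @slot objective final (best) objective value
#' @slot attempts data.frame of all attempts (start/final objective, stages,
#'   retained flag)
#' @slot protocol list of protocol settings
#' @slot seed integer seed the run is reproducible from
#' @export
setClass("FitResult",
  representation(par = "data.frame", objective = "numeric",
                 attempts = "data.frame", protocol = "list",
                 seed = "integer"))

#' MCAResult: metabolic control analysis at a reference state
#'
#' @slot EC scaled elasticity matrix (reaction x species); NA where the
#'   log-derivative is undefined (zero rate or zero concentration)
#' @slot FCC scaled flux control coefficient matrix (flux x enzyme); rows are
#'   defined for reactions with non-zero reference flux
#' @slot CCC scaled concentration control coefficient matrix (species x
#'   enzyme); rows are defined for species with non-zero reference
#'   concentration
#' @slot state reference state (uM)
#' @slot fluxes reference fluxes (uM/h)
#' @slot atSteadyState logical; summation theorems only hold at steady state
#' @export
setClass("MCAResult",
  representation(EC = "matrix", FCC = "matrix", CCC = "matrix",
                 state = "numeric", fluxes = "numeric",
                 atSteadyState = "logical"))

#' DoseResponseFit: Hill dose-survival fit
#'
#' Survival is modeled as \eqn{100/(1+(d/EC_{50})^{h})} percent, which is
#' 100\% at zero dose and decreases with dose for a positive Hill exponent h.
#'
#' @slot ec50 half-effect dose (same unit as the input doses)
#' @slot hill Hill exponent (dimensionless)
#' @slot se standard errors c(ec50, hill) from the fit Jacobian
#' @slot vcov 2x2 covariance of (log ec50, hill)
#' @slot data the dose/survival table used
#' @export
setClass("DoseResponseFit",
  representation(ec50 = "numeric", hill = "numeric", se = "numeric",
                 vcov = "matrix", data = "data.frame"))

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d reactions, %d species (%d fluorinated, %d hypothetical reactions)\n",
              nrow(object@reactions), nrow(object@species),
              sum(object@species$fluorinated),
              sum(object@reactions$hypothetical)))
  n <- countParameters(object)
  cat(sprintf("parameters: %d total (%d free after sharing/fixing)\n",
              n$total, n$free))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over %.3g-%.3g h, %d species, %d fluxes (ATP mode: %s)\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@states), ncol(object@fluxes), object@atpMode))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d parameters, objective %.6g, %d/%d attempts retained (seed %d)\n",
              nrow(object@par), object@objective,
              sum(object@attempts$retained), nrow(object@attempts),
              object@seed))
  print(object@par, digits = 5)
})

setMethod("show", "MCAResult", function(object) {
  cat(sprintf("MCAResult: %d reactions x %d species%s\n",
              nrow(object@EC), ncol(object@EC),
              if (object@atSteadyState) " (at steady state)" else
                " (off steady state: summation theorems need not hold)"))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit: EC50 = %.4g +/- %.2g, Hill = %.4g +/- %.2g (n = %d points)\n",
              object@ec50, object@se[1], object@hill, object@se[2],
              nrow(object@data)))
})
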