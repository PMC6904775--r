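#' Scaled elasticity coefficients
#'
#' Elasticities \eqn{\epsilon^v_x = (x/v) \partial v/\partial x} by analytic
#' differentiation of the rate-law kernels. Entries whose log-derivative is
#' undefined (zero rate or zero concentration) are reported as NA rather
#' than propagating NaN. For an irreversible Michaelis-Menten reaction the
#' substrate elasticity is Km/(Km+S), between 0 and 1.
#'
#' @param net a [ReactionNetwork-class]
#' @param state named reference state (uM)
#' @return reaction x species matrix of scaled elasticities
#' @export
elasticities <- function(net, state) {
  state <- state[speciesIds(net)]
  if (anyNA(state)) stop("state must name every species")
  v <- reactionRates(net, state)
  dvdx <- rateJacobianFull(net, state)
  EC <- dvdx * rep(state, each = nrow(dvdx)) / v
  EC[v == 0, ] <- NA_real_
  EC[, state == 0] <- NA_real_
  dimnames(EC) <- dimnames(dvdx)
  EC
}

#' Flux and concentration control coefficients
#'
#' Control coefficients at a steady state by the structural matrix method:
#' with N the stoichiometry over the dynamically active species, dv/dx the
#' analytic rate Jacobian and M = N dv/dx, the response of the state to a
#' unit relative activity change of enzyme k (scaling Vf and Vr jointly, so
#' dv_k/de_k = v_k) solves M dx = -N_k v_k subject to the local conserved
#' quantities (left null vectors of M) staying fixed - the general form of
#' link-matrix reduction, which also covers moieties that are only
#' conserved locally because the depleted state has switched pathways off.
#' Scaled coefficients follow as
#' \eqn{C^S_{sk} = dx_s/x_s} and \eqn{C^J_{jk} = ((dv/dx)_j dx + 1_{j=k} v_k)/J_j}.
#'
#' Species that influence no rate at the reference state (pure accumulator
#' sinks whose steady content is historical) are excluded; their rows, rows
#' of species at zero concentration, and flux rows of reactions with zero
#' reference flux are NA. At a converged steady state every defined FCC row
#' sums to 1 and every defined CCC row to 0 (summation theorems).
#'
#' @param net a [ReactionNetwork-class]
#' @param ss result of [steadyState()] (or a list with `state` and `fluxes`)
#' @param atp the [atpModel()] the steady state was computed under
#' @param relTol relative threshold below which a flux (vs the largest
#'   flux) or a concentration (vs the largest dynamic concentration) counts
#'   as zero, i.e. as a numerical residual of the steady-state solve rather
#'   than a defined reference value
#' @return list(FCC, CCC) with full-size matrices (flux x enzyme and
#'   species x enzyme), NA rows where undefined
#' @export
controlCoefficients <- function(net, ss, atp = atpModel(), relTol = 1e-9) {
  ids <- speciesIds(net)
  x <- ss$state[ids]
  v <- as.numeric(ss$fluxes)
  nR <- nReactions(net)
  dvdxFull <- rateJacobianFull(net, x)
  dynIdx <- dynamicIndices(net, atp)
  Sfull <- stoichiometryMatrix(net)

  # kinetically active species: dynamic and entering at least one rate law
  act <- dynIdx[colSums(dvdxFull[, dynIdx, drop = FALSE] != 0) > 0]
  if (!length(act)) stop("no kinetically active species at this state")
  N <- Sfull[act, , drop = FALSE]
  dvdx <- dvdxFull[, act, drop = FALSE]
  M <- N %*% dvdx

  # local conserved quantities: left null space of M, detected on the
  # column-equilibrated matrix (null vectors are invariant to column scaling)
  cn <- pmax(sqrt(colSums(M^2)), .Machine$double.xmin)
  sv <- svd(t(M %*% diag(1 / cn, length(cn))))
  nullIdx <- which(sv$d < max(sv$d) * 1e-8)
  W <- t(sv$v[, nullIdx, drop = FALSE])

  A <- rbind(M, W)
  dc <- pmax(sqrt(colSums(A^2)), .Machine$double.xmin)
  qrA <- qr(A %*% diag(1 / dc, length(dc)))
  solveA <- function(b) qr.coef(qrA, c(b, rep(0, nrow(W)))) / dc

  dX <- matrix(vapply(seq_len(nR), function(k) solveA(-N[, k] * v[k]),
                      numeric(length(act))),
               nrow = length(act), ncol = nR)

  CCC <- matrix(NA_real_, nSpecies(net), nR,
                dimnames = list(ids, paste0("r", net@reactions$index)))
  keepS <- x[act] > relTol * max(x[act])
  defS <- act[keepS]
  CCC[defS, ] <- dX[keepS, , drop = FALSE] / x[defS]

  dV <- dvdx %*% dX + diag(v, nR)
  FCC <- matrix(NA_real_, nR, nR,
                dimnames = list(paste0("r", net@reactions$index),
                                paste0("r", net@reactions$index)))
  defJ <- which(abs(v) > relTol * max(abs(v)))
  FCC[defJ, ] <- dV[defJ, , drop = FALSE] / v[defJ]
  list(FCC = FCC, CCC = CCC)
}

#' Metabolic control analysis at a reference state
#'
#' Combines [elasticities()] and [controlCoefficients()] into an
#' [MCAResult-class]. The natural reference is the long-run steady state
#' from [steadyState()]; any other state is accepted with a warning that
#' the summation theorems need not hold there.
#'
#' @param net a [ReactionNetwork-class]
#' @param ss a [steadyState()] result; computed from the network's defaults
#'   when missing
#' @param atp the [atpModel()] defining the reference conditions
#' @return an [MCAResult-class]
#' @examples
#' \donttest{
#' res <- mca(buildNetwork())
#' rowSums(fcc(res), na.rm = TRUE)  # 1 for every defined flux row
#' }
#' @export
mca <- function(net, ss = NULL, atp = atpModel()) {
  if (is.null(ss)) ss <- steadyState(net, atp = atp)
  atSS <- isTRUE(ss$converged)
  if (!atSS)
    warning("reference state is not a converged steady state; control-coefficient summation theorems need not hold")
  cc <- controlCoefficients(net, ss, atp = atp)
  new("MCAResult", EC = elasticities(net, ss$state), FCC = cc$FCC,
      CCC = cc$CCC, state = ss$state, fluxes = ss$fluxes,
      atSteadyState = atSS)
}

#' @rdname mcaAccessors
#' @export
fcc <- function(x) x@FCC

#' MCAResult accessors
#' @param x an [MCAResult-class]
#' @name mcaAccessors
#' @export
ccc <- function(x) x@CCC

#' @rdname mcaAccessors
#' @export
ec <- function(x) x@EC

#' Extreme control/elasticity entries
#'
#' Scans each coefficient matrix for its most positive and most negative
#' finite entries, reporting cause (the perturbed quantity: species for EC,
#' enzyme for FCC/CCC), effect (the responding rate, flux or
#' concentration) and value; ties within a relative 1e-9 are all listed.
#' A matrix with no finite non-zero entry contributes no rows and flags the
#' result as degenerate.
#'
#' @param result an [MCAResult-class]
#' @return data.frame(coefficient, extreme, cause, effect, value) with
#'   attribute "degenerate" naming matrices without usable entries
#' @export
mcaExtremes <- function(result) {
  scan1 <- function(mat, coefName, causeDim) {
    out <- list(); degenerate <- TRUE
    vals <- mat[is.finite(mat) & mat != 0]
    if (length(vals)) {
      degenerate <- FALSE
      for (ext in c("Max. neg.", "Max. pos.")) {
        target <- if (ext == "Max. neg.") min(vals) else max(vals)
        if ((ext == "Max. neg.") == (target < 0)) {
          hits <- which(is.finite(mat) &
                          abs(mat - target) <= abs(target) * 1e-9,
                        arr.ind = TRUE)
          cause <- if (causeDim == "col") colnames(mat)[hits[, 2]] else
            rownames(mat)[hits[, 1]]
          effect <- if (causeDim == "col") rownames(mat)[hits[, 1]] else
            colnames(mat)[hits[, 2]]
          out[[length(out) + 1]] <- data.frame(
            coefficient = coefName, extreme = ext, cause = cause,
            effect = effect, value = mat[hits])
        }
      }
    }
    list(rows = out, degenerate = degenerate)
  }
  parts <- list(EC = scan1(result@EC, "EC", "col"),
                FCC = scan1(result@FCC, "FCC", "col"),
                CCC = scan1(result@CCC, "CCC", "col"))
  rows <- unlist(lapply(parts, `[[`, "rows"), recursive = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(coefficient = character(), extreme = character(),
               cause = character(), effect = character(),
               value = numeric())
  attr(out, "degenerate") <-
    names(parts)[vapply(parts, `[[`, logical(1), "degenerate")]
  out
}
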