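#' ATP handling model
#'
#' The experiment the model targets runs under ATP depletion: the relative
#' ATP level starts at 1, halves within about an hour and is near zero by
#' 4 h. Two modes are provided.
#'
#' \describe{
#'   \item{forced (default)}{ATP follows a fitted monotone decay
#'     \eqn{ATP_{rel}(t) = 1/(1+(t/t_{50})^s)} with half-time `t50` (h) and
#'     shape `s`; ADP complements the adenylate pool,
#'     ADP(t) = ATP(0)+ADP(0)-ATP(t). The fluorinated species are the only
#'     ODE states.}
#'   \item{dynamic}{ATP and ADP are state variables and a first-order
#'     ATP -> ADP sink of rate constant `kAtp` (per h) is appended,
#'     representing bulk non-fluorinated ATPase activity. The sink is
#'     plumbing for the depletion boundary condition, not a reaction of the
#'     metabolic network itself; set `kAtp = 0` to switch it off.}
#' }
#'
#' The default shape (t50 = 1 h, s = 2.2) puts the relative level at 0.5 by
#' 1 h and below 0.05 by 4 h; kAtp = 0.8/h gives the dynamic mode the same
#' qualitative decay.
#'
#' @param mode "forced" or "dynamic"
#' @param t50 forced-mode half-time, h
#' @param shape forced-mode shape exponent (dimensionless)
#' @param kAtp dynamic-mode first-order sink rate, 1/h
#' @return an object of class "atpModel"
#' @examples
#' m <- atpModel()
#' atpRelative(c(0, 1, 4), m)  # 1, 0.5, < 0.05
#' @export
atpModel <- function(mode = c("forced", "dynamic"), t50 = 1, shape = 2.2,
                     kAtp = 0.8) {
  mode <- match.arg(mode)
  stopifnot(t50 > 0, shape > 0, kAtp >= 0)
  structure(list(mode = mode, t50 = t50, shape = shape, kAtp = kAtp),
            class = "atpModel")
}

#' Relative forced ATP curve
#' @param t times, h
#' @param model an [atpModel()]
#' @return relative ATP level, 1 at t = 0, non-increasing
#' @export
atpRelative <- function(t, model = atpModel()) {
  stopifnot(all(t >= 0))
  1 / (1 + (t / model$t50)^model$shape)
}

# Precompute a vectorized evaluation plan grouped by rate-law class: species
# indices into the full state and parameter vectors aligned per reaction.
# Rebuilt whenever parameters change.
compileNetwork <- function(net) {
  ids <- speciesIds(net)
  pars <- reactionParameters(net)
  law <- net@reactions$rateLaw
  sub1 <- vapply(net@reactions$substrates, function(s) match(s[1], ids), 0L)
  sub2 <- vapply(net@reactions$substrates,
                 function(s) match(s[2], ids)[1], 0L)
  prod1 <- vapply(net@reactions$products, function(s) match(s[1], ids), 0L)
  prod2 <- vapply(net@reactions$products,
                  function(s) match(s[2], ids)[1], 0L)
  pv <- function(idx, nm) vapply(pars[idx], `[[`, numeric(1), nm)
  g <- list(nR = length(law), nS = length(ids),
            irr = which(law == "irr_mm"), rev = which(law == "rev_mm"),
            ping = which(law == "ping_pong"))
  if (length(g$irr)) {
    g$iS <- sub1[g$irr]; g$iV <- pv(g$irr, "V"); g$iKm <- pv(g$irr, "Km")
  }
  if (length(g$rev)) {
    g$rS <- sub1[g$rev]; g$rP <- prod1[g$rev]
    g$rVf <- pv(g$rev, "Vf"); g$rVr <- pv(g$rev, "Vr")
    g$rKms <- pv(g$rev, "Kms"); g$rKmp <- pv(g$rev, "Kmp")
  }
  if (length(g$ping)) {
    g$pA <- sub1[g$ping]; g$pB <- sub2[g$ping]
    g$pP <- prod1[g$ping]; g$pQ <- prod2[g$ping]
    for (nm in c("Keq", "Kia", "Kiq", "Kma", "Kmb", "Kmp", "Kmq",
                 "Vf", "Vr"))
      g[[paste0("p", nm)]] <- pv(g$ping, nm)
  }
  g
}

# vectorized signed rates from a compiled plan (x clipped at 0 by callers)
ratesPlan <- function(g, x) {
  v <- numeric(g$nR)
  if (length(g$irr)) {
    S <- x[g$iS]
    v[g$irr] <- g$iV * S / (g$iKm + S)
  }
  if (length(g$rev)) {
    S <- x[g$rS] / g$rKms; P <- x[g$rP] / g$rKmp
    v[g$rev] <- (g$rVf * S - g$rVr * P) / (1 + S + P)
  }
  if (length(g$ping)) {
    A <- x[g$pA]; B <- x[g$pB]; P <- x[g$pP]; Q <- x[g$pQ]
    num <- g$pVf * g$pVr * (A * B - P * Q / g$pKeq)
    den <- g$pVr * g$pKmb * A + g$pVr * g$pKma * B + g$pVr * A * B +
      g$pVf * g$pKmq * P / g$pKeq + g$pVf * g$pKmp * Q / g$pKeq +
      g$pVf * P * Q / g$pKeq + g$pVr * g$pKma * B * Q / g$pKiq +
      g$pVf * g$pKmq * A * P / (g$pKia * g$pKeq)
    v[g$ping] <- ifelse(den > 0, num / den, 0)
  }
  v
}

# vectorized analytic dv/dx (reaction x species) from a compiled plan
dvdxPlan <- function(g, x) {
  J <- matrix(0, g$nR, g$nS)
  add <- function(J, rows, cols, val) {
    J[cbind(rows, cols)] <- J[cbind(rows, cols)] + val
    J
  }
  if (length(g$irr)) {
    S <- x[g$iS]
    J <- add(J, g$irr, g$iS, g$iV * g$iKm / (g$iKm + S)^2)
  }
  if (length(g$rev)) {
    S <- x[g$rS] / g$rKms; P <- x[g$rP] / g$rKmp
    den <- 1 + S + P
    num <- g$rVf * S - g$rVr * P
    J <- add(J, g$rev, g$rS, (g$rVf * den - num) / (g$rKms * den^2))
    J <- add(J, g$rev, g$rP, (-g$rVr * den - num) / (g$rKmp * den^2))
  }
  if (length(g$ping)) {
    A <- x[g$pA]; B <- x[g$pB]; P <- x[g$pP]; Q <- x[g$pQ]
    num <- g$pVf * g$pVr * (A * B - P * Q / g$pKeq)
    den <- g$pVr * g$pKmb * A + g$pVr * g$pKma * B + g$pVr * A * B +
      g$pVf * g$pKmq * P / g$pKeq + g$pVf * g$pKmp * Q / g$pKeq +
      g$pVf * P * Q / g$pKeq + g$pVr * g$pKma * B * Q / g$pKiq +
      g$pVf * g$pKmq * A * P / (g$pKia * g$pKeq)
    ok <- den > 0
    d2 <- ifelse(ok, den^2, 1)
    dd <- function(dnum, dden) ifelse(ok, (dnum * den - num * dden) / d2, 0)
    J <- add(J, g$ping, g$pA,
             dd(g$pVf * g$pVr * B,
                g$pVr * g$pKmb + g$pVr * B +
                  g$pVf * g$pKmq * P / (g$pKia * g$pKeq)))
    J <- add(J, g$ping, g$pB,
             dd(g$pVf * g$pVr * A,
                g$pVr * g$pKma + g$pVr * A + g$pVr * g$pKma * Q / g$pKiq))
    J <- add(J, g$ping, g$pP,
             dd(-g$pVf * g$pVr * Q / g$pKeq,
                g$pVf * g$pKmq / g$pKeq + g$pVf * Q / g$pKeq +
                  g$pVf * g$pKmq * A / (g$pKia * g$pKeq)))
    J <- add(J, g$ping, g$pQ,
             dd(-g$pVf * g$pVr * P / g$pKeq,
                g$pVf * g$pKmp / g$pKeq + g$pVf * P / g$pKeq +
                  g$pVr * g$pKma * B / g$pKiq))
  }
  J
}

#' Reaction rates at a state
#' @param net a [ReactionNetwork-class]
#' @param state full named state vector (uM)
#' @return signed rates (uM/h), one per reaction
#' @export
reactionRates <- function(net, state) {
  g <- compileNetwork(net)
  state <- pmax(state[speciesIds(net)], 0)
  stats::setNames(ratesPlan(g, state), paste0("r", net@reactions$index))
}

# dv/dx over the full species set, by analytic kernel differentiation
rateJacobianFull <- function(net, state, plan = compileNetwork(net)) {
  x <- pmax(state[speciesIds(net)], 0)
  J <- dvdxPlan(plan, x)
  dimnames(J) <- list(paste0("r", net@reactions$index), speciesIds(net))
  J
}

# indices of ODE state species for a given ATP mode
dynamicIndices <- function(net, atp) {
  ids <- speciesIds(net)
  dyn <- !net@species$boundary
  if (atp$mode == "forced" && all(c("ATP", "ADP") %in% ids))
    dyn <- dyn & !(ids %in% c("ATP", "ADP"))
  which(dyn)
}

#' Simulate a network time course
#'
#' Integrates dx/dt = S v(x) with a stiff adaptive solver (the rate
#' constants of the shipped model span more than ten orders of magnitude).
#' In forced ATP mode the ATP/ADP pair is imposed from the depletion curve;
#' in dynamic mode it is part of the state and the sink of the
#' [atpModel()] applies. Boundary species are held constant.
#'
#' @param net a [ReactionNetwork-class]
#' @param x0 named initial state (uM); defaults to the network's
#' @param times increasing output grid, h
#' @param atp an [atpModel()]
#' @param rtol,atol relative/absolute integrator tolerances
#' @return a [Trajectory-class] with full states, per-reaction fluxes and
#'   observable group sums at every output time
#' @examples
#' traj <- simulateNetwork(buildNetwork(), times = seq(0, 17, 1))
#' @export
simulateNetwork <- function(net, x0 = initialState(net),
                            times = seq(0, 17, by = 0.1),
                            atp = atpModel(), rtol = 1e-8, atol = 1e-9) {
  stopifnot(all(diff(times) > 0), all(x0 >= 0))
  ids <- speciesIds(net)
  x0 <- x0[ids]
  if (anyNA(x0)) stop("x0 must name every species")
  plan <- compileNetwork(net)
  dynIdx <- dynamicIndices(net, atp)
  forced <- atp$mode == "forced" && all(c("ATP", "ADP") %in% ids)
  if (forced) {
    atp0 <- x0[["ATP"]]; pool <- x0[["ATP"]] + x0[["ADP"]]
  }
  hasAtp <- all(c("ATP", "ADP") %in% ids)
  iATP <- match("ATP", ids); iADP <- match("ADP", ids)

  fullState <- function(t, y) {
    x <- x0
    x[dynIdx] <- y
    if (forced) {
      x[iATP] <- atp0 * atpRelative(t, atp)
      x[iADP] <- pool - x[iATP]
    }
    x
  }
  Sfull <- stoichiometryMatrix(net)
  dynSink <- !forced && hasAtp && atp$mode == "dynamic" && atp$kAtp > 0
  deriv <- function(t, y, parms) {
    x <- pmax(fullState(t, y), 0)
    v <- ratesPlan(plan, x)
    dx <- as.numeric(Sfull %*% v)
    if (dynSink) {
      sink <- atp$kAtp * x[iATP]
      dx[iATP] <- dx[iATP] - sink
      dx[iADP] <- dx[iADP] + sink
    }
    list(dx[dynIdx])
  }
  sol <- deSolve::lsoda(y = x0[dynIdx], times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (nrow(sol) < length(times)) {
    tFail <- times[nrow(sol) + 1]
    stop(sprintf("integration failed at t = %.4g h (diagnostics: %s)",
                 tFail, paste(attr(sol, "istate"), collapse = " ")))
  }
  states <- matrix(NA_real_, length(times), length(ids),
                   dimnames = list(NULL, ids))
  for (i in seq_along(times))
    states[i, ] <- fullState(times[i], sol[i, -1])
  neg <- states < 0
  if (any(neg)) {
    warning(sprintf("clipping %d negative concentration values (min %.3g uM) to 0",
                    sum(neg), min(states)))
    states[neg] <- 0
  }
  fluxes <- matrix(NA_real_, length(times), plan$nR,
                   dimnames = list(NULL, paste0("r", net@reactions$index)))
  for (i in seq_along(times))
    fluxes[i, ] <- ratesPlan(plan, states[i, ])
  obs <- applyObservables(net, states)
  new("Trajectory", times = times, states = states, fluxes = fluxes,
      observables = obs, atpMode = atp$mode)
}

#' Dominant resultant fluxes per time window
#'
#' Ranks reactions by the absolute time-averaged (trapezoidal) flux inside
#' each window, reporting the signed mean so reverse fluxes are visible.
#' Reactions whose mean flux is exactly zero are dropped from the ranking.
#'
#' @param traj a [Trajectory-class]
#' @param windows list of c(t0, t1) pairs, h
#' @param net optional [ReactionNetwork-class] to label reactions by enzyme
#' @return data.frame(window, rank, reaction, enzyme, meanFlux)
#' @export
fluxReport <- function(traj, windows, net = NULL) {
  if (!length(windows)) stop("no windows given")
  if (!is.list(windows)) windows <- list(windows)
  out <- list()
  for (w in windows) {
    stopifnot(length(w) == 2, w[1] < w[2])
    sel <- traj@times >= w[1] & traj@times <= w[2]
    if (sum(sel) < 2)
      stop(sprintf("window [%g, %g] contains fewer than two grid points",
                   w[1], w[2]))
    tt <- traj@times[sel]
    f <- traj@fluxes[sel, , drop = FALSE]
    wts <- diff(tt)
    avg <- apply(f, 2, function(v)
      sum((v[-1] + v[-length(v)]) / 2 * wts) / (max(tt) - min(tt)))
    keep <- which(avg != 0)
    ord <- keep[order(-abs(avg[keep]))]
    if (!length(ord)) next
    lab <- if (is.null(net)) colnames(traj@fluxes)[ord] else
      net@reactions$ec[ord]
    out[[length(out) + 1]] <- data.frame(
      windowStart = w[1], windowEnd = w[2], rank = seq_along(ord),
      reaction = colnames(traj@fluxes)[ord], enzyme = lab,
      meanFlux = unname(avg[ord]))
  }
  if (!length(out))
    return(data.frame(windowStart = numeric(), windowEnd = numeric(),
                      rank = integer(), reaction = character(),
                      enzyme = character(), meanFlux = numeric()))
  do.call(rbind, out)
}

#' Find a steady state
#'
#' Long stiff integration over expanding horizons followed by Newton
#' polishing. The Newton step solves the stacked least-squares system
#' [J; C] d = [-f; 0], where C holds the network's conservation vectors
#' (computed as the numerical left null space of the dynamic stoichiometry
#' submatrix), so conserved totals - e.g. total fluorine - are preserved
#' exactly and structurally singular directions are handled. In forced ATP
#' mode the reference has ATP at its depleted asymptote (0) with ADP
#' carrying the adenylate pool.
#'
#' @param net a [ReactionNetwork-class]
#' @param x0 starting state; defaults to the network's initial state
#' @param atp an [atpModel()]
#' @param tol convergence threshold on max |dx/dt| (uM/h)
#' @param tmax largest integration horizon tried, h
#' @return list(state, fluxes, residual, converged, nonVanishing); if no
#'   convergence within the horizon, converged = FALSE is returned
#'   explicitly (with a warning), never a silent partial answer
#' @export
steadyState <- function(net, x0 = initialState(net), atp = atpModel(),
                        tol = 1e-8, tmax = 1e6) {
  ids <- speciesIds(net)
  x0 <- x0[ids]
  plan <- compileNetwork(net)
  dynIdx <- dynamicIndices(net, atp)
  forced <- atp$mode == "forced" && all(c("ATP", "ADP") %in% ids)
  x <- x0
  if (forced) {  # depleted asymptote of the forced curve
    pool <- x[["ATP"]] + x[["ADP"]]
    x[["ATP"]] <- 0; x[["ADP"]] <- pool
  }
  Sfull <- stoichiometryMatrix(net)
  Sdyn <- Sfull[dynIdx, , drop = FALSE]
  fDyn <- function(x) as.numeric(Sdyn %*% reactionRatesPlan(plan, x, net))

  # sink appended in dynamic mode enters derivatives but not Sdyn; handle by
  # augmenting f directly
  hasAtp <- all(c("ATP", "ADP") %in% ids)
  iATP <- match("ATP", ids)
  addSink <- !forced && hasAtp && atp$mode == "dynamic" && atp$kAtp > 0
  fWithSink <- function(x) {
    f <- fDyn(x)
    if (addSink) {
      d <- match(c(match("ATP", ids), match("ADP", ids)), dynIdx)
      f[d[1]] <- f[d[1]] - atp$kAtp * x[iATP]
      f[d[2]] <- f[d[2]] + atp$kAtp * x[iATP]
    }
    f
  }

  # stage 1: relax by integration
  horizon <- 100
  repeat {
    traj <- simulateNetwork(net, x, times = c(0, horizon), atp = atpFixed(atp),
                            rtol = 1e-10, atol = 1e-12)
    x[dynIdx] <- traj@states[2, dynIdx]
    if (max(abs(fWithSink(x))) < 1e-3 || horizon >= tmax) break
    horizon <- horizon * 10
  }

  # stage 2: Newton polish on the dynamic subspace with conservation rows
  Cons <- conservationVectors(Sdyn)
  for (it in 1:60) {
    f <- fWithSink(x)
    if (max(abs(f)) < max(tol * 1e-4, 1e-13)) break
    dvdx <- rateJacobianFull(net, x, plan)[, dynIdx, drop = FALSE]
    J <- Sdyn %*% dvdx
    if (addSink) {
      d <- match(c(match("ATP", ids), match("ADP", ids)), dynIdx)
      J[d[1], d[1]] <- J[d[1], d[1]] - atp$kAtp
      J[d[2], d[1]] <- J[d[2], d[1]] + atp$kAtp
    }
    A <- rbind(J, Cons)
    b <- c(-f, rep(0, nrow(Cons)))
    step <- tryCatch(qr.solve(A, b, tol = 1e-14),
                     error = function(e) as.numeric(MASS::ginv(A) %*% b))
    lam <- 1
    for (half in 1:40) {
      xn <- x
      xn[dynIdx] <- x[dynIdx] + lam * step
      if (all(xn[dynIdx] >= -1e-12)) break
      lam <- lam / 2
    }
    xn[dynIdx] <- pmax(xn[dynIdx], 0)
    if (max(abs(fWithSink(xn))) >= max(abs(f)) && lam == 1) {
      lam <- 0.25
      xn[dynIdx] <- pmax(x[dynIdx] + lam * step, 0)
    }
    x <- xn
  }
  res <- max(abs(fWithSink(x)))
  conv <- res < tol
  if (!conv)
    warning(sprintf("steady state not converged: max |dx/dt| = %.3g uM/h after horizon %g h",
                    res, horizon))
  v <- reactionRatesPlan(plan, x, net)
  names(v) <- paste0("r", net@reactions$index)
  list(state = x, fluxes = v, residual = res, converged = conv,
       nonVanishing = ids[x > 1e-6])
}

# internal: rates from a precompiled plan
reactionRatesPlan <- function(plan, x, net) {
  ratesPlan(plan, pmax(x[speciesIds(net)], 0))
}

# forced ATP curve frozen at its asymptote, for relaxation integrations that
# start from an already-depleted state
atpFixed <- function(atp) {
  if (atp$mode != "forced") return(atp)
  a <- atp
  a$t50 <- 1e-12  # curve ~0 for all t > 0
  a
}

# numerical left null space (conservation vectors) of a stoichiometry block
conservationVectors <- function(S) {
  if (!nrow(S)) return(matrix(0, 0, 0))
  sv <- svd(t(S), nu = 0, nv = nrow(S))
  d <- c(sv$d, rep(0, nrow(S) - length(sv$d)))
  null <- which(d < max(d, 1) * 1e-10)
  t(sv$v[, null, drop = FALSE])
}
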