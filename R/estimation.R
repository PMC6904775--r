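#' Fit protocol settings
#'
#' Bundles the pattern-search protocol: Hooke-Jeeves iteration limit 50,
#' tolerance 1e-5 on the pattern step, step-shrink factor rho 0.2,
#' inverse-variance ("scaled standard deviation") weighting, an objective
#' pre-minimization threshold of 0.15, consecutive-attempt convergence when
#' the objective changes by less than 1e-6, and retention of the five most
#' accurate attempts for the fit statistics.
#'
#' @param itLim Hooke-Jeeves iteration limit per stage
#' @param tol termination threshold on the exploratory step size
#' @param rho step shrink factor in (0, 1)
#' @param preminThreshold target objective for the pre-minimization stage
#' @param convergenceThreshold objective variation between consecutive
#'   stages below which an attempt is converged
#' @param nBest number of most accurate attempts retained for statistics
#' @param maxStages cap on consecutive stages per attempt
#' @export
fitProtocol <- function(itLim = 50, tol = 1e-5, rho = 0.2,
                        preminThreshold = 0.15,
                        convergenceThreshold = 1e-6, nBest = 5,
                        maxStages = 25) {
  stopifnot(itLim >= 1, tol > 0, rho > 0, rho < 1, preminThreshold > 0,
            convergenceThreshold > 0, nBest >= 1, maxStages >= 1)
  list(itLim = itLim, tol = tol, rho = rho,
       preminThreshold = preminThreshold,
       convergenceThreshold = convergenceThreshold, nBest = nBest,
       maxStages = maxStages)
}

#' Free-parameter view of a network
#'
#' `free` names the searched coordinates as "group.name" (e.g. "g3.Vf") for
#' rate-law parameters or "init.<species>" for initial concentrations.
#' Fixed parameters and link targets are rejected. `freeParameters()` lists
#' every legal coordinate.
#'
#' @param net a [ReactionNetwork-class]
#' @return character vector of coordinate names
#' @export
freeParameters <- function(net) {
  out <- character()
  for (g in names(net@paramGroups)) {
    for (nm in names(net@paramGroups[[g]])) {
      if (any(net@paramFixed$group == g & net@paramFixed$name == nm)) next
      if (any(net@paramLinks$group == g & net@paramLinks$name == nm)) next
      out <- c(out, paste0(g, ".", nm))
    }
  }
  c(out, paste0("init.", speciesIds(net)))
}

getFreeParams <- function(net, free) {
  vapply(free, function(f) {
    p <- strsplit(f, ".", fixed = TRUE)[[1]]
    if (p[1] == "init") unname(initialState(net)[p[2]])
    else unname(resolveParams(net, p[1])[p[2]])
  }, numeric(1))
}

setFreeParams <- function(net, free, values) {
  for (i in seq_along(free)) {
    p <- strsplit(free[i], ".", fixed = TRUE)[[1]]
    if (p[1] == "init")
      net@species$initial[match(p[2], net@species$id)] <- values[i]
    else net <- setParameter(net, p[1], p[2], values[i])
  }
  net
}

#' Weighted least-squares objective for observable time courses
#'
#' Simulates the network at the data's time points, applies the observable
#' grouping and returns \eqn{\sum_s w_s \sum_t (model - observed)^2}. The
#' default "scaled standard deviation" weights are inverse variances,
#' \eqn{w_s = 1/sd(observed_s)^2}, so every series contributes on a common
#' scale regardless of its concentration range. A failed simulation returns
#' +Inf (with the cause recorded as a warning) so a surrounding search can
#' continue.
#'
#' @param net a [ReactionNetwork-class] carrying the candidate parameters
#' @param data data.frame with a `time` column and one column per observable
#'   group to fit (columns absent from the network's grouping are ignored)
#' @param weights optional named per-series weights; default inverse
#'   variance of each observed series
#' @param atp an [atpModel()]
#' @param x0 initial state override
#' @return non-negative scalar; 0 iff the model reproduces the data exactly
#' @export
wlsObjective <- function(net, data, weights = NULL, atp = atpModel(),
                         x0 = initialState(net)) {
  stopifnot("time" %in% names(data))
  series <- intersect(names(data), names(net@observables))
  if (!length(series)) stop("data contains no known observable column")
  if (is.null(weights)) {
    # inverse-variance weights; the sd is floored at a small fraction of the
    # series scale so that conserved (constant) series such as total
    # fluorine cannot blow up the weight through numerical wiggle
    weights <- vapply(series, function(s) {
      v <- stats::sd(data[[s]])
      floor <- 1e-6 * max(abs(data[[s]]), 1)
      v <- max(if (is.finite(v)) v else 0, floor)
      1 / v^2
    }, numeric(1))
  }
  if (any(weights <= 0)) stop("weights must be positive")
  tGrid <- data$time
  t0 <- min(0, tGrid)
  times <- sort(unique(c(t0, tGrid)))
  traj <- tryCatch(
    suppressWarnings(simulateNetwork(net, x0 = x0, times = times,
                                     atp = atp)),
    error = function(e) e)
  if (inherits(traj, "error")) {
    warning("simulation failed in objective: ", conditionMessage(traj))
    return(Inf)
  }
  idx <- match(tGrid, traj@times)
  obj <- 0
  for (s in series) {
    r <- traj@observables[idx, s] - data[[s]]
    obj <- obj + weights[[s]] * sum(r^2)
  }
  obj
}

#' Hooke-Jeeves pattern search
#'
#' Derivative-free minimization alternating exploratory coordinate moves
#' with pattern (extrapolation) moves; the exploratory step shrinks by `rho`
#' whenever no move improves, and the search stops when the step drops
#' below `tol` or `itLim` exploratory cycles are spent. Deterministic for a
#' given start.
#'
#' @param f objective function of a numeric vector
#' @param x0 finite start point within bounds
#' @param lower,upper box bounds (recycled)
#' @param rho step shrink factor in (0, 1)
#' @param tol termination threshold on the step size
#' @param itLim maximum exploratory cycles
#' @param stepInit initial step size (recycled); default 10% of the box or
#'   0.5 for unbounded coordinates
#' @return list(par, value, iterations, converged, boundsActive)
#' @export
hookeJeeves <- function(f, x0, lower = -Inf, upper = Inf, rho = 0.2,
                        tol = 1e-5, itLim = 50, stepInit = NULL) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  stopifnot(all(is.finite(x0)), all(x0 >= lower), all(x0 <= upper),
            rho > 0, rho < 1, tol > 0)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  if (is.null(stepInit)) {
    span <- upper - lower
    stepInit <- ifelse(is.finite(span), 0.1 * span, 0.5)
  }
  h <- rep_len(stepInit, n)
  fb <- f(x0)
  if (!is.finite(fb)) stop("objective not finite at the start point")

  explore <- function(x, fx) {
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        xt <- x; xt[i] <- min(max(x[i] + s * h[i], lower[i]), upper[i])
        if (xt[i] == x[i]) next
        ft <- f(xt)
        if (is.finite(ft) && ft < fx) { x <- xt; fx <- ft; break }
      }
    }
    list(x = x, f = fx)
  }

  b <- x0
  it <- 0
  while (it < itLim && max(h) >= tol) {
    it <- it + 1
    e <- explore(b, fb)
    if (e$f < fb) {
      # pattern moves: extrapolate along the improvement direction
      repeat {
        xp <- clamp(2 * e$x - b)
        b <- e$x; fb <- e$f
        fp <- f(xp)
        e2 <- explore(xp, if (is.finite(fp)) fp else Inf)
        if (e2$f < fb) e <- e2 else break
      }
    } else {
      h <- h * rho
    }
  }
  active <- b <= lower + 1e-12 * pmax(abs(lower), 1) |
    b >= upper - 1e-12 * pmax(abs(upper), 1)
  list(par = b, value = fb, iterations = it,
       converged = max(h) < tol, boundsActive = active & is.finite(lower))
}

#' Multi-start Hooke-Jeeves fit with per-parameter statistics
#'
#' Runs the staged estimation protocol on the selected free parameters,
#' searching in log10 space (the model's parameter values span many orders
#' of magnitude). Each attempt starts from a log-uniform draw within the
#' bounds (default +/- `decades` decades around the current registry
#' values), is pre-minimized once, then re-launched from its own result
#' until the objective improves by less than the convergence threshold.
#' The `nBest` most accurate attempts are retained and summarized per
#' parameter as bfv (best-fit value), avg, stds (sample standard deviation)
#' and devStds = |bfv - avg|/stds (0 when stds is 0).
#'
#' @param net a [ReactionNetwork-class]
#' @param data observable time-course data.frame (see [wlsObjective()])
#' @param free character vector of free-coordinate names (see
#'   [freeParameters()])
#' @param protocol a [fitProtocol()]
#' @param nAttempts number of starts (must be >= protocol$nBest)
#' @param seed integer seed; the whole fit is reproducible from it
#' @param decades half-width of the log10 search box around start values
#' @param atp an [atpModel()]
#' @param startAtCurrent if TRUE the first attempt starts at the registry
#'   values instead of a random draw
#' @return a [FitResult-class]
#' @export
multistartFit <- function(net, data, free, protocol = fitProtocol(),
                          nAttempts = 10, seed = 1, decades = 3,
                          atp = atpModel(), startAtCurrent = FALSE) {
  if (nAttempts < protocol$nBest)
    stop("nAttempts must be at least protocol$nBest")
  p0 <- getFreeParams(net, free)
  if (any(p0 <= 0))
    stop("log-space search requires positive start values for all free parameters")
  l0 <- log10(p0)
  lower <- l0 - decades; upper <- l0 + decades
  fLog <- function(lp) {
    n2 <- setFreeParams(net, free, 10^lp)
    suppressWarnings(wlsObjective(n2, data, atp = atp))
  }

  set.seed(seed)
  starts <- matrix(stats::runif(nAttempts * length(free)), nAttempts)
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  if (startAtCurrent) starts[1, ] <- l0

  attempts <- vector("list", nAttempts)
  for (a in seq_len(nAttempts)) {
    x <- starts[a, ]
    f0 <- fLog(x)
    if (!is.finite(f0)) {
      attempts[[a]] <- list(ok = FALSE, start = starts[a, ],
                            startObjective = f0, objective = Inf,
                            stages = 0L, preMinimized = FALSE,
                            par = rep(NA_real_, length(free)))
      next
    }
    r <- hookeJeeves(fLog, x, lower, upper, rho = protocol$rho,
                     tol = protocol$tol, itLim = protocol$itLim)
    stages <- 1L
    trace <- r$value
    while (stages < protocol$maxStages) {
      r2 <- hookeJeeves(fLog, r$par, lower, upper, rho = protocol$rho,
                        tol = protocol$tol, itLim = protocol$itLim)
      stages <- stages + 1L
      trace <- c(trace, r2$value)
      improved <- r$value - r2$value
      r <- r2
      if (improved < protocol$convergenceThreshold) break
    }
    attempts[[a]] <- list(ok = TRUE, start = starts[a, ],
                          startObjective = f0,
                          objective = r$value, stages = stages,
                          preMinimized = trace[1] < protocol$preminThreshold,
                          par = 10^r$par)
  }

  obj <- vapply(attempts, `[[`, numeric(1), "objective")
  okIdx <- which(is.finite(obj))
  if (length(okIdx) < protocol$nBest)
    warning(sprintf("only %d of %d attempts succeeded; statistics use all of them",
                    length(okIdx), nAttempts))
  retained <- okIdx[order(obj[okIdx])][seq_len(min(protocol$nBest,
                                                   length(okIdx)))]
  if (!length(retained)) stop("no attempt produced a finite objective")
  best <- retained[1]
  parMat <- do.call(rbind, lapply(attempts[retained], `[[`, "par"))
  colnames(parMat) <- free
  bfv <- parMat[1, ]
  avg <- colMeans(parMat)
  stds <- apply(parMat, 2, stats::sd)
  stds[is.na(stds)] <- 0
  devStds <- ifelse(stds > 0, abs(bfv - avg) / stds, 0)

  attTab <- data.frame(
    attempt = seq_len(nAttempts),
    startObjective = vapply(attempts, `[[`, numeric(1), "startObjective"),
    objective = obj,
    stages = vapply(attempts, `[[`, integer(1), "stages"),
    preMinimized = vapply(attempts, `[[`, logical(1), "preMinimized"),
    retained = seq_len(nAttempts) %in% retained)

  new("FitResult",
      par = data.frame(parameter = free, bfv = unname(bfv),
                       avg = unname(avg), stds = unname(stds),
                       devStds = unname(devStds)),
      objective = unname(obj[best]), attempts = attTab,
      protocol = protocol, seed = as.integer(seed))
}

#' Predicted-vs-observed fit quality
#'
#' Pools every fitted observable series and regresses model predictions on
#' observations; returns the coefficient of determination R^2 together with
#' the pooled pairs.
#'
#' @param net a [ReactionNetwork-class] carrying fitted parameters
#' @param data the observable time-course data the model was fitted to
#' @param atp an [atpModel()]
#' @return list(r2, pairs = data.frame(series, time, observed, predicted))
#' @export
fitQuality <- function(net, data, atp = atpModel()) {
  series <- intersect(names(data), names(net@observables))
  tGrid <- data$time
  times <- sort(unique(c(min(0, tGrid), tGrid)))
  traj <- simulateNetwork(net, times = times, atp = atp)
  idx <- match(tGrid, traj@times)
  pairs <- do.call(rbind, lapply(series, function(s)
    data.frame(series = s, time = tGrid, observed = data[[s]],
               predicted = traj@observables[idx, s])))
  fit <- stats::lm(predicted ~ observed, data = pairs)
  list(r2 = summary(fit)$r.squared, pairs = pairs)
}
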