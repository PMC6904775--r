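#' Generate a synthetic NMR-style observable time course
#'
#' Forward-simulates the network from its generating parameters, applies
#' the observable grouping and adds relative Gaussian noise, emulating the
#' study design the package targets: hourly 19F spectra over 1-17 h of six
#' observable groups with the fluorinated pools normalized to 1 mM total,
#' under forced ATP depletion. The t = 0 point is excluded from the
#' "observed" table (the experiment has no time-zero spectrum); the sealed
#' ground truth keeps it.
#'
#' The default 5% relative noise approximates the integration error of a
#' 1-h, 488-scan spectrum. Noisy values are truncated at 0. Everything is a
#' pure function of (configuration, seed).
#'
#' @param net generating network; defaults to [buildNetwork()]
#' @param times observation grid, h
#' @param noiseSd relative Gaussian noise standard deviation per point
#' @param seed integer seed (mandatory when noiseSd > 0)
#' @param atp an [atpModel()]
#' @param x0 generating initial state
#' @return list(observed = data.frame(time, groups...),
#'   truth = list(noiseless data.frame incl. t = 0, x0, seed, noiseSd))
#' @export
generateTimeCourse <- function(net = buildNetwork(), times = 1:17,
                               noiseSd = 0.05, seed = NULL,
                               atp = atpModel(), x0 = initialState(net)) {
  stopifnot(noiseSd >= 0)
  if (noiseSd > 0 && is.null(seed))
    stop("a seed is mandatory for noisy output")
  grid <- sort(unique(c(0, times)))
  traj <- simulateNetwork(net, x0 = x0, times = grid, atp = atp)
  clean <- data.frame(time = grid, traj@observables, check.names = FALSE)
  obs <- clean[match(times, grid), , drop = FALSE]
  rownames(obs) <- NULL
  if (noiseSd > 0) {
    set.seed(seed)
    for (s in setdiff(names(obs), "time"))
      obs[[s]] <- pmax(obs[[s]] * (1 + stats::rnorm(nrow(obs), 0, noiseSd)),
                       0)
  }
  list(observed = obs,
       truth = list(noiseless = clean, x0 = x0, seed = seed,
                    noiseSd = noiseSd))
}

#' Generate a relative ATP depletion curve
#'
#' The 31P-observable: relative ATP level with ATP(0) = 1, non-increasing,
#' at or below 0.5 by the half-time and below 0.05 by 4 h under the default
#' shape. Optional relative noise applies to t > 0 points only (the t = 0
#' anchor is the normalization).
#'
#' @param times grid, h (must include only t >= 0)
#' @param atp an [atpModel()] providing the forced-curve parameters
#' @param noiseSd relative Gaussian noise
#' @param seed integer seed (mandatory when noiseSd > 0)
#' @return data.frame(time, atp) with atp relative to t = 0
#' @export
generateAtpCurve <- function(times = 0:17, atp = atpModel(),
                             noiseSd = 0, seed = NULL) {
  stopifnot(noiseSd >= 0)
  if (noiseSd > 0 && is.null(seed))
    stop("a seed is mandatory for noisy output")
  a <- atpRelative(times, atp)
  if (noiseSd > 0) {
    set.seed(seed)
    jitter <- 1 + stats::rnorm(length(a), 0, noiseSd)
    jitter[times == 0] <- 1
    a <- pmax(a * jitter, 0)
  }
  data.frame(time = times, atp = a)
}

#' Generate a synthetic dose-survival table
#'
#' Draws replicate survival values around the Hill dose-survival curve with
#' relative Gaussian noise, truncated to [0, 100]%, mirroring a plating
#' assay with five independent repetitions per dose.
#'
#' @param ec50,hill generating Hill parameters (dose unit follows `doses`)
#' @param doses positive dose levels
#' @param replicates replicates per dose
#' @param noiseSd relative Gaussian noise on survival
#' @param seed integer seed (mandatory when noiseSd > 0)
#' @return data.frame(dose, replicate, survival)
#' @examples
#' generateDoseSurvival(18, 0.51, doses = c(1, 10, 100, 1000),
#'                      noiseSd = 0, replicates = 2)
#' @export
generateDoseSurvival <- function(ec50 = 18, hill = 0.51,
                                 doses = 10^seq(0, 4, length.out = 8),
                                 replicates = 5, noiseSd = 0.10,
                                 seed = NULL) {
  stopifnot(all(doses > 0), replicates >= 1, noiseSd >= 0)
  if (noiseSd > 0 && is.null(seed))
    stop("a seed is mandatory for noisy output")
  mu <- hillSurvival(doses, ec50, hill)
  out <- data.frame(dose = rep(doses, each = replicates),
                    replicate = rep(seq_len(replicates), length(doses)),
                    survival = rep(mu, each = replicates))
  if (noiseSd > 0) {
    set.seed(seed)
    out$survival <- pmin(pmax(
      out$survival * (1 + stats::rnorm(nrow(out), 0, noiseSd)), 0), 100)
  }
  out
}
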