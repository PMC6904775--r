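#' Hill dose-survival model
#'
#' Percent survival at a given dose,
#' \eqn{survival(d) = 100/(1+(d/EC_{50})^{h})}: 100\% at zero dose, 50\% at
#' the EC50, strictly decreasing in dose for a positive Hill exponent h.
#' Dose and EC50 must share a unit; the model is scale-free in it.
#'
#' @param dose non-negative dose(s)
#' @param ec50 positive half-effect dose, same unit as `dose`
#' @param hill Hill exponent (dimensionless)
#' @return percent survival in [0, 100]
#' @examples
#' hillSurvival(18, 18, 0.51)  # 50
#' @export
hillSurvival <- function(dose, ec50, hill) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and non-negative")
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be positive")
  100 / (1 + (dose / ec50)^hill)
}

#' Fit the Hill dose-survival model
#'
#' Nonlinear least squares in log-dose space: survival is modeled as
#' 100/(1 + exp(h (log d - log EC50))) and (log EC50, h) estimated by
#' Levenberg-Marquardt, which makes the fit equivariant under rescaling the
#' dose unit. Standard errors come from the fit Jacobian; the 95% pointwise
#' confidence band for the mean curve uses the delta method.
#'
#' Data with no identifiable decreasing trend (e.g. survival increasing
#' with dose, or flat) fail explicitly.
#'
#' @param dose positive doses (replicates as repeated values)
#' @param survival percent survival in [0, 100], same length as dose
#' @return a [DoseResponseFit-class]
#' @examples
#' d <- rep(c(1, 10, 100, 1000), each = 3)
#' fitDoseResponse(d, hillSurvival(d, 18, 0.51))
#' @export
fitDoseResponse <- function(dose, survival) {
  stopifnot(length(dose) == length(survival))
  if (any(dose <= 0)) stop("doses must be positive (log-dose fit)")
  if (length(unique(dose)) < 4)
    stop("at least 4 distinct dose levels are required")
  df <- data.frame(ld = log(dose), y = survival)
  slope <- stats::coef(stats::lm(y ~ ld, df))[2]
  if (!is.finite(slope) || slope >= 0)
    stop("not identifiable: survival does not decrease with dose")
  # start: EC50 near where the observed survival crosses 50%
  lec0 <- df$ld[which.min(abs(df$y - 50))]
  fit <- minpack.lm::nlsLM(y ~ 100 / (1 + exp(h * (ld - lec))),
                           data = df,
                           start = list(lec = lec0, h = max(-slope / 25, 0.1)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["h"]] <= 0) stop("not identifiable: non-positive Hill exponent")
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  ec50 <- exp(cf[["lec"]])
  new("DoseResponseFit",
      ec50 = ec50, hill = cf[["h"]],
      se = c(ec50 = ec50 * se[["lec"]], hill = se[["h"]]),
      vcov = stats::vcov(fit),
      data = data.frame(dose = dose, survival = survival))
}

#' Predicted survival and 95% confidence band from a fit
#' @param fit a [DoseResponseFit-class]
#' @param dose positive doses to predict at
#' @return data.frame(dose, fit, lower, upper) in percent survival
#' @export
predictSurvival <- function(fit, dose) {
  stopifnot(all(dose > 0))
  lec <- log(fit@ec50); h <- fit@hill
  ld <- log(dose)
  mu <- 100 / (1 + exp(h * (ld - lec)))
  # delta method on (lec, h)
  e <- exp(h * (ld - lec))
  dmu <- cbind(lec = 100 * e * h / (1 + e)^2,
               h = -100 * e * (ld - lec) / (1 + e)^2)
  seMu <- sqrt(rowSums((dmu %*% fit@vcov) * dmu))
  z <- stats::qnorm(0.975)
  data.frame(dose = dose, fit = mu,
             lower = pmax(mu - z * seMu, 0),
             upper = pmin(mu + z * seMu, 100))
}

#' Transverse relaxation time from a Lorentzian linewidth
#'
#' For a Lorentzian NMR line the full width at half maximum relates to the
#' transverse (spin-spin) relaxation time as \eqn{T_2 = 1/(\pi \Delta\nu_{1/2})}.
#' A ~17 Hz halfwidth, as observed for the broad fluorinated-RNA signal,
#' corresponds to a T2 of about 20 ms.
#'
#' @param halfwidth full width at half maximum, Hz (positive)
#' @return T2 in seconds
#' @examples
#' t2FromLinewidth(17)    # ~0.019 s
#' t2FromLinewidth(1/pi)  # exactly 1 s
#' @export
t2FromLinewidth <- function(halfwidth) {
  if (any(!is.finite(halfwidth)) || any(halfwidth <= 0))
    stop("halfwidth must be positive")
  1 / (pi * halfwidth)
}

#' @rdname t2FromLinewidth
#' @param t2 transverse relaxation time, seconds (positive)
#' @export
linewidthFromT2 <- function(t2) {
  if (any(!is.finite(t2)) || any(t2 <= 0)) stop("t2 must be positive")
  1 / (pi * t2)
}
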