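#' Enzyme rate-law kernels
#'
#' Closed-form rate laws used by the 5-FU metabolism network: irreversible
#' Michaelis-Menten, reversible Michaelis-Menten, and the reversible
#' Ping Pong Bi Bi mechanism in Cleland's form. Concentrations are in uM and
#' rates in uM/h throughout the package.
#'
#' The reversible Michaelis-Menten law is
#' \deqn{v = \frac{V_f S/K_{ms} - V_r P/K_{mp}}{1 + S/K_{ms} + P/K_{mp}}}
#' and the reversible Ping Pong Bi Bi law is Cleland's two-substrate,
#' two-product substituted-enzyme rate
#' \deqn{v = \frac{V_f V_r (AB - PQ/K_{eq})}{V_r K_{mb} A + V_r K_{ma} B +
#'   V_r A B + V_f K_{mq} P/K_{eq} + V_f K_{mp} Q/K_{eq} + V_f P Q/K_{eq} +
#'   V_r K_{ma} B Q/K_{iq} + V_f K_{mq} A P/(K_{ia} K_{eq})}}
#' whose parameter set \{Keq, Kia, Kiq, Kma, Kmb, Kmp, Kmq, Vf, Vr\} is the
#' one used by common biochemical-network simulators.
#'
#' All kernels return 0 at an all-zero state (a fixed point of the network);
#' if a denominator underflows to zero the rate is returned as 0 with a
#' warning.
#'
#' @param S,P,A,B,Q non-negative concentrations (uM)
#' @param V,Vf,Vr maximal rates (uM/h), non-negative
#' @param Km,Kms,Kmp,Kma,Kmb,Kmq apparent Michaelis constants (uM), positive
#' @param Kia,Kiq inhibition constants (uM), positive
#' @param Keq equilibrium constant (dimensionless), positive
#' @return signed rate in uM/h (irreversible form is non-negative)
#' @examples
#' rateIrrMM(100, V = 10, Km = 100)   # half saturation: 5
#' rateRevMM(0, 0, 1, 1, 1, 1)        # empty state: 0
#' @name rateLaws
NULL

checkConc <- function(...) {
  x <- c(...)
  if (any(!is.finite(x)) || any(x < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  invisible(TRUE)
}

#' @rdname rateLaws
#' @export
rateIrrMM <- function(S, V, Km) {
  checkConc(S)
  stopifnot(V >= 0, Km > 0)
  V * S / (Km + S)
}

#' @rdname rateLaws
#' @export
rateRevMM <- function(S, P, Vf, Vr, Kms, Kmp) {
  checkConc(S, P)
  stopifnot(Vf >= 0, Vr >= 0, Kms > 0, Kmp > 0)
  (Vf * S / Kms - Vr * P / Kmp) / (1 + S / Kms + P / Kmp)
}

#' @rdname rateLaws
#' @export
ratePingPong <- function(A, B, P, Q, Keq, Kia, Kiq, Kma, Kmb, Kmp, Kmq,
                         Vf, Vr) {
  checkConc(A, B, P, Q)
  stopifnot(Keq > 0, Kia > 0, Kiq > 0, Kma > 0, Kmb > 0, Kmp > 0, Kmq > 0,
            Vf >= 0, Vr >= 0)
  num <- Vf * Vr * (A * B - P * Q / Keq)
  den <- Vr * Kmb * A + Vr * Kma * B + Vr * A * B +
    Vf * Kmq * P / Keq + Vf * Kmp * Q / Keq + Vf * P * Q / Keq +
    Vr * Kma * B * Q / Kiq + Vf * Kmq * A * P / (Kia * Keq)
  if (den == 0) {
    if (num != 0) warning("ping-pong denominator underflow; returning 0")
    return(0)
  }
  num / den
}

# Analytic partial derivatives of the kernels with respect to each
# concentration argument; these back the elasticity computation and the
# steady-state Jacobian. Each returns a named vector over the kernel's
# concentration arguments.

dRateIrrMM <- function(S, V, Km) {
  c(S = V * Km / (Km + S)^2)
}

dRateRevMM <- function(S, P, Vf, Vr, Kms, Kmp) {
  den <- 1 + S / Kms + P / Kmp
  num <- Vf * S / Kms - Vr * P / Kmp
  c(S = (Vf / Kms * den - num / Kms) / den^2,
    P = (-Vr / Kmp * den - num / Kmp) / den^2)
}

dRatePingPong <- function(A, B, P, Q, Keq, Kia, Kiq, Kma, Kmb, Kmp, Kmq,
                          Vf, Vr) {
  num <- Vf * Vr * (A * B - P * Q / Keq)
  den <- Vr * Kmb * A + Vr * Kma * B + Vr * A * B +
    Vf * Kmq * P / Keq + Vf * Kmp * Q / Keq + Vf * P * Q / Keq +
    Vr * Kma * B * Q / Kiq + Vf * Kmq * A * P / (Kia * Keq)
  if (den == 0) return(c(A = 0, B = 0, P = 0, Q = 0))
  dnum <- c(A = Vf * Vr * B, B = Vf * Vr * A,
            P = -Vf * Vr * Q / Keq, Q = -Vf * Vr * P / Keq)
  dden <- c(A = Vr * Kmb + Vr * B + Vf * Kmq * P / (Kia * Keq),
            B = Vr * Kma + Vr * A + Vr * Kma * Q / Kiq,
            P = Vf * Kmq / Keq + Vf * Q / Keq + Vf * Kmq * A / (Kia * Keq),
            Q = Vf * Kmp / Keq + Vf * P / Keq + Vr * Kma * B / Kiq)
  (dnum * den - num * dden) / den^2
}
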