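# Closed-form quantities of the constant-rate birth-death process started
# from one individual. All formulas are evaluated through exp(-r*t) so that
# large r*t never overflows; the pure-birth case mu = 0 gets its own analytic
# branch wherever a ratio would otherwise be 0/0.

#' Kendall extinction probability
#'
#' Probability that a single individual has no extant offspring after time
#' `t` under a constant-rate birth-death process:
#' `p0(t) = mu * (exp(r*t) - 1) / (lambda * exp(r*t) - mu)` with
#' `r` `= lambda - mu`. Identically zero in the pure-birth case.
#'
#' @param t Forward time(s); non-negative, vectorised.
#' @param bd A [bd_params()] object.
#' @return Probabilities in `[0, 1)`, one per element of `t`.
#' @examples
#' bd_p0(4, bd_params(0.5, 0.25, 10))
#' @export
bd_p0 <- function(t, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (bd$mu == 0) return(rep(0, length(t)))
  e <- exp(-bd$r * t)
  bd$mu * (-expm1(-bd$r * t)) / (bd$lambda - bd$mu * e)
}

#' Kendall one-lineage probability
#'
#' Probability that a single individual has exactly one extant offspring
#' after time `t`: `p1(t) = r^2 * exp(r*t) / (lambda * exp(r*t) - mu)^2`,
#' which reduces to `exp(-lambda * t)` when `mu = 0` (the Yule offspring
#' count is geometric).
#'
#' @inheritParams bd_p0
#' @return Probabilities in `(0, 1]`, one per element of `t`.
#' @examples
#' bd_p1(3, bd_params(0.5, 0, 10))  # exp(-1.5)
#' @export
bd_p1 <- function(t, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  e <- exp(-bd$r * t)
  bd$r^2 * e / (bd$lambda - bd$mu * e)^2
}

#' Expected population size of the birth-death process
#'
#' The unconditioned expectation grows exponentially: `E[N(t)] = exp(r*t)`
#' (extinct trajectories counted as zero).
#'
#' @inheritParams bd_p0
#' @return Expected sizes, one per element of `t`.
#' @export
bd_expected_size <- function(t, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  exp(bd$r * t)
}

#' Expected population size conditioned on survival
#'
#' Expectation of the population size at time `t` given that the process is
#' still alive at the later time `T = bd$origin`. Conditioning on survival
#' inflates the early part of the curve relative to `exp(r*t)` - the
#' "push of the past". For `0 <= t <= T`,
#' \deqn{E[N(t) \mid N(T) > 0] = \frac{e^{rt}}{1 - p_0(T)}
#'   \left[1 - \frac{(1-\eta_t)^2 z}{(1-\eta_t z)^2}\right],}
#' with \eqn{\eta_t = \lambda p_0(t)/\mu} and \eqn{z = p_0(T - t)}: given
#' \eqn{N(t) = n}, survival to `T` fails with probability \eqn{z^n}, and
#' \eqn{N(t)} is geometric on the positive integers. When `mu = 0` the
#' conditioning is vacuous and the curve is `exp(lambda*t)`.
#'
#' @param t Forward time(s) in `[0, T]`; vectorised.
#' @param bd A [bd_params()] object; `bd$origin` is the survival horizon `T`.
#' @return Conditioned expected sizes, one per element of `t`.
#' @examples
#' bd <- bd_params(0.5, 0.45, 15)
#' bd_expected_size_conditioned(c(0, 5, 15), bd)
#' @export
bd_expected_size_conditioned <- function(t, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(t > bd$origin)) stop("'t' must not exceed the origin time T")
  if (bd$mu == 0) return(exp(bd$lambda * t))
  eta <- bd$lambda * bd_p0(t, bd) / bd$mu
  z <- bd_p0(bd$origin - t, bd)
  bracket <- 1 - (1 - eta)^2 * z / (1 - eta * z)^2
  exp(bd$r * t + log(bracket) - log1p(-bd_p0(bd$origin, bd)))
}

# Auxiliary CDF u(tau) = p0(tau)/p0(T) (extinction time conditioned on
# extinction by T) and the geometric parameter beta = lambda p0(T)/mu of the
# surviving tip count, together with their mu -> 0 limits.
bd_aux_u <- function(tau, bd) {
  if (bd$mu == 0) {
    (-expm1(-bd$lambda * tau)) / (-expm1(-bd$lambda * bd$origin))
  } else {
    bd_p0(tau, bd) / bd_p0(bd$origin, bd)
  }
}

bd_aux_du <- function(tau, bd) {
  # derivative of u: f(tau | T) = mu p1(tau) / p0(T); Yule limit
  if (bd$mu == 0) {
    bd$lambda * exp(-bd$lambda * tau) / (-expm1(-bd$lambda * bd$origin))
  } else {
    bd$mu * bd_p1(tau, bd) / bd_p0(bd$origin, bd)
  }
}

bd_aux_beta <- function(bd) {
  if (bd$mu == 0) -expm1(-bd$lambda * bd$origin)
  else bd$lambda * bd_p0(bd$origin, bd) / bd$mu
}

# h(x) = ((1+x) log(1+x) - x) / x^2 and its derivative, series-protected
# near x = 0 where the closed form cancels.
h_fun <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- 1 / 2 - xs / 6 + xs^2 / 12 - xs^3 / 20
  xl <- x[!small]
  out[!small] <- ((1 + xl) * log1p(xl) - xl) / xl^2
  out
}

h_prime <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- -1 / 6 + xs / 6 - 3 * xs^2 / 20 + 2 * xs^3 / 15
  xl <- x[!small]
  g <- (1 + xl) * log1p(xl) - xl
  out[!small] <- (xl * log1p(xl) - 2 * g) / xl^3
  out
}

#' Pairwise coalescent-time CDF under the birth-death model
#'
#' Cumulative distribution of the time (backward from the present) to the
#' most recent common ancestor of two individuals drawn uniformly at random
#' from the population extant at time `T`, conditional on at least two
#' individuals surviving. Writing `u = p0(tau)/p0(T)` and
#' `beta = lambda p0(T)/mu` (the geometric parameter of the surviving tip
#' count), the CDF is
#' \deqn{F_{BD}(\tau) = 2u\,\frac{(1+x)\log(1+x) - x}{x^2}, \quad
#'   x = \frac{\beta(1-u)}{1-\beta},}
#' the closed-form sum of a geometric mixture over tip counts of maxima of
#' iid coalescent depths. In the pure-birth limit
#' `u = (1 - exp(-lambda*tau))/(1 - exp(-lambda*T))` and
#' `beta = 1 - exp(-lambda*T)`. All probability mass lies in `[0, T]`:
#' the CDF is 1 for `tau >= T`.
#'
#' @param tau Backward time(s) from the present; non-negative, vectorised.
#' @param bd A [bd_params()] object.
#' @return Probabilities, one per element of `tau`.
#' @examples
#' bd <- bd_params(0.5, 0.25, 10)
#' bd_pair_cdf(c(0, 5, 10, 12), bd)
#' @seealso [bd_pair_density()], [sample_bd_pair_times()] for the
#'   simulation-based check.
#' @export
bd_pair_cdf <- function(tau, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  out <- rep(1, length(tau))
  inside <- tau < bd$origin
  if (any(inside)) {
    u <- bd_aux_u(tau[inside], bd)
    beta <- bd_aux_beta(bd)
    x <- beta * (1 - u) / (1 - beta)
    out[inside] <- 2 * u * h_fun(x)
  }
  out
}

#' Pairwise coalescent-time density under the birth-death model
#'
#' Probability density of the pairwise coalescence time whose CDF is
#' [bd_pair_cdf()]. The density is supported on `[0, T]` and returns 0 for
#' `tau > T` (the process started at time `T` in the past, so no pair can
#' coalesce earlier than the origin).
#'
#' @inheritParams bd_pair_cdf
#' @return Densities, one per element of `tau`.
#' @examples
#' bd <- bd_params(0.5, 0.25, 10)
#' stats::integrate(bd_pair_density, 0, 10, bd = bd)  # integrates to 1
#' @export
bd_pair_density <- function(tau, bd) {
  stopifnot(inherits(bd, "bd_params"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  out <- numeric(length(tau))
  inside <- tau <= bd$origin
  if (any(inside)) {
    u <- bd_aux_u(tau[inside], bd)
    beta <- bd_aux_beta(bd)
    x <- beta * (1 - u) / (1 - beta)
    dF_du <- 2 * h_fun(x) - 2 * u * h_prime(x) * beta / (1 - beta)
    out[inside] <- dF_du * bd_aux_du(tau[inside], bd)
  }
  out
}
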