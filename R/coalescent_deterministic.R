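# The deterministic exponential-growth coalescent (CD) and the variant whose
# population-size function is the survival-conditioned birth-death mean (CDN).
# Backward time tau relates to forward time by t = T - tau; every CDN
# evaluation goes through that single mapping.

#' Coalescent-time density under deterministic exponential growth
#'
#' Two lineages sampled at the present coalesce at backward time `tau` with
#' hazard `1/(N(tau) * rho)`, `N(tau) = N0 * exp(-r*tau)`. For the standard
#' rate (`variant = "per_N"`) the density is
#' \deqn{f_{CD}(\tau) = \frac{e^{r\tau}}{\Theta}
#'   \exp\!\left(-\frac{e^{r\tau}-1}{r\Theta}\right), \quad \Theta = N_0\rho,}
#' supported on all of `(0, Inf)` - in particular beyond the origin time
#' `T = log(N0)/r` of the matching birth-death process. The
#' `"per_N_minus_1"` variant replaces the pair rate by
#' `1/((N(tau) - 1) * rho)`; its hazard diverges as `N(tau)` approaches 1,
#' so all mass falls inside `[0, T)`.
#'
#' @param tau Backward time(s); non-negative, vectorised.
#' @param cd A [cd_params()] object.
#' @param variant `"per_N"` (default) or `"per_N_minus_1"`.
#' @return Densities, one per element of `tau`.
#' @examples
#' cd <- cd_params(r = 0.475, N0 = 1e4, rho = 1)
#' stats::integrate(cd_pair_density, 0, Inf, cd = cd)
#' @export
cd_pair_density <- function(tau, cd, variant = c("per_N", "per_N_minus_1")) {
  stopifnot(inherits(cd, "cd_params"))
  variant <- match.arg(variant)
  if (any(tau < 0)) stop("'tau' must be non-negative")
  if (variant == "per_N") {
    # evaluated in log space: for large tau the hazard factor overflows
    # while the survival factor underflows; their product is a clean 0
    exp(cd$r * tau - expm1(cd$r * tau) / (cd$r * cd$theta)) / cd$theta
  } else {
    # hazard 1/((N0 e^{-r tau} - 1) rho); support [0, log(N0)/r)
    e <- exp(cd$r * tau)
    out <- numeric(length(tau))
    ok <- e < cd$N0
    haz <- e[ok] / (cd$rho * (cd$N0 - e[ok]))
    out[ok] <- haz * ((cd$N0 - e[ok]) / (cd$N0 - 1))^(1 / (cd$rho * cd$r))
    out
  }
}

#' Coalescent-time CDF under deterministic exponential growth
#'
#' Integral of [cd_pair_density()]:
#' `F_CD(tau) = 1 - exp(-(exp(r*tau) - 1)/(r*theta))` for the standard rate;
#' the `"per_N_minus_1"` variant has the closed form
#' `1 - ((N0 - exp(r*tau))/(N0 - 1))^(1/(rho*r))`, which reaches 1 exactly at
#' `tau = log(N0)/r`.
#'
#' @inheritParams cd_pair_density
#' @return Probabilities, one per element of `tau`.
#' @export
cd_pair_cdf <- function(tau, cd, variant = c("per_N", "per_N_minus_1")) {
  stopifnot(inherits(cd, "cd_params"))
  variant <- match.arg(variant)
  if (any(tau < 0)) stop("'tau' must be non-negative")
  if (variant == "per_N") {
    -expm1(-expm1(cd$r * tau) / (cd$r * cd$theta))
  } else {
    e <- pmin(exp(cd$r * tau), cd$N0)
    1 - ((cd$N0 - e) / (cd$N0 - 1))^(1 / (cd$rho * cd$r))
  }
}

#' Probability of coalescence within the duration of the process
#'
#' Probability that two lineages coalesce within the backward interval
#' `[0, T]` under the deterministic coalescent, i.e. `F_CD(T)`. By default
#' `T` is the origin time `log(N0)/r` of the matching birth-death process,
#' at which the deterministic population size has declined to one
#' individual. The complement is the mass the CD model places on coalescence
#' *before the origin of the process* - its characteristic pathology.
#'
#' @param cd A [cd_params()] object.
#' @param T Upper end of the backward interval; defaults to `log(N0)/r`.
#' @param variant `"per_N"` (default) or `"per_N_minus_1"`.
#' @return A probability (strictly below 1 for the `"per_N"` rate).
#' @examples
#' cd <- cd_from_bd(bd_params(0.5, 0, origin_time_for_N(1e4, 0.5, 0)))
#' cd_prob_coal_within(cd)        # below 1
#' @export
cd_prob_coal_within <- function(cd, T = log(cd$N0) / cd$r,
                                variant = c("per_N", "per_N_minus_1")) {
  stopifnot(inherits(cd, "cd_params"))
  if (T <= 0) stop("'T' must be positive")
  cd_pair_cdf(T, cd, match.arg(variant))
}

#' Large-population limit of the ancestral coalescence mass
#'
#' As `N0 -> Inf` with the birth-death mapping `r` `= lambda - mu`,
#' `rho = 1/(2*lambda)` and `T = log(N0)/r`, the probability that a pair
#' coalesces *ancestral to the origin* under the deterministic coalescent
#' converges to
#' \deqn{1 - F_{CD}(T) \to e^{-1/(\rho r)} = e^{-2\lambda/(\lambda-\mu)}.}
#' At `mu = 0` this is `exp(-2) = 0.135`; it decreases with increasing `mu`
#' and vanishes as `mu -> lambda`.
#'
#' @param bd A [bd_params()] object (only `lambda` and `mu` are used).
#' @return The limiting ancestral probability mass.
#' @examples
#' cd_ancestral_mass_limit(bd_params(0.5, 0, 1))      # exp(-2)
#' cd_ancestral_mass_limit(bd_params(0.5, 0.45, 1))   # much smaller
#' @export
cd_ancestral_mass_limit <- function(bd) {
  stopifnot(inherits(bd, "bd_params"))
  exp(-1 / (bd$rho * bd$r))
}

# Cumulative coalescent hazard of the CDN model at sorted backward times:
# Lambda(tau) = int_0^tau ds / (rho * N_BD(T - s)), accumulated segment by
# segment with adaptive quadrature.
cdn_cum_hazard <- function(tau, bd, variant = c("per_N", "per_N_minus_1"),
                           rho = bd$rho) {
  variant <- match.arg(variant)
  hazard <- function(s) {
    n <- bd_expected_size_conditioned(bd$origin - s, bd)
    if (variant == "per_N") 1 / (rho * n) else 1 / (rho * pmax(n - 1, 0))
  }
  ord <- order(tau)
  ts <- tau[ord]
  cum <- numeric(length(ts))
  lo <- 0
  acc <- 0
  for (i in seq_along(ts)) {
    if (variant == "per_N_minus_1" && ts[i] >= bd$origin) {
      # the conditioned mean reaches 1 at tau = T, where this rate's hazard
      # has a non-integrable divergence: the cumulative hazard is infinite
      cum[i] <- Inf
      next
    }
    if (ts[i] > lo) {
      acc <- acc + stats::integrate(hazard, lo, ts[i], rel.tol = 1e-10,
                                    abs.tol = 1e-12, stop.on.error = FALSE)$value
      lo <- ts[i]
    }
    cum[i] <- acc
  }
  cum[order(ord)]
}

#' Coalescent-time CDF with the survival-conditioned population size
#'
#' The CDN model replaces the deterministic exponential `N(tau)` of the CD
#' model by the birth-death expected population size conditioned on survival
#' ([bd_expected_size_conditioned()] evaluated at forward time `t = T - tau`).
#' That size function is only defined on `[0, T]`, so the distribution is
#' defective: the CDF value at `T` is below 1 and the deficit
#' ([cdn_no_coal_mass()]) is the probability that the pair never coalesces.
#' The cumulative hazard has no elementary antiderivative and is computed by
#' adaptive quadrature of `1/(rho * N_BD(T - s))`.
#'
#' @param tau Backward time(s) in `[0, T]`; vectorised.
#' @param bd A [bd_params()] object.
#' @param variant `"per_N"` (default) or `"per_N_minus_1"`; the latter uses
#'   pair rate `1/((N_BD - 1) * rho)`, whose hazard diverges at `tau = T`
#'   where the conditioned mean reaches 1, so it leaves no atom.
#' @param rho Generation time; defaults to `1/(2*lambda)`.
#' @return Probabilities, one per element of `tau`.
#' @examples
#' bd <- bd_params(0.5, 0.25, 10)
#' cdn_pair_cdf(c(2, 5, 10), bd)
#' @export
cdn_pair_cdf <- function(tau, bd, variant = c("per_N", "per_N_minus_1"),
                         rho = bd$rho) {
  stopifnot(inherits(bd, "bd_params"))
  variant <- match.arg(variant)
  if (any(tau < 0)) stop("'tau' must be non-negative")
  if (any(tau > bd$origin)) stop("'tau' must not exceed the origin time T")
  -expm1(-cdn_cum_hazard(tau, bd, variant, rho))
}

#' Coalescent-time density with the survival-conditioned population size
#'
#' Density companion of [cdn_pair_cdf()]:
#' `f_CDN(tau) = exp(-Lambda(tau)) / (rho * N_BD(T - tau))` on `[0, T]` and 0
#' beyond `T` (the conditioned size function is undefined there; the missing
#' mass is reported by [cdn_no_coal_mass()], not folded into the density).
#'
#' @inheritParams cdn_pair_cdf
#' @return Densities, one per element of `tau`.
#' @export
cdn_pair_density <- function(tau, bd, variant = c("per_N", "per_N_minus_1"),
                             rho = bd$rho) {
  stopifnot(inherits(bd, "bd_params"))
  variant <- match.arg(variant)
  if (any(tau < 0)) stop("'tau' must be non-negative")
  out <- numeric(length(tau))
  inside <- tau <= bd$origin
  if (any(inside)) {
    n <- bd_expected_size_conditioned(bd$origin - tau[inside], bd)
    haz <- if (variant == "per_N") 1 / (rho * n) else 1 / (rho * (n - 1))
    H <- cdn_cum_hazard(tau[inside], bd, variant, rho)
    out[inside] <- ifelse(is.finite(H), haz * exp(-H), 0)
  }
  out
}

#' No-coalescence atom of the CDN model
#'
#' Probability that a pair of lineages fails to coalesce anywhere in
#' `[0, T]` under the CDN model: `exp(-Lambda(T))`. Zero for the
#' `"per_N_minus_1"` rate, whose hazard diverges at `T`.
#'
#' @inheritParams cdn_pair_cdf
#' @return A probability.
#' @export
cdn_no_coal_mass <- function(bd, variant = c("per_N", "per_N_minus_1"),
                             rho = bd$rho) {
  stopifnot(inherits(bd, "bd_params"))
  variant <- match.arg(variant)
  if (variant == "per_N_minus_1") return(0)
  exp(-cdn_cum_hazard(bd$origin, bd, variant, rho))
}
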