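#' Birth-death model parameters
#'
#' Bundle the three parameters of a constant-rate birth-death (BD) process
#' started from a single individual: the per-capita birth rate `lambda`, the
#' per-capita death rate `mu` and the forward duration (time since origin)
#' `origin`. Derived quantities are stored alongside: the net growth rate
#' `r` `= lambda - mu`, the basic reproductive number `R0 = lambda/mu`
#' (`Inf` when `mu = 0`) and the pairwise-coalescence generation time
#' `rho = 1/(2*lambda)` that links the BD process to its coalescent
#' approximations.
#'
#' @param lambda Per-capita birth (transmission) rate; positive.
#' @param mu Per-capita death (removal) rate; `0 <= mu < lambda`.
#' @param origin Time `T` since the origin of the process; positive.
#'
#' @return An object of class `"bd_params"`: a list with elements `lambda`,
#'   `mu`, `origin`, `r`, `R0` and `rho`.
#' @examples
#' bd <- bd_params(lambda = 0.5, mu = 0.25, origin = 10)
#' bd$R0
#' @seealso [cd_params()], [cd_from_bd()]
#' @export
bd_params <- function(lambda, mu, origin) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(origin), length(origin) == 1L, is.finite(origin))
  if (lambda <= 0) stop("'lambda' must be positive")
  if (mu < 0 || mu >= lambda) stop("'mu' must satisfy 0 <= mu < lambda")
  if (origin <= 0) stop("'origin' must be positive")
  structure(
    list(lambda = lambda, mu = mu, origin = origin,
         r = lambda - mu,
         R0 = if (mu > 0) lambda / mu else Inf,
         rho = 1 / (2 * lambda)),
    class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat("Constant-rate birth-death parameters\n")
  cat(sprintf("  lambda = %g, mu = %g, origin T = %g\n", x$lambda, x$mu, x$origin))
  cat(sprintf("  r = %g, R0 = %g, rho = 1/(2 lambda) = %g\n", x$r, x$R0, x$rho))
  invisible(x)
}

#' Deterministic exponential-growth coalescent parameters
#'
#' Parameters of the coalescent with deterministic exponential population
#' growth (CD model): growth rate `r`, present-day population size `N0` and
#' generation time `rho`. Two lineages coalesce at backward time `tau` with
#' rate `1/(N(tau) * rho)` where `N(tau) = N0 * exp(-r * tau)`. The product
#' `theta = N0 * rho` is stored as well.
#'
#' @param r Population growth rate; positive.
#' @param N0 Present-day population size; greater than 1.
#' @param rho Generation time; positive.
#'
#' @return An object of class `"cd_params"`: a list with elements `r`, `N0`,
#'   `rho` and `theta`.
#' @examples
#' cd <- cd_params(r = 0.25, N0 = 1e4, rho = 1)
#' cd$theta
#' @export
cd_params <- function(r, N0, rho) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(N0), length(N0) == 1L, is.finite(N0),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (r <= 0) stop("'r' must be positive")
  if (N0 <= 1) stop("'N0' must be greater than 1")
  if (rho <= 0) stop("'rho' must be positive")
  structure(list(r = r, N0 = N0, rho = rho, theta = N0 * rho),
            class = "cd_params")
}

#' @export
print.cd_params <- function(x, ...) {
  cat("Deterministic exponential-growth coalescent parameters\n")
  cat(sprintf("  r = %g, N0 = %g, rho = %g, theta = N0 rho = %g\n",
              x$r, x$N0, x$rho, x$theta))
  invisible(x)
}

#' Map birth-death parameters onto the deterministic coalescent
#'
#' Applies the standard parameter correspondence between the BD process and
#' the exponential-growth coalescent: growth rate `r` `= lambda - mu`,
#' present-day size `N0 = exp((lambda - mu) * T)` (the unconditioned expected
#' BD population size at the present) and generation time `rho = 1/(2*lambda)`.
#'
#' @param bd A [bd_params()] object.
#' @return A [cd_params()] object.
#' @examples
#' cd_from_bd(bd_params(0.5, 0.25, origin = log(100) / 0.25))
#' @export
cd_from_bd <- function(bd) {
  stopifnot(inherits(bd, "bd_params"))
  cd_params(r = bd$r, N0 = exp(bd$r * bd$origin), rho = bd$rho)
}

#' Origin time for a target conditioned population size
#'
#' Returns the duration `T` such that the expected BD population size at `T`,
#' conditioned on survival to `T`, equals `N`. The conditioned mean at the
#' end of the process is `(lambda * exp(r*T) - mu)/r`, giving the closed form
#' `T = log((r*N + mu)/lambda) / r`, which reduces to `log(N)/lambda` in the
#' pure-birth (Yule) case.
#'
#' @param N Target expected number of individuals; greater than 1.
#' @param lambda Per-capita birth rate.
#' @param mu Per-capita death rate, `0 <= mu < lambda`.
#' @return The origin time `T` (scalar).
#' @examples
#' origin_time_for_N(1e4, lambda = 0.5, mu = 0)   # log(1e4)/0.5
#' @export
origin_time_for_N <- function(N, lambda, mu) {
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N))
  if (N <= 1) stop("'N' must be greater than 1")
  if (lambda <= 0) stop("'lambda' must be positive")
  if (mu < 0 || mu >= lambda) stop("'mu' must satisfy 0 <= mu < lambda")
  r <- lambda - mu
  log((r * N + mu) / lambda) / r
}
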