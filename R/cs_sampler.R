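# The stochastic coalescent (CS): backward-in-time pairwise coalescence
# sampling along realized birth-death trajectories, and the coal_cdf
# container shared by all four models.

variant_code <- function(variant) {
  match(match.arg(variant, c("per_N", "per_N_minus_1")),
        c("per_N", "per_N_minus_1")) - 1L
}

#' Sample a pairwise coalescence time along one trajectory
#'
#' Traces two lineages backward from the present (`tau = 0`, forward time
#' `T`) through the piecewise-constant population size of a realized
#' birth-death trajectory. Within a segment of constant size `N` the
#' coalescence hazard is `1/(N * rho)` (`variant = "per_N"`) or
#' `1/((N - 1) * rho)` (`"per_N_minus_1"`); the draw inverts the piecewise
#' cumulative hazard exactly, with no time discretisation. If the cumulative
#' hazard over `[0, T]` is exhausted before coalescence, the pair fails to
#' coalesce and `NA` is returned (a first-class outcome: the trajectory's
#' population size is undefined beyond its origin). Under `"per_N_minus_1"`
#' the hazard is infinite wherever `N = 1`, so the walk coalesces on
#' entering such a segment and `NA` never occurs.
#'
#' @param traj A `"bd_trajectory"` simulated with condition
#'   `"at_least_two_at_T"` (two lineages must exist at the present).
#' @param rho Generation time.
#' @param variant `"per_N"` (default) or `"per_N_minus_1"`.
#' @param m Number of draws from the same trajectory (draws from one
#'   trajectory are dependent through it).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `m`: backward coalescence times in
#'   `(0, T]`, with `NA` marking no coalescence.
#' @examples
#' bd <- bd_params(0.5, 0.25, 8)
#' tr <- simulate_bd_trajectory(bd, condition = "at_least_two_at_T", seed = 2)
#' sample_cs_time(tr, rho = bd$rho, seed = 3)
#' @export
sample_cs_time <- function(traj, rho, variant = c("per_N", "per_N_minus_1"),
                           m = 1L, seed = NULL) {
  stopifnot(inherits(traj, "bd_trajectory"), rho > 0, m >= 1)
  variant <- match.arg(variant)
  if (traj$n_final < 2L)
    stop("'traj' must have at least two individuals at T ",
         "(simulate with condition = \"at_least_two_at_T\")")
  maybe_set_seed(seed)
  cpp_cs_draws_for_traj(traj$times, traj$types, traj$n_final, traj$T,
                        rho, variant_code(variant), as.integer(m))
}

#' Model-labelled cumulative distribution of pairwise coalescence time
#'
#' Container shared by the analytic models (BD, CD, CDN) and the simulated
#' stochastic coalescent (CS): a CDF evaluated on a backward-time grid in
#' `[0, T]` plus an explicit no-coalescence atom, so that
#' `cdf value at T + atom = 1` (up to Monte-Carlo error for CS).
#'
#' @param model `"bd"`, `"cd"`, `"cdn"` or `"cs"`.
#' @param tau Ordered backward-time grid in `[0, T]`.
#' @param cdf CDF values parallel to `tau`.
#' @param no_coalescence_mass Probability that the pair never coalesces in
#'   `[0, T]` (for CD this is the mass ancestral to `T`).
#' @param bd The [bd_params()] the curve refers to.
#' @param rate_variant `"per_N"` or `"per_N_minus_1"`.
#' @param n_replicates Number of Monte-Carlo replicates (0 for analytic).
#' @param seed Seed used for a simulated curve (`NA` for analytic).
#' @return An object of class `"coal_cdf"`.
#' @seealso [model_cdf_grid()], [estimate_cs_cdf()]
#' @export
coal_cdf <- function(model, tau, cdf, no_coalescence_mass, bd,
                     rate_variant = "per_N", n_replicates = 0L, seed = NA) {
  model <- match.arg(model, c("bd", "cd", "cdn", "cs"))
  rate_variant <- match.arg(rate_variant, c("per_N", "per_N_minus_1"))
  stopifnot(inherits(bd, "bd_params"), length(tau) == length(cdf),
            !is.unsorted(tau), all(cdf >= -1e-12), all(cdf <= 1 + 1e-12))
  if (is.unsorted(cdf)) stop("'cdf' must be non-decreasing")
  structure(
    list(model = model, rate_variant = rate_variant, tau = tau,
         cdf = pmin(pmax(cdf, 0), 1),
         no_coalescence_mass = no_coalescence_mass,
         n_replicates = as.integer(n_replicates), params = bd, seed = seed),
    class = "coal_cdf")
}

#' @export
print.coal_cdf <- function(x, ...) {
  cat(sprintf(
    "coal_cdf [%s, %s]: %d grid points on [0, %g], F(T) = %.4f, atom = %.4f%s\n",
    toupper(x$model), x$rate_variant, length(x$tau), max(x$tau),
    x$cdf[length(x$cdf)], x$no_coalescence_mass,
    if (x$n_replicates > 0) sprintf(", %d replicates", x$n_replicates) else ""))
  invisible(x)
}

#' @export
as.data.frame.coal_cdf <- function(x, ...) {
  data.frame(model = x$model, rate_variant = x$rate_variant,
             tau = x$tau, cdf = x$cdf,
             no_coalescence_mass = x$no_coalescence_mass,
             n_replicates = x$n_replicates,
             lambda = x$params$lambda, mu = x$params$mu,
             T = x$params$origin,
             seed = if (is.null(x$seed)) NA else x$seed)
}

#' Write a coal_cdf as CSV
#'
#' Columns: `model, rate_variant, tau, cdf, no_coalescence_mass,
#' n_replicates, lambda, mu, T, seed`.
#'
#' @param x A `"coal_cdf"` or a list of them (stacked into one file).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coal_cdf_csv <- function(x, path) {
  if (inherits(x, "coal_cdf")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_tau_grid <- function(T) seq(0, T, length.out = 513L)

#' Analytic coalescent-time CDF of a model on a grid
#'
#' Evaluates the BD, CD or CDN pairwise coalescent-time CDF on a backward
#' time grid and packages it as a [coal_cdf()] with its no-coalescence atom
#' (0 for BD; the ancestral mass `1 - F_CD(T)` for CD; the defective-mass
#' atom for CDN).
#'
#' @param model `"bd"`, `"cd"` or `"cdn"` (use [estimate_cs_cdf()] for CS).
#' @param bd A [bd_params()] object.
#' @param tau_grid Backward-time grid; default 512 equal steps on `[0, T]`
#'   ending exactly at `T`.
#' @param rate_variant `"per_N"` or `"per_N_minus_1"` (ignored by BD).
#' @return A `"coal_cdf"` object.
#' @examples
#' bd <- bd_params(0.5, 0.25, 10)
#' model_cdf_grid("bd", bd)
#' @export
model_cdf_grid <- function(model, bd, tau_grid = NULL,
                           rate_variant = c("per_N", "per_N_minus_1")) {
  model <- match.arg(model, c("bd", "cd", "cdn"))
  rate_variant <- match.arg(rate_variant)
  stopifnot(inherits(bd, "bd_params"))
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(bd$origin)
  if (model == "bd") {
    coal_cdf("bd", tau_grid, bd_pair_cdf(tau_grid, bd), 0, bd, "per_N")
  } else if (model == "cd") {
    cd <- cd_from_bd(bd)
    vals <- cd_pair_cdf(tau_grid, cd, rate_variant)
    coal_cdf("cd", tau_grid, vals, 1 - vals[length(vals)], bd, rate_variant)
  } else {
    vals <- cdn_pair_cdf(tau_grid, bd, rate_variant)
    coal_cdf("cdn", tau_grid, vals, 1 - vals[length(vals)], bd, rate_variant)
  }
}

#' Monte-Carlo estimate of the stochastic-coalescent CDF
#'
#' Simulates `n_traj` conditioned birth-death trajectories and draws the
#' pairwise coalescence time backward along each (one draw per trajectory by
#' default, keeping the ensemble draws independent). The empirical CDF on
#' the grid, together with the fraction of no-coalescence outcomes, makes up
#' the CS curve.
#'
#' @param bd A [bd_params()] object.
#' @param n_traj Number of trajectories.
#' @param variant `"per_N"` (default) or `"per_N_minus_1"`.
#' @param tau_grid Backward-time grid; default as in [model_cdf_grid()].
#' @param rho Generation time; defaults to `1/(2*lambda)`.
#' @param draws_per_traj Draws per trajectory (dependent within one
#'   trajectory; keep at 1 for simple standard-error accounting).
#' @param condition Trajectory conditioning; the default requires two
#'   individuals at the present so a pair can be sampled.
#' @param seed Optional integer seed.
#' @return A `"coal_cdf"` with `n_replicates = n_traj` and attribute
#'   `"acceptance"` (fraction of trajectories accepted by the rejection
#'   sampler).
#' @examples
#' cs <- estimate_cs_cdf(bd_params(0.5, 0.25, 8), n_traj = 200, seed = 1)
#' cs
#' @export
estimate_cs_cdf <- function(bd, n_traj, variant = c("per_N", "per_N_minus_1"),
                            tau_grid = NULL, rho = bd$rho,
                            draws_per_traj = 1L,
                            condition = c("at_least_two_at_T", "survival"),
                            seed = NULL) {
  stopifnot(inherits(bd, "bd_params"), n_traj >= 1, rho > 0)
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(bd$origin)
  maybe_set_seed(seed)
  draws <- cpp_cs_times(bd$lambda, bd$mu, bd$origin, rho,
                        variant_code(variant), as.integer(n_traj),
                        as.integer(draws_per_traj),
                        condition_code(condition))
  attempts <- attr(draws, "attempts")
  x <- as.vector(draws)
  n <- length(x)
  coal <- sort(x[!is.na(x)])
  vals <- findInterval(tau_grid, coal) / n
  out <- coal_cdf("cs", tau_grid, vals, mean(is.na(x)), bd, variant,
                  n_replicates = n_traj,
                  seed = if (is.null(seed)) NA else seed)
  attr(out, "acceptance") <- n_traj / attempts
  out
}

#' Renormalize a `[0, T]`-supported CDF to reach 1 at T
#'
#' Divides the CDF values by the coalesced-by-`T` fraction, turning a
#' defective distribution into the conditional distribution given
#' coalescence within `[0, T]` - the form used as a prior on coalescence
#' times given a proposed origin.
#'
#' @param x A `"coal_cdf"`.
#' @return A `"coal_cdf"` with terminal value 1 and zero atom.
#' @export
normalize_coal_cdf <- function(x) {
  stopifnot(inherits(x, "coal_cdf"))
  top <- x$cdf[length(x$cdf)]
  if (top <= 0) stop("cannot normalize a curve with no mass in [0, T]")
  x$cdf <- x$cdf / top
  x$no_coalescence_mass <- 0
  x
}

#' Plot cumulative coalescent-time distributions
#'
#' Overlay of one or more [coal_cdf()] curves in the style of the model
#' comparison figures: solid lines for the `per_N` rate, dotted for
#' `per_N_minus_1`, with an end marker at `T` showing the coalesced-by-`T`
#' fraction.
#'
#' @param x A `"coal_cdf"` or list of them.
#' @param main Plot title.
#' @param cols Optional named colours per model.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_coal_cdf <- function(x, main = "", cols = NULL, ...) {
  if (inherits(x, "coal_cdf")) x <- list(x)
  if (is.null(cols))
    cols <- c(bd = "black", cd = "blue", cdn = "skyblue", cs = "red")
  T <- max(vapply(x, function(c) max(c$tau), numeric(1)))
  graphics::plot(NULL, xlim = c(0, T), ylim = c(0, 1),
                 xlab = "backward time from present",
                 ylab = "P(coalescence by tau)", main = main, ...)
  for (curve in x) {
    lty <- if (curve$rate_variant == "per_N") 1 else 3
    graphics::lines(curve$tau, curve$cdf, col = cols[[curve$model]], lty = lty)
    graphics::points(max(curve$tau), curve$cdf[length(curve$cdf)],
                     pch = 16, cex = 0.6, col = cols[[curve$model]])
  }
  graphics::legend("bottomright", bty = "n",
                   legend = toupper(vapply(x, `[[`, "", "model")),
                   lty = vapply(x, function(c)
                     if (c$rate_variant == "per_N") 1 else 3, numeric(1)),
                   col = vapply(x, function(c) cols[[c$model]], ""))
  invisible(NULL)
}
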