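# Stochastic coalescent sampling along trajectories and the coal_cdf
# container.

# Hand-built trajectory: births at t = 1 and t = 2, so backward from T = 3
# the population size is 3 on tau in [0, 1], 2 on [1, 2] and 1 on [2, 3].
hand_traj <- structure(
  list(times = c(1, 2), types = c(1L, 1L), sizes = c(2L, 3L),
       n_final = 3L, T = 3, condition = "at_least_two_at_T", attempts = 1L),
  class = "bd_trajectory")

# Closed-form piecewise-exponential CDF of the per_N draw on hand_traj, rho = 1
hand_cdf_per_N <- function(tau) {
  H <- ifelse(tau <= 1, tau / 3,
              ifelse(tau <= 2, 1 / 3 + (tau - 1) / 2,
                     5 / 6 + pmin(tau - 2, 1)))
  -expm1(-H)
}

test_that("per_N draws on a fixed 3-segment trajectory match the hand-computed law", {
  x <- sample_cs_time(hand_traj, rho = 1, m = 1e6, seed = 21)
  atom_hat <- mean(is.na(x))
  atom <- exp(-11 / 6)           # survive hazards 1/3, 1/2, 1 over unit segments
  expect_lt(abs(atom_hat - atom), 3 * binom_se(atom, 1e6))

  coal <- x[!is.na(x)]
  expect_true(all(coal > 0 & coal <= 3))
  # KS of the coalesced part against the conditional closed form
  cond_cdf <- function(tau) hand_cdf_per_N(tau) / (1 - atom)
  expect_lt(ks_distance(coal, cond_cdf), 0.005)
})

test_that("per_N_minus_1 on the same trajectory collapses at the N = 1 epoch", {
  x <- sample_cs_time(hand_traj, rho = 1, variant = "per_N_minus_1",
                      m = 1e6, seed = 22)
  expect_false(anyNA(x))
  expect_true(all(x <= 2))       # hazard infinite once N = 1, entered at tau = 2
  # atom at exactly tau = 2: survive hazards 1/2 then 1 over the unit segments
  p2 <- exp(-3 / 2)
  expect_lt(abs(mean(x == 2) - p2), 3 * binom_se(p2, 1e6))
  # continuous part: F(tau) = 1 - exp(-H), H = tau/2 on [0,1], 1/2 + (tau-1) on [1,2)
  for (tau in c(0.5, 1, 1.5, 1.9)) {
    H <- if (tau <= 1) tau / 2 else 1 / 2 + (tau - 1)
    expect_lt(abs(mean(x <= tau) - (-expm1(-H))),
              3 * binom_se(-expm1(-H), 1e6) + 1e-4)
  }
})

test_that("a constant-size trajectory gives exponential coalescence times", {
  # no events: N = 5 throughout; with T far beyond the mean waiting time the
  # truncation is negligible and tau ~ Exp(1/(5 * rho))
  const_traj <- structure(
    list(times = numeric(0), types = integer(0), sizes = integer(0),
         n_final = 5L, T = 500, condition = "at_least_two_at_T", attempts = 1L),
    class = "bd_trajectory")
  x <- sample_cs_time(const_traj, rho = 2, m = 2e5, seed = 23)
  expect_false(anyNA(x))
  expect_lt(ks_distance(x, stats::pexp, rate = 1 / 10), 0.01)
})

test_that("sample_cs_time enforces its precondition", {
  lone <- structure(
    list(times = numeric(0), types = integer(0), sizes = integer(0),
         n_final = 1L, T = 5, condition = "survival", attempts = 1L),
    class = "bd_trajectory")
  expect_error(sample_cs_time(lone, rho = 1), "at least two")
})

test_that("estimate_cs_cdf returns a coherent empirical coal_cdf", {
  bd <- bd_params(0.5, 0.25, 8)
  cs <- estimate_cs_cdf(bd, n_traj = 2000, seed = 24)
  expect_s3_class(cs, "coal_cdf")
  expect_identical(cs$model, "cs")
  expect_equal(cs$n_replicates, 2000L)
  expect_true(all(diff(cs$cdf) >= 0))
  # every coalesced draw lies in (0, T], so the terminal value plus the
  # no-coalescence fraction is exactly 1
  expect_equal(cs$cdf[length(cs$cdf)] + cs$no_coalescence_mass, 1)
  expect_gt(cs$no_coalescence_mass, 0)
  expect_true(attr(cs, "acceptance") > 0 && attr(cs, "acceptance") <= 1)

  # n_traj = 1: the empirical CDF is a single step
  one <- estimate_cs_cdf(bd, n_traj = 1, seed = 25)
  expect_true(all(one$cdf %in% c(0, 1)))
})

test_that("per_N_minus_1 never returns NO_COALESCENCE over 1e5 draws", {
  bd <- bd_params(0.5, 0.25, 6)
  tr <- simulate_bd_trajectory(bd, condition = "at_least_two_at_T", seed = 26)
  x <- sample_cs_time(tr, rho = bd$rho, variant = "per_N_minus_1",
                      m = 1e5, seed = 27)
  expect_false(anyNA(x))
  cs <- estimate_cs_cdf(bd, n_traj = 3000, variant = "per_N_minus_1", seed = 28)
  expect_identical(cs$no_coalescence_mass, 0)
  expect_equal(cs$cdf[length(cs$cdf)], 1)
})

test_that("per_N_minus_1 times are stochastically younger than per_N", {
  bd <- bd_params(0.5, 0.25, 8)
  n <- 5000
  csN <- estimate_cs_cdf(bd, n_traj = n, variant = "per_N", seed = 29)
  cs1 <- estimate_cs_cdf(bd, n_traj = n, variant = "per_N_minus_1", seed = 30)
  # pointwise CDF dominance within Monte-Carlo error (the N-1 hazard is
  # larger everywhere on every trajectory)
  tol <- 3 * sqrt(0.5 / n)
  expect_true(all(cs1$cdf >= csN$cdf - tol))
  expect_gt(max(cs1$cdf - csN$cdf), 0)
})

test_that("CS agreement with BD at R0 = 1.05 improves as N0 grows", {
  lambda <- 0.5; mu <- lambda / 1.05
  dist_for <- function(N0, seed) {
    bd <- bd_params(lambda, mu, origin_time_for_N(N0, lambda, mu))
    cs <- estimate_cs_cdf(bd, n_traj = 2000, seed = seed)
    max(abs(cs$cdf - bd_pair_cdf(cs$tau, bd)))
  }
  d_small <- dist_for(10, 31)
  d_large <- dist_for(1000, 32)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.05)
})

test_that("identical seeds reproduce the CS curve bit for bit", {
  bd <- bd_params(0.5, 0.25, 7)
  a <- estimate_cs_cdf(bd, n_traj = 500, seed = 33)
  b <- estimate_cs_cdf(bd, n_traj = 500, seed = 33)
  expect_identical(a, b)
})

test_that("coal_cdf validates its inputs and round-trips through CSV", {
  bd <- bd_params(0.5, 0.25, 10)
  tau <- seq(0, 10, length.out = 11)
  expect_error(coal_cdf("bd", tau, rev(seq(0, 1, length.out = 11)), 0, bd),
               "non-decreasing")
  expect_error(coal_cdf("nope", tau, seq(0, 1, length.out = 11), 0, bd))

  x <- model_cdf_grid("bd", bd, tau)
  expect_output(print(x), "BD")
  df <- as.data.frame(x)
  expect_named(df, c("model", "rate_variant", "tau", "cdf",
                     "no_coalescence_mass", "n_replicates",
                     "lambda", "mu", "T", "seed"))
  path <- tempfile(fileext = ".csv")
  write_coal_cdf_csv(list(x, model_cdf_grid("cd", bd, tau)), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 22L)
  expect_equal(back$cdf[back$model == "bd"], x$cdf, tolerance = 1e-12)
  unlink(path)
})

test_that("normalize_coal_cdf rescales to 1 at T and drops the atom", {
  bd <- bd_params(0.5, 0.025, 7)        # R0 = 20: CD has real ancestral mass
  cd <- model_cdf_grid("cd", bd)
  expect_lt(cd$cdf[length(cd$cdf)], 1)
  norm <- normalize_coal_cdf(cd)
  expect_equal(norm$cdf[length(norm$cdf)], 1)
  expect_identical(norm$no_coalescence_mass, 0)
  zero <- coal_cdf("cs", c(0, 1), c(0, 0), 1, bd)
  expect_error(normalize_coal_cdf(zero), "no mass")
})

test_that("plot_coal_cdf draws without error", {
  bd <- bd_params(0.5, 0.25, 8)
  curves <- list(model_cdf_grid("bd", bd), model_cdf_grid("cd", bd))
  path <- tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  expect_no_error(plot_coal_cdf(curves, main = "smoke"))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
  unlink(path)
})
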