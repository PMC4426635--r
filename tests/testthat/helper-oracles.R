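# Shared helpers: an independent composite-Simpson integrator (used as the
# second route wherever adaptive quadrature is the implementation), and the
# study parameter grid.

simpson <- function(f, lower, upper, n = 2001L) {
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(lower, upper, length.out = n)
  w <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
  sum(w * f(x)) * (x[2] - x[1]) / 3
}

study_grid <- expand.grid(R0 = c(1.05, 1.3, 1.6, 2, 4, 10, 20),
                          N0 = c(10, 100, 1000, 10000))

grid_bd_params <- function(lambda = 0.5) {
  lapply(seq_len(nrow(study_grid)), function(i) {
    mu <- lambda / study_grid$R0[i]
    bd_params(lambda, mu, origin_time_for_N(study_grid$N0[i], lambda, mu))
  })
}

# Binomial Monte-Carlo standard error
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
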