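# Gillespie trajectory simulator, full-genealogy simulator and the
# pairwise-coalescence oracle built on them.

test_that("trajectory structure: unit steps, consistent final size, condition honoured", {
  bd <- bd_params(0.5, 0.25, 10)
  tr <- simulate_bd_trajectory(bd, condition = "at_least_two_at_T", seed = 1)
  expect_s3_class(tr, "bd_trajectory")
  expect_true(all(tr$types %in% c(-1L, 1L)))
  expect_equal(tr$sizes, 1L + cumsum(tr$types))
  expect_true(all(tr$sizes >= 0))
  expect_equal(tr$n_final, tr$sizes[length(tr$sizes)])
  expect_gte(tr$n_final, 2L)
  expect_true(all(diff(tr$times) > 0) && all(tr$times > 0 & tr$times < 10))

  # survival: size positive throughout
  tr <- simulate_bd_trajectory(bd, condition = "survival", seed = 2)
  expect_true(all(tr$sizes >= 1L))

  df <- as.data.frame(tr)
  expect_named(df, c("time", "event", "popsize_after"))
  expect_true(all(df$event %in% c("birth", "death")))
  expect_output(print(tr), "trajectory")
})

test_that("mu = 0 trajectories are non-decreasing and accepted on the first attempt", {
  yule <- bd_params(0.5, 0, 6)
  tr <- simulate_bd_trajectory(yule, condition = "survival", seed = 3)
  expect_true(all(tr$types == 1L))
  expect_true(all(diff(tr$sizes) == 1L))
  expect_equal(tr$attempts, 1)
})

test_that("first-event waiting time and event type follow the Gillespie law", {
  # from N = 1 the first event is at an Exp(lambda + mu) time and is a birth
  # with probability lambda/(lambda + mu); T is large enough that censoring
  # beyond T has probability < 1e-6
  lambda <- 0.5; mu <- 0.3
  bd <- bd_params(lambda, mu, 20)
  set.seed(4)
  n <- 5000
  first_t <- numeric(n)
  first_birth <- logical(n)
  for (i in seq_len(n)) {
    tr <- simulate_bd_trajectory(bd, condition = "none")
    first_t[i] <- tr$times[1]
    first_birth[i] <- tr$types[1] == 1L
  }
  expect_lt(ks_distance(first_t, stats::pexp, rate = lambda + mu), 0.025)
  p <- lambda / (lambda + mu)
  expect_lt(abs(mean(first_birth) - p), 3 * binom_se(p, n))
})

test_that("survival acceptance fraction matches 1 - p0(T) within 3 SE", {
  bd <- bd_params(0.5, 0.25, 10)
  n <- 2e4
  sizes <- trajectory_size_matrix(bd, n, grid = bd$origin,
                                  condition = "survival", seed = 5)
  acc <- attr(sizes, "acceptance")
  p <- 1 - bd_p0(bd$origin, bd)
  n_attempts <- n / acc
  expect_lt(abs(acc - p), 3 * binom_se(p, n_attempts))
  expect_true(all(sizes[, 1] >= 1L))
})

test_that("survival-conditioned mean curve matches the closed form within 3 SE", {
  bd <- bd_params(0.5, 0.45, 8)
  grid <- c(1, 2, 4, 6, 8)
  n <- 2e4
  sizes <- trajectory_size_matrix(bd, n, grid, condition = "survival", seed = 6)
  m_hat <- colMeans(sizes)
  se <- apply(sizes, 2, stats::sd) / sqrt(n)
  m <- bd_expected_size_conditioned(grid, bd)
  expect_true(all(abs(m_hat - m) < 3 * se))
  # push of the past: the conditioned curve exceeds exp(r*t)
  expect_true(all(m > exp(bd$r * grid)))
})

test_that("simulated genealogies are valid binary trees with correct tip times", {
  bd <- bd_params(0.5, 0.25, 6)
  tree <- simulate_bd_tree(bd, seed = 7)
  expect_s3_class(tree, "phylo")
  report <- utils::capture.output(ape::checkValidPhylo(tree))
  expect_false(any(grepl("FATAL|MODERATE", report)))

  # every internal node has exactly two children
  internal <- unique(tree$edge[, 1])
  expect_true(all(tabulate(tree$edge[, 1])[internal] == 2L))

  # tip depths (including the root edge) are T for extant tips, < T otherwise
  depth <- ape::node.depth.edgelength(tree) + tree$root.edge
  ntip <- length(tree$tip.label)
  extant <- tree$tip.label %in% attr(tree, "extant_tips")
  expect_equal(depth[seq_len(ntip)][extant],
               rep(bd$origin, sum(extant)), tolerance = 1e-12)
  expect_true(all(depth[seq_len(ntip)][!extant] < bd$origin))
  expect_gte(sum(extant), 2L)
})

test_that("extant tip counts follow the conditional geometric law (chi-squared)", {
  # given survival the extant count is geometric; conditioned on >= 2 at T,
  # P(n) = (1 - beta) * beta^(n - 2) with beta = lambda * p0(T) / mu
  bd <- bd_params(0.5, 0.2, 4)
  beta <- bd$lambda * bd_p0(bd$origin, bd) / bd$mu
  set.seed(8)
  n_rep <- 1500
  tips <- integer(n_rep)
  for (i in seq_len(n_rep))
    tips[i] <- length(attr(simulate_bd_tree(bd), "extant_tips"))
  # categories n = 2..10 and a pooled tail n >= 11
  counts <- tabulate(pmin(tips, 11L) - 1L, nbins = 10L)
  probs <- c((1 - beta) * beta^(0:8), beta^9)
  pval <- stats::chisq.test(counts, p = probs)$p.value
  expect_gt(pval, 0.001)
})

test_that("mu = 0 trees are Yule trees with the right mean tip count", {
  yule <- bd_params(0.5, 0, 3)
  beta <- -expm1(-yule$lambda * yule$origin)
  m_cond <- 2 + beta / (1 - beta)           # mean of the >= 2-conditioned geometric
  sd_cond <- sqrt(beta) / (1 - beta)
  set.seed(9)
  n_rep <- 2000
  tips <- integer(n_rep)
  for (i in seq_len(n_rep))
    tips[i] <- length(attr(simulate_bd_tree(yule), "extant_tips"))
  expect_lt(abs(mean(tips) - m_cond), 3 * sd_cond / sqrt(n_rep))
})

test_that("Newick round-trip preserves topology and branch lengths to 1e-12", {
  tree <- simulate_bd_tree(bd_params(0.5, 0.25, 6), seed = 10)
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, path, digits = 17)
  back <- ape::read.tree(path)
  expect_true(ape::all.equal.phylo(tree, back, use.edge.length = TRUE,
                                   tolerance = 1e-12))
  expect_equal(sort(back$edge.length), sort(tree$edge.length), tolerance = 1e-12)
  unlink(path)
})

test_that("pair coalescence time of a 2-tip tree is the root split deterministically", {
  # hand-built tree: progenitor lives 2 time units (root edge), splits, both
  # children survive 3 units to the present T = 5
  tree <- structure(
    list(edge = rbind(c(3L, 1L), c(3L, 2L)), edge.length = c(3, 3),
         Nnode = 1L, tip.label = c("t1", "t2"), root.edge = 2),
    class = "phylo", order = "cladewise")
  attr(tree, "extant_tips") <- c("t1", "t2")
  attr(tree, "origin") <- 5
  expect_equal(pair_coalescence_time(tree, seed = 1), 3)
  expect_equal(pair_coalescence_time(tree, seed = 99), 3)
})

test_that("pair times lie in (0, T] and are exchangeable across seeds", {
  bd <- bd_params(0.5, 0.25, 8)
  a <- sample_bd_pair_times(3000, bd, seed = 11)
  b <- sample_bd_pair_times(3000, bd, seed = 12)
  expect_true(all(a > 0 & a <= bd$origin))
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.001)
})

test_that("fixed seeds reproduce trajectories, trees and pair times exactly", {
  bd <- bd_params(0.5, 0.25, 7)
  expect_identical(simulate_bd_trajectory(bd, seed = 13),
                   simulate_bd_trajectory(bd, seed = 13))
  t1 <- simulate_bd_tree(bd, seed = 14)
  t2 <- simulate_bd_tree(bd, seed = 14)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
  expect_identical(sample_bd_pair_times(100, bd, seed = 15),
                   sample_bd_pair_times(100, bd, seed = 15))
})

test_that("trajectory TSV export writes the documented schema", {
  tr <- simulate_bd_trajectory(bd_params(0.5, 0.25, 5), seed = 16)
  path <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  df <- utils::read.delim(path)
  expect_named(df, c("time", "event", "popsize_after"))
  expect_equal(nrow(df), length(tr$times))
  unlink(path)
})
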