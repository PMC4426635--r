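# R-side interface to the Gillespie core: population trajectories, full
# genealogies (as ape "phylo" trees) and the pairwise-coalescence oracle.

condition_code <- function(condition) {
  match(match.arg(condition, c("none", "survival", "at_least_two_at_T")),
        c("none", "survival", "at_least_two_at_T")) - 1L
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Simulate a birth-death population trajectory
#'
#' Exact event-driven forward simulation: with `n` individuals alive the
#' waiting time to the next event is exponential with rate
#' `n * (lambda + mu)` and the event is a birth with probability
#' `lambda/(lambda + mu)`. Conditioning (`"survival"`: at least one
#' individual alive throughout `[0, T]`; `"at_least_two_at_T"`: at least two
#' at `T`) is implemented by rejection - trajectories are re-simulated until
#' the condition holds, with a guard that aborts after 1e7 rejections.
#'
#' @param bd A [bd_params()] object.
#' @param condition `"none"`, `"survival"` or `"at_least_two_at_T"`.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first so the call is reproducible in isolation.
#' @return An object of class `"bd_trajectory"`: a list with `times` (event
#'   times), `types` (+1 birth / -1 death), `sizes` (population size after
#'   each event), `n_final`, `T`, `condition` and `attempts` (trajectories
#'   simulated, including rejected ones).
#' @examples
#' tr <- simulate_bd_trajectory(bd_params(0.5, 0.25, 10),
#'                              condition = "survival", seed = 1)
#' tail(as.data.frame(tr))
#' @export
simulate_bd_trajectory <- function(bd,
                                   condition = c("survival", "none",
                                                 "at_least_two_at_T"),
                                   seed = NULL) {
  stopifnot(inherits(bd, "bd_params"))
  condition <- match.arg(condition)
  maybe_set_seed(seed)
  res <- cpp_sim_trajectory(bd$lambda, bd$mu, bd$origin,
                            condition_code(condition))
  structure(
    list(times = res$times, types = res$types, sizes = res$sizes,
         n_final = res$n_final, T = bd$origin, condition = condition,
         attempts = res$attempts),
    class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(
    "Birth-death trajectory: %d events on [0, %g], final size %d (%s)\n",
    length(x$times), x$T, x$n_final, x$condition))
  invisible(x)
}

#' @export
as.data.frame.bd_trajectory <- function(x, ...) {
  data.frame(time = x$times,
             event = ifelse(x$types > 0, "birth", "death"),
             popsize_after = x$sizes)
}

#' Export a trajectory as tab-separated text
#'
#' Writes columns `time`, `event` (`birth`/`death`) and `popsize_after`.
#'
#' @param traj A `"bd_trajectory"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "bd_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Population sizes of a trajectory ensemble on a time grid
#'
#' Simulates `n` conditioned trajectories and reads their piecewise-constant
#' population size off at the requested forward times. Used to check the
#' survival-conditioned mean curve (the "push of the past") against
#' [bd_expected_size_conditioned()].
#'
#' @inheritParams simulate_bd_trajectory
#' @param n Number of accepted trajectories.
#' @param grid Forward times in `[0, T]` at which sizes are recorded.
#' @return An `n` x `length(grid)` integer matrix with attribute
#'   `"acceptance"`, the fraction of simulated trajectories accepted.
#' @export
trajectory_size_matrix <- function(bd, n, grid,
                                   condition = c("survival", "none",
                                                 "at_least_two_at_T"),
                                   seed = NULL) {
  stopifnot(inherits(bd, "bd_params"), n >= 1, all(grid >= 0),
            all(grid <= bd$origin))
  condition <- match.arg(condition)
  maybe_set_seed(seed)
  res <- cpp_trajectory_size_matrix(bd$lambda, bd$mu, bd$origin, as.integer(n),
                                    condition_code(condition), grid)
  out <- res$sizes
  attr(out, "acceptance") <- n / res$attempts
  out
}

#' Simulate a full birth-death genealogy
#'
#' Simulates the complete tree of the process (including lineages that die
#' before the present) and returns it as an [ape::read.tree()]-compatible
#' `"phylo"` object with a root edge of length equal to the progenitor's
#' lifespan. Extant tips (alive at `T`) are labelled `t1..tn`; extinct tips
#' are labelled `x1..xm`.
#'
#' @inheritParams simulate_bd_trajectory
#' @param condition `"at_least_two_at_T"` (default, so that a pair of extant
#'   tips can be sampled), `"survival"` or `"none"`.
#' @return A `"phylo"` object with attributes `extant_tips` (labels of tips
#'   alive at `T`), `origin` (`T`) and `attempts`.
#' @examples
#' tree <- simulate_bd_tree(bd_params(0.5, 0.25, 5), seed = 1)
#' attr(tree, "extant_tips")
#' @export
simulate_bd_tree <- function(bd,
                             condition = c("at_least_two_at_T", "survival",
                                           "none"),
                             seed = NULL) {
  stopifnot(inherits(bd, "bd_params"))
  condition <- match.arg(condition)
  maybe_set_seed(seed)
  res <- cpp_sim_tree(bd$lambda, bd$mu, bd$origin, condition_code(condition))
  parent <- res$parent
  m <- length(parent)
  if (m < 3L)
    stop("the simulated genealogy has fewer than two tips; use a condition ",
         "that guarantees a pair, or retry")
  is_tip <- res$status != 0L
  ntip <- sum(is_tip)
  id <- integer(m)
  id[is_tip] <- seq_len(ntip)
  id[!is_tip] <- ntip + seq_len(m - ntip)  # creation order: parents precede children
  child <- which(parent > 0L)
  edge <- cbind(id[parent[child]], id[child])
  edge_len <- res$tend[child] - res$tstart[child]
  labels <- character(ntip)
  extant <- res$status == 2L & is_tip
  labels[id[extant]] <- paste0("t", seq_len(sum(extant)))
  dead <- res$status == 1L
  labels[id[dead]] <- paste0("x", seq_len(sum(dead)))
  tree <- structure(
    list(edge = edge, edge.length = edge_len, Nnode = m - ntip,
         tip.label = labels, root.edge = res$tend[1]),
    class = "phylo", order = "cladewise")
  attr(tree, "extant_tips") <- labels[id[extant]]
  attr(tree, "origin") <- bd$origin
  attr(tree, "attempts") <- res$attempts
  tree
}

#' Coalescence time of two random extant tips of a simulated tree
#'
#' Draws two distinct extant tips uniformly at random and returns the
#' backward time (from the present `T`) of their most recent common
#' ancestor's split.
#'
#' @param tree A tree from [simulate_bd_tree()] (needs at least two extant
#'   tips and the `extant_tips`/`origin` attributes).
#' @param seed Optional integer seed.
#' @return A single backward time in `(0, T]`.
#' @export
pair_coalescence_time <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  extant <- attr(tree, "extant_tips")
  T <- attr(tree, "origin")
  if (is.null(extant) || is.null(T))
    stop("'tree' must carry the 'extant_tips' and 'origin' attributes set by simulate_bd_tree()")
  if (length(extant) < 2L)
    stop("at least two extant tips are required")
  maybe_set_seed(seed)
  pick <- sample(extant, 2L)
  mrca <- ape::getMRCA(tree, pick)
  depth <- ape::node.depth.edgelength(tree)[mrca]
  root_edge <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  T - (root_edge + depth)
}

#' Pairwise coalescence times from an ensemble of simulated genealogies
#'
#' Simulates `n` independent trees conditioned on at least two extant tips
#' and returns one random-pair coalescence time per tree. This is the
#' brute-force oracle against which the closed-form pairwise distribution
#' ([bd_pair_cdf()]) is validated.
#'
#' @inheritParams simulate_bd_trajectory
#' @param n Number of trees (one time per tree).
#' @return A numeric vector of `n` backward coalescence times.
#' @examples
#' taus <- sample_bd_pair_times(1000, bd_params(0.5, 0.25, 8), seed = 1)
#' @export
sample_bd_pair_times <- function(n, bd, seed = NULL) {
  stopifnot(inherits(bd, "bd_params"), n >= 1)
  maybe_set_seed(seed)
  cpp_pair_times(bd$lambda, bd$mu, bd$origin, as.integer(n))
}

#' Kolmogorov-Smirnov distance between a sample and a CDF
#'
#' Sup-distance between the empirical CDF of `x` and the analytic CDF
#' `cdf_fun` (the two-sided KS statistic).
#'
#' @param x Numeric sample.
#' @param cdf_fun Vectorised CDF function.
#' @param ... Passed on to `cdf_fun`.
#' @return The KS statistic.
#' @export
ks_distance <- function(x, cdf_fun, ...) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf_fun(x, ...)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}
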