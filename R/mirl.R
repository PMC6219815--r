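#' Sparse modular inverse reinforcement learning fit
#'
#' Estimates per-module rewards and discount factors from observed
#' navigation trajectories by maximizing the L1-regularized Boltzmann
#' log-likelihood.  The objective is concave in the rewards at fixed
#' discount factors, so the fit nests a proximal-gradient convex solver
#' (rewards initialized at zero, soft-thresholding for the L1 term)
#' inside a grid search over the module discount factors with step
#' `epsilon`, which locates the global optimum to `epsilon` precision in
#' each `gamma`.
#'
#' With `search = "exhaustive"` every combination on the `gamma` grid is
#' visited (capped at `grid_cap` nodes).  For
#' three or more modules the default `"auto"` switches to a staged
#' search: an exhaustive pass on a uniformly thinned grid followed by
#' full-resolution passes in windows around the best coarse nodes, which
#' visits every grid value of each coordinate near the optimum at a small
#' fraction of the cost.  `refine = TRUE` adds one local refinement at
#' `epsilon/4` around the best node.
#'
#' The confidence parameter `eta` is fixed (default 1) during fitting:
#' only the product `eta * r` is identifiable, so the reward scale
#' absorbs the decision maker's confidence and recovery is meaningful on
#' normalized rewards.
#'
#' @param data A [mirl_dataset()] (or a single trajectory): the pooled
#'   trials to fit, e.g. all-but-one trials of one subject in one task.
#' @param modules Character vector of module names to estimate
#'   (default the three study modules).
#' @param eta Fixed confidence-in-optimality parameter.
#' @param lambda Nonnegative L1 regularization constant (cognitive
#'   capacity factor); 0 by default, appropriate for small module sets.
#' @param epsilon Discount-factor grid step.
#' @param gamma_max Upper end of the discount grid (grid is
#'   `seq(0, gamma_max, by = epsilon)`).
#' @param search `"auto"`, `"exhaustive"` or `"staged"`.
#' @param refine Add one `epsilon/4` local refinement around the best
#'   node.
#' @param tol Convergence tolerance of the inner solver.
#' @param maxit Iteration cap of the inner solver.
#' @param grid_cap Maximum number of exhaustive grid nodes before an
#'   error advises a coarser `epsilon` or fewer modules.
#' @param node_budget Approximate node budget per stage of the staged
#'   search.
#' @param nearest_k Per-module lookahead windows used when composing the
#'   likelihood (see [module_params()]); defaults to
#'   [default_nearest_k()].
#' @return An object of class `"mirl"`; see [coef.mirl()],
#'   [summary.mirl()], [predict.mirl()], [simulate.mirl()].
#' @examples
#' env <- generate_environment(n_targets = 4, n_obstacles = 0, seed = 1)
#' truth <- module_set_from(c("target", "path"), c(0.6, 0.4), c(0.7, 0.9))
#' d <- mirl_dataset(lapply(1:3, function(i)
#'   rollout(env, truth, policy("softmax", eta = 2, seed = i))))
#' fit <- mirl(d, modules = c("target", "path"), epsilon = 0.1)
#' coef(fit)
#' @export
mirl <- function(data, modules = c("target", "obstacle", "path"), eta = 1,
                 lambda = 0, epsilon = 0.02, gamma_max = 0.98,
                 search = c("auto", "exhaustive", "staged"), refine = FALSE,
                 tol = 1e-8, maxit = 10000L, grid_cap = 1e6,
                 node_budget = 20000, nearest_k = default_nearest_k(modules)) {
  search <- match.arg(search)
  stopifnot(eta > 0, lambda >= 0, epsilon > 0, epsilon < 1,
            gamma_max >= 0, gamma_max < 1)
  feats <- mirl_features(data, modules, nearest_k = nearest_k)
  N <- length(modules)
  grid <- gamma_grid(epsilon, gamma_max)
  cand <- rep(list(grid), N)
  r_free <- rep(TRUE, N)
  sr <- gamma_search(feats, cand, eta, lambda, r_init = numeric(N),
                     r_free = r_free, tol = tol, maxit = maxit,
                     search = search, node_budget = node_budget,
                     grid_cap = grid_cap)
  gammas <- sr$gammas
  rewards <- sr$rewards
  objective <- sr$objective
  profile <- gamma_profile(sr, cand, modules)
  if (refine) {
    rf <- refine_pass(feats, gammas, rewards, eta, lambda, r_free, tol,
                      maxit, epsilon, gamma_max, objective)
    gammas <- rf$gammas; rewards <- rf$rewards; objective <- rf$objective
  }

  ll <- loglik_from_features(feats, rewards, gammas, eta)
  names(rewards) <- names(gammas) <- modules
  norm_r <- if (any(rewards != 0)) normalize_rewards(rewards) else rewards
  structure(list(
    call = match.call(),
    module_names = modules,
    rewards = rewards, gammas = gammas, normalized = norm_r,
    objective = objective, loglik = ll,
    active = modules[rewards != 0],
    eta = eta, lambda = lambda, epsilon = epsilon, gamma_max = gamma_max,
    search = sr$search, n_nodes = sr$n_nodes, profile = profile,
    nearest_k = setNames(rep_len(nearest_k, length(modules)), modules),
    n_trajectories = if (inherits(data, "mirl_dataset")) length(data) else 1L,
    n_steps = feats$T,
    data = data), class = "mirl")
}

gamma_grid <- function(epsilon, gamma_max) {
  g <- seq(0, gamma_max, by = epsilon)
  if (gamma_max - g[length(g)] > epsilon / 2) g <- c(g, gamma_max)
  g
}

#' Convex reward fit at fixed discount factors
#'
#' Maximizes the regularized log-likelihood over module rewards with the
#' discount factors held fixed (the convex subproblem of [mirl()]),
#' by proximal-gradient ascent from zero rewards with soft-thresholding.
#'
#' @inheritParams mirl
#' @param gammas Named (or ordered) per-module discount factors in
#'   `[0, 1)`, aligned with `modules`.
#' @param r_init Starting rewards.
#' @return List with `rewards` (named), `objective` and `loglik`.
#' @export
fit_rewards_fixed_gamma <- function(data, gammas,
                                    modules = names(gammas), eta = 1,
                                    lambda = 0, tol = 1e-8, maxit = 10000L,
                                    r_init = NULL,
                                    nearest_k = default_nearest_k(modules)) {
  stopifnot(all(gammas >= 0), all(gammas < 1))
  if (is.null(modules)) stop("module names required (name `gammas`)")
  feats <- mirl_features(data, modules, nearest_k = nearest_k)
  N <- length(modules)
  if (is.null(r_init)) r_init <- numeric(N)
  res <- cpp_fit_rewards(feats$dist, feats$obs, feats$T, feats$K,
                         gammas = as.numeric(gammas), eta = eta,
                         lambda = lambda, r_init = r_init,
                         r_free = rep(TRUE, N), tol = tol, maxit = maxit)
  list(rewards = setNames(res$rewards, modules),
       objective = res$objective, loglik = res$loglik)
}

#' Normalize module rewards to unit absolute sum
#'
#' Divides each reward by the sum of absolute rewards, preserving signs,
#' so magnitudes are comparable across subjects and tasks (and across the
#' unidentifiable `eta * r` scale).
#'
#' @param rewards Numeric vector with at least one nonzero entry.
#' @return Normalized rewards; absolute values sum to one.
#' @export
normalize_rewards <- function(rewards) {
  s <- sum(abs(rewards))
  if (s == 0) stop("cannot normalize all-zero rewards")
  rewards / s
}

#' Tabulate one or more fits as a delimited-ready data frame
#'
#' @param fits A `"mirl"` fit or list of fits.
#' @param subjects,tasks Optional label vectors aligned with `fits`.
#' @return Data frame with one row per subject/task/module.
#' @export
result_table <- function(fits, subjects = NULL, tasks = NULL) {
  if (inherits(fits, "mirl")) fits <- list(fits)
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject = if (is.null(subjects)) NA else subjects[i],
               task = if (is.null(tasks)) NA else tasks[i],
               module = f$module_names,
               reward = unname(f$rewards),
               normalized_reward = unname(f$normalized),
               gamma = unname(f$gammas),
               objective = f$objective,
               stringsAsFactors = FALSE)
  }))
}
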