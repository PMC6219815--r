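# Hand-built fixtures shared across test files.  All rooms are generated
# in code; nothing is read from disk.

# A straight east-west path along y = y0 with `n` waypoints one cell
# apart, plus optional hand-placed targets/obstacles.
straight_env <- function(n_wp = 10, targets = NULL, obstacles = NULL,
                         y0 = 3, x0 = 1, cell = 0.572, K = 16) {
  wp <- cbind(x0 + (seq_len(n_wp) - 1) * cell, y0)
  make_environment(grid_spec(cell_size = cell), action_set(K),
                   targets = targets, obstacles = obstacles, waypoints = wp)
}

# Module set with all-object sums (no lookahead window) for analytic cases.
flat_modules <- function(names, rewards, gammas) {
  module_set_from(names, rewards, gammas, nearest_k = Inf)
}

# Tiny seeded dataset from known parameters; defaults small enough for
# fast unit tests.
tiny_dataset <- function(seed = 1, n_traj = 2, eta = 3,
                         rewards = c(0.3, -0.3, 0.4),
                         gammas = c(0.7, 0.65, 0.93),
                         n_targets = 4, n_obstacles = 4, max_steps = 300) {
  truth <- module_set_from(c("target", "obstacle", "path"), rewards, gammas)
  trajs <- lapply(seq_len(n_traj), function(i) {
    env <- generate_environment(n_targets = n_targets,
                                n_obstacles = n_obstacles,
                                seed = seed * 100 + i)
    rollout(env, truth, policy("softmax", eta = eta, seed = seed * 200 + i),
            max_steps = max_steps, subject = "S1", task = 4, trial = i)
  })
  list(data = mirl_dataset(trajs), truth = truth)
}

# Reference log-likelihood built directly from per-state softmax
# probabilities (independent of the feature-table/C++ path).
brute_loglik <- function(data, modules, eta = 1) {
  if (inherits(data, "mirl_trajectory")) data <- mirl_dataset(data)
  sum(vapply(unclass(data), function(traj) {
    al <- replay_states(traj)
    sum(vapply(seq_along(traj$actions), function(t) {
      st <- modirl:::state_at(traj, t, al)
      p <- action_likelihoods(traj$env, st, modules, eta = eta)
      log(p[traj$actions[t] + 1])
    }, 0))
  }, 0))
}
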