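test_that("module_q follows the closed form r * gamma^d", {
  expect_equal(module_q(module_params("m", 1, 0.5), 2), 0.25)
  expect_equal(module_q(module_params("m", -1, 0.5), 1), -0.5)
  # zero-distance limit holds even for a myopic module (0^0 = 1)
  expect_equal(module_q(module_params("m", 3, 0), 0), 3)
  expect_equal(module_q(module_params("m", 3, 0.99), 0), 3)
  expect_error(module_params("m", 1, 1), "gamma")
  expect_error(module_params("m", 1, -0.1), "gamma")
})

test_that("module_q strictly decreases in distance for positive reward", {
  p <- module_params("m", 2, 0.8)
  d <- seq(0, 10, by = 0.25)
  expect_true(all(diff(module_q(p, d)) < 0))
})

test_that("global_q sums module contributions over live objects", {
  # two modules with one object each at post-action distance 1 (east)
  env <- straight_env(n_wp = 2, targets = rbind(c(3.144, 3)),
                      obstacles = rbind(c(3.144, 3 + 0.572)))
  st <- env_state(env, start = c(2, 3))
  mods <- flat_modules(c("target", "obstacle"), c(1, -1), c(0.5, 0.5))
  # symmetric rewards at equal distances cancel
  d_t <- distance_after_action(env, st, 0L,
                               which(env$objects$module == "target"))
  d_o <- distance_after_action(env, st, 0L,
                               which(env$objects$module == "obstacle"))
  q <- global_q(env, st, 0L, mods)
  expect_equal(q, 0.5^d_t - 0.5^d_o)

  # one module, two objects: contributions add (0.5 + 0.25 at d = 1, 2)
  env2 <- straight_env(n_wp = 2,
                       targets = rbind(c(2 + 2 * 0.572, 3),
                                       c(2 + 3 * 0.572, 3)))
  st2 <- env_state(env2, start = c(2, 3))
  m2 <- flat_modules("target", 1, 0.5)
  expect_equal(global_q(env2, st2, 0L, m2), 0.75, tolerance = 1e-12)

  # all-zero rewards give a null field for every action
  m0 <- flat_modules(c("target", "path"), c(0, 0), c(0.5, 0.9))
  qs <- vapply(0:15, function(a) global_q(env2, st2, a, m0), 0)
  expect_equal(qs, rep(0, 16))
})

test_that("global_q is additive over disjoint module sets", {
  env <- generate_environment(seed = 17)
  st <- env_state(env)
  a <- module_set(module_params("target", 0.7, 0.8))
  b <- module_set(module_params("obstacle", -0.4, 0.6),
                  module_params("path", 0.5, 0.93, nearest_k = 2))
  ab <- module_set(c(unclass(a), unclass(b)))
  for (act in c(0L, 3L, 9L, 14L)) {
    expect_equal(global_q(env, st, act, ab),
                 global_q(env, st, act, a) + global_q(env, st, act, b),
                 tolerance = 1e-12)
  }
})

test_that("softmax likelihoods: uniformity, analytic case, eta limits", {
  env <- straight_env(n_wp = 2)
  st <- env_state(env, start = c(4, 5))
  m0 <- flat_modules("target", 0, 0.5)    # no objects of this module live
  p <- action_likelihoods(env, st, m0, eta = 1)
  expect_equal(p, rep(1 / 16, 16), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # K = 2, Q = (ln 2, 0) -> (2/3, 1/3)
  expect_equal(modirl:::softmax_probs(c(log(2), 0)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  # eta = 0 is uniform regardless of Q
  mods <- flat_modules("path", 5, 0.9)
  p0 <- action_likelihoods(env, st, mods, eta = 0)
  expect_equal(p0, rep(1 / 16, 16), tolerance = 1e-12)
})

test_that("likelihoods are invariant under (c*eta, r/c) rescaling", {
  env <- generate_environment(seed = 23)
  st <- env_state(env)
  for (c_ in c(0.25, 4, 17)) {
    m1 <- module_set_from(c("target", "obstacle", "path"),
                          c(0.5, -0.3, 0.6), c(0.7, 0.6, 0.9))
    m2 <- module_set_from(c("target", "obstacle", "path"),
                          c(0.5, -0.3, 0.6) / c_, c(0.7, 0.6, 0.9))
    p1 <- action_likelihoods(env, st, m1, eta = 2)
    p2 <- action_likelihoods(env, st, m2, eta = 2 * c_)
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("likelihood vectors sum to one across random states", {
  env <- generate_environment(seed = 29)
  mods <- module_set_from(c("target", "obstacle", "path"),
                          c(0.4, -0.2, 0.4), c(0.8, 0.7, 0.92))
  tr <- rollout(env, mods, policy("softmax", eta = 2, seed = 4),
                max_steps = 120)
  al <- replay_states(tr)
  for (t in seq(1, length(tr$actions), by = 5)) {
    st <- modirl:::state_at(tr, t, al)
    expect_equal(sum(action_likelihoods(env, st, mods, eta = 2)), 1,
                 tolerance = 1e-12)
  }
})

test_that("select_action: greedy tie-break and seeded softmax draws", {
  expect_equal(select_action(c(0, 5, 5), policy("greedy")), 1L)
  expect_equal(select_action(c(7, 5, 5), policy("greedy")), 0L)
  # a probability-one action is always drawn
  pol <- policy("softmax", eta = 50, seed = 1)
  expect_equal(modirl:::with_local_seed(1,
    select_action(c(0, 100, 0), pol)), 1L)
  # identical seeds give identical rollout action sequences
  env <- generate_environment(seed = 41)
  mods <- module_set_from(c("target", "path"), c(0.4, 0.5), c(0.7, 0.93))
  t1 <- rollout(env, mods, policy("softmax", eta = 2, seed = 9))
  t2 <- rollout(env, mods, policy("softmax", eta = 2, seed = 9))
  expect_identical(t1$actions, t2$actions)
})

test_that("greedy path following consumes waypoints in order", {
  env <- generate_environment(n_targets = 0, n_obstacles = 0, seed = 7)
  mods <- module_set(module_params("path", 0.5, 0.93, nearest_k = 2))
  tr <- rollout(env, mods, policy("greedy"), max_steps = 400)
  al <- replay_states(tr)
  # goal reached
  expect_false(al[nrow(al), env$goal_id])
  # consumption times of waypoints are sorted along the path
  ct <- apply(al[, env$waypoint_ids, drop = FALSE], 2,
              function(col) if (any(!col)) which(!col)[1] else NA)
  expect_true(all(diff(ct[!is.na(ct)]) >= 0))
  expect_lte(mean(is.na(ct)), 0.2)   # nearly all waypoints visited
})

test_that("zero-reward greedy agent repeats action 0 until the cap", {
  # waypoints sit far from the agent's course so nothing terminates it
  wp <- cbind(1, 5 + (0:3) * 0.572)
  env <- make_environment(grid_spec(), action_set(), waypoints = wp)
  mods <- flat_modules(c("target", "path"), c(0, 0), c(0.5, 0.9))
  tr <- rollout(env, mods, policy("greedy"), max_steps = 30,
                start = c(1, 1))
  expect_equal(length(tr$actions), 30)
  expect_true(all(tr$actions == 0L))
})

test_that("greedy agent intercepts a lone eastward target monotonically", {
  env <- straight_env(n_wp = 2, targets = rbind(c(6, 3)), y0 = 6, x0 = 1)
  mods <- flat_modules("target", 1, 0.8)
  tr <- rollout(env, mods, policy("greedy"), max_steps = 50,
                start = c(2, 3))
  tid <- which(env$objects$module == "target")
  al <- replay_states(tr)
  d <- sqrt((tr$positions[, 1] - 6)^2 + (tr$positions[, 2] - 3)^2)
  k <- which(!al[, tid])[1]              # consumption step
  expect_false(is.na(k))
  expect_true(all(diff(d[1:k]) < 0))
})

test_that("value surface: flat without rewards, peaked at objects, linear in r", {
  env <- straight_env(n_wp = 2, targets = rbind(c(4, 4)))
  m0 <- flat_modules(c("target", "path"), c(0, 0), c(0.8, 0.9))
  s0 <- value_surface(env, m0, resolution = 0.5)
  expect_true(all(s0$value == 0))

  m1 <- flat_modules("target", 1, 0.8)
  s1 <- value_surface(env, m1, resolution = 0.25)
  peak <- which(s1$value == max(s1$value), arr.ind = TRUE)[1, ]
  expect_equal(s1$x[peak[1]], 4, tolerance = 0.26)
  expect_equal(s1$y[peak[2]], 4, tolerance = 0.26)

  m2 <- flat_modules("target", 2, 0.8)
  s2 <- value_surface(env, m2, resolution = 0.25)
  expect_equal(s2$value, 2 * s1$value, tolerance = 1e-12)
})

test_that("modular state enumeration grows additively, joint multiplicatively", {
  # small synthetic module state spaces: per-module discrete domains
  sizes <- c(12L, 9L, 7L)
  spaces <- lapply(sizes, seq_len)
  modular_cost <- sum(vapply(spaces, length, 0L))
  joint <- expand.grid(spaces)
  expect_equal(modular_cost, sum(sizes))
  expect_equal(nrow(joint), prod(sizes))
  # adding one more module: modular cost grows by its size, joint by a factor
  extra <- 5L
  expect_equal(sum(c(sizes, extra)), modular_cost + extra)
  expect_equal(prod(c(sizes, extra)), nrow(joint) * extra)
  expect_lt(modular_cost + extra, prod(c(sizes, extra)))
})
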