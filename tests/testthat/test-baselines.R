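test_that("task relevance map encodes the four instruction conditions", {
  expect_equal(task_relevance(1), c(target = 0, obstacle = 0, path = 1))
  expect_equal(task_relevance(2), c(target = 0, obstacle = -1, path = 1))
  expect_equal(task_relevance(3), c(target = 1, obstacle = 0, path = 1))
  expect_equal(task_relevance(4), c(target = 1, obstacle = -1, path = 1))
  expect_error(task_relevance(5))
})

test_that("binary-reward agent clamps rewards and estimates discounts only", {
  td <- tiny_dataset(seed = 21, n_traj = 3, rewards = c(0, -1, 1),
                     max_steps = 250)
  rel <- task_relevance(2)        # path +1, obstacle -1, target 0
  fit <- mirl_binary(td$data, rel, epsilon = 0.05)
  expect_identical(unname(fit$rewards), unname(as.numeric(rel)))
  expect_s3_class(fit, "mirl")
  # the irrelevant module's discount is not searched
  expect_equal(unname(fit$gammas["target"]), 0)
  # refits on different data only move the discounts
  td2 <- tiny_dataset(seed = 22, n_traj = 3, rewards = c(0, -1, 1),
                      max_steps = 250)
  fit2 <- mirl_binary(td2$data, rel, epsilon = 0.05)
  expect_identical(fit2$rewards, fit$rewards)
  # determinism given data and config
  fit3 <- mirl_binary(td$data, rel, epsilon = 0.05)
  expect_identical(coef(fit3), coef(fit))
})

test_that("binary-reward agent recovers discounts from unit-reward data", {
  truth_g <- c(target = 0.7, obstacle = 0.65, path = 0.9)
  truth <- module_set_from(names(truth_g), c(1, -1, 1), unname(truth_g))
  trajs <- lapply(1:16, function(i) {
    env <- generate_environment(n_targets = 10, n_obstacles = 10,
                                seed = 700 + i)
    rollout(env, truth, policy("softmax", eta = 4, seed = 80 + i),
            max_steps = 600)
  })
  fit <- mirl_binary(mirl_dataset(trajs), task_relevance(4), eta = 4,
                     epsilon = 0.02)
  for (m in names(truth_g)) {
    expect_lte(abs(fit$gammas[[m]] - truth_g[[m]]), 0.02 + 1e-9)
  }
})

test_that("fixed-discount agent pins gamma and recovers rewards", {
  shared_g <- 0.8
  truth <- module_set_from(c("target", "obstacle", "path"),
                           c(1.2, -0.9, 1.5), rep(shared_g, 3))
  trajs <- lapply(1:8, function(i) {
    env <- generate_environment(seed = 800 + i)
    rollout(env, truth, policy("softmax", eta = 2, seed = 90 + i),
            max_steps = 500)
  })
  d <- mirl_dataset(trajs)
  fit <- mirl_fixed_gamma(d, shared_g)
  expect_true(all(fit$gammas == shared_g))
  expect_equal(unname(fit$normalized),
               unname(normalize_rewards(c(1.2, -0.9, 1.5))),
               tolerance = 0.05)
  # when the pinned discount equals the shared truth, reward recovery
  # matches the full fit
  full <- mirl(d, epsilon = 0.05)
  expect_equal(unname(fit$normalized), unname(full$normalized),
               tolerance = 0.05)
})

test_that("estimating discounts beats a wrong fixed discount out of sample", {
  truth <- module_set_from(c("target", "obstacle", "path"),
                           c(1.3, -1.0, 1.4), c(0.8, 0.6, 0.94))
  trajs <- lapply(1:6, function(i) {
    env <- generate_environment(seed = 900 + i)
    rollout(env, truth, policy("softmax", eta = 3, seed = 60 + i),
            max_steps = 500)
  })
  train <- mirl_dataset(trajs[1:5])
  held <- mirl_dataset(trajs[6])
  full <- mirl(train, epsilon = 0.05)
  fixed <- mirl_fixed_gamma(train, 0.3)
  ll_full <- log_likelihood(held, fitted_modules(full))
  ll_fixed <- log_likelihood(held, fitted_modules(fixed))
  expect_gte(ll_full, ll_fixed)
})

test_that("value iteration on the joint MDP converges below tolerance", {
  env <- generate_environment(seed = 101)
  spec <- joint_mdp_spec(gamma = 0.99, vi_tol = 1e-6)
  mdp <- modirl:::joint_mdp(env, spec)
  res <- modirl:::joint_vi(mdp, c(target = 1, obstacle = -1, path = 0.5),
                           spec)
  expect_lt(res$residual, 1e-6)
  expect_equal(dim(res$Q), c(mdp$n, 16))
  # state-space cap is enforced
  tiny <- joint_mdp_spec(cell_size = 0.1, max_states = 100)
  expect_error(modirl:::joint_mdp(env, tiny), "max_states")
})

test_that("Bayesian IRL matches the modular greedy policy in a one-object world", {
  # with a single rewarded object the modular decomposition is trivial,
  # so the joint fit and the modular fit should induce the same greedy
  # policy wherever the object still shapes the field (after it is
  # consumed the modular field is empty and both policies are arbitrary)
  truth <- module_set_from("target", 4, 0.8)
  starts <- list(c(1.2, 1.5), c(7.3, 5.9), c(2.1, 5.4), c(6.8, 1.4),
                 c(4.2, 6.1), c(1.8, 3.6))
  mk <- function(i) {
    env <- generate_environment(n_targets = 1, n_obstacles = 0,
                                seed = 110 + i)
    rollout(env, truth, policy("softmax", eta = 6, seed = 10 + i),
            max_steps = 25, start = starts[[i]])
  }
  train <- mirl_dataset(lapply(1:5, mk))
  bfit <- birl(train, joint_mdp_spec(gamma = 0.8), maxit = 150)
  mfit <- mirl(train, modules = "target", epsilon = 0.05)
  # the learned joint reward puts positive weight on target occupancy
  expect_gt(bfit$weights[["target"]], 0)
  held <- mk(6)
  live <- replay_states(held)[seq_along(held$actions),
                              which(held$env$objects$module == "target")]
  expect_gte(sum(live), 5)
  pa_b <- policy_actions(bfit, held)
  pa_m <- policy_actions(mfit, held)
  agree <- mean(modirl:::angular_diff_deg(pa_b, pa_m, 16)[live])
  # same greedy policy up to about one heading bin of discretization
  expect_lte(agree, 25)
})
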