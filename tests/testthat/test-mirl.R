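test_that("convex reward fit recovers scaled rewards at the true discounts", {
  truth_r <- c(1, -1, 1)
  truth_g <- c(0.7, 0.65, 0.93)
  truth <- module_set_from(c("target", "obstacle", "path"), truth_r, truth_g)
  trajs <- lapply(1:12, function(i) {
    env <- generate_environment(n_targets = 8, n_obstacles = 8,
                                seed = 600 + i)
    rollout(env, truth, policy("softmax", eta = 3, seed = 70 + i),
            max_steps = 400)
  })
  d <- mirl_dataset(trajs)
  fr <- fit_rewards_fixed_gamma(d, setNames(truth_g,
                                            c("target", "obstacle", "path")))
  est <- normalize_rewards(fr$rewards)
  expect_equal(unname(est), unname(normalize_rewards(truth_r)),
               tolerance = 0.05)
  # ascent from the origin never ends below the origin's objective
  m0 <- module_set_from(c("target", "obstacle", "path"), c(0, 0, 0), truth_g)
  expect_gte(fr$objective, mirl_objective(d, m0))
})

test_that("uniform-random behavior with a penalty shrinks all rewards to zero", {
  env <- generate_environment(seed = 91)
  set.seed(14)
  acts <- sample(0:15, 150, replace = TRUE)
  st <- env_state(env)
  pos <- matrix(st$pos, ncol = 2)
  for (a in acts) {
    st <- env_step(env, st, a)
    pos <- rbind(pos, st$pos)
  }
  d <- mirl_dataset(trajectory(env, pos, acts))
  fr <- fit_rewards_fixed_gamma(d, c(target = 0.7, obstacle = 0.7,
                                     path = 0.9), lambda = 5)
  expect_equal(unname(fr$rewards), c(0, 0, 0))
})

test_that("negative objective is midpoint-convex in the rewards at fixed gamma", {
  td <- tiny_dataset(seed = 6, n_traj = 2, max_steps = 150)
  gam <- c(0.7, 0.6, 0.9)
  f <- function(r, lambda = 0.5)
    mirl_objective(td$data,
                   module_set_from(c("target", "obstacle", "path"), r, gam),
                   lambda = lambda)
  set.seed(10)
  for (i in 1:25) {
    r1 <- rnorm(3, sd = 2); r2 <- rnorm(3, sd = 2)
    mid <- f((r1 + r2) / 2)
    expect_gte(mid, (f(r1) + f(r2)) / 2 - 1e-9)
  }
})

test_that("fit matches an independent exhaustive-lattice oracle (1 module)", {
  truth <- module_set_from("target", 1.6, 0.7)
  env <- generate_environment(n_targets = 6, n_obstacles = 0, seed = 55)
  tr <- rollout(env, truth, policy("softmax", eta = 1, seed = 5),
                max_steps = 25)
  d <- mirl_dataset(tr)
  fit <- mirl(d, modules = "target", epsilon = 0.02, search = "exhaustive")
  feats <- modirl:::mirl_features(d, "target")
  grid <- modirl:::gamma_grid(0.02, 0.98)
  oracle <- max(vapply(grid, function(g) {
    stats::optimize(function(r)
      modirl:::loglik_from_features(feats, r, g, 1),
      interval = c(-40, 40), maximum = TRUE, tol = 1e-10)$objective
  }, 0))
  expect_equal(fit$objective, oracle, tolerance = 1e-6)
})

test_that("fit matches an independent exhaustive-lattice oracle (2 modules)", {
  truth <- module_set_from(c("target", "path"), c(1.2, 1.8), c(0.7, 0.9))
  env <- generate_environment(n_targets = 5, n_obstacles = 0, seed = 66)
  tr <- rollout(env, truth, policy("softmax", eta = 1, seed = 9),
                max_steps = 30)
  d <- mirl_dataset(tr)
  fit <- mirl(d, modules = c("target", "path"), epsilon = 0.1,
              gamma_max = 0.9, search = "exhaustive")
  feats <- modirl:::mirl_features(d, c("target", "path"))
  grid <- modirl:::gamma_grid(0.1, 0.9)
  nodes <- expand.grid(g1 = grid, g2 = grid)
  oracle <- max(vapply(seq_len(nrow(nodes)), function(i) {
    gg <- c(nodes$g1[i], nodes$g2[i])
    best <- -Inf
    for (start in list(c(0, 0), c(2, 2))) {
      o <- stats::optim(start, function(r)
        -modirl:::loglik_from_features(feats, r, gg, 1),
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14))
      best <- max(best, -o$value)
    }
    best
  }, 0))
  expect_equal(fit$objective, oracle, tolerance = 1e-6)
})

test_that("staged search agrees with exhaustive search on a 3-module fit", {
  td <- tiny_dataset(seed = 9, n_traj = 3, max_steps = 200)
  f_st <- mirl(td$data, epsilon = 0.05, search = "staged")
  f_ex <- mirl(td$data, epsilon = 0.05, search = "exhaustive")
  expect_equal(f_st$objective, f_ex$objective, tolerance = 1e-8)
  expect_equal(f_st$gammas, f_ex$gammas)
})

test_that("fits are deterministic given data and configuration", {
  td <- tiny_dataset(seed = 12, n_traj = 2, max_steps = 150)
  f1 <- mirl(td$data, epsilon = 0.05)
  f2 <- mirl(td$data, epsilon = 0.05)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$profile, f2$profile)
})

test_that("lambda sweep: active-set size is non-increasing", {
  td <- tiny_dataset(seed = 15, n_traj = 2, max_steps = 200)
  gam <- c(target = 0.7, obstacle = 0.65, path = 0.93)
  sizes <- vapply(c(0, 1, 3, 8, 20, 60, 200), function(l) {
    fr <- fit_rewards_fixed_gamma(td$data, gam, lambda = l)
    sum(fr$rewards != 0)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0L)   # huge penalty kills everything
})

test_that("normalize_rewards preserves signs and unit absolute sum", {
  expect_equal(normalize_rewards(c(2, -2, 4)), c(0.25, -0.25, 0.5))
  expect_equal(normalize_rewards(c(1, 0, 0)), c(1, 0, 0))
  set.seed(2)
  for (i in 1:10) {
    r <- rnorm(4)
    n <- normalize_rewards(r)
    expect_equal(sum(abs(n)), 1, tolerance = 1e-12)
    expect_equal(sign(n), sign(r))
  }
  expect_error(normalize_rewards(c(0, 0)), "zero")
})

test_that("grid cap rejects oversized exhaustive searches with advice", {
  td <- tiny_dataset(seed = 16, n_traj = 1, max_steps = 60)
  expect_error(mirl(td$data, epsilon = 0.02, search = "exhaustive",
                    grid_cap = 1000),
               "coarser")
})

test_that("gamma profile and result table are well-formed", {
  td <- tiny_dataset(seed = 17, n_traj = 2, max_steps = 150)
  fit <- mirl(td$data, epsilon = 0.1)
  expect_equal(sort(unique(fit$profile$module)),
               sort(c("target", "obstacle", "path")))
  best <- max(fit$profile$objective, na.rm = TRUE)
  expect_equal(best, fit$objective, tolerance = 1e-9)
  tab <- result_table(fit, subjects = "S1", tasks = "4")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(abs(tab$normalized_reward)), 1, tolerance = 1e-12)
  expect_true(all(c("subject", "task", "module", "reward",
                    "normalized_reward", "gamma", "objective")
                  %in% names(tab)))
})
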