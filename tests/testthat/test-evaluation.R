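test_that("angular difference: zero on own greedy actions, 180 when opposed", {
  env <- generate_environment(seed = 121)
  mods <- module_set_from(c("target", "obstacle", "path"),
                          c(0.5, -0.4, 0.6), c(0.7, 0.6, 0.93))
  tr <- rollout(env, mods, policy("greedy"), max_steps = 120)
  expect_equal(angular_difference(tr, mods), 0)
  # flip every action by 8 bins (180 degrees)
  opp <- trajectory(env, tr$positions, (tr$actions + 8L) %% 16L)
  # replay of flipped actions against the same positions: the greedy
  # agent still proposes the original headings
  expect_equal(angular_difference(opp, mods), 180)
  expect_error(angular_difference(
    trajectory(env, tr$positions[1, , drop = FALSE], integer(0)), mods),
    "empty")
})

test_that("angular difference against a uniform reference averages 90 degrees", {
  # enumerate the 16 absolute bin differences to any fixed action
  for (a in c(0L, 5L, 12L)) {
    diffs <- modirl:::angular_diff_deg(0:15, a, 16)
    expect_equal(mean(diffs), 90)
    expect_true(all(diffs >= 0 & diffs <= 180))
  }
})

test_that("angular difference is invariant under global rotation", {
  env <- generate_environment(seed = 131)
  mods <- module_set_from(c("target", "path"), c(0.5, 0.5), c(0.7, 0.93))
  tr <- rollout(env, mods, policy("softmax", eta = 2, seed = 3),
                max_steps = 80)
  pred <- policy_actions(mods, tr)
  base <- mean(modirl:::angular_diff_deg(pred, tr$actions, 16))
  for (rot in c(1L, 4L, 9L)) {
    rotated <- mean(modirl:::angular_diff_deg((pred + rot) %% 16L,
                                              (tr$actions + rot) %% 16L, 16))
    expect_equal(rotated, base, tolerance = 1e-12)
  }
})

test_that("interception counts are consistent, bounded, and reproducible", {
  env <- generate_environment(seed = 141)
  mods <- module_set_from(c("target", "obstacle", "path"),
                          c(0.5, -0.4, 0.6), c(0.75, 0.6, 0.93))
  tr <- rollout(env, mods, policy("softmax", eta = 4, seed = 8),
                max_steps = 600)
  n1 <- count_intercepted(tr)
  expect_lte(n1[["target"]], 12)
  expect_lte(n1[["obstacle"]], 12)
  expect_identical(count_intercepted(tr), n1)
  # a room without obstacles cannot produce obstacle hits
  env0 <- straight_env(n_wp = 8)
  tr0 <- rollout(env0, module_set(module_params("path", 1, 0.9)),
                 policy("greedy"), max_steps = 50)
  expect_equal(count_intercepted(tr0)[["obstacle"]], 0L)
})

test_that("trajectory clouds: greedy degeneracy, density bookkeeping, determinism", {
  env <- generate_environment(n_targets = 4, n_obstacles = 4, seed = 151)
  mods <- module_set_from(c("target", "obstacle", "path"),
                          c(0.4, -0.3, 0.6), c(0.7, 0.6, 0.93))
  gcl <- trajectory_cloud(env, mods, n_rollouts = 5, seed = 1,
                          greedy = TRUE, max_steps = 200)
  for (i in 2:5) {
    expect_identical(gcl$trajectories[[i]]$positions,
                     gcl$trajectories[[1]]$positions)
  }
  cl <- trajectory_cloud(env, mods, eta = 3, n_rollouts = 6, seed = 2,
                         max_steps = 200)
  total_positions <- sum(vapply(unclass(cl$trajectories),
                                function(t) nrow(t$positions), 0L))
  expect_equal(sum(cl$density$count), total_positions)
  cl2 <- trajectory_cloud(env, mods, eta = 3, n_rollouts = 6, seed = 2,
                          max_steps = 200)
  expect_identical(cl$density$count, cl2$density$count)
  # different seeds give different clouds
  cl3 <- trajectory_cloud(env, mods, eta = 3, n_rollouts = 6, seed = 3,
                          max_steps = 200)
  expect_false(identical(cl$density$count, cl3$density$count))
})

test_that("leave-one-out fits every fold and skips singleton groups", {
  subs <- sample_subjects(2, seed = 400)
  cohort <- suppressMessages(
    simulate_dataset(subs, tasks = 3, trials_per_task = 3, seed = 401,
                     n_targets = 6, n_obstacles = 6))
  rep1 <- leave_one_out(cohort$data, epsilon = 0.1, search = "staged")
  expect_equal(nrow(rep1), 6)           # 2 subjects x 3 folds
  expect_equal(as.integer(table(rep1$subject)), c(3L, 3L))
  expect_true(all(rep1$angular_deg >= 0 & rep1$angular_deg <= 180))
  fits <- attr(rep1, "fits")
  expect_length(fits, 6)
  # each fold trained on 2 of the 3 trials
  expect_true(all(vapply(fits, function(f) f$n_trajectories, 0L) == 2L))

  # singleton group warns and is skipped
  one <- cohort$data[1:3]   # two trials of one subject, one of the other
  expect_warning(rep2 <- leave_one_out(one, epsilon = 0.1), "single")
  expect_equal(nrow(rep2), 2)

  agg <- aggregate_report(rep1, by = "subject")
  expect_equal(nrow(agg), 2)
  expect_true(all(agg$n == 3))
})

test_that("task-4 synthesis follows the combination rules", {
  fake <- function(norm, gam) {
    structure(list(module_names = names(norm), normalized = norm,
                   gammas = gam), class = "mirl")
  }
  t2 <- fake(c(target = 0.05, obstacle = -0.45, path = 0.5),
             c(target = 0.3, obstacle = 0.65, path = 0.92))
  t3 <- fake(c(target = 0.4, obstacle = -0.1, path = 0.3),
             c(target = 0.75, obstacle = 0.4, path = 0.94))
  syn <- synthesize_task4(t2, t3)
  # raw combination: target from task 3, obstacle from task 2, path mean
  expect_equal(unname(syn$rewards_raw["path"]), 0.4)
  expect_equal(unname(syn$rewards_raw["target"]), 0.4)
  expect_equal(unname(syn$rewards_raw["obstacle"]), -0.45)
  # discounts synthesized the same way
  expect_equal(unname(syn$gammas["target"]), 0.75)
  expect_equal(unname(syn$gammas["obstacle"]), 0.65)
  expect_equal(unname(syn$gammas["path"]), 0.93)
  # re-normalized rewards
  expect_equal(sum(abs(syn$rewards)), 1, tolerance = 1e-12)
  # missing module coverage is an error
  t2bad <- fake(c(target = 1), c(target = 0.5))
  expect_error(synthesize_task4(t2bad, t3), "path")
})
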