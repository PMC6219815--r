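#' Default parameter ranges of the synthetic cohort
#'
#' Between-subject heterogeneity of the generator: base module weights
#' are drawn from a symmetric Dirichlet over (target, obstacle, path),
#' discount factors uniformly per module (path high and stable, target
#' and obstacle lower and more variable), and the behavioral confidence
#' `eta` uniformly.  Task-irrelevant modules keep a small fraction
#' (`irrelevant_scale`) of their weight, mimicking residual obstacle
#' avoidance under irrelevant instructions; the obstacle reward is
#' negative.
#'
#' @return Named list of ranges, overridable entry-wise via the `ranges`
#'   argument of [sample_subjects()].
#' @export
default_subject_ranges <- function() {
  list(alpha = c(2, 2, 3),
       weights = NULL,                     # fixed base weights (skip Dirichlet)
       min_weight = 0.12,                  # rejection floor per module weight
       gamma = list(target = c(0.60, 0.85), obstacle = c(0.55, 0.80),
                    path = c(0.88, 0.96)),
       eta = c(3, 8),
       irrelevant_scale = 0.2)
}

#' Sample a cohort of synthetic subjects
#'
#' Each subject owns one base weight vector, one discount factor per
#' module and one behavioral `eta`, shared across task conditions; the
#' task instruction only rescales (down-weights or zeroes) irrelevant
#' modules.  This makes module parameters transferable across tasks, the
#' regime in which cross-task synthesis is exact.
#'
#' @param n Number of subjects (the study cohort has 25).
#' @param seed Integer seed.
#' @param ranges Overrides merged into [default_subject_ranges()].
#' @return List of `"synthetic_subject"` objects.
#' @export
sample_subjects <- function(n = 25L, seed, ranges = list()) {
  rg <- modifyList(default_subject_ranges(), ranges)
  with_local_seed(seed, lapply(seq_len(n), function(i) {
    w <- if (!is.null(rg$weights)) rg$weights
    else {
      # reject draws with a near-irrelevant module: every module of the
      # study cohort carries appreciable weight (cf. the floor of human
      # normalized reward estimates), and the discount factor of a
      # near-zero-reward module would be unidentifiable by design
      repeat {
        g <- rgamma(3, shape = rep_len(rg$alpha, 3))
        g <- g / sum(g)
        if (min(g) >= rg$min_weight) break
      }
      g
    }
    names(w) <- c("target", "obstacle", "path")
    gam <- vapply(c("target", "obstacle", "path"), function(m)
      runif(1, rg$gamma[[m]][1], rg$gamma[[m]][2]), 0)
    structure(list(id = sprintf("S%02d", i),
                   base_weights = w, gammas = gam,
                   eta = runif(1, rg$eta[1], rg$eta[2]),
                   irrelevant_scale = rg$irrelevant_scale),
              class = "synthetic_subject")
  }))
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject %s> eta %.2f\n", x$id, x$eta))
  print(round(rbind(weight = x$base_weights, gamma = x$gammas), 3))
  invisible(x)
}

#' True module set of a subject under a task condition
#'
#' @param subject A `"synthetic_subject"`.
#' @param task Task condition 1--4.
#' @return A [module_set()] with the subject's true parameters (obstacle
#'   reward negative; irrelevant modules scaled down).
#' @export
subject_modules <- function(subject, task) {
  rel <- task_relevance(task)
  sign <- c(target = 1, obstacle = -1, path = 1)
  scale <- ifelse(rel != 0, 1, subject$irrelevant_scale)
  r <- sign * subject$base_weights * scale
  module_set_from(names(r), unname(r), unname(subject$gammas[names(r)]))
}

#' Simulate a behavioral dataset from a synthetic cohort
#'
#' For every subject, task and trial a fresh environment is generated
#' (objects and path differ per trial; subjects share the per-trial
#' environments, as in the study) and a softmax rollout is produced under
#' the subject's true parameters.  Rollouts that hit the step cap without
#' reaching the goal are regenerated with the next derived seed (logged
#' via `message`).
#'
#' @param subjects From [sample_subjects()].
#' @param tasks Task conditions to simulate (default all four).
#' @param trials_per_task Trials per subject and task (study: 4).
#' @param seed Integer master seed; all environment and rollout seeds are
#'   derived from it.
#' @param n_targets,n_obstacles Objects per environment.
#' @param grid,actions Room geometry and action set.
#' @param max_steps Rollout cap; generously high by default so that
#'   essentially every trial ends at the goal naturally, as the study's
#'   human trials do -- regenerating capped rollouts would select the
#'   sample on goal completion and bias estimation.
#' @return List of class `"synthetic_cohort"` with `data` (a
#'   [mirl_dataset()]), `truth` (per subject/task/module parameter table)
#'   and `trial_seeds` (per-trial provenance).
#' @export
simulate_dataset <- function(subjects, tasks = 1:4, trials_per_task = 4L,
                             seed, n_targets = 12L, n_obstacles = 12L,
                             grid = grid_spec(), actions = action_set(),
                             max_steps = 2000L) {
  stopifnot(trials_per_task >= 1L)
  trajs <- list(); truth <- list(); seeds <- list()
  for (task in tasks) {
    for (trial in seq_len(trials_per_task)) {
      env_seed <- derive_seed(seed, "env", task, trial)
      env <- generate_environment(grid, actions, n_targets, n_obstacles,
                                  seed = env_seed)
      for (sub in subjects) {
        mods <- subject_modules(sub, task)
        attempt <- 0L
        repeat {
          rseed <- derive_seed(seed, "roll", sub$id, task, trial, attempt)
          tr <- rollout(env, mods, policy("softmax", eta = sub$eta,
                                          seed = rseed),
                        max_steps = max_steps, subject = sub$id,
                        task = task, trial = trial)
          done <- !replay_states(tr)[nrow(tr$positions), env$goal_id]
          if (done || attempt >= 5L) break
          attempt <- attempt + 1L
          message(sprintf(
            "rollout %s/task%s/trial%s hit step cap; regenerating (%d)",
            sub$id, task, trial, attempt))
        }
        trajs[[length(trajs) + 1L]] <- tr
        seeds[[length(seeds) + 1L]] <- data.frame(
          subject = sub$id, task = task, trial = trial,
          env_seed = env_seed, rollout_seed = rseed,
          stringsAsFactors = FALSE)
      }
    }
    for (sub in subjects) {
      mods <- subject_modules(sub, task)
      truth[[length(truth) + 1L]] <- data.frame(
        subject = sub$id, task = task, module = names(mods),
        reward = unname(module_rewards(mods)),
        normalized_reward = unname(normalize_rewards(module_rewards(mods))),
        gamma = unname(module_gammas(mods)), eta = sub$eta,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(data = mirl_dataset(trajs),
                 truth = do.call(rbind, truth),
                 trial_seeds = do.call(rbind, seeds), seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- dataset_meta(x$data)
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d tasks, %d trajectories (seed %d)\n",
    length(unique(m$subject)), length(unique(m$task)), nrow(m), x$seed))
  invisible(x)
}

#' Parameter-recovery report
#'
#' Refits the model per subject-by-task group on nested subsets of the
#' group's trajectories and reports the error of the estimates against
#' the generator's ground truth: mean absolute error of normalized
#' rewards over all modules, and of discount factors over the modules
#' with nonzero true reward (the discount of an unrewarded module is
#' unidentifiable).  Optionally also evaluates held-out policy agreement
#' for the modular fit and the Bayesian IRL baseline, the
#' sample-efficiency comparison.
#'
#' @param cohort A [simulate_dataset()] result.
#' @param sizes Numbers of training trajectories per fit.
#' @param heldout Also compute held-out angular difference (uses the last
#'   trajectory of each group, never part of training).
#' @param compare_birl Include the non-modular Bayesian IRL baseline
#'   (implies `heldout = TRUE` for its rows).
#' @param ... Passed to [mirl()] (e.g. `epsilon`, `search`).
#' @return Data frame: subject, task, n_traj, agent, reward_mae,
#'   gamma_mae, angular_deg.
#' @export
recovery_report <- function(cohort, sizes = c(1L, 2L, 4L), heldout = FALSE,
                            compare_birl = FALSE, ...) {
  data <- cohort$data
  meta <- dataset_meta(data)
  truth <- cohort$truth
  if (compare_birl) heldout <- TRUE
  rows <- list()
  for (grp in unique(paste(meta$subject, meta$task, sep = "\r"))) {
    idx <- which(paste(meta$subject, meta$task, sep = "\r") == grp)
    sub <- meta$subject[idx[1]]; task <- meta$task[idx[1]]
    tr <- truth[truth$subject == sub & truth$task == task, ]
    tr <- tr[match(c("target", "obstacle", "path"), tr$module), ]
    held_idx <- idx[length(idx)]
    for (n in sizes) {
      train <- idx[seq_len(min(n, length(idx) - heldout))]
      fit <- mirl(data[train], ...)
      est_n <- fit$normalized[tr$module]
      identifiable <- tr$reward != 0
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub, task = task, n_traj = length(train), agent = "mirl",
        reward_mae = mean(abs(est_n - tr$normalized_reward)),
        gamma_mae = mean(abs(fit$gammas[tr$module][identifiable] -
                               tr$gamma[identifiable])),
        angular_deg = if (heldout)
          angular_difference(data[[held_idx]], fit) else NA_real_,
        stringsAsFactors = FALSE)
      if (compare_birl) {
        bfit <- birl(data[train])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub, task = task, n_traj = length(train),
          agent = "birl", reward_mae = NA_real_, gamma_mae = NA_real_,
          angular_deg = angular_difference(data[[held_idx]], bfit),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
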