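#' Mean angular difference between an agent and observed behavior
#'
#' Places the agent in every observed state of a trajectory, takes its
#' greedy action, and averages the absolute circular difference (degrees,
#' in `[0, 180]`) between the agent's heading and the observed heading —
#' the local policy-agreement metric of the evaluation protocol.
#'
#' @param traj A [trajectory()] of observed behavior.
#' @param agent A fitted agent or [module_set()] with a
#'   [policy_actions()] method.
#' @param per_step Return the per-step differences instead of their mean.
#' @return Mean (or vector of) angular difference in degrees.
#' @export
angular_difference <- function(traj, agent, per_step = FALSE) {
  if (length(traj$actions) == 0L) stop("empty trajectory")
  pred <- policy_actions(agent, traj)
  d <- angular_diff_deg(pred, traj$actions, traj$env$actions$K)
  if (per_step) d else mean(d)
}

#' Objects intercepted along a trajectory
#'
#' Tallies, per module, how many objects were consumed by the end of the
#' trajectory (targets collected, obstacles hit, waypoints visited).
#'
#' @param traj A [trajectory()].
#' @param env Environment (defaults to the trajectory's own).
#' @return Named integer vector of consumed counts per module.
#' @export
count_intercepted <- function(traj, env = traj$env) {
  final_alive <- replay_states(traj)[nrow(traj$positions), ]
  mods <- c("target", "obstacle", "path")
  out <- vapply(mods, function(nm) {
    idx <- env$objects$module == nm
    sum(idx) - sum(final_alive[idx])
  }, 0L)
  setNames(as.integer(out), mods)
}

#' Trajectory cloud of a stochastic agent
#'
#' Runs many seeded softmax rollouts of a module set from a fixed start
#' in a fixed environment, yielding the empirical distribution of
#' hypothetical trajectories in which an observed trajectory can be
#' situated, plus a per-cell visit-frequency field for overlay plots.
#'
#' @param env A `"mirl_environment"`.
#' @param modules A [module_set()].
#' @param eta Softmax confidence of the rollouts.
#' @param n_rollouts Number of rollouts (default 100).
#' @param seed Integer seed; rollout `i` uses a seed derived from it.
#' @param start Optional start position.
#' @param max_steps Step cap per rollout.
#' @param resolution Cell size of the density field (default: grid cell).
#' @param greedy Use greedy selection (all rollouts identical).
#' @return Object of class `"trajectory_cloud"`: a [mirl_dataset()] in
#'   `$trajectories` and a density list (`x`, `y`, `count`) in
#'   `$density`; the density counts sum to the total number of visited
#'   positions.
#' @export
trajectory_cloud <- function(env, modules, eta = 1, n_rollouts = 100L,
                             seed = 1L, start = NULL, max_steps = 500L,
                             resolution = env$grid$cell_size,
                             greedy = FALSE) {
  stopifnot(n_rollouts >= 1L)
  trajs <- lapply(seq_len(n_rollouts), function(i) {
    pol <- if (greedy) policy("greedy")
    else policy("softmax", eta = eta, seed = derive_seed(seed, "cloud", i))
    rollout(env, modules, pol, max_steps = max_steps, start = start,
            trial = i)
  })
  xs <- seq(0, env$grid$room_width, by = resolution)
  ys <- seq(0, env$grid$room_height, by = resolution)
  count <- matrix(0, length(xs) - 1L, length(ys) - 1L)
  for (tr in trajs) {
    ix <- pmin(length(xs) - 1L, 1L + floor(tr$positions[, 1] / resolution))
    iy <- pmin(length(ys) - 1L, 1L + floor(tr$positions[, 2] / resolution))
    for (k in seq_along(ix)) count[ix[k], iy[k]] <- count[ix[k], iy[k]] + 1
  }
  structure(list(trajectories = mirl_dataset(trajs),
                 density = list(x = xs, y = ys, count = count),
                 n_rollouts = n_rollouts, seed = seed),
            class = "trajectory_cloud")
}

#' @export
print.trajectory_cloud <- function(x, ...) {
  cat(sprintf("<trajectory_cloud> %d rollouts, %d recorded positions\n",
              x$n_rollouts, sum(x$density$count)))
  invisible(x)
}

#' @export
plot.trajectory_cloud <- function(x, traj = NULL, ...) {
  env <- x$trajectories[[1]]$env
  plot(NA, xlim = c(0, env$grid$room_width),
       ylim = c(0, env$grid$room_height), asp = 1,
       xlab = "x (m)", ylab = "y (m)", ...)
  for (tr in unclass(x$trajectories))
    graphics::lines(tr$positions, col = grDevices::adjustcolor("darkgreen",
                                                               0.08))
  ob <- env$objects
  graphics::points(ob$x[ob$module == "target"], ob$y[ob$module == "target"],
                   pch = 19, col = "blue")
  graphics::points(ob$x[ob$module == "obstacle"],
                   ob$y[ob$module == "obstacle"], pch = 15, col = "red")
  graphics::points(ob$x[ob$module == "path"], ob$y[ob$module == "path"],
                   pch = 20, col = "gray", cex = 0.5)
  if (!is.null(traj)) graphics::lines(traj$positions, lwd = 2)
  invisible(x)
}

#' Leave-one-out cross evaluation
#'
#' For every subject-by-task group with at least two trials, fits the
#' agent on all-but-one trials and evaluates the greedy policy agreement
#' (and interception counts) on the held-out trial, whose environment is
#' novel to the fit.  Groups with a single trial are skipped with a
#' warning.
#'
#' @param data A [mirl_dataset()] with subject/task/trial labels.
#' @param fitter Function `(data, ...) ->` fitted agent with a
#'   [policy_actions()] method; default [mirl()].
#' @param ... Passed to `fitter`.
#' @return Data frame of class `"mirl_loo"`: one row per held-out trial
#'   with `angular_deg`, interception counts and step count; fitted
#'   objects in the `fits` attribute.
#' @export
leave_one_out <- function(data, fitter = mirl, ...) {
  meta <- dataset_meta(data)
  key <- paste(meta$subject, meta$task, sep = "\r")
  rows <- list(); fits <- list()
  for (grp in unique(key)) {
    idx <- which(key == grp)
    if (length(idx) < 2L) {
      warning("group ", gsub("\r", " / ", grp),
              " has a single trial; skipped")
      next
    }
    for (i in idx) {
      fit <- fitter(data[setdiff(idx, i)], ...)
      held <- data[[i]]
      hit <- count_intercepted(held)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = meta$subject[i], task = meta$task[i],
        trial = meta$trial[i],
        angular_deg = angular_difference(held, fit),
        targets = hit[["target"]], obstacles = hit[["obstacle"]],
        waypoints = hit[["path"]], steps = length(held$actions),
        stringsAsFactors = FALSE)
      fits[[length(fits) + 1L]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("mirl_loo", class(out))
  out
}

#' Aggregate an evaluation table with between-unit standard errors
#'
#' @param report A [leave_one_out()] report (or any data frame with an
#'   `angular_deg` column).
#' @param by Grouping column (default `"task"`).
#' @return Data frame of means and standard errors of the mean.
#' @export
aggregate_report <- function(report, by = "task") {
  sp <- split(report$angular_deg, report[[by]])
  data.frame(group = names(sp),
             mean_angular_deg = vapply(sp, mean, 0),
             sem = vapply(sp, function(v)
               stats::sd(v) / sqrt(length(v)), 0),
             n = lengths(sp), row.names = NULL)
}

#' Synthesize task-4 parameters from task-2 and task-3 fits
#'
#' Tests cross-task stability of module parameters: the target module's
#' reward (and discount) is taken from the path+target condition, the
#' obstacle module's from the path+obstacle condition, and the shared
#' path module's is averaged; rewards are then re-normalized.  If modules
#' are independent and transferable, the synthesized parameters should
#' match a direct fit of the combined condition.
#'
#' @param est_task2 Fit from the path+obstacle condition (covers
#'   `obstacle` and `path`).
#' @param est_task3 Fit from the path+target condition (covers `target`
#'   and `path`).
#' @return List with `rewards` (normalized, named) and `gammas`.
#' @export
synthesize_task4 <- function(est_task2, est_task3) {
  need <- function(fit, mods)
    if (!all(mods %in% fit$module_names))
      stop("fit does not cover module(s): ",
           paste(setdiff(mods, fit$module_names), collapse = ", "))
  need(est_task2, c("obstacle", "path")); need(est_task3, c("target", "path"))
  r2 <- est_task2$normalized; r3 <- est_task3$normalized
  g2 <- est_task2$gammas; g3 <- est_task3$gammas
  r <- c(target = unname(r3["target"]), obstacle = unname(r2["obstacle"]),
         path = unname((r2["path"] + r3["path"]) / 2))
  g <- c(target = unname(g3["target"]), obstacle = unname(g2["obstacle"]),
         path = unname((g2["path"] + g3["path"]) / 2))
  list(rewards = normalize_rewards(r), rewards_raw = r, gammas = g)
}
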