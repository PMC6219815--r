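#' Observed trajectory of (state, action) pairs
#'
#' A trajectory stores the environment it was observed in, the sequence of
#' agent positions (rows of `positions`; `T + 1` rows for `T` actions) and
#' the 0-based action indices.  The full state sequence (live-object
#' flags) is deterministic given the environment and positions and is
#' reconstructed on demand by [replay_states()].
#'
#' @param env The `"mirl_environment"` of the trial.
#' @param positions `(T+1) x 2` matrix of positions in meters.
#' @param actions Integer vector of `T` action indices in `0 .. K-1`.
#' @param subject,task,trial Labels.
#' @return An object of class `"mirl_trajectory"`.
#' @export
trajectory <- function(env, positions, actions, subject = NA, task = NA,
                       trial = NA) {
  positions <- as.matrix(positions)
  actions <- as.integer(actions)
  stopifnot(nrow(positions) == length(actions) + 1L,
            all(actions >= 0L), all(actions < env$actions$K))
  structure(list(env = env, positions = positions, actions = actions,
                 subject = subject, task = task, trial = trial),
            class = "mirl_trajectory")
}

#' @export
print.mirl_trajectory <- function(x, ...) {
  cat(sprintf("<mirl_trajectory> %d steps (subject %s, task %s, trial %s)\n",
              length(x$actions), as.character(x$subject),
              as.character(x$task), as.character(x$trial)))
  invisible(x)
}

#' Replay the state sequence of a trajectory
#'
#' Re-derives the live-object flags at every step by replaying the
#' recorded positions through the deterministic consumption rule
#' (objects within their consumption radius of the agent disappear; see
#' [env_step()]).
#'
#' @param traj A [trajectory()].
#' @return Logical matrix with `T + 1` rows (states before each action,
#'   plus the final state) and one column per environment object.
#' @export
replay_states <- function(traj) {
  env <- traj$env
  n_obj <- nrow(env$objects)
  radius <- consumption_radius(env)
  alive <- matrix(TRUE, nrow(traj$positions), n_obj)
  cur <- rep(TRUE, n_obj)
  for (i in seq_len(nrow(traj$positions))) {
    p <- traj$positions[i, ]
    if (any(cur)) {
      idx <- which(cur)
      d <- sqrt((env$objects$x[idx] - p[1])^2 + (env$objects$y[idx] - p[2])^2)
      cur[idx[d <= radius[idx]]] <- FALSE
    }
    alive[i, ] <- cur
  }
  alive
}

# EnvState before action t (1-based) of a trajectory.
state_at <- function(traj, t, alive_mat = replay_states(traj)) {
  structure(list(pos = traj$positions[t, ], alive = alive_mat[t, ],
                 step_index = t - 1L), class = "env_state")
}

#' Bundle trajectories into a dataset
#'
#' @param trajectories List of [trajectory()] objects.
#' @return An object of class `"mirl_dataset"`; its `meta` attribute is a
#'   data frame of subject/task/trial labels and step counts.
#' @export
mirl_dataset <- function(trajectories) {
  if (inherits(trajectories, "mirl_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, TRUE, "mirl_trajectory")))
  meta <- data.frame(
    subject = vapply(trajectories, function(x) as.character(x$subject), ""),
    task = vapply(trajectories, function(x) as.character(x$task), ""),
    trial = vapply(trajectories, function(x) as.character(x$trial), ""),
    steps = vapply(trajectories, function(x) length(x$actions), 0L),
    stringsAsFactors = FALSE)
  structure(trajectories, meta = meta, class = "mirl_dataset")
}

#' @export
print.mirl_dataset <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<mirl_dataset> %d trajectories, %d steps total\n",
              length(x), sum(m$steps)))
  invisible(x)
}

#' @export
`[.mirl_dataset` <- function(x, i) {
  mirl_dataset(unclass(x)[i])
}

dataset_meta <- function(data) attr(data, "meta")

# ---- likelihood feature tables -------------------------------------------
#
# For each trajectory step t and each candidate action a we need, per
# module, the distances (in step units) from the successor position to
# every live object of that module (truncated to the module's nearest_k
# window).  These are precomputed once per dataset: for module n a
# (T_total*K) x M_n matrix of distances, with -1 marking dead/absent
# objects, plus the row index of each observed (t, a_t) pair.  All
# likelihood code (R and C++) consumes this table.
mirl_features <- function(data, module_names,
                          nearest_k = default_nearest_k(module_names)) {
  nearest_k <- rep_len(nearest_k, length(module_names))
  if (inherits(data, "mirl_trajectory")) data <- mirl_dataset(data)
  stopifnot(inherits(data, "mirl_dataset"), length(data) >= 1L)
  K <- data[[1]]$env$actions$K
  per_mod <- lapply(module_names, function(nm) list())
  obs <- integer(0)
  total_t <- 0L
  for (traj in unclass(data)) {
    env <- traj$env
    stopifnot(env$actions$K == K)
    alive_mat <- replay_states(traj)
    Tn <- length(traj$actions)
    stepv <- action_steps(env$actions, env$grid)
    mod_idx <- lapply(module_names, function(nm)
      which(env$objects$module == nm))
    # successor positions for all (t, a): (T*K) x 2
    px <- rep(traj$positions[seq_len(Tn), 1], each = K) + stepv[, 1]
    py <- rep(traj$positions[seq_len(Tn), 2], each = K) + stepv[, 2]
    px <- pmin(pmax(px, 0), env$grid$room_width)
    py <- pmin(pmax(py, 0), env$grid$room_height)
    for (j in seq_along(module_names)) {
      idx <- mod_idx[[j]]
      if (!length(idx)) {
        per_mod[[j]][[length(per_mod[[j]]) + 1L]] <-
          matrix(numeric(0), nrow = Tn * K, ncol = 0)
        next
      }
      d <- sqrt(outer(px, env$objects$x[idx], "-")^2 +
                  outer(py, env$objects$y[idx], "-")^2) / env$grid$cell_size
      dead <- !alive_mat[rep(seq_len(Tn), each = K), idx, drop = FALSE]
      d[dead] <- Inf
      d <- truncate_nearest(d, nearest_k[j])
      d[!is.finite(d)] <- -1
      per_mod[[j]][[length(per_mod[[j]]) + 1L]] <- d
    }
    obs <- c(obs, (total_t + seq_len(Tn) - 1L) * K + traj$actions)
    total_t <- total_t + Tn
  }
  dist <- lapply(per_mod, function(lst) {
    mx <- max(vapply(lst, ncol, 0L))
    lst <- lapply(lst, function(m) {
      if (ncol(m) < mx)
        m <- cbind(m, matrix(-1, nrow(m), mx - ncol(m)))
      m
    })
    do.call(rbind, lst)
  })
  names(dist) <- module_names
  list(dist = dist, obs = obs, T = total_t, K = K,
       module_names = module_names)
}

# Per-module feature phi_n(t, a) = sum_m gamma^d over live objects,
# returned as a T x K matrix (R reference path; the solver uses C++).
phi_matrix <- function(dist_n, gamma, T, K) {
  if (ncol(dist_n) == 0) return(matrix(0, T, K))
  g <- gamma^dist_n
  g[dist_n < 0] <- 0
  matrix(rowSums(g), T, K, byrow = TRUE)
}

#' Log-likelihood of a dataset under a module set
#'
#' The Boltzmann trajectory log-likelihood: for each observed step, the
#' log-probability of the observed action under the softmax policy induced
#' by the composed modular Q-values, summed over all steps of all
#' trajectories.  Distances are recomputed from the stored positions by
#' replaying each trajectory through its environment.  Stabilized with
#' log-sum-exp.
#'
#' @param data A [mirl_dataset()] (or single trajectory).
#' @param modules A [module_set()].
#' @param eta Confidence parameter (default 1).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(data, modules, eta = 1) {
  feats <- mirl_features(data, names(modules),
                         nearest_k = module_nearest_k(modules))
  loglik_from_features(feats, module_rewards(modules),
                       module_gammas(modules), eta)
}

loglik_from_features <- function(feats, rewards, gammas, eta) {
  q <- matrix(0, feats$T, feats$K)
  for (j in seq_along(feats$dist))
    q <- q + rewards[j] * phi_matrix(feats$dist[[j]], gammas[j],
                                     feats$T, feats$K)
  q <- eta * q
  mx <- apply(q, 1, max)
  lse <- mx + log(rowSums(exp(q - mx)))
  sum(t(q)[feats$obs + 1L]) - sum(lse)
}

#' Regularized modular IRL objective
#'
#' The sparse modular IRL objective: the trajectory log-likelihood minus
#' an L1 penalty `lambda * sum_n |r_n|` on the module rewards.  The
#' penalty acts as a cognitive-capacity factor: at the optimum it drives
#' the rewards of unattended modules exactly to zero.
#'
#' @inheritParams log_likelihood
#' @param lambda Nonnegative regularization constant.
#' @return Scalar objective value.
#' @export
mirl_objective <- function(data, modules, eta = 1, lambda = 0) {
  log_likelihood(data, modules, eta) - lambda * sum(abs(module_rewards(modules)))
}
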