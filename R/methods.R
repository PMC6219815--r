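#' @export
print.mirl <- function(x, digits = 3, ...) {
  cat("Sparse modular IRL fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Data: %d trajectories, %d decision steps\n",
              x$n_trajectories, x$n_steps))
  print(round(coef(x), digits))
  cat(sprintf("log-likelihood %.3f, objective %.3f (eta = %g, lambda = %g)\n",
              x$loglik, x$objective, x$eta, x$lambda))
  cat("Active modules:",
      if (length(x$active)) paste(x$active, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Coefficients of a modular IRL fit
#'
#' @param object A `"mirl"` fit.
#' @param ... Unused.
#' @return Matrix with one row per module and columns `reward`,
#'   `normalized` and `gamma`.
#' @export
coef.mirl <- function(object, ...) {
  cbind(reward = object$rewards, normalized = object$normalized,
        gamma = object$gammas)
}

#' @export
logLik.mirl <- function(object, ...) {
  structure(object$loglik, df = 2L * length(object$module_names),
            nobs = object$n_steps, class = "logLik")
}

#' @export
summary.mirl <- function(object, ...) {
  structure(list(fit = object, coef = coef(object)),
            class = "summary.mirl")
}

#' @export
print.summary.mirl <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf(
    "Discount grid: step %g on [0, %g]; %s search over %d nodes\n",
    f$epsilon, f$gamma_max, f$search, f$n_nodes))
  inb <- stats::aggregate(objective ~ module, f$profile,
                          function(v) max(v, na.rm = TRUE))
  cat("Per-module best profile objective:\n")
  print(inb, row.names = FALSE)
  invisible(x)
}

#' Fitted module set of a modular IRL fit
#'
#' @param object A `"mirl"` fit.
#' @return A [module_set()] with the estimated parameters.
#' @export
fitted_modules <- function(object) {
  nk <- object$nearest_k
  if (is.null(nk)) nk <- default_nearest_k(object$module_names)
  module_set_from(object$module_names, object$rewards, object$gammas,
                  nearest_k = nk)
}

#' Greedy actions of a fitted agent in observed states
#'
#' Generic used by the evaluation harness: place the agent in every state
#' of an observed trajectory and return its (greedy) 0-based action
#' indices.  Methods exist for module sets, [mirl()] fits (and its
#' baseline variants) and [birl()] fits, so the harness is
#' agent-agnostic.
#'
#' @param object A fitted agent.
#' @param traj A [trajectory()].
#' @param ... Method-specific arguments.
#' @return Integer vector of `T` action indices.
#' @export
policy_actions <- function(object, traj, ...) UseMethod("policy_actions")

#' @export
policy_actions.module_set <- function(object, traj, ...) {
  env <- traj$env
  alive_mat <- replay_states(traj)
  vapply(seq_along(traj$actions), function(t) {
    st <- state_at(traj, t, alive_mat)
    which.max(global_q_all(env, st, object)) - 1L
  }, 0L)
}

#' @export
policy_actions.mirl <- function(object, traj, ...) {
  policy_actions(fitted_modules(object), traj)
}

#' Predict action choices in observed states
#'
#' @param object A `"mirl"` fit.
#' @param newdata A trajectory or dataset.
#' @param type `"action"` for greedy 0-based action indices,
#'   `"probs"` for the softmax action-probability matrix (rows = steps),
#'   using the fit's `eta`.
#' @param ... Unused.
#' @return Per-trajectory vector/matrix, or a list of them for a dataset.
#' @export
predict.mirl <- function(object, newdata, type = c("action", "probs"), ...) {
  type <- match.arg(type)
  mods <- fitted_modules(object)
  one <- function(traj) {
    if (type == "action") return(policy_actions(mods, traj))
    alive_mat <- replay_states(traj)
    t(vapply(seq_along(traj$actions), function(t) {
      action_likelihoods(traj$env, state_at(traj, t, alive_mat), mods,
                         eta = object$eta)
    }, numeric(traj$env$actions$K)))
  }
  if (inherits(newdata, "mirl_trajectory")) return(one(newdata))
  lapply(unclass(newdata), one)
}

#' Angular residuals of a fit
#'
#' Per-step absolute angular differences (degrees, in `[0, 180]`) between
#' the fitted greedy policy and the observed actions.
#'
#' @param object A `"mirl"` fit.
#' @param newdata Trajectory or dataset (default: training data).
#' @param ... Unused.
#' @return Numeric vector of degrees over all steps.
#' @export
residuals.mirl <- function(object, newdata = object$data, ...) {
  if (inherits(newdata, "mirl_trajectory")) newdata <- mirl_dataset(newdata)
  unlist(lapply(unclass(newdata), function(traj) {
    pred <- policy_actions(object, traj)
    angular_diff_deg(pred, traj$actions, traj$env$actions$K)
  }))
}

#' Simulate trajectories from a fitted agent
#'
#' Softmax rollouts of the fitted module set in an environment, i.e. the
#' generative direction of the model: given the estimated rewards and
#' discount factors, reproduce hypothetical navigation behavior.
#'
#' @param object A `"mirl"` fit.
#' @param nsim Number of rollouts.
#' @param seed Integer seed.
#' @param env Environment to navigate (defaults to the environment of the
#'   first training trajectory).
#' @param eta Behavioral confidence for the rollouts (default: the fit's
#'   `eta`).
#' @param start Optional start position.
#' @param max_steps Step cap per rollout.
#' @param ... Unused.
#' @return A [mirl_dataset()] of simulated trajectories.
#' @export
simulate.mirl <- function(object, nsim = 1, seed = 1L, env = NULL,
                          eta = object$eta, start = NULL, max_steps = 500L,
                          ...) {
  if (is.null(env)) env <- object$data[[1]]$env
  mods <- fitted_modules(object)
  mirl_dataset(lapply(seq_len(nsim), function(i)
    rollout(env, mods, policy("softmax", eta = eta,
                              seed = derive_seed(seed, "sim", i)),
            max_steps = max_steps, start = start, trial = i)))
}

#' Plot a modular IRL fit
#'
#' `which = "profile"` draws the discount-factor profile (best attained
#' objective at each grid value, per module); `which = "surface"` draws
#' the value surface of the fitted module set in an environment.
#'
#' @param x A `"mirl"` fit.
#' @param which `"profile"` or `"surface"`.
#' @param env Environment for `which = "surface"`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.mirl <- function(x, which = c("profile", "surface"), env = NULL, ...) {
  which <- match.arg(which)
  if (which == "profile") {
    prof <- x$profile
    mods <- unique(prof$module)
    wide <- sapply(mods, function(m) prof$objective[prof$module == m])
    graphics::matplot(gamma_grid(x$epsilon, x$gamma_max), wide, type = "l",
                      lty = 1, xlab = expression(gamma),
                      ylab = "profile objective", ...)
    graphics::legend("bottomleft", legend = mods, lty = 1,
                     col = seq_along(mods), bty = "n")
  } else {
    if (is.null(env)) env <- x$data[[1]]$env
    plot(value_surface(env, fitted_modules(x)), ...)
  }
  invisible(x)
}

# Absolute circular difference (degrees) between action indices on a
# K-heading compass; result in [0, 180].
angular_diff_deg <- function(a, b, K) {
  bin <- 360 / K
  d <- abs(a - b) %% K
  d <- pmin(d, K - d)
  d * bin
}
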