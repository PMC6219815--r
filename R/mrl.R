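#' Parameters of one behavioral module
#'
#' A module is a subtask (path following, target collection, obstacle
#' avoidance, ...) modeled as its own small MDP with a private scalar
#' reward `r` and discount factor `gamma`, sharing the action set with the
#' other modules.  Obstacle-like modules typically carry negative reward;
#' no sign constraint is imposed.
#'
#' Each module may restrict its Q-value sum to its `nearest_k` live
#' objects (a lookahead window, available for experimentation); by
#' default all live objects of every module enter the sum.
#'
#' @param name Module label.
#' @param reward Scalar reward (sign-free).
#' @param gamma Discount factor in `[0, 1)`.
#' @param nearest_k Number of nearest live objects entering the module's
#'   Q sum (`Inf` = all).
#' @return An object of class `"module_params"`.
#' @export
module_params <- function(name, reward, gamma, nearest_k = Inf) {
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)")
  stopifnot(nearest_k >= 1)
  structure(list(name = as.character(name), reward = as.numeric(reward),
                 gamma = as.numeric(gamma), nearest_k = nearest_k),
            class = "module_params")
}

#' Default per-module lookahead windows
#'
#' `Inf` (all live objects enter the module Q sum) for every module; a
#' finite per-module window can be supplied anywhere a `nearest_k`
#' argument appears.  See [module_params()].
#'
#' @param names Module names.
#' @return Named numeric vector of `nearest_k` values.
#' @export
default_nearest_k <- function(names) {
  setNames(rep(Inf, length(names)), names)
}

#' An ordered set of modules
#'
#' @param ... `module_params` objects (or one list of them).
#' @return An object of class `"module_set"`.
#' @export
module_set <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && !inherits(mods[[1]], "module_params"))
    mods <- mods[[1]]
  stopifnot(length(mods) >= 1L,
            all(vapply(mods, inherits, TRUE, "module_params")))
  nm <- vapply(mods, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("module names must be unique")
  names(mods) <- nm
  structure(mods, class = "module_set")
}

#' Build a module set from parallel vectors
#'
#' @param names Module labels.
#' @param rewards,gammas Numeric vectors aligned with `names`.
#' @param nearest_k Per-module lookahead windows (recycled).
#' @return A [module_set()].
#' @export
module_set_from <- function(names, rewards, gammas,
                            nearest_k = default_nearest_k(names)) {
  nearest_k <- rep_len(nearest_k, length(names))
  module_set(mapply(module_params, names, rewards, gammas, nearest_k,
                    SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

module_rewards <- function(modules) vapply(modules, `[[`, 0, "reward")
module_gammas <- function(modules) vapply(modules, `[[`, 0, "gamma")
module_nearest_k <- function(modules)
  vapply(modules, function(m) if (is.null(m$nearest_k)) Inf else m$nearest_k, 0)

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set>\n")
  print(data.frame(module = names(x), reward = module_rewards(x),
                   gamma = module_gammas(x), row.names = NULL))
  invisible(x)
}

#' Closed-form module action value
#'
#' Under deterministic dynamics, a policy that heads straight for the
#' module object gives the module Q-value \eqn{r \gamma^d}, where `d` is the
#' distance (in step units) between the agent and the object after the
#' action.  The convention `0^0 = 1` is used so that a myopic module
#' (`gamma = 0`) still values immediate interception (`d = 0` yields `r`).
#'
#' @param params A [module_params()].
#' @param d Nonnegative distance(s) in step units.
#' @return Numeric value(s) \eqn{r \gamma^d}.
#' @export
module_q <- function(params, d) {
  stopifnot(all(d >= 0))
  if (params$gamma < 0 || params$gamma >= 1) stop("gamma must lie in [0, 1)")
  params$reward * params$gamma^d
}

#' Global action value by module summation
#'
#' The global Q-value of an action is the sum of `module_q` over all
#' modules and all of their live object instances (assuming independent
#' per-object transition functions).  Modules with no live objects
#' contribute zero.  Optionally each module's sum may be truncated to its
#' `nearest_k` closest live objects.
#'
#' @param env A `"mirl_environment"`.
#' @param state An [env_state()].
#' @param action Action index in `0 .. K-1`.
#' @param modules A [module_set()].
#' @param nearest_k Optional scalar override of every module's own
#'   `nearest_k` field (`NULL`: use the fields).
#' @return Scalar global Q-value.
#' @export
global_q <- function(env, state, action, modules, nearest_k = NULL) {
  qs <- global_q_all(env, state, modules, nearest_k)
  qs[action + 1L]
}

# Q-values of all K actions at once (vectorized core used by policies).
global_q_all <- function(env, state, modules, nearest_k = NULL) {
  K <- env$actions$K
  succ <- t(t(action_steps(env$actions, env$grid)) + state$pos)
  succ[, 1] <- pmin(pmax(succ[, 1], 0), env$grid$room_width)
  succ[, 2] <- pmin(pmax(succ[, 2], 0), env$grid$room_height)
  q <- numeric(K)
  for (mod in modules) {
    idx <- which(state$alive & env$objects$module == mod$name)
    if (!length(idx)) next
    nk <- if (is.null(nearest_k)) mod$nearest_k else nearest_k
    if (is.null(nk)) nk <- Inf
    dx <- outer(succ[, 1], env$objects$x[idx], "-")
    dy <- outer(succ[, 2], env$objects$y[idx], "-")
    d <- sqrt(dx^2 + dy^2) / env$grid$cell_size     # K x M
    d <- truncate_nearest(d, nk)
    q <- q + rowSums(mod$reward * mod$gamma^d)
  }
  q
}

# Reduce each row to its k smallest finite entries (returned as an
# n x k matrix; ties broken toward lower column index).  Entries that
# were non-finite (dead objects) come back as NA.
truncate_nearest <- function(d, k) {
  if (!is.finite(k) || ncol(d) <= k) return(d)
  n <- nrow(d)
  work <- d
  work[!is.finite(work)] <- Inf
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    idx <- max.col(-work, ties.method = "first")
    sel <- cbind(seq_len(n), idx)
    v <- work[sel]
    out[, j] <- ifelse(is.finite(v), v, NA_real_)
    work[sel] <- Inf
  }
  out
}

#' Boltzmann (softmax) action likelihoods
#'
#' The probability of choosing each action is proportional to
#' `exp(eta * Q(s, a))`, where `eta` is the confidence-in-optimality
#' parameter: `eta = 0` gives a uniform policy and large `eta` approaches
#' greedy selection.  Computed with max-subtraction for numerical
#' stability; the returned vector sums to one.
#'
#' @inheritParams global_q
#' @param eta Nonnegative confidence parameter.
#' @return Probability vector of length `K`.
#' @export
action_likelihoods <- function(env, state, modules, eta = 1,
                               nearest_k = NULL) {
  stopifnot(eta >= 0)
  softmax_probs(eta * global_q_all(env, state, modules, nearest_k))
}

softmax_probs <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Action-selection policy
#'
#' @param mode `"greedy"` (argmax of Q, ties broken toward the lowest
#'   action index) or `"softmax"` (seeded draw from the Boltzmann
#'   likelihoods).
#' @param eta Confidence parameter for softmax selection.
#' @param seed Integer seed for the softmax draws.
#' @return An object of class `"mirl_policy"`.
#' @export
policy <- function(mode = c("greedy", "softmax"), eta = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "softmax") stopifnot(eta > 0)
  structure(list(mode = mode, eta = eta, seed = as.integer(seed)),
            class = "mirl_policy")
}

#' Select an action from Q-values under a policy
#'
#' Greedy selection takes the argmax with ties broken deterministically
#' toward the lowest action index; softmax selection draws from the
#' Boltzmann likelihoods.  When drawing, supply `rng = TRUE` inside an
#' externally seeded context, or rely on the policy's seed via [rollout()].
#'
#' @param q Numeric vector of Q-values (length `K`).
#' @param pol A [policy()].
#' @return 0-based action index.
#' @export
select_action <- function(q, pol) {
  if (pol$mode == "greedy") return(which.max(q) - 1L)
  p <- softmax_probs(pol$eta * q)
  sample.int(length(p), 1L, prob = p) - 1L
}

#' Roll out a trajectory under a module set and policy
#'
#' Starting at `start` (the environment's start by default), repeatedly
#' selects an action, applies the deterministic transition, and records
#' the (state, action) pair, until the goal is consumed or `max_steps` is
#' reached.  Softmax rollouts are reproducible via the policy's seed.
#'
#' @param env A `"mirl_environment"`.
#' @param modules A [module_set()].
#' @param pol A [policy()].
#' @param max_steps Step cap.
#' @param start Optional start position.
#' @param subject,task,trial Optional labels attached to the trajectory.
#' @return A `"mirl_trajectory"` (see [trajectory()]).
#' @export
rollout <- function(env, modules, pol = policy("greedy"), max_steps = 500L,
                    start = NULL, subject = NA, task = NA, trial = NA) {
  run <- function() {
    st <- env_state(env, start)
    pos <- matrix(st$pos, ncol = 2)
    acts <- integer(0)
    while (!is_terminal(env, st, max_steps)) {
      q <- global_q_all(env, st, modules)
      a <- select_action(q, pol)
      st <- env_step(env, st, a)
      acts <- c(acts, a)
      pos <- rbind(pos, st$pos)
    }
    trajectory(env, positions = pos, actions = acts,
               subject = subject, task = task, trial = trial)
  }
  if (pol$mode == "softmax") with_local_seed(pol$seed, run()) else run()
}

#' Value surface over the room
#'
#' An action-free potential for visualization: at each grid point `x`,
#' `V(x) = sum_n sum_m r_n * gamma_n^{d(x, obj_{n,m})}` with distances in
#' step units, summed over live objects.  Positive-reward objects raise
#' the surface around themselves; the discount factor sets the spatial
#' decay rate.
#'
#' @param env A `"mirl_environment"`.
#' @param modules A [module_set()].
#' @param resolution Grid spacing in meters (default: the cell size).
#' @param state Optional [env_state()] restricting the sum to live
#'   objects; all objects by default.
#' @return A list of class `"value_surface"` with fields `x`, `y` and the
#'   `value` matrix (`length(x)` rows by `length(y)` columns).
#' @export
value_surface <- function(env, modules, resolution = env$grid$cell_size,
                          state = NULL) {
  stopifnot(resolution > 0)
  xs <- seq(0, env$grid$room_width, by = resolution)
  ys <- seq(0, env$grid$room_height, by = resolution)
  alive <- if (is.null(state)) rep(TRUE, nrow(env$objects)) else state$alive
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  v <- matrix(0, length(xs), length(ys))
  for (mod in modules) {
    idx <- which(alive & env$objects$module == mod$name)
    if (!length(idx)) next
    d <- sqrt(outer(pts[, 1], env$objects$x[idx], "-")^2 +
                outer(pts[, 2], env$objects$y[idx], "-")^2) /
      env$grid$cell_size
    nk <- mod$nearest_k
    if (is.null(nk)) nk <- Inf
    d <- truncate_nearest(d, nk)
    v <- v + matrix(rowSums(mod$reward * mod$gamma^d),
                    length(xs), length(ys))
  }
  structure(list(x = xs, y = ys, value = v), class = "value_surface")
}

#' @export
plot.value_surface <- function(x, ...) {
  graphics::filled.contour(x$x, x$y, x$value, asp = 1,
                           xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Export a value surface as a delimited numeric table
#'
#' Writes a matrix of values with a header row of x-coordinates and a
#' leading column of y-coordinates.
#'
#' @param surface A [value_surface()].
#' @param path Output file.
#' @export
write_value_surface <- function(surface, path) {
  tab <- cbind(y = surface$y, t(surface$value))
  colnames(tab) <- c("y", as.character(surface$x))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
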