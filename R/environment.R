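#' Grid specification for the navigation room
#'
#' The room is continuous; the grid's `cell_size` sets the agent's step
#' length (one action moves one cell length), the waypoint spacing of the
#' path, and the default resolution of value surfaces.  The default cell of
#' 0.572 m is about one walking stride; performance of the model is robust
#' for cells in roughly 0.3--0.9 m.
#'
#' @param cell_size Step length in meters.
#' @param room_width,room_height Room dimensions in meters.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(cell_size = 0.572, room_width = 8.5, room_height = 7.3) {
  stopifnot(cell_size > 0, room_width > 0, room_height > 0)
  structure(list(cell_size = cell_size, room_width = room_width,
                 room_height = room_height), class = "grid_spec")
}

#' Discrete action set of uniformly spaced headings
#'
#' Actions are indexed `0 .. K-1`; action `k` is a step of one cell length
#' along heading `k * 360/K` degrees, measured counterclockwise from the
#' +x axis.  The default `K = 16` gives 22.5 degree bins.
#'
#' @param K Number of actions.
#' @return An object of class `"action_set"` with fields `K` and
#'   `headings` (degrees).
#' @export
action_set <- function(K = 16L) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  structure(list(K = K, headings = (0:(K - 1L)) * (360 / K)),
            class = "action_set")
}

# Unit displacement vectors (rows) for each action, scaled by cell_size.
action_steps <- function(actions, grid) {
  th <- actions$headings * pi / 180
  cbind(cos(th), sin(th)) * grid$cell_size
}

clip_to_room <- function(pos, grid) {
  c(min(max(pos[1], 0), grid$room_width),
    min(max(pos[2], 0), grid$room_height))
}

#' Construct a navigation environment from explicit components
#'
#' Lower-level constructor used by [generate_environment()] and by tests
#' that need hand-placed objects.  Objects are point instances grouped by
#' module label; the waypoints (module `"path"`) are an ordered sequence
#' ending at the goal, whose consumption terminates a trial.
#'
#' @param grid A [grid_spec()].
#' @param actions An [action_set()].
#' @param targets,obstacles Matrices (or 2-column data frames) of object
#'   coordinates in meters; may have zero rows.
#' @param waypoints Matrix of ordered waypoint coordinates (>= 1 row); the
#'   last row is the goal.
#' @param start Agent start position; defaults to the first waypoint.
#' @param seed Integer recorded for provenance (`NA` for hand-built rooms).
#' @return An object of class `"mirl_environment"`.
#' @export
make_environment <- function(grid, actions, targets = NULL, obstacles = NULL,
                             waypoints, start = NULL, seed = NA_integer_) {
  stopifnot(inherits(grid, "grid_spec"), inherits(actions, "action_set"))
  as_mat <- function(x) {
    if (is.null(x)) return(matrix(numeric(0), ncol = 2))
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    stopifnot(ncol(x) == 2)
    x
  }
  targets <- as_mat(targets); obstacles <- as_mat(obstacles)
  waypoints <- as_mat(waypoints)
  if (nrow(waypoints) < 1) stop("waypoint sequence must be non-empty")
  if (nrow(waypoints) > 1) {
    gap <- sqrt(rowSums(diff(waypoints)^2))
    if (any(gap > 1.5 * grid$cell_size + 1e-9))
      stop("consecutive waypoints more than 1.5 cells apart")
  }
  xy <- rbind(targets, obstacles, waypoints)
  module <- rep(c("target", "obstacle", "path"),
                c(nrow(targets), nrow(obstacles), nrow(waypoints)))
  inside <- xy[, 1] >= 0 & xy[, 1] <= grid$room_width &
    xy[, 2] >= 0 & xy[, 2] <= grid$room_height
  if (nrow(xy) && !all(inside)) stop("object positions must lie inside the room")
  objects <- data.frame(module = module, x = xy[, 1], y = xy[, 2],
                        stringsAsFactors = FALSE)
  wp_ids <- which(module == "path")
  if (is.null(start)) start <- waypoints[1, ]
  structure(list(grid = grid, actions = actions, objects = objects,
                 waypoint_ids = wp_ids, goal_id = wp_ids[length(wp_ids)],
                 start = as.numeric(start), seed = seed),
            class = "mirl_environment")
}

#' @export
print.mirl_environment <- function(x, ...) {
  n <- table(factor(x$objects$module, c("target", "obstacle", "path")))
  cat(sprintf(
    "<mirl_environment> %.1f x %.1f m room, cell %.3f m, %d actions\n",
    x$grid$room_width, x$grid$room_height, x$grid$cell_size, x$actions$K))
  cat(sprintf("  %d targets, %d obstacles, %d waypoints (last = goal); seed %s\n",
              n[["target"]], n[["obstacle"]], n[["path"]],
              as.character(x$seed)))
  invisible(x)
}

# Smooth random path across the room: 4-6 control points spanning the
# width, interpolated with natural cubic splines and resampled at
# cell_size arc-length so consecutive waypoints are one step apart.
random_path <- function(grid, margin = 0.4) {
  k <- sample(4:6, 1)
  xs <- seq(margin, grid$room_width - margin, length.out = k)
  xs[-c(1, k)] <- xs[-c(1, k)] + runif(k - 2, -0.25, 0.25)
  # gentle meander: y follows a bounded random walk across control points
  h <- grid$room_height
  ys <- numeric(k)
  ys[1] <- runif(1, 0.25 * h, 0.75 * h)
  for (i in 2:k)
    ys[i] <- min(max(ys[i - 1] + runif(1, -0.3 * h, 0.3 * h), 0.15 * h),
                 0.85 * h)
  tt <- seq_len(k)
  dense <- seq(1, k, length.out = 60 * k)
  px <- spline(tt, xs, xout = dense, method = "natural")$y
  py <- spline(tt, ys, xout = dense, method = "natural")$y
  px <- pmin(pmax(px, 0.05), grid$room_width - 0.05)
  py <- pmin(pmax(py, 0.05), grid$room_height - 0.05)
  resample_polyline(cbind(px, py), grid$cell_size)
}

# Arc-length resampling of a polyline at a fixed spacing.
resample_polyline <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < spacing) stop("polyline shorter than one step")
  s <- seq(0, total, by = spacing)
  if (total - s[length(s)] > spacing / 2) s <- c(s, total)
  x <- approx(cum, pts[, 1], xout = s)$y
  y <- approx(cum, pts[, 2], xout = s)$y
  cbind(x, y)
}

#' Generate a random trial environment
#'
#' Draws a smooth random path from one side of the room to a goal and
#' scatters target and obstacle objects uniformly at random, with a minimum
#' pairwise separation of one cell (also kept clear of the waypoints so the
#' path itself remains walkable).  A fixed seed yields a byte-identical
#' environment; every trial of the study uses a fresh seed so object
#' positions and path shape differ between trials.
#'
#' @param grid A [grid_spec()].
#' @param actions An [action_set()].
#' @param n_targets,n_obstacles Object counts (defaults 12 and 12).
#' @param seed Integer seed.
#' @param max_tries Total rejection-sampling attempts before the room is
#'   declared too crowded.
#' @return A `"mirl_environment"`.
#' @export
generate_environment <- function(grid = grid_spec(), actions = action_set(),
                                 n_targets = 12L, n_obstacles = 12L, seed,
                                 max_tries = 4000L) {
  stopifnot(n_targets >= 0, n_obstacles >= 0, !missing(seed))
  with_local_seed(seed, {
    wp <- random_path(grid)
    sep <- grid$cell_size
    margin <- 0.3
    placed <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(placed) < n_targets + n_obstacles) {
      if (tries >= max_tries)
        stop("object placement failed after ", max_tries,
             " attempts: room too crowded")
      tries <- tries + 1L
      p <- c(runif(1, margin, grid$room_width - margin),
             runif(1, margin, grid$room_height - margin))
      d_obj <- if (nrow(placed)) min(sqrt(colSums((t(placed) - p)^2))) else Inf
      d_wp <- min(sqrt(colSums((t(wp) - p)^2)))
      if (d_obj >= sep && d_wp >= sep) placed <- rbind(placed, p)
    }
    make_environment(grid, actions,
                     targets = placed[seq_len(n_targets), , drop = FALSE],
                     obstacles = placed[n_targets + seq_len(n_obstacles), ,
                                        drop = FALSE],
                     waypoints = wp, seed = as.integer(seed))
  })
}

#' Initial state of an environment
#'
#' The agent starts at the environment's start position (the first
#' waypoint); any object already within its consumption radius of the
#' start -- in particular that first waypoint -- counts as consumed at
#' step 0.
#'
#' @param env A `"mirl_environment"`.
#' @param start Optional alternative start position (meters).
#' @return An object of class `"env_state"` with fields `pos`, `alive`
#'   (logical per object) and `step_index`.
#' @export
env_state <- function(env, start = NULL) {
  pos <- if (is.null(start)) env$start else as.numeric(start)
  alive <- rep(TRUE, nrow(env$objects))
  if (length(alive)) {
    d <- sqrt((env$objects$x - pos[1])^2 + (env$objects$y - pos[2])^2)
    alive[d <= consumption_radius(env)] <- FALSE
  }
  structure(list(pos = pos, alive = alive, step_index = 0L),
            class = "env_state")
}

#' Deterministic environment transition
#'
#' Moves the agent one cell length along the chosen heading, clipping at
#' the room walls; any live object within its consumption radius of the
#' new position is consumed: half a cell (the collision radius) for
#' targets and obstacles, one cell (the half-width of the walkable
#' corridor) for path waypoints, which count as visited when the agent
#' walks along the path rather than exactly over them.  Objects never
#' reappear, so the live set shrinks monotonically along a trajectory.
#'
#' @param env A `"mirl_environment"`.
#' @param state An [env_state()].
#' @param action Action index in `0 .. K-1`.
#' @return The successor `"env_state"`.
#' @export
env_step <- function(env, state, action) {
  K <- env$actions$K
  stopifnot(action >= 0, action < K)
  stp <- action_steps(env$actions, env$grid)[action + 1L, ]
  pos <- clip_to_room(state$pos + stp, env$grid)
  alive <- state$alive
  if (any(alive)) {
    idx <- which(alive)
    d <- sqrt((env$objects$x[idx] - pos[1])^2 + (env$objects$y[idx] - pos[2])^2)
    alive[idx[d <= consumption_radius(env)[idx]]] <- FALSE
  }
  structure(list(pos = pos, alive = alive,
                 step_index = state$step_index + 1L), class = "env_state")
}

#' Distance to an object after taking an action
#'
#' The module state abstraction: the Euclidean distance, in step units
#' (meters divided by the cell size), from the agent's successor position
#' to a live module object.  This is the exponent `d` of the closed-form
#' module value \eqn{r \gamma^d}.
#'
#' @param env A `"mirl_environment"`.
#' @param state An [env_state()].
#' @param action Action index in `0 .. K-1`.
#' @param obj Row index of the object in `env$objects`.
#' @return Nonnegative real distance in step units.
#' @export
distance_after_action <- function(env, state, action, obj) {
  if (!state$alive[obj]) stop("object ", obj, " has been consumed")
  stp <- action_steps(env$actions, env$grid)[action + 1L, ]
  pos <- clip_to_room(state$pos + stp, env$grid)
  sqrt((env$objects$x[obj] - pos[1])^2 +
         (env$objects$y[obj] - pos[2])^2) / env$grid$cell_size
}

# Per-object consumption radii: collision radius (0.5 cell) for point
# objects, visit radius (1 cell) for path waypoints.
consumption_radius <- function(env) {
  ifelse(env$objects$module == "path", 1, 0.5) * env$grid$cell_size
}

#' Trial termination test
#'
#' A trial ends when the goal (the final waypoint) has been consumed, or
#' when the step cap is reached.
#'
#' @param env A `"mirl_environment"`.
#' @param state An [env_state()].
#' @param max_steps Step cap (default 500).
#' @return Logical flag.
#' @export
is_terminal <- function(env, state, max_steps = 500L) {
  !state$alive[env$goal_id] || state$step_index >= max_steps
}
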