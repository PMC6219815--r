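# Conventions used by all files: 0-based action indices, headings
# counterclockwise from +x, meters everywhere, origin at the room's
# south-west corner, full coordinate precision.

env_schema_version <- "1"

#' Write / read an environment as a structured YAML document
#'
#' Lossless round trip of the room geometry, action set, module-grouped
#' object coordinates, ordered waypoint list and seed.  Reading validates
#' the schema: a missing required key or an unknown key is an error
#' naming the offending key.
#'
#' @param env A `"mirl_environment"`.
#' @param path File path.
#' @return `read_environment` returns the environment; `write_environment`
#'   its path, invisibly.
#' @export
write_environment <- function(env, path) {
  coords <- function(idx)
    lapply(idx, function(i) c(env$objects$x[i], env$objects$y[i]))
  doc <- list(
    version = env_schema_version,
    cell_size = env$grid$cell_size,
    room_width = env$grid$room_width,
    room_height = env$grid$room_height,
    n_actions = env$actions$K,
    seed = if (is.na(env$seed)) "NA" else env$seed,
    start = as.numeric(env$start),
    targets = coords(which(env$objects$module == "target")),
    obstacles = coords(which(env$objects$module == "obstacle")),
    waypoints = coords(env$waypoint_ids))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  doc <- yaml::read_yaml(path)
  required <- c("version", "cell_size", "room_width", "room_height",
                "n_actions", "seed", "start", "targets", "obstacles",
                "waypoints")
  miss <- setdiff(required, names(doc))
  if (length(miss)) stop("environment file missing key: ", miss[1])
  unknown <- setdiff(names(doc), required)
  if (length(unknown)) stop("unknown key in environment file: ", unknown[1])
  mat <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, as.numeric))
  }
  wp <- mat(doc$waypoints)
  if (is.null(wp)) stop("environment file missing key: waypoints")
  make_environment(grid_spec(doc$cell_size, doc$room_width, doc$room_height),
                   action_set(doc$n_actions),
                   targets = mat(doc$targets), obstacles = mat(doc$obstacles),
                   waypoints = wp, start = as.numeric(doc$start),
                   seed = if (identical(doc$seed, "NA")) NA_integer_
                   else as.integer(doc$seed))
}

#' Discretize a raw planar trajectory into states and actions
#'
#' Raw position samples (meters) are arc-length resampled at the grid's
#' cell size, each step's action is the nearest heading bin of its
#' displacement direction (boundary ties to the lower index), and the
#' state sequence is rebuilt against the trial's environment by replaying
#' object consumption.
#'
#' @param positions Matrix of raw planar points (>= 2 rows, meters).
#' @param env The trial's `"mirl_environment"` (provides grid and action
#'   set).
#' @param subject,task,trial Labels.
#' @return A [trajectory()].
#' @export
discretize_trajectory <- function(positions, env, subject = NA, task = NA,
                                  trial = NA) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, all(is.finite(positions)))
  pts <- resample_polyline(positions, env$grid$cell_size)
  K <- env$actions$K
  bw <- 360 / K
  d <- diff(pts)
  ang <- (atan2(d[, 2], d[, 1]) * 180 / pi) %% 360
  # boundary ties (exactly half a bin width) go to the lower index; the
  # 1e-9 guard keeps exact boundaries there despite rounding
  acts <- as.integer(ceiling(ang / bw - 0.5 - 1e-9) %% K)
  trajectory(env, pts, acts, subject = subject, task = task, trial = trial)
}

#' Write / read a behavioral dataset directory
#'
#' `write_dataset` writes one `trajectories.csv` (one row per position
#' sample: subject, task, trial, time index, x, y, action taken at that
#' sample — empty on the final sample — and the trial's environment
#' file) plus per-trial environment YAML files under `envs/`.
#' `read_dataset` reconstructs the dataset losslessly.
#'
#' @param data A [mirl_dataset()].
#' @param dir Directory (created if needed).
#' @return `read_dataset` returns a [mirl_dataset()].
#' @export
write_dataset <- function(data, dir) {
  dir.create(file.path(dir, "envs"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(data), function(i) {
    tr <- data[[i]]
    ef <- sprintf("envs/env_%04d.yaml", i)
    write_environment(tr$env, file.path(dir, ef))
    n <- nrow(tr$positions)
    data.frame(subject = as.character(tr$subject),
               task = as.character(tr$task),
               trial = as.character(tr$trial), t = seq_len(n) - 1L,
               x = tr$positions[, 1], y = tr$positions[, 2],
               action = c(tr$actions, NA), env_file = ef,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "trajectories.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  tab <- read.csv(file.path(dir, "trajectories.csv"),
                  colClasses = c(subject = "character", task = "character",
                                 trial = "character"))
  if (any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop("non-finite coordinates in trajectories.csv")
  key <- paste(tab$subject, tab$task, tab$trial, tab$env_file, sep = "\r")
  envs <- new.env()
  trajs <- lapply(unique(key), function(k) {
    sel <- tab[key == k, ]
    sel <- sel[order(sel$t), ]
    if (any(diff(sel$t) <= 0)) stop("time index not monotone within trial")
    ef <- sel$env_file[1]
    if (!exists(ef, envir = envs, inherits = FALSE))
      assign(ef, read_environment(file.path(dir, ef)), envir = envs)
    trajectory(envs[[ef]], cbind(sel$x, sel$y),
               sel$action[-nrow(sel)], subject = sel$subject[1],
               task = sel$task[1], trial = sel$trial[1])
  })
  mirl_dataset(trajs)
}

#' Read a run configuration file
#'
#' YAML configuration for the command-line interface.  Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Named list of settings merged over defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(seed = 1L, n_subjects = 2L, tasks = 4L,
                   trials_per_task = 4L, n_targets = 12L, n_obstacles = 12L,
                   cell_size = 0.572, room_width = 8.5, room_height = 7.3,
                   n_actions = 16L, eta = 1, lambda = 0, epsilon = 0.02,
                   gamma_max = 0.98, search = "auto", gamma_fixed = 0.5,
                   n_rollouts = 100L, max_steps = 500L)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  modifyList(defaults, cfg)
}

# Structured provenance sidecar written by every CLI run.
write_run_log <- function(dir, subcommand, cfg, seed) {
  flat <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ";")
  hash <- 0
  for (ch in utf8ToInt(flat)) hash <- (hash * 31 + ch) %% 2147483647
  yaml::write_yaml(list(subcommand = subcommand, seed = seed,
                        config = cfg, config_checksum = hash,
                        package_version =
                          as.character(utils::packageVersion("modirl"))),
                   file.path(dir, "run_log.yaml"))
}
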