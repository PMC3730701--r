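.trajectory_schema <- 1L

#' Save a trajectory to disk
#'
#' Writes a columnar container (one array per field, times as a named axis)
#' with a JSON sidecar (`<path>.json`) holding the configuration and schema
#' version.  The round trip through [load_trajectory()] is lossless.
#'
#' @param traj a `soup_trajectory`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "soup_trajectory"))
  payload <- list(schema = .trajectory_schema,
                  times = traj$times, positions = traj$positions,
                  velocities = traj$velocities, chem = traj$chem,
                  closed_mask = traj$closed_mask, kappa = traj$kappa,
                  n_clamped = traj$n_clamped)
  saveRDS(payload, path)
  jsonlite::write_json(list(schema = .trajectory_schema,
                            config = unclass(traj$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trajectory from disk
#'
#' @param path path written by [save_trajectory()].
#' @return a `soup_trajectory`.
#' @export
load_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable trajectory container ", path, ": ",
         conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$schema))
    stop("corrupt trajectory container: missing schema field")
  if (payload$schema != .trajectory_schema)
    stop("trajectory container schema ", payload$schema,
         " does not match supported schema ", .trajectory_schema)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing config sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfg <- do.call(ensemble_config, meta$config[names(formals(ensemble_config))])
  traj <- list(config = cfg, times = payload$times,
               positions = payload$positions,
               velocities = payload$velocities, chem = payload$chem,
               closed_mask = payload$closed_mask, kappa = payload$kappa,
               n_clamped = payload$n_clamped)
  class(traj) <- "soup_trajectory"
  traj
}

#' Flatten a trajectory to a per-frame data frame
#'
#' One row per (frame, subsystem): time, subsystem id, position, velocity
#' and electrochemical coordinates, closed flag and rate parameter.  Used
#' by the CSV export.
#'
#' @param x a `soup_trajectory`.
#' @param ... unused.
#' @return a data.frame with `n_frames * n_subsystems` rows.
#' @export
as.data.frame.soup_trajectory <- function(x, ...) {
  nf <- length(x$times)
  n <- dim(x$positions)[2]
  d <- dim(x$positions)[3]
  df <- data.frame(time = rep(x$times, each = n),
                   subsystem = rep(seq_len(n), nf))
  for (c in seq_len(d))
    df[[paste0("pos", c)]] <- as.vector(t(x$positions[, , c]))
  for (c in seq_len(d))
    df[[paste0("vel", c)]] <- as.vector(t(x$velocities[, , c]))
  for (c in 1:3)
    df[[paste0("chem", c)]] <- as.vector(t(x$chem[, , c]))
  df$closed <- rep(x$closed_mask, nf)
  df$kappa <- rep(x$kappa, nf)
  df
}

#' Export a trajectory as CSV
#'
#' @param traj a `soup_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version, the logged design
#' decisions of the analysis chain, and a timestamp alongside an output
#' file, so any result can be reproduced from its manifest.
#'
#' @param path manifest output path (JSON).
#' @param config the `ensemble_config` used.
#' @param seed the seed(s) used.
#' @param decisions named list of analysis decisions to record.
#' @param outputs character vector of files this manifest describes.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, decisions = list(),
                           outputs = character()) {
  manifest <- list(
    package = "primsoup",
    version = as.character(utils::packageVersion("primsoup")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    decisions = decisions,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
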