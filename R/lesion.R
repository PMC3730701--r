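#' Apply a functional lesion to a partition class
#'
#' Renders every subsystem carrying the target label functionally closed:
#' Newtonian interactions are preserved and the subsystems keep sensing
#' their neighbours, but they can no longer affect the electrochemical
#' states of others (their adjacency columns are zeroed by the integrator).
#' Nothing else about the state changes, and the operation is idempotent.
#'
#' @param state an `ensemble_state` (typically the last frame of a run).
#' @param partition a `blanket_partition` for the same ensemble.
#' @param target one of `"none"`, `"sensory"`, `"active"`, `"internal"`.
#' @return the state with an updated `closed_mask`.
#' @export
apply_lesion <- function(state, partition, target) {
  targets <- c("none", "sensory", "active", "internal")
  if (!(is.character(target) && length(target) == 1 && target %in% targets))
    stop("unknown lesion target: ", paste(target, collapse = ", "),
         " (must be one of ", paste(targets, collapse = ", "), ")")
  if (target == "none") return(state)
  state$closed_mask <- state$closed_mask |
    (as.character(partition$labels) == target)
  state
}

# mean distance of the given subsystems from their own centroid, per frame
dispersion_series <- function(traj, members) {
  vapply(seq_along(traj$times), function(f) {
    p <- matrix(traj$positions[f, members, ], length(members))
    ctr <- colMeans(p)
    mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
  }, numeric(1))
}

integrity_report <- function(traj, partition) {
  labels <- as.character(partition$labels)
  internal <- which(labels == "internal")
  blanket <- which(labels %in% c("sensory", "active"))
  members <- c(internal, blanket)
  disp <- dispersion_series(traj, members)
  # final-frame geometry: internal subsystems pushed beyond the median
  # blanket radius count as extruded
  f <- length(traj$times)
  pm <- matrix(traj$positions[f, members, ], length(members))
  ctr <- colMeans(pm)
  rad <- function(idx) {
    p <- matrix(traj$positions[f, idx, ], length(idx))
    sqrt(rowSums(sweep(p, 2, ctr)^2))
  }
  extrusion <- if (length(blanket) == 0) NA_integer_
               else sum(rad(internal) > stats::median(rad(blanket)))
  list(dispersion_series = disp,
       extrusion_count = extrusion,
       final_over_initial_dispersion = disp[length(disp)] / disp[1])
}

#' Run a lesion experiment
#'
#' Continues the simulation from the trajectory's final state for
#' `duration` seconds with the lesion applied, and computes an integrity
#' report (mean centroid distance of the internal and blanket subsystems
#' over time, the extrusion count, and the final/initial dispersion ratio).
#' A no-lesion control is run from the same state with the same seed, so
#' differences are attributable to the lesion alone.
#'
#' @param traj a `soup_trajectory`.
#' @param partition a `blanket_partition` for the trajectory.
#' @param target lesion target (see [apply_lesion()]).
#' @param duration continuation length in seconds.
#' @param seed RNG seed shared by the lesion and control arms.
#' @return an object of class `lesion_experiment`: a list with `target`,
#'   `lesion` and `control` integrity reports, and the continuations
#'   themselves (`lesion_traj`, `control_traj`).  Output metadata records
#'   the "oscillator death" interpretation of structural decay.
#' @export
run_lesion_experiment <- function(traj, partition, target, duration = 512,
                                  seed = traj$config$seed) {
  state0 <- state_at(traj)
  lesioned <- apply_lesion(state0, partition, target)
  set.seed(seed)
  lesion_traj <- continue_simulation(lesioned, traj$config, duration)
  set.seed(seed)
  control_traj <- continue_simulation(state0, traj$config, duration)
  out <- list(target = target,
              lesion = integrity_report(lesion_traj, partition),
              control = integrity_report(control_traj, partition),
              lesion_traj = lesion_traj, control_traj = control_traj,
              metadata = list(
                phenomenon = "oscillator death",
                metric = "mean centroid distance of internal + blanket"))
  class(out) <- "lesion_experiment"
  out
}

#' @export
print.lesion_experiment <- function(x, ...) {
  cat(sprintf("Lesion experiment: target = %s\n", x$target))
  cat(sprintf("  dispersion ratio (final/initial): lesion %.3f vs control %.3f\n",
              x$lesion$final_over_initial_dispersion,
              x$control$final_over_initial_dispersion))
  cat(sprintf("  extruded internal subsystems: lesion %d vs control %d\n",
              x$lesion$extrusion_count, x$control$extrusion_count))
  invisible(x)
}
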