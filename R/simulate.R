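# parameter list handed to the compiled integrator
integrator_params <- function(config) {
  fp <- config$force_params
  list(dt = config$dt,
       coupling_radius = config$coupling_radius,
       sigma = config$lorenz_params[1],
       rayleigh = config$lorenz_params[2],
       beta = config$lorenz_params[3],
       repulsion_strength = fp$repulsion_strength,
       attraction_strength = fp$attraction_strength,
       viscosity_coeff = fp$viscosity_coeff,
       well_stiffness = fp$well_stiffness,
       noise_sd = config$noise_sd,
       dist_clamp = .dist_clamp,
       coherence_scale = .coherence_scale,
       repulsion_screen = .repulsion_screen)
}

#' Advance the ensemble by one Euler--Maruyama step
#'
#' Positions advance with the current velocities; velocities receive the
#' Newtonian acceleration plus `noise_sd * sqrt(dt)` Gaussian increments;
#' electrochemical states receive the Lorenz-form flow plus the same kind of
#' increment.  The contact adjacency is recomputed from the current positions.
#' All right-hand sides are evaluated on the pre-step state.
#'
#' @param state an `ensemble_state`.
#' @param config an [ensemble_config()] object.
#' @return the updated `ensemble_state`, with `time` advanced by `dt`.
#' @export
step <- function(state, config) {
  res <- soup_integrate_cpp(state$positions, state$velocities, state$chem,
                            state$kappa, state$closed_mask,
                            integrator_params(config), state$time,
                            n_steps = 1L, save_every = 1L)
  f <- 2L  # frame after the step
  out <- state
  out$positions  <- matrix(res$positions[f, , ], nrow(state$positions))
  out$velocities <- matrix(res$velocities[f, , ], nrow(state$positions))
  out$chem       <- matrix(res$chem[f, , ], nrow(state$positions))
  out$time <- state$time + config$dt
  out
}

#' Simulate the primordial soup
#'
#' Initialises the ensemble from the configuration's seed and integrates the
#' coupled stochastic differential equations with the forward Euler
#' (Euler--Maruyama) method, saving a frame every `save_interval` seconds
#' (including the initial state).
#'
#' @param config an [ensemble_config()] object.
#' @param verbose log progress and critical events (close encounters) to
#'   stderr.
#' @return an object of class `soup_trajectory`: a list with `config`,
#'   `times`, and time-indexed arrays `positions`, `velocities`
#'   (frames x n x d), `chem` (frames x n x 3), plus `closed_mask` and
#'   `kappa`.
#' @examples
#' cfg <- ensemble_config(n_subsystems = 16, duration = 2, seed = 7)
#' traj <- simulate_soup(cfg)
#' traj
#' @export
simulate_soup <- function(config, verbose = FALSE) {
  validate_config(config)
  state <- init_ensemble(config)
  n_steps <- round(config$duration / config$dt)
  save_every <- round(config$save_interval / config$dt)
  if (verbose)
    message(sprintf("integrating %d subsystems for %g s (%d steps)",
                    config$n_subsystems, config$duration, n_steps))
  res <- soup_integrate_cpp(state$positions, state$velocities, state$chem,
                            state$kappa, state$closed_mask,
                            integrator_params(config), 0,
                            n_steps = as.integer(n_steps),
                            save_every = as.integer(save_every))
  if (verbose && res$n_clamped > 0)
    message(sprintf("critical events: %d pair-steps below the %g distance clamp",
                    res$n_clamped, .dist_clamp))
  traj <- list(config = config, times = res$times,
               positions = res$positions, velocities = res$velocities,
               chem = res$chem, closed_mask = state$closed_mask,
               kappa = state$kappa, n_clamped = res$n_clamped)
  class(traj) <- "soup_trajectory"
  traj
}

#' Continue a simulation from a given state
#'
#' Integrates onwards from `state` for `duration` seconds under `config`,
#' using the current RNG stream (callers seed it explicitly).  Used by the
#' lesion experiments, which restart the soup from a trajectory's final
#' state with an altered closed mask.
#'
#' @param state an `ensemble_state` to start from.
#' @param config an [ensemble_config()] object (its `duration` is ignored).
#' @param duration seconds to integrate.
#' @return a `soup_trajectory` covering the continuation.
#' @export
continue_simulation <- function(state, config, duration) {
  n_steps <- round(duration / config$dt)
  save_every <- round(config$save_interval / config$dt)
  res <- soup_integrate_cpp(state$positions, state$velocities, state$chem,
                            state$kappa, state$closed_mask,
                            integrator_params(config), state$time,
                            n_steps = as.integer(n_steps),
                            save_every = as.integer(save_every))
  traj <- list(config = config, times = res$times,
               positions = res$positions, velocities = res$velocities,
               chem = res$chem, closed_mask = state$closed_mask,
               kappa = state$kappa, n_clamped = res$n_clamped)
  class(traj) <- "soup_trajectory"
  traj
}

#' Extract the ensemble state at a saved frame
#'
#' @param traj a `soup_trajectory`.
#' @param frame frame index (default: last).
#' @return an `ensemble_state`.
#' @export
state_at <- function(traj, frame = length(traj$times)) {
  n <- dim(traj$positions)[2]
  state <- list(positions = matrix(traj$positions[frame, , ], n),
                velocities = matrix(traj$velocities[frame, , ], n),
                chem = matrix(traj$chem[frame, , ], n),
                kappa = traj$kappa, closed_mask = traj$closed_mask,
                time = traj$times[frame])
  class(state) <- "ensemble_state"
  state
}

#' @export
print.soup_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "Soup trajectory: %d subsystems in %d-D, %d frames over [%g, %g] s\n",
    d[2], d[3], d[1], x$times[1], x$times[length(x$times)]))
  cat(sprintf("  %d functionally closed subsystems; seed %d\n",
              sum(x$closed_mask), x$config$seed))
  invisible(x)
}
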