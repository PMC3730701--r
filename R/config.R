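#' Ensemble configuration
#'
#' Builds and validates the full parameter set of the soup simulator: ensemble
#' size, spatial dimension, integration settings, coupling radius, the fraction
#' of functionally closed subsystems, Lorenz-form parameters of the
#' electrochemical flow, Newtonian force parameters, noise amplitude and seed.
#'
#' Defaults reproduce the study conditions: 128 subsystems in two dimensions,
#' forward-Euler steps of 1/512 s, unit-variance random fluctuations, contact
#' coupling within a distance of one, and a randomly chosen third of the
#' subsystems rendered functionally closed (their adjacency columns are
#' zeroed, so they cannot influence the electrochemical states of others).
#'
#' @param n_subsystems number of subsystems in the ensemble.
#' @param space_dim spatial dimension of the Newtonian motion.
#' @param dt integration step in seconds.
#' @param duration simulated time in seconds.
#' @param save_interval spacing of saved frames in seconds; must be an
#'   integer multiple of `dt`.
#' @param coupling_radius contact distance below which subsystems couple.
#' @param closed_fraction fraction of subsystems rendered functionally closed.
#' @param lorenz_params length-3 numeric: Prandtl-like, Rayleigh-like and
#'   geometric parameters of the Lorenz-form electrochemical flow.
#' @param force_params named list with elements `repulsion_strength`,
#'   `attraction_strength`, `viscosity_coeff`, `well_stiffness`
#'   (all non-negative).
#' @param noise_sd standard deviation of the unit-time random fluctuations
#'   entering the velocity and electrochemical equations.
#' @param seed integer seed for all randomness in the run.
#' @return an object of class `ensemble_config` (a validated list).
#' @examples
#' cfg <- ensemble_config(n_subsystems = 16, duration = 4)
#' cfg$dt
#' @export
ensemble_config <- function(n_subsystems = 128L,
                            space_dim = 2L,
                            dt = 1 / 512,
                            duration = 2048,
                            save_interval = 1,
                            coupling_radius = 1,
                            closed_fraction = 1 / 3,
                            lorenz_params = c(10, 32, 8 / 3),
                            force_params = list(),
                            noise_sd = 1,
                            seed = 1L) {
  fp <- utils::modifyList(default_force_params(), force_params)
  cfg <- list(
    n_subsystems = as.integer(n_subsystems),
    space_dim = as.integer(space_dim),
    dt = dt,
    duration = duration,
    save_interval = save_interval,
    coupling_radius = coupling_radius,
    closed_fraction = closed_fraction,
    lorenz_params = as.numeric(lorenz_params),
    force_params = fp,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "ensemble_config"
  validate_config(cfg)
  cfg
}

# Pairwise-force constants tuned once to the "restless soup" regime: the
# ensemble falls to the bottom of the well, neighbours jostle within the
# coupling radius, and near-collisions are blown apart by the inverse-square
# law without destroying ergodicity.
default_force_params <- function() {
  list(
    repulsion_strength = 1,
    attraction_strength = 2,
    viscosity_coeff = 12,
    well_stiffness = 1 / 8
  )
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = NULL)
  ))
}

#' Validate an ensemble configuration
#'
#' Checks every field of an `ensemble_config`; the first offending field is
#' reported in a `config_error`.  Called by the constructor and by anything
#' that mutates a configuration.
#'
#' @param cfg an `ensemble_config` object (or a bare list with its fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk <- function(field, ok, msg) if (!isTRUE(ok)) config_error(field, msg)
  chk("n_subsystems", length(cfg$n_subsystems) == 1 && !is.na(cfg$n_subsystems)
      && cfg$n_subsystems >= 1, "must be a positive integer")
  chk("space_dim", length(cfg$space_dim) == 1 && !is.na(cfg$space_dim) &&
      cfg$space_dim >= 1 && cfg$space_dim <= 8, "must be an integer in 1..8")
  chk("dt", is.numeric(cfg$dt) && length(cfg$dt) == 1 && is.finite(cfg$dt) &&
      cfg$dt > 0, "must be > 0")
  chk("duration", is.numeric(cfg$duration) && length(cfg$duration) == 1 &&
      is.finite(cfg$duration) && cfg$duration >= 0, "must be >= 0")
  chk("save_interval", is.numeric(cfg$save_interval) &&
      cfg$save_interval > 0, "must be > 0")
  ratio <- cfg$save_interval / cfg$dt
  chk("save_interval", abs(ratio - round(ratio)) < 1e-8,
      "must be an integer multiple of dt")
  chk("coupling_radius", is.numeric(cfg$coupling_radius) &&
      cfg$coupling_radius > 0, "must be > 0")
  chk("closed_fraction", is.numeric(cfg$closed_fraction) &&
      cfg$closed_fraction >= 0 && cfg$closed_fraction <= 1,
      "must lie in [0, 1]")
  chk("lorenz_params", is.numeric(cfg$lorenz_params) &&
      length(cfg$lorenz_params) == 3 && all(is.finite(cfg$lorenz_params)),
      "must be three finite reals")
  fp <- cfg$force_params
  need <- c("repulsion_strength", "attraction_strength", "viscosity_coeff",
            "well_stiffness")
  chk("force_params", is.list(fp) && setequal(names(fp), need),
      paste("must have exactly the fields", paste(need, collapse = ", ")))
  for (f in need)
    chk(paste0("force_params$", f), is.numeric(fp[[f]]) &&
        length(fp[[f]]) == 1 && is.finite(fp[[f]]) && fp[[f]] >= 0,
        "must be a non-negative real")
  chk("noise_sd", is.numeric(cfg$noise_sd) && length(cfg$noise_sd) == 1 &&
      is.finite(cfg$noise_sd) && cfg$noise_sd >= 0, "must be >= 0")
  chk("seed", length(cfg$seed) == 1 && !is.na(cfg$seed), "must be an integer")
  invisible(cfg)
}

#' Load an ensemble configuration from a JSON file
#'
#' Reads a flat JSON object whose keys are the fields of [ensemble_config()]
#' (with `force_params` as a nested object).  Missing keys take the defaults;
#' unknown keys are an error.
#'
#' @param path path to the JSON file.
#' @return an `ensemble_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed configuration JSON in ", path, ": ",
                         conditionMessage(e)))
  if (!is.list(raw)) stop("configuration must be a JSON object")
  known <- names(formals(ensemble_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(ensemble_config, raw)
}

#' Write an ensemble configuration to JSON
#'
#' @param config an `ensemble_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ensemble_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat("Ensemble configuration\n")
  cat(sprintf("  %d subsystems in %d-D, dt = 1/%g s, duration = %g s\n",
              x$n_subsystems, x$space_dim, 1 / x$dt, x$duration))
  cat(sprintf("  coupling radius %g, closed fraction %.3f, noise sd %g\n",
              x$coupling_radius, x$closed_fraction, x$noise_sd))
  cat(sprintf("  Lorenz parameters (%g, %g, %g)\n", x$lorenz_params[1],
              x$lorenz_params[2], x$lorenz_params[3]))
  fp <- x$force_params
  cat(sprintf("  forces: repulsion %g, attraction %g, viscosity %g, well %g\n",
              fp$repulsion_strength, fp$attraction_strength,
              fp$viscosity_coeff, fp$well_stiffness))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
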