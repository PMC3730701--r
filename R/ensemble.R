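# Internal constants shared by the R right-hand sides and the compiled
# integrator.  The coherence scale sets how similar two subsystems' third
# electrochemical states must be for the gated attraction to be net
# attractive; the clamp bounds pairwise distances away from zero in the
# force law.
.coherence_scale <- 8
.dist_clamp <- 1e-6
# screening length of the repulsion, in units of the coupling radius: the
# force is inverse-square in the near field and negligible beyond a few
# coupling radii (all interactions are short-range)
.repulsion_screen <- 2

#' Initialise the ensemble state
#'
#' Positions, velocities and the three electrochemical states are drawn from
#' the standard normal distribution using the configuration's seed.  Each
#' subsystem receives its own rate parameter \eqn{\kappa^{(i)} = 2^{-2U^8}}
#' with \eqn{U \sim \mathrm{Uniform}(0,1)}, giving many fast subsystems with
#' rate constants near one and a few slower ones.  A random subset of
#' `round(n * closed_fraction)` subsystems is flagged functionally closed.
#'
#' @param config an [ensemble_config()] object.
#' @return an object of class `ensemble_state`: a list with `positions`,
#'   `velocities` (n x d), `chem` (n x 3), `kappa`, `closed_mask`, `time`.
#' @export
init_ensemble <- function(config) {
  validate_config(config)
  n <- config$n_subsystems
  d <- config$space_dim
  set.seed(config$seed)
  positions  <- matrix(stats::rnorm(n * d), n, d)
  velocities <- matrix(stats::rnorm(n * d), n, d)
  chem       <- matrix(stats::rnorm(n * 3), n, 3)
  u <- stats::runif(n)
  kappa <- 2^(-2 * u^8)
  n_closed <- round(n * config$closed_fraction)
  closed_mask <- rep(FALSE, n)
  if (n_closed > 0)
    closed_mask[sample.int(n, n_closed)] <- TRUE
  state <- list(positions = positions, velocities = velocities, chem = chem,
                kappa = kappa, closed_mask = closed_mask, time = 0)
  class(state) <- "ensemble_state"
  state
}

#' Contact adjacency matrix
#'
#' `A[i, j] = 1` when subsystem `j` influences subsystem `i`: the two lie
#' within the coupling radius, `i != j`, and `j` is not functionally closed.
#' Column `j` therefore encodes the directed influences *from* `j` to its
#' children; closing a subsystem zeroes its column but leaves its row (it
#' still senses its neighbours).
#'
#' @param positions n x d matrix of positions.
#' @param coupling_radius contact distance.
#' @param closed_mask logical n-vector of functionally closed subsystems.
#' @return binary n x n matrix with zero diagonal.
#' @export
contact_neighbors <- function(positions, coupling_radius,
                              closed_mask = rep(FALSE, nrow(positions))) {
  n <- nrow(positions)
  D <- as.matrix(stats::dist(positions))
  A <- (D <= coupling_radius) * 1
  dimnames(A) <- NULL
  diag(A) <- 0
  A[, closed_mask] <- 0
  A
}

#' Local average of electrochemical states
#'
#' Mean of the electrochemical 3-vectors over subsystem `i` and its
#' in-neighbours (the subsystems whose adjacency column feeds `i`).  The
#' subsystem itself is always included, so the average is defined for
#' isolated subsystems.
#'
#' @param chem n x 3 matrix of electrochemical states.
#' @param A binary adjacency matrix from [contact_neighbors()].
#' @param i subsystem index.
#' @return a length-3 numeric vector.
#' @export
local_average <- function(chem, A, i) {
  members <- unique(c(i, which(A[i, ] == 1)))
  colMeans(chem[members, , drop = FALSE])
}

# local averages for all subsystems at once (matrix form of local_average)
local_average_all <- function(chem, A) {
  counts <- rowSums(A) + 1
  (chem + A %*% chem) / counts
}

#' Electrochemical flow
#'
#' Lorenz-form flow per subsystem, scaled by its rate parameter
#' \eqn{\kappa^{(i)}}, with the local average \eqn{\bar x^{(i)}} of the
#' coupled subsystems entering both linearly and nonlinearly:
#' \deqn{\dot x_1 = \kappa\,\sigma(\bar x_2 - x_1)}
#' \deqn{\dot x_2 = \kappa(\rho\,\bar x_1 - x_2 - \bar x_1 x_3)}
#' \deqn{\dot x_3 = \kappa(\bar x_1 x_2 - \beta x_3)}
#' so the Rayleigh parameter of the flow is effectively state-dependent,
#' \eqn{\bar x_1(\rho - x_3)}.  An isolated subsystem (local average equal to
#' its own state) follows the textbook Lorenz equations.
#'
#' @param state an `ensemble_state`.
#' @param A binary adjacency matrix.
#' @param lorenz_params length-3 numeric `(sigma, rho, beta)`.
#' @return n x 3 matrix of time derivatives of the electrochemical states.
#' @export
electrochemical_flow <- function(state, A, lorenz_params = c(10, 32, 8 / 3)) {
  sg <- lorenz_params[1]; rh <- lorenz_params[2]; be <- lorenz_params[3]
  x <- state$chem
  v <- local_average_all(x, A)
  k <- state$kappa
  cbind(k * sg * (v[, 2] - x[, 1]),
        k * (rh * v[, 1] - x[, 2] - v[, 1] * x[, 3]),
        k * (v[, 1] * x[, 2] - be * x[, 3]))
}

#' Newtonian acceleration
#'
#' Pairwise forces (strong inverse-square repulsion plus a weaker
#' short-range attraction gated by the coherence of the third
#' electrochemical states: subsystems with similar third states attract,
#' dissimilar ones repel; the attractive profile
#' \eqn{(r/\rho)\exp(-r^2/2\rho^2)} peaks at the coupling radius \eqn{\rho}
#' and is negligible beyond a few radii), a viscous drag proportional to
#' velocity, and a quadratic potential well centred at the origin.  The
#' attractive bond is a reciprocal electrochemical exchange, so pairs
#' involving a functionally closed subsystem (which cannot exert
#' electrochemical influence) form no bond, symmetrically.  Pairwise forces
#' obey Newton's third law exactly; pair distances are clamped below at
#' `1e-6` to avoid singularities (clamped encounters trigger a warning).
#'
#' @param state an `ensemble_state`.
#' @param force_params named list as in [ensemble_config()].
#' @param coupling_radius contact distance setting the attraction range.
#' @return n x d matrix of accelerations.
#' @export
newtonian_acceleration <- function(state, force_params = default_force_params(),
                                   coupling_radius = 1) {
  p <- state$positions
  n <- nrow(p); d <- ncol(p)
  fp <- force_params
  D <- as.matrix(stats::dist(p))
  clamped <- D < .dist_clamp & row(D) != col(D)
  if (any(clamped)) {
    warning("pairwise distance clamped at ", .dist_clamp,
            " for ", sum(clamped) / 2, " pair(s)")
    D[clamped] <- .dist_clamp
  }
  diag(D) <- Inf  # no self-force
  z <- state$chem[, 3]
  DZ2 <- outer(z, z, "-")^2
  coh <- (.coherence_scale^2 - DZ2) / (.coherence_scale^2 + DZ2)
  # the bond is a reciprocal electrochemical exchange: pairs involving a
  # functionally closed subsystem form no bond (symmetrically)
  open_pair <- outer(!state$closed_mask, !state$closed_mask, "&")
  Dr <- D / coupling_radius
  fmag <- fp$repulsion_strength / D^2 *
    exp(-Dr^2 / (2 * .repulsion_screen^2)) -
    fp$attraction_strength * coh * open_pair * Dr * exp(-0.5 * Dr^2)
  diag(fmag) <- 0
  force <- matrix(0, n, d)
  for (c in seq_len(d)) {
    U <- outer(p[, c], p[, c], "-") / D  # unit vector component, i minus j
    force[, c] <- rowSums(fmag * U)
  }
  force - fp$viscosity_coeff * state$velocities - fp$well_stiffness * p
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("Ensemble state: %d subsystems in %d-D at t = %g s (%d closed)\n",
              nrow(x$positions), ncol(x$positions), x$time,
              sum(x$closed_mask)))
  invisible(x)
}
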