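# Independent oracles used across the suite.  These are deliberately naive
# implementations (plain loops, set construction) kept separate from the
# package's own code paths.

# forward-Euler integration of the textbook Lorenz system (sigma, rho, beta),
# optionally scaled by a rate constant; returns the (n_steps+1) x 3 path
reference_lorenz <- function(x0, dt, n_steps, params = c(10, 32, 8 / 3),
                             kappa = 1) {
  out <- matrix(0, n_steps + 1, 3)
  x <- as.numeric(x0)
  out[1, ] <- x
  for (s in seq_len(n_steps)) {
    d <- c(params[1] * (x[2] - x[1]),
           params[2] * x[1] - x[2] - x[1] * x[3],
           x[1] * x[2] - params[3] * x[3])
    x <- x + kappa * d * dt
    out[s + 1, ] <- x
  }
  out
}

# brute-force Markov blanket of node i in a digraph whose adjacency follows
# the column convention (A[r, c] = 1 means c -> r): parents, children and
# parents of children, constructed as explicit sets
brute_force_blanket <- function(A, i) {
  parents <- which(A[i, ] == 1)
  children <- which(A[, i] == 1)
  coparents <- unique(unlist(lapply(children, function(ch) which(A[ch, ] == 1))))
  setdiff(sort(unique(c(parents, children, coparents))), i)
}

random_digraph <- function(n, p = 0.3) {
  A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

# minimal hand-built trajectory object for analysis-level tests
fake_trajectory <- function(positions, chem, times,
                            closed_mask = rep(FALSE, dim(positions)[2]),
                            save_interval = 1, coupling_radius = 1) {
  n <- dim(positions)[2]
  cfg <- ensemble_config(n_subsystems = n, duration = max(times),
                         save_interval = save_interval,
                         coupling_radius = coupling_radius, seed = 1)
  traj <- list(config = cfg, times = times, positions = positions,
               velocities = array(0, dim(positions)), chem = chem,
               closed_mask = closed_mask, kappa = rep(1, n), n_clamped = 0)
  class(traj) <- "soup_trajectory"
  traj
}

fake_partition <- function(labels, A = NULL) {
  n <- length(labels)
  lab <- factor(labels, levels = c("external", "sensory", "active",
                                   "internal"))
  out <- list(labels = lab, chi = as.numeric(labels == "internal"),
              A_window = A, B = NULL, eigenvector = rep(1, n),
              eigenvalue = NA, k = sum(labels == "internal"))
  class(out) <- "blanket_partition"
  out
}

# a synthetic trajectory whose internal chem is smooth AR(1) noise and whose
# external positions are random walks; optionally one external subsystem is
# doctored to be a linear readout of the internal states
synthetic_inference_traj <- function(seed, doctored = NULL, T = 160,
                                     n = 20, k = 4) {
  set.seed(seed)
  ar1 <- function(T, rho = 0.9) {
    x <- numeric(T)
    for (t in 2:T) x[t] <- rho * x[t - 1] + rnorm(1)
    x
  }
  chem <- array(0, c(T, n, 3))
  for (i in 1:k) for (c in 1:3) chem[, i, c] <- ar1(T)
  pos <- array(0, c(T, n, 2))
  for (i in (k + 1):n) for (c in 1:2) pos[, i, c] <- ar1(T)
  if (!is.null(doctored)) {
    # external position = filtered mix of internal eigenvariates + noise
    M <- do.call(cbind, lapply(1:3, function(c) chem[, 1:k, c]))
    emb <- temporal_embed(M, 8, 1)
    X <- eigenvariates(emb, 12)
    valid <- attr(emb, "valid_rows")
    sd1 <- sd(X[, 1])
    pos[valid, doctored, 1] <- (X[, 1] + 0.5 * X[, 2]) / sd1 +
      0.05 * rnorm(length(valid))
    pos[valid, doctored, 2] <- (X[, 2] - X[, 3]) / sd1 +
      0.05 * rnorm(length(valid))
  }
  traj <- fake_trajectory(pos, chem, times = 0:(T - 1))
  labels <- c(rep("internal", k), rep("active", 2),
              rep("external", n - k - 2))
  list(traj = traj, partition = fake_partition(labels))
}

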