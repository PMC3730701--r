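#' Standard-form (Helmholtz) flow system
#'
#' A flow expressed in terms of a scalar Gibbs energy \eqn{G(x)} (the
#' negative log of the ergodic density), a symmetric positive semi-definite
#' diffusion tensor \eqn{\Gamma} (half the covariance of the random
#' fluctuations) and an antisymmetric solenoidal operator \eqn{R}:
#' \deqn{f(x) = -(\Gamma + R)\,\nabla G(x).}
#' With this flow, \eqn{p(x) = \exp(-G(x))} is the stationary solution of
#' the Fokker--Planck equation.
#'
#' @param G function of a state vector returning the Gibbs energy.
#' @param grad_G function returning the gradient of `G`.
#' @param Gamma symmetric PSD diffusion matrix.
#' @param R antisymmetric matrix; rejected unless
#'   \eqn{\|R + R^T\|_\infty \le 10^{-12}}.
#' @param dims optional named list partitioning the coordinates into
#'   external/sensory/active/internal blocks.
#' @return an object of class `standard_form_system`.
#' @export
standard_form_system <- function(G, grad_G, Gamma, R, dims = NULL) {
  Gamma <- as.matrix(Gamma); R <- as.matrix(R)
  stopifnot(nrow(Gamma) == ncol(Gamma), all(dim(R) == dim(Gamma)))
  if (max(abs(R + t(R))) > 1e-12)
    stop("R is not antisymmetric: ||R + R^T|| = ", max(abs(R + t(R))))
  if (max(abs(Gamma - t(Gamma))) > 1e-12)
    stop("Gamma must be symmetric")
  ev <- eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop("Gamma must be positive semi-definite")
  out <- list(G = G, grad_G = grad_G, Gamma = Gamma, R = R, dims = dims)
  class(out) <- "standard_form_system"
  out
}

#' Quadratic (Ornstein--Uhlenbeck) standard-form system
#'
#' Convenience constructor for Gibbs energy \eqn{G(x) = x^T P x / 2}
#' (Gaussian ergodic density with precision `P`).
#'
#' @param P symmetric positive-definite precision matrix.
#' @param Gamma,R as in [standard_form_system()].
#' @return a `standard_form_system`.
#' @export
quadratic_standard_form <- function(P, Gamma, R) {
  P <- as.matrix(P)
  force(P)
  standard_form_system(
    G = function(x) 0.5 * sum(x * (P %*% x)),
    grad_G = function(x) drop(P %*% x),
    Gamma = Gamma, R = R)
}

#' Flow of a standard-form system
#'
#' \eqn{f(x) = -(\Gamma + R)\,\nabla G(x)}; the \eqn{\Gamma} part descends
#' the Gibbs energy while the solenoidal \eqn{R} part circulates on the
#' isocontours of the ergodic density.
#'
#' @param sys a `standard_form_system`.
#' @param x state vector.
#' @return the flow vector at `x`.
#' @export
flow_from_standard_form <- function(sys, x) {
  drop(-(sys$Gamma + sys$R) %*% sys$grad_G(x))
}

#' Fokker--Planck residual of the candidate stationary density
#'
#' Evaluates \eqn{\nabla\cdot(\Gamma \nabla p - f p)} with
#' \eqn{p = \exp(-G)} on a regular two-dimensional grid using central
#' differences, and returns the maximum absolute residual over the interior.
#' A residual that vanishes (second order) under grid refinement certifies
#' that \eqn{\exp(-G)} is stationary under the flow.
#'
#' @param sys a `standard_form_system` (two-dimensional).
#' @param grid list of two monotone coordinate vectors with equal spacing.
#' @param flow optional flow function `f(x)` overriding the standard form
#'   (used to demonstrate that corrupted flows fail the check).
#' @return maximum absolute residual over interior grid points.
#' @export
fokker_planck_residual <- function(sys, grid, flow = NULL) {
  stopifnot(length(grid) == 2)
  x1 <- grid[[1]]; x2 <- grid[[2]]
  h1 <- diff(x1); h2 <- diff(x2)
  if (max(abs(h1 - h1[1])) > 1e-12 || max(abs(h2 - h2[1])) > 1e-12)
    stop("grid must be uniformly spaced")
  h1 <- h1[1]; h2 <- h2[1]
  n1 <- length(x1); n2 <- length(x2)
  if (is.null(flow)) flow <- function(x) flow_from_standard_form(sys, x)
  p <- matrix(0, n1, n2); f1 <- matrix(0, n1, n2); f2 <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    x <- c(x1[i], x2[j])
    p[i, j] <- exp(-sys$G(x))
    fx <- flow(x)
    f1[i, j] <- fx[1]; f2[i, j] <- fx[2]
  }
  d1 <- function(M, h, axis) {  # central difference along axis, NA at edges
    out <- matrix(NA_real_, n1, n2)
    if (axis == 1) out[2:(n1 - 1), ] <-
        (M[3:n1, ] - M[1:(n1 - 2), ]) / (2 * h)
    else out[, 2:(n2 - 1)] <-
        (M[, 3:n2] - M[, 1:(n2 - 2)]) / (2 * h)
    out
  }
  G <- sys$Gamma
  # flux J = Gamma grad p - f p, then residual = div J
  J1 <- G[1, 1] * d1(p, h1, 1) + G[1, 2] * d1(p, h2, 2) - f1 * p
  J2 <- G[2, 1] * d1(p, h1, 1) + G[2, 2] * d1(p, h2, 2) - f2 * p
  resid <- d1(J1, h1, 1) + d1(J2, h2, 2)
  max(abs(resid), na.rm = TRUE)
}

#' Linear-Gaussian model over a blanket partition
#'
#' A joint Gaussian density over external (\eqn{\psi}), sensory, active and
#' internal (\eqn{\lambda}) coordinates, specified by its precision matrix
#' and mean.  The tractable instantiation on which the variational
#' free-energy lemma can be verified constructively: the exact posterior
#' over \eqn{\psi} and the log evidence are available in closed form.
#'
#' @param precision symmetric positive-definite matrix over all coordinates.
#' @param mean mean vector.
#' @param dims named list of index vectors `psi`, `s`, `a`, `lambda`
#'   partitioning the coordinates.
#' @return an object of class `gaussian_model`.
#' @export
gaussian_model <- function(precision, mean, dims) {
  precision <- as.matrix(precision)
  d <- nrow(precision)
  stopifnot(length(mean) == d,
            setequal(names(dims), c("psi", "s", "a", "lambda")),
            setequal(unlist(dims), seq_len(d)))
  if (max(abs(precision - t(precision))) > 1e-10)
    stop("precision must be symmetric")
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision must be positive-definite")
  out <- list(precision = precision, mean = as.numeric(mean), dims = dims)
  class(out) <- "gaussian_model"
  out
}

# indices of the blanket-plus-internal coordinates, in model order
v_indices <- function(model) sort(unlist(model$dims[c("s", "a", "lambda")]))

# assemble the full coordinate vector from psi and (s, a, lambda) values
full_vector <- function(model, psi, blanket_state, lambda_value) {
  x <- numeric(nrow(model$precision))
  x[model$dims$psi] <- psi
  x[model$dims$s] <- blanket_state$s
  x[model$dims$a] <- blanket_state$a
  x[model$dims$lambda] <- lambda_value
  x
}

#' Variational free energy of a Gaussian model
#'
#' \eqn{F = E_q[G(\psi, s, a, \lambda)] - H[q]}: the expected Gibbs energy
#' (negative log joint) under a Gaussian variational density
#' \eqn{q(\psi) = N(m, S)} minus the entropy of \eqn{q}.  Both terms are in
#' closed form.  \eqn{F} upper-bounds the negative log evidence
#' \eqn{-\ln p(s, a, \lambda)} with gap equal to the Kullback--Leibler
#' divergence from \eqn{q} to the exact posterior; the bound is attained
#' exactly when \eqn{q} is the posterior.
#'
#' @param model a `gaussian_model`.
#' @param blanket_state list with numeric `s` and `a`.
#' @param q_mean,q_cov mean and positive-definite covariance of `q`.
#' @param lambda_value value of the internal coordinates.
#' @return the free energy (scalar).
#' @export
free_energy <- function(model, blanket_state, q_mean, q_cov, lambda_value) {
  q_cov <- as.matrix(q_cov)
  ev <- eigen(q_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("q covariance must be positive-definite")
  P <- model$precision
  dpsi <- length(model$dims$psi)
  d <- nrow(P)
  zeta <- full_vector(model, q_mean, blanket_state, lambda_value) - model$mean
  Ppp <- P[model$dims$psi, model$dims$psi, drop = FALSE]
  logdetP <- determinant(P, logarithm = TRUE)$modulus
  # E_q[G]: quadratic form at the mean plus the trace coupling to S,
  # including the joint density's normalising constant
  eG <- 0.5 * (sum(zeta * (P %*% zeta)) + sum(Ppp * q_cov)) +
    0.5 * (d * log(2 * pi) - as.numeric(logdetP))
  Hq <- 0.5 * (dpsi * (1 + log(2 * pi)) +
               as.numeric(determinant(q_cov, logarithm = TRUE)$modulus))
  eG - Hq
}

#' Closed-form log evidence of the blanket-plus-internal state
#'
#' \eqn{\ln p(s, a, \lambda)}: the Gaussian marginal of the joint over the
#' non-external coordinates, evaluated at the given values.
#'
#' @inheritParams free_energy
#' @return the log marginal likelihood (scalar).
#' @export
log_evidence <- function(model, blanket_state, lambda_value) {
  v <- v_indices(model)
  Sigma <- solve(model$precision)
  Svv <- Sigma[v, v, drop = FALSE]
  x <- full_vector(model, numeric(length(model$dims$psi)), blanket_state,
                   lambda_value)
  dev <- x[v] - model$mean[v]
  U <- chol(Svv)
  z <- backsolve(U, dev, transpose = TRUE)
  -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

#' Exact Gaussian posterior over the external coordinates
#'
#' Closed-form conditional \eqn{p(\psi \mid s, a, \lambda)} of the joint
#' Gaussian: mean \eqn{\mu_\psi - P_{\psi\psi}^{-1} P_{\psi v}(v - \mu_v)},
#' covariance \eqn{P_{\psi\psi}^{-1}}.
#'
#' @inheritParams free_energy
#' @return list with `mean` and `cov`.
#' @export
exact_posterior <- function(model, blanket_state, lambda_value) {
  P <- model$precision
  psi <- model$dims$psi
  v <- v_indices(model)
  x <- full_vector(model, numeric(length(psi)), blanket_state, lambda_value)
  Ppp <- P[psi, psi, drop = FALSE]
  Ppv <- P[psi, v, drop = FALSE]
  S <- solve(Ppp)
  m <- model$mean[psi] - drop(S %*% Ppv %*% (x[v] - model$mean[v]))
  list(mean = m, cov = S)
}

#' Minimize free energy over the Gaussian variational family
#'
#' Gradient-based (BFGS) minimization of [free_energy()] over the mean and
#' covariance of \eqn{q}, the covariance parametrized by its log-Cholesky
#' factor.  At the optimum the variational density equals the exact
#' posterior and the free energy equals the negative log evidence.
#'
#' @inheritParams free_energy
#' @param init optional list with starting `mean` and `cov`.
#' @param maxit iteration budget.
#' @return list with `mean`, `cov`, `free_energy`, `convergence` (0 for
#'   success), `iterations`.
#' @export
optimize_variational <- function(model, blanket_state, lambda_value,
                                 init = NULL, maxit = 500) {
  P <- model$precision
  psi <- model$dims$psi
  dpsi <- length(psi)
  Ppp <- P[psi, psi, drop = FALSE]
  ltri <- which(lower.tri(diag(dpsi)))
  pack <- function(m, S) {
    L <- t(chol(S))
    c(m, log(diag(L)), L[ltri])
  }
  unpack <- function(th) {
    m <- th[seq_len(dpsi)]
    L <- matrix(0, dpsi, dpsi)
    diag(L) <- exp(th[dpsi + seq_len(dpsi)])
    L[ltri] <- th[-seq_len(2 * dpsi)]
    list(m = m, L = L, S = L %*% t(L))
  }
  fn <- function(th) {
    u <- unpack(th)
    free_energy(model, blanket_state, u$m, u$S, lambda_value)
  }
  gr <- function(th) {
    u <- unpack(th)
    zeta <- full_vector(model, u$m, blanket_state, lambda_value) - model$mean
    gm <- (P %*% zeta)[psi]
    Sinv <- chol2inv(chol(u$S))
    GL <- (Ppp - Sinv) %*% u$L
    c(gm, diag(GL) * diag(u$L), GL[ltri])
  }
  if (is.null(init)) init <- list(mean = numeric(dpsi), cov = diag(dpsi))
  th0 <- pack(init$mean, init$cov)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  if (opt$convergence != 0)
    stop("variational optimization failed to converge (code ",
         opt$convergence, "): ", opt$message)
  u <- unpack(opt$par)
  list(mean = u$m, cov = u$S, free_energy = opt$value,
       convergence = opt$convergence, iterations = opt$counts[["function"]])
}

#' Sample the stationary density of a linear standard-form flow
#'
#' Integrates \eqn{dx = -(\Gamma + R) P x\, dt + \sqrt{2\Gamma}\, dW} with
#' Euler--Maruyama, discards a burn-in and thins heavily, returning
#' approximately independent draws whose histogram can be compared with the
#' Gaussian ergodic density \eqn{\exp(-x^T P x/2)}.
#'
#' @param P precision of the quadratic Gibbs energy.
#' @param Gamma,R diffusion and solenoidal matrices.
#' @param n_samples number of retained samples.
#' @param dt integration step.
#' @param thin steps between retained samples.
#' @param burn burn-in steps.
#' @return n_samples x d matrix of samples.
#' @export
ou_stationary_samples <- function(P, Gamma, R, n_samples = 20000,
                                  dt = 0.002, thin = 1500, burn = 5000) {
  drift <- -(as.matrix(Gamma) + as.matrix(R)) %*% as.matrix(P)
  M <- t(chol(2 * as.matrix(Gamma)))
  ou_sample_cpp(drift, M, dt, as.integer(n_samples), as.integer(thin),
                as.integer(burn))
}

#' Run the free-energy verification battery
#'
#' Constructive checks of the standard-form results on tractable systems:
#' flow vanishes at the mode; the Fokker--Planck residual of
#' \eqn{\exp(-G)} converges at second order under grid refinement (with and
#' without solenoidal flow) while a corrupted non-antisymmetric flow fails;
#' the variational optimum of a random linear-Gaussian model equals the
#' exact posterior, with free energy equal to negative log evidence; and
#' the long-run histogram of a simulated standard-form flow matches the
#' ergodic density.
#'
#' @param seed RNG seed.
#' @param n_models number of random Gaussian models for the lemma check.
#' @return a data.frame with one row per check (`check`, `value`, `pass`),
#'   of class `fep_report`.
#' @export
fep_check <- function(seed = 1, n_models = 100) {
  set.seed(seed)
  rows <- list()
  add <- function(check, value, pass)
    rows[[length(rows) + 1]] <<- data.frame(check = check, value = value,
                                            pass = pass)

  P2 <- matrix(c(1.5, 0.4, 0.4, 1.0), 2)
  R2 <- matrix(c(0, 0.7, -0.7, 0), 2)
  sys_plain <- quadratic_standard_form(P2, diag(2), matrix(0, 2, 2))
  sys_sol <- quadratic_standard_form(P2, diag(2), R2)
  add("flow at mode", max(abs(flow_from_standard_form(sys_sol, c(0, 0)))),
      max(abs(flow_from_standard_form(sys_sol, c(0, 0)))) < 1e-12)

  grids <- function(h) list(seq(-4, 4, by = h), seq(-4, 4, by = h))
  for (nm in c("gradient-only", "solenoidal")) {
    sys <- if (nm == "gradient-only") sys_plain else sys_sol
    r1 <- fokker_planck_residual(sys, grids(0.2))
    r2 <- fokker_planck_residual(sys, grids(0.1))
    order_est <- log2(r1 / r2)
    add(paste("Fokker-Planck convergence order,", nm), order_est,
        order_est > 1.5 && order_est < 2.5)
  }
  bad_flow <- function(x) drop(-(diag(2) + matrix(c(0, 0.7, 0.7, 0), 2)) %*%
                                 sys_plain$grad_G(x))
  r_bad <- fokker_planck_residual(sys_plain, grids(0.1), flow = bad_flow)
  add("corrupted-R residual (must not vanish)", r_bad, r_bad > 1e-3)

  worst_gap <- 0; worst_par <- 0
  for (i in seq_len(n_models)) {
    d <- 5
    A <- matrix(stats::rnorm(d * d), d)
    prec <- crossprod(A) + diag(d) * 0.5
    mu <- stats::rnorm(d)
    mod <- gaussian_model(prec, mu, list(psi = 1:2, s = 3, a = 4, lambda = 5))
    bs <- list(s = stats::rnorm(1), a = stats::rnorm(1))
    lam <- stats::rnorm(1)
    opt <- optimize_variational(mod, bs, lam)
    ref <- exact_posterior(mod, bs, lam)
    gap <- abs(opt$free_energy + log_evidence(mod, bs, lam))
    par_err <- max(abs(opt$mean - ref$mean), abs(opt$cov - ref$cov))
    worst_gap <- max(worst_gap, gap)
    worst_par <- max(worst_par, par_err)
  }
  add("max |F - (-log evidence)| at optimum", worst_gap, worst_gap < 1e-6)
  add("max |q* - exact posterior|", worst_par, worst_par < 1e-6)

  X <- ou_stationary_samples(P2, diag(2), R2)
  Sigma <- solve(P2)
  pvals <- vapply(1:2, function(k) {
    br <- stats::qnorm(seq(0, 1, length.out = 21), 0, sqrt(Sigma[k, k]))
    counts <- table(cut(X[, k], br))
    stats::chisq.test(as.numeric(counts))$p.value
  }, numeric(1))
  add("ergodic-density GOF p-value (min over axes)", min(pvals),
      min(pvals) > 0.01)

  out <- do.call(rbind, rows)
  class(out) <- c("fep_report", "data.frame")
  out
}

#' @export
print.fep_report <- function(x, ...) {
  cat("Free-energy verification battery\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-45s %.4g\n", if (x$pass[i]) "PASS" else "FAIL",
                x$check[i], x$value[i]))
  invisible(x)
}
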