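P2 <- matrix(c(1.5, 0.4, 0.4, 1.0), 2)
R2 <- matrix(c(0, 0.7, -0.7, 0), 2)

test_that("the standard-form constructor enforces its algebraic structure", {
  expect_error(quadratic_standard_form(P2, diag(2),
                                       matrix(c(0, 0.7, -0.7 + 1e-6, 0), 2)),
               "antisymmetric")
  expect_error(quadratic_standard_form(P2, matrix(c(1, 0.2, 0.1, 1), 2),
                                       matrix(0, 2, 2)), "symmetric")
  expect_error(quadratic_standard_form(P2, -diag(2), matrix(0, 2, 2)),
               "semi-definite")
})

test_that("the flow descends the Gibbs energy and circulates on isocontours", {
  sys <- quadratic_standard_form(P2, diag(2), R2)
  expect_equal(flow_from_standard_form(sys, c(0, 0)), c(0, 0))

  # gradient-only case with unit curvature: Ornstein-Uhlenbeck drift -Gamma x
  Gam <- matrix(c(2, 0.5, 0.5, 1), 2)
  ou <- quadratic_standard_form(diag(2), Gam, matrix(0, 2, 2))
  x <- c(0.3, -1.2)
  expect_equal(flow_from_standard_form(ou, x), drop(-Gam %*% x))

  # pure solenoidal flow is orthogonal to the gradient everywhere
  sol <- quadratic_standard_form(P2, matrix(0, 2, 2), R2)
  set.seed(16)
  for (i in 1:25) {
    x <- rnorm(2)
    f <- flow_from_standard_form(sol, x)
    expect_lt(abs(sum(f * sol$grad_G(x))), 1e-12)
  }
})

test_that("exp(-G) is Fokker-Planck stationary at second order", {
  grids <- function(h) list(seq(-4, 4, by = h), seq(-4, 4, by = h))
  for (R in list(matrix(0, 2, 2), R2)) {
    sys <- quadratic_standard_form(P2, diag(2), R)
    r1 <- fokker_planck_residual(sys, grids(0.2))
    r2 <- fokker_planck_residual(sys, grids(0.1))
    expect_gt(log2(r1 / r2), 1.5)
    expect_lt(log2(r1 / r2), 2.5)
  }
  # corrupted (non-antisymmetric) circulation leaves a finite residual
  sys <- quadratic_standard_form(P2, diag(2), matrix(0, 2, 2))
  bad <- function(x) drop(-(diag(2) + matrix(c(0, 0.7, 0.7, 0), 2)) %*%
                            sys$grad_G(x))
  expect_gt(fokker_planck_residual(sys, grids(0.1), flow = bad), 1e-3)
})

random_gaussian_model <- function(d = 5) {
  A <- matrix(rnorm(d * d), d)
  gaussian_model(crossprod(A) + 0.5 * diag(d), rnorm(d),
                 list(psi = 1:2, s = 3, a = 4, lambda = 5))
}

test_that("free energy equals negative log evidence exactly at the posterior", {
  set.seed(17)
  mod <- random_gaussian_model()
  bs <- list(s = rnorm(1), a = rnorm(1))
  lam <- rnorm(1)
  post <- exact_posterior(mod, bs, lam)
  F_post <- free_energy(mod, bs, post$mean, post$cov, lam)
  expect_equal(F_post, -log_evidence(mod, bs, lam), tolerance = 1e-10)

  # widening the covariance strictly increases free energy
  F_wide <- free_energy(mod, bs, post$mean, 1.5 * post$cov, lam)
  expect_gt(F_wide, F_post)
  expect_error(free_energy(mod, bs, post$mean, -post$cov, lam),
               "positive-definite")
})

test_that("the free-energy gap equals the Gaussian KL divergence", {
  gauss_kl <- function(m0, S0, m1, S1) {
    # KL( N(m0,S0) || N(m1,S1) )
    d <- length(m0)
    0.5 * (sum(diag(solve(S1, S0))) +
             drop(t(m1 - m0) %*% solve(S1, m1 - m0)) - d +
             determinant(S1)$modulus - determinant(S0)$modulus)
  }
  set.seed(18)
  worst <- 0
  for (i in 1:1000) {
    mod <- random_gaussian_model()
    bs <- list(s = rnorm(1), a = rnorm(1))
    lam <- rnorm(1)
    post <- exact_posterior(mod, bs, lam)
    m <- post$mean + rnorm(2, sd = 0.5)
    L <- matrix(c(exp(rnorm(1, sd = 0.3)), rnorm(1, sd = 0.2), 0,
                  exp(rnorm(1, sd = 0.3))), 2)
    S <- L %*% t(L)
    gap <- free_energy(mod, bs, m, S, lam) + log_evidence(mod, bs, lam)
    kl <- as.numeric(gauss_kl(m, S, post$mean, post$cov))
    expect_gte(gap, -1e-10)   # Gibbs inequality
    worst <- max(worst, abs(gap - kl))
  }
  expect_lt(worst, 1e-8)      # the gap is exactly the KL divergence
})

test_that("variational optimization converges to the exact posterior", {
  set.seed(19)
  for (i in 1:5) {
    mod <- random_gaussian_model()
    bs <- list(s = rnorm(1), a = rnorm(1))
    lam <- rnorm(1)
    opt <- optimize_variational(mod, bs, lam)
    post <- exact_posterior(mod, bs, lam)
    expect_lt(max(abs(opt$mean - post$mean)), 1e-6)
    expect_lt(max(abs(opt$cov - post$cov)), 1e-6)
    expect_equal(opt$free_energy, -log_evidence(mod, bs, lam),
                 tolerance = 1e-8)
  }
  # initialised at the posterior the optimizer has (almost) nothing to do
  mod <- random_gaussian_model()
  bs <- list(s = 0.3, a = -0.1)
  post <- exact_posterior(mod, bs, 0.2)
  opt <- optimize_variational(mod, bs, 0.2,
                              init = list(mean = post$mean, cov = post$cov))
  expect_equal(opt$free_energy, -log_evidence(mod, bs, 0.2),
               tolerance = 1e-10)
})

test_that("the simulated standard-form flow reproduces the ergodic density", {
  set.seed(20)
  X <- ou_stationary_samples(P2, diag(2), R2, n_samples = 20000,
                             dt = 0.002, thin = 1500, burn = 5000)
  Sigma <- solve(P2)
  expect_equal(unname(cov(X)), Sigma, tolerance = 0.1)
  for (k in 1:2) {
    br <- qnorm(seq(0, 1, length.out = 21), 0, sqrt(Sigma[k, k]))
    counts <- as.numeric(table(cut(X[, k], br)))
    expect_gt(chisq.test(counts)$p.value, 0.01)
  }
})
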