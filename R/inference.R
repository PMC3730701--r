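#' Temporal embedding of a multichannel series
#'
#' For each channel, builds columns at every integer lag from `-L` to `+L`
#' where `L = lag_seconds / sample_interval`, keeping only the rows for which
#' all lags are in range (no wraparound).  Row `t` of the output corresponds
#' to row `L + t` of the input.
#'
#' @param series T x c numeric matrix (one column per channel).
#' @param lag_seconds maximum lag in seconds (symmetric).
#' @param sample_interval spacing of the rows in seconds.
#' @return an object of class `embedded_series`: the `(T - 2L) x (c (2L+1))`
#'   matrix with attributes `lags`, `valid_rows` (indices into the original
#'   series) and `channel` (channel index of each column).
#' @export
temporal_embed <- function(series, lag_seconds, sample_interval = 1) {
  series <- as.matrix(series)
  T <- nrow(series); c <- ncol(series)
  L <- round(lag_seconds / sample_interval)
  if (T <= 2 * L)
    stop("series too short (", T, " rows) for embedding with ", 2 * L + 1,
         " lags")
  valid <- (L + 1):(T - L)
  lags <- -L:L
  out <- matrix(0, length(valid), c * length(lags))
  channel <- integer(c * length(lags))
  col <- 1
  for (ch in seq_len(c)) {
    for (l in lags) {
      out[, col] <- series[valid + l, ch]
      channel[col] <- ch
      col <- col + 1
    }
  }
  structure(out, lags = lags, valid_rows = valid, channel = channel,
            class = c("embedded_series", "matrix"))
}

#' Principal eigenvariates of an embedded series
#'
#' Left singular vectors scaled by their singular values — the principal
#' temporal patterns of the (column-centred) embedded series.  Sign is fixed
#' deterministically so that the largest-magnitude loading of each component
#' is positive.
#'
#' @param embedded matrix (typically an `embedded_series`).
#' @param n_components number of components to return.
#' @return T x n_components matrix of eigenvariates.
#' @export
eigenvariates <- function(embedded, n_components) {
  X <- scale(unclass(embedded), center = TRUE, scale = FALSE)
  if (n_components > min(dim(X)))
    stop("n_components (", n_components, ") exceeds the matrix rank bound ",
         min(dim(X)))
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
}

#' Canonical variates analysis with Bartlett's chi-squared statistic
#'
#' Canonical correlations between two multivariate series from the
#' generalized eigenproblem of the cross-covariance, Wilks'
#' \eqn{\Lambda = \prod_i (1 - r_i^2)}, and Bartlett's transformation
#' \eqn{\chi^2 = -(T - 1 - (p + q + 1)/2)\,\ln\Lambda} with \eqn{p q}
#' degrees of freedom.  Rank-deficient covariance blocks are
#' ridge-regularized with \eqn{\epsilon = 10^{-8}\,\mathrm{tr}(S)/\dim(S)}.
#'
#' @param X T x p matrix.
#' @param Y T x q matrix.
#' @return an object of class `cva_result` with `canonical_correlations`,
#'   `wilks_lambda`, `chi2`, `dof`, `p_value`, and the first canonical
#'   variate pair `predicted` (from X) and `actual` (from Y).
#' @export
cva <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  T <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != T) stop("X and Y must have the same number of rows")
  if (T <= p + q + 1)
    stop("too few rows (", T, ") for CVA with p + q = ", p + q)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (T - 1)
  Syy <- crossprod(Yc) / (T - 1)
  Sxy <- crossprod(Xc, Yc) / (T - 1)
  ridge <- function(S) S + diag(1e-8 * sum(diag(S)) / nrow(S), nrow(S))
  Rx <- chol(ridge(Sxx))
  Ry <- chol(ridge(Syy))
  # whitened cross-covariance Rx^-T Sxy Ry^-1; its singular values are the
  # canonical correlations
  W <- backsolve(Rx, Sxy, transpose = TRUE)
  M <- t(backsolve(Ry, t(W), transpose = TRUE))
  sv <- svd(M)
  r <- pmin(pmax(sv$d, 0), 1 - 1e-12)
  wilks <- prod(1 - r^2)
  chi2 <- max(0, -(T - 1 - (p + q + 1) / 2) * log(wilks))
  dof <- p * q
  a <- backsolve(Rx, sv$u[, 1])
  b <- backsolve(Ry, sv$v[, 1])
  out <- list(canonical_correlations = r, wilks_lambda = wilks,
              chi2 = chi2, dof = dof,
              p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
              predicted = drop(Xc %*% a) * r[1], actual = drop(Yc %*% b))
  class(out) <- "cva_result"
  out
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf(
    "CVA: Wilks' lambda = %.4g, chi2(%d) = %.2f, p = %.3g\n",
    x$wilks_lambda, x$dof, x$chi2, x$p_value))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$canonical_correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Time-reversal surrogate
#'
#' Reverses the rows of a series.  Destroys any statistical coupling with a
#' second (unreversed) series while preserving the within-series correlation
#' structure — the null used by [predictability_map()].
#'
#' @param Y T x q matrix.
#' @return Y with rows in reverse order.
#' @export
time_flip_null <- function(Y) {
  Y <- as.matrix(Y)
  Y[rev(seq_len(nrow(Y))), , drop = FALSE]
}

#' Exceedance p-value under the max-null scheme
#'
#' The largest statistic of the null analysis protects against false
#' positives at a per-test level of `1/n_tests`.  The probability of seeing
#' strictly more than `count` exceedances by chance is the upper binomial
#' tail \eqn{P(\mathrm{Bin}(n, 1/n) > \mathrm{count})}.
#'
#' @param count observed number of true statistics above the null maximum.
#' @param n_tests number of tests (external subsystems).
#' @return the exceedance probability.
#' @examples
#' exceedance_pvalue(5, 82)  # 0.00052
#' @export
exceedance_pvalue <- function(count, n_tests) {
  stopifnot(count >= 0, count <= n_tests, n_tests >= 1)
  stats::pbinom(count, n_tests, 1 / n_tests, lower.tail = FALSE)
}

#' Predictability of external motion from internal dynamics
#'
#' The test for self-organized perception: summarises the internal
#' electrochemical dynamics over the trailing `analysis_window` seconds by
#' the first `n_components` eigenvariates of the temporally embedded series
#' (lags of plus/minus `lag_seconds`), then asks — for each external
#' subsystem — whether a linear mixture of those eigenvariates predicts its
#' motion (position in `d` dimensions), using [cva()].  The identical
#' analysis on time-reversed external series provides the null; the number
#' of true statistics above the null maximum yields the exceedance p-value.
#'
#' @param traj a `soup_trajectory`.
#' @param partition a `blanket_partition` for the trajectory.
#' @param analysis_window trailing window in seconds.
#' @param lag_seconds embedding half-width in seconds.
#' @param n_components number of eigenvariates.
#' @return an object of class `predictability_map` with `chi2_true`,
#'   `chi2_null` (per external subsystem), `threshold` (max of the null),
#'   `n_exceed`, `p_value`, the index `best` of the best-predicted
#'   subsystem and its CVA (`best_cva`), plus decision metadata.
#' @export
predictability_map <- function(traj, partition, analysis_window = 512,
                               lag_seconds = 16, n_components = 32) {
  t_end <- traj$times[length(traj$times)]
  span <- t_end - traj$times[1]
  if (analysis_window > span + 1e-9)
    stop("analysis_window (", analysis_window,
         " s) exceeds the trajectory span (", span, " s)")
  frames <- which(traj$times >= t_end - analysis_window - 1e-9)
  labels <- as.character(partition$labels)
  internal <- which(labels == "internal")
  external <- which(labels == "external")
  if (length(external) < 1) stop("partition has no external subsystems")
  n <- dim(traj$positions)[2]
  d <- dim(traj$positions)[3]
  # internal functional states: chem channels of the internal subsystems
  chem_int <- do.call(cbind, lapply(1:3, function(c)
    matrix(traj$chem[frames, internal, c], nrow = length(frames))))
  emb <- temporal_embed(chem_int, lag_seconds, traj$config$save_interval)
  X <- eigenvariates(emb, n_components)
  valid <- attr(emb, "valid_rows")
  chi2_true <- chi2_null <- numeric(length(external))
  best_cva <- NULL
  for (ei in seq_along(external)) {
    e <- external[ei]
    Y <- matrix(traj$positions[frames, e, ], ncol = d)[valid, , drop = FALSE]
    fit <- cva(X, Y)
    chi2_true[ei] <- fit$chi2
    chi2_null[ei] <- cva(X, time_flip_null(Y))$chi2
    if (ei == which.max(chi2_true[seq_len(ei)])) best_cva <- fit
  }
  threshold <- max(chi2_null)
  n_exceed <- sum(chi2_true > threshold)
  out <- list(chi2_true = chi2_true, chi2_null = chi2_null,
              threshold = threshold, n_exceed = n_exceed,
              p_value = exceedance_pvalue(n_exceed, length(external)),
              external = external, best = external[which.max(chi2_true)],
              best_cva = best_cva,
              decisions = list(
                embedding = sprintf("lags of +/- %g s on the %g s frame grid",
                                    lag_seconds, traj$config$save_interval),
                n_components = n_components,
                response = "position, no detrending",
                chi2 = "Bartlett transformation of Wilks' lambda",
                null = "time-reversal of the external series"))
  class(out) <- "predictability_map"
  out
}

#' @export
print.predictability_map <- function(x, ...) {
  cat(sprintf(
    "Predictability map over %d external subsystems\n", length(x$chi2_true)))
  cat(sprintf("  null threshold (max) chi2 = %.2f; %d true value(s) exceed it\n",
              x$threshold, x$n_exceed))
  cat(sprintf("  exceedance p-value = %.3g\n", x$p_value))
  cat(sprintf("  best-predicted subsystem: #%d (chi2 = %.2f)\n", x$best,
              max(x$chi2_true)))
  invisible(x)
}
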