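#' Windowed adjacency matrix
#'
#' Element-wise OR of the contact adjacency over all saved frames in the
#' trailing `window` seconds of a trajectory: two subsystems are coupled if
#' they were within the coupling radius on at least one occasion during the
#' window.  This accommodates the fact that the contact graph is itself a
#' stochastic process.
#'
#' @param traj a `soup_trajectory`.
#' @param window trailing window in seconds (must not exceed the trajectory).
#' @return binary n x n adjacency matrix (closed columns zeroed).
#' @export
window_adjacency <- function(traj, window) {
  t_end <- traj$times[length(traj$times)]
  span <- t_end - traj$times[1]
  if (window > span + 1e-9)
    stop("window (", window, " s) exceeds the trajectory span (", span, " s)")
  frames <- which(traj$times >= t_end - window - 1e-9)
  n <- dim(traj$positions)[2]
  A <- matrix(0, n, n)
  for (f in frames) {
    pos <- matrix(traj$positions[f, , ], n)
    A <- pmax(A, contact_neighbors(pos, traj$config$coupling_radius,
                                   traj$closed_mask))
  }
  A
}

#' Markov blanket matrix
#'
#' \eqn{B = A + A^T + A^T A}: with columns of `A` encoding directed influence
#' from each state to its children, the support of row \eqn{i} of `B` is
#' exactly the Markov blanket of node \eqn{i} — its parents (\eqn{A}),
#' children (\eqn{A^T}) and parents of its children (\eqn{A^T A}).
#'
#' @param A binary n x n adjacency matrix with zero diagonal.
#' @return non-negative n x n matrix (symmetric).
#' @export
blanket_matrix <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(diag(A) != 0)) stop("adjacency matrix must have zero diagonal")
  A + t(A) + crossprod(A)
}

#' Spectral partition into internal, sensory, active and external states
#'
#' Computes the principal eigenvector of the Markov blanket matrix `B`
#' (non-negative by Perron--Frobenius; its entries measure membership of the
#' most interconnected cluster).  The `k` subsystems with the largest entries
#' are the internal states; their Markov blanket is recovered as the support
#' of \eqn{B \chi} minus the internal set and split into sensory states
#' (those with an incoming edge from some external subsystem) and active
#' states (the rest).  Everything else is external (hidden).
#'
#' @param A binary n x n adjacency matrix (typically from
#'   [window_adjacency()]).
#' @param k number of internal states.
#' @return an object of class `blanket_partition` with `labels` (factor over
#'   external/sensory/active/internal), `chi`, `A_window`, `B`,
#'   `eigenvector`, `eigenvalue` and `k`.
#' @export
principal_partition <- function(A, k) {
  n <- nrow(A)
  if (k >= n) stop("k (", k, ") must be smaller than the number of subsystems (",
                   n, ")")
  B <- blanket_matrix(A)
  if (all(B == 0))
    stop("degenerate adjacency: B is identically zero, no principal cluster")
  eig <- eigen(B, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (sum(v) < 0) v <- -v  # Perron sign convention: non-negative on support
  if (n >= 2 && abs(eig$values[1] - eig$values[2]) < 1e-10)
    warning("principal eigenvalue nearly degenerate (disconnected blanket ",
            "matrix?); using the component with the largest eigenvalue")
  ord <- order(-v, seq_len(n))  # ties broken by lowest index
  internal <- sort(ord[seq_len(k)])
  if (k < n && v[ord[k]] - v[ord[k + 1]] < 1e-12)
    message("tie at rank k broken by lowest index")
  chi <- as.numeric(seq_len(n) %in% internal)
  bchi <- as.numeric(B %*% chi)
  blanket <- setdiff(which(bchi > 0), internal)
  external <- setdiff(seq_len(n), c(internal, blanket))
  sensory <- blanket[vapply(blanket, function(b)
    any(A[b, external] == 1), logical(1))]
  active <- setdiff(blanket, sensory)
  labels <- rep("external", n)
  labels[internal] <- "internal"
  labels[sensory] <- "sensory"
  labels[active] <- "active"
  out <- list(labels = factor(labels,
                              levels = c("external", "sensory", "active",
                                         "internal")),
              chi = chi, A_window = A, B = B, eigenvector = v,
              eigenvalue = eig$values[1], k = k)
  class(out) <- "blanket_partition"
  out
}

#' Verify the conditional-independence structure of a partition
#'
#' A valid Markov blanket admits no direct edges between internal and
#' external subsystems in either direction.  Returns every violating edge
#' and the counts of each label.
#'
#' @param A binary n x n adjacency matrix.
#' @param partition a `blanket_partition`.
#' @return a list with `violations` (two-column matrix of offending edges,
#'   zero rows when valid), `counts` (table of labels) and `valid`.
#' @export
verify_blanket <- function(A, partition) {
  labels <- as.character(partition$labels)
  internal <- which(labels == "internal")
  external <- which(labels == "external")
  viol <- which(A[internal, external, drop = FALSE] != 0 |
                t(A[external, internal, drop = FALSE]) != 0, arr.ind = TRUE)
  violations <- cbind(internal = internal[viol[, 1]],
                      external = external[viol[, 2]])
  list(violations = violations,
       counts = table(partition$labels),
       valid = nrow(violations) == 0)
}

#' @export
print.blanket_partition <- function(x, ...) {
  cat("Markov blanket partition (principal cluster, spectral)\n")
  print(table(x$labels))
  cat(sprintf("  principal eigenvalue %.3f, k = %d internal states\n",
              x$eigenvalue, x$k))
  invisible(x)
}

#' Compute the principal Markov blanket of a trajectory
#'
#' Convenience wrapper: windowed adjacency over the trailing `window`
#' seconds, then the spectral partition with `k` internal states.
#'
#' @param traj a `soup_trajectory`.
#' @param window trailing window in seconds.
#' @param k number of internal states.
#' @return a `blanket_partition`.
#' @export
markov_blanket <- function(traj, window = 256, k = 8) {
  principal_partition(window_adjacency(traj, window), k)
}
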