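# Time-lagged independent component analysis.
#
# Solves the generalized symmetric eigenproblem C_tau v = lambda C0 v on the
# symmetrized lagged covariance, with rank-deficient C0 handled by projecting
# onto its dominant eigenspace before the whitened solve.

#' Fit a TICA model
#'
#' Pools, over all trajectories, the instantaneous covariance `C0` and the
#' symmetrized time-lagged covariance `C_tau` of the mean-free features,
#' using every sliding-window pair `(x_t, x_{t+lag})`. The mean and `C0` are
#' estimated symmetrically from both window halves, so reversing every
#' trajectory in time leaves the model unchanged. Components are sorted by
#' decreasing eigenvalue (autocorrelation at the lag) and normalized to unit
#' `C0`-norm.
#'
#' @param tracks list of numeric matrices (frames x features), or a single
#'   matrix.
#' @param lag lag in frames (>= 1); every track must be longer than `lag`.
#' @param n_components number of components to keep (default 5).
#' @param epsilon relative eigenvalue cutoff for the rank of `C0`
#'   (default 1e-8).
#' @return a `tica_model` with `mean`, `c0`, `ctau`, `lag`, `eigenvalues`
#'   and `components` (columns).
#' @export
fit_tica <- function(tracks, lag, n_components = 5, epsilon = 1e-8) {
  if (is.matrix(tracks)) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1, lag >= 1)
  d <- ncol(tracks[[1]])
  if (any(vapply(tracks, nrow, 1L) <= lag)) {
    stop("every track must be longer than the lag (", lag, " frames)")
  }
  # pass 1: symmetric mean over both window halves
  s <- numeric(d)
  n_pairs <- 0
  for (X in tracks) {
    Tn <- nrow(X)
    i0 <- seq_len(Tn - lag)
    s <- s + colSums(X[i0, , drop = FALSE]) + colSums(X[i0 + lag, , drop = FALSE])
    n_pairs <- n_pairs + length(i0)
  }
  mu <- s / (2 * n_pairs)
  # pass 2: pooled covariances
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  for (X in tracks) {
    Tn <- nrow(X)
    i0 <- seq_len(Tn - lag)
    A <- sweep(X[i0, , drop = FALSE], 2, mu)
    B <- sweep(X[i0 + lag, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- (Ct + t(Ct)) / (2 * n_pairs)
  if (all(diag(C0) < 1e-14)) stop("all features are constant")
  # whiten on C0's dominant eigenspace
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- epsilon * max(e0$values)
  keep <- which(e0$values > tol)
  if (length(keep) < 1) stop("covariance has no usable rank")
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), length(keep))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lambda <- em$values[ord]
  V <- W %*% em$vectors[, ord, drop = FALSE]   # unit C0-norm by construction
  k <- min(n_components, ncol(V))
  structure(
    list(mean = mu, c0 = C0, ctau = Ct, lag = lag,
         eigenvalues = lambda, components = V[, seq_len(k), drop = FALSE],
         n_components = k),
    class = "tica_model"
  )
}

#' Project features onto TICA components
#'
#' @param model a `tica_model`.
#' @param x frames x features matrix (feature dimension must match the
#'   model).
#' @return frames x n_components matrix.
#' @export
tica_transform <- function(model, x) {
  stopifnot(inherits(model, "tica_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop("feature dimension mismatch: model has ", length(model$mean),
         ", data has ", ncol(x))
  }
  sweep(x, 2, model$mean) %*% model$components
}

#' @export
print.tica_model <- function(x, ...) {
  cat("TICA model: lag", x$lag, "frames,", x$n_components, "components\n")
  cat("leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 5), digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}
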