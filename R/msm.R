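# Reversible Markov state model estimation: sliding-window counts, ergodic
# trimming, detailed-balance maximum likelihood, spectrum and implied
# timescales.

#' Sliding-window transition count matrix
#'
#' Counts every pair `(s_t, s_{t+lag})` over all valid `t` in every
#' trajectory.
#'
#' @param dtrajs list of integer label vectors (1-based), or one vector.
#' @param lag lag in frames (>= 1).
#' @param n_states number of states (defaults to the largest label seen).
#' @return dense `n_states x n_states` count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  if (all(vapply(dtrajs, length, 1L) <= lag)) {
    stop("lag (", lag, ") is not shorter than any trajectory")
  }
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, 1L))
  keep <- dtrajs[vapply(dtrajs, length, 1L) > lag]
  ii <- unlist(lapply(keep, function(s) s[seq_len(length(s) - lag)]),
               use.names = FALSE)
  jj <- unlist(lapply(keep, function(s) s[seq_len(length(s) - lag) + lag]),
               use.names = FALSE)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n_states, n_states))
  as.matrix(C)
}

#' Largest ergodic (strongly connected) component
#'
#' @param counts square count matrix.
#' @return list with `active` (state indices of the largest strongly
#'   connected component of the directed count graph) and `counts`
#'   restricted to it.
#' @export
trim_ergodic <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("count matrix is empty")
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # among largest components prefer the one with the most counts
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    mass <- vapply(big, function(b) {
      idx <- which(comp$membership == b)
      sum(counts[idx, idx])
    }, numeric(1))
    big <- big[which.max(mass)]
  }
  active <- which(comp$membership == big)
  list(active = active, counts = counts[active, active, drop = FALSE])
}

#' Maximum-likelihood reversible transition matrix
#'
#' Fixed-point iteration on the symmetrized flow matrix
#' `x_ij = (c_ij + c_ji) / (c_i/x_i + c_j/x_j)` until the maximum relative
#' change falls below `tol`. The stationary distribution is read off the
#' row sums of `x`; the spectrum is computed from the
#' similarity-symmetrized transition matrix, so eigenvalues are real.
#'
#' @param counts irreducible count matrix (run [trim_ergodic()] first).
#' @param lag lag (frames) at which the counts were taken.
#' @param frame_interval physical time per frame (default 1).
#' @param active_set optional state indices the counts refer to.
#' @param tol convergence tolerance on the relative change (default 1e-10).
#' @param max_iter iteration cap (default 1e5).
#' @return a `markov_model` with the transition matrix, stationary
#'   distribution, eigenvalues and implied timescales.
#' @export
estimate_reversible <- function(counts, lag = 1, frame_interval = 1,
                                active_set = NULL, tol = 1e-10,
                                max_iter = 1e5) {
  C <- as.matrix(counts)
  n <- nrow(C)
  if (is.null(active_set)) active_set <- seq_len(n)
  c_i <- rowSums(C)
  if (any(c_i == 0)) stop("counts are not irreducible: empty row present")
  Csym <- C + t(C)
  X <- Csym / sum(C)                      # symmetric start
  x_i <- rowSums(X)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- outer(c_i / x_i, c_i / x_i, "+")
    Xn <- Csym / denom
    Xn <- Xn * (Csym > 0)
    xn_i <- rowSums(Xn)
    delta <- max(abs(xn_i - x_i) / pmax(xn_i, 1e-300))
    X <- Xn
    x_i <- xn_i
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("reversible estimator did not converge after ", max_iter,
         " iterations (last relative change ", format(delta), ")")
  }
  T_mat <- X / x_i
  pi <- x_i / sum(x_i)
  sp <- msm_spectrum(T_mat, pi)
  its <- implied_from_eigen(sp$values, lag * frame_interval)
  structure(
    list(counts = C, active_set = active_set, transition_matrix = T_mat,
         stationary_distribution = pi, eigenvalues = sp$values,
         right_eigenvectors = sp$right, lag = lag,
         frame_interval = frame_interval, implied_timescales = its,
         iterations = it),
    class = "markov_model"
  )
}

# real spectrum of a reversible T via the pi-symmetrized similar matrix
msm_spectrum <- function(T_mat, pi) {
  s <- sqrt(pi)
  S <- diag(s) %*% T_mat %*% diag(1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  right <- (1 / s) * e$vectors[, ord, drop = FALSE]
  # normalize: first right eigenvector is the constant vector
  right <- sweep(right, 2, right[1, ], "/")
  list(values = vals, right = right)
}

implied_from_eigen <- function(values, lag_time) {
  lam <- values[-1]
  its <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  its[ok] <- -lag_time / log(lam[ok])
  its
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Reversible Markov model:", nrow(x$transition_matrix), "states, lag",
      x$lag, "frames\n")
  cat("slowest implied timescales:",
      paste(format(utils::head(x$implied_timescales, 4), digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Implied timescales across lags
#'
#' Estimates a reversible model at each lag and tabulates
#' `t_i = -lag / log(lambda_i)` for the top `n_timescales` non-trivial
#' eigenvalues. Lags that fail to estimate are skipped with a warning.
#' Non-positive eigenvalues yield `NA` timescales.
#'
#' @param dtrajs list of integer label vectors.
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many timescales to report (default 4).
#' @param frame_interval physical time per frame.
#' @return data.frame with columns `lag`, `timescale_index`, `timescale`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 4,
                               frame_interval = 1) {
  rows <- list()
  for (lag in lags) {
    res <- tryCatch({
      C <- count_matrix(dtrajs, lag)
      tr <- trim_ergodic(C)
      m <- estimate_reversible(tr$counts, lag = lag,
                               frame_interval = frame_interval,
                               active_set = tr$active)
      utils::head(m$implied_timescales, n_timescales)
    }, error = function(e) {
      warning("lag ", lag, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- data.frame(
      lag = lag, timescale_index = seq_along(res) + 1L, timescale = res)
  }
  do.call(rbind, rows)
}

#' Markov model from a known transition matrix
#'
#' Wraps a given row-stochastic matrix as a `markov_model` (stationary
#' distribution from the leading left eigenvector), bypassing estimation.
#' Useful for computing passage times of exactly specified chains.
#'
#' @param T_mat row-stochastic matrix.
#' @param lag lag in frames; `frame_interval` physical time per frame.
#' @return a `markov_model` (without counts).
#' @export
markov_model_from_transition <- function(T_mat, lag = 1,
                                         frame_interval = 1) {
  T_mat <- as.matrix(T_mat)
  stopifnot(nrow(T_mat) == ncol(T_mat), all(T_mat >= 0),
            max(abs(rowSums(T_mat) - 1)) < 1e-10)
  e <- eigen(t(T_mat))
  i1 <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i1])
  pi <- pi / sum(pi)
  vals <- eigen(T_mat, only.values = TRUE)$values
  vals <- sort(Re(vals[abs(Im(vals)) < 1e-12]), decreasing = TRUE)
  structure(
    list(counts = NULL, active_set = seq_len(nrow(T_mat)),
         transition_matrix = T_mat, stationary_distribution = pi,
         eigenvalues = vals, right_eigenvectors = NULL, lag = lag,
         frame_interval = frame_interval,
         implied_timescales = implied_from_eigen(vals, lag * frame_interval),
         iterations = 0L),
    class = "markov_model"
  )
}

#' Adaptive-sampling respawn selection
#'
#' Chooses starting microstates for a new simulation epoch, favouring
#' poorly sampled clusters: cluster `i` is drawn with probability
#' proportional to `1 / (1 + count_i)` (uniform when all counts are zero,
#' by the same formula).
#'
#' @param counts non-negative per-cluster visit counts.
#' @param n_new number of respawn states to draw (with replacement).
#' @param seed integer seed.
#' @return integer vector of cluster indices, length `n_new`.
#' @export
select_respawn_states <- function(counts, n_new, seed = 1L) {
  stopifnot(all(counts >= 0), n_new >= 1)
  w <- 1 / (1 + counts)
  set.seed(as.integer(seed))
  sample.int(length(counts), n_new, replace = TRUE, prob = w)
}
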