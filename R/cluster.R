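# Mini-batch k-means discretization of the TICA space.

#' Mini-batch k-means clustering of projected coordinates
#'
#' Scalable k-means in the style of Sculley (2010): centers are seeded by
#' k-means++ on a subsample, updated over mini-batches with per-center
#' learning rates `1/n_assigned`, then polished by a few full-data Lloyd
#' passes (empty clusters are re-seeded from the farthest points). All
#' frames are finally assigned to their nearest center. Deterministic
#' under a fixed seed.
#'
#' @param coords list of frames x d matrices (or one matrix).
#' @param k number of clusters (default 800).
#' @param seed integer seed.
#' @param batch_size mini-batch size (default 1000).
#' @param n_iter number of mini-batch updates (default 200).
#' @param refine_iter full-data Lloyd refinement passes (default 5).
#' @return list with `centers` (k x d), `dtrajs` (list of integer label
#'   vectors, 1-based) and `k`; class `cluster_model`.
#' @export
cluster_microstates <- function(coords, k = 800, seed = 1L,
                                batch_size = 1000L, n_iter = 200L,
                                refine_iter = 5L) {
  if (is.matrix(coords)) coords <- list(coords)
  X <- do.call(rbind, coords)
  n <- nrow(X)
  if (k > n) stop("k (", k, ") exceeds the number of frames (", n, ")")
  set.seed(as.integer(seed))
  centers <- kmeanspp_init(X, k)
  counts <- numeric(k)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, min(batch_size, n))
    B <- X[idx, , drop = FALSE]
    a <- nearest_center(B, centers)
    for (c_id in unique(a)) {
      rows <- which(a == c_id)
      for (r in rows) {
        counts[c_id] <- counts[c_id] + 1
        eta <- 1 / counts[c_id]
        centers[c_id, ] <- (1 - eta) * centers[c_id, ] + eta * B[r, ]
      }
    }
  }
  # Lloyd polish over the full data
  for (it in seq_len(refine_iter)) {
    lab <- nearest_center(X, centers)
    sums <- rowsum(X, lab)
    sizes <- tabulate(lab, k)
    present <- as.integer(rownames(sums))
    centers[present, ] <- sums / sizes[present]
    if (length(present) < k) {
      # re-seed empty clusters from points farthest from their center
      empty <- setdiff(seq_len(k), present)
      d2 <- rowSums((X - centers[lab, , drop = FALSE])^2)
      far <- order(d2, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- X[far, , drop = FALSE]
    }
  }
  labels <- nearest_center(X, centers)
  lens <- vapply(coords, nrow, 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  dtrajs <- Map(function(s, e) labels[s:e], starts, ends)
  structure(list(centers = centers, dtrajs = dtrajs, k = k,
                 seed = as.integer(seed)),
            class = "cluster_model")
}

# k-means++ seeding on a subsample: greedy D^2-weighted center choice
kmeanspp_init <- function(X, k, subsample = 100000L) {
  n <- nrow(X)
  S <- if (n > subsample) X[sample.int(n, subsample), , drop = FALSE] else X
  m <- nrow(S)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- S[sample.int(m, 1), ]
  d2 <- rowSums(sweep(S, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      pick <- sample.int(m, 1)
    } else {
      pick <- sample.int(m, 1, prob = d2)
    }
    centers[j, ] <- S[pick, ]
    d2 <- pmin(d2, rowSums(sweep(S, 2, centers[j, ])^2))
  }
  centers
}

# chunked nearest-center assignment (squared Euclidean)
nearest_center <- function(X, centers, chunk = NULL) {
  n <- nrow(X)
  if (is.null(chunk)) chunk <- max(1000L, as.integer(5e6 / nrow(centers)))
  out <- integer(n)
  cc <- rowSums(centers^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    G <- X[s:e, , drop = FALSE] %*% t(centers)
    D <- sweep(-2 * G, 2, cc, "+")
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' Assign new coordinates to existing cluster centers
#'
#' @param model a `cluster_model`.
#' @param coords frames x d matrix.
#' @return integer vector of 1-based cluster labels.
#' @export
assign_clusters <- function(model, coords) {
  stopifnot(inherits(model, "cluster_model"))
  nearest_center(as.matrix(coords), model$centers)
}
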