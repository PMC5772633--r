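# Metastable lumping: PCCA+-style spectral clustering of microstates,
# splitting out a bulk macrostate by the interaction flag, and core-set
# milestoning.

#' Lump microstates into metastable macrostates (PCCA+)
#'
#' Spectral coordinates are the top `n_macro` right eigenvectors of the
#' reversible transition matrix (the first being the constant vector).
#' Simplex vertices are seeded by the furthest-point rule (the inner simplex
#' algorithm); fuzzy memberships follow from the linear transform mapping
#' vertex rows to the unit simplex, clipped to `[0, 1]` and row-normalized.
#' Crisp labels are the argmax memberships.
#'
#' @param model a `markov_model`.
#' @param n_macro number of macrostates (default 4).
#' @return a `macrostate_map`: `labels` (per microstate), `membership`
#'   (microstates x macrostates, rows sum to 1), `n_macro`, `bulk_id`
#'   (`NA` until [split_bulk()]), and the model's `active_set`.
#' @export
pcca_lump <- function(model, n_macro = 4) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$transition_matrix)
  if (n_macro > n) stop("n_macro (", n_macro, ") exceeds ", n, " states")
  if (n_macro == n) {
    membership <- diag(n)
    labels <- seq_len(n)
  } else {
    Psi <- model$right_eigenvectors[, seq_len(n_macro), drop = FALSE]
    verts <- inner_simplex_vertices(Psi, n_macro)
    A <- solve(Psi[verts, , drop = FALSE])
    chi <- Psi %*% A
    chi[chi < 0] <- 0
    chi[chi > 1] <- 1
    rs <- rowSums(chi)
    rs[rs == 0] <- 1
    membership <- chi / rs
    labels <- max.col(membership, ties.method = "first")
  }
  structure(
    list(labels = labels, membership = membership, n_macro = n_macro,
         bulk_id = NA_integer_, active_set = model$active_set),
    class = "macrostate_map"
  )
}

# furthest-point seeding of simplex vertices in spectral coordinates
inner_simplex_vertices <- function(Psi, k) {
  n <- nrow(Psi)
  verts <- integer(k)
  verts[1] <- which.max(rowSums(Psi^2))
  Q <- Psi
  for (j in 2:k) {
    v <- Q[verts[j - 1], ]
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      Q <- Q - (Q %*% (v / nv)) %*% t(v / nv)
    }
    d <- rowSums(Q^2)
    d[verts[seq_len(j - 1)]] <- -Inf
    verts[j] <- which.max(d)
  }
  verts
}

#' Split a bulk macrostate out by the interaction flag
#'
#' Microstates whose frames are in the majority flagged 0 (ligand in bulk
#' solvent) are reassigned to a new bulk macrostate; ties at exactly 50
#' percent go to bulk. Run after [pcca_lump()], at cluster granularity.
#'
#' @param map a `macrostate_map`.
#' @param dtrajs the microstate trajectories (labels in the *original*
#'   cluster numbering).
#' @param flags list of 0/1 vectors aligned frame-wise with `dtrajs`
#'   (1 = interacting, 0 = bulk).
#' @return the map with `n_macro + 1` states and `bulk_id` set; unchanged
#'   (with a warning) if no frame is flagged bulk.
#' @export
split_bulk <- function(map, dtrajs, flags) {
  stopifnot(inherits(map, "macrostate_map"))
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (!is.list(flags)) flags <- list(flags)
  stopifnot(length(dtrajs) == length(flags))
  all_s <- unlist(dtrajs, use.names = FALSE)
  all_f <- unlist(flags, use.names = FALSE)
  stopifnot(length(all_s) == length(all_f))
  if (all(all_f == 1)) {
    warning("no bulk-flagged frames; map unchanged")
    return(map)
  }
  n_micro <- length(map$labels)
  # fraction of flag=0 frames per active microstate
  idx <- match(all_s, map$active_set)
  ok <- !is.na(idx)
  tot <- tabulate(idx[ok], n_micro)
  bulk0 <- tabulate(idx[ok & all_f == 0], n_micro)
  frac0 <- ifelse(tot > 0, bulk0 / tot, 0)
  bulk_id <- map$n_macro + 1L
  to_bulk <- frac0 >= 0.5 & tot > 0
  labels <- map$labels
  labels[to_bulk] <- bulk_id
  membership <- cbind(map$membership, 0)
  membership[to_bulk, ] <- 0
  membership[to_bulk, bulk_id] <- 1
  map$labels <- labels
  map$membership <- membership
  map$n_macro <- bulk_id
  map$bulk_id <- bulk_id
  map
}

#' Core-set milestoning of microstate trajectories
#'
#' Cores are the microstates whose macrostate membership is at least
#' `threshold`; a macrostate whose core would be empty falls back to its
#' maximum-membership microstate (with a warning). Frames are relabeled to
#' the last visited core microstate; frames before the first core visit are
#' dropped. Re-estimating the model on the returned trajectories counts
#' only transitions between cores, which removes spurious recrossings at
#' cluster borders.
#'
#' @param map a `macrostate_map`.
#' @param dtrajs microstate trajectories (original cluster numbering).
#' @param threshold membership threshold for core states (default 0.9).
#' @return list with `dtrajs` (milestoned, core labels only), `cores`
#'   (list of microstate index vectors per macrostate, in active-set
#'   numbering) and `core_states` (the union, original numbering).
#' @export
core_assign <- function(map, dtrajs, threshold = 0.9) {
  stopifnot(inherits(map, "macrostate_map"))
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  cores <- vector("list", map$n_macro)
  for (m in seq_len(map$n_macro)) {
    members <- which(map$labels == m)
    core <- members[map$membership[members, m] >= threshold]
    if (!length(core) && length(members)) {
      core <- members[which.max(map$membership[members, m])]
      warning("macrostate ", m, " has no microstate above threshold ",
              threshold, "; using its maximum-membership microstate")
    }
    cores[[m]] <- core
  }
  core_micro <- sort(unlist(cores))
  core_orig <- map$active_set[core_micro]
  out <- lapply(dtrajs, function(s) {
    is_core <- s %in% core_orig
    if (!any(is_core)) return(integer(0))
    lab <- s
    lab[!is_core] <- NA_integer_
    first <- which(is_core)[1]
    lab <- lab[first:length(lab)]
    filled <- lab
    last <- lab[1]
    for (t in seq_along(lab)) {
      if (is.na(filled[t])) filled[t] <- last else last <- filled[t]
    }
    filled
  })
  list(dtrajs = out, cores = cores, core_states = core_orig)
}

#' Map microstate trajectories to macrostate trajectories
#'
#' @param map a `macrostate_map`.
#' @param dtrajs microstate trajectories (original cluster numbering);
#'   states outside the active set become `NA`.
#' @return list of integer macrostate sequences.
#' @export
macrostate_trajectories <- function(map, dtrajs) {
  stopifnot(inherits(map, "macrostate_map"))
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lapply(dtrajs, function(s) {
    idx <- match(s, map$active_set)
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(idx)
    out[ok] <- map$labels[idx[ok]]
    out
  })
}
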