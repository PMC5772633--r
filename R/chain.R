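# Ground-truth discrete Markov chains for the binding testbed.

#' Construct a ground-truth Markov chain
#'
#' Bundles a row-stochastic transition matrix with state labels and the
#' physical time per lag step. Used as the generating process for synthetic
#' discrete trajectories and as the analytic reference when validating the
#' estimation pipeline.
#'
#' @param transition_matrix square numeric matrix; rows must sum to 1 and all
#'   entries must be non-negative.
#' @param state_labels character vector naming the states (defaults to
#'   `S1..Sn`).
#' @param lag_time physical time per step, in microseconds.
#' @return an object of class `gt_chain` with elements `transition_matrix`,
#'   `state_labels`, `lag_time` and `n_states`.
#' @export
ground_truth_chain <- function(transition_matrix,
                               state_labels = NULL,
                               lag_time = 1) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) {
    stop("transition_matrix must be square")
  }
  if (any(P < 0)) {
    stop("transition_matrix entries must be non-negative")
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("transition_matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  n <- nrow(P)
  if (is.null(state_labels)) {
    state_labels <- paste0("S", seq_len(n))
  }
  stopifnot(length(state_labels) == n, lag_time > 0)
  dimnames(P) <- list(state_labels, state_labels)
  structure(
    list(transition_matrix = P, state_labels = state_labels,
         lag_time = lag_time, n_states = n),
    class = "gt_chain"
  )
}

#' Default five-state ligand-binding chain
#'
#' A ground-truth chain mimicking the metastable topology of a ligand binding
#' to a GPCR through an extracellular vestibule: a bulk state exchanging
#' quickly with the vestibule, a slow rate-limiting vestibule-to-bound step,
#' an alternative route through an orthosteric intermediate, and an
#' off-pathway state that exchanges only with the bound pose. Rates were
#' chosen (at 0.1 microseconds per lag step) so that the analytic
#' bulk-to-bound mean first passage time is of order 7 microseconds and the
#' indirect (via-intermediate) share of binding events is close to 30 percent.
#'
#' @param lag_time time per step in microseconds (default 0.1).
#' @return a `gt_chain` with states bulk, vestibule, intermediate, bound,
#'   offpath.
#' @export
default_binding_chain <- function(lag_time = 0.1) {
  P <- rbind(
    bulk         = c(0.900, 0.1000, 0.0000, 0.0000, 0.00),
    vestibule    = c(0.060, 0.9082, 0.0108, 0.0210, 0.00),
    intermediate = c(0.000, 0.0100, 0.9600, 0.0300, 0.00),
    bound        = c(0.000, 0.0020, 0.0000, 0.9880, 0.01),
    offpath      = c(0.000, 0.0000, 0.0000, 0.0200, 0.98)
  )
  ground_truth_chain(P, rownames(P), lag_time = lag_time)
}

#' Sample discrete trajectories from a ground-truth chain
#'
#' Iterated categorical sampling from the rows of the transition matrix.
#' Each trajectory draws from its own substream (a fixed offset of `seed`),
#' so increasing `n_traj` never changes earlier trajectories.
#'
#' @param chain a `gt_chain`.
#' @param n_traj number of trajectories.
#' @param n_steps length of each trajectory (states, including the start).
#' @param start_distribution probability vector over states for the first
#'   frame; defaults to all mass on state 1.
#' @param seed integer seed.
#' @return list of integer vectors (1-based state indices), length `n_traj`.
#' @export
sample_discrete_trajectories <- function(chain, n_traj, n_steps,
                                         start_distribution = NULL,
                                         seed = 1L) {
  stopifnot(inherits(chain, "gt_chain"), n_traj >= 1, n_steps >= 1)
  n <- chain$n_states
  if (is.null(start_distribution)) {
    start_distribution <- c(1, rep(0, n - 1))
  }
  stopifnot(length(start_distribution) == n,
            abs(sum(start_distribution) - 1) < 1e-8)
  cum_rows <- t(apply(chain$transition_matrix, 1, cumsum))
  cum_start <- cumsum(start_distribution)
  lapply(seq_len(n_traj), function(j) {
    set.seed(traj_substream(seed, j))
    u <- stats::runif(n_steps)
    s <- integer(n_steps)
    s[1] <- findInterval(u[1], cum_start, left.open = TRUE) + 1L
    if (n_steps > 1) {
      for (t in 2:n_steps) {
        s[t] <- findInterval(u[t], cum_rows[s[t - 1L], ],
                             left.open = TRUE) + 1L
      }
    }
    s
  })
}

# Fixed-offset substream so trajectory j is reproducible independently of
# how many trajectories are requested.
traj_substream <- function(seed, j) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(j)) %% 2147483647)
}

#' Exact mean first passage time of a chain
#'
#' Solves the absorbing-chain linear system: with the target made absorbing,
#' m_i = 1 + sum_j P_ij m_j over non-target states. Returns the passage time
#' both in lag steps and in physical time.
#'
#' @param chain a `gt_chain`.
#' @param source source state (index or label).
#' @param target target state or states (indices or labels).
#' @return list with `steps` and `time` (steps times `lag_time`).
#' @export
analytic_mfpt <- function(chain, source, target) {
  stopifnot(inherits(chain, "gt_chain"))
  src <- resolve_state(chain, source)
  tgt <- resolve_state(chain, target)
  if (any(src %in% tgt)) stop("source must differ from target")
  P <- chain$transition_matrix
  keep <- setdiff(seq_len(chain$n_states), tgt)
  Q <- P[keep, keep, drop = FALSE]
  A <- diag(length(keep)) - Q
  m <- tryCatch(solve(A, rep(1, length(keep))),
                error = function(e) stop("target unreachable from source: ",
                                         conditionMessage(e)))
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("target unreachable from source")
  }
  steps <- m[match(src, keep)]
  list(steps = unname(steps), time = unname(steps) * chain$lag_time)
}

resolve_state <- function(chain, state) {
  if (is.character(state)) {
    idx <- match(state, chain$state_labels)
    if (any(is.na(idx))) stop("unknown state label: ",
                              paste(state[is.na(idx)], collapse = ", "))
    return(idx)
  }
  state <- as.integer(state)
  stopifnot(all(state >= 1), all(state <= chain$n_states))
  state
}

#' Analytic indirect-pathway fraction of a binding chain
#'
#' First-step analysis on the embedded jump chain: a binding event runs from
#' the last bulk visit to the first arrival in `bound`; it is indirect iff it
#' passes through `marker`. The fraction is P(reach bound before bulk and
#' visit marker) / P(reach bound before bulk), starting from the first state
#' entered from bulk.
#'
#' @param chain a `gt_chain`.
#' @param bulk,bound,marker state indices or labels.
#' @return the indirect fraction in `[0, 1]`.
#' @export
analytic_indirect_fraction <- function(chain, bulk = "bulk",
                                       bound = "bound",
                                       marker = "intermediate") {
  b <- resolve_state(chain, bulk)
  d <- resolve_state(chain, bound)
  m <- resolve_state(chain, marker)
  P <- chain$transition_matrix
  n <- chain$n_states
  entry <- which(P[b, ] > 0 & seq_len(n) != b)
  # h: probability of hitting bound before bulk; hm: same but visiting marker.
  interior <- setdiff(seq_len(n), c(b, d))
  h <- hm <- numeric(n)
  h[d] <- 1
  hm[d] <- 0
  # Solve h on interior states: h_i = sum_j P_ij h_j with h_bulk=0, h_bound=1
  Q <- P[interior, interior, drop = FALSE]
  rhs <- P[interior, d]
  h[interior] <- solve(diag(length(interior)) - Q, rhs)
  # For hm, states equal to marker convert to "visited": from marker onwards
  # any success counts, so hm_marker = h_marker; elsewhere propagate.
  int2 <- setdiff(interior, m)
  Q2 <- P[int2, int2, drop = FALSE]
  rhs2 <- as.vector(P[int2, m, drop = FALSE] %*% h[m])
  hm[m] <- h[m]
  if (length(int2)) {
    hm[int2] <- solve(diag(length(int2)) - Q2, rhs2)
  }
  p_entry <- P[b, entry] / sum(P[b, entry])
  succ <- sum(p_entry * h[entry])
  ind <- sum(p_entry * hm[entry])
  ind / succ
}
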