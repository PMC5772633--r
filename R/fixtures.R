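# Synthetic fixtures: ideal-geometry phenylalanine fragments, dose-response
# tables, and binary contact-feature embeddings of discrete state sequences.

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) construction: returns the
#' position `d` with bond length `|cd| = bond`, bond angle `b-c-d = angle`
#' and signed dihedral `a-b-c-d = dihedral`, consistent with [dihedral()].
#'
#' @param a,b,c positions of the three preceding atoms (length-3 numerics).
#' @param bond Angstrom; `angle`, `dihedral_deg` in degrees.
#' @return length-3 numeric position.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral_deg) {
  ang <- angle * pi / 180
  tor <- dihedral_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Minimal phenylalanine fragment with prescribed chi1/chi2
#'
#' Builds atoms N, CA, CB, CG, CD1 with ideal bond lengths and angles such
#' that the measured sidechain dihedrals chi1 = N-CA-CB-CG and
#' chi2 = CA-CB-CG-CD1 equal the requested values. Used as a round-trip
#' fixture for rotamer measurement.
#'
#' @param chi1,chi2 target dihedrals in degrees, in `(-180, 180]`.
#' @return a `structure_model` (see [read_structure()]) with one PHE residue.
#' @export
make_phe_fixture <- function(chi1, chi2) {
  stopifnot(chi1 > -180, chi1 <= 180, chi2 > -180, chi2 <= 180)
  n  <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  # CB off the N-CA axis at the tetrahedral angle
  ang_n_ca_cb <- 110.5
  cb <- ca + 1.530 * c(cos(pi - ang_n_ca_cb * pi / 180),
                       sin(pi - ang_n_ca_cb * pi / 180), 0)
  cg  <- place_atom(n, ca, cb, 1.530, 114.0, chi1)
  cd1 <- place_atom(ca, cb, cg, 1.390, 120.0, chi2)
  xyz <- rbind(n, ca, cb, cg, cd1)
  atoms <- data.frame(
    serial = 1:5,
    name = c("N", "CA", "CB", "CG", "CD1"),
    element = c("N", "C", "C", "C", "C"),
    resno = 1L,
    resname = "PHE",
    chain = "A",
    stringsAsFactors = FALSE
  )
  new_structure_model(new_topology(atoms, ligand = integer(0)), xyz,
                      source = "make_phe_fixture")
}

#' Ground truth for a simulated competition binding assay
#'
#' @param ic50 half-maximal inhibitory concentration, M.
#' @param hill Hill slope (dimensionless).
#' @param l_conc radioligand concentration, M.
#' @param kd radioligand dissociation constant, M.
#' @param noise_sd Gaussian noise on percent-inhibition readings.
#' @param seed integer seed.
#' @return an `assay_truth` list.
#' @export
assay_truth <- function(ic50, hill = 1, l_conc = 1e-9, kd = 1e-9,
                        noise_sd = 0, seed = 1L) {
  stopifnot(ic50 > 0, l_conc >= 0, kd > 0, noise_sd >= 0)
  structure(list(ic50 = ic50, hill = hill, l_conc = l_conc, kd = kd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "assay_truth")
}

#' Simulate percent-inhibition dose-response data
#'
#' Percent inhibition follows the logistic
#' `100 / (1 + (ic50 / c)^hill)` plus seeded Gaussian noise.
#'
#' @param truth an [assay_truth()] object.
#' @param concentrations competitor concentrations, M (all > 0).
#' @return data.frame with columns `concentration`, `inhibition`.
#' @export
generate_dose_response <- function(truth, concentrations) {
  stopifnot(inherits(truth, "assay_truth"), all(concentrations > 0))
  y <- 100 / (1 + (truth$ic50 / concentrations)^truth$hill)
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    y <- y + stats::rnorm(length(y), sd = truth$noise_sd)
  }
  data.frame(concentration = concentrations, inhibition = y)
}

#' Embed discrete state sequences into noisy binary contact features
#'
#' Each ground-truth state emits a characteristic binary contact pattern
#' over `n_features` pseudo-residues; every bit is flipped independently
#' with probability `flip_prob` per frame. A per-frame interaction flag is
#' emitted alongside: non-bulk states raise the flag with probability
#' `flag_prob_contact`, the bulk state with probability
#' `1 - flag_prob_bulk0`. This mirrors the statistical structure the
#' contact-map + bulk-flag featurization produces on real trajectories.
#'
#' @param dtrajs list of integer state sequences (1-based).
#' @param n_states number of ground-truth states.
#' @param n_features number of binary features (default 20).
#' @param flip_prob per-bit noise probability (default 0.02; contact
#'   flicker in well-separated metastable poses is sparse and localized).
#' @param flag_prob_bulk0 probability that a bulk frame has flag 0
#'   (default 0.95).
#' @param flag_prob_contact probability that a non-bulk frame has flag 1
#'   (default 0.98).
#' @param patterns optional `n_states x n_features` 0/1 matrix of state
#'   contact patterns; defaults to disjoint blocks with the bulk state all
#'   zero.
#' @param bulk_state index of the bulk state (default 1).
#' @param seed integer seed.
#' @return list with `contacts` (list of frames x features 0/1 matrices)
#'   and `flags` (list of 0/1 vectors).
#' @export
embed_chain_features <- function(dtrajs, n_states, n_features = 20,
                                 flip_prob = 0.02,
                                 flag_prob_bulk0 = 0.95,
                                 flag_prob_contact = 0.98,
                                 patterns = NULL, bulk_state = 1L,
                                 seed = 1L) {
  stopifnot(is.list(dtrajs), n_features >= n_states)
  if (is.null(patterns)) {
    patterns <- matrix(0, n_states, n_features)
    width <- floor(n_features / n_states)
    for (s in seq_len(n_states)) {
      if (s == bulk_state) next
      cols <- ((s - 1) * width + 1):(s * width)
      patterns[s, cols] <- 1
    }
  }
  stopifnot(nrow(patterns) == n_states, ncol(patterns) == n_features)
  contacts <- vector("list", length(dtrajs))
  flags <- vector("list", length(dtrajs))
  for (j in seq_along(dtrajs)) {
    set.seed(traj_substream(seed + 104729L, j))
    s <- dtrajs[[j]]
    m <- patterns[s, , drop = FALSE]
    flips <- matrix(stats::runif(length(m)) < flip_prob, nrow(m), ncol(m))
    m <- abs(m - flips)                  # XOR with the noise mask
    p_flag <- ifelse(s == bulk_state, 1 - flag_prob_bulk0, flag_prob_contact)
    flags[[j]] <- as.integer(stats::runif(length(s)) < p_flag)
    contacts[[j]] <- m
  }
  list(contacts = contacts, flags = flags)
}
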