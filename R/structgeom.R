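# Structure geometry: signed dihedrals, sidechain chi1/chi2 rotamers,
# Kabsch superposition and RMSD, inter-atom distances, circular rotamer
# outlier detection and representative-pose selection.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention:
#' `atan2((n1 x n2) . b2_hat, n1 . n2)` with `b1 = p2 - p1`,
#' `b2 = p3 - p2`, `b3 = p4 - p3`, `n1 = b1 x b2`, `n2 = b2 x b3`.
#' Result in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 length-3 numeric positions (Angstrom).
#' @return degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("degenerate geometry: collinear or coincident points")
  }
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Measure sidechain chi1/chi2 of a residue
#'
#' `chi1 = dihedral(N, CA, CB, CG)`; `chi2 = dihedral(CA, CB, CG, CD1)`
#' (phenylalanine/tyrosine-type sidechains). Missing atoms yield `NA` for
#' the affected angle rather than an error.
#'
#' @param structure a `structure_model`.
#' @param resno residue number; `chain` optionally disambiguates.
#' @param chain chain id or `NULL`.
#' @return data.frame (one row) with `structure_id`, `resno`, `chi1`,
#'   `chi2`, `missing` (comma-separated missing atom names or `""`).
#' @export
measure_chi <- function(structure, resno, chain = NULL) {
  atoms <- structure$topology$atoms
  sel <- atoms$resno == resno
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  pick <- function(nm) {
    i <- which(sel & atoms$name == nm)
    if (length(i) == 0) return(NULL)
    structure$xyz[i[1], ]
  }
  pts <- lapply(c("N", "CA", "CB", "CG", "CD1"), pick)
  names(pts) <- c("N", "CA", "CB", "CG", "CD1")
  missing <- names(pts)[vapply(pts, is.null, logical(1))]
  chi1 <- chi2 <- NA_real_
  if (!any(c("N", "CA", "CB", "CG") %in% missing)) {
    chi1 <- dihedral(pts$N, pts$CA, pts$CB, pts$CG)
  }
  if (!any(c("CA", "CB", "CG", "CD1") %in% missing)) {
    chi2 <- dihedral(pts$CA, pts$CB, pts$CG, pts$CD1)
  }
  data.frame(structure_id = structure$source %||% NA_character_,
             resno = resno, chi1 = chi1, chi2 = chi2,
             missing = paste(missing, collapse = ","),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kabsch least-squares superposition
#'
#' Centroid shift plus SVD rotation (with reflection correction), applied
#' to the mobile coordinates; RMSD is computed over the paired atoms after
#' the transform. At least two pairs are required (RMSD is well defined for
#' two, though the rotation is then underdetermined).
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param pairing optional 2-column index matrix (mobile, reference);
#'   defaults to row-wise pairing.
#' @return list with `rotation` (3 x 3), `translation`, `rmsd` and
#'   `transformed` (all mobile atoms moved).
#' @export
kabsch_superpose <- function(mobile, reference, pairing = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (is.null(pairing)) {
    stopifnot(nrow(mobile) == nrow(reference))
    pairing <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  }
  if (nrow(pairing) < 2) stop("need at least 2 paired atoms")
  A <- mobile[pairing[, 1], , drop = FALSE]
  B <- reference[pairing[, 2], , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(A, 2, ca) %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  transformed <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  list(rotation = R, translation = cb - ca %*% t(R), rmsd = rmsd,
       transformed = transformed)
}

#' Distance between two atoms of a structure
#'
#' @param structure a `structure_model`.
#' @param atom_a,atom_b atom selectors: either atom indices or lists
#'   `list(resno =, name =, chain =)`.
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(structure, atom_a, atom_b) {
  idx <- function(sel) {
    if (is.numeric(sel)) return(as.integer(sel))
    atoms <- structure$topology$atoms
    i <- which(atoms$resno == sel$resno & atoms$name == sel$name &
                 (is.null(sel$chain) | atoms$chain == (sel$chain %||% "")))
    if (!length(i)) stop("atom not found: resno ", sel$resno, " name ",
                         sel$name)
    i[1]
  }
  a <- idx(atom_a)
  b <- idx(atom_b)
  sqrt(sum((structure$xyz[a, ] - structure$xyz[b, ])^2))
}

# circular distance between two angles, degrees in [0, 180]
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Rotamer outlier detection against a reference set
#'
#' An observation is an outlier iff the minimum circular chi1 distance to
#' the reference set exceeds `threshold`. Chi2 distances are reported for
#' context but do not decide the flag.
#'
#' @param chi1,chi2 observed angles, degrees.
#' @param reference data.frame with columns `chi1`, `chi2` (degrees).
#' @param threshold degrees (default 30).
#' @return list with `outlier` (flag on chi1), `min_chi1_distance`,
#'   `min_chi2_distance`, `nearest` (row index of nearest chi1 reference).
#' @export
rotamer_outlier <- function(chi1, chi2, reference, threshold = 30) {
  stopifnot(nrow(reference) >= 1)
  d1 <- circular_distance(chi1, reference$chi1)
  d2 <- if (!is.null(reference$chi2) && !is.na(chi2)) {
    circular_distance(chi2, reference$chi2)
  } else NA_real_
  list(outlier = min(d1) > threshold,
       min_chi1_distance = min(d1),
       min_chi2_distance = if (all(is.na(d2))) NA_real_ else min(d2, na.rm = TRUE),
       nearest = which.min(d1))
}

#' Select the representative frame closest to a reference pose
#'
#' After superposing each frame onto the reference on `align_atoms`
#' (typically CA atoms), returns the frame minimizing the RMSD of
#' `rmsd_atoms` (typically pocket sidechain atoms) to the reference.
#' Ties resolve to the lowest frame index.
#'
#' @param traj a `bk_trajectory`.
#' @param reference a `structure_model`.
#' @param align_pairs 2-column matrix of (trajectory atom, reference atom)
#'   indices used for the superposition.
#' @param rmsd_pairs 2-column matrix of (trajectory atom, reference atom)
#'   indices scored after superposition.
#' @return list with `frame` (index) and `rmsd` (per-frame vector).
#' @export
representative_pose <- function(traj, reference, align_pairs, rmsd_pairs) {
  stopifnot(inherits(traj, "bk_trajectory"),
            inherits(reference, "structure_model"))
  n_frames <- dim(traj$coords)[1]
  if (n_frames < 1) stop("empty frame set")
  scores <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- matrix(traj$coords[f, , ], dim(traj$coords)[2], 3)
    sup <- kabsch_superpose(xyz, reference$xyz, align_pairs)
    moved <- sup$transformed[rmsd_pairs[, 1], , drop = FALSE]
    ref <- reference$xyz[rmsd_pairs[, 2], , drop = FALSE]
    scores[f] <- sqrt(mean(rowSums((moved - ref)^2)))
  }
  list(frame = which.min(scores), rmsd = scores)
}
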