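# Protein-ligand contact featurization: topology/trajectory containers,
# PDB reading, ligand feature-atom selection, residue contact map and the
# bulk flag.

new_topology <- function(atoms, ligand = integer(0)) {
  required <- c("serial", "name", "element", "resno", "resname", "chain")
  stopifnot(is.data.frame(atoms), all(required %in% names(atoms)))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  structure(list(atoms = atoms, ligand = as.integer(ligand)),
            class = "bk_topology")
}

#' @export
print.bk_topology <- function(x, ...) {
  cat("bk_topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      length(x$ligand), "ligand atoms\n")
  invisible(x)
}

new_structure_model <- function(topology, xyz, source = NA_character_) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(inherits(topology, "bk_topology"),
            nrow(xyz) == nrow(topology$atoms),
            all(is.finite(xyz)))
  structure(list(topology = topology, xyz = xyz, source = source),
            class = "structure_model")
}

#' Build a trajectory container
#'
#' @param topology a `bk_topology`.
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param frame_interval physical time per saved frame (arbitrary but
#'   positive; microseconds throughout this package).
#' @return a `bk_trajectory`.
#' @export
bk_trajectory <- function(topology, coords, frame_interval = 1) {
  stopifnot(inherits(topology, "bk_topology"), frame_interval > 0)
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(1, dim(coords)))
  }
  stopifnot(length(dim(coords)) == 3,
            dim(coords)[2] == nrow(topology$atoms), dim(coords)[3] == 3)
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "bk_trajectory")
}

#' Read a PDB structure
#'
#' Thin wrapper around [bio3d::read.pdb()] producing the package's topology
#' and single-frame coordinate containers. Alternate locations are resolved
#' by keeping, per atom, the record with the highest occupancy (ties go to
#' altloc "A", then first listed). Elements come from the PDB element
#' column; when absent they are inferred from the atom name (leading
#' letters, with a warning for H-prefix heuristics).
#'
#' @param path PDB file.
#' @param ligand_resname optional residue name(s); matching residues (often
#'   HETATM records) form the ligand selection.
#' @return a `structure_model` with elements `topology`, `xyz`, `source`.
#' @export
read_structure <- function(path, ligand_resname = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z))) {
    stop("PDB '", path, "' contains missing coordinates")
  }
  # altloc resolution: group by chain/residue/atom name
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    pref <- ifelse(alt == "A", 0.5, 0) # tie-break toward altloc A
    ord <- order(key, -(occ + 1e-6 * pref))
    keep <- !duplicated(key[ord])
    at <- at[ord[keep], , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- trimws(elem)
  missing_el <- is.na(elem) | elem == ""
  if (any(missing_el)) {
    guess <- sub("^[0-9']*", "", at$elety[missing_el])
    guess <- toupper(substr(guess, 1, 1))
    if (any(guess == "H")) {
      warning("element column absent for some atoms; ",
              "using H* name-prefix heuristic")
    }
    elem[missing_el] <- guess
  }
  if (anyDuplicated(at$eleno)) {
    stop("PDB '", path, "' has duplicate atom serial numbers")
  }
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    resno = at$resno, resname = trimws(at$resid), chain = at$chain,
    stringsAsFactors = FALSE
  )
  ligand <- integer(0)
  if (!is.null(ligand_resname)) {
    ligand <- which(atoms$resname %in% ligand_resname)
  }
  topo <- new_topology(atoms, ligand)
  new_structure_model(topo, cbind(at$x, at$y, at$z), source = path)
}

# covalent radii (Angstrom) for distance-based bond inference
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

#' Select ligand feature atoms
#'
#' Returns the ligand atoms used for contact featurization: all ligand
#' oxygens and nitrogens, plus ligand carbons that have no bonded hydrogen.
#' Bonds are inferred from the reference coordinates: two atoms are bonded
#' when their distance is below 1.2 times the sum of their covalent radii.
#'
#' @param structure a `structure_model` whose topology has a non-empty
#'   ligand selection.
#' @return integer vector of atom indices (rows of the topology).
#' @export
ligand_feature_atoms <- function(structure) {
  topo <- structure$topology
  lig <- topo$ligand
  if (length(lig) == 0) stop("topology has no ligand selection")
  atoms <- topo$atoms
  el <- toupper(atoms$element)
  keep <- lig[el[lig] %in% c("O", "N")]
  carb <- lig[el[lig] == "C"]
  if (length(carb)) {
    # hydrogens anywhere in the ligand; bond inference within the ligand
    hyd <- lig[el[lig] == "H"]
    has_h <- vapply(carb, function(i) {
      if (!length(hyd)) return(FALSE)
      d <- sqrt(colSums((t(structure$xyz[hyd, , drop = FALSE]) -
                           structure$xyz[i, ])^2))
      rc <- .covalent_radii[["C"]] + .covalent_radii[["H"]]
      any(d < 1.2 * rc)
    }, logical(1))
    keep <- c(keep, carb[!has_h])
  }
  keep <- sort(unique(keep))
  if (!length(keep)) {
    stop("no usable ligand feature atoms (no O/N and all carbons bear H)")
  }
  keep
}

#' Binary residue contact map
#'
#' For each frame and protein residue, records 1 iff the minimum distance
#' between any heavy atom of the residue and any ligand feature atom is
#' strictly below `cutoff`.
#'
#' @param traj a `bk_trajectory`.
#' @param feature_atoms ligand feature atom indices (see
#'   [ligand_feature_atoms()]).
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return integer matrix frames x residues with residue keys as column
#'   names.
#' @export
contact_map <- function(traj, feature_atoms, cutoff = 5) {
  stopifnot(inherits(traj, "bk_trajectory"), length(feature_atoms) >= 1)
  atoms <- traj$topology$atoms
  protein <- setdiff(seq_len(nrow(atoms)), traj$topology$ligand)
  heavy <- protein[toupper(atoms$element[protein]) != "H"]
  if (!length(heavy)) stop("no protein residues with heavy atoms")
  reskey <- paste(atoms$chain[heavy], atoms$resno[heavy], sep = ":")
  resf <- factor(reskey, levels = unique(reskey))
  n_frames <- dim(traj$coords)[1]
  out <- matrix(0L, n_frames, nlevels(resf),
                dimnames = list(NULL, levels(resf)))
  for (f in seq_len(n_frames)) {
    lig_xyz <- traj$coords[f, feature_atoms, , drop = FALSE]
    dim(lig_xyz) <- c(length(feature_atoms), 3)
    prot_xyz <- traj$coords[f, heavy, , drop = FALSE]
    dim(prot_xyz) <- c(length(heavy), 3)
    d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
      2 * prot_xyz %*% t(lig_xyz)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    out[f, ] <- as.integer(tapply(mind, resf, min) < cutoff)
  }
  out
}

#' Bulk flag
#'
#' Per frame, 1 iff any ligand feature atom is strictly closer than `cutoff`
#' to any protein CA atom; 0 marks frames with the ligand in bulk solvent.
#'
#' @inheritParams contact_map
#' @param cutoff Angstrom (default 10).
#' @return integer vector of length `n_frames`.
#' @export
bulk_flag <- function(traj, feature_atoms, cutoff = 10) {
  stopifnot(inherits(traj, "bk_trajectory"), length(feature_atoms) >= 1)
  atoms <- traj$topology$atoms
  protein <- setdiff(seq_len(nrow(atoms)), traj$topology$ligand)
  ca <- protein[atoms$name[protein] == "CA"]
  if (!length(ca)) stop("protein has no CA atoms")
  n_frames <- dim(traj$coords)[1]
  flag <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    lig_xyz <- matrix(traj$coords[f, feature_atoms, ],
                      length(feature_atoms), 3)
    ca_xyz <- matrix(traj$coords[f, ca, ], length(ca), 3)
    d2 <- outer(rowSums(ca_xyz^2), rowSums(lig_xyz^2), "+") -
      2 * ca_xyz %*% t(lig_xyz)
    flag[f] <- as.integer(min(d2) < cutoff^2)
  }
  flag
}
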