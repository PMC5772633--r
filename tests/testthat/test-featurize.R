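test_that("PDB reading preserves atoms, residues and ligand selection", {
  path <- tiny_complex_pdb()
  s <- read_structure(path, ligand_resname = "LIG")
  expect_s3_class(s, "structure_model")
  expect_identical(nrow(s$topology$atoms), 12L)
  expect_identical(s$topology$atoms$name[1], "CA")
  expect_identical(s$topology$atoms$resname[6], "LIG")
  expect_identical(s$topology$atoms$resno[4], 3L)
  expect_length(s$topology$ligand, 7)
  expect_equal(s$xyz[5, ], c(8, 1.4, 0), ignore_attr = TRUE)
})

test_that("altloc records keep the highest occupancy, ties prefer A", {
  df <- rbind(
    pdb_row(1, "CA", "ALA", "A", 1, 0, 0, 0, "C", alt = "A", occ = 0.4),
    pdb_row(2, "CA", "ALA", "A", 1, 9, 9, 9, "C", alt = "B", occ = 0.6),
    pdb_row(3, "CB", "ALA", "A", 1, 1, 0, 0, "C", alt = "A", occ = 0.5),
    pdb_row(4, "CB", "ALA", "A", 1, 7, 7, 7, "C", alt = "B", occ = 0.5)
  )
  s <- read_structure(write_test_pdb(df))
  expect_identical(nrow(s$topology$atoms), 2L)
  # CA: occupancy 0.6 wins; CB: tie -> altloc A
  expect_equal(s$xyz[s$topology$atoms$name == "CA", ], c(9, 9, 9),
               ignore_attr = TRUE)
  expect_equal(s$xyz[s$topology$atoms$name == "CB", ], c(1, 0, 0),
               ignore_attr = TRUE)
})

test_that("ligand feature atoms keep O/N and H-free carbons only", {
  s <- read_structure(tiny_complex_pdb(), ligand_resname = "LIG")
  fa <- ligand_feature_atoms(s)
  names_fa <- s$topology$atoms$name[fa]
  expect_setequal(names_fa, c("N1", "C1", "O1"))
  # all-hydrogenated carbon ligand has no usable atoms
  df <- rbind(
    pdb_row(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_row(2, "C1", "LIG", "L", 9, 0, 5, 0, "C", record = "HETATM"),
    pdb_row(3, "H1", "LIG", "L", 9, 1.0, 5, 0, "H", record = "HETATM"),
    pdb_row(4, "H2", "LIG", "L", 9, -1.0, 5, 0, "H", record = "HETATM"),
    pdb_row(5, "H3", "LIG", "L", 9, 0, 6.0, 0, "H", record = "HETATM"),
    pdb_row(6, "H4", "LIG", "L", 9, 0, 5, 1.0, "H", record = "HETATM")
  )
  s2 <- read_structure(write_test_pdb(df), ligand_resname = "LIG")
  expect_error(ligand_feature_atoms(s2), "no usable")
})

make_traj_fixture <- function(lig_xyz) {
  # residue 1 CA at origin; ligand single N at lig_xyz per frame
  atoms <- data.frame(serial = 1:2, name = c("CA", "N1"),
                      element = c("C", "N"), resno = c(1L, 9L),
                      resname = c("ALA", "LIG"), chain = c("A", "L"),
                      stringsAsFactors = FALSE)
  topo <- bindkin:::new_topology(atoms, ligand = 2L)
  n <- nrow(lig_xyz)
  coords <- array(0, c(n, 2, 3))
  for (f in seq_len(n)) coords[f, 2, ] <- lig_xyz[f, ]
  bk_trajectory(topo, coords)
}

test_that("contact map applies a strict 5 A cutoff", {
  traj <- make_traj_fixture(rbind(c(4.9, 0, 0), c(5.1, 0, 0),
                                  c(5.0, 0, 0), c(0, 0, 0)))
  cm <- contact_map(traj, feature_atoms = 2L, cutoff = 5)
  expect_equal(as.vector(cm), c(1L, 0L, 0L, 1L))  # 5.0 exactly: no contact
})

test_that("bulk flag applies a strict 10 A cutoff to CA distances", {
  traj <- make_traj_fixture(rbind(c(9.9, 0, 0), c(10.1, 0, 0),
                                  c(10.0, 0, 0)))
  bf <- bulk_flag(traj, feature_atoms = 2L, cutoff = 10)
  expect_identical(bf, c(1L, 0L, 0L))
  empty <- make_traj_fixture(matrix(numeric(0), 0, 3))
  expect_identical(bulk_flag(empty, feature_atoms = 2L), integer(0))
})

test_that("contact map equals the brute-force double loop", {
  set.seed(31)
  n_prot <- 30
  atoms <- data.frame(
    serial = seq_len(n_prot + 4),
    name = c(rep(c("CA", "CB", "O"), length.out = n_prot),
             "N1", "C1", "O1", "C2"),
    element = c(rep(c("C", "C", "O"), length.out = n_prot),
                "N", "C", "O", "C"),
    resno = c(rep(1:10, each = 3), rep(50L, 4)),
    resname = c(rep("ALA", n_prot), rep("LIG", 4)),
    chain = c(rep("A", n_prot), rep("L", 4)),
    stringsAsFactors = FALSE
  )
  topo <- bindkin:::new_topology(atoms, ligand = n_prot + 1:4)
  n_frames <- 8
  coords <- array(stats::runif(n_frames * nrow(atoms) * 3, 0, 15),
                  c(n_frames, nrow(atoms), 3))
  traj <- bk_trajectory(topo, coords)
  fa <- n_prot + 1:4
  cm <- contact_map(traj, fa, cutoff = 5)
  for (f in seq_len(n_frames)) {
    for (r in 1:10) {
      ratoms <- which(atoms$resno == r & atoms$chain == "A")
      mind <- Inf
      for (i in ratoms) for (j in fa) {
        mind <- min(mind, sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)))
      }
      expect_identical(unname(cm[f, r]), as.integer(mind < 5))
    }
  }
})

test_that("contact map is invariant under joint rigid motion and monotone in cutoff", {
  set.seed(32)
  atoms <- data.frame(serial = 1:6, name = c("CA", "CB", "CA", "CB", "N1", "C1"),
                      element = c("C", "C", "C", "C", "N", "C"),
                      resno = c(1L, 1L, 2L, 2L, 9L, 9L),
                      resname = c("A", "A", "B", "B", "LIG", "LIG"),
                      chain = c("A", "A", "A", "A", "L", "L"),
                      stringsAsFactors = FALSE)
  topo <- bindkin:::new_topology(atoms, ligand = 5:6)
  coords <- array(stats::runif(5 * 6 * 3, 0, 10), c(5, 6, 3))
  traj <- bk_trajectory(topo, coords)
  cm <- contact_map(traj, 5:6, cutoff = 5)
  # rigid motion: rotate about z by 77 degrees, translate (3, -2, 7)
  th <- 77 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coords2 <- coords
  for (f in 1:5) {
    coords2[f, , ] <- t(R %*% t(coords[f, , ])) +
      matrix(c(3, -2, 7), 6, 3, byrow = TRUE)
  }
  cm2 <- contact_map(bk_trajectory(topo, coords2), 5:6, cutoff = 5)
  expect_identical(cm, cm2)
  # monotonicity: enlarging the cutoff never removes a contact
  cm_wide <- contact_map(traj, 5:6, cutoff = 8)
  expect_true(all(cm_wide >= cm))
})
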