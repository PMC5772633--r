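test_that("dihedral matches the signed convention on canonical arrangements", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("dihedral is rigid-motion invariant and reversal-symmetric", {
  set.seed(61)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(12), 4, 3)
    d <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                  error = function(e) NA)
    if (is.na(d)) next
    # random rotation (QR of a Gaussian matrix) + translation
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::rnorm(3)
    moved <- pts %*% t(Q) + matrix(shift, 4, 3, byrow = TRUE)
    d2 <- dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ])
    expect_equal(d2, d, tolerance = 1e-8)
    # reversing the point order preserves the angle (same sign, IUPAC)
    d3 <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(abs(d3), abs(d), tolerance = 1e-8)
  }
})

test_that("measured chi values round-trip the reported rotamers", {
  for (ang in list(c(-174.4, 72.9), c(-90.8, 70.2), c(-90.8, -68.9),
                   c(70.2, 106.8))) {
    obs <- measure_chi(make_phe_fixture(ang[1], ang[2]), 1)
    expect_equal(c(obs$chi1, obs$chi2), ang, tolerance = 1e-6)
  }
  # missing CD1: chi1 still measured, chi2 flagged
  s <- make_phe_fixture(-60, 90)
  keep <- s$topology$atoms$name != "CD1"
  s$topology$atoms <- s$topology$atoms[keep, ]
  s$xyz <- s$xyz[keep, ]
  obs <- measure_chi(s, 1)
  expect_equal(obs$chi1, -60, tolerance = 1e-6)
  expect_true(is.na(obs$chi2))
  expect_match(obs$missing, "CD1")
})

test_that("Kabsch superposition removes rigid motions exactly", {
  set.seed(62)
  A <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(c(5, 5, 5), 10, 3, byrow = TRUE)
  out <- kabsch_superpose(B, A)
  expect_equal(out$rmsd, 0, tolerance = 1e-10)
  expect_equal(out$transformed, A, tolerance = 1e-10)
})

test_that("Kabsch RMSD matches brute-force minimization on tiny systems", {
  # two unit-separated points vs a coincident pair: best possible RMSD 0.5
  mob <- rbind(c(0, 0, 0), c(1, 0, 0))
  ref <- rbind(c(3, 3, 3), c(3, 3, 3))
  expect_equal(kabsch_superpose(mob, ref)$rmsd, 0.5, tolerance = 1e-10)
  # 3-point toy: compare to a dense rotation-grid search
  set.seed(63)
  mob3 <- matrix(stats::rnorm(9), 3, 3)
  ref3 <- matrix(stats::rnorm(9), 3, 3)
  got <- kabsch_superpose(mob3, ref3)$rmsd
  ca <- colMeans(mob3); cb <- colMeans(ref3)
  A0 <- sweep(mob3, 2, ca); B0 <- sweep(ref3, 2, cb)
  best <- Inf
  angs <- seq(0, 2 * pi, length.out = 25)[-25]
  for (a in angs) for (b in angs) for (c in angs) {
    Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rx <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
    M <- A0 %*% t(Rz %*% Ry %*% Rx)
    best <- min(best, sqrt(mean(rowSums((M - B0)^2))))
  }
  expect_lte(got, best + 1e-9)        # SVD solution is never worse
  expect_lt(best - got, 0.05)          # and the grid approaches it
})

test_that("atom distances use plain Euclidean geometry", {
  atoms <- data.frame(serial = 1:3, name = c("OE1", "NH1", "CA"),
                      element = c("O", "N", "C"), resno = c(30L, 50L, 50L),
                      resname = c("GLU", "ARG", "ARG"), chain = "A",
                      stringsAsFactors = FALSE)
  topo <- bindkin:::new_topology(atoms)
  s <- bindkin:::new_structure_model(topo, rbind(c(0, 0, 0), c(3, 4, 0),
                                                 c(0, 0, 2.7)))
  expect_equal(atom_distance(s, 1, 2), 5)
  expect_equal(atom_distance(s, 1, 3), 2.7)
  expect_equal(atom_distance(s, list(resno = 30, name = "OE1"),
                             list(resno = 50, name = "NH1")), 5)
  expect_error(atom_distance(s, list(resno = 99, name = "XX"), 1),
               "not found")
})

test_that("rotamer outliers use circular chi1 distances", {
  ref <- data.frame(chi1 = stats::rnorm(20, -90.8, 8),
                    chi2 = stats::rnorm(20, 70.2, 10))
  out <- rotamer_outlier(-174.4, 72.9, ref, threshold = 30)
  expect_true(out$outlier)
  expect_gt(out$min_chi1_distance, 30)
  same <- rotamer_outlier(ref$chi1[1], ref$chi2[1], ref)
  expect_false(same$outlier)
  expect_equal(same$min_chi1_distance, 0)
  # wrap-around: 179 vs -179 are 2 degrees apart
  wrap <- rotamer_outlier(179, 0, data.frame(chi1 = -179, chi2 = 0))
  expect_equal(wrap$min_chi1_distance, 2)
  expect_false(wrap$outlier)
})

test_that("representative pose selection returns the closest frame", {
  ref <- make_phe_fixture(-90, 70)
  n_atoms <- nrow(ref$xyz)
  # frames: perturbed copies with increasing sidechain displacement
  shifts <- c(2, 1, 3)
  coords <- array(NA_real_, c(3, n_atoms, 3))
  for (f in 1:3) {
    xyz <- ref$xyz
    xyz[4:5, 1] <- xyz[4:5, 1] + shifts[f]   # displace CG/CD1 only
    coords[f, , ] <- xyz
  }
  traj <- bk_trajectory(ref$topology, coords)
  pairs_align <- cbind(1:3, 1:3)   # N, CA, CB
  pairs_rmsd <- cbind(4:5, 4:5)    # CG, CD1
  out <- representative_pose(traj, ref, pairs_align, pairs_rmsd)
  expect_identical(out$frame, 2L)
  # a frame identical to the reference wins with RMSD 0
  coords[3, , ] <- ref$xyz
  out2 <- representative_pose(bk_trajectory(ref$topology, coords), ref,
                              pairs_align, pairs_rmsd)
  expect_identical(out2$frame, 3L)
  expect_equal(out2$rmsd[3], 0, tolerance = 1e-10)
})
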