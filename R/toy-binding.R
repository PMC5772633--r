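# Toy overdamped Langevin simulation of a single pseudo-ligand particle.

#' Parameters for the toy binding simulator
#'
#' @param well_centers numeric matrix (n_wells x 3) of basin centers, in
#'   Angstrom. Typically bulk / vestibule / bound positions.
#' @param well_depths numeric vector of well depths in kcal/mol (positive =
#'   attractive).
#' @param well_width Gaussian width sigma of each well, Angstrom.
#' @param temperature Kelvin.
#' @param diffusion_coefficient Angstrom^2 per step.
#' @param flat_bottom_bounds `c(x1, x2, y1, y2, z1, z2)` in Angstrom; the
#'   restraint is zero inside this cuboid.
#' @param flat_bottom_k restraint force constant, kcal/(mol Angstrom^2).
#' @param n_steps number of integration steps.
#' @param start optional starting position (defaults to the first well
#'   center).
#' @param seed integer seed.
#' @return a `toy_binding_params` list.
#' @export
toy_binding_params <- function(well_centers,
                               well_depths,
                               well_width = 3,
                               temperature = 298,
                               diffusion_coefficient = 0.05,
                               flat_bottom_bounds = c(-20, 20, -20, 20, -20, 35),
                               flat_bottom_k = 5,
                               n_steps = 10000L,
                               start = NULL,
                               seed = 1L) {
  well_centers <- matrix(as.numeric(well_centers), ncol = 3)
  stopifnot(length(well_depths) == nrow(well_centers),
            well_width > 0, temperature >= 0,
            length(flat_bottom_bounds) == 6, flat_bottom_k >= 0,
            n_steps >= 1)
  b <- flat_bottom_bounds
  if (!(b[1] < b[2] && b[3] < b[4] && b[5] < b[6])) {
    stop("flat_bottom_bounds must satisfy x1<x2, y1<y2, z1<z2")
  }
  if (diffusion_coefficient <= 0) stop("diffusion coefficient must be > 0")
  if (is.null(start)) start <- well_centers[1, ]
  structure(
    list(well_centers = well_centers, well_depths = as.numeric(well_depths),
         well_width = well_width, temperature = temperature,
         diffusion_coefficient = diffusion_coefficient,
         flat_bottom_bounds = b, flat_bottom_k = flat_bottom_k,
         n_steps = as.integer(n_steps), start = as.numeric(start),
         seed = as.integer(seed)),
    class = "toy_binding_params"
  )
}

# Gradient of the sum-of-Gaussian-wells potential at position x (length 3).
gaussian_well_gradient <- function(x, centers, depths, sigma) {
  d <- sweep(centers, 2, x)              # centers - x
  r2 <- rowSums(d * d)
  w <- depths * exp(-r2 / (2 * sigma^2)) / sigma^2
  # U = -sum depths * exp(-r^2/2s^2); dU/dx = -sum depths*exp(...)*(c-x)/s^2
  -colSums(d * w)
}

#' Simulate a toy ligand-binding trajectory
#'
#' Overdamped Langevin (Euler-Maruyama) dynamics of a single point ligand in
#' a landscape of Gaussian wells centered on pseudo-receptor sites, confined
#' by a flat-bottom cuboid restraint: whenever the particle leaves the box it
#' feels a restoring force of magnitude `flat_bottom_k` times the distance
#' beyond the boundary, directed toward the reference receptor site (the
#' first row of `receptor_sites`).
#'
#' @param params a `toy_binding_params` object.
#' @param receptor_sites numeric matrix (n x 3) of fixed pseudo-residue
#'   centers, Angstrom; the first row is the restraint reference point.
#' @return matrix `n_steps x 3` of ligand positions (Angstrom), with
#'   attribute `params`.
#' @export
simulate_toy_binding <- function(params, receptor_sites) {
  stopifnot(inherits(params, "toy_binding_params"))
  receptor_sites <- matrix(as.numeric(receptor_sites), ncol = 3)
  if (nrow(receptor_sites) < 1) stop("need at least one receptor site")
  D <- params$diffusion_coefficient
  if (params$temperature > 0) {
    RT <- GAS_CONSTANT_KCAL * params$temperature
    mobility <- D / RT
    noise_sd <- sqrt(2 * D)
  } else {
    # deterministic zero-temperature limit: gradient descent, no noise
    mobility <- D
    noise_sd <- 0
  }
  b <- params$flat_bottom_bounds
  lo <- b[c(1, 3, 5)]
  hi <- b[c(2, 4, 6)]
  ref <- receptor_sites[1, ]
  set.seed(params$seed)
  xi <- matrix(stats::rnorm(params$n_steps * 3, sd = noise_sd), ncol = 3)
  out <- matrix(NA_real_, params$n_steps, 3)
  x <- params$start
  for (t in seq_len(params$n_steps)) {
    g <- gaussian_well_gradient(x, params$well_centers, params$well_depths,
                                params$well_width)
    f <- -g
    clamped <- pmin(pmax(x, lo), hi)
    excess <- sqrt(sum((x - clamped)^2))
    if (excess > 0) {
      to_ref <- ref - x
      nr <- sqrt(sum(to_ref^2))
      if (nr > 0) {
        f <- f + params$flat_bottom_k * excess * to_ref / nr
      }
    }
    x <- x + mobility * f + xi[t, ]
    out[t, ] <- x
  }
  attr(out, "params") <- params
  out
}

#' Wrap a toy ligand path and receptor sites as a trajectory
#'
#' Builds a minimal topology (one CA pseudo-atom per receptor site, one
#' ligand nitrogen) so that the contact-map and bulk-flag featurizers can
#' run on toy Langevin output.
#'
#' @param ligand_xyz frames x 3 matrix of ligand positions (Angstrom),
#'   e.g. the output of [simulate_toy_binding()].
#' @param receptor_sites n x 3 matrix of fixed pseudo-residue centers.
#' @param frame_interval physical time per frame.
#' @return a `bk_trajectory` whose ligand selection is the single N atom.
#' @export
toy_complex_trajectory <- function(ligand_xyz, receptor_sites,
                                   frame_interval = 1) {
  ligand_xyz <- matrix(as.numeric(ligand_xyz), ncol = 3)
  receptor_sites <- matrix(as.numeric(receptor_sites), ncol = 3)
  n_sites <- nrow(receptor_sites)
  atoms <- data.frame(
    serial = seq_len(n_sites + 1),
    name = c(rep("CA", n_sites), "N1"),
    element = c(rep("C", n_sites), "N"),
    resno = c(seq_len(n_sites), 900L),
    resname = c(rep("GLY", n_sites), "LIG"),
    chain = c(rep("A", n_sites), "L"),
    stringsAsFactors = FALSE
  )
  topo <- new_topology(atoms, ligand = n_sites + 1L)
  n_frames <- nrow(ligand_xyz)
  coords <- array(NA_real_, c(n_frames, n_sites + 1, 3))
  for (s in seq_len(n_sites)) {
    coords[, s, ] <- matrix(receptor_sites[s, ], n_frames, 3, byrow = TRUE)
  }
  coords[, n_sites + 1, ] <- ligand_xyz
  bk_trajectory(topo, coords, frame_interval = frame_interval)
}

#' Gas constant in kcal/(mol K)
#' @keywords internal
GAS_CONSTANT_KCAL <- 1.98720e-3

#' Avogadro constant, 1/mol
#' @keywords internal
AVOGADRO <- 6.02214e23
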