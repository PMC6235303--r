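## Synthetic trajectories with analytically known statistics.  These define
## the validation conditions for every estimator in the package: no physical
## dynamics is simulated -- frames are i.i.d. in space (or Markovian in shell
## occupancy), which is exactly what the structural estimators assume.

.single_site_water_topology <- function(n) {
  make_topology(name = rep("O", n), resname = rep("WAT", n),
                resid = seq_len(n), species = rep("WATER", n),
                element = rep("O", n))
}

#' Ideal-gas box: i.i.d. uniform single-site waters
#'
#' The null system for pair-correlation and voxel-density estimators: the
#' pair-correlation function of a uniform box is 1 in every bin and its
#' voxel-based translational entropy vanishes in the sampling limit.
#'
#' @param n number of particles.
#' @param b a [box()].
#' @param n_frames number of frames.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param dt frame spacing in ps.
#' @return a [trajectory()].
#' @export
generate_uniform_box <- function(n, b, n_frames, seed = 1, dt = 1) {
  b <- as_box(b)
  top <- .single_site_water_topology(n)
  coords <- .with_seed(seed, {
    array(runif(n * 3 * n_frames) * rep(as.numeric(b), each = n),
          dim = c(n, 3, n_frames))
  })
  trajectory(top, coords, b, dt = dt)
}

#' Box with a prescribed radial density profile
#'
#' Particles are placed by rejection sampling so that their density at
#' distance r from a reference point (or perpendicular distance from a
#' reference axis) is proportional to `profile(r)`.  The empirical radial
#' density converges to the profile as frames accumulate, giving a
#' ground-truth target for pair-correlation estimators and first-peak
#' detection.
#'
#' @param profile vectorized function of r (Angstrom) returning a bounded,
#'   non-negative relative density.
#' @param n particles per frame.
#' @param b a [box()].
#' @param n_frames frames to generate.
#' @param reference either a 3-vector (point) or
#'   `list(point =, dir =)` (axis).
#' @param seed RNG seed.
#' @param dt frame spacing (ps).
#' @param profile_max upper bound of `profile`; estimated on a fine grid when
#'   not given.  An unbounded profile is an error.
#' @return a [trajectory()].
#' @export
generate_radial_profile_box <- function(profile, n, b, n_frames,
                                        reference = c(0, 0, 0), seed = 1,
                                        dt = 1, profile_max = NULL) {
  b <- as_box(b)
  bl <- as.numeric(b)
  r_upper <- sqrt(sum(bl^2))
  if (is.null(profile_max)) {
    grid <- seq(0, r_upper, length.out = 4096)
    profile_max <- max(profile(grid))
  }
  if (!is.finite(profile_max) || profile_max <= 0)
    stop("profile must be bounded, positive somewhere, and finite")
  axis_mode <- is.list(reference)
  ref_point <- if (axis_mode) reference$point else reference
  ref_dir <- if (axis_mode) .unit(reference$dir)
  radial_r <- function(P) {
    d <- sweep(P, 2, ref_point)
    if (axis_mode) {
      proj <- drop(d %*% ref_dir)
      d <- d - outer(proj, ref_dir)
    }
    sqrt(rowSums(d * d))
  }
  top <- .single_site_water_topology(n)
  total <- n * n_frames
  coords <- .with_seed(seed, {
    acc <- matrix(0, 0, 3)
    while (nrow(acc) < total) {
      m <- max(4L * (total - nrow(acc)), 1024L)
      P <- matrix(runif(m * 3), m, 3) * rep(bl, each = m)
      keep <- runif(m) < profile(radial_r(P)) / profile_max
      acc <- rbind(acc, P[keep, , drop = FALSE])
    }
    acc[seq_len(total), , drop = FALSE]
  })
  arr <- array(0, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames))
    arr[, , f] <- coords[((f - 1) * n + 1):(f * n), ]
  trajectory(top, arr, b, dt = dt)
}

#' Two-state Markov shell-occupancy series
#'
#' Each molecule is inside or outside a region; per frame it stays inside
#' with probability `p_stay` and enters from outside with probability
#' `p_enter`.  Completed stays are geometrically distributed, so the analytic
#' mean residence time is `dt / (1 - p_stay)` -- the ground truth for the
#' residence-time estimator.  Initial states are drawn from the stationary
#' distribution (all absent when `p_enter = 0`).
#'
#' @param p_stay per-frame probability of remaining in the region; must be
#'   `< 1`.
#' @param p_enter per-frame entry probability.
#' @param n_molecules,n_frames series dimensions.
#' @param dt frame spacing (ps).
#' @param seed RNG seed.
#' @return list with `series` (logical `n_molecules x n_frames` matrix),
#'   `dt`, and `analytic_mrt` (`dt / (1 - p_stay)`).
#' @export
generate_markov_occupancy <- function(p_stay, p_enter, n_molecules, n_frames,
                                      dt = 0.1, seed = 1) {
  if (p_stay >= 1) stop("p_stay must be < 1")
  if (p_stay < 0 || p_enter < 0 || p_enter > 1) stop("probabilities must lie in [0,1]")
  series <- .with_seed(seed, {
    s <- matrix(FALSE, n_molecules, n_frames)
    p0 <- if (p_enter == 0) 0 else p_enter / (p_enter + 1 - p_stay)
    state <- runif(n_molecules) < p0
    s[, 1] <- state
    for (f in seq_len(n_frames - 1L)) {
      u <- runif(n_molecules)
      state <- ifelse(state, u < p_stay, u < p_enter)
      s[, f + 1L] <- state
    }
    s
  })
  list(series = series, dt = dt, analytic_mrt = dt / (1 - p_stay))
}

#' Ideal straight double-helix fixture
#'
#' A rigid idealized B-form duplex along the z axis: per base-pair level each
#' strand carries P, OP1 and C1' atoms at canonical-like cylindrical radii;
#' optional minor-groove atoms (N3, O2, and N2/H21/H22 on every third level)
#' sit on the minor-groove side.  Strand II is antiparallel (residue j of
#' strand II occupies level `n_bp + 1 - j`).  The geometry is exact, so
#' derived quantities (axis, end-to-end distance, groove side, helicoidal
#' angles) have closed-form values.
#'
#' @param n_bp number of base pairs (>= 4).
#' @param rise axial rise per base pair (Angstrom).
#' @param twist helical twist per base pair (degrees).
#' @param groove_atoms include minor-groove atoms.
#' @param b box; default comfortably larger than the helix.
#' @return a single-frame [trajectory()] whose topology is two SOLUTE
#'   strands.
#' @export
generate_helix_fixture <- function(n_bp, rise = 3.38, twist = 36,
                                   groove_atoms = FALSE, b = NULL) {
  if (n_bp < 4) stop("n_bp must be >= 4")
  r_p <- 8.91; r_op <- 9.8; r_c1 <- 5.9; r_g <- 5.0
  ## phosphates sit +-77 deg around the minor-groove bisector; C1' pairs are
  ## diametral so base-pair midpoints lie exactly on the axis
  ph_p <- 77; ph_c1 <- 90
  lev_z <- (seq_len(n_bp) - 1) * rise
  lev_phi <- (seq_len(n_bp) - 1) * twist * pi / 180
  cyl <- function(r, phi, z) c(r * cos(phi), r * sin(phi), z)
  deg <- pi / 180

  add <- function(acc, nm, pos) {
    acc$name <- c(acc$name, nm)
    acc$pos <- rbind(acc$pos, pos)
    acc
  }
  build_strand <- function(strand) {
    acc <- list(name = character(), pos = NULL, resid = integer())
    for (j in seq_len(n_bp)) {
      lev <- if (strand == 1) j else n_bp + 1L - j    # antiparallel partner
      sgn <- if (strand == 1) 1 else -1
      phi <- lev_phi[lev]; z <- lev_z[lev]
      names0 <- length(acc$name)
      acc <- add(acc, "P", cyl(r_p, phi + sgn * ph_p * deg, z))
      acc <- add(acc, "OP1", cyl(r_op, phi + sgn * (ph_p + 8) * deg, z))
      acc <- add(acc, "C1'", cyl(r_c1, phi + sgn * ph_c1 * deg, z))
      if (groove_atoms) {
        if (strand == 1) {
          acc <- add(acc, "N3", cyl(r_g, phi, z))
          if (j %% 3 == 0) {
            acc <- add(acc, "N2", cyl(r_g - 0.8, phi + 12 * deg, z))
            acc <- add(acc, "H21", cyl(r_g - 0.1, phi + 20 * deg, z + 0.3))
            acc <- add(acc, "H22", cyl(r_g - 0.1, phi + 24 * deg, z - 0.3))
          }
        } else {
          acc <- add(acc, "O2", cyl(r_g, phi - 8 * deg, z))
        }
      }
      acc$resid <- c(acc$resid, rep(j, length(acc$name) - names0))
    }
    acc
  }
  s1 <- build_strand(1)
  s2 <- build_strand(2)
  name <- c(s1$name, s2$name)
  pos <- rbind(s1$pos, s2$pos)
  resid <- c(s1$resid, s2$resid)
  chain <- rep(c("A", "B"), c(length(s1$name), length(s2$name)))
  n <- length(name)
  if (is.null(b)) {
    span <- max(lev_z) + 40
    b <- box(60, 60, max(60, span))
  }
  b <- as_box(b)
  ## center the helix in the box
  pos <- sweep(pos, 2, as.numeric(b) / 2 - c(0, 0, max(lev_z) / 2), "+")
  top <- make_topology(name = name, resname = rep("DNA", n), resid = resid,
                       species = rep("SOLUTE", n), chain = chain,
                       positions = pos)
  trajectory(top, array(pos, dim = c(n, 3, 1)), b)
}

#' Constructed donor--hydrogen--acceptor geometry
#'
#' Builds a single frame holding one hydroxyl-like donor (O-H, bond length
#' 0.9572 Angstrom) and one acceptor oxygen placed so that the donor-acceptor
#' distance is exactly `d` and the D-H-A angle (at the hydrogen) is exactly
#' `angle` -- a boundary fixture for the hydrogen-bond detector.
#'
#' @param d donor-acceptor distance (Angstrom), > 0.
#' @param angle D-H-A angle in degrees, in \[0, 180\].
#' @param b box (default 50 Angstrom cube; fixture sits at the center).
#' @return a single-frame [trajectory()] of two water-class molecules.
#' @export
generate_hbond_fixture <- function(d, angle, b = box(50, 50, 50)) {
  if (d <= 0) stop("d must be positive")
  if (angle < 0 || angle > 180) stop("angle must lie in [0, 180] degrees")
  b <- as_box(b)
  bond <- 0.9572
  beta <- (180 - angle) * pi / 180
  ## solve |D->A| = d with A on the ray from H at angle beta from the H->D
  ## back-direction
  L <- -bond * cos(beta) + sqrt(bond^2 * cos(beta)^2 - bond^2 + d^2)
  ctr <- as.numeric(b) / 2
  D <- ctr
  H <- ctr + c(bond, 0, 0)
  A <- H + L * c(cos(beta), sin(beta), 0)
  pos <- rbind(D, H, A)
  top <- make_topology(name = c("O", "H1", "O"),
                       resname = c("DON", "DON", "ACC"),
                       resid = c(1L, 1L, 2L),
                       species = rep("WATER", 3),
                       element = c("O", "H", "O"),
                       positions = pos)
  trajectory(top, array(pos, dim = c(3, 3, 1)), b)
}

#' Independent Brownian walkers
#'
#' Per-axis displacements are i.i.d. normal with variance `2 * d0 * dt`, so
#' the mean squared displacement is `6 * d0 * t` and the diffusion estimator
#' should recover `d0`.  Coordinates are unwrapped (the box is metadata
#' only).
#'
#' @param n number of particles.
#' @param d0 diffusion coefficient (Angstrom^2/ps).
#' @param n_frames frames.
#' @param dt frame spacing (ps).
#' @param seed RNG seed.
#' @param b box used as metadata.
#' @return a [trajectory()].
#' @export
generate_brownian_box <- function(n, d0, n_frames, dt = 0.1, seed = 1,
                                  b = box(1000, 1000, 1000)) {
  b <- as_box(b)
  top <- .single_site_water_topology(n)
  coords <- .with_seed(seed, {
    arr <- array(0, dim = c(n, 3, n_frames))
    arr[, , 1] <- matrix(runif(n * 3), n, 3) * rep(as.numeric(b), each = n)
    sdv <- sqrt(2 * d0 * dt)
    for (f in 2:n_frames)
      arr[, , f] <- arr[, , f - 1] + matrix(rnorm(n * 3, sd = sdv), n, 3)
    arr
  })
  trajectory(top, coords, b, dt = dt)
}

#' Rigid three-site water block
#'
#' A set of rigid TIP3P-like waters (O-H 0.9572 Angstrom, H-O-H 104.52
#' degrees) with random positions and orientations, with charges and
#' Lennard-Jones parameters, for exercising the energetics stages.
#'
#' @param n number of waters.
#' @param b a [box()].
#' @param n_frames frames (i.i.d. placements).
#' @param seed RNG seed.
#' @param q_o,q_h site charges (e).
#' @param sigma_o,eps_o oxygen LJ parameters (Angstrom, kcal/mol).
#' @param dt frame spacing (ps).
#' @return a [trajectory()].
#' @export
generate_water3_box <- function(n, b, n_frames = 1, seed = 1,
                                q_o = -0.834, q_h = 0.417,
                                sigma_o = 3.15061, eps_o = 0.1521, dt = 1) {
  b <- as_box(b)
  bl <- as.numeric(b)
  bond <- 0.9572
  half <- 104.52 / 2 * pi / 180
  base <- rbind(c(0, 0, 0),
                bond * c(sin(half), cos(half), 0),
                bond * c(-sin(half), cos(half), 0))
  coords <- .with_seed(seed, {
    arr <- array(0, dim = c(3 * n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      for (i in seq_len(n)) {
        R <- .random_rotation()
        org <- runif(3) * bl
        arr[(3 * i - 2):(3 * i), , f] <- sweep(base %*% t(R), 2, org, "+")
      }
    }
    arr
  })
  top <- make_topology(
    name = rep(c("O", "H1", "H2"), n),
    resname = rep("WAT", 3 * n),
    resid = rep(seq_len(n), each = 3),
    species = rep("WATER", 3 * n),
    element = rep(c("O", "H", "H"), n),
    charge = rep(c(q_o, q_h, q_h), n),
    sigma = rep(c(sigma_o, 0, 0), n),
    epsilon = rep(c(eps_o, 0, 0), n),
    bonded_heavy = as.integer(rep(c(NA, 0, 0), n) + rep(3 * seq_len(n) - 2, each = 3)))
  trajectory(top, coords, b, dt = dt)
}

.random_rotation <- function() {
  ## uniform random rotation via normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
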