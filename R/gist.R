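## Voxel-based inhomogeneous solvation thermodynamics.  Per frame, every
## water whose oxygen falls inside the grid contributes its full interaction
## energy with the (restrained) solute to its voxel's E_sw, and HALF of its
## interaction with every other water to E_ww -- so voxel/region sums are
## additive and the pair energy is conserved.  The per-water reference
## comparison against the neat-water value Eww0 doubles the region sum,
## because Eww0 is the full per-water interaction energy.

COULOMB_K <- 332.0636  # kcal * Angstrom / (mol * e^2)
K_BOLTZ <- 0.0019872041  # kcal / (mol * K)

#' Create an empty voxel grid
#'
#' @param origin 3-vector, corner of the grid (Angstrom).
#' @param spacing cubic voxel edge (Angstrom, default 0.5).
#' @param dims integer 3-vector of voxel counts.
#' @return object of class `voxel_grid` with per-voxel accumulators `n_k`
#'   (visit counts), `e_sw`, `e_ww` (kcal/mol sums) and `n_frames`.
#' @export
voxel_grid <- function(origin, spacing = 0.5, dims) {
  dims <- as.integer(dims)
  if (length(origin) != 3 || length(dims) != 3 || any(dims < 1))
    stop("origin and dims must be 3-vectors, dims positive")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims,
                 n_k = array(0, dims), e_sw = array(0, dims),
                 e_ww = array(0, dims), n_frames = 0L),
            class = "voxel_grid")
}

#' Grid covering a set of points with a margin
#'
#' @param points n x 3 coordinate matrix (e.g. the solute).
#' @param spacing voxel edge (Angstrom).
#' @param margin padding beyond the bounding box (Angstrom).
#' @export
grid_around <- function(points, spacing = 0.5, margin = 4) {
  lo <- apply(points, 2, min) - margin
  hi <- apply(points, 2, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  voxel_grid(lo, spacing, dims)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dims, collapse = " x "), "voxels of",
      x$spacing, "A;", x$n_frames, "frames accumulated\n")
  invisible(x)
}

## voxel linear index of positions; NA when outside the grid
.voxel_index <- function(grid, pos) {
  ijk <- floor(sweep(sweep(pos, 2, grid$origin), 2, grid$spacing, "/"))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$dims[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$dims[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$dims[3]
  idx <- 1 + ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3])
  idx[!ok] <- NA
  as.integer(idx)
}

## pair-energy matrix (Coulomb + 12-6 LJ, Lorentz-Berthelot) between
## row atoms i (charges qi, sigma si, eps ei at Pi) and column atoms j
.energy_matrix <- function(Pi, qi, si, ei, Pj, qj, sj, ej, b, r_cut = NULL) {
  r <- .pbc_dist_mat(Pi, Pj, b)
  r[r < 1e-12] <- NA
  E <- COULOMB_K * outer(qi, qj) / r
  eps <- sqrt(outer(ei, ej))
  lj_on <- eps > 0
  if (any(lj_on)) {
    sig <- outer(si, sj, "+") / 2
    sr6 <- (sig / r)^6
    E <- E + ifelse(lj_on, 4 * eps * (sr6^2 - sr6), 0)
  }
  if (!is.null(r_cut)) E[r > r_cut] <- 0
  E[is.na(E)] <- 0
  E
}

#' Accumulate waters and energies into a voxel grid
#'
#' The solute must be identical in every frame (a restrained solute), and no
#' solvent species other than water may be present (strip crowders and ions
#' first with [strip_species()]).  Each frame, every water whose oxygen lies
#' in a voxel adds 1 to that voxel's visit count, its full solute interaction
#' to `e_sw`, and half of its interaction with every other water (in-grid or
#' not) to `e_ww`.
#'
#' @param traj a [trajectory()] containing only SOLUTE and WATER species.
#' @param grid a [voxel_grid()].
#' @param r_cut optional interaction cutoff (Angstrom); default: full
#'   minimum-image sum.
#' @param tol allowed per-atom solute drift between frames (Angstrom).
#' @return the populated grid.
#' @export
gist_accumulate <- function(traj, grid, r_cut = NULL, tol = 1e-6) {
  a <- traj$topology$atoms
  other <- setdiff(unique(a$species), c("SOLUTE", "WATER"))
  if (length(other))
    stop("non-water solvent present (", paste(other, collapse = ", "),
         "); strip crowders/ions before voxel analysis")
  sol <- which(a$species == "SOLUTE")
  wat <- which(a$species == "WATER")
  if (!length(wat)) stop("no water in trajectory")
  wmol <- a$mol_id[wat]
  ox <- wat[toupper(a$element[wat]) == "O"]
  ox <- ox[!duplicated(a$mol_id[ox])]          # one oxygen per water
  if (length(ox) != length(unique(wmol)))
    stop("every water molecule needs an oxygen site for voxel assignment")
  oxmol <- a$mol_id[ox]
  nf <- n_frames(traj)
  if (length(sol) && nf > 1) {
    drift <- max(abs(traj$coords[sol, , , drop = FALSE] -
                       c(traj$coords[sol, , 1])))
    if (drift > tol)
      stop("solute moves between frames (max drift ", signif(drift, 3),
           " A > tol); voxel analysis requires a restrained solute")
  }
  trivial_energy <- all(a$charge[c(sol, wat)] == 0) &&
    all(a$epsilon[c(sol, wat)] == 0)
  for (f in seq_len(nf)) {
    pos <- frame_coords(traj, f)
    b <- traj$boxes[f, ]
    vi <- .voxel_index(grid, pos[ox, , drop = FALSE])
    ing <- !is.na(vi)
    if (any(ing)) {
      tab <- tabulate(vi[ing], nbins = prod(grid$dims))
      grid$n_k <- grid$n_k + array(tab, grid$dims)
    }
    if (!trivial_energy && any(ing)) {
      ## per-water solute-water energy
      e_sw_w <- numeric(length(ox))
      if (length(sol)) {
        Em <- .energy_matrix(pos[wat, , drop = FALSE], a$charge[wat],
                             a$sigma[wat], a$epsilon[wat],
                             pos[sol, , drop = FALSE], a$charge[sol],
                             a$sigma[sol], a$epsilon[sol], b, r_cut)
        per_atom <- rowSums(Em)
        e_sw_w <- as.numeric(rowsum(per_atom, wmol)[as.character(oxmol), ])
      }
      ## per-water half water-water energy
      Eww <- .energy_matrix(pos[wat, , drop = FALSE], a$charge[wat],
                            a$sigma[wat], a$epsilon[wat],
                            pos[wat, , drop = FALSE], a$charge[wat],
                            a$sigma[wat], a$epsilon[wat], b, r_cut)
      Eww[outer(wmol, wmol, "==")] <- 0
      per_atom <- rowSums(Eww)
      e_ww_w <- 0.5 * as.numeric(rowsum(per_atom, wmol)[as.character(oxmol), ])
      idx <- vi[ing]
      add_to <- function(acc, vals) {
        rs <- rowsum(vals, idx)
        flat <- numeric(prod(grid$dims))
        flat[as.integer(rownames(rs))] <- rs
        acc + array(flat, grid$dims)
      }
      grid$e_sw <- add_to(grid$e_sw, e_sw_w[ing])
      grid$e_ww <- add_to(grid$e_ww, e_ww_w[ing])
    }
    grid$n_frames <- grid$n_frames + 1L
  }
  grid
}

#' Per-voxel dimensionless water density
#'
#' `g_k = N_k / (rho0 * V_k * N_f)`, zero where a voxel was never visited.
#'
#' @param grid a populated [voxel_grid()].
#' @param rho0 bulk water number density (molecules/Angstrom^3).
#' @return array of `g` values with the grid's dimensions.
#' @export
voxel_g <- function(grid, rho0) {
  if (grid$n_frames < 1) stop("grid has no accumulated frames")
  if (rho0 <= 0) stop("rho0 must be positive")
  grid$n_k / (rho0 * grid$spacing^3 * grid$n_frames)
}

#' Assemble the per-water solvation free energy
#'
#' `dG = dE_sw + dE_ww - TdS_trans`, the normalized free energy per water in
#' a region relative to bulk, with the orientational entropy term excluded.
#'
#' @param de_sw,de_ww,tds_trans component values in kcal/mol per water.
#' @return kcal/mol per water.
#' @examples
#' gist_free_energy(-4.0760, 2.5469, -0.2313) # -1.2978
#' @export
gist_free_energy <- function(de_sw, de_ww, tds_trans) {
  de_sw + de_ww - tds_trans
}

#' Region thermodynamics from a voxel grid
#'
#' Sums the voxel accumulators over a region and normalizes per water:
#' mean water count `N_R = sum N_k / N_f`;
#' `dE_sw = sum E_sw_k / (N_f * N_R)`;
#' `dE_ww = 2 * sum E_ww_k / (N_f * N_R) - Eww0` (the half-assignment
#' convention undone against the full per-water bulk reference);
#' `TdS_trans = -kB * T * sum (N_k/N_f) * ln g_k / N_R` (first-order
#' translational term); and `dG = dE_sw + dE_ww - TdS_trans`.
#'
#' @param grid a populated [voxel_grid()].
#' @param rho0 bulk water density (molecules/Angstrom^3).
#' @param eww0 mean water-water interaction energy per water in neat water
#'   (kcal/mol), the energy reference.
#' @param temperature absolute temperature (K, default 300).
#' @param mask optional logical array (grid dims) defining the region;
#'   default: the whole grid.
#' @return object of class `gist_summary` with `tds_trans`, `de_sw`,
#'   `de_ww`, `dg_norm`, `mean_water_count` and the reference constants.
#' @export
gist_region_summary <- function(grid, rho0, eww0, temperature = 300,
                                mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, grid$dims)
  if (!any(mask)) stop("empty region mask")
  nf <- grid$n_frames
  n_mean <- sum(grid$n_k[mask]) / nf
  if (n_mean <= 0) stop("no waters observed in the region")
  g <- voxel_g(grid, rho0)
  occ <- mask & grid$n_k > 0
  tds <- -K_BOLTZ * temperature *
    sum((grid$n_k[occ] / nf) * log(g[occ])) / n_mean
  de_sw <- sum(grid$e_sw[mask]) / (nf * n_mean)
  de_ww <- 2 * sum(grid$e_ww[mask]) / (nf * n_mean) - eww0
  structure(list(tds_trans = tds, de_sw = de_sw, de_ww = de_ww,
                 dg_norm = gist_free_energy(de_sw, de_ww, tds),
                 mean_water_count = n_mean, rho0 = rho0, eww0 = eww0,
                 temperature = temperature),
            class = "gist_summary")
}

#' @export
print.gist_summary <- function(x, ...) {
  cat(sprintf(
    "per-water region thermodynamics (kcal/mol):\n  dE_sw = %.4f  dE_ww = %.4f  TdS_trans = %.4f  dG = %.4f\n  mean waters in region: %.2f\n",
    x$de_sw, x$de_ww, x$tds_trans, x$dg_norm, x$mean_water_count))
  invisible(x)
}

#' Count molecules of a species within a margin of the solute surface
#'
#' Molecule-level any-atom membership, e.g. crowders within 15 Angstrom of
#' the solute for binding-free-energy normalization.
#'
#' @inheritParams shell_membership
#' @param margin distance from the solute surface (Angstrom, default 15).
#' @param species species class to count (default CROWDER).
#' @return integer count.
#' @export
count_within_margin <- function(traj, frame = 1L, solute_sel, margin = 15,
                                species = "CROWDER") {
  mem <- shell_membership(traj, frame, solute_sel, cutoff = margin,
                          water_probe = "all")
  length(mem[[species]])
}

#' Binding free energy per crowder from end-state components
#'
#' Per snapshot,
#' `dG_bind = (E_complex + G_complex) - (E_solute + G_solute) -
#'  (E_crowders + G_crowders)`, divided by the number of crowders within the
#' margin (`n_c`), then averaged over snapshots.  The solvation terms are
#' supplied externally (e.g. from an integral-equation solvent model).
#'
#' @param components data frame with columns `e_complex, g_complex, e_solute,
#'   g_solute, e_crowders, g_crowders, n_c` (one row per snapshot).
#' @return list with `mean`, `sd` (kcal/mol per crowder) and `per_snapshot`.
#' @export
binding_free_energy <- function(components) {
  need <- c("e_complex", "g_complex", "e_solute", "g_solute",
            "e_crowders", "g_crowders", "n_c")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing component column(s): ",
                         paste(miss, collapse = ", "))
  if (any(components$n_c <= 0)) stop("n_c must be positive in every snapshot")
  dg <- with(components,
             (e_complex + g_complex) - (e_solute + g_solute) -
               (e_crowders + g_crowders))
  per <- dg / components$n_c
  list(mean = mean(per), sd = if (length(per) > 1) sd(per) else 0,
       per_snapshot = per)
}
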