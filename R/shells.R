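## Solvation-shell membership, replacement statistics, residence times and
## diffusion.  "Solute surface" means every solute atom, hydrogens included;
## a solvent molecule is a shell member when any of its probe atoms lies
## within the cutoff (molecule-level, any-atom rule).

.probe_atoms <- function(atoms, water_probe = "O") {
  idx <- which(atoms$species %in% c("WATER", "CROWDER", "CATION", "ANION"))
  if (identical(water_probe, "O")) {
    drop <- atoms$species == "WATER" & toupper(atoms$element) != "O"
    ## keep all atoms of waters that have no oxygen at all (unusual topologies)
    has_o <- tapply(toupper(atoms$element) == "O", atoms$mol_id, any)
    drop <- drop & has_o[atoms$mol_id]
    idx <- idx[!drop[idx]]
  }
  idx
}

#' Solvation-shell membership for one frame
#'
#' A molecule belongs to the shell when the minimum-image distance from any
#' of its probe atoms to any atom of the solute selection is `<= cutoff`.
#' The default probe is the oxygen for water molecules and every atom for
#' other species.
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param solute_sel atom indices defining the surface (non-empty).
#' @param cutoff shell cutoff in Angstrom (default 3.5).
#' @param water_probe `"O"` (default) or `"all"`.
#' @return named list of member molecule-id vectors per species
#'   (WATER, CROWDER, CATION, ANION).
#' @export
shell_membership <- function(traj, frame = 1L, solute_sel, cutoff = 3.5,
                             water_probe = "O") {
  if (!length(solute_sel)) stop("empty solute selection")
  a <- traj$topology$atoms
  probe <- .probe_atoms(a, water_probe)
  pos <- frame_coords(traj, frame)
  b <- traj$boxes[frame, ]
  out <- list(WATER = integer(), CROWDER = integer(),
              CATION = integer(), ANION = integer())
  if (!length(probe)) return(out)
  dmin <- .min_dist_to_set(pos[probe, , drop = FALSE],
                           pos[solute_sel, , drop = FALSE], b)
  hit <- probe[dmin <= cutoff]
  for (sp in names(out))
    out[[sp]] <- sort(unique(a$mol_id[hit][a$species[hit] == sp]))
  out
}

#' Per-frame shell occupancy series
#'
#' @inheritParams shell_membership
#' @param frames frame indices (default all).
#' @return object of class `shell_series`: per-frame counts per species plus
#'   means and standard deviations.
#' @export
shell_series <- function(traj, solute_sel, cutoff = 3.5, water_probe = "O",
                         frames = seq_len(n_frames(traj))) {
  counts <- t(vapply(frames, function(f) {
    m <- shell_membership(traj, f, solute_sel, cutoff, water_probe)
    lengths(m)
  }, numeric(4)))
  colnames(counts) <- c("WATER", "CROWDER", "CATION", "ANION")
  structure(list(frames = frames, counts = counts,
                 mean = colMeans(counts), sd = apply(counts, 2, sd),
                 cutoff = cutoff),
            class = "shell_series")
}

#' @export
print.shell_series <- function(x, ...) {
  cat("shell series (cutoff", x$cutoff, "A):\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  invisible(x)
}

#' Waters replaced per crowder molecule
#'
#' The mean depletion of shell waters relative to the crowder-free system,
#' per crowder present in the shell:
#' `(n_ref_water - n_crowded_water) / n_crowder`.
#'
#' @param n_ref_water mean shell water count of the reference (0% crowder)
#'   system.
#' @param n_crowded_water mean shell water count of the crowded system.
#' @param n_crowder mean shell crowder count of the crowded system (> 0).
#' @return waters replaced per crowder.
#' @examples
#' replacement_ratio(743.09, 470.32, 134.44) # ~2.03
#' @export
replacement_ratio <- function(n_ref_water, n_crowded_water, n_crowder) {
  if (n_crowder <= 0) stop("n_crowder must be positive")
  (n_ref_water - n_crowded_water) / n_crowder
}

#' Atoms lining the minor-groove water spine
#'
#' Selects the minor-groove donor/acceptor atoms (N3, N2, H21, H22, O2) of
#' the solute.
#'
#' @param topology a [make_topology()] topology.
#' @return integer atom indices.
#' @export
spine_atoms <- function(topology) {
  a <- topology$atoms
  which(a$species == "SOLUTE" & a$name %in% c("N3", "N2", "H21", "H22", "O2"))
}

#' Minor-groove spine membership for one frame
#'
#' Same molecule-level any-probe-atom rule as [shell_membership()], with the
#' surface restricted to the minor-groove spine atoms.
#'
#' @inheritParams shell_membership
#' @param spine_sel spine atom indices (default: [spine_atoms()] of the
#'   topology).
#' @export
spine_membership <- function(traj, frame = 1L,
                             spine_sel = spine_atoms(traj$topology),
                             cutoff = 3.5, water_probe = "O") {
  if (!length(spine_sel)) stop("no spine atoms in topology")
  shell_membership(traj, frame, spine_sel, cutoff, water_probe)
}

#' Occupancy matrix of a region over a trajectory
#'
#' @inheritParams shell_membership
#' @param species species class whose molecules are tracked.
#' @param frames frame indices.
#' @return logical matrix, one row per molecule of `species` (rownames are
#'   molecule ids), one column per frame.
#' @export
occupancy_matrix <- function(traj, solute_sel, cutoff = 3.5,
                             species = "WATER", water_probe = "O",
                             frames = seq_len(n_frames(traj))) {
  a <- traj$topology$atoms
  mols <- sort(unique(a$mol_id[a$species == species]))
  occ <- matrix(FALSE, length(mols), length(frames),
                dimnames = list(mols, NULL))
  for (i in seq_along(frames)) {
    mem <- shell_membership(traj, frames[i], solute_sel, cutoff, water_probe)
    occ[match(mem[[species]], mols), i] <- TRUE
  }
  occ
}

#' Residence times and mean residence time from an occupancy series
#'
#' A stay is a maximal run of consecutive frames in which a molecule occupies
#' the region.  Stays touching the start or end of the series are flagged
#' censored; by default they are included in the mean residence time
#' (excluding them biases the MRT low).
#'
#' @param occupancy logical matrix, molecules x frames (see
#'   [occupancy_matrix()] or [generate_markov_occupancy()]).
#' @param dt frame spacing in ps.
#' @param include_censored include boundary-touching stays in the MRT.
#' @param threshold optional duration (ps); the fraction of stays exceeding
#'   it is reported as `fraction_exceeding`.
#' @return object of class `residence`: `records` (molecule, entry frame,
#'   exit frame (exclusive), duration ps, censored), `mrt`, `n_stays`, and
#'   optionally `fraction_exceeding`.  With no stays at all, `mrt` is `NA`
#'   with a warning.
#' @export
residence_times <- function(occupancy, dt, include_censored = TRUE,
                            threshold = NULL) {
  if (dt <= 0) stop("dt must be positive")
  occupancy <- as.matrix(occupancy)
  nf <- ncol(occupancy)
  recs <- vector("list", nrow(occupancy))
  for (m in seq_len(nrow(occupancy))) {
    r <- rle(as.logical(occupancy[m, ]))
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    inside <- which(r$values)
    recs[[m]] <- data.frame(
      molecule = m, entry = starts[inside], exit = ends[inside] + 1L,
      duration = r$lengths[inside] * dt,
      censored = starts[inside] == 1L | ends[inside] == nf)
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    warning("no stays in the occupancy series; MRT undefined")
    return(structure(list(records = NULL, mrt = NA_real_, n_stays = 0L,
                          dt = dt), class = "residence"))
  }
  use <- if (include_censored) rep(TRUE, nrow(records)) else !records$censored
  mrt <- if (any(use)) mean(records$duration[use]) else NA_real_
  out <- list(records = records, mrt = mrt, n_stays = nrow(records), dt = dt)
  if (!is.null(threshold))
    out$fraction_exceeding <- mean(records$duration > threshold)
  structure(out, class = "residence")
}

#' @export
print.residence <- function(x, ...) {
  cat("residence:", x$n_stays, "stays, MRT =", signif(x$mrt, 4), "ps\n")
  invisible(x)
}

## rebuild the boolean occupancy series from residence records (round-trip
## check used by the tests)
reconstruct_occupancy <- function(records, n_molecules, n_frames) {
  occ <- matrix(FALSE, n_molecules, n_frames)
  for (i in seq_len(nrow(records)))
    occ[records$molecule[i], records$entry[i]:(records$exit[i] - 1L)] <- TRUE
  occ
}

#' Diffusion coefficient from mean squared displacement
#'
#' Computes MSD(tau) over lag times inside `fit_window` (non-overlapping time
#' origins by default) and fits a line; the Einstein relation gives
#' `D = slope / 6`.  Coordinates must be unwrapped.  A poor linear fit
#' (R^2 below `r2_warn`, e.g. ballistic motion) is flagged with a warning.
#'
#' @param traj a [trajectory()] with unwrapped coordinates.
#' @param sel atom indices to track.
#' @param fit_window lag-time range `c(t_min, t_max)` in ps.
#' @param origins `"nonoverlapping"` (default) or `"overlapping"`.
#' @param r2_warn R^2 threshold below which the fit is flagged.
#' @return list with `D` (Angstrom^2/ps), `msd` data frame (tau, msd),
#'   `r_squared`, and `fit` (the `lm` object).
#' @export
msd_diffusion <- function(traj, sel = seq_len(traj$topology$n_atoms),
                          fit_window, origins = c("nonoverlapping",
                                                  "overlapping"),
                          r2_warn = 0.99) {
  origins <- match.arg(origins)
  nf <- n_frames(traj)
  lags <- seq_len(nf - 1L)
  lags <- lags[lags * traj$dt >= fit_window[1] & lags * traj$dt <= fit_window[2]]
  if (length(lags) < 2)
    stop("fit_window must contain at least two lag times within the trajectory")
  X <- traj$coords[sel, , , drop = FALSE]
  msd <- vapply(lags, function(lag) {
    org <- if (origins == "nonoverlapping") seq(1L, nf - lag, by = lag)
           else seq_len(nf - lag)
    acc <- 0
    for (t0 in org) {
      d <- X[, , t0 + lag] - X[, , t0]
      acc <- acc + mean(rowSums(d * d))
    }
    acc / length(org)
  }, 0)
  tau <- lags * traj$dt
  fit <- lm(msd ~ tau)
  r2 <- summary(fit)$r.squared
  if (is.na(r2)) r2 <- 1   # zero-variance MSD (e.g. static particles)
  if (r2 < r2_warn)
    warning("MSD is not linear over the fit window (R^2 = ",
            signif(r2, 4), "); diffusive regime questionable")
  list(D = unname(coef(fit)[2] / 6), msd = data.frame(tau = tau, msd = msd),
       r_squared = r2, fit = fit)
}
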