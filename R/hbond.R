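#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: a donor-heavy/hydrogen/acceptor triple is a hydrogen
#' bond when the minimum-image donor-acceptor distance is `<= d_cut` and the
#' D-H-A angle, measured at the hydrogen, is `>= angle_cut` (both cutoffs
#' inclusive).  A donor with two hydrogens may bond two distinct acceptors,
#' but a given (donor, acceptor) pair is reported once per frame even if both
#' hydrogens qualify.
#'
#' @param traj a [trajectory()] whose topology carries donor/acceptor flags.
#' @param frame frame index.
#' @param d_cut donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param angle_cut D-H-A angle cutoff (degrees, default 135).
#' @return data frame with columns `donor_heavy, hydrogen, acceptor, d_da,
#'   angle_dha, frame`, ordered by (donor, acceptor).
#' @export
detect_hbonds <- function(traj, frame = 1L, d_cut = 3.5, angle_cut = 135) {
  a <- traj$topology$atoms
  if (!any(a$is_donor_heavy) || !any(a$is_acceptor))
    stop("topology lacks donor/acceptor annotation")
  hyd <- which(a$is_hydrogen & !is.na(a$bonded_heavy))
  hyd <- hyd[a$is_donor_heavy[a$bonded_heavy[hyd]]]
  acc <- which(a$is_acceptor)
  pos <- frame_coords(traj, frame)
  b <- traj$boxes[frame, ]
  if (!length(hyd) || !length(acc)) return(.empty_hbonds())

  don <- a$bonded_heavy[hyd]
  dmat <- .pbc_dist_mat(pos[don, , drop = FALSE], pos[acc, , drop = FALSE], b)
  ## inclusive cutoffs, robust to round-off on exact-boundary geometries
  cand <- which(dmat <= d_cut + 1e-9 & outer(don, acc, "!="), arr.ind = TRUE)
  if (!nrow(cand)) return(.empty_hbonds())

  hi <- hyd[cand[, 1]]
  di <- don[cand[, 1]]
  ai <- acc[cand[, 2]]
  v_hd <- .pbc_delta(pos[di, , drop = FALSE] - pos[hi, , drop = FALSE], b)
  v_ha <- .pbc_delta(pos[ai, , drop = FALSE] - pos[hi, , drop = FALSE], b)
  dot <- rowSums(v_hd * v_ha)
  nn <- sqrt(rowSums(v_hd^2) * rowSums(v_ha^2))
  ang <- acos(pmax(-1, pmin(1, dot / nn))) * 180 / pi
  ok <- ang >= angle_cut - 1e-9
  if (!any(ok)) return(.empty_hbonds())

  out <- data.frame(donor_heavy = di[ok], hydrogen = hi[ok],
                    acceptor = ai[ok], d_da = dmat[cand][ok],
                    angle_dha = ang[ok], frame = frame)
  out <- out[order(out$donor_heavy, out$acceptor, out$hydrogen), ]
  dup <- duplicated(out[, c("donor_heavy", "acceptor")])
  out <- out[!dup, ]
  rownames(out) <- NULL
  out
}

.empty_hbonds <- function() {
  data.frame(donor_heavy = integer(), hydrogen = integer(),
             acceptor = integer(), d_da = numeric(), angle_dha = numeric(),
             frame = integer())
}

.HB_CLASSES <- c("WW", "WE", "EW", "EE", "SW", "SE", "SS")

.hb_class <- function(donor_species, acceptor_species) {
  key <- paste(donor_species, acceptor_species)
  map <- c("WATER WATER" = "WW", "WATER CROWDER" = "WE",
           "CROWDER WATER" = "EW", "CROWDER CROWDER" = "EE",
           "SOLUTE WATER" = "SW", "WATER SOLUTE" = "SW",
           "SOLUTE CROWDER" = "SE", "CROWDER SOLUTE" = "SE",
           "SOLUTE SOLUTE" = "SS")
  unname(map[key])
}

#' Classify hydrogen bonds and count per class, whole-system and local
#'
#' Classes are determined by (donor species, acceptor species): WW, WE
#' (water donates to crowder), EW (crowder donates to water), EE, SW
#' (solute-water either direction), SE, SS.  A bond is LOCAL when its donor
#' heavy atom or its acceptor lies within `local_cutoff` of any solute atom.
#' Normalizers count water and crowder molecules with any atom in the region.
#'
#' @param hbonds output of [detect_hbonds()] for this frame.
#' @param traj the [trajectory()].
#' @param frame frame index the bonds belong to.
#' @param solute_sel solute atom indices (required for LOCAL counts; when
#'   `NULL` only WHOLE counts are returned).
#' @param local_cutoff local-region distance from the solute surface
#'   (Angstrom, default 7).
#' @return list with `whole` and `local` count vectors over classes, and
#'   normalizers `n_water`/`n_crowder` (whole) and `n_water_local` /
#'   `n_crowder_local`.
#' @export
classify_hbonds <- function(hbonds, traj, frame = 1L, solute_sel = NULL,
                            local_cutoff = 7) {
  a <- traj$topology$atoms
  cls <- .hb_class(a$species[hbonds$donor_heavy], a$species[hbonds$acceptor])
  whole <- vapply(.HB_CLASSES, function(k) sum(cls == k, na.rm = TRUE), 0L)
  n_water <- length(unique(a$mol_id[a$species == "WATER"]))
  n_crowder <- length(unique(a$mol_id[a$species == "CROWDER"]))
  out <- list(whole = whole, n_water = n_water, n_crowder = n_crowder)
  if (!is.null(solute_sel)) {
    if (!length(solute_sel)) stop("empty solute selection")
    pos <- frame_coords(traj, frame)
    b <- traj$boxes[frame, ]
    S <- pos[solute_sel, , drop = FALSE]
    probe <- sort(unique(c(hbonds$donor_heavy, hbonds$acceptor)))
    near <- logical(nrow(pos))
    if (length(probe))
      near[probe] <- .min_dist_to_set(pos[probe, , drop = FALSE], S, b) <= local_cutoff
    is_local <- near[hbonds$donor_heavy] | near[hbonds$acceptor]
    local <- vapply(.HB_CLASSES, function(k)
      sum(cls == k & is_local, na.rm = TRUE), 0L)
    solv <- which(a$species %in% c("WATER", "CROWDER"))
    dmin <- .min_dist_to_set(pos[solv, , drop = FALSE], S, b)
    in_reg <- unique(a$mol_id[solv][dmin <= local_cutoff])
    out$local <- local
    out$n_water_local <- sum(tapply(a$species, a$mol_id, `[`, 1)[in_reg] == "WATER")
    out$n_crowder_local <- sum(tapply(a$species, a$mol_id, `[`, 1)[in_reg] == "CROWDER")
  }
  out
}

#' Per-frame hydrogen-bond class counts over a trajectory
#'
#' @inheritParams classify_hbonds
#' @inheritParams detect_hbonds
#' @param frames frame indices (default all).
#' @return data frame with one row per frame: whole-system counts per class,
#'   local counts (suffix `_local`) when `solute_sel` is given, and the
#'   normalizers.
#' @export
hbond_class_series <- function(traj, solute_sel = NULL, d_cut = 3.5,
                               angle_cut = 135, local_cutoff = 7,
                               frames = seq_len(n_frames(traj))) {
  rows <- lapply(frames, function(f) {
    hb <- detect_hbonds(traj, f, d_cut, angle_cut)
    cc <- classify_hbonds(hb, traj, f, solute_sel, local_cutoff)
    row <- c(frame = f, cc$whole)
    if (!is.null(cc$local)) {
      loc <- cc$local
      names(loc) <- paste0(names(loc), "_local")
      row <- c(row, loc, n_water_local = cc$n_water_local,
               n_crowder_local = cc$n_crowder_local)
    }
    c(row, n_water = cc$n_water, n_crowder = cc$n_crowder)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Maximum continuous lifetime of hydrogen bonds
#'
#' For each (donor heavy, acceptor) pair, the longest run of consecutive
#' frames in which the bond is present (via any hydrogen of the donor),
#' multiplied by the frame spacing.  Continuity is strict: one broken frame
#' ends a run.
#'
#' @param traj a [trajectory()].
#' @param pairs optional two-column matrix / data frame of
#'   (donor_heavy, acceptor) pairs defining the universe; pairs never bonded
#'   report 0.  Default: all pairs ever observed.
#' @param d_cut,angle_cut detection cutoffs, as in [detect_hbonds()].
#' @param frames frame indices to scan.
#' @return data frame with `donor_heavy, acceptor, max_lifetime` (ps).
#' @export
hbond_max_lifetime <- function(traj, pairs = NULL, d_cut = 3.5,
                               angle_cut = 135,
                               frames = seq_len(n_frames(traj))) {
  nf <- length(frames)
  obs <- lapply(seq_along(frames), function(i) {
    hb <- detect_hbonds(traj, frames[i], d_cut, angle_cut)
    if (nrow(hb)) cbind(hb$donor_heavy, hb$acceptor, i) else NULL
  })
  obs <- do.call(rbind, obs)
  key_all <- if (!is.null(obs)) paste(obs[, 1], obs[, 2]) else character()
  if (is.null(pairs)) {
    if (is.null(obs)) return(data.frame(donor_heavy = integer(),
                                        acceptor = integer(),
                                        max_lifetime = numeric()))
    pairs <- unique(obs[, 1:2, drop = FALSE])
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  pkey <- paste(pairs[, 1], pairs[, 2])
  max_run <- setNames(numeric(length(pkey)), pkey)
  if (!is.null(obs)) {
    sp <- split(obs[, 3], key_all)
    for (k in names(sp)) {
      if (!k %in% pkey) next
      fr <- sort(sp[[k]])
      runs <- rle(cumsum(c(1L, diff(fr) != 1L)))$lengths
      max_run[k] <- max(runs)
    }
  }
  data.frame(donor_heavy = pairs[, 1], acceptor = pairs[, 2],
             max_lifetime = unname(max_run) * traj$dt)
}
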