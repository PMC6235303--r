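## Curvilinear-helicoidal coordinates (D, R, A) around a duplex axis.
## D is the continuous base-pair-level coordinate, R the perpendicular
## distance from the axis, and A the azimuth (degrees, [0, 360)) measured
## from the base-pair long-axis reference about the tangent by the
## right-hand rule.  The long-axis reference is C1'(strand II) - C1'(strand
## I), orthogonalized against the tangent, which places the minor groove of
## an ideal B-form fixture at A = 90 degrees, inside the minor-groove
## window [33, 147].

#' Build per-frame helical reference frames
#'
#' `straight_fit` fits a least-squares line through the per-level C1'-C1'
#' midpoints of the duplex; axis points are the midpoint projections onto
#' the line.  Strands are the first two solute molecules carrying C1' atoms;
#' strand II is taken antiparallel (its residue j sits at level n+1-j).
#' `supplied` accepts externally computed axes (points, tangents,
#' references per level), validated for orthonormality.
#'
#' @param traj a [trajectory()].
#' @param duplex_sel atom selection of the duplex (default: all SOLUTE).
#' @param mode `"straight_fit"` or `"supplied"`.
#' @param supplied for `mode = "supplied"`: list (one entry per frame) of
#'   lists with `points` (n x 3), `tangent` (n x 3 unit rows), `ref`
#'   (n x 3 unit rows orthogonal to tangent).
#' @param frames frame indices.
#' @return object of class `helical_frames`: `n_levels`, `frames` (indices)
#'   and `per_frame` (points, tangent rows, ref rows, axial coordinates `s`,
#'   mean `rise`).
#' @export
build_helical_frames <- function(traj, duplex_sel = NULL,
                                 mode = c("straight_fit", "supplied"),
                                 supplied = NULL,
                                 frames = seq_len(n_frames(traj))) {
  mode <- match.arg(mode)
  if (mode == "supplied") {
    stopifnot(length(supplied) == length(frames))
    for (pf in supplied) .validate_frame_set(pf)
    n <- nrow(supplied[[1]]$points)
    return(structure(list(n_levels = n, frames = frames,
                          per_frame = lapply(supplied, .finish_frame_set)),
                     class = "helical_frames"))
  }
  a <- traj$topology$atoms
  if (is.null(duplex_sel)) duplex_sel <- which(a$species == "SOLUTE")
  c1 <- duplex_sel[a$name[duplex_sel] == "C1'"]
  if (!length(c1)) stop("no C1' atoms in the duplex selection")
  mols <- unique(a$mol_id[c1])
  if (length(mols) < 2) stop("duplex requires two strands bearing C1' atoms")
  s1 <- c1[a$mol_id[c1] == mols[1]][order(a$resid[c1[a$mol_id[c1] == mols[1]]])]
  s2 <- c1[a$mol_id[c1] == mols[2]][order(a$resid[c1[a$mol_id[c1] == mols[2]]])]
  n <- length(s1)
  if (n < 4) stop("fewer than 4 base-pair levels")
  if (length(s2) != n) stop("strands have unequal C1' counts")
  s2 <- rev(s2)                       # antiparallel partner: level i <- resid n+1-i
  per_frame <- lapply(frames, function(f) {
    pos <- frame_coords(traj, f)
    P1 <- pos[s1, , drop = FALSE]
    P2 <- pos[s2, , drop = FALSE]
    mid <- (P1 + P2) / 2
    ctr <- colMeans(mid)
    sv <- svd(sweep(mid, 2, ctr))
    t_hat <- sv$v[, 1]
    s_lev <- drop(sweep(mid, 2, ctr) %*% t_hat)
    if (s_lev[n] < s_lev[1]) { t_hat <- -t_hat; s_lev <- -s_lev }
    pts <- sweep(outer(s_lev, t_hat), 2, ctr, "+")
    ref <- t(vapply(seq_len(n), function(i) {
      u <- P2[i, ] - P1[i, ]
      u <- u - sum(u * t_hat) * t_hat
      .unit(u)
    }, numeric(3)))
    list(points = pts, tangent = matrix(t_hat, n, 3, byrow = TRUE),
         ref = ref, s = s_lev, rise = mean(diff(s_lev)))
  })
  structure(list(n_levels = n, frames = frames, per_frame = per_frame),
            class = "helical_frames")
}

.validate_frame_set <- function(pf) {
  stopifnot(is.matrix(pf$points), ncol(pf$points) == 3)
  n <- nrow(pf$points)
  stopifnot(nrow(pf$tangent) == n, nrow(pf$ref) == n)
  for (i in seq_len(n)) {
    t_i <- pf$tangent[i, ]; u_i <- pf$ref[i, ]
    if (abs(sum(t_i^2) - 1) > 1e-6 || abs(sum(u_i^2) - 1) > 1e-6 ||
        abs(sum(t_i * u_i)) > 1e-6)
      stop("supplied frames not orthonormal at level ", i)
  }
  invisible(pf)
}

.finish_frame_set <- function(pf) {
  seglen <- sqrt(rowSums(diff(pf$points)^2))
  pf$s <- c(0, cumsum(seglen))
  pf$rise <- mean(seglen)
  pf
}

#' @export
print.helical_frames <- function(x, ...) {
  cat("helical_frames:", x$n_levels, "levels x", length(x$frames),
      "frames, rise =", signif(x$per_frame[[1]]$rise, 4), "A\n")
  invisible(x)
}

#' Map Cartesian positions to (D, R, A)
#'
#' Positions are projected onto the piecewise-linear axis; D is the
#' continuous level coordinate (level i at D = i), R the perpendicular
#' distance, and A the azimuth from the level's long-axis reference (the
#' level nearest to D), in degrees [0, 360).
#'
#' @param pos an m x 3 matrix (or 3-vector) of positions.
#' @param hf a [build_helical_frames()] result.
#' @param frame index into `hf$frames` (default 1).
#' @param overhang allowed extrapolation beyond the terminal levels, in
#'   levels (default 1).
#' @param on_overflow `"error"` (default) or `"na"` for positions beyond
#'   the overhang.
#' @return data frame with columns `d`, `r`, `a`.
#' @export
map_to_chc <- function(pos, hf, frame = 1L, overhang = 1,
                       on_overflow = c("error", "na")) {
  on_overflow <- match.arg(on_overflow)
  pf <- hf$per_frame[[frame]]
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  n <- hf$n_levels
  P <- pf$points
  nseg <- n - 1L
  m <- nrow(pos)
  alpha <- matrix(0, m, nseg)
  dist2 <- matrix(0, m, nseg)
  for (j in seq_len(nseg)) {
    tj <- P[j + 1, ] - P[j, ]
    lj2 <- sum(tj^2)
    rel <- sweep(pos, 2, P[j, ])
    aj <- drop(rel %*% tj) / lj2
    ac <- pmin(1, pmax(0, aj))
    foot <- outer(ac, tj)
    dd <- rel - foot
    alpha[, j] <- aj
    dist2[, j] <- rowSums(dd * dd)
  }
  best <- max.col(-dist2, ties.method = "first")
  aj <- alpha[cbind(seq_len(m), best)]
  ## unclamp only on the terminal segments (overhang region)
  a_eff <- pmin(1, pmax(0, aj))
  a_eff[best == 1L & aj < 0] <- aj[best == 1L & aj < 0]
  a_eff[best == nseg & aj > 1] <- aj[best == nseg & aj > 1]
  d <- best + a_eff
  bad <- d < 1 - overhang | d > n + overhang
  if (any(bad)) {
    if (on_overflow == "error")
      stop("position(s) beyond the axial overhang")
    d[bad] <- NA
  }
  r <- numeric(m); ang <- numeric(m)
  for (i in seq_len(m)) {
    if (is.na(d[i])) { r[i] <- NA; ang[i] <- NA; next }
    j <- best[i]
    tj <- .unit(P[j + 1, ] - P[j, ])
    foot <- P[j, ] + (d[i] - j) * (P[j + 1, ] - P[j, ])
    v <- pos[i, ] - foot
    v <- v - sum(v * tj) * tj
    r[i] <- sqrt(sum(v * v))
    lev <- min(n, max(1L, as.integer(round(d[i]))))
    u <- pf$ref[lev, ]
    u <- .unit(u - sum(u * tj) * tj)
    w <- .cross3(tj, u)
    ang[i] <- (atan2(sum(v * w), sum(v * u)) * 180 / pi) %% 360
  }
  data.frame(d = d, r = r, a = ang)
}

#' Inverse CHC mapping
#'
#' Reconstructs Cartesian positions from (D, R, A) with the same level /
#' reference conventions as [map_to_chc()]; on a straight axis the two are
#' mutual inverses to machine precision.
#'
#' @param d,r,a coordinate vectors.
#' @inheritParams map_to_chc
#' @return m x 3 matrix of positions.
#' @export
chc_to_cartesian <- function(d, r, a, hf, frame = 1L) {
  pf <- hf$per_frame[[frame]]
  n <- hf$n_levels
  P <- pf$points
  m <- length(d)
  out <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    j <- min(n - 1L, max(1L, as.integer(floor(d[i]))))
    tj <- .unit(P[j + 1, ] - P[j, ])
    foot <- P[j, ] + (d[i] - j) * (P[j + 1, ] - P[j, ])
    lev <- min(n, max(1L, as.integer(round(d[i]))))
    u <- pf$ref[lev, ]
    u <- .unit(u - sum(u * tj) * tj)
    w <- .cross3(tj, u)
    th <- a[i] * pi / 180
    out[i, ] <- foot + r[i] * (cos(th) * u + sin(th) * w)
  }
  out
}

#' CHC coordinates of selected atoms over frames
#'
#' @param traj a [trajectory()].
#' @param ion_sel atom indices to map (e.g. `select_atoms(top, "species
#'   CATION")`).
#' @param hf a [build_helical_frames()] result covering `frames`.
#' @param frames frame indices (must match `hf$frames`).
#' @param overhang extrapolation allowance (levels).
#' @return data frame with `frame, atom, d, r, a`; positions beyond the
#'   overhang get NA coordinates.
#' @export
chc_coords <- function(traj, ion_sel, hf, frames = hf$frames, overhang = 1) {
  out <- lapply(seq_along(frames), function(i) {
    fidx <- match(frames[i], hf$frames)
    co <- map_to_chc(frame_coords(traj, frames[i])[ion_sel, , drop = FALSE],
                     hf, fidx, overhang = overhang, on_overflow = "na")
    cbind(frame = frames[i], atom = ion_sel, co)
  })
  do.call(rbind, out)
}

CHC_MOLAR <- 1660.539   # Angstrom^3 * M per molecule (1 / (N_A * 1e-27))

#' Histogram ion visits in helicoidal bins and convert to molarity
#'
#' Default bin sizes follow the helicoidal-analysis convention: 1/6 level in
#' D, 0.5 Angstrom in R, 5 degrees in A.  Bin volumes use the curvilinear
#' metric `dD * rise * R_center * dA(rad) * dR`; molarity is
#' `counts / (n_frames * V_bin) * 1660.539`.
#'
#' @param coords data frame from [chc_coords()].
#' @param n_frames number of frames the counts are averaged over.
#' @param rise mean axial rise per level (Angstrom).
#' @param d_range,r_max D and R windows; A always spans [0, 360).
#' @param d_bin,r_bin,a_bin bin widths (levels, Angstrom, degrees).
#' @return object of class `chc_grid` with `counts` (3D array D x R x A),
#'   bin break vectors, `n_frames`, `rise`.
#' @export
chc_histogram <- function(coords, n_frames, rise, d_range, r_max = 10.25,
                          d_bin = 1 / 6, r_bin = 0.5, a_bin = 5) {
  db <- seq(d_range[1], d_range[2], by = d_bin)
  rb <- seq(0, r_max, by = r_bin)
  ab <- seq(0, 360, by = a_bin)
  ok <- !is.na(coords$d) & coords$d >= d_range[1] & coords$d < db[length(db)] &
    coords$r < rb[length(rb)]
  di <- findInterval(coords$d[ok], db, rightmost.closed = TRUE)
  ri <- findInterval(coords$r[ok], rb, rightmost.closed = TRUE)
  ai <- findInterval(coords$a[ok] %% 360, ab, rightmost.closed = TRUE)
  nd <- length(db) - 1L; nr <- length(rb) - 1L; na_ <- length(ab) - 1L
  counts <- array(0, c(nd, nr, na_))
  lin <- di + nd * (ri - 1L) + nd * nr * (ai - 1L)
  tab <- tabulate(lin, nbins = nd * nr * na_)
  counts <- array(tab, c(nd, nr, na_))
  structure(list(counts = counts, d_breaks = db, r_breaks = rb,
                 a_breaks = ab, n_frames = n_frames, rise = rise),
            class = "chc_grid")
}

## curvilinear bin volumes (same dims as counts)
.chc_bin_volumes <- function(grid) {
  dd <- diff(grid$d_breaks) * grid$rise
  dr <- diff(grid$r_breaks)
  rc <- (grid$r_breaks[-1] + grid$r_breaks[-length(grid$r_breaks)]) / 2
  da <- diff(grid$a_breaks) * pi / 180
  outer(dd, rc * dr, "*") %o% da
}

#' Molarity map from a CHC histogram
#'
#' @param grid a [chc_histogram()] result.
#' @return 3D array of molarity (mol/L).
#' @export
chc_molarity <- function(grid) {
  grid$counts / (grid$n_frames * .chc_bin_volumes(grid)) * CHC_MOLAR
}

#' 2D marginal molarity map
#'
#' Integrates the third coordinate: counts are summed and divided by the
#' summed bin volume, so each marginal conserves the total visitation count.
#'
#' @param grid a [chc_histogram()] result.
#' @param plane `"DA"`, `"DR"` or `"RA"`.
#' @return 2D molarity matrix.
#' @export
chc_marginal <- function(grid, plane = c("DA", "DR", "RA")) {
  plane <- match.arg(plane)
  V <- .chc_bin_volumes(grid)
  ax <- switch(plane, DA = 2L, DR = 3L, RA = 1L)
  cts <- apply(grid$counts, setdiff(1:3, ax), sum)
  vol <- apply(V, setdiff(1:3, ax), sum)
  cts / (grid$n_frames * vol) * CHC_MOLAR
}

#' Groove occupancy from CHC coordinates
#'
#' The minor groove is the window `a_minor` in A with `r <= r_max` and D in
#' `d_range`; the major groove is the complement in A within the same R and
#' D windows.  Returns per-frame counts and running cumulative means (for
#' convergence monitoring).
#'
#' @param coords data frame from [chc_coords()].
#' @param a_minor minor-groove azimuth window in degrees (default
#'   `c(33, 147)`).
#' @param r_max radial window (default 10.25 Angstrom).
#' @param d_range level window (default `c(2, 22)`).
#' @return data frame with `frame, minor, major, minor_cum, major_cum`.
#' @export
groove_occupancy <- function(coords, a_minor = c(33, 147), r_max = 10.25,
                             d_range = c(2, 22)) {
  ok <- !is.na(coords$d) & coords$r <= r_max &
    coords$d >= d_range[1] & coords$d <= d_range[2]
  in_minor <- ok & coords$a >= a_minor[1] & coords$a <= a_minor[2]
  in_major <- ok & !in_minor
  fr <- sort(unique(coords$frame))
  minor <- vapply(fr, function(f) sum(in_minor & coords$frame == f), 0)
  major <- vapply(fr, function(f) sum(in_major & coords$frame == f), 0)
  data.frame(frame = fr, minor = minor, major = major,
             minor_cum = cumsum(minor) / seq_along(fr),
             major_cum = cumsum(major) / seq_along(fr))
}
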