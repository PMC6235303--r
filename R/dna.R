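## DNA structural metrics: optimal superposition (Horn quaternion method,
## exact and reflection-safe), RMSD/RMSF, axis-based end-to-end distance and
## bending angle, direction-aware groove widths, essential-dynamics PCA and
## eigenvector-set similarity indices.

#' Optimal rigid-body superposition (quaternion method)
#'
#' Least-squares rotation + translation of `mobile` onto `ref` via the
#' eigendecomposition of Horn's 4x4 key matrix (never produces a
#' reflection).
#'
#' @param mobile,ref n x 3 coordinate matrices (same n, n >= 3
#'   non-collinear).
#' @return list with `xyz` (fitted mobile), `rotation` (3 x 3), `rmsd`.
#' @export
superpose <- function(mobile, ref) {
  if (nrow(mobile) != nrow(ref)) stop("coordinate sets differ in size")
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(ref, 2, cr)
  M <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  ## R rotates mobile column-vectors onto the reference: row form uses t(R)
  fitted <- sweep(P %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  list(xyz = fitted, rotation = R, rmsd = rmsd)
}

#' Per-frame RMSD after optimal superposition
#'
#' @param traj a [trajectory()].
#' @param ref reference coordinates (n_sel x 3 matrix) or a frame index into
#'   `traj` (default the first frame).
#' @param fit_sel atom indices used both for fitting and for the RMSD.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
superpose_rmsd <- function(traj, ref = 1L,
                           fit_sel = seq_len(traj$topology$n_atoms)) {
  if (length(ref) == 1 && is.numeric(ref))
    ref <- frame_coords(traj, ref)[fit_sel, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f)
    superpose(frame_coords(traj, f)[fit_sel, , drop = FALSE], ref)$rmsd, 0)
}

## superpose every frame of a selection onto a common mean structure
.fitted_ensemble <- function(traj, fit_sel) {
  nf <- n_frames(traj)
  X <- array(0, dim = c(length(fit_sel), 3, nf))
  ref <- frame_coords(traj, 1L)[fit_sel, , drop = FALSE]
  for (f in seq_len(nf))
    X[, , f] <- superpose(frame_coords(traj, f)[fit_sel, , drop = FALSE], ref)$xyz
  mean_str <- apply(X, c(1, 2), mean)
  for (f in seq_len(nf)) X[, , f] <- superpose(X[, , f], mean_str)$xyz
  list(X = X, mean = apply(X, c(1, 2), mean))
}

#' Root mean square fluctuation per residue
#'
#' Frames are superposed onto their mean structure; the per-atom fluctuation
#' about the mean is averaged (mass-unweighted) over each residue's atoms.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param fit_sel atom indices.
#' @return data frame with `resid` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, fit_sel = seq_len(traj$topology$n_atoms)) {
  if (n_frames(traj) < 2) stop("RMSF needs at least two frames")
  fe <- .fitted_ensemble(traj, fit_sel)
  dev2 <- apply(sweep(fe$X, c(1, 2), fe$mean), 1, function(m) mean(colSums(m^2)))
  per_atom <- sqrt(dev2)
  resid <- traj$topology$atoms$resid[fit_sel]
  agg <- tapply(per_atom, resid, mean)
  data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg))
}

#' End-to-end distance and bending angle of the duplex axis
#'
#' The end-to-end distance is between the first and last points of the
#' straight-fit helical axis.  The bending angle is computed midpoint-hinge
#' style: straight axes are fitted separately to the first and second halves
#' of the level midpoints and the angle between their directions is
#' subtracted from 180 degrees (180 = straight).
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param duplex_sel duplex selection (default all SOLUTE).
#' @return list with `end_to_end` (Angstrom) and `bend_angle` (degrees).
#' @export
end_to_end_bend <- function(traj, frame = 1L, duplex_sel = NULL) {
  hf <- build_helical_frames(traj, duplex_sel, frames = frame)
  pf <- hf$per_frame[[1]]
  n <- hf$n_levels
  if (n < 3) stop("degenerate axis")
  e2e <- sqrt(sum((pf$points[n, ] - pf$points[1, ])^2))
  ## half-axis fits use the raw level midpoints (the global straight-fit
  ## points are collinear by construction)
  a <- traj$topology$atoms
  if (is.null(duplex_sel)) duplex_sel <- which(a$species == "SOLUTE")
  c1 <- duplex_sel[a$name[duplex_sel] == "C1'"]
  mols <- unique(a$mol_id[c1])
  s1 <- c1[a$mol_id[c1] == mols[1]][order(a$resid[c1[a$mol_id[c1] == mols[1]]])]
  s2 <- rev(c1[a$mol_id[c1] == mols[2]][order(a$resid[c1[a$mol_id[c1] == mols[2]]])])
  pos <- frame_coords(traj, frame)
  mid <- (pos[s1, , drop = FALSE] + pos[s2, , drop = FALSE]) / 2
  h <- ceiling(n / 2)
  dir_fit <- function(M, fwd) {
    sv <- svd(sweep(M, 2, colMeans(M)))
    d <- sv$v[, 1]
    proj <- drop(sweep(M, 2, colMeans(M)) %*% d)
    if ((proj[length(proj)] - proj[1]) * fwd < 0) d <- -d
    d
  }
  d1 <- dir_fit(mid[1:h, , drop = FALSE], 1)
  d2 <- dir_fit(mid[h:n, , drop = FALSE], 1)
  bend <- 180 - .angle_deg(d1, d2)
  list(end_to_end = e2e, bend_angle = bend)
}

#' Groove widths from cross-strand phosphate distances
#'
#' For each interior base-pair level, the minor (major) groove raw width is
#' the minimum cross-strand P-P distance over partner-level offsets in the
#' 5' (3') backbone direction, and the reported width subtracts 5.8 Angstrom
#' for the van der Waals radii of the two phosphates.  Terminal pairs are
#' excluded; a clashed geometry (raw width < 5.8) yields a negative width
#' with a warning.
#'
#' @param p1,p2 phosphate coordinate matrices for strand I and strand II,
#'   one row per level, both ordered by level (strand II already mapped to
#'   levels, i.e. reversed from its 5'->3' residue order).
#' @param minor_offsets,major_offsets partner-level offsets searched for
#'   each groove (defaults 0..6 and -6..0).
#' @param vdw_correction subtracted from raw distances (Angstrom).
#' @return data frame with `level`, `minor`, `major` (Angstrom), interior
#'   levels only.
#' @export
groove_widths <- function(p1, p2, minor_offsets = 0:6, major_offsets = -6:0,
                          vdw_correction = 5.8) {
  n <- nrow(p1)
  if (nrow(p2) != n) stop("strands have unequal phosphate counts")
  lev <- 2:(n - 1)
  width_dir <- function(l, offs) {
    js <- l + offs
    js <- js[js >= 1 & js <= n]
    if (!length(js)) return(NA_real_)
    min(sqrt(rowSums((p2[js, , drop = FALSE] -
                        matrix(p1[l, ], length(js), 3, byrow = TRUE))^2)))
  }
  minor <- vapply(lev, width_dir, 0, offs = minor_offsets) - vdw_correction
  major <- vapply(lev, width_dir, 0, offs = major_offsets) - vdw_correction
  if (any(c(minor, major) < 0, na.rm = TRUE))
    warning("negative groove width: phosphates closer than the vdW correction")
  data.frame(level = lev, minor = minor, major = major)
}

#' Essential-dynamics PCA of a fitted ensemble
#'
#' Frames are superposed onto their mean structure and the 3N x 3N positional
#' covariance is eigendecomposed.  Eigenvalues are variances (Angstrom^2) in
#' descending order; projections are the centered frame coordinates on the
#' eigenvectors.
#'
#' @param traj a [trajectory()].
#' @param fit_sel atom indices analysed (default: solute heavy atoms when a
#'   solute exists, else all atoms).
#' @param n_components number of components kept (default
#'   `min(100, 3N, n_frames - 1)`); rank deficiency truncates with a
#'   warning.
#' @return object of class `traj_pca`: `mean` (n x 3), `eigenvalues`,
#'   `eigenvectors` (3N x k, orthonormal columns), `projections`
#'   (frames x k), `cumulative_variance`.
#' @export
trajectory_pca <- function(traj, fit_sel = NULL, n_components = NULL) {
  a <- traj$topology$atoms
  if (is.null(fit_sel)) {
    fit_sel <- which(a$species == "SOLUTE" & !a$is_hydrogen)
    if (!length(fit_sel)) fit_sel <- seq_len(traj$topology$n_atoms)
  }
  nf <- n_frames(traj)
  if (nf < 2) stop("PCA needs at least two frames")
  fe <- .fitted_ensemble(traj, fit_sel)
  ## frames x 3N, column order x1 y1 z1 x2 y2 z2 ...
  X <- t(apply(fe$X, 3, function(m) as.numeric(t(m))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nf - 1)
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  rank <- sum(vals > max(vals) * 1e-12)
  k <- n_components
  if (is.null(k)) k <- min(100L, ncol(X), nf - 1L)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; truncating")
    k <- rank
  }
  structure(list(mean = fe$mean, eigenvalues = vals[seq_len(k)],
                 all_eigenvalues = vals,
                 eigenvectors = ev$vectors[, seq_len(k), drop = FALSE],
                 projections = Xc %*% ev$vectors[, seq_len(k), drop = FALSE],
                 cumulative_variance = cumsum(vals)[seq_len(k)] / sum(vals),
                 total_variance = sum(vals), fit_sel = fit_sel),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  cat("trajectory PCA:", length(x$eigenvalues), "components;",
      sprintf("PC1+PC2 capture %.1f%% of variance\n",
              100 * x$cumulative_variance[min(2, length(x$eigenvalues))]))
  invisible(x)
}

#' Similarity indices between two essential-dynamics eigenvector sets
#'
#' `gamma` is the subspace overlap: the mean over the first `n` eigenvectors
#' of A of their squared projections onto the first `n` of B (equivalently
#' the squared RMSIP).  It is 1 for identical subspaces, 0 for orthogonal
#' ones, and invariant under within-set permutations.  `zeta` weights the
#' pairwise diagonal overlaps by eigenvalue importance,
#' `sum_i w_i (a_i . b_i)^2 / sum_i w_i` with `w_i = sqrt(lambdaA_i
#' lambdaB_i)`: it is 1 only for identical sets in identical order and
#' decreases when eigenvectors are interchanged.
#'
#' @param A,B [trajectory_pca()] results over the same atom selection.
#' @param n number of leading eigenvectors compared (default 10).
#' @return list with `gamma` and `zeta`, both in \[0, 1\].
#' @export
similarity_indices <- function(A, B, n = 10) {
  if (nrow(A$eigenvectors) != nrow(B$eigenvectors))
    stop("eigenvector sets have mismatched dimensionality")
  n <- min(n, ncol(A$eigenvectors), ncol(B$eigenvectors))
  VA <- A$eigenvectors[, seq_len(n), drop = FALSE]
  VB <- B$eigenvectors[, seq_len(n), drop = FALSE]
  ovl <- crossprod(VA, VB)
  gamma <- sum(ovl^2) / n
  w <- sqrt(A$eigenvalues[seq_len(n)] * B$eigenvalues[seq_len(n)])
  zeta <- sum(w * diag(ovl)^2) / sum(w)
  list(gamma = gamma, zeta = zeta)
}
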