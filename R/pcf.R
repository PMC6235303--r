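#' Bulk number density of a selection
#'
#' Counts the distinct molecules touched by the selection and divides by the
#' mean box volume over the trajectory -- the convention used to normalize
#' all pair-correlation functions, so that crowding-dependent bulk densities
#' are taken from the same system they normalize.
#'
#' @param traj a [trajectory()].
#' @param sel integer atom indices (see [select_atoms()]).
#' @return molecules per cubic Angstrom.
#' @export
bulk_density <- function(traj, sel) {
  if (!length(sel)) stop("empty selection")
  n_mol <- length(unique(traj$topology$atoms$mol_id[sel]))
  mean_vol <- mean(apply(traj$boxes, 1, prod))
  n_mol / mean_vol
}

#' Pair-correlation function g(r)
#'
#' Histograms minimum-image distances from every reference atom to every
#' target atom over all frames, and normalizes each shell by the ideal-gas
#' expectation `rho_bulk * V_shell`, with `rho_bulk` the target species' bulk
#' density from the same trajectory (overridable via `rho_bulk`).  Self pairs
#' and pairs within the same molecule are excluded.
#'
#' @param traj a [trajectory()].
#' @param ref_sel,target_sel atom index vectors (non-empty).
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @param r_max histogram range; must not exceed half the smallest box
#'   length (default: that bound).
#' @param rho_bulk optional bulk density override (molecules/Angstrom^3).
#' @return object of class `pcf` with fields `r` (bin centers), `g`,
#'   `bin_edges`, `raw_counts`, `rho_bulk`, `n_ref`, `n_frames`.
#' @export
compute_pcf <- function(traj, ref_sel, target_sel, bin_width = 0.1,
                        r_max = NULL, rho_bulk = NULL) {
  if (!length(ref_sel) || !length(target_sel)) stop("empty selection")
  half_min <- min(traj$boxes) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    stop("r_max (", r_max, ") exceeds half the smallest box length (",
         half_min, ")")
  if (bin_width <= 0) stop("bin_width must be positive")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  mol <- traj$topology$atoms$mol_id
  same_mol <- outer(mol[ref_sel], mol[target_sel], "==")
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    pos <- frame_coords(traj, f)
    d <- .pbc_dist_mat(pos[ref_sel, , drop = FALSE],
                       pos[target_sel, , drop = FALSE], traj$boxes[f, ])
    d <- d[!same_mol]
    d <- d[d < r_max]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges,
                                               rightmost.closed = TRUE), nb)
  }
  if (is.null(rho_bulk)) rho_bulk <- bulk_density(traj, target_sel)
  vshell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (length(ref_sel) * nf * rho_bulk * vshell)
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 bin_edges = edges, raw_counts = counts,
                 rho_bulk = rho_bulk, n_ref = length(ref_sel),
                 n_frames = nf, bin_width = bin_width),
            class = "pcf")
}

#' @export
print.pcf <- function(x, ...) {
  cat("pcf:", length(x$g), "bins of", x$bin_width, "A, rho_bulk =",
      signif(x$rho_bulk, 4), "/A^3\n")
  invisible(x)
}

#' @export
plot.pcf <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (Å)", ylab = "g(r)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' First peak and first minimum of a g(r)
#'
#' Scans a centered moving average of g (window `smooth_window` bins; ties
#' broken toward smaller r) for the first local maximum exceeding 1 and the
#' first local minimum after it -- the integration limit for coordination
#' numbers.
#'
#' @param pcf a [compute_pcf()] result.
#' @param smooth_window moving-average window in bins (odd; default 5).
#' @return list with `r_peak`, `r_min`, `g_peak` and the smoothed curve.
#'   When g never falls again after the peak, `r_min` is the last bin center
#'   (with a warning).
#' @export
find_first_extrema <- function(pcf, smooth_window = 5) {
  g <- pcf$g
  w <- as.integer(smooth_window)
  if (w < 1) stop("smooth_window must be >= 1")
  if (w %% 2 == 0) w <- w + 1L
  if (length(g) < 2 * w) stop("pcf has too few bins for this smooth_window")
  s <- as.numeric(stats::filter(g, rep(1 / w, w), sides = 2))
  ok <- which(!is.na(s))
  lo <- ok[1]; hi <- ok[length(ok)]
  ipeak <- NA_integer_
  for (i in (lo + 1):(hi - 1)) {
    if (s[i] > 1 && s[i] > s[i - 1] && s[i] >= s[i + 1]) { ipeak <- i; break }
  }
  if (is.na(ipeak)) stop("no first peak: smoothed g(r) never exceeds 1 at a local maximum")
  imin <- NA_integer_
  if (ipeak + 1 <= hi - 1) {
    for (j in (ipeak + 1):(hi - 1)) {
      if (s[j] < s[j - 1] && s[j] <= s[j + 1]) { imin <- j; break }
    }
  }
  if (is.na(imin)) {
    warning("no first minimum found after the peak; using the last bin")
    imin <- hi
  }
  list(r_peak = pcf$r[ipeak], r_min = pcf$r[imin], g_peak = pcf$g[ipeak],
       smoothed = s)
}

#' Coordination number by trapezoid quadrature
#'
#' Integrates `rho_bulk * 4 pi r^2 g(r)` from 0 to `r_m` on the bin centers
#' (with exact endpoints at r = 0 and r = r_m, g interpolated linearly), the
#' expected number of target molecules within `r_m` of a reference atom.
#'
#' @param pcf a [compute_pcf()] result.
#' @param r_m integration limit (Angstrom), typically the first minimum of
#'   g(r); must lie within the histogram range.
#' @return non-negative coordination number.
#' @export
coordination_number <- function(pcf, r_m) {
  if (r_m <= 0 || r_m > pcf$bin_edges[length(pcf$bin_edges)] + 1e-9)
    stop("r_m outside the pcf range")
  rc <- pcf$r
  keep <- rc < r_m
  g_rm <- approx(rc, pcf$g, xout = r_m, rule = 2)$y
  r <- c(0, rc[keep], r_m)
  gg <- c(0, pcf$g[keep], g_rm)       # integrand is 0 at r = 0 regardless of g
  f <- pcf$rho_bulk * 4 * pi * r^2 * gg
  f[1] <- 0
  sum(diff(r) * (f[-1] + f[-length(f)]) / 2)
}
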