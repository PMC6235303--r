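## Shared fixture builders and independent brute-force oracles.  The oracles
## are deliberately naive (explicit loops, full image enumeration) so they
## stay independent of the implementation paths they check.

## minimum-image distance by explicit enumeration of all 27 periodic images
bf_min_image <- function(p, q, b) {
  b <- as.numeric(b)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    qq <- q + c(i, j, k) * b
    best <- min(best, sqrt(sum((p - qq)^2)))
  }
  best
}

## brute-force count of inter-molecular pairs within r of each other
bf_pair_count <- function(pos, ref, target, mol_id, r, b) {
  cnt <- 0L
  for (i in ref) for (j in target) {
    if (mol_id[i] == mol_id[j]) next
    if (bf_min_image(pos[i, ], pos[j, ], b) < r) cnt <- cnt + 1L
  }
  cnt
}

## brute-force hydrogen-bond enumeration: every (donor-heavy, H, acceptor)
## triple filtered on the geometric criteria, then one bond per (D, A) pair
bf_hbonds <- function(traj, frame = 1L, d_cut = 3.5, angle_cut = 135) {
  a <- traj$topology$atoms
  pos <- frame_coords(traj, frame)
  b <- traj$boxes[frame, ]
  found <- list()
  for (h in which(a$is_hydrogen)) {
    d_heavy <- a$bonded_heavy[h]
    if (is.na(d_heavy) || !a$is_donor_heavy[d_heavy]) next
    for (acc in which(a$is_acceptor)) {
      if (acc == d_heavy) next
      dda <- bf_min_image(pos[d_heavy, ], pos[acc, ], b)
      if (dda > d_cut + 1e-9) next
      ## D-H-A angle at the hydrogen, minimum-image vectors
      mi_vec <- function(from, to) {
        d <- to - from
        d - as.numeric(b) * round(d / as.numeric(b))
      }
      v1 <- mi_vec(pos[h, ], pos[d_heavy, ])
      v2 <- mi_vec(pos[h, ], pos[acc, ])
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < angle_cut - 1e-9) next
      found[[length(found) + 1L]] <- c(d_heavy, acc)
    }
  }
  if (!length(found)) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, found))
}

## random mixed box: single-site waters, 3-atom crowders (O-H plus a carbon),
## and monatomic ions around an optional helix solute
build_mixed_system <- function(n_water, n_crowder = 0, n_cation = 0,
                               n_anion = 0, n_frames = 1, b = box(25, 25, 25),
                               seed = 1, helix_bp = 0) {
  bl <- as.numeric(b)
  name <- character(); resname <- character(); resid <- integer()
  species <- character(); element <- character(); chain <- character()
  sol_pos <- NULL
  if (helix_bp > 0) {
    hx <- generate_helix_fixture(helix_bp, groove_atoms = TRUE, b = b)
    a <- hx$topology$atoms
    name <- a$name; resname <- a$resname; resid <- a$resid
    species <- a$species; element <- a$element; chain <- a$chain
    sol_pos <- frame_coords(hx, 1)
  }
  rid <- if (length(resid)) max(resid) else 0L
  add_mol <- function(nm, rn, sp, el) {
    rid <<- rid + 1L
    name <<- c(name, nm); resname <<- c(resname, rep(rn, length(nm)))
    resid <<- c(resid, rep(rid, length(nm)))
    species <<- c(species, rep(sp, length(nm)))
    element <<- c(element, el); chain <<- c(chain, rep("S", length(nm)))
  }
  for (i in seq_len(n_water)) add_mol("O", "WAT", "WATER", "O")
  for (i in seq_len(n_crowder))
    add_mol(c("C1", "O1", "HO1"), "EG", "CROWDER", c("C", "O", "H"))
  for (i in seq_len(n_cation)) add_mol("NA", "NA", "CATION", "N")
  for (i in seq_len(n_anion)) add_mol("CL", "CL", "ANION", "C")
  n <- length(name)
  n_sol <- if (is.null(sol_pos)) 0L else nrow(sol_pos)

  coords <- crowdsolv:::.with_seed(seed, {
    arr <- array(0, dim = c(n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      pos <- matrix(0, n, 3)
      if (n_sol) pos[1:n_sol, ] <- sol_pos
      i <- n_sol + 1L
      while (i <= n) {
        org <- runif(3) * bl
        k <- sum(resid == resid[i])   # atoms in this molecule
        offs <- matrix(runif(3 * k, -0.5, 0.5), k, 3)
        offs[1, ] <- 0
        pos[i:(i + k - 1L), ] <- sweep(offs, 2, org, "+")
        i <- i + k
      }
      arr[, , f] <- pos
    }
    arr
  })
  ## crowder hydroxyl hydrogens bond to their O1
  bonded <- rep(NA_integer_, n)
  hyd <- which(element == "H" & species == "CROWDER")
  bonded[hyd] <- hyd - 1L
  top <- make_topology(name = name, resname = resname, resid = resid,
                       species = species, element = element, chain = chain,
                       positions = coords[, , 1], bonded_heavy = bonded)
  trajectory(top, coords, b, dt = 0.1)
}

## hand-built pcf object for quadrature tests
synthetic_pcf <- function(g_fun, rho_bulk, r_max = 6, bin_width = 0.1) {
  edges <- seq(0, r_max, by = bin_width)
  r <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(r = r, g = g_fun(r), bin_edges = edges,
                 raw_counts = rep(0, length(r)), rho_bulk = rho_bulk,
                 n_ref = 1L, n_frames = 1L, bin_width = bin_width),
            class = "pcf")
}

## synthetic PCA-like objects for similarity-index tests
synthetic_pca <- function(vectors, values) {
  structure(list(eigenvectors = vectors, eigenvalues = values),
            class = "traj_pca")
}

## orthonormal basis columns via QR of a seeded random matrix
random_orthonormal <- function(dim, k, seed = 1) {
  crowdsolv:::.with_seed(seed, qr.Q(qr(matrix(rnorm(dim * dim), dim, dim)))[, seq_len(k), drop = FALSE])
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * outer(u, u)
}
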