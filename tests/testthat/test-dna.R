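test_that("superposition RMSD is zero for identical and rigidly moved structures", {
  hx <- generate_helix_fixture(8)
  X <- frame_coords(hx, 1)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  R <- rotation_about(c(0.3, 1, -0.2), 71)
  Y <- sweep(X %*% t(R), 2, c(5, -8, 2), "+")
  expect_lt(superpose(Y, X)$rmsd, 1e-10)
  expect_lt(superpose(X, Y)$rmsd, 1e-10)
  ## invariance under rigid motion of either argument
  Z <- X + matrix(rnorm(length(X), sd = 0.5), nrow(X), 3)
  r1 <- superpose(Z, X)$rmsd
  r2 <- superpose(sweep(Z %*% t(R), 2, c(1, 2, 3), "+"), X)$rmsd
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(r1, superpose(X, Z)$rmsd, tolerance = 1e-10)
})

test_that("superposition matches the bio3d oracle on noisy conformers", {
  library(bio3d)
  set.seed(5)
  X <- frame_coords(generate_helix_fixture(6), 1)
  Y <- X + matrix(rnorm(length(X), sd = 0.8), nrow(X), 3)
  mine <- superpose(Y, X)$rmsd
  oracle <- bio3d::rmsd(as.numeric(t(X)), as.numeric(t(Y)), fit = TRUE)
  ## bio3d rounds its reported RMSD to three decimals
  expect_equal(round(mine, 3), oracle)
})

test_that("RMSF recovers a constructed oscillation and ignores frame order", {
  hx <- generate_helix_fixture(8)
  X <- frame_coords(hx, 1)
  n <- nrow(X)
  nf <- 40
  arr <- array(rep(X, nf), c(n, 3, nf))
  ## static trajectory: all zeros
  tr0 <- trajectory(hx$topology, arr, frame_box(hx, 1))
  expect_true(all(rmsf(tr0)$rmsf < 1e-12))
  ## one residue oscillating +-a along x
  a_amp <- 0.6
  res1 <- which(hx$topology$atoms$resid == 4 & hx$topology$atoms$chain == "A")
  for (f in seq_len(nf))
    arr[res1, 1, f] <- X[res1, 1] + a_amp * (-1)^f
  tr <- trajectory(hx$topology, arr, frame_box(hx, 1))
  out <- rmsf(tr)
  moving <- out$rmsf[out$resid == 4]
  ## resid 4 exists on both strands; strand A moves, so the residue mean is a/2 + fit noise
  expect_gt(moving, a_amp / 2 * 0.9)
  perm <- tr
  perm$coords <- tr$coords[, , sample(nf)]
  expect_equal(rmsf(perm)$rmsf, out$rmsf, tolerance = 1e-10)
  expect_error(rmsf(tr0, fit_sel = 1:3), NA)
  expect_error(rmsf(trajectory(hx$topology, arr[, , 1, drop = FALSE],
                               frame_box(hx, 1))), "two frames")
})

test_that("bending angle reads 90 for a hinged duplex and the arc chord value for an arc", {
  hx <- generate_helix_fixture(24)
  eb0 <- end_to_end_bend(hx, 1)
  expect_equal(eb0$bend_angle, 180, tolerance = 1e-6)
  expect_equal(eb0$end_to_end, 23 * 3.38, tolerance = 1e-9)

  ## bend the upper half by 90 degrees about the mid-level
  pos <- frame_coords(hx, 1)
  zmid <- sort(unique(round(pos[, 3], 6)))[12]
  hinge <- c(30, 30, zmid)
  R <- rotation_about(c(1, 0, 0), 90)
  up <- pos[, 3] > zmid + 1e-6
  bent <- pos
  bent[up, ] <- sweep(sweep(bent[up, ], 2, hinge) %*% t(R), 2, hinge, "+")
  trb <- trajectory(hx$topology, array(bent, c(nrow(pos), 3, 1)),
                    box(120, 120, 120))
  expect_equal(end_to_end_bend(trb, 1)$bend_angle, 90, tolerance = 3)

  ## circular-arc axis: total turn theta -> bend = 180 - theta / 2
  n <- 21; theta <- 40 * pi / 180; rad <- 60
  phi <- seq(0, theta, length.out = n)
  mid <- cbind(rad * sin(phi), rad * (1 - cos(phi)), 0)
  perp <- cbind(0, 0, 1)
  c1 <- c2 <- matrix(0, n, 3)
  for (i in 1:n) {
    c1[i, ] <- mid[i, ] + 5.9 * perp
    c2[i, ] <- mid[i, ] - 5.9 * perp
  }
  ## antiparallel: strand B resid j occupies level n+1-j
  top <- make_topology(name = rep("C1'", 2 * n), resname = rep("DNA", 2 * n),
                       resid = c(1:n, 1:n),
                       species = rep("SOLUTE", 2 * n),
                       element = rep("C", 2 * n),
                       chain = rep(c("A", "B"), each = n))
  pos_arc <- rbind(c1, c2[n:1, ])
  tra <- trajectory(top, array(pos_arc + 100, c(2 * n, 3, 1)),
                    box(400, 400, 400))
  eb <- end_to_end_bend(tra, 1)
  expect_equal(eb$bend_angle, 180 - 40 / 2, tolerance = 0.5)
})

test_that("groove widths subtract the phosphate vdW correction and order minor < major", {
  ## two straight parallel strands separated by d: width = d - 5.8 everywhere
  n <- 10; d <- 18
  p1 <- cbind(0, 0, seq_len(n) * 3.4)
  p2 <- cbind(d, 0, seq_len(n) * 3.4)
  gw <- groove_widths(p1, p2)
  expect_true(all(abs(gw$minor - (d - 5.8)) < 1e-9))
  expect_true(all(abs(gw$major - (d - 5.8)) < 1e-9))
  expect_equal(gw$level, 2:(n - 1))

  ## ideal B-like fixture: minor strictly below major at every interior level
  hx <- generate_helix_fixture(12)
  a <- hx$topology$atoms
  pos <- frame_coords(hx, 1)
  i1 <- which(a$name == "P" & a$chain == "A")
  i2 <- which(a$name == "P" & a$chain == "B")
  P1 <- pos[i1[order(a$resid[i1])], ]
  P2 <- pos[rev(i2[order(a$resid[i2])]), ]   # map strand II residues to levels
  gw2 <- groove_widths(P1, P2)
  expect_true(all(gw2$minor < gw2$major))
  ## oracle: the minor raw width is the global minimum over all offsets
  for (k in seq_along(gw2$level)) {
    l <- gw2$level[k]
    dists <- apply(P2, 1, function(q) sqrt(sum((P1[l, ] - q)^2)))
    expect_equal(gw2$minor[k], min(dists) - 5.8, tolerance = 1e-9)
  }

  ## clashed fixture: negative width with a warning
  expect_warning(gw3 <- groove_widths(p1, cbind(4, 0, seq_len(n) * 3.4)),
                 "negative groove width")
  expect_true(all(gw3$minor < 0))
})

test_that("PCA isolates a constructed mode and conserves total variance", {
  hx <- generate_helix_fixture(8)
  X <- frame_coords(hx, 1)
  n <- nrow(X)
  set.seed(3)
  mode1 <- matrix(rnorm(n * 3), n, 3)
  ## orthogonalize against rigid-body motions so superposition keeps the mode
  ctr <- sweep(X, 2, colMeans(X))
  cross_all <- function(e) t(apply(ctr, 1, function(x)
    c(e[2] * x[3] - e[3] * x[2], e[3] * x[1] - e[1] * x[3],
      e[1] * x[2] - e[2] * x[1])))
  rigid <- cbind(
    sapply(1:3, function(k) as.numeric(t(matrix(diag(3)[k, ], n, 3, byrow = TRUE)))),
    sapply(1:3, function(k) as.numeric(t(cross_all(diag(3)[, k])))))
  m <- as.numeric(t(mode1))
  for (j in seq_len(ncol(rigid))) {
    b <- rigid[, j]; b <- b / sqrt(sum(b^2))
    m <- m - sum(m * b) * b
  }
  mode1 <- matrix(m, n, 3, byrow = TRUE)
  mode1 <- mode1 / sqrt(sum(mode1^2))
  nf <- 50
  amp <- 2 * sin(seq(0, 8 * pi, length.out = nf))
  arr <- array(0, c(n, 3, nf))
  for (f in 1:nf) arr[, , f] <- X + amp[f] * mode1
  tr <- trajectory(hx$topology, arr, frame_box(hx, 1))
  pc <- suppressWarnings(trajectory_pca(tr, fit_sel = 1:n, n_components = 5))
  expect_gt(pc$cumulative_variance[1], 0.99)
  v1 <- matrix(pc$eigenvectors[, 1], ncol = 3, byrow = TRUE)
  expect_gt(abs(sum(v1 * mode1)), 0.99)
  ## trace conservation: eigenvalue sum equals total positional variance
  expect_equal(sum(pc$all_eigenvalues), pc$total_variance, tolerance = 1e-8)
  ## eigenvectors orthonormal
  expect_lt(max(abs(crossprod(pc$eigenvectors) - diag(ncol(pc$eigenvectors)))),
            1e-8)
  ## duplicated frame set: identical leading eigenvector up to sign
  tr2 <- trajectory(hx$topology, arr[, , c(1:nf, 1:nf)], frame_box(hx, 1))
  pc2 <- suppressWarnings(trajectory_pca(tr2, fit_sel = 1:n, n_components = 1))
  expect_gt(abs(sum(pc$eigenvectors[, 1] * pc2$eigenvectors[, 1])), 1 - 1e-6)
})

test_that("white-noise coordinates produce no dominant principal component", {
  n <- 12
  top <- make_topology(name = rep("C", n), resname = rep("DNA", n),
                       resid = seq_len(n), species = rep("SOLUTE", n),
                       element = rep("C", n))
  set.seed(8)
  base <- matrix(runif(n * 3, 0, 20), n, 3)
  nf <- 600
  arr <- array(0, c(n, 3, nf))
  for (f in 1:nf) arr[, , f] <- base + matrix(rnorm(n * 3, sd = 0.3), n, 3)
  tr <- trajectory(top, arr, box(30, 30, 30))
  pc <- trajectory_pca(tr, fit_sel = 1:n, n_components = 3 * n - 6)
  vals <- pc$eigenvalues
  expect_lt(max(vals) / mean(vals), 2)
})

test_that("similarity indices are bounded, permutation-tested and eigenvalue-aware", {
  dim3n <- 30
  V <- random_orthonormal(dim3n, 8, seed = 2)
  lam <- sort(runif(8, 0.5, 5), decreasing = TRUE)
  A <- synthetic_pca(V, lam)
  ## self similarity
  si <- similarity_indices(A, A, n = 5)
  expect_equal(si$gamma, 1, tolerance = 1e-12)
  expect_equal(si$zeta, 1, tolerance = 1e-12)
  ## orthogonal sets
  W <- random_orthonormal(dim3n, 16, seed = 2)[, 9:16]
  B <- synthetic_pca(W, lam)
  so <- similarity_indices(A, B, n = 5)
  expect_equal(so$gamma, 0, tolerance = 1e-12)
  expect_equal(so$zeta, 0, tolerance = 1e-12)
  ## swapping the first two eigenvectors: gamma invariant, zeta drops
  Vsw <- V; Vsw[, 1:2] <- V[, 2:1]
  C <- synthetic_pca(Vsw, lam)
  ss <- similarity_indices(A, C, n = 5)
  expect_equal(ss$gamma, 1, tolerance = 1e-12)
  expect_lt(ss$zeta, 0.99)
  expect_gte(ss$zeta, 0)
  expect_error(similarity_indices(A, synthetic_pca(V[1:10, ], lam)),
               "dimensionality")
})
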