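test_that("single charge pair accumulates the closed-form Coulomb energy", {
  top <- make_topology(name = c("X", "O"), resname = c("SOL", "WAT"),
                       resid = 1:2, species = c("SOLUTE", "WATER"),
                       element = c("C", "O"), charge = c(1, 1))
  pos <- rbind(c(5, 5, 5), c(5, 5, 8.322))
  tr <- trajectory(top, array(pos, c(2, 3, 1)), box(50, 50, 50))
  g <- gist_accumulate(tr, voxel_grid(c(0, 0, 0), 1, c(50, 50, 50)))
  expect_equal(sum(g$e_sw), 332.0636 / 3.322, tolerance = 1e-10)
  expect_equal(sum(g$n_k), 1)
})

test_that("zero parameters give zero energies; the half convention conserves pair energy", {
  tr <- generate_uniform_box(50, box(10, 10, 10), 2, seed = 3)
  g <- gist_accumulate(tr, voxel_grid(c(0, 0, 0), 1, c(10, 10, 10)))
  expect_true(all(g$e_sw == 0) && all(g$e_ww == 0))

  ## two charged waters only: sum of half-assigned E_ww equals the pair energy
  top <- make_topology(name = c("O", "O"), resname = c("WAT", "WAT"),
                       resid = 1:2, species = c("WATER", "WATER"),
                       element = c("O", "O"), charge = c(-0.8, 0.4),
                       sigma = c(3.2, 3.2), epsilon = c(0.15, 0.15))
  pos <- rbind(c(4, 4, 4), c(4, 4, 7))
  tr2 <- trajectory(top, array(pos, c(2, 3, 1)), box(20, 20, 20))
  g2 <- gist_accumulate(tr2, voxel_grid(c(0, 0, 0), 1, c(20, 20, 20)))
  e_pair <- 332.0636 * (-0.8 * 0.4) / 3 + 4 * 0.15 * ((3.2 / 3)^12 - (3.2 / 3)^6)
  expect_equal(sum(g2$e_ww), e_pair, tolerance = 1e-10)
})

test_that("voxel sums equal direct double-loop energies on a charged system", {
  hx <- generate_helix_fixture(4, b = box(16, 16, 16))
  a_h <- hx$topology$atoms
  wtr <- generate_water3_box(25, box(16, 16, 16), n_frames = 2, seed = 5)
  a_w <- wtr$topology$atoms
  pos_h <- frame_coords(hx, 1)
  n <- nrow(pos_h) + nrow(a_w)
  arr <- array(0, c(n, 3, 2))
  for (f in 1:2) arr[, , f] <- rbind(pos_h, frame_coords(wtr, f))
  charges <- c(rep(-0.3, nrow(pos_h)), a_w$charge)
  top <- make_topology(
    name = c(a_h$name, a_w$name), resname = c(a_h$resname, a_w$resname),
    resid = c(a_h$resid, a_w$resid + 100L),
    species = c(a_h$species, a_w$species),
    element = c(a_h$element, a_w$element), charge = charges,
    sigma = c(rep(3.5, nrow(pos_h)), a_w$sigma),
    epsilon = c(rep(0.1, nrow(pos_h)), a_w$epsilon),
    chain = c(a_h$chain, rep("W", nrow(a_w))), positions = arr[, , 1])
  tr <- trajectory(top, arr, box(16, 16, 16))
  grid <- voxel_grid(c(0, 0, 0), 1, c(16, 16, 16))
  grid <- gist_accumulate(tr, grid)

  a <- tr$topology$atoms
  b <- c(16, 16, 16)
  pair_e <- function(i, j, pos) {
    d <- bf_min_image(pos[i, ], pos[j, ], b)
    e <- 332.0636 * a$charge[i] * a$charge[j] / d
    if (a$epsilon[i] > 0 && a$epsilon[j] > 0) {
      s <- (a$sigma[i] + a$sigma[j]) / 2
      eps <- sqrt(a$epsilon[i] * a$epsilon[j])
      e <- e + 4 * eps * ((s / d)^12 - (s / d)^6)
    }
    e
  }
  sol <- which(a$species == "SOLUTE")
  wat <- which(a$species == "WATER")
  esw <- eww <- 0
  for (f in 1:2) {
    pos <- frame_coords(tr, f)
    for (i in wat) for (j in sol) esw <- esw + pair_e(i, j, pos)
    for (ii in seq_along(wat)) for (jj in seq_len(ii - 1L)) {
      i <- wat[ii]; j <- wat[jj]
      if (a$mol_id[i] != a$mol_id[j]) eww <- eww + pair_e(i, j, pos)
    }
  }
  expect_equal(sum(grid$e_sw) / grid$n_frames, esw / 2, tolerance = 1e-8)
  expect_equal(2 * sum(grid$e_ww) / grid$n_frames, 2 * eww / 2, tolerance = 1e-8)
  ## visit counts: every water oxygen is inside the grid each frame
  expect_equal(sum(grid$n_k) / grid$n_frames, 25)
})

test_that("accumulation rejects moving solutes and non-water solvent", {
  hx <- generate_helix_fixture(4, b = box(20, 20, 20))
  a_h <- hx$topology$atoms
  top <- make_topology(name = c(a_h$name, "O"),
                       resname = c(a_h$resname, "WAT"),
                       resid = c(a_h$resid, 1L),
                       species = c(a_h$species, "WATER"),
                       element = c(a_h$element, "O"),
                       chain = c(a_h$chain, "W"))
  arr <- array(0, c(top$n_atoms, 3, 2))
  arr[, , 1] <- rbind(frame_coords(hx, 1), c(1, 1, 1))
  arr[, , 2] <- rbind(frame_coords(hx, 1) + 0.01, c(1, 1, 1))
  tr <- trajectory(top, arr, box(20, 20, 20))
  expect_error(gist_accumulate(tr, voxel_grid(c(0, 0, 0), 1, c(20, 20, 20))),
               "restrained")
  mixed <- build_mixed_system(10, n_crowder = 2, b = box(20, 20, 20))
  expect_error(gist_accumulate(mixed, voxel_grid(c(0, 0, 0), 1, c(20, 20, 20))),
               "non-water solvent")
  stripped <- strip_species(mixed, keep = c("SOLUTE", "WATER"))
  expect_silent(g <- gist_accumulate(stripped,
                                     voxel_grid(c(0, 0, 0), 1, c(20, 20, 20))))
  expect_equal(sum(g$n_k), 10)
})

test_that("voxel g is the normalized visit density", {
  g <- voxel_grid(c(0, 0, 0), 0.5, c(4, 4, 4))
  g$n_frames <- 10L
  rho0 <- 0.0334
  g$n_k[2, 3, 1] <- rho0 * 0.5^3 * 10   # exactly bulk occupancy
  gg <- voxel_g(g, rho0)
  expect_equal(gg[2, 3, 1], 1)
  expect_equal(gg[1, 1, 1], 0)          # empty voxel
})

test_that("region summary vanishes for an ideal gas and is negative for structured density", {
  tr <- generate_uniform_box(400, box(20, 20, 20), 60, seed = 19)
  grid <- gist_accumulate(tr, voxel_grid(c(2, 2, 2), 2, c(8, 8, 8)))
  rho0 <- 400 / 8000
  gs <- gist_region_summary(grid, rho0 = rho0, eww0 = 0)
  expect_lt(abs(gs$tds_trans), 0.02)
  expect_equal(gs$de_sw, 0)
  expect_equal(gs$de_ww, 0)
  expect_equal(mean(voxel_g(grid, rho0)), 1, tolerance = 0.01)

  ## peaked density, zero energies: TdS_trans strictly negative (Jensen)
  prof <- function(r) exp(-(r - 4)^2 / 2) * 3 + 0.2
  ts <- generate_radial_profile_box(prof, 400, box(20, 20, 20), 40,
                                    reference = c(10, 10, 10), seed = 23)
  grid2 <- gist_accumulate(ts, voxel_grid(c(2, 2, 2), 2, c(8, 8, 8)))
  gs2 <- gist_region_summary(grid2, rho0 = bulk_density(ts, 1:400), eww0 = 0)
  expect_lt(gs2$tds_trans, -0.05)
})

test_that("the free-energy assembly reproduces the published component sums", {
  expect_equal(gist_free_energy(-4.0760, 2.5469, -0.2313), -1.2978)
  expect_equal(gist_free_energy(-4.4875, 4.6386, 0.1309), 0.0202,
               tolerance = 1e-9)
})

test_that("OpenDX export round-trips and places the occupied voxel correctly", {
  g <- voxel_grid(c(1, 2, 3), 0.5, c(3, 4, 5))
  g$n_frames <- 2L
  g$n_k[2, 1, 4] <- 6
  f <- withr::local_tempfile(fileext = ".dx")
  export_density(g, f, quantity = "number_density")
  rd <- read_dx(f)
  expect_identical(rd$dims, g$dims)
  expect_equal(rd$origin, c(1, 2, 3) + 0.25)
  want <- g$n_k / (0.5^3 * 2)
  expect_identical(rd$values, want)
  expect_equal(sum(rd$values > 0), 1)
  expect_equal(which(rd$values > 0, arr.ind = TRUE)[1, ],
               c(dim1 = 2, dim2 = 1, dim3 = 4))
  ## empty grid: all-zero field
  g0 <- voxel_grid(c(0, 0, 0), 1, c(2, 2, 2)); g0$n_frames <- 1L
  f0 <- withr::local_tempfile(fileext = ".dx")
  export_density(g0, f0, quantity = "number_density")
  expect_true(all(read_dx(f0)$values == 0))
})

test_that("margin counting is boundary-exact and matches a brute-force scan", {
  ## exact boundary: lone solute atom, crowders at 14.9 and 15.1
  pos <- rbind(c(25, 25, 25), c(25 + 14.9, 25, 25), c(25 - 15.1, 25, 25))
  top <- make_topology(name = c("X", "C1", "C1"),
                       resname = c("SOL", "EG", "EG"), resid = 1:3,
                       species = c("SOLUTE", "CROWDER", "CROWDER"),
                       element = c("C", "C", "C"), positions = pos)
  tr <- trajectory(top, array(pos, c(3, 3, 1)), box(60, 60, 60))
  expect_equal(count_within_margin(tr, 1, 1L, margin = 15), 1L)

  ## random crowders vs direct distance scan
  tr2 <- build_mixed_system(0, n_crowder = 60, b = box(40, 40, 40), seed = 27,
                            helix_bp = 6)
  a2 <- tr2$topology$atoms
  sol2 <- which(a2$species == "SOLUTE")
  pos2 <- frame_coords(tr2, 1)
  got <- count_within_margin(tr2, 1, sol2, margin = 15)
  crw_mols <- unique(a2$mol_id[a2$species == "CROWDER"])
  bf <- sum(vapply(crw_mols, function(m) {
    idx <- which(a2$mol_id == m)
    any(vapply(idx, function(i)
      any(apply(pos2[sol2, ], 1, function(s)
        bf_min_image(s, pos2[i, ], tr2$boxes[1, ])) <= 15), TRUE))
  }, TRUE))
  expect_equal(got, bf)
})

test_that("binding free energy assembles, normalizes and averages components", {
  one <- data.frame(e_complex = -10, g_complex = -5, e_solute = -6,
                    g_solute = -3, e_crowders = -2, g_crowders = -1, n_c = 2)
  expect_equal(binding_free_energy(one)$mean, -1.5)
  zero <- one; zero[1, 1:6] <- 0
  expect_equal(binding_free_energy(zero)$mean, 0)
  two <- rbind(one, one)
  bf <- binding_free_energy(two)
  expect_equal(bf$sd, 0)
  bad <- one; bad$n_c <- 0
  expect_error(binding_free_energy(bad), "positive")
  expect_error(binding_free_energy(one[, -1]), "missing component")
})
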