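test_that("shell membership applies the molecule-level any-probe-atom rule", {
  hx <- generate_helix_fixture(6)
  sol_pos <- frame_coords(hx, 1)
  a <- hx$topology$atoms
  ## water O at 3.4 A (member), water O at 3.6 A (not), crowder with one O at
  ## 3.0 A and the rest beyond (member by the any-atom rule)
  anchor <- sol_pos[1, ]
  dir <- c(1, 0, 0)
  wat1 <- anchor + 3.4 * dir
  wat2 <- anchor + 3.6 * dir
  crw <- rbind(anchor + 5.0 * dir,       # C1 beyond
               anchor + 3.0 * dir,       # O1 inside
               anchor + 5.5 * dir)       # HO1 beyond
  pos <- rbind(sol_pos, wat1, wat2, crw)
  top <- make_topology(
    name = c(a$name, "O", "O", "C1", "O1", "HO1"),
    resname = c(a$resname, "WAT", "WAT", "EG", "EG", "EG"),
    resid = c(a$resid, 1L, 2L, 3L, 3L, 3L),
    species = c(a$species, "WATER", "WATER", rep("CROWDER", 3)),
    element = c(a$element, "O", "O", "C", "O", "H"),
    chain = c(a$chain, rep("S", 5)), positions = pos)
  tr <- trajectory(top, array(pos, c(nrow(pos), 3, 1)), frame_box(hx, 1))
  sol <- select_atoms(top, "species SOLUTE")
  mem <- shell_membership(tr, 1, sol, cutoff = 3.5)
  watmols <- top$atoms$mol_id[top$atoms$name == "O" & top$atoms$species == "WATER"]
  expect_true(watmols[1] %in% mem$WATER)
  expect_false(watmols[2] %in% mem$WATER)
  expect_length(mem$CROWDER, 1)
  expect_error(shell_membership(tr, 1, integer()), "empty")
})

test_that("replacement ratios reproduce the published worked examples", {
  expect_equal(round(replacement_ratio(70.03, 52.92, 11.18), 2), 1.53)
  expect_equal(round(replacement_ratio(743.09, 470.32, 134.44), 2), 2.03)
  expect_equal(replacement_ratio(55, 55, 12), 0)
  expect_error(replacement_ratio(10, 8, 0), "positive")
})

test_that("shell-series means feed the replacement arithmetic consistently", {
  ## two runs differing only in crowder insertion near a helix
  hx <- generate_helix_fixture(6)
  b <- frame_box(hx, 1)
  ref <- build_mixed_system(150, n_crowder = 0, n_frames = 3, b = b,
                            seed = 21, helix_bp = 6)
  crw <- build_mixed_system(150, n_crowder = 40, n_frames = 3, b = b,
                            seed = 22, helix_bp = 6)
  sol_r <- select_atoms(ref$topology, "species SOLUTE")
  sol_c <- select_atoms(crw$topology, "species SOLUTE")
  ss_r <- shell_series(ref, sol_r)
  ss_c <- shell_series(crw, sol_c)
  expect_gt(ss_c$mean["CROWDER"], 0)
  rr <- replacement_ratio(ss_r$mean["WATER"], ss_c$mean["WATER"],
                          ss_c$mean["CROWDER"])
  expect_equal(unname(rr),
               (ss_r$mean[["WATER"]] - ss_c$mean[["WATER"]]) /
                 ss_c$mean[["CROWDER"]])
  ## per-species member sets are disjoint: totals add up
  mem <- shell_membership(crw, 1, sol_c)
  expect_equal(length(unlist(mem)), length(unique(unlist(mem))))
})

test_that("spine membership counts solvent near minor-groove atoms only", {
  hx <- generate_helix_fixture(8, groove_atoms = TRUE)
  a <- hx$topology$atoms
  spine <- spine_atoms(hx$topology)
  expect_true(all(a$name[spine] %in% c("N3", "N2", "H21", "H22", "O2")))
  sol_pos <- frame_coords(hx, 1)
  ## five waters within 3.2 A of N3 atoms; one water near the backbone only
  n3 <- spine[a$name[spine] == "N3"][1:5]
  wpos <- sol_pos[n3, ] + matrix(c(0, 0, 1) * 3.2, 5, 3, byrow = TRUE)
  backbone <- which(a$name == "P")[1]
  wfar <- sol_pos[backbone, ] + c(3.0, 0, 0) * sol_pos[backbone, 1:3] /
    sqrt(sum(sol_pos[backbone, ]^2))
  wfar <- sol_pos[backbone, ] * (1 + 3 / sqrt(sum(sol_pos[backbone, ]^2)))
  pos <- rbind(sol_pos, wpos, wfar)
  top <- make_topology(
    name = c(a$name, rep("O", 6)),
    resname = c(a$resname, rep("WAT", 6)),
    resid = c(a$resid, 1:6),
    species = c(a$species, rep("WATER", 6)),
    element = c(a$element, rep("O", 6)),
    chain = c(a$chain, rep("W", 6)), positions = pos)
  tr <- trajectory(top, array(pos, c(nrow(pos), 3, 1)), frame_box(hx, 1))
  mem <- spine_membership(tr, 1, spine_atoms(top))
  expect_length(mem$WATER, 5)
})

test_that("residence records round-trip the occupancy series and censoring is flagged", {
  occ <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4)
  rt <- residence_times(occ, dt = 0.1)
  expect_equal(nrow(rt$records), 1)
  expect_equal(rt$records$duration, 0.3)
  expect_equal(rt$mrt, 0.3)
  expect_true(rt$records$censored)   # touches the series start

  mo <- generate_markov_occupancy(0.7, 0.2, 50, 300, dt = 0.1, seed = 13)
  rt2 <- residence_times(mo$series, 0.1)
  rebuilt <- crowdsolv:::reconstruct_occupancy(rt2$records, 50, 300)
  expect_identical(rebuilt, unname(mo$series))
  ## excluding censored stays changes only which stays enter the mean
  rt3 <- residence_times(mo$series, 0.1, include_censored = FALSE)
  expect_equal(rt3$n_stays, rt2$n_stays)
  expect_equal(rt3$mrt,
               mean(rt2$records$duration[!rt2$records$censored]))
  ## fraction exceeding a threshold
  rt4 <- residence_times(mo$series, 0.1, threshold = 0.25)
  expect_equal(rt4$fraction_exceeding,
               mean(rt2$records$duration > 0.25))
})

test_that("occupancy-matrix shells feed residence analysis", {
  hx <- generate_helix_fixture(6)
  tr <- build_mixed_system(80, n_frames = 5, b = frame_box(hx, 1), seed = 31,
                           helix_bp = 6)
  sol <- select_atoms(tr$topology, "species SOLUTE")
  occ <- occupancy_matrix(tr, sol, cutoff = 3.5)
  expect_equal(dim(occ), c(80, 5))
  counts <- colSums(occ)
  ss <- shell_series(tr, sol)
  expect_equal(unname(counts), unname(ss$counts[, "WATER"]))
})

test_that("MSD diffusion recovers the generator and flags non-diffusive motion", {
  ## stationary particles: D = 0
  still <- generate_uniform_box(50, box(30, 30, 30), 1, seed = 1)
  arr <- array(rep(still$coords[, , 1], 20), c(50, 3, 20))
  tr0 <- trajectory(still$topology, arr, box(30, 30, 30), dt = 0.1)
  expect_equal(msd_diffusion(tr0, fit_window = c(0.2, 1.5))$D, 0)

  tb <- generate_brownian_box(300, d0 = 0.2, n_frames = 150, dt = 0.1,
                              seed = 17)
  fit <- msd_diffusion(tb, fit_window = c(0.3, 4))
  expect_equal(fit$D, 0.2, tolerance = 0.05)

  ## ballistic motion: MSD quadratic, flagged by the R^2 check
  n <- 40
  arr <- array(0, c(n, 3, 60))
  v <- matrix(rnorm(n * 3), n, 3)
  for (f in 1:60) arr[, , f] <- v * (f - 1) * 0.1
  top <- make_topology(name = rep("O", n), resname = rep("WAT", n),
                       resid = seq_len(n), species = rep("WATER", n),
                       element = rep("O", n))
  trb <- trajectory(top, arr, box(1000, 1000, 1000), dt = 0.1)
  expect_warning(msd_diffusion(trb, fit_window = c(0.3, 4)), "not linear")
})
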