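test_that("identical spec and seed give bit-identical trajectories", {
  spec <- trajectory_spec(n_frames = 20, n_ligands = 2, onset_frame = 5,
                          contact_fraction = 0.5, seed = 11)
  a <- gen_membrane_trajectory(spec)
  b <- gen_membrane_trajectory(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$truth$contact, b$truth$contact)
  expect_identical(a$topology$atoms, b$topology$atoms)
  c <- gen_membrane_trajectory(trajectory_spec(n_frames = 20, n_ligands = 2,
                                               onset_frame = 5,
                                               contact_fraction = 0.5,
                                               seed = 12))
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("a ligand with full contact fraction touches the membrane from its onset", {
  spec <- trajectory_spec(n_frames = 100, dt = 0.1, n_ligands = 1,
                          onset_frame = 40, contact_fraction = 1, seed = 2)
  sim <- gen_membrane_trajectory(spec)
  sc <- compute_contact_score(sim$trajectory, sim$topology, cutoff = 4)
  expect_identical(unname(sc$contact[, 1]), c(rep(FALSE, 39), rep(TRUE, 61)))
  expect_identical(sc$total, 61)
})

test_that("zero contact fraction yields zero contact score", {
  spec <- trajectory_spec(n_frames = 50, n_ligands = 3,
                          contact_fraction = 0, seed = 5)
  sim <- gen_membrane_trajectory(spec)
  # independent check by brute-force distances
  expect_false(any(oracle_contact_matrix(sim$trajectory, sim$topology, 4)))
  sc <- compute_contact_score(sim$trajectory, sim$topology, cutoff = 4)
  expect_identical(sc$total, 0)
})

test_that("slab geometry is sane: leaflets, sterols and ganglioside rises", {
  for (kind in c("GM1-like", "GM3-like", "GT1b-like")) {
    sim <- gen_membrane_trajectory(trajectory_spec(
      n_frames = 2, n_ganglioside = 4, ganglioside_kind = kind,
      n_ligands = 0, seed = 3))
    top <- sim$topology
    z <- sim$trajectory$coords[, 3, 1]
    upper <- top$molecules$id[top$molecules$leaflet == "upper"]
    expect_true(all(z[top$atoms$molecule_id %in% upper] > 0))
    popc_up <- top$molecules$id[top$molecules$species_label == "POPC" &
                                  top$molecules$leaflet == "upper"]
    gang <- top$molecules$id[top$molecules$role == "ganglioside"]
    chol_up <- top$molecules$id[top$molecules$species_label == "CHOL" &
                                  top$molecules$leaflet == "upper"]
    z_popc <- max(z[top$atoms$molecule_id %in% popc_up])
    expect_equal(max(z[top$atoms$molecule_id %in% gang]) - z_popc,
                 c("GM1-like" = 12, "GM3-like" = 8, "GT1b-like" = 16)[[kind]])
    expect_lt(max(z[top$atoms$molecule_id %in% chol_up]), z_popc)
  }
})

test_that("trajectory spec validation rejects inconsistent requests", {
  expect_error(trajectory_spec(n_frames = 10, onset_frame = 11),
               "onset_frame")
  expect_error(trajectory_spec(contact_fraction = 1.2), "contact_fraction")
  expect_error(trajectory_spec(n_ganglioside = 2), "ganglioside_kind")
  expect_error(trajectory_spec(ganglioside_kind = "GM1-like"),
               "n_ganglioside")
  expect_error(trajectory_spec(ganglioside_kind = "GM2"), "ganglioside_kind")
  expect_error(
    trajectory_spec(n_ligands = 2,
                    dimer = list(members = c(1, 2), stacked_from_frame = 10,
                                 dissociate_at_frame = 10)),
    "dissociate_at_frame")
  expect_error(
    trajectory_spec(n_ligands = 2, onset_frame = c(3, NA),
                    contact_fraction = 0.5,
                    dimer = list(members = c(1, 2))),
    "contact schedule")
})

test_that("noiseless tensiometry curves return the break point exactly", {
  sim <- gen_tensiometry_curve(tensiometry_spec(break_point = 42,
                                                noise_sigma = 0, seed = 1))
  est <- estimate_cmc(sim$curve)
  expect_equal(est$cmc, 42, tolerance = 1e-6)
  # determinism of the noisy generator
  s1 <- gen_tensiometry_curve(tensiometry_spec(noise_sigma = 0.3, seed = 7))
  s2 <- gen_tensiometry_curve(tensiometry_spec(noise_sigma = 0.3, seed = 7))
  expect_identical(s1$curve$tension_mN_per_m, s2$curve$tension_mN_per_m)
})

test_that("tensiometry spec enforces segment support and slope ordering", {
  expect_error(tensiometry_spec(break_point = 90,
                                concentrations = seq(5, 100, 5)),
               "each side")
  expect_error(tensiometry_spec(slope_below = 0, slope_above = -0.5),
               "slope")
  expect_error(tensiometry_spec(concentrations = c(5, 4, 10, 50, 60, 70)),
               "increasing")
})

test_that("kinetics generator honours its model and seed", {
  flat <- gen_kinetics_curve(kinetics_spec(pi0 = 18, rate_k = 0,
                                           delta_pi_inf = 5, noise_sigma = 0))
  expect_true(all(flat$curve$pressure_mN_per_m == 18))
  s1 <- gen_kinetics_curve(kinetics_spec(noise_sigma = 0.2, seed = 4))
  s2 <- gen_kinetics_curve(kinetics_spec(noise_sigma = 0.2, seed = 4))
  expect_identical(s1$curve, s2$curve)
  expect_error(kinetics_spec(duration = -1), "duration")
  expect_error(kinetics_spec(rate_k = -0.1), "rate_k")
})

test_that("aggregate image series shrink, clamp at zero and stay seeded", {
  frozen <- gen_aggregate_image_series(aggregate_image_spec(
    shrink_rate = 0, n_frames = 3, noise_sigma = 2, seed = 5))
  # same statistical field, different noise draw per frame; radii constant
  expect_true(all(frozen$truth$radii_px == 50))
  gone <- gen_aggregate_image_series(aggregate_image_spec(
    disks = cbind(cx = 60, cy = 60, radius_t0 = 20), shrink_rate = 10,
    n_frames = 5, seed = 5))
  expect_equal(gone$truth$area_px2[3:5], c(0, 0, 0))
  expect_true(all(gone$images[[4]]$pixels == 210))
  a <- gen_aggregate_image_series(aggregate_image_spec(noise_sigma = 3,
                                                       seed = 8))
  b <- gen_aggregate_image_series(aggregate_image_spec(noise_sigma = 3,
                                                       seed = 8))
  expect_identical(a$images[[1]]$pixels, b$images[[1]]$pixels)
  expect_error(aggregate_image_spec(disks = cbind(cx = 10, cy = 10,
                                                  radius_t0 = 50)),
               "inside")
})

test_that("planted contact schedules have binomially distributed totals", {
  p <- 0.6
  f0 <- 21L
  nf <- 100L
  n_after <- nf - f0 + 1L
  expected <- p * n_after
  sd3 <- 3 * sqrt(n_after * p * (1 - p))
  totals <- vapply(1:10, function(s) {
    sim <- gen_membrane_trajectory(trajectory_spec(
      n_frames = nf, n_ligands = 1, onset_frame = f0,
      contact_fraction = p, seed = s))
    sum(sim$truth$contact[, 1])
  }, numeric(1))
  expect_true(all(abs(totals - expected) <= sd3))
})
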