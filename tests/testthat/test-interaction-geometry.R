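test_that("stacking follows the distance and angle thresholds", {
  parallel <- two_ring_system(offset = c(0, 0, 3.5), tilt_deg = 0)
  st <- detect_stacking_pairs(parallel$traj, parallel$top)
  expect_true(all(st$stacked))
  expect_equal(st$min_centroid_dist, 3.5)

  perp <- two_ring_system(offset = c(0, 0, 3.5), tilt_deg = 90)
  expect_false(any(detect_stacking_pairs(perp$traj, perp$top)$stacked))

  far <- two_ring_system(offset = c(0, 0, 6.0), tilt_deg = 0)
  expect_false(any(detect_stacking_pairs(far$traj, far$top)$stacked))
  # but a larger d_max re-admits it (threshold monotonicity at the edge)
  expect_true(all(detect_stacking_pairs(far$traj, far$top,
                                        d_max = 6.5)$stacked))

  tilted <- two_ring_system(offset = c(0, 0, 3.5), tilt_deg = 29)
  expect_true(all(detect_stacking_pairs(tilted$traj, tilted$top)$stacked))
  expect_false(any(detect_stacking_pairs(tilted$traj, tilted$top,
                                         angle_max = 28)$stacked))
})

test_that("stacking flags match the cross-product oracle on random systems", {
  for (seed in 1:10) {
    s <- random_small_system(seed)
    st <- detect_stacking_pairs(s$traj, s$top, d_max = 8, angle_max = 40)
    expect_identical(
      st$stacked,
      oracle_stacked_flags(s$traj, s$top, s$ligand_ids[1], s$ligand_ids[2],
                           d_max = 8, angle_max = 40))
  }
})

test_that("stacking is symmetric and monotone in its thresholds", {
  for (seed in 11:15) {
    s <- random_small_system(seed)
    st1 <- detect_stacking_pairs(s$traj, s$top, d_max = 6, angle_max = 30)
    st2 <- detect_stacking_pairs(s$traj, s$top, d_max = 9, angle_max = 60)
    expect_true(all(st2$stacked >= st1$stacked))
    # symmetry: swap ligand roles by reversing molecule order in topology
    top_sw <- s$top
    top_sw$molecules <- top_sw$molecules[rev(seq_len(nrow(top_sw$molecules))), ]
    st_sw <- detect_stacking_pairs(s$traj, top_sw, d_max = 6, angle_max = 30)
    expect_identical(st_sw$stacked, st1$stacked)
  }
})

test_that("rigid rotation leaves stacking and classification unchanged", {
  s <- random_small_system(42)
  rot <- withr::with_seed(99, random_rotation())
  traj_rot <- s$traj
  for (f in seq_len(n_frames(s$traj))) {
    traj_rot$coords[, , f] <- s$traj$coords[, , f] %*% t(rot)
  }
  st <- detect_stacking_pairs(s$traj, s$top)
  st_rot <- detect_stacking_pairs(traj_rot, s$top)
  expect_identical(st$stacked, st_rot$stacked)
  expect_equal(st$min_centroid_dist, st_rot$min_centroid_dist,
               tolerance = 1e-9)
  cc <- classify_contacts(s$traj, s$top, 1, s$ligand_ids[1])
  cc_rot <- classify_contacts(traj_rot, s$top, 1, s$ligand_ids[1])
  expect_identical(contact_signature(cc), contact_signature(cc_rot))
  expect_equal(cc$angle, cc_rot$angle, tolerance = 1e-9)
})

# minimal H-bond fixture: ligand hydroxyl (O + H) against a partner oxygen
hbond_system <- function(d_oo, h_between = TRUE) {
  lt <- seroraft:::ligand_template()
  # ligand = indole template plus an explicit hydroxyl H (atom 14)
  atoms <- rbind(
    data.frame(id = 1:13, element = lt$elements, mass = lt$masses,
               molecule_id = 1L),
    data.frame(id = 14L, element = "H", mass = 1.008, molecule_id = 1L),
    data.frame(id = 15L, element = "O", mass = 15.999, molecule_id = 2L))
  mols <- data.frame(id = 1:2, species_label = c("SERO", "CHOL"),
                     role = c("ligand", "sterol"), leaflet = c("n/a", "upper"))
  top <- topology(atoms, mols,
                  rings = list(`1` = lapply(lt$rings, identity)),
                  hbond_donors = 10L, hbond_acceptors = 15L,
                  donor_hydrogens = list(`10` = 14L))
  coords <- array(0, dim = c(15, 3, 1))
  coords[1:13, , 1] <- lt$coords
  o10 <- lt$coords[10, ]
  dir <- c(-1, 0, 0)
  if (h_between) {
    coords[14, , 1] <- o10 + 0.97 * dir          # D-H toward the acceptor
  } else {
    coords[14, , 1] <- o10 - 0.97 * dir          # points away: bent geometry
  }
  coords[15, , 1] <- o10 + d_oo * dir
  list(top = top, traj = trajectory(coords, dt = 0.1, box = c(50, 50, 50)))
}

test_that("hydrogen bonds need both the distance and the donor angle", {
  s <- hbond_system(2.8, h_between = TRUE)
  cc <- classify_contacts(s$traj, s$top, 1, 1)
  expect_true("hbond" %in% cc$class)
  expect_equal(cc$distance[cc$class == "hbond"], 2.8)
  expect_gt(cc$angle[cc$class == "hbond"], 170)

  far <- hbond_system(4.5, h_between = TRUE)
  cc_far <- classify_contacts(far$traj, far$top, 1, 1)
  expect_false("hbond" %in% cc_far$class)

  bent <- hbond_system(2.8, h_between = FALSE)
  cc_bent <- classify_contacts(bent$traj, bent$top, 1, 1)
  expect_false("hbond" %in% cc_bent$class)
  # the close oxygen pair falls through to van der Waals
  expect_true("vdw" %in% cc_bent$class)
})

test_that("a carbon above the ring face is CH-pi, in the plane it is vdW", {
  lt <- seroraft:::ligand_template()
  atoms <- rbind(
    data.frame(id = 1:13, element = lt$elements, mass = lt$masses,
               molecule_id = 1L),
    data.frame(id = 14L, element = "C", mass = 12.011, molecule_id = 2L))
  mols <- data.frame(id = 1:2, species_label = c("SERO", "CHOL"),
                     role = c("ligand", "sterol"), leaflet = c("n/a", "upper"))
  top <- topology(atoms, mols, rings = list(`1` = lapply(lt$rings, identity)))
  mk <- function(pos) {
    coords <- array(0, dim = c(14, 3, 1))
    coords[1:13, , 1] <- lt$coords
    coords[14, , 1] <- pos
    trajectory(coords, dt = 0.1, box = c(50, 50, 50))
  }
  # 3.5 A directly above the six-ring centroid (origin)
  cc <- classify_contacts(mk(c(0, 0, 3.5)), top, 1, 1)
  expect_true("ch_pi" %in% cc$class)
  expect_equal(cc$angle[cc$class == "ch_pi"][1], 90)
  # same distance but in the ring plane: vdW only
  cc2 <- classify_contacts(mk(c(3.5 + 2.18, 0, 0)), top, 1, 1)
  expect_false("ch_pi" %in% cc2$class)
  expect_true("vdw" %in% cc2$class)
  expect_error(classify_contacts(mk(c(0, 0, 3.5)), top, 5, 1), "frame")
})

test_that("contact taxonomy matches exhaustive rule evaluation", {
  for (seed in 16:25) {
    s <- random_small_system(seed)
    for (l in s$ligand_ids) {
      cc <- classify_contacts(s$traj, s$top, 1, l)
      expect_identical(contact_signature(cc),
                       oracle_contact_signature(s$traj, s$top, 1, l))
    }
  }
})

mk_stack_series <- function(stacked, dist) {
  n <- length(stacked)
  tibble::tibble(ligand_i = 1L, ligand_j = 2L, frame = seq_len(n),
                 time_ns = (seq_len(n) - 1) * 0.1, stacked = stacked,
                 min_centroid_dist = dist)
}

test_that("dissociation events honour dwell hysteresis", {
  s <- mk_stack_series(c(rep(TRUE, 20), rep(FALSE, 20)),
                       c(rep(3.5, 20), rep(9, 20)))
  ev <- detect_dissociation_event(s, dwell_frames = 5)
  expect_equal(ev$formed_at_frame, 1L)
  expect_equal(ev$dissociated_at_frame, 21L)
  expect_equal(ev$dissociated_at_ns, 2.0)

  none <- mk_stack_series(rep(FALSE, 30), rep(12, 30))
  ev0 <- detect_dissociation_event(none)
  expect_true(is.na(ev0$formed_at_frame))
  expect_true(is.na(ev0$dissociated_at_frame))

  # flickering: alternate stacked/unstacked every frame -> no event at all
  flick <- mk_stack_series(rep(c(TRUE, FALSE), 20), rep(c(3.5, 9), 20))
  evf <- detect_dissociation_event(flick, dwell_frames = 5)
  expect_true(is.na(evf$formed_at_frame))

  # brief excursions below dwell length do not count as dissociation
  d <- c(rep(3.5, 10), 9, 9, rep(3.5, 10), rep(9, 8))
  st <- d < 5
  part <- mk_stack_series(st, d)
  evp <- detect_dissociation_event(part, dwell_frames = 5)
  expect_equal(evp$formed_at_frame, 1L)
  expect_equal(evp$dissociated_at_frame, 23L)

  expect_error(detect_dissociation_event(s, dwell_frames = 0), "dwell")
})

test_that("planted generator dimers are recovered to the frame", {
  spec <- trajectory_spec(n_frames = 80, n_ligands = 3,
                          dimer = list(members = c(2, 3),
                                       stacked_from_frame = 8,
                                       dissociate_at_frame = 50), seed = 31)
  sim <- gen_membrane_trajectory(spec)
  st <- detect_stacking_pairs(sim$trajectory, sim$topology)
  ids <- sim$truth$ligand_molecule_ids[c(2, 3)]
  sub <- st[st$ligand_i == min(ids) & st$ligand_j == max(ids), ]
  ev <- detect_dissociation_event(sub)
  expect_equal(ev$formed_at_frame, 8L)
  expect_equal(ev$dissociated_at_frame, 50L)
  # the non-dimer pairs never form a sustained dimer
  l1 <- sim$truth$ligand_molecule_ids[1]
  for (j in ids) {
    other <- st[st$ligand_i == min(l1, j) & st$ligand_j == max(l1, j), ]
    expect_true(is.na(detect_dissociation_event(other)$formed_at_frame))
  }
})

test_that("ligands without ring annotations are rejected", {
  atoms <- data.frame(id = 1:12, element = "C", mass = 12.011,
                      molecule_id = rep(1:2, each = 6))
  mols <- data.frame(id = 1:2, species_label = "SERO", role = "ligand",
                     leaflet = "n/a")
  top <- topology(atoms, mols)   # no rings
  coords <- array(runif(36), dim = c(12, 3, 1))
  traj <- trajectory(coords, dt = 0.1, box = c(10, 10, 10))
  expect_error(detect_stacking_pairs(traj, top), "ring")
})
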