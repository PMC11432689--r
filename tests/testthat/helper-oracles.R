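# Brute-force oracles and random-system fixtures. Every oracle below is an
# independent re-derivation of the metric from its definition (explicit
# loops, cross-product ring normals) and must never call the production
# code path it checks.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a small random membrane + 2-ligand system with per-frame random
# coordinates; includes stray hydrogens to exercise heavy-atom filtering
random_small_system <- function(seed) {
  withr::with_seed(seed, {
    nf <- sample(3:8, 1)
    lt <- seroraft:::ligand_template()

    atoms <- list(); mols <- list()
    donors <- integer(); acceptors <- integer()
    next_id <- 1L; mol_id <- 0L
    add_mol <- function(n_heavy, n_h, species, role, leaflet) {
      mol_id <<- mol_id + 1L
      el <- c(sample(c("C", "N", "O", "P"), n_heavy, replace = TRUE),
              rep("H", n_h))
      ids <- next_id:(next_id + length(el) - 1L)
      next_id <<- next_id + length(el)
      atoms[[length(atoms) + 1L]] <<- data.frame(
        id = ids, element = el,
        mass = ifelse(el == "H", 1.008, 12.011), molecule_id = mol_id)
      mols[[length(mols) + 1L]] <<- data.frame(
        id = mol_id, species_label = species, role = role, leaflet = leaflet)
      # roughly one polar annotation per molecule
      heavy <- ids[el != "H"]
      if (runif(1) < 0.7) donors <<- c(donors, sample(heavy, 1))
      if (runif(1) < 0.7) acceptors <<- c(acceptors, sample(heavy, 1))
      ids
    }
    for (i in seq_len(sample(2:4, 1))) {
      add_mol(sample(3:5, 1), sample(0:2, 1), "POPC", "phospholipid", "upper")
    }
    add_mol(sample(3:5, 1), sample(0:1, 1), "POPC", "phospholipid", "lower")
    add_mol(4, 0, "CHOL", "sterol", "upper")
    if (runif(1) < 0.5) add_mol(5, 1, "GANG", "ganglioside", "upper")

    rings <- list()
    lig_ids <- integer(2)
    for (l in 1:2) {
      mol_id <- mol_id + 1L
      lig_ids[l] <- mol_id
      ids <- next_id:(next_id + nrow(lt$coords) - 1L)
      next_id <- next_id + nrow(lt$coords)
      atoms[[length(atoms) + 1L]] <- data.frame(
        id = ids, element = lt$elements, mass = lt$masses,
        molecule_id = mol_id)
      mols[[length(mols) + 1L]] <- data.frame(
        id = mol_id, species_label = "SERO", role = "ligand",
        leaflet = "n/a")
      rings[[as.character(mol_id)]] <- lapply(lt$rings, function(r) ids[r])
      donors <- c(donors, ids[lt$donors])
      acceptors <- c(acceptors, ids[lt$acceptors])
    }
    top <- topology(do.call(rbind, atoms), do.call(rbind, mols),
                    rings = rings, hbond_donors = donors,
                    hbond_acceptors = acceptors)

    n_at <- nrow(top$atoms)
    coords <- array(NA_real_, dim = c(n_at, 3, nf))
    for (f in seq_len(nf)) {
      xyz <- matrix(runif(n_at * 3, 0, 25), n_at, 3)
      xyz[, 3] <- runif(n_at, -25, 25)
      for (l in 1:2) {
        rows <- which(top$atoms$molecule_id == lig_ids[l])
        xyz[rows, ] <- lt$coords %*% t(random_rotation())
        xyz[rows, ] <- sweep(xyz[rows, ], 2, runif(3, 0, 20), `+`)
      }
      coords[, , f] <- xyz
    }
    list(top = top,
         traj = trajectory(coords, dt = 0.1, box = c(30, 30, 60)),
         ligand_ids = lig_ids)
  })
}

# ---- oracles ----------------------------------------------------------

oracle_protrusion <- function(traj, top, species, leaflet = "upper") {
  mols <- top$molecules$id[top$molecules$species_label == species &
                             top$molecules$leaflet == leaflet]
  out <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    mx <- c()
    for (m in mols) {
      rows <- which(top$atoms$molecule_id == m & top$atoms$element != "H")
      best <- -Inf
      for (r in rows) best <- max(best, traj$coords[r, 3, f])
      mx <- c(mx, best)
    }
    out[f] <- mean(mx)
  }
  out
}

oracle_com_z <- function(traj, top, mol) {
  rows <- which(top$atoms$molecule_id == mol)
  out <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    num <- 0; den <- 0
    for (r in rows) {
      num <- num + top$atoms$mass[r] * traj$coords[r, 3, f]
      den <- den + top$atoms$mass[r]
    }
    out[f] <- num / den
  }
  out
}

oracle_contact_matrix <- function(traj, top, cutoff,
                                  include_ganglioside = TRUE) {
  roles <- c("phospholipid", "sterol",
             if (include_ganglioside) "ganglioside")
  mem_rows <- which(top$atoms$molecule_id %in%
                      top$molecules$id[top$molecules$role %in% roles] &
                      top$atoms$element != "H")
  lig <- top$molecules$id[top$molecules$role == "ligand"]
  out <- matrix(FALSE, n_frames(traj), length(lig))
  for (f in seq_len(n_frames(traj))) {
    for (k in seq_along(lig)) {
      rows <- which(top$atoms$molecule_id == lig[k] &
                      top$atoms$element != "H")
      hit <- FALSE
      for (a in rows) {
        for (b in mem_rows) {
          d <- sqrt(sum((traj$coords[a, , f] - traj$coords[b, , f])^2))
          if (d <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      out[f, k] <- hit
    }
  }
  out
}

# ring normal by the cross product of two edge vectors (independent of the
# SVD plane fit used in production; identical for planar rings)
oracle_ring <- function(xyz) {
  centroid <- colMeans(xyz)
  v1 <- xyz[2, ] - xyz[1, ]
  v2 <- xyz[3, ] - xyz[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  list(centroid = centroid, normal = n / sqrt(sum(n^2)))
}

oracle_angle_deg <- function(u, v) {
  ca <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

oracle_stacked_flags <- function(traj, top, mol_i, mol_j,
                                 d_max = 5, angle_max = 30) {
  ri <- top$rings[[as.character(mol_i)]]
  rj <- top$rings[[as.character(mol_j)]]
  out <- logical(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    stacked <- FALSE
    for (a in ri) {
      ga <- oracle_ring(xyz[match(a, top$atoms$id), ])
      for (b in rj) {
        gb <- oracle_ring(xyz[match(b, top$atoms$id), ])
        d <- sqrt(sum((ga$centroid - gb$centroid)^2))
        if (d <= d_max &&
            oracle_angle_deg(ga$normal, gb$normal) <= angle_max) {
          stacked <- TRUE
        }
      }
    }
    out[f] <- stacked
  }
  out
}

# exhaustive rule evaluation of the contact taxonomy; returns a sorted
# signature "class:partner_atom" per contact for set comparison
oracle_contact_signature <- function(traj, top, frame, lig,
                                     hbond_d = 3.5, chpi_d = 4.0,
                                     chpi_elev_min = 60, vdw_d = 4.0) {
  xyz <- traj$coords[, , frame]
  at <- top$atoms
  partner_mols <- setdiff(top$molecules$id, lig)
  par_rows <- which(at$molecule_id %in% partner_mols & at$element != "H")
  lig_rows <- which(at$molecule_id == lig & at$element != "H")
  sig <- character()
  used <- integer()
  for (lr in lig_rows) {
    for (pr in par_rows) {
      d <- sqrt(sum((xyz[lr, ] - xyz[pr, ])^2))
      if (d > hbond_d) next
      ld <- at$id[lr] %in% top$hbond_donors
      la <- at$id[lr] %in% top$hbond_acceptors
      pd <- at$id[pr] %in% top$hbond_donors
      pa <- at$id[pr] %in% top$hbond_acceptors
      if ((ld && pa) || (la && pd)) {
        sig <- c(sig, paste0("hbond:", at$id[pr]))
        used <- c(used, pr)
      }
    }
  }
  for (ring in top$rings[[as.character(lig)]]) {
    g <- oracle_ring(xyz[match(ring, at$id), ])
    for (pr in par_rows) {
      if (at$element[pr] != "C") next
      if (at$id[pr] %in% c(top$hbond_donors, top$hbond_acceptors)) next
      v <- xyz[pr, ] - g$centroid
      d <- sqrt(sum(v^2))
      if (d == 0 || d > chpi_d) next
      if (90 - oracle_angle_deg(v, g$normal) >= chpi_elev_min) {
        sig <- c(sig, paste0("ch_pi:", at$id[pr]))
        used <- c(used, pr)
      }
    }
  }
  for (pr in setdiff(par_rows, used)) {
    dmin <- Inf
    for (lr in lig_rows) {
      dmin <- min(dmin, sqrt(sum((xyz[lr, ] - xyz[pr, ])^2)))
    }
    if (dmin <= vdw_d) sig <- c(sig, paste0("vdw:", at$id[pr]))
  }
  sort(unique(sig))
}

contact_signature <- function(contacts) {
  if (nrow(contacts) == 0) return(character(0))
  sort(unique(paste0(contacts$class, ":", contacts$partner_atom)))
}

# tiny hand-built two-ring system for stacking unit tests: each "ligand"
# is a single planar hexagon; ring j is ring i translated/rotated
two_ring_system <- function(offset = c(0, 0, 3.5), tilt_deg = 0,
                            n_frames = 1) {
  hexagon <- t(vapply(0:5, function(k) {
    1.4 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  tilt <- tilt_deg * pi / 180
  rot <- rbind(c(1, 0, 0),
               c(0, cos(tilt), -sin(tilt)),
               c(0, sin(tilt), cos(tilt)))
  ring2 <- hexagon %*% t(rot)
  ring2 <- sweep(ring2, 2, offset, `+`)
  atoms <- data.frame(id = 1:12, element = "C", mass = 12.011,
                      molecule_id = rep(1:2, each = 6))
  mols <- data.frame(id = 1:2, species_label = "SERO", role = "ligand",
                     leaflet = "n/a")
  top <- topology(atoms, mols,
                  rings = list(`1` = list(1:6), `2` = list(7:12)))
  coords <- array(rep(rbind(hexagon, ring2), n_frames),
                  dim = c(12, 3, n_frames))
  list(top = top, traj = trajectory(coords, dt = 0.1, box = c(50, 50, 50)))
}
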