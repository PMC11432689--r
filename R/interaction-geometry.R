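#' Ring centroid and best-fit plane normal
#'
#' Centroid is the unweighted mean of the ring-atom coordinates; the normal
#' is the singular direction of the centered coordinates with the smallest
#' singular value (best-fit plane), reported sign-free.
#'
#' @param coords numeric matrix of ring-atom coordinates (rows = atoms).
#' @return list with `centroid` (3-vector) and `normal` (unit 3-vector).
#' @export
ring_geometry <- function(coords) {
  abort_if(nrow(coords) < 3, "a ring needs at least 3 atoms")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  list(centroid = centroid, normal = normal)
}

ligand_ring_geoms <- function(top, xyz, mol_id) {
  rr <- top$rings[[as.character(mol_id)]]
  abort_if(is.null(rr) || length(rr) == 0,
           "ligand molecule ", mol_id, " has no ring annotations")
  lapply(rr, function(ids) ring_geometry(xyz[atom_rows_by_id(top, ids), ,
                                             drop = FALSE]))
}

#' Detect pi-stacked ligand pairs frame by frame
#'
#' Two ligands are stacked in a frame when some ring of one and some ring of
#' the other have centroids within `d_max` and best-fit plane normals within
#' `angle_max` of parallel (angles folded to `[0, 90]` degrees, sign-free).
#' The minimum ring-centroid distance per frame is reported for use by
#' [detect_dissociation_event()].
#'
#' @param traj an `srf_trajectory`.
#' @param top matching `srf_topology`; every ligand must carry ring
#'   annotations.
#' @param d_max maximum ring-centroid distance, Angstrom.
#' @param angle_max maximum inter-normal angle, degrees.
#' @return tibble of class `srf_stacking_series` with one row per ligand
#'   pair per frame: `ligand_i`, `ligand_j`, `frame`, `time_ns`, `stacked`,
#'   `min_centroid_dist`; thresholds kept as attributes.
#' @export
detect_stacking_pairs <- function(traj, top, d_max = 5.0, angle_max = 30) {
  abort_if(d_max <= 0, "d_max must be positive")
  abort_if(angle_max <= 0 || angle_max > 90,
           "angle_max must lie in (0, 90] degrees")
  lig <- molecule_ids_by_role(top, "ligand")
  abort_if(length(lig) < 2, "need at least two ligands for stacking")
  for (m in lig) {
    abort_if(is.null(top$rings[[as.character(m)]]),
             "ligand molecule ", m, " has no ring annotations")
  }
  pairs <- utils::combn(lig, 2)
  nf <- n_frames(traj)
  tt <- frame_times(traj)
  out <- vector("list", ncol(pairs) * nf)
  k <- 0L
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = FALSE][, , 1]
    geoms <- lapply(lig, function(m) ligand_ring_geoms(top, xyz, m))
    names(geoms) <- as.character(lig)
    for (p in seq_len(ncol(pairs))) {
      gi <- geoms[[as.character(pairs[1, p])]]
      gj <- geoms[[as.character(pairs[2, p])]]
      stacked <- FALSE
      dmin <- Inf
      for (a in gi) {
        for (b in gj) {
          d <- sqrt(sum((a$centroid - b$centroid)^2))
          dmin <- min(dmin, d)
          if (!stacked && d <= d_max &&
              folded_angle_deg(a$normal, b$normal) <= angle_max) {
            stacked <- TRUE
          }
        }
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        ligand_i = pairs[1, p], ligand_j = pairs[2, p],
        frame = f, time_ns = tt[f], stacked = stacked,
        min_centroid_dist = dmin)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ligand_i, res$ligand_j, res$frame), ]
  attr(res, "d_max") <- d_max
  attr(res, "angle_max") <- angle_max
  class(res) <- c("srf_stacking_series", class(res))
  res
}

#' Detect dimer formation and dissociation from a stacking series
#'
#' A dimer is formed at the first time the stacked flag holds for
#' `dwell_frames` consecutive frames; it dissociates at the first subsequent
#' time the minimum ring-centroid distance stays at or above `release_d` for
#' `dwell_frames` consecutive frames. The dwell requirement on both sides is
#' a hysteresis that prevents flickering frames from being double-counted as
#' events.
#'
#' @param series rows of a `srf_stacking_series` for one ligand pair.
#' @param dwell_frames consecutive-frame requirement (>= 1).
#' @param release_d centroid distance treated as fully separated, Angstrom.
#' @return list of class `srf_dissociation_event`: `formed_at_ns` /
#'   `dissociated_at_ns` (NA when absent), corresponding frames, thresholds.
#' @export
detect_dissociation_event <- function(series, dwell_frames = 5,
                                      release_d = 8.0) {
  abort_if(!is_count(dwell_frames, 1L),
           "dwell_frames must be a positive count")
  abort_if(nrow(series) == 0, "empty stacking series")
  abort_if(length(unique(paste(series$ligand_i, series$ligand_j))) > 1,
           "series must describe a single ligand pair")
  series <- series[order(series$frame), ]
  stacked <- series$stacked
  n <- length(stacked)
  run_start <- function(flags, from) {
    # first index >= from where flags holds dwell_frames consecutively
    if (n - dwell_frames + 1L < from) return(NA_integer_)
    for (f in from:(n - dwell_frames + 1L)) {
      if (all(flags[f:(f + dwell_frames - 1L)])) return(f)
    }
    NA_integer_
  }
  formed <- run_start(stacked, 1L)
  dissociated <- NA_integer_
  if (!is.na(formed)) {
    released <- series$min_centroid_dist >= release_d
    dissociated <- run_start(released, formed + 1L)
  }
  structure(list(
    ligand_i = series$ligand_i[1], ligand_j = series$ligand_j[1],
    formed_at_frame = if (is.na(formed)) NA_integer_ else series$frame[formed],
    formed_at_ns = if (is.na(formed)) NA_real_ else series$time_ns[formed],
    dissociated_at_frame = if (is.na(dissociated)) NA_integer_ else
      series$frame[dissociated],
    dissociated_at_ns = if (is.na(dissociated)) NA_real_ else
      series$time_ns[dissociated],
    dwell_frames = dwell_frames, release_d = release_d
  ), class = "srf_dissociation_event")
}

#' @export
print.srf_dissociation_event <- function(x, ...) {
  cat("<srf_dissociation_event> pair (", x$ligand_i, ", ", x$ligand_j, "): ",
      sep = "")
  if (is.na(x$formed_at_frame)) {
    cat("never formed\n")
  } else if (is.na(x$dissociated_at_frame)) {
    cat(sprintf("formed at %g ns, no dissociation\n", x$formed_at_ns))
  } else {
    cat(sprintf("formed at %g ns, dissociated at %g ns\n",
                x$formed_at_ns, x$dissociated_at_ns))
  }
  invisible(x)
}

#' Classify ligand-partner contacts in one frame
#'
#' Geometric contact taxonomy between one ligand and a set of partner
#' molecules, with classes mutually exclusive in priority order
#' hbond > ch_pi > vdw:
#'
#' * **hbond** - donor and acceptor heavy atoms (one on each side) within
#'   `hbond_d`; when the donor's hydrogen is annotated
#'   (`donor_hydrogens` in the topology) the donor-H-acceptor angle must
#'   also be at least `hbond_angle_min`, otherwise the distance criterion
#'   alone is used.
#' * **ch_pi** - an apolar partner carbon (element C, not an annotated donor
#'   or acceptor) within `chpi_d` of a ligand ring centroid, with elevation
#'   of at least `chpi_elev_min` degrees above the ring plane.
#' * **vdw** - any remaining heavy-atom pair within `vdw_d` whose partner
#'   atom was not already consumed by a higher class.
#'
#' @param traj an `srf_trajectory`.
#' @param top matching `srf_topology`.
#' @param frame frame index (1-based).
#' @param ligand_id ligand molecule id.
#' @param partner_ids molecule ids to classify against (default: all
#'   non-ligand molecules).
#' @param hbond_d,hbond_angle_min,chpi_d,chpi_elev_min,vdw_d thresholds
#'   (Angstrom / degrees); standard literature values by default.
#' @return tibble with columns `class`, `ligand_atom` (atom id, or `NA` for
#'   ring contacts), `ligand_ring`, `partner_atom`, `partner_molecule`,
#'   `distance`, `angle` (donor angle or elevation; `NA` for vdw).
#' @export
classify_contacts <- function(traj, top, frame, ligand_id,
                              partner_ids = NULL,
                              hbond_d = 3.5, hbond_angle_min = 120,
                              chpi_d = 4.0, chpi_elev_min = 60,
                              vdw_d = 4.0) {
  nf <- n_frames(traj)
  abort_if(!is_count(frame, 1L) || frame > nf,
           "frame ", frame, " out of range 1..", nf)
  abort_if(!(ligand_id %in% molecule_ids_by_role(top, "ligand")),
           "molecule ", ligand_id, " is not a ligand")
  if (is.null(partner_ids)) {
    partner_ids <- setdiff(top$molecules$id, ligand_id)
  }
  xyz <- traj$coords[, , frame, drop = FALSE][, , 1]
  at <- top$atoms
  lig_rows <- heavy_rows(top, ligand_id)
  par_rows <- unlist(lapply(partner_ids, function(m) heavy_rows(top, m)))
  abort_if(length(par_rows) == 0, "no partner heavy atoms")

  donors <- top$hbond_donors
  acceptors <- top$hbond_acceptors
  is_donor <- at$id %in% donors
  is_acceptor <- at$id %in% acceptors
  res <- list()
  used_partner <- integer()

  # --- hydrogen bonds --------------------------------------------------
  hb_pairs <- rbind(
    expand.grid(l = lig_rows[is_donor[lig_rows]],
                p = par_rows[is_acceptor[par_rows]], lig_is_donor = TRUE),
    expand.grid(l = lig_rows[is_acceptor[lig_rows]],
                p = par_rows[is_donor[par_rows]], lig_is_donor = FALSE)
  )
  for (i in seq_len(nrow(hb_pairs))) {
    lr <- hb_pairs$l[i]; pr <- hb_pairs$p[i]
    d <- sqrt(sum((xyz[lr, ] - xyz[pr, ])^2))
    if (d > hbond_d) next
    donor_row <- if (hb_pairs$lig_is_donor[i]) lr else pr
    acc_row <- if (hb_pairs$lig_is_donor[i]) pr else lr
    ang <- NA_real_
    h_id <- top$donor_hydrogens[[as.character(at$id[donor_row])]]
    if (!is.null(h_id)) {
      hrow <- atom_rows_by_id(top, as.integer(h_id))
      v1 <- xyz[donor_row, ] - xyz[hrow, ]
      v2 <- xyz[acc_row, ] - xyz[hrow, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < hbond_angle_min) next
    }
    res[[length(res) + 1L]] <- tibble::tibble(
      class = "hbond", ligand_atom = at$id[lr], ligand_ring = NA_character_,
      partner_atom = at$id[pr], partner_molecule = at$molecule_id[pr],
      distance = d, angle = ang)
    used_partner <- c(used_partner, pr)
  }

  # --- CH-pi -----------------------------------------------------------
  geoms <- ligand_ring_geoms(top, xyz, ligand_id)
  apolar_c <- par_rows[at$element[par_rows] == "C" &
                         !is_donor[par_rows] & !is_acceptor[par_rows]]
  for (rn in names(geoms)) {
    g <- geoms[[rn]]
    for (pr in apolar_c) {
      v <- xyz[pr, ] - g$centroid
      d <- sqrt(sum(v^2))
      if (d > chpi_d || d == 0) next
      # elevation is measured from the ring plane; the folded angle is from
      # the normal, so elevation = 90 - fold(angle to normal)
      elev <- 90 - folded_angle_deg(v, g$normal)
      if (elev >= chpi_elev_min) {
        res[[length(res) + 1L]] <- tibble::tibble(
          class = "ch_pi", ligand_atom = NA_integer_, ligand_ring = rn,
          partner_atom = at$id[pr], partner_molecule = at$molecule_id[pr],
          distance = d, angle = elev)
        used_partner <- c(used_partner, pr)
      }
    }
  }

  # --- van der Waals ---------------------------------------------------
  free_par <- setdiff(par_rows, used_partner)
  for (pr in free_par) {
    d2 <- sq_dist_to(xyz[lig_rows, , drop = FALSE], xyz[pr, ])
    j <- which.min(d2)
    d <- sqrt(d2[j])
    if (d <= vdw_d) {
      res[[length(res) + 1L]] <- tibble::tibble(
        class = "vdw", ligand_atom = at$id[lig_rows[j]],
        ligand_ring = NA_character_, partner_atom = at$id[pr],
        partner_molecule = at$molecule_id[pr], distance = d,
        angle = NA_real_)
    }
  }

  if (length(res) == 0) {
    return(tibble::tibble(class = character(), ligand_atom = integer(),
                          ligand_ring = character(), partner_atom = integer(),
                          partner_molecule = integer(), distance = numeric(),
                          angle = numeric()))
  }
  do.call(rbind, res)
}
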