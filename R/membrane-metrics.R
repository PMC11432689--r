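#' Species-wise average protrusion profile
#'
#' The "membrane surface" line for a lipid species: per frame, the mean over
#' all upper-leaflet molecules of that species of the per-molecule maximum
#' heavy-atom z coordinate. Hydrogens are excluded; the upper leaflet is the
#' one at positive z under the package-wide axis convention.
#'
#' @param traj an `srf_trajectory`.
#' @param top the matching `srf_topology`.
#' @param species_label species to profile, e.g. `"POPC"` or `"CHOL"`.
#' @param leaflet which leaflet defines the surface (default `"upper"`).
#' @return tibble with columns `frame`, `time_ns`, `protrusion_z` (Angstrom),
#'   one row per frame; attribute `species_label`.
#' @export
average_protrusion_series <- function(traj, top, species_label,
                                      leaflet = "upper") {
  mols <- top$molecules$id[top$molecules$species_label == species_label &
                             top$molecules$leaflet == leaflet]
  abort_if(length(mols) == 0, "no ", leaflet, "-leaflet molecules with ",
           "species_label ", dQuote(species_label))
  rows_per_mol <- lapply(mols, function(m) heavy_rows(top, m))
  abort_if(any(lengths(rows_per_mol) == 0),
           "a ", species_label, " molecule has no heavy atoms")
  nf <- n_frames(traj)
  prot <- numeric(nf)
  for (f in seq_len(nf)) {
    z <- traj$coords[, 3, f]
    mx <- vapply(rows_per_mol, function(r) max(z[r]), numeric(1))
    prot[f] <- mean(mx)
  }
  out <- tibble::tibble(frame = seq_len(nf), time_ns = frame_times(traj),
                        protrusion_z = prot)
  attr(out, "species_label") <- species_label
  out
}

#' Ligand mass-center z profile
#'
#' Mass-weighted mean z of one ligand molecule, per frame (all atoms,
#' weighted by the topology masses).
#'
#' @inheritParams average_protrusion_series
#' @param ligand_id molecule id of the ligand.
#' @return tibble with columns `frame`, `time_ns`, `com_z` (Angstrom).
#' @export
ligand_com_series <- function(traj, top, ligand_id) {
  abort_if(!(ligand_id %in% top$molecules$id), "unknown molecule id ",
           ligand_id)
  rows <- which(top$atoms$molecule_id == ligand_id)
  abort_if(length(rows) == 0, "molecule ", ligand_id, " has no atoms")
  m <- top$atoms$mass[rows]
  abort_if(any(m <= 0), "non-positive atom mass in molecule ", ligand_id)
  nf <- n_frames(traj)
  com <- numeric(nf)
  for (f in seq_len(nf)) {
    com[f] <- sum(m * traj$coords[rows, 3, f]) / sum(m)
  }
  tibble::tibble(frame = seq_len(nf), time_ns = frame_times(traj),
                 com_z = com)
}

#' Membrane-contact score over a trajectory
#'
#' Assigns +1 per frame to every ligand whose minimum heavy-atom distance to
#' any heavy atom of a membrane molecule is within `cutoff` (closed
#' interval: a pair at exactly the cutoff counts). The per-frame score is
#' the number of ligands in contact (0..n_ligands) and the total sums all
#' frames.
#'
#' An alternative mode (`mode = "com_below"`) scores a ligand instead when
#' its mass-center z lies at or below the average protrusion of
#' `protrusion_species`, for comparison with the distance definition.
#'
#' @inheritParams average_protrusion_series
#' @param cutoff heavy-atom contact distance, Angstrom (> 0).
#' @param include_ganglioside should ganglioside atoms count as membrane
#'   surface? Default `TRUE`.
#' @param mode `"distance"` (default) or `"com_below"`.
#' @param protrusion_species surface species for `"com_below"` mode.
#' @return list of class `srf_contact_score`: `per_frame` tibble
#'   (`frame`, `time_ns`, `score`), `per_ligand` totals, `total`,
#'   `cutoff`, `n_ligands`, and the per-ligand per-frame logical matrix
#'   `contact`.
#' @export
compute_contact_score <- function(traj, top, cutoff = 4.0,
                                  include_ganglioside = TRUE,
                                  mode = c("distance", "com_below"),
                                  protrusion_species = "POPC") {
  mode <- match.arg(mode)
  abort_if(!is_scalar_num(cutoff) || cutoff <= 0,
           "cutoff must be a positive distance (Angstrom)")
  lig <- molecule_ids_by_role(top, "ligand")
  abort_if(length(lig) == 0, "topology has no ligand molecules")
  mem_roles <- c("phospholipid", "sterol",
                 if (include_ganglioside) "ganglioside")
  mem <- molecule_ids_by_role(top, mem_roles)
  abort_if(length(mem) == 0, "topology has no membrane molecules")

  nf <- n_frames(traj)
  contact <- matrix(FALSE, nf, length(lig),
                    dimnames = list(NULL, as.character(lig)))
  if (mode == "distance") {
    mem_rows <- unlist(lapply(mem, function(m) heavy_rows(top, m)))
    lig_rows <- lapply(lig, function(m) heavy_rows(top, m))
    cut2 <- cutoff * cutoff
    for (f in seq_len(nf)) {
      xyz <- traj$coords[, , f, drop = FALSE][, , 1]
      mpts <- xyz[mem_rows, , drop = FALSE]
      for (k in seq_along(lig)) {
        hit <- FALSE
        for (r in lig_rows[[k]]) {
          if (min(sq_dist_to(mpts, xyz[r, ])) <= cut2) {
            hit <- TRUE
            break
          }
        }
        contact[f, k] <- hit
      }
    }
  } else {
    prot <- average_protrusion_series(traj, top, protrusion_species)
    for (k in seq_along(lig)) {
      com <- ligand_com_series(traj, top, lig[k])
      contact[, k] <- com$com_z <= prot$protrusion_z
    }
  }
  score <- rowSums(contact)
  structure(list(
    per_frame = tibble::tibble(frame = seq_len(nf),
                               time_ns = frame_times(traj), score = score),
    per_ligand = setNames(colSums(contact), as.character(lig)),
    total = sum(score), cutoff = cutoff, mode = mode,
    n_ligands = length(lig), contact = contact
  ), class = "srf_contact_score")
}

#' @export
print.srf_contact_score <- function(x, ...) {
  cat("<srf_contact_score> total ", x$total, " over ",
      nrow(x$per_frame), " frames x ", x$n_ligands, " ligands (",
      x$mode, " mode, cutoff ", x$cutoff, " A)\n", sep = "")
  cat("  per ligand: ", paste(sprintf("%s=%d", names(x$per_ligand),
                                      x$per_ligand), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Detect the insertion onset of a ligand
#'
#' The onset is the first frame `f` at which the ligand mass-center drops to
#' or below the membrane-surface (protrusion) line and stays inserted: the
#' condition must hold for `persistence_frames` consecutive frames starting
#' at `f`, and in at least `occupancy_min` of all frames from `f` to the end
#' of the trajectory ("lasts until the end"). Brief dips that do not persist
#' are ignored.
#'
#' @param com tibble from [ligand_com_series()].
#' @param protrusion tibble from [average_protrusion_series()], on the same
#'   frame grid.
#' @param persistence_frames consecutive frames required at onset (>= 1).
#' @param occupancy_min minimum inserted fraction of frames from the onset
#'   to the end, in `[0, 1]`.
#' @return list of class `srf_insertion_report`: `onset_frame` and
#'   `onset_time_ns` (both `NA` when no onset qualifies),
#'   `occupancy_after_onset`, and the parameters used.
#' @export
detect_insertion_onset <- function(com, protrusion, persistence_frames = 10,
                                   occupancy_min = 0.9) {
  abort_if(nrow(com) != nrow(protrusion),
           "com and protrusion series have different lengths (",
           nrow(com), " vs ", nrow(protrusion), ")")
  abort_if(!is_count(persistence_frames, 1L),
           "persistence_frames must be a positive count")
  abort_if(occupancy_min < 0 || occupancy_min > 1,
           "occupancy_min must lie in [0, 1]")
  below <- com$com_z <= protrusion$protrusion_z
  n <- length(below)
  onset <- NA_integer_
  occ <- NA_real_
  last_start <- n - persistence_frames + 1L
  if (last_start >= 1L) {
    for (f in seq_len(last_start)) {
      if (all(below[f:(f + persistence_frames - 1L)])) {
        tail_occ <- mean(below[f:n])
        if (tail_occ >= occupancy_min) {
          onset <- f
          occ <- tail_occ
          break
        }
      }
    }
  }
  structure(list(
    onset_frame = onset,
    onset_time_ns = if (is.na(onset)) NA_real_ else com$time_ns[onset],
    occupancy_after_onset = occ,
    persistence_frames = persistence_frames,
    occupancy_min = occupancy_min
  ), class = "srf_insertion_report")
}

#' @export
print.srf_insertion_report <- function(x, ...) {
  if (is.na(x$onset_frame)) {
    cat("<srf_insertion_report> no insertion detected\n")
  } else {
    cat(sprintf(
      "<srf_insertion_report> onset at frame %d (t = %g ns), occupancy %.3f\n",
      x$onset_frame, x$onset_time_ns, x$occupancy_after_onset))
  }
  invisible(x)
}
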