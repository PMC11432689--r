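#' Specification for a synthetic membrane trajectory
#'
#' Defines a seeded, fully reproducible stand-in for an all-atom membrane
#' simulation: a static jittered-lattice POPC/cholesterol slab (optionally
#' carrying gangliosides in the upper leaflet), plus ligand molecules that
#' random-walk in the water phase and are tethered to the membrane surface
#' on a planted, per-frame Bernoulli contact schedule after their onset
#' frame. Because every event is planted, downstream estimators (contact
#' score, insertion onset, stacking dissociation) can be validated against
#' exact ground truth.
#'
#' @param n_frames number of frames (>= 1).
#' @param dt ns per frame.
#' @param n_popc,n_chol phospholipid / sterol count per leaflet.
#' @param n_ganglioside ganglioside count (upper leaflet only, as in the
#'   outer leaflet of a postsynaptic membrane).
#' @param ganglioside_kind `"none"`, `"GM1-like"`, `"GM3-like"` or
#'   `"GT1b-like"`; controls how far the sugar headgroup extends above the
#'   phospholipid plane (+12, +8, +16 Angstrom respectively).
#' @param n_ligands number of ligand (serotonin-like) molecules.
#' @param onset_frame integer vector (length 1 or `n_ligands`): first frame
#'   at which a ligand may touch the membrane; `NA` for never.
#' @param contact_fraction per-ligand probability in `[0, 1]` that a frame at
#'   or after the onset is a contact frame (drawn i.i.d., seeded), so the
#'   expected contact-score contribution is analytically known.
#' @param dimer optional `list(members = c(i, j), stacked_from_frame,
#'   dissociate_at_frame)`: the two member ligands hold parallel rings at
#'   3.5 Angstrom centroid separation from `stacked_from_frame` until
#'   `dissociate_at_frame` (NA = never dissociates), then separate to
#'   > 8 Angstrom. Members may not also carry a contact schedule.
#' @param jitter_sigma lateral lattice placement jitter, Angstrom.
#' @param walk_sigma per-frame ligand random-walk step, Angstrom.
#' @param box optional 3 box lengths (Angstrom); derived from the lattice
#'   when omitted.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `srf_trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 250, dt = 0.1,
                            n_popc = 32, n_chol = 32,
                            n_ganglioside = 0, ganglioside_kind = "none",
                            n_ligands = 3,
                            onset_frame = NA, contact_fraction = 0,
                            dimer = NULL,
                            jitter_sigma = 0.5, walk_sigma = 1.0,
                            box = NULL, seed = 1L) {
  abort_if(!is_count(n_frames, 1L), "n_frames must be a positive count")
  abort_if(!is_scalar_num(dt) || dt <= 0, "dt must be positive (ns)")
  abort_if(!is_count(n_popc, 1L), "need at least one phospholipid per leaflet")
  abort_if(!is_count(n_chol, 0L) || !is_count(n_ganglioside, 0L),
           "molecule counts must be non-negative integers")
  abort_if(!is_count(n_ligands, 0L), "n_ligands must be a count")
  kinds <- c("none", names(ganglioside_rise))
  abort_if(!(ganglioside_kind %in% kinds),
           "ganglioside_kind must be one of: ", paste(kinds, collapse = ", "))
  abort_if(ganglioside_kind == "none" && n_ganglioside > 0,
           "n_ganglioside > 0 requires a ganglioside_kind")
  abort_if(ganglioside_kind != "none" && n_ganglioside == 0,
           "ganglioside_kind set but n_ganglioside is 0")

  onset_frame <- as.integer(rep_len(onset_frame, max(n_ligands, 1L)))
  contact_fraction <- rep_len(contact_fraction, max(n_ligands, 1L))
  abort_if(any(contact_fraction < 0 | contact_fraction > 1),
           "contact_fraction must lie in [0, 1]")
  set <- !is.na(onset_frame)
  abort_if(any(onset_frame[set] < 1L | onset_frame[set] > n_frames),
           "onset_frame must lie within 1..n_frames when set")

  if (!is.null(dimer)) {
    abort_if(is.null(dimer$members) || length(dimer$members) != 2 ||
               anyDuplicated(dimer$members) > 0,
             "dimer$members must be two distinct ligand indices")
    abort_if(any(dimer$members < 1 | dimer$members > n_ligands),
             "dimer members outside 1..n_ligands")
    dimer$stacked_from_frame <- as.integer(dimer$stacked_from_frame %||% 1L)
    abort_if(dimer$stacked_from_frame < 1L ||
               dimer$stacked_from_frame > n_frames,
             "dimer stacked_from_frame outside trajectory")
    da <- dimer$dissociate_at_frame %||% NA
    if (!is.na(da)) {
      abort_if(da <= dimer$stacked_from_frame,
               "dissociate_at_frame must exceed stacked_from_frame")
      abort_if(da > n_frames, "dissociate_at_frame beyond trajectory")
    }
    dimer$dissociate_at_frame <- as.integer(da)
    abort_if(any(set[dimer$members]),
             "dimer members may not also carry a contact schedule")
  }

  # lattice footprint: upper leaflet holds the most molecules
  n_upper <- n_popc + n_chol + n_ganglioside
  k <- ceiling(sqrt(max(n_upper, n_popc + n_chol)))
  side <- max(48, k * 8)
  if (is.null(box)) box <- c(side, side, 120)
  abort_if(length(box) != 3 || any(box <= 0), "box must be 3 positive lengths")
  abort_if(box[1] < k * 8 || box[2] < k * 8,
           "box too small for the requested lattice")
  abort_if(!is.null(dimer) && box[1] < 40,
           "box x-length must be >= 40 to hold a separated dimer")

  structure(list(
    n_frames = as.integer(n_frames), dt = dt,
    n_popc = as.integer(n_popc), n_chol = as.integer(n_chol),
    n_ganglioside = as.integer(n_ganglioside),
    ganglioside_kind = ganglioside_kind,
    n_ligands = as.integer(n_ligands),
    onset_frame = onset_frame, contact_fraction = contact_fraction,
    dimer = dimer, jitter_sigma = jitter_sigma, walk_sigma = walk_sigma,
    box = as.numeric(box), seed = as.integer(seed)
  ), class = "srf_trajectory_spec")
}

# fixed geometry constants of the slab model (Angstrom)
.slab <- list(head_z = 20, spacing = 8, contact_depth = -0.5,
              contact_jitter = 0.3, anchor_jitter = 0.3,
              hover_gap = 6, stack_dz = 3.5)

#' Generate a synthetic membrane trajectory with planted ground truth
#'
#' Builds the slab, plants the contact schedules, insertion onsets and the
#' optional pi-stacked dimer described by the [trajectory_spec()], and
#' returns the topology (with ring and H-bond annotations), the trajectory
#' and a ground-truth sidecar.
#'
#' The upper phospholipid choline plane sits at z = +21 Angstrom (phosphate
#' plane +20), the lower leaflet mirrored at negative z; sterol OH groups
#' sit slightly below the phosphate plane and ganglioside headgroups extend
#' above the phospholipid maximum by a kind-dependent rise. Contact frames
#' tether the ligand flat among the headgroups (mass-center below the
#' phospholipid protrusion line, within heavy-atom contact range);
#' non-contact frames keep every ligand atom > 5 Angstrom clear of the
#' membrane.
#'
#' @param spec an `srf_trajectory_spec`.
#' @return list of class `srf_traj_sim`: `topology`, `trajectory`, and
#'   `truth` (per-ligand contact matrix, onset frames/times, dimer plan,
#'   the POPC protrusion height).
#' @export
gen_membrane_trajectory <- function(spec) {
  abort_if(!inherits(spec, "srf_trajectory_spec"),
           "spec must come from trajectory_spec()")
  withr::with_seed(spec$seed, gen_membrane_trajectory_impl(spec))
}

gen_membrane_trajectory_impl <- function(spec) {
  zh <- .slab$head_z
  sp <- .slab$spacing
  rise <- if (spec$ganglioside_kind == "none") 0 else
    ganglioside_rise[[spec$ganglioside_kind]]
  floor_z <- zh + 1 + rise + .slab$hover_gap
  ceil_z <- spec$box[3] / 2 - 2

  # --- membrane lattice ------------------------------------------------
  k <- ceiling(sqrt(max(spec$n_popc + spec$n_chol + spec$n_ganglioside,
                        spec$n_popc + spec$n_chol)))
  site_xy <- as.matrix(expand.grid(x = (seq_len(k) - 0.5) * sp,
                                   y = (seq_len(k) - 0.5) * sp))

  upper_roles <- sample(c(rep("phospholipid", spec$n_popc),
                          rep("sterol", spec$n_chol),
                          rep("ganglioside", spec$n_ganglioside)))
  lower_roles <- sample(c(rep("phospholipid", spec$n_popc),
                          rep("sterol", spec$n_chol)))

  tmpl_of <- function(role) switch(role,
    phospholipid = popc_template(),
    sterol = chol_template(),
    ganglioside = ganglioside_template(rise))
  label_of <- function(role) switch(role,
    phospholipid = "POPC", sterol = "CHOL",
    ganglioside = spec$ganglioside_kind)

  atoms <- list(); mols <- list(); mem_coords <- list()
  donors <- integer(); acceptors <- integer()
  next_atom <- 1L; mol_id <- 0L
  place_lipid <- function(role, leaflet, xy) {
    tm <- tmpl_of(role)
    n <- nrow(tm$coords)
    jit <- rnorm(2, 0, spec$jitter_sigma)
    zsgn <- if (leaflet == "upper") 1 else -1
    co <- tm$coords
    co[, 3] <- zsgn * (zh + co[, 3])
    co[, 1] <- co[, 1] + xy[1] + jit[1]
    co[, 2] <- co[, 2] + xy[2] + jit[2]
    mol_id <<- mol_id + 1L
    ids <- next_atom:(next_atom + n - 1L)
    next_atom <<- next_atom + n
    atoms[[length(atoms) + 1L]] <<- tibble::tibble(
      id = ids, element = tm$elements, mass = tm$masses, molecule_id = mol_id)
    mols[[length(mols) + 1L]] <<- tibble::tibble(
      id = mol_id, species_label = label_of(role), role = role,
      leaflet = leaflet)
    mem_coords[[length(mem_coords) + 1L]] <<- co
    donors <<- c(donors, ids[tm$donors])
    acceptors <<- c(acceptors, ids[tm$acceptors])
    invisible(NULL)
  }
  for (i in seq_along(upper_roles)) {
    place_lipid(upper_roles[i], "upper", site_xy[i, ])
  }
  for (i in seq_along(lower_roles)) {
    place_lipid(lower_roles[i], "lower", site_xy[i, ])
  }
  membrane <- do.call(rbind, mem_coords)
  n_mem <- nrow(membrane)

  # --- ligand bookkeeping ----------------------------------------------
  lt <- ligand_template()
  n_lat <- nrow(lt$coords)
  com_local <- colSums(lt$coords * lt$masses) / sum(lt$masses)
  lig_rel <- sweep(lt$coords, 2, com_local)

  rings <- list()
  lig_mol_ids <- integer(spec$n_ligands)
  lig_atom_start <- integer(spec$n_ligands)
  for (l in seq_len(spec$n_ligands)) {
    mol_id <- mol_id + 1L
    lig_mol_ids[l] <- mol_id
    ids <- next_atom:(next_atom + n_lat - 1L)
    lig_atom_start[l] <- next_atom
    next_atom <- next_atom + n_lat
    atoms[[length(atoms) + 1L]] <- tibble::tibble(
      id = ids, element = lt$elements, mass = lt$masses, molecule_id = mol_id)
    mols[[length(mols) + 1L]] <- tibble::tibble(
      id = mol_id, species_label = "SERO", role = "ligand", leaflet = "n/a")
    rings[[as.character(mol_id)]] <- lapply(lt$rings, function(r) ids[r])
    donors <- c(donors, ids[lt$donors])
    acceptors <- c(acceptors, ids[lt$acceptors])
  }

  top <- topology(do.call(rbind, atoms), do.call(rbind, mols), rings = rings,
                  hbond_donors = donors, hbond_acceptors = acceptors)

  # --- planted schedules ------------------------------------------------
  nf <- spec$n_frames
  contact <- matrix(FALSE, nf, max(spec$n_ligands, 1L))
  upper_popc_heads <- which(vapply(seq_along(upper_roles), function(i)
    upper_roles[i] == "phospholipid", logical(1)))
  # phosphate xy per upper POPC molecule (row 2 of the template)
  popc_sites <- do.call(rbind, lapply(upper_popc_heads, function(i)
    mem_coords[[i]][2, 1:2]))

  lig_site <- matrix(NA_real_, spec$n_ligands, 2)
  hover_xy <- matrix(NA_real_, spec$n_ligands, 2)
  for (l in seq_len(spec$n_ligands)) {
    lig_site[l, ] <- popc_sites[sample.int(nrow(popc_sites), 1L), ] + c(2, 0)
    hover_xy[l, ] <- runif(2, 8, spec$box[1:2] - 8)
    f0 <- spec$onset_frame[l]
    if (!is.na(f0)) {
      idx <- f0:nf
      contact[idx, l] <- runif(length(idx)) < spec$contact_fraction[l]
    }
  }

  dim_members <- spec$dimer$members %||% integer()
  if (length(dim_members) == 2) {
    a1 <- c(spec$box[1] * 0.25, spec$box[2] * 0.5, floor_z + 3)
    a2 <- c(spec$box[1] * 0.75, spec$box[2] * 0.5, floor_z + 3)
    dim_anchor <- rbind(a1, a2)
  }

  # --- frames -----------------------------------------------------------
  coords <- array(NA_real_, dim = c(n_mem + spec$n_ligands * n_lat, 3, nf))
  for (f in seq_len(nf)) coords[seq_len(n_mem), , f] <- membrane

  reflect <- function(x, lo, hi) {
    # reflect a scalar into [lo, hi]
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    lo + ifelse(y > span, 2 * span - y, y)
  }

  place_ligand <- function(f, l, com) {
    rows <- (n_mem + (l - 1L) * n_lat + 1L):(n_mem + l * n_lat)
    coords[rows, , f] <<- sweep(lig_rel, 2, com, `+`)
  }

  for (l in seq_len(spec$n_ligands)) {
    if (l %in% dim_members) next
    pos <- c(hover_xy[l, ], floor_z + 5)
    for (f in seq_len(nf)) {
      if (contact[f, l]) {
        com <- c(lig_site[l, ] + rnorm(2, 0, .slab$contact_jitter),
                 zh + .slab$contact_depth + rnorm(1, 0, 0.2))
      } else {
        step <- rnorm(3, 0, spec$walk_sigma)
        pos <- c(reflect(pos[1] + step[1], 2, spec$box[1] - 2),
                 reflect(pos[2] + step[2], 2, spec$box[2] - 2),
                 reflect(pos[3] + step[3], floor_z, ceil_z))
        com <- pos
      }
      place_ligand(f, l, com)
    }
  }

  if (length(dim_members) == 2) {
    sf <- spec$dimer$stacked_from_frame
    da <- spec$dimer$dissociate_at_frame
    for (f in seq_len(nf)) {
      stacked <- f >= sf && (is.na(da) || f < da)
      if (stacked) {
        base <- dim_anchor[1, ]
        place_ligand(f, dim_members[1], base)
        place_ligand(f, dim_members[2], base + c(0, 0, .slab$stack_dz))
      } else {
        for (m in 1:2) {
          place_ligand(f, dim_members[m],
                       dim_anchor[m, ] + rnorm(3, 0, .slab$anchor_jitter))
        }
      }
    }
  }

  truth <- list(
    contact = contact,
    onset_frame = spec$onset_frame,
    onset_time_ns = (spec$onset_frame - 1L) * spec$dt,
    contact_fraction = spec$contact_fraction,
    dimer = spec$dimer,
    popc_protrusion_z = zh + 1,
    ligand_molecule_ids = lig_mol_ids,
    seed = spec$seed
  )
  structure(list(topology = top,
                 trajectory = trajectory(coords, dt = spec$dt, box = spec$box),
                 truth = truth, spec = spec),
            class = "srf_traj_sim")
}

#' @export
print.srf_traj_sim <- function(x, ...) {
  cat("<srf_traj_sim> seed ", x$truth$seed, "\n", sep = "")
  print(x$topology)
  print(x$trajectory)
  invisible(x)
}
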