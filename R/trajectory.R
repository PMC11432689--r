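#' Multi-frame coordinate trajectory
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom,
#' aligned to the atom order of the companion [topology()]. The membrane
#' normal is the +z axis and the upper leaflet has positive z; frame `f`
#' corresponds to time `(f - 1) * dt` nanoseconds.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom). A
#'   zero-frame trajectory is allowed (`n_atoms x 3 x 0`).
#' @param dt time per frame, ns (> 0).
#' @param box box lengths, 3-vector (Angstrom).
#' @return An object of class `srf_trajectory`.
#' @export
trajectory <- function(coords, dt, box) {
  abort_if(!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3,
           "coords must be an n_atoms x 3 x n_frames array")
  abort_if(!is_scalar_num(dt) || dt <= 0, "dt must be a positive scalar (ns)")
  abort_if(length(box) != 3 || any(!is.finite(box)) || any(box <= 0),
           "box must be 3 positive lengths (Angstrom)")
  abort_if(any(!is.finite(coords)), "trajectory coordinates must be finite")
  structure(list(coords = coords, dt = dt, box = as.numeric(box)),
            class = "srf_trajectory")
}

#' @export
print.srf_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<srf_trajectory> ", d[1], " atoms, ", d[3], " frames, dt = ",
      x$dt, " ns (", format(n_frames(x) * x$dt), " ns total)\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param traj an `srf_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

frame_coords <- function(traj, frame) {
  nf <- n_frames(traj)
  abort_if(!is_count(frame, 1L) || frame > nf,
           "frame ", frame, " out of range 1..", nf)
  traj$coords[, , frame, drop = FALSE][, , 1]
}

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks (atom-count line, comment line, one `element x y z`
#' line per atom); the comment line carries the frame time as `t=<ns>`.
#' Coordinates are printed with three decimals, the format's customary
#' precision.
#'
#' @param traj an `srf_trajectory`.
#' @param top the matching `srf_topology` (supplies element symbols).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, top, path) {
  na <- dim(traj$coords)[1]
  abort_if(na != nrow(top$atoms),
           "atom-count mismatch: trajectory has ", na,
           " atoms, topology has ", nrow(top$atoms))
  el <- top$atoms$element
  con <- file(path, open = "wt")
  on.exit(close(con))
  tt <- frame_times(traj)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = FALSE]
    writeLines(c(
      as.character(na),
      sprintf("t=%.6g", tt[f]),
      sprintf("%s %.3f %.3f %.3f", el, xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1])
    ), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file; every frame must carry the same atom count.
#' @param dt time per frame in ns (XYZ itself does not mandate one).
#' @param box box lengths (Angstrom); default generous slab.
#' @return An `srf_trajectory` with frames in file order. Parse failures
#'   (inconsistent atom counts, non-numeric coordinates, truncated frames)
#'   raise an error naming the frame.
#' @export
read_xyz_trajectory <- function(path, dt, box = c(100, 100, 200)) {
  abort_if(!file.exists(path), "trajectory file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  elements <- NULL
  i <- 1L
  f <- 0L
  n_at <- NA_integer_
  while (i <= length(lines)) {
    f <- f + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    abort_if(is.na(nat) || nat < 0,
             "XYZ parse error at frame ", f, ": bad atom-count line ", i)
    if (is.na(n_at)) n_at <- nat
    abort_if(nat != n_at, "XYZ parse error at frame ", f,
             ": atom count ", nat, " differs from first frame (", n_at, ")")
    abort_if(i + 1L + nat > length(lines),
             "XYZ parse error at frame ", f, ": truncated frame")
    block <- lines[(i + 2L):(i + 1L + nat)]
    if (nat > 0) {
      parts <- strsplit(trimws(block), "[[:space:]]+")
      bad <- which(lengths(parts) < 4)
      abort_if(length(bad) > 0, "XYZ parse error at frame ", f,
               ", atom line ", bad[1], ": expected 'element x y z'")
      el <- vapply(parts, `[[`, "", 1L)
      co <- suppressWarnings(
        vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      badnum <- which(apply(is.na(co), 2, any))
      abort_if(length(badnum) > 0, "XYZ parse error at frame ", f,
               ", atom line ", badnum[1], ": non-numeric coordinate")
      if (is.null(elements)) elements <- el
      frames[[f]] <- t(co)
    } else {
      frames[[f]] <- matrix(numeric(), 0, 3)
    }
    i <- i + 2L + nat
  }
  nf <- length(frames)
  na <- if (nf > 0) nrow(frames[[1]]) else 0L
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (k in seq_len(nf)) coords[, , k] <- frames[[k]]
  tr <- trajectory(coords, dt = dt, box = box)
  attr(tr, "elements") <- elements
  tr
}

#' Import a multi-model PDB file as a trajectory
#'
#' Convenience importer for trajectories exported as multi-model PDB. Each
#' MODEL becomes a frame; molecules are taken from the residue numbering and
#' roles must be supplied explicitly (the file format carries none).
#' Coordinates are assumed whole-molecule (no periodic-boundary unwrapping
#' is attempted). Requires the `bio3d` package.
#'
#' @param path PDB file with one or more MODEL blocks.
#' @param dt ns per model.
#' @param role_by_resid named character vector mapping residue names (e.g.
#'   `"POPC"`) to topology roles.
#' @param box box lengths (Angstrom).
#' @return list with elements `trajectory` and `topology`.
#' @export
read_pdb_trajectory <- function(path, dt, role_by_resid, box = c(100, 100, 200)) {
  abort_if(!requireNamespace("bio3d", quietly = TRUE),
           "read_pdb_trajectory requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  nat <- nrow(at)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nat, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  mol_key <- paste(at$chain, at$resno, sep = ":")
  mol_id <- as.integer(factor(mol_key, levels = unique(mol_key)))
  resid_of_mol <- at$resid[!duplicated(mol_id)]
  abort_if(!all(resid_of_mol %in% names(role_by_resid)),
           "no role mapping for residue ",
           setdiff(resid_of_mol, names(role_by_resid))[1])
  element <- ifelse(nzchar(at$elesy %||% ""), at$elesy,
                    substr(trimws(at$elety), 1, 1))
  mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)
  mass <- unname(mass_table[element])
  mass[is.na(mass)] <- 12.011
  atoms <- tibble::tibble(id = seq_len(nat), element = element,
                          mass = mass, molecule_id = mol_id)
  mols <- tibble::tibble(
    id = unique(mol_id),
    species_label = resid_of_mol,
    role = unname(role_by_resid[resid_of_mol]),
    leaflet = "n/a"
  )
  list(trajectory = trajectory(coords, dt = dt, box = box),
       topology = topology(atoms, mols))
}
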