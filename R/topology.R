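#' Molecular topology with species roles and interaction annotations
#'
#' A topology describes the static chemistry behind a trajectory: which atoms
#' belong to which molecule, what role each molecule plays in the membrane
#' system (ligand, phospholipid, sterol or ganglioside), which leaflet it sits
#' in, plus the annotations needed by the interaction-geometry module:
#' aromatic-ring atom cycles and hydrogen-bond donor/acceptor atoms.
#'
#' Coordinates live in the companion [trajectory()] object; the topology only
#' fixes atom order, elements and masses (amu).
#'
#' @param atoms data frame with columns `id` (unique integer), `element`
#'   (symbol, `"H"` marks hydrogens which are excluded from heavy-atom
#'   metrics), `mass` (amu, > 0) and `molecule_id`.
#' @param molecules data frame with columns `id`, `species_label` (free text,
#'   e.g. `"POPC"`), `role` (one of `"ligand"`, `"phospholipid"`, `"sterol"`,
#'   `"ganglioside"`) and `leaflet` (`"upper"`, `"lower"` or `"n/a"`).
#' @param rings named list keyed by molecule id (as character); each entry is
#'   a list of integer vectors, one per ring, giving the atom-id cycle
#'   (length >= 5).
#' @param hbond_donors,hbond_acceptors integer vectors of atom ids.
#' @param donor_hydrogens optional named list mapping a donor atom id (as
#'   character) to the id of its covalently bound hydrogen; enables the
#'   angle criterion in [classify_contacts()].
#'
#' @return An object of class `srf_topology`.
#' @seealso [read_topology()], [write_topology()]
#' @export
topology <- function(atoms, molecules, rings = list(),
                     hbond_donors = integer(), hbond_acceptors = integer(),
                     donor_hydrogens = NULL) {
  atoms <- tibble::as_tibble(atoms)
  molecules <- tibble::as_tibble(molecules)
  top <- structure(
    list(atoms = atoms, molecules = molecules, rings = rings,
         hbond_donors = as.integer(hbond_donors),
         hbond_acceptors = as.integer(hbond_acceptors),
         donor_hydrogens = donor_hydrogens,
         schema_version = 1L),
    class = "srf_topology"
  )
  validate_topology(top)
}

topology_roles <- c("ligand", "phospholipid", "sterol", "ganglioside")
topology_leaflets <- c("upper", "lower", "n/a")

validate_topology <- function(top) {
  a <- top$atoms
  m <- top$molecules
  need_a <- c("id", "element", "mass", "molecule_id")
  abort_if(!all(need_a %in% names(a)),
           "topology atoms need columns: ", paste(need_a, collapse = ", "))
  need_m <- c("id", "species_label", "role", "leaflet")
  abort_if(!all(need_m %in% names(m)),
           "topology molecules need columns: ", paste(need_m, collapse = ", "))
  abort_if(anyDuplicated(a$id) > 0, "duplicate atom id: ",
           a$id[anyDuplicated(a$id)])
  abort_if(anyDuplicated(m$id) > 0, "duplicate molecule id")
  abort_if(!all(a$molecule_id %in% m$id),
           "atom references unknown molecule id")
  bad_role <- setdiff(unique(m$role), topology_roles)
  abort_if(length(bad_role) > 0,
           "unknown molecule role ", dQuote(bad_role[1]),
           " (allowed: ", paste(topology_roles, collapse = ", "), ")")
  bad_leaf <- setdiff(unique(m$leaflet), topology_leaflets)
  abort_if(length(bad_leaf) > 0, "unknown leaflet label ", dQuote(bad_leaf[1]))
  abort_if(any(!is.finite(a$mass)) || any(a$mass <= 0),
           "atom masses must be positive and finite")
  for (mol in names(top$rings)) {
    abort_if(!(mol %in% as.character(m$id)),
             "rings reference unknown molecule id ", mol)
    for (ring in top$rings[[mol]]) {
      abort_if(length(ring) < 5, "ring in molecule ", mol,
               " has fewer than 5 atoms")
      missing <- setdiff(ring, a$id)
      abort_if(length(missing) > 0, "ring in molecule ", mol,
               " references missing atom id ", missing[1])
    }
  }
  for (ids in list(top$hbond_donors, top$hbond_acceptors)) {
    missing <- setdiff(ids, a$id)
    abort_if(length(missing) > 0,
             "H-bond annotation references missing atom id ", missing[1])
  }
  top
}

#' @export
print.srf_topology <- function(x, ...) {
  cat("<srf_topology> ", nrow(x$atoms), " atoms in ",
      nrow(x$molecules), " molecules\n", sep = "")
  cat("  roles: ",
      paste(sprintf("%s=%d", names(table(x$molecules$role)),
                    table(x$molecules$role)), collapse = ", "), "\n", sep = "")
  nr <- sum(lengths(x$rings))
  cat("  rings: ", nr, "; donors: ", length(x$hbond_donors),
      "; acceptors: ", length(x$hbond_acceptors), "\n", sep = "")
  invisible(x)
}

# row indices (into atoms table) of heavy atoms of one molecule
heavy_rows <- function(top, molecule_id) {
  which(top$atoms$molecule_id == molecule_id & top$atoms$element != "H")
}

atom_rows_by_id <- function(top, atom_ids) {
  match(atom_ids, top$atoms$id)
}

molecule_ids_by_role <- function(top, roles) {
  top$molecules$id[top$molecules$role %in% roles]
}

#' Write a topology to its JSON interchange form
#'
#' @param top an `srf_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  obj <- list(
    schema_version = top$schema_version,
    atoms = top$atoms,
    molecules = top$molecules,
    rings = lapply(top$rings, function(rr) lapply(rr, as.integer)),
    hbond_donors = top$hbond_donors,
    hbond_acceptors = top$hbond_acceptors
  )
  if (!is.null(top$donor_hydrogens)) obj$donor_hydrogens <- top$donor_hydrogens
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a topology from JSON
#'
#' Validates against the same invariants as [topology()]; malformed files
#' fail with a message naming the offending field.
#'
#' @param path JSON file written by [write_topology()] (or compatible).
#' @return An `srf_topology`.
#' @export
read_topology <- function(path) {
  abort_if(!file.exists(path), "topology file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  abort_if(is.null(obj$atoms), "topology JSON: missing $atoms")
  abort_if(is.null(obj$molecules), "topology JSON: missing $molecules")
  rings <- obj$rings
  if (is.null(rings) || length(rings) == 0) {
    rings <- list()
  } else {
    rings <- lapply(rings, function(rr) {
      if (is.matrix(rr)) rr <- split(rr, seq_len(nrow(rr)))
      lapply(rr, as.integer)
    })
  }
  dh <- obj$donor_hydrogens
  if (!is.null(dh)) dh <- as.list(dh)
  topology(atoms = obj$atoms, molecules = obj$molecules, rings = rings,
           hbond_donors = obj$hbond_donors %||% integer(),
           hbond_acceptors = obj$hbond_acceptors %||% integer(),
           donor_hydrogens = dh)
}
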