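#' Load and validate a pipeline configuration
#'
#' A configuration describes an end-to-end run: one or more membrane
#' systems (either synthetic-trajectory parameters or paths to an XYZ
#' trajectory plus topology JSON), the metric parameters, and optional
#' tensiometry, kinetics and imaging stages. Configurations are plain lists
#' and are conventionally written as YAML.
#'
#' @param config list, or path to a YAML file.
#' @return validated list of class `srf_pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "config must be a list or a YAML path")
  config$scenario <- config$scenario %||% "unnamed scenario"
  config$seed <- as.integer(config$seed %||% 1L)
  m <- config$metrics %||% list()
  config$metrics <- list(
    cutoff = m$cutoff %||% 4.0,
    include_ganglioside = m$include_ganglioside %||% TRUE,
    persistence_frames = m$persistence_frames %||% 10L,
    occupancy_min = m$occupancy_min %||% 0.9,
    stacking_d_max = m$stacking_d_max %||% 5.0,
    stacking_angle_max = m$stacking_angle_max %||% 30,
    dwell_frames = m$dwell_frames %||% 5L,
    release_d = m$release_d %||% 8.0)
  for (s in config$systems %||% list()) {
    abort_if(is.null(s$name), "every system needs a name")
    if (!is.null(s$traj_xyz) || !is.null(s$topology_json)) {
      abort_if(is.null(s$traj_xyz) || is.null(s$topology_json),
               "system ", s$name,
               ": file input needs both traj_xyz and topology_json")
    }
  }
  structure(config, class = "srf_pipeline_config")
}

run_system_stage <- function(sys, cfg, sys_seed) {
  met <- cfg$metrics
  if (!is.null(sys$traj_xyz)) {
    abort_if(!file.exists(sys$traj_xyz),
             "system ", sys$name, ": missing trajectory file ", sys$traj_xyz)
    abort_if(!file.exists(sys$topology_json),
             "system ", sys$name, ": missing topology file ", sys$topology_json)
    top <- read_topology(sys$topology_json)
    traj <- read_xyz_trajectory(sys$traj_xyz, dt = sys$dt %||% 0.1)
    truth <- NULL
  } else {
    fields <- intersect(names(sys), names(formals(trajectory_spec)))
    spec <- do.call(trajectory_spec, c(sys[fields], list(seed = sys_seed)))
    sim <- gen_membrane_trajectory(spec)
    top <- sim$topology
    traj <- sim$trajectory
    truth <- sim$truth
  }
  score <- compute_contact_score(traj, top, cutoff = met$cutoff,
                                 include_ganglioside = met$include_ganglioside)
  prot <- average_protrusion_series(traj, top, "POPC")
  lig <- molecule_ids_by_role(top, "ligand")
  onsets <- vapply(lig, function(l) {
    rep <- detect_insertion_onset(
      ligand_com_series(traj, top, l), prot,
      persistence_frames = met$persistence_frames,
      occupancy_min = met$occupancy_min)
    rep$onset_time_ns
  }, numeric(1))
  events <- NULL
  if (length(lig) >= 2 && length(top$rings) > 0) {
    st <- detect_stacking_pairs(traj, top, d_max = met$stacking_d_max,
                                angle_max = met$stacking_angle_max)
    pair_key <- unique(st[, c("ligand_i", "ligand_j")])
    events <- lapply(seq_len(nrow(pair_key)), function(i) {
      sub <- st[st$ligand_i == pair_key$ligand_i[i] &
                  st$ligand_j == pair_key$ligand_j[i], ]
      detect_dissociation_event(sub, dwell_frames = met$dwell_frames,
                                release_d = met$release_d)
    })
    events <- Filter(function(e) !is.na(e$formed_at_frame), events)
  }
  list(name = sys$name, score_total = score$total,
       per_ligand = score$per_ligand, onset_ns = onsets,
       events = events, truth = truth, seed = sys_seed)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: per-system
#' trajectory metrics (contact score, insertion onsets, stacking events),
#' then tensiometry (CMC), kinetics (adsorption fit) and imaging
#' (aggregate-area series). Each stage runs independently: a failing stage
#' is recorded under `$errors` with its message while the other stages'
#' results are retained. Identical config + seed reproduces the bundle
#' exactly.
#'
#' @param config an [pipeline_config()] (or list / YAML path coerced by
#'   it).
#' @return list of class `srf_report_bundle` with elements `provenance`,
#'   `systems` (tibble of score totals and onset times), `events`, `cmc`,
#'   `kinetics`, `areas`, `errors`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  sys_results <- list()
  for (i in seq_along(cfg$systems %||% list())) {
    sys <- cfg$systems[[i]]
    res <- tryCatch(run_system_stage(sys, cfg, sys_seed = cfg$seed + i),
                    error = function(e) note_error(paste0("system:", sys$name), e))
    if (!is.null(res)) sys_results[[length(sys_results) + 1L]] <- res
  }
  systems <- NULL
  if (length(sys_results) > 0) {
    systems <- tibble::tibble(
      name = vapply(sys_results, `[[`, "", "name"),
      score_total = vapply(sys_results, `[[`, numeric(1), "score_total"),
      onset_ns = I(lapply(sys_results, `[[`, "onset_ns")),
      seed = vapply(sys_results, `[[`, numeric(1), "seed"))
  }
  events <- unlist(lapply(sys_results, `[[`, "events"), recursive = FALSE)

  cmc <- NULL
  if (!is.null(cfg$tensiometry)) {
    cmc <- tryCatch({
      fields <- intersect(names(cfg$tensiometry),
                          names(formals(tensiometry_spec)))
      spec <- do.call(tensiometry_spec,
                      c(cfg$tensiometry[fields], list(seed = cfg$seed + 101L)))
      sim <- gen_tensiometry_curve(spec)
      est <- estimate_cmc(sim$curve)
      list(cmc_mM = est$cmc, degenerate = est$degenerate,
           truth_break_point = sim$truth$break_point)
    }, error = function(e) note_error("tensiometry", e))
  }

  kinetics <- NULL
  if (!is.null(cfg$kinetics)) {
    kinetics <- tryCatch({
      fields <- intersect(names(cfg$kinetics), names(formals(kinetics_spec)))
      spec <- do.call(kinetics_spec,
                      c(cfg$kinetics[fields], list(seed = cfg$seed + 202L)))
      sim <- gen_kinetics_curve(spec)
      fit <- fit_binding_kinetics(sim$curve)
      list(pi0 = fit$pi0, delta_pi_inf = fit$delta_pi_inf,
           rate_k = fit$rate_k, delta_pi_60min = fit$delta_pi_at(60),
           truth = sim$truth[c("pi0", "delta_pi_inf", "rate_k")])
    }, error = function(e) note_error("kinetics", e))
  }

  areas <- NULL
  if (!is.null(cfg$images)) {
    areas <- tryCatch({
      fields <- intersect(names(cfg$images),
                          names(formals(aggregate_image_spec)))
      spec <- do.call(aggregate_image_spec,
                      c(cfg$images[fields], list(seed = cfg$seed + 303L)))
      sim <- gen_aggregate_image_series(spec)
      aggregate_area_series(sim$images)
    }, error = function(e) note_error("images", e))
  }

  provenance <- list(
    scenario = cfg$scenario,
    package_version = as.character(packageVersion("seroraft")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    metrics = cfg$metrics)
  structure(list(provenance = provenance, systems = systems, events = events,
                 cmc = cmc, kinetics = kinetics, areas = areas,
                 errors = errors),
            class = "srf_report_bundle")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Render a report bundle as JSON or markdown
#'
#' The provenance block (scenario, package version, seed, config hash,
#' metric parameters) always comes first so every number in the report is
#' traceable to its inputs.
#'
#' @param bundle an `srf_report_bundle` from [run_pipeline()].
#' @param format `"json"` or `"markdown"`.
#' @param path optional output file.
#' @return the document as a character scalar, invisibly when written to
#'   `path`.
#' @export
generate_report <- function(bundle, format = c("json", "markdown"),
                            path = NULL) {
  format <- match.arg(format)
  abort_if(!inherits(bundle, "srf_report_bundle"),
           "bundle must come from run_pipeline()")
  if (format == "json") {
    obj <- bundle_to_list(bundle)
    doc <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE))
  } else {
    doc <- bundle_to_markdown(bundle)
  }
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

bundle_to_list <- function(b) {
  ev <- lapply(b$events %||% list(), function(e) {
    list(ligand_i = e$ligand_i, ligand_j = e$ligand_j,
         formed_at_ns = e$formed_at_ns,
         dissociated_at_ns = e$dissociated_at_ns)
  })
  list(provenance = b$provenance,
       systems = if (is.null(b$systems)) NULL else {
         df <- as.data.frame(b$systems)
         df$onset_ns <- lapply(df$onset_ns, as.numeric)
         df
       },
       events = ev, cmc = b$cmc, kinetics = b$kinetics,
       areas = if (is.null(b$areas)) NULL else as.data.frame(b$areas),
       errors = b$errors)
}

bundle_to_markdown <- function(b) {
  num <- function(x) sprintf("%.6g", x)
  lines <- c("# seroraft report", "",
             "## Provenance", "",
             paste0("- scenario: ", b$provenance$scenario),
             paste0("- package version: ", b$provenance$package_version),
             paste0("- seed: ", b$provenance$seed),
             paste0("- config hash: ", b$provenance$config_hash), "")
  if (!is.null(b$systems)) {
    lines <- c(lines, "## Membrane systems", "",
               "| system | score total | onsets (ns) |",
               "|---|---|---|",
               vapply(seq_len(nrow(b$systems)), function(i) {
                 on <- as.numeric(b$systems$onset_ns[[i]])
                 sprintf("| %s | %s | %s |", b$systems$name[i],
                         num(b$systems$score_total[i]),
                         paste(ifelse(is.na(on), "none", num(on)),
                               collapse = ", "))
               }, ""), "")
  }
  for (e in b$events %||% list()) {
    lines <- c(lines, sprintf(
      "- dimer (%d, %d): formed %s ns, dissociated %s ns",
      e$ligand_i, e$ligand_j, num(e$formed_at_ns),
      if (is.na(e$dissociated_at_ns)) "never" else num(e$dissociated_at_ns)))
  }
  if (!is.null(b$cmc)) {
    lines <- c(lines, "", "## CMC", "",
               paste0("- estimate: ", num(b$cmc$cmc_mM), " mM"),
               paste0("- planted break point: ",
                      num(b$cmc$truth_break_point), " mM"))
  }
  if (!is.null(b$kinetics)) {
    lines <- c(lines, "", "## Adsorption kinetics", "",
               sprintf("- delta_pi_inf = %s mN/m, k = %s /min, delta_pi(60 min) = %s mN/m",
                       num(b$kinetics$delta_pi_inf), num(b$kinetics$rate_k),
                       num(b$kinetics$delta_pi_60min)))
  }
  if (!is.null(b$areas)) {
    lines <- c(lines, "", "## Aggregate areas", "",
               "| time | area (px^2) | area (mm^2) | components |",
               "|---|---|---|---|",
               vapply(seq_len(nrow(b$areas)), function(i) {
                 sprintf("| %s | %s | %s | %d |", num(b$areas$time[i]),
                         num(b$areas$area_px2[i]), num(b$areas$area_mm2[i]),
                         as.integer(b$areas$n_components[i]))
               }, ""))
  }
  if (length(b$errors) > 0) {
    lines <- c(lines, "", "## Stage errors", "",
               sprintf("- %s: %s", names(b$errors), unlist(b$errors)))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.srf_report_bundle <- function(x, ...) {
  cat("<srf_report_bundle> scenario: ", x$provenance$scenario, "\n", sep = "")
  if (!is.null(x$systems)) print(x$systems)
  if (length(x$errors) > 0) {
    cat("stage errors: ", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
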