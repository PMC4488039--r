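# Pipeline driver: chains the stages of database construction
# (fixtures -> init -> ingest -> georef -> geo -> qaqc -> export) from a
# single master configuration, with a line-oriented provenance run log.
# Each stage is idempotent on identical inputs and refuses to run before
# its prerequisites, so a build is resumable and every export can be
# traced to the inputs and configuration that produced it.

#' Load a master pipeline configuration
#'
#' @param config a YAML file path or a named list. Recognized keys:
#'   `store` (store directory), `crs`, `census_min_area_ha` (default 4),
#'   `tolerance_m` (default 100), `data_dir` (where fixture/source files
#'   live), `fixtures` (n_lakes, seed, styles, n_samples, error_rate,
#'   egregious_rate), `sources` (list of table/mapping/sites file
#'   triples), `export` (dir, major, patch, created_date, change_notes),
#'   `run_log` (log file path).
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$store)) stop("config lacks a store path")
  cfg$census_min_area_ha <- cfg$census_min_area_ha %||% 4
  cfg$tolerance_m <- cfg$tolerance_m %||% 100
  cfg$data_dir <- cfg$data_dir %||% file.path(dirname(cfg$store), "data")
  cfg$run_log <- cfg$run_log %||% file.path(dirname(cfg$store), "run.log")
  cfg$export <- cfg$export %||% list()
  cfg$export$dir <- cfg$export$dir %||% file.path(dirname(cfg$store), "exports")
  cfg
}

log_run <- function(cfg, stage, info = list()) {
  tf <- tempfile()
  yaml::write_yaml(cfg, tf)
  digest <- substr(unname(tools::md5sum(tf)), 1, 12)
  unlink(tf)
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, config_digest = digest),
           info)
  dir.create(dirname(cfg$run_log), recursive = TRUE, showWarnings = FALSE)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = cfg$run_log, append = TRUE, sep = "")
  invisible(rec)
}

stage_fixtures <- function(cfg) {
  fx <- cfg$fixtures %||% list()
  n_lakes <- fx$n_lakes %||% 24
  seed <- fx$seed %||% 1
  styles <- fx$styles %||% c("wide_state", "long_citizen", "odd_university")
  dd <- cfg$data_dir
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  ls <- gen_landscape(n_lakes = n_lakes, seed = seed)
  write_geojson(ls$waterbodies, file.path(dd, "waterbodies.geojson"))
  write_geojson(ls$zones, file.path(dd, "zones.geojson"))
  write_geojson(ls$landcover, file.path(dd, "landcover.geojson"))
  utils::write.csv(ls$streams, file.path(dd, "streams.csv"), row.names = FALSE)
  utils::write.csv(ls$ledger$lakes, file.path(dd, "ledger_lakes.csv"),
                   row.names = FALSE)
  sources <- list()
  for (k in seq_along(styles)) {
    st <- styles[[k]]
    src <- gen_source_dataset(ls, style = st,
                              n_samples = fx$n_samples %||% 4,
                              error_rate = fx$error_rate %||% 0,
                              egregious_rate = fx$egregious_rate %||% 0,
                              censored_rate = fx$censored_rate %||% 0,
                              seed = seed + k)
    tb <- file.path(dd, paste0(st, ".csv"))
    mp <- file.path(dd, paste0(st, "_mapping.yaml"))
    si <- file.path(dd, paste0(st, "_sites.csv"))
    utils::write.csv(src$table, tb, row.names = FALSE)
    yaml::write_yaml(unclass(src$mapping), mp)
    utils::write.csv(src$sites, si, row.names = FALSE)
    utils::write.csv(src$ledger$values,
                     file.path(dd, paste0(st, "_ledger_values.csv")),
                     row.names = FALSE)
    utils::write.csv(src$ledger$sites,
                     file.path(dd, paste0(st, "_ledger_sites.csv")),
                     row.names = FALSE)
    sources[[k]] <- list(table = tb, mapping = mp, sites = si,
                         provider_type = src$ledger$provider_type,
                         provider_name = paste0("Synthetic ", st, " provider"))
  }
  yaml::write_yaml(sources, file.path(dd, "sources.yaml"))
  log_run(cfg, "fixtures", list(n_lakes = n_lakes, seed = seed,
                                n_sources = length(sources)))
  invisible(ls)
}

stage_init <- function(cfg, overwrite = FALSE) {
  if (dir.exists(cfg$store) &&
      file.exists(file.path(cfg$store, "manifest.json")) && !overwrite) {
    log_run(cfg, "init", list(skipped = TRUE))
    return(invisible(open_store(cfg$store)))
  }
  store <- init_store(cfg$store,
                      config = list(crs = cfg$crs,
                                    census_min_area_ha = cfg$census_min_area_ha),
                      overwrite = overwrite)
  log_run(cfg, "init", list(created = TRUE))
  invisible(store)
}

pipeline_sources <- function(cfg) {
  if (!is.null(cfg$sources)) return(cfg$sources)
  sf <- file.path(cfg$data_dir, "sources.yaml")
  if (file.exists(sf)) return(yaml::read_yaml(sf))
  stop("no sources configured: run the fixtures stage or list sources in the config")
}

stage_ingest <- function(cfg) {
  store <- open_store(cfg$store)
  vocab <- load_vocabulary(cfg$vocabulary %||%
                             system.file("extdata", "vocabulary.yaml",
                                         package = "limnopipe"))
  add_variables(store, vocab)
  wb_file <- file.path(cfg$data_dir, "waterbodies.geojson")
  if (!file.exists(wb_file))
    stop("missing prerequisite: waterbody layer ", wb_file,
         " (run the fixtures stage or provide inputs)")
  if (nrow(store$tables$lakes) == 0) {
    wb <- read_geojson(wb_file)
    wb <- census_filter(wb, min_area_ha = cfg$census_min_area_ha)
    add_lakes(store, wb)
  }
  staged <- list()
  issues_all <- list()
  for (src in pipeline_sources(cfg)) {
    mapping <- load_mapping(src$mapping)
    sid <- mapping$source_id
    if (sid %in% store$tables$sources$source_id) next  # idempotent rerun
    add_source(store, sid, src$provider_type %||% "state",
               src$provider_name %||% sid,
               checklist = list(methods = TRUE, depth = TRUE,
                                location = TRUE, unaggregated = !mapping$aggregated))
    add_program(store, paste0(sid, "_p1"), sid)
    tab <- utils::read.csv(src$table, colClasses = "character",
                           check.names = FALSE)
    h <- harmonize_table(tab, mapping, vocab)
    h$observations$program_id <- paste0(sid, "_p1")
    staged[[sid]] <- h$observations
    issues_all[[sid]] <- h$issues
  }
  if (length(staged)) {
    stg <- do.call(rbind, staged)
    utils::write.csv(stg, file.path(store$path, "staged_observations.csv"),
                     row.names = FALSE, na = "")
  }
  iss <- if (length(issues_all)) do.call(rbind, issues_all) else empty_issue_frame()
  utils::write.csv(iss, file.path(store$path, "harmonization_issues.csv"),
                   row.names = FALSE)
  store_save(store)
  log_run(cfg, "ingest", list(n_sources = nrow(store$tables$sources),
                              n_staged = if (length(staged)) nrow(do.call(rbind, staged)) else 0,
                              n_issues = nrow(iss)))
  invisible(store)
}

stage_georef <- function(cfg) {
  store <- open_store(cfg$store)
  if (nrow(store$tables$lakes) == 0)
    stop("missing prerequisite: no lakes loaded (run ingest before georef)")
  lakes <- store$tables$lakes[store$tables$lakes$is_census, , drop = FALSE]
  lakes$geometry <- lapply(lakes$lake_id, function(id) lake_geometry(store, id))
  all_matches <- list()
  for (src in pipeline_sources(cfg)) {
    sites <- utils::read.csv(src$sites, stringsAsFactors = FALSE)
    gr <- georeference_dataset(sites, lakes, tolerance_m = cfg$tolerance_m)
    all_matches[[length(all_matches) + 1]] <- gr$matches
  }
  matches <- do.call(rbind, all_matches)
  # optional human review decisions
  if (!is.null(cfg$review_decisions) && file.exists(cfg$review_decisions))
    matches <- apply_review_decisions(matches, cfg$review_decisions)
  store$tables$site_matches <- matches[, names(store_table_prototypes()$site_matches)]
  # attach staged observations through attachable matches
  stg_file <- file.path(store$path, "staged_observations.csv")
  n_attached <- 0L
  if (file.exists(stg_file) && nrow(store$tables$observations) == 0) {
    # read as text so provenance cell text survives byte-for-byte
    stg <- utils::read.csv(stg_file, colClasses = "character", na.strings = "")
    for (cn in c("value", "sample_depth_m", "detection_limit"))
      stg[[cn]] <- as.numeric(stg[[cn]])
    stg$source_row_ref <- as.integer(stg$source_row_ref)
    attachable <- matches[!is.na(matches$lake_id) & !matches$needs_review, ,
                          drop = FALSE]
    key <- paste(attachable$source_id, attachable$site_ref)
    skey <- paste(stg$source_id, stg$site_ref)
    stg$lake_id <- attachable$lake_id[match(skey, key)]
    keep <- !is.na(stg$lake_id)
    obs <- stg[keep, , drop = FALSE]
    obs$site_ref <- NULL
    add_observations(store, obs)
    n_attached <- sum(keep)
  }
  store_save(store)
  log_run(cfg, "georef", list(n_sites = nrow(matches),
                              n_review = sum(matches$needs_review),
                              n_attached = n_attached))
  invisible(store)
}

stage_geo <- function(cfg) {
  store <- open_store(cfg$store)
  if (nrow(store$tables$lakes) == 0)
    stop("missing prerequisite: no lakes loaded (run ingest before geo)")
  lakes <- store$tables$lakes[store$tables$lakes$is_census, , drop = FALSE]
  lakes$geometry <- lapply(lakes$lake_id, function(id) lake_geometry(store, id))
  zones <- read_geojson(file.path(cfg$data_dir, "zones.geojson"))
  landcover <- read_geojson(file.path(cfg$data_dir, "landcover.geojson"))
  streams <- utils::read.csv(file.path(cfg$data_dir, "streams.csv"),
                             stringsAsFactors = FALSE)
  # zone catalogue: input zones + shoreline buffers
  buf <- build_buffer_zones(lakes, distances_m = cfg$buffer_distances_m %||% c(100, 500))
  zdefs <- rbind(
    data.frame(zone_id = zones$zone_id, zone_type = zones$zone_type,
               buffer_distance_m = NA_real_, lake_id = NA_integer_,
               stringsAsFactors = FALSE),
    buf$zone_defs[, c("zone_id", "zone_type", "buffer_distance_m", "lake_id")])
  store$tables$zone_defs <- zdefs
  store$tables$zone_membership <- assign_zone_membership(lakes, zones)
  # land-cover composition for every non-buffer zone and 100 m buffer ring
  zm <- list()
  for (i in seq_len(nrow(zones))) {
    zm[[length(zm) + 1]] <- zonal_summary_categorical(
      zones[i, , drop = FALSE], landcover)
  }
  store$tables$zone_metrics <- do.call(rbind, zm)
  # connectivity classes as lake-level metrics on the run log
  net <- build_flow_network(streams, lakes, snap_m = cfg$snap_m %||% 50)
  conn <- classify_all_lakes(net)
  utils::write.csv(conn, file.path(store$path, "connectivity.csv"),
                   row.names = FALSE)
  store_save(store)
  log_run(cfg, "geo", list(n_zones = nrow(zdefs),
                           n_metrics = nrow(store$tables$zone_metrics),
                           n_classified = nrow(conn)))
  invisible(store)
}

stage_qaqc <- function(cfg) {
  store <- open_store(cfg$store)
  if (nrow(store$tables$observations) == 0)
    stop("missing prerequisite: no observations loaded (run ingest and georef before qaqc)")
  vocab <- load_vocabulary(cfg$vocabulary %||%
                             system.file("extdata", "vocabulary.yaml",
                                         package = "limnopipe"))
  rules <- load_qaqc_rules(cfg$qaqc_rules %||%
                             system.file("extdata", "qaqc_rules.yaml",
                                         package = "limnopipe"))
  qaqc_store(store, vocab, rules)
  rep <- qaqc_report(store, out_dir = store$path)
  store_save(store)
  log_run(cfg, "qaqc", list(n_flags = rep$n_flags, n_deleted = rep$n_deleted,
                            flag_rate = rep$flag_rate))
  invisible(store)
}

stage_export <- function(cfg) {
  store <- open_store(cfg$store)
  if (nrow(store$tables$observations) == 0)
    stop("missing prerequisite: no observations loaded (run the earlier stages before export)")
  vocab <- load_vocabulary(cfg$vocabulary %||%
                             system.file("extdata", "vocabulary.yaml",
                                         package = "limnopipe"))
  ex <- cfg$export
  ver <- register_version(store, major = ex$major %||% 1L,
                          patch = ex$patch %||% 0L,
                          change_notes = ex$change_notes %||% "initial export",
                          created_date = ex$created_date %||% as.character(Sys.Date()))
  manifest <- export_flat(store, ex$dir, version = ver)
  doc <- write_user_doc(store, manifest, vocab, ex$dir)
  store_save(store)
  log_run(cfg, "export", list(version = ver$version_string,
                              n_cells = manifest$observation_count,
                              doc = basename(doc)))
  invisible(manifest)
}

stage_report <- function(cfg) {
  store <- open_store(cfg$store)
  rep <- qaqc_report(store)
  log_run(cfg, "report", list(n_flags = rep$n_flags))
  rep
}

#' Run pipeline stages from a master configuration
#'
#' Stages run in canonical order regardless of the order given. Each
#' appends a provenance record (inputs, configuration digest, counts) to
#' the run log; reruns on identical inputs are no-ops for already
#' completed work.
#'
#' @param config YAML path or list (see [load_pipeline_config()]).
#' @param stages character vector drawn from fixtures, init, ingest,
#'   georef, geo, qaqc, export, report; default runs everything.
#' @param overwrite passed to the init stage.
#' @return invisibly, the result of the last stage.
#' @export
run_pipeline <- function(config,
                         stages = c("fixtures", "init", "ingest", "georef",
                                    "geo", "qaqc", "export"),
                         overwrite = FALSE) {
  cfg <- load_pipeline_config(config)
  order <- c("fixtures", "init", "ingest", "georef", "geo", "qaqc",
             "export", "report")
  unknown <- setdiff(stages, order)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- order[order %in% stages]
  res <- NULL
  for (st in stages) {
    res <- switch(st,
                  fixtures = stage_fixtures(cfg),
                  init = stage_init(cfg, overwrite = overwrite),
                  ingest = stage_ingest(cfg),
                  georef = stage_georef(cfg),
                  geo = stage_geo(cfg),
                  qaqc = stage_qaqc(cfg),
                  export = stage_export(cfg),
                  report = stage_report(cfg))
  }
  invisible(res)
}
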