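# The relational core of the pipeline: a vertical observation module
# (sources -> programs -> observations) joined to the geospatial module
# (zones, zone metrics) through the aggregated-lakes table, with QAQC
# flags, review-queue matches and export versions alongside.
#
# The store lives in memory as an environment of data.frames and persists
# to a plain-text store directory: one CSV per table, the schema as SQL
# DDL text, a JSON manifest, and geometry layers as GeoJSON under layers/.

store_table_prototypes <- function() {
  list(
    lakes = data.frame(
      lake_id = integer(), source_polygon_id = character(), name = character(),
      centroid_x = numeric(), centroid_y = numeric(), area_ha = numeric(),
      geometry_ref = character(), is_census = logical(),
      excluded_reason = character(), stringsAsFactors = FALSE),
    sources = data.frame(
      source_id = character(), provider_type = character(),
      provider_name = character(), provenance_uri = character(),
      mc_methods = logical(), mc_depth = logical(), mc_location = logical(),
      mc_unaggregated = logical(), stringsAsFactors = FALSE),
    programs = data.frame(
      program_id = character(), source_id = character(),
      sampling_type = character(), temporal_resolution = character(),
      stringsAsFactors = FALSE),
    variables = data.frame(
      canonical_name = character(), long_name = character(),
      canonical_units = character(), category = character(),
      valid_min = numeric(), valid_max = numeric(), egregious_max = numeric(),
      stringsAsFactors = FALSE),
    observations = data.frame(
      obs_id = integer(), lake_id = integer(), program_id = character(),
      variable = character(), value = numeric(), sample_date = character(),
      sample_depth_m = numeric(), depth_code = character(),
      censor_code = character(), detection_limit = numeric(),
      method_code = character(), source_id = character(),
      source_row_ref = integer(), source_column_ref = character(),
      original_value_text = character(), original_units = character(),
      live = logical(), stringsAsFactors = FALSE),
    flags = data.frame(
      flag_id = integer(), target_type = character(), obs_id = integer(),
      zone_id = character(), metric_name = character(), rule_id = character(),
      severity = character(), disposition = character(), note = character(),
      stringsAsFactors = FALSE),
    zone_defs = data.frame(
      zone_id = character(), zone_type = character(),
      buffer_distance_m = numeric(), lake_id = integer(),
      stringsAsFactors = FALSE),
    zone_metrics = data.frame(
      zone_id = character(), theme = character(), metric_name = character(),
      value = numeric(), units = character(), year = integer(),
      flag = character(), stringsAsFactors = FALSE),
    zone_membership = data.frame(
      lake_id = integer(), zone_id = character(), zone_type = character(),
      flag = character(), stringsAsFactors = FALSE),
    site_matches = data.frame(
      source_id = character(), site_ref = character(), lake_id = integer(),
      method = character(), distance_m = numeric(), needs_review = logical(),
      note = character(), stringsAsFactors = FALSE),
    versions = data.frame(
      version_string = character(), created_date = character(),
      dataset_count = integer(), observation_count = integer(),
      change_notes = character(), stringsAsFactors = FALSE)
  )
}

sql_type_for <- function(v) {
  switch(class(v)[1],
         integer = "INTEGER", numeric = "REAL", logical = "BOOLEAN",
         "TEXT")
}

#' Emit the store schema as SQL DDL text
#'
#' Documentation artifact: the plain-text CREATE TABLE statements matching
#' the store's relational layout.
#'
#' @return character scalar of SQL DDL.
#' @export
store_schema_sql <- function() {
  protos <- store_table_prototypes()
  stmts <- vapply(names(protos), function(tn) {
    p <- protos[[tn]]
    cols <- paste0("  ", names(p), " ", vapply(p, sql_type_for, character(1)))
    paste0("CREATE TABLE ", tn, " (\n", paste(cols, collapse = ",\n"), "\n);")
  }, character(1))
  paste(stmts, collapse = "\n\n")
}

#' Initialize a new pipeline store
#'
#' Creates the store directory with empty tables, the SQL schema document
#' and a manifest, and returns an open store handle.
#'
#' @param path directory to create the store in.
#' @param config optional named list of configuration recorded in the
#'   manifest (e.g. `census_min_area_ha`, `crs`).
#' @param overwrite replace an existing store at `path`? Default FALSE;
#'   initializing over an existing store without `overwrite` is an error.
#' @return a `limno_store` handle.
#' @export
init_store <- function(path, config = list(), overwrite = FALSE) {
  if (dir.exists(path) && file.exists(file.path(path, "manifest.json"))) {
    if (!overwrite)
      stop("store already exists at ", path, " (use overwrite = TRUE)")
    unlink(path, recursive = TRUE)
  }
  dir.create(file.path(path, "layers"), recursive = TRUE, showWarnings = FALSE)
  store <- new.env(parent = emptyenv())
  store$path <- normalizePath(path)
  store$tables <- store_table_prototypes()
  store$config <- config
  class(store) <- "limno_store"
  writeLines(store_schema_sql(), file.path(path, "schema.sql"))
  store_save(store)
  store
}

#' Persist a store's tables and manifest to its directory
#' @param store a `limno_store` handle.
#' @return the store, invisibly.
#' @export
store_save <- function(store) {
  for (tn in names(store$tables)) {
    utils::write.csv(store$tables[[tn]],
                     file.path(store$path, paste0(tn, ".csv")),
                     row.names = FALSE, na = "")
  }
  manifest <- list(
    format = "limnopipe-store", format_version = 1L,
    config = store$config,
    tables = lapply(store$tables, nrow)
  )
  jsonlite::write_json(manifest, file.path(store$path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(store)
}

#' Open an existing pipeline store
#' @param path store directory created by [init_store()].
#' @return a `limno_store` handle.
#' @export
open_store <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no store manifest at ", path)
  manifest <- jsonlite::fromJSON(mf)
  store <- new.env(parent = emptyenv())
  store$path <- normalizePath(path)
  store$config <- as.list(manifest$config)
  protos <- store_table_prototypes()
  store$tables <- lapply(names(protos), function(tn) {
    f <- file.path(path, paste0(tn, ".csv"))
    proto <- protos[[tn]]
    if (!file.exists(f)) return(proto)
    classes <- vapply(proto, function(v) class(v)[1], character(1))
    df <- utils::read.csv(f, colClasses = "character", na.strings = "")
    if (nrow(df) == 0) return(proto)
    for (cn in names(proto)) {
      df[[cn]] <- switch(classes[[cn]],
                         integer = as.integer(df[[cn]]),
                         numeric = as.numeric(df[[cn]]),
                         logical = as.logical(df[[cn]]),
                         as.character(df[[cn]]))
    }
    df[, names(proto), drop = FALSE]
  })
  names(store$tables) <- names(protos)
  class(store) <- "limno_store"
  store
}

#' @export
print.limno_store <- function(x, ...) {
  cat("<limno_store> at", x$path, "\n")
  for (tn in names(x$tables)) cat(sprintf("  %-16s %d rows\n", tn, nrow(x$tables[[tn]])))
  invisible(x)
}

store_append <- function(store, table, rows) {
  proto <- store_table_prototypes()[[table]]
  missing <- setdiff(names(proto), names(rows))
  for (cn in missing) rows[[cn]] <- proto[[cn]][NA_integer_][seq_len(nrow(rows))]
  store$tables[[table]] <- rbind(store$tables[[table]], rows[, names(proto), drop = FALSE])
  invisible(store)
}

#' Register a source dataset and its minimum-requirements checklist
#'
#' A source may only contribute observations when all four minimum
#' requirements hold: methods metadata present, sample depth reported,
#' location reported, and values not pre-aggregated into means or medians.
#'
#' @param store a `limno_store`.
#' @param source_id unique source identifier.
#' @param provider_type one of federal, state, tribal, citizen, nonprofit,
#'   university, LTER.
#' @param provider_name human-readable provider name.
#' @param checklist named logical vector/list with elements `methods`,
#'   `depth`, `location`, `unaggregated`.
#' @param provenance_uri optional locator of the original dataset.
#' @export
add_source <- function(store, source_id, provider_type, provider_name,
                       checklist, provenance_uri = NA_character_) {
  types <- c("federal", "state", "tribal", "citizen", "nonprofit",
             "university", "LTER")
  if (!provider_type %in% types)
    stop("unknown provider_type: ", provider_type)
  if (source_id %in% store$tables$sources$source_id)
    stop("duplicate source_id: ", source_id)
  need <- c("methods", "depth", "location", "unaggregated")
  if (!all(need %in% names(checklist)))
    stop("checklist must name: ", paste(need, collapse = ", "))
  store_append(store, "sources", data.frame(
    source_id = source_id, provider_type = provider_type,
    provider_name = provider_name, provenance_uri = provenance_uri,
    mc_methods = isTRUE(checklist[["methods"]]),
    mc_depth = isTRUE(checklist[["depth"]]),
    mc_location = isTRUE(checklist[["location"]]),
    mc_unaggregated = isTRUE(checklist[["unaggregated"]]),
    stringsAsFactors = FALSE))
}

#' Register a sampling program under a source
#' @param store a `limno_store`.
#' @param program_id unique program identifier.
#' @param source_id existing source the program belongs to.
#' @param sampling_type "survey" or "long_term".
#' @param temporal_resolution free-text description.
#' @export
add_program <- function(store, program_id, source_id,
                        sampling_type = "survey",
                        temporal_resolution = NA_character_) {
  if (!source_id %in% store$tables$sources$source_id)
    stop("program references unknown source_id: ", source_id)
  if (!sampling_type %in% c("survey", "long_term"))
    stop("sampling_type must be survey or long_term")
  store_append(store, "programs", data.frame(
    program_id = program_id, source_id = source_id,
    sampling_type = sampling_type, temporal_resolution = temporal_resolution,
    stringsAsFactors = FALSE))
}

#' Load census/candidate lakes into the aggregated-lakes table
#'
#' Surrogate integer `lake_id`s are assigned in input order, continuing
#' from the current maximum; the source polygon identifier is preserved
#' for traceability.
#'
#' @param store a `limno_store`.
#' @param lakes layer data.frame from [census_filter()] (needs columns
#'   source_polygon_id, name, area_ha, is_census, excluded_reason and a
#'   geometry list-column).
#' @return the store, with lake_id added to nothing; lakes are stored and
#'   their geometries written under layers/.
#' @export
add_lakes <- function(store, lakes) {
  n0 <- nrow(store$tables$lakes)
  ids <- seq_len(nrow(lakes)) + n0
  cent <- t(vapply(lakes$geometry, poly_centroid, numeric(2)))
  geom_ref <- sprintf("layers/lake_%06d.geojson", ids)
  rows <- data.frame(
    lake_id = as.integer(ids),
    source_polygon_id = as.character(lakes$source_polygon_id),
    name = if ("name" %in% names(lakes)) as.character(lakes$name) else NA_character_,
    centroid_x = cent[, 1], centroid_y = cent[, 2],
    area_ha = lakes$area_ha, geometry_ref = geom_ref,
    is_census = lakes$is_census,
    excluded_reason = if ("excluded_reason" %in% names(lakes))
      as.character(lakes$excluded_reason) else NA_character_,
    stringsAsFactors = FALSE)
  bad <- rows$area_ha <= 0
  if (any(bad)) stop("lake area_ha must be positive: ",
                     paste(rows$source_polygon_id[bad], collapse = ", "))
  for (i in seq_along(ids)) {
    layer <- data.frame(lake_id = ids[i], stringsAsFactors = FALSE)
    layer$geometry <- list(lakes$geometry[[i]])
    attr(layer, "crs") <- store$config$crs
    write_geojson(layer, file.path(store$path, geom_ref[i]))
  }
  store_append(store, "lakes", rows)
}

#' Read a stored lake geometry
#' @param store a `limno_store`.
#' @param lake_id the lake's surrogate key.
#' @return the polygon vertex matrix.
#' @export
lake_geometry <- function(store, lake_id) {
  lk <- store$tables$lakes
  i <- match(lake_id, lk$lake_id)
  if (is.na(i)) stop("unknown lake_id: ", lake_id)
  read_geojson(file.path(store$path, lk$geometry_ref[i]))$geometry[[1]]
}

#' Append harmonized observations to the vertical store
#'
#' Enforces the minimum-requirements rule (all four checklist items must be
#' true for the source), resolvable lake/program references, resolvable
#' variables, and non-empty provenance.
#'
#' @param store a `limno_store`.
#' @param observations data.frame in the observation layout produced by
#'   [harmonize_table()] plus a `lake_id` column from georeferencing.
#' @export
add_observations <- function(store, observations) {
  if (nrow(observations) == 0) return(invisible(store))
  src <- store$tables$sources
  for (sid in unique(observations$source_id)) {
    i <- match(sid, src$source_id)
    if (is.na(i)) stop("observations reference unknown source_id: ", sid)
    if (!all(src$mc_methods[i], src$mc_depth[i], src$mc_location[i],
             src$mc_unaggregated[i]))
      stop("source ", sid, " fails the minimum-requirements checklist; ",
           "its observations cannot be loaded")
  }
  if (!all(observations$program_id %in% store$tables$programs$program_id))
    stop("observations reference unknown program_id")
  if (!all(observations$lake_id %in% store$tables$lakes$lake_id))
    stop("observations reference unknown lake_id")
  known_vars <- store$tables$variables$canonical_name
  bad <- !observations$variable %in% known_vars
  if (any(bad))
    stop("unknown variable(s): ", paste(unique(observations$variable[bad]), collapse = ", "))
  n0 <- nrow(store$tables$observations)
  observations$obs_id <- as.integer(seq_len(nrow(observations)) + n0)
  observations$live <- TRUE
  store_append(store, "observations", observations)
}

#' Load a controlled vocabulary's variable definitions into the store
#' @param store a `limno_store`.
#' @param vocab a `controlled_vocabulary` from [load_vocabulary()].
#' @export
add_variables <- function(store, vocab) {
  store$tables$variables <- vocab$variables[, names(store_table_prototypes()$variables)]
  invisible(store)
}

#' Check referential integrity of a store
#'
#' Reports every dangling foreign reference, duplicate key,
#' minimum-requirements checklist failure for sources with loaded
#' observations, and census/flag invariant violation. An empty result
#' means the store is consistent.
#'
#' @param store a `limno_store`.
#' @return data.frame with columns table, id, problem (0 rows if clean).
#' @export
validate_integrity <- function(store) {
  v <- list()
  add <- function(table, id, problem)
    v[[length(v) + 1]] <<- data.frame(table = table, id = as.character(id),
                                      problem = problem, stringsAsFactors = FALSE)
  tb <- store$tables
  dup <- function(x) unique(x[duplicated(x)])
  for (d in dup(tb$lakes$lake_id)) add("lakes", d, "duplicate lake_id")
  for (d in dup(tb$sources$source_id)) add("sources", d, "duplicate source_id")
  for (d in dup(tb$programs$program_id)) add("programs", d, "duplicate program_id")
  for (d in dup(tb$variables$canonical_name)) add("variables", d, "duplicate canonical_name")
  for (d in dup(tb$zone_defs$zone_id)) add("zone_defs", d, "duplicate zone_id")
  bad <- !tb$programs$source_id %in% tb$sources$source_id
  for (id in tb$programs$program_id[bad]) add("programs", id, "source_id does not resolve")
  ob <- tb$observations
  bad <- !ob$lake_id %in% tb$lakes$lake_id
  for (id in ob$obs_id[bad]) add("observations", id, "lake_id does not resolve")
  bad <- !ob$program_id %in% tb$programs$program_id
  for (id in ob$obs_id[bad]) add("observations", id, "program_id does not resolve")
  bad <- !ob$variable %in% tb$variables$canonical_name
  for (id in ob$obs_id[bad]) add("observations", id, "variable not in vocabulary")
  bad <- is.na(ob$source_id) | is.na(ob$source_row_ref) |
    is.na(ob$source_column_ref) | is.na(ob$original_value_text)
  for (id in ob$obs_id[bad]) add("observations", id, "provenance fields incomplete")
  bad <- is.na(ob$value) &
    !(ob$censor_code == "below_detection" & !is.na(ob$detection_limit))
  for (id in ob$obs_id[bad])
    add("observations", id, "value absent without a censored detection limit")
  # checklist rule: any source with loaded observations must pass all four
  src <- tb$sources
  with_obs <- unique(ob$source_id)
  for (sid in with_obs) {
    i <- match(sid, src$source_id)
    if (is.na(i)) { add("observations", sid, "source_id does not resolve"); next }
    fails <- c(methods = !src$mc_methods[i], depth = !src$mc_depth[i],
               location = !src$mc_location[i], unaggregated = !src$mc_unaggregated[i])
    for (nm in names(fails)[fails])
      add("sources", sid, paste0("metadata_checklist.", nm,
                                 " = FALSE but observations are loaded"))
  }
  # census invariant
  lk <- tb$lakes
  min_ha <- store$config$census_min_area_ha
  if (is.null(min_ha)) min_ha <- 4
  bad <- lk$is_census & (!is.na(lk$excluded_reason) | lk$area_ha < min_ha)
  for (id in lk$lake_id[bad]) add("lakes", id, "census lake violates census invariants")
  # flags: egregious <=> deleted; flagged targets resolve
  fl <- tb$flags
  bad <- (fl$severity == "egregious") != (fl$disposition == "deleted")
  for (id in fl$flag_id[bad]) add("flags", id, "severity/disposition mismatch")
  bad <- fl$target_type == "observation" & !fl$obs_id %in% ob$obs_id
  for (id in fl$flag_id[bad]) add("flags", id, "obs_id does not resolve")
  bad <- fl$target_type == "metric" & !fl$zone_id %in% tb$zone_defs$zone_id
  for (id in fl$flag_id[bad]) add("flags", id, "zone_id does not resolve")
  bad <- fl$target_type == "lake" & !fl$obs_id %in% tb$lakes$lake_id
  for (id in fl$flag_id[bad]) add("flags", id, "lake target does not resolve")
  # zone metric join property
  bad <- !tb$zone_metrics$zone_id %in% tb$zone_defs$zone_id
  for (id in unique(tb$zone_metrics$zone_id[bad]))
    add("zone_metrics", id, "zone_id does not resolve")
  # deletion audit: every non-live observation has a deleted flag
  dead <- ob$obs_id[!ob$live]
  audited <- fl$obs_id[fl$disposition == "deleted" & fl$target_type == "observation"]
  for (id in setdiff(dead, audited))
    add("observations", id, "deleted without an audit FlagRecord")
  if (length(v) == 0)
    return(data.frame(table = character(), id = character(),
                      problem = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Record a new export version
#'
#' Version strings follow MAJOR.DDD.PATCH where DDD is the count of loaded
#' source datasets zero-padded to three digits (so a first release with 40
#' datasets is "1.040.0"). Versions must strictly increase.
#'
#' @param store a `limno_store`.
#' @param major major version component.
#' @param patch patch component.
#' @param change_notes free-text notes for the user documentation.
#' @param created_date ISO date string; defaults to today (pass a fixed
#'   date for reproducible exports).
#' @return the new version row (data.frame of 1 row).
#' @export
register_version <- function(store, major = 1L, patch = 0L,
                             change_notes = "",
                             created_date = as.character(Sys.Date())) {
  ds_count <- nrow(store$tables$sources)
  obs_count <- sum(store$tables$observations$live)
  vs <- sprintf("%d.%03d.%d", major, ds_count, patch)
  prev <- store$tables$versions$version_string
  if (length(prev) > 0) {
    cmp <- utils::compareVersion(vs, prev[length(prev)])
    if (cmp <= 0)
      stop("version ", vs, " does not increase over ", prev[length(prev)])
  }
  row <- data.frame(version_string = vs, created_date = created_date,
                    dataset_count = as.integer(ds_count),
                    observation_count = as.integer(obs_count),
                    change_notes = change_notes, stringsAsFactors = FALSE)
  store_append(store, "versions", row)
  row
}
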