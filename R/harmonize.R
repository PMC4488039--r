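# Declarative harmonization of heterogeneous source tables into canonical
# vertical observations. Each source ships with a mapping configuration (a
# YAML file) describing its orientation (wide or long), column roles,
# units, date format and censor-code conventions; the engine transposes
# the table, converts units, translates censor codes and records full
# cell-level provenance. Mappings are data, not code, so every import is
# reproducible from (table, mapping, vocabulary).

#' Load a source-mapping configuration
#'
#' @param path YAML mapping file. Required keys: `source_id`,
#'   `orientation` ("wide" or "long"), `aggregated` (logical), `columns`
#'   (map of source column name to either a `role` entry or, for wide
#'   variable columns, a `{variable, unit}` binding), `date_format`
#'   (strptime format). Optional: `censor_conventions` (map of value
#'   prefix to censor code), `unit_defaults` (map canonical variable ->
#'   unit symbol), `thousands_sep`, `depth_code_default`.
#' @return a `source_mapping` object (validated list).
#' @export
load_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  validate_mapping(m)
}

#' Validate a mapping list and return it as a `source_mapping`
#' @param m a list in the layout documented at [load_mapping()].
#' @return a `source_mapping`.
#' @export
validate_mapping <- function(m) {
  if (is.null(m$source_id)) stop("mapping lacks source_id")
  if (!identical(m$orientation, "wide") && !identical(m$orientation, "long"))
    stop("mapping orientation must be 'wide' or 'long'")
  if (is.null(m$aggregated)) m$aggregated <- FALSE
  roles <- vapply(m$columns, function(b) b$role %||% NA_character_, character(1))
  if (sum(roles == "site_id", na.rm = TRUE) != 1)
    stop("mapping must bind exactly one site_id column")
  if (sum(roles == "date", na.rm = TRUE) != 1)
    stop("mapping must bind exactly one date column")
  var_bound <- vapply(m$columns, function(b) !is.null(b$variable), logical(1))
  if (m$orientation == "wide" && !any(var_bound))
    stop("wide mapping must bind at least one variable column")
  if (m$orientation == "long") {
    for (need in c("variable_name", "value"))
      if (!any(roles == need, na.rm = TRUE))
        stop("long mapping must bind a ", need, " column")
  }
  if (is.null(m$date_format)) m$date_format <- "%Y-%m-%d"
  if (is.null(m$censor_conventions)) m$censor_conventions <- list()
  if (is.null(m$unit_defaults)) m$unit_defaults <- list()
  if (is.null(m$depth_code_default)) m$depth_code_default <- "unknown"
  structure(m, class = "source_mapping")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mapping_role_col <- function(mapping, role) {
  for (cn in names(mapping$columns))
    if (identical(mapping$columns[[cn]]$role, role)) return(cn)
  NULL
}

# Parse one cell's text into (value, censor_code, detection_limit) under
# the mapping's censor conventions. Returns NULL when unparseable.
parse_value_cell <- function(text, censor_conventions, thousands_sep = NULL) {
  t <- trimws(text)
  censor <- "none"
  limit <- NA_real_
  for (pfx in names(censor_conventions)) {
    if (startsWith(t, pfx)) {
      censor <- censor_conventions[[pfx]]
      t <- trimws(substring(t, nchar(pfx) + 1))
      break
    }
  }
  if (!is.null(thousands_sep)) t <- gsub(thousands_sep, "", t, fixed = TRUE)
  num <- suppressWarnings(as.numeric(t))
  if (is.na(num)) return(NULL)
  if (censor == "below_detection") {
    limit <- num
    num <- NA_real_
  } else if (censor == "above_detection") {
    limit <- num
  }
  list(value = num, censor_code = censor, detection_limit = limit)
}

empty_observation_frame <- function() {
  data.frame(site_ref = character(), variable = character(), value = numeric(),
             sample_date = character(), sample_depth_m = numeric(),
             depth_code = character(), censor_code = character(),
             detection_limit = numeric(), method_code = character(),
             source_id = character(), source_row_ref = integer(),
             source_column_ref = character(), original_value_text = character(),
             original_units = character(), stringsAsFactors = FALSE)
}

empty_issue_frame <- function() {
  data.frame(source_id = character(), source_row_ref = integer(),
             source_column_ref = character(), original_text = character(),
             problem = character(), stringsAsFactors = FALSE)
}

#' Harmonize a raw source table into canonical vertical observations
#'
#' Transposes a wide or long table into one observation per non-missing
#' harmonizable cell (wide) or row (long), converting every value to the
#' variable's canonical unit and translating the source's censor codes.
#' Unparseable or unresolvable cells are reported as issues, never
#' silently dropped. Sources whose mapping declares `aggregated: true`
#' are rejected outright: pre-aggregated values violate the pipeline's
#' minimum dataset requirements.
#'
#' @param raw_table data.frame as read from the source CSV (character or
#'   mixed columns are fine; cells are handled as text).
#' @param mapping a `source_mapping` from [load_mapping()].
#' @param vocab a `controlled_vocabulary` from [load_vocabulary()].
#' @return list with `observations` (site-keyed observation data.frame,
#'   values in canonical units) and `issues` (data.frame of skipped cells
#'   with reasons).
#' @export
harmonize_table <- function(raw_table, mapping, vocab) {
  if (!inherits(mapping, "source_mapping")) mapping <- validate_mapping(mapping)
  if (isTRUE(mapping$aggregated))
    stop("source ", mapping$source_id, " is marked aggregated: pre-aggregated ",
         "values (means/medians) violate the minimum dataset requirements")
  missing_cols <- setdiff(names(mapping$columns), names(raw_table))
  if (length(missing_cols))
    stop("mapping references columns absent from the table: ",
         paste(missing_cols, collapse = ", "))

  obs <- list(); iss <- list()
  push_issue <- function(row, col, text, problem)
    iss[[length(iss) + 1]] <<- data.frame(
      source_id = mapping$source_id, source_row_ref = as.integer(row),
      source_column_ref = col, original_text = as.character(text),
      problem = problem, stringsAsFactors = FALSE)

  site_col <- mapping_role_col(mapping, "site_id")
  date_col <- mapping_role_col(mapping, "date")
  depth_col <- mapping_role_col(mapping, "depth")
  method_col <- mapping_role_col(mapping, "method")
  n <- nrow(raw_table)
  if (n == 0)
    return(list(observations = empty_observation_frame(),
                issues = empty_issue_frame()))

  as_text <- function(x) ifelse(is.na(x), NA_character_, as.character(x))
  dates <- as.Date(as_text(raw_table[[date_col]]), format = mapping$date_format)
  depths <- if (!is.null(depth_col)) {
    dunit <- mapping$columns[[depth_col]]$unit %||% "m"
    convert_units(suppressWarnings(as.numeric(as_text(raw_table[[depth_col]]))),
                  dunit, "m", vocab)
  } else rep(NA_real_, n)
  methods <- if (!is.null(method_col)) as_text(raw_table[[method_col]]) else rep(NA_character_, n)
  sites <- as_text(raw_table[[site_col]])

  canon_units <- stats::setNames(vocab$variables$canonical_units,
                                 vocab$variables$canonical_name)

  emit <- function(row, col, text, canonical, unit) {
    if (is.na(dates[row])) {
      push_issue(row, col, text, "unparseable or missing date")
      return(invisible())
    }
    parsed <- parse_value_cell(text, mapping$censor_conventions, mapping$thousands_sep)
    if (is.null(parsed)) {
      push_issue(row, col, text, "value failed numeric parse")
      return(invisible())
    }
    target <- canon_units[[canonical]]
    val <- tryCatch(convert_units(parsed$value, unit, target, vocab),
                    error = function(e) e)
    if (inherits(val, "error")) {
      push_issue(row, col, text, conditionMessage(val))
      return(invisible())
    }
    lim <- if (is.na(parsed$detection_limit)) NA_real_ else
      convert_units(parsed$detection_limit, unit, target, vocab)
    obs[[length(obs) + 1]] <<- data.frame(
      site_ref = sites[row], variable = canonical, value = val,
      sample_date = as.character(dates[row]), sample_depth_m = depths[row],
      depth_code = if (is.na(depths[row])) mapping$depth_code_default else "point",
      censor_code = parsed$censor_code, detection_limit = lim,
      method_code = methods[row], source_id = mapping$source_id,
      source_row_ref = as.integer(row), source_column_ref = col,
      original_value_text = as.character(text),
      original_units = normalize_unit_symbol(unit), stringsAsFactors = FALSE)
  }

  if (mapping$orientation == "wide") {
    var_cols <- names(mapping$columns)[
      vapply(mapping$columns, function(b) !is.null(b$variable), logical(1))]
    for (col in var_cols) {
      bind <- mapping$columns[[col]]
      canonical <- resolve_variable(bind$variable, vocab)
      if (is.na(canonical))
        stop("mapping binds column ", col, " to unknown variable: ", bind$variable)
      unit <- bind$unit %||% mapping$unit_defaults[[canonical]] %||%
        canon_units[[canonical]]
      texts <- as_text(raw_table[[col]])
      for (row in seq_len(n)) {
        t <- texts[row]
        if (is.na(t) || trimws(t) == "") next  # empty cell: nothing to harmonize
        emit(row, col, t, canonical, unit)
      }
    }
  } else {
    var_col <- mapping_role_col(mapping, "variable_name")
    val_col <- mapping_role_col(mapping, "value")
    unit_col <- mapping_role_col(mapping, "unit")
    terms <- as_text(raw_table[[var_col]])
    texts <- as_text(raw_table[[val_col]])
    units <- if (!is.null(unit_col)) as_text(raw_table[[unit_col]]) else rep(NA_character_, n)
    canonicals <- resolve_variable(terms, vocab)
    for (row in seq_len(n)) {
      t <- texts[row]
      if (is.na(t) || trimws(t) == "") next
      if (is.na(canonicals[row])) {
        push_issue(row, var_col, terms[row], "unknown variable term (no synonym)")
        next
      }
      unit <- units[row]
      if (is.na(unit) || unit == "")
        unit <- mapping$unit_defaults[[canonicals[row]]] %||% canon_units[[canonicals[row]]]
      emit(row, val_col, t, canonicals[row], unit)
    }
  }

  observations <- if (length(obs)) do.call(rbind, obs) else empty_observation_frame()
  issues <- if (length(iss)) do.call(rbind, iss) else empty_issue_frame()
  list(observations = observations, issues = issues)
}

#' Apply a detection-limit policy to censored observations
#'
#' The default "retain" policy keeps censored values as reported (value
#' absent for below-detection results, the limit recorded). The
#' "half_limit" policy substitutes value = detection_limit / 2 for
#' below-detection results and marks the substitution in a
#' `dl_substituted` column so a QAQC flag can be attached.
#'
#' @param observations observation data.frame (harmonized layout).
#' @param policy "retain" or "half_limit".
#' @return the observation data.frame, with a logical `dl_substituted`
#'   column.
#' @export
apply_detection_limit_policy <- function(observations, policy = c("retain", "half_limit")) {
  policy <- match.arg(policy)
  observations$dl_substituted <- FALSE
  below <- observations$censor_code == "below_detection"
  if (policy == "half_limit" && any(below)) {
    no_limit <- below & is.na(observations$detection_limit)
    if (any(no_limit))
      stop("half-limit substitution requested but ", sum(no_limit),
           " below-detection observation(s) record no detection limit")
    observations$value[below] <- observations$detection_limit[below] / 2
    observations$dl_substituted[below] <- TRUE
  }
  observations
}
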