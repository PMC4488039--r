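# Two-tier QAQC engine. The geo tier verifies zone metrics and lake
# attributes and only ever flags (NOT_ECOLOGICAL, BEYOND_PRIOR,
# NOT_FEASIBLE, FALSE_NA). The limno tier screens observations: values
# beyond the deliberately extreme egregious threshold are deleted with an
# audit record; implausible or internally inconsistent values are flagged
# questionable and kept. Rule application is scripted, deterministic and
# idempotent, so the screening is repeatable and free of observer bias.

#' Load a QAQC rule configuration
#' @param path rules YAML; defaults to the packaged rule set.
#' @return list with `limno` and `geo` rule lists.
#' @export
load_qaqc_rules <- function(path = system.file("extdata", "qaqc_rules.yaml",
                                               package = "limnopipe")) {
  rules <- yaml::read_yaml(path)
  for (tier in c("limno", "geo")) {
    for (r in rules[[tier]]) {
      if (is.null(r$rule_id) || is.null(r$category) || is.null(r$severity))
        stop("malformed rule in tier ", tier)
      if (r$category == "EGREGIOUS" && !identical(r$disposition, "deleted"))
        stop("EGREGIOUS rules must delete: ", r$rule_id)
      if (r$category != "EGREGIOUS" && identical(r$disposition, "deleted"))
        stop("only EGREGIOUS rules may delete: ", r$rule_id)
    }
  }
  rules
}

flag_row <- function(target_type = NA_character_, obs_id = NA_integer_,
                     zone_id = NA_character_, metric_name = NA_character_,
                     rule_id = NA_character_, severity = NA_character_,
                     disposition = NA_character_, note = "") {
  data.frame(flag_id = NA_integer_, target_type = target_type,
             obs_id = as.integer(obs_id), zone_id = zone_id,
             metric_name = metric_name, rule_id = rule_id,
             severity = severity, disposition = disposition, note = note,
             stringsAsFactors = FALSE)
}

#' Apply limno-tier QAQC rules to observations
#'
#' Pure screening function: takes harmonized observations (canonical
#' units, with obs_id and the lake/date/depth sample key) and the
#' variable thresholds, returns the flags and the obs_ids to delete.
#' Values above a variable's egregious_max are deletions; values outside
#' [valid_min, valid_max] are questionable; dissolved/total pairs
#' measured in the same sample where the dissolved fraction exceeds the
#' total are flagged INCONSISTENT on both observations.
#'
#' @param observations data.frame with obs_id, lake_id, variable, value,
#'   sample_date, sample_depth_m, depth_code.
#' @param vocab a `controlled_vocabulary` (thresholds per variable).
#' @param rules rule list from [load_qaqc_rules()].
#' @return list with `flags` (FlagRecord data.frame) and
#'   `deleted_obs_ids` (integer vector).
#' @export
apply_limno_rules <- function(observations, vocab,
                              rules = load_qaqc_rules()) {
  vars <- vocab$variables
  thr <- function(v, col) {
    i <- match(v, vars$canonical_name)
    if (anyNA(i)) stop("missing threshold configuration for variable(s): ",
                       paste(unique(v[is.na(i)]), collapse = ", "))
    vars[[col]][i]
  }
  ob <- observations
  flags <- list()
  add <- function(ids, rule, note = "")
    if (length(ids)) flags[[length(flags) + 1]] <<- do.call(rbind, lapply(ids, function(id)
      flag_row("observation", obs_id = id, rule_id = rule$rule_id,
               severity = rule$severity, disposition = rule$disposition,
               note = note)))
  rl <- stats::setNames(rules$limno,
                        vapply(rules$limno, `[[`, character(1), "rule_id"))
  has_val <- !is.na(ob$value)
  emax <- thr(ob$variable, "egregious_max")
  vmax <- thr(ob$variable, "valid_max")
  vmin <- thr(ob$variable, "valid_min")
  egregious <- has_val & ob$value > emax
  if (!is.null(rl$limno_egregious_max))
    add(ob$obs_id[egregious], rl$limno_egregious_max,
        "exceeds egregious_max; deleted with audit")
  if (!is.null(rl$limno_above_valid_max))
    add(ob$obs_id[has_val & !egregious & ob$value > vmax], rl$limno_above_valid_max)
  if (!is.null(rl$limno_below_valid_min))
    add(ob$obs_id[has_val & ob$value < vmin], rl$limno_below_valid_min)
  incons <- rl$limno_dissolved_exceeds_total
  if (!is.null(incons)) {
    key <- paste(ob$lake_id, ob$sample_date, ob$depth_code,
                 ifelse(is.na(ob$sample_depth_m), "-", ob$sample_depth_m), sep = "|")
    for (pair in incons$pairs) {
      di <- which(ob$variable == pair$dissolved & has_val)
      ti <- which(ob$variable == pair$total & has_val)
      if (!length(di) || !length(ti)) next
      tmax <- tapply(ob$value[ti], key[ti], max)
      hit_d <- di[!is.na(tmax[key[di]]) & ob$value[di] > tmax[key[di]]]
      hit_t <- unlist(lapply(key[hit_d], function(k) ti[key[ti] == k]))
      add(unique(c(ob$obs_id[hit_d], ob$obs_id[hit_t])), incons,
          paste0(pair$dissolved, " > ", pair$total, " in same sample"))
    }
  }
  flags <- if (length(flags)) unique(do.call(rbind, flags)) else
    flag_row("observation")[0, ]
  deleted <- unique(flags$obs_id[flags$disposition == "deleted"])
  list(flags = flags, deleted_obs_ids = deleted)
}

#' Apply geo-tier QAQC rules to zone metrics and lake attributes
#'
#' The geo tier verifies and flags only; no value is ever altered or
#' deleted. Categories: NOT_ECOLOGICAL (e.g. a proportion outside
#' [0, 1]), NOT_FEASIBLE (mean depth exceeding maximum depth),
#' BEYOND_PRIOR (beyond configured prior-study maxima), FALSE_NA (a
#' metric reported not-available although the source layer covers the
#' zone).
#'
#' @param zone_metrics ZoneMetric data.frame (zone_id, metric_name,
#'   value, units, flag).
#' @param lake_attributes data.frame with lake_id and optional meandepth
#'   and maxdepth columns (metres).
#' @param rules rule list from [load_qaqc_rules()].
#' @return FlagRecord data.frame.
#' @export
apply_geo_rules <- function(zone_metrics, lake_attributes = NULL,
                            rules = load_qaqc_rules()) {
  flags <- list()
  rg <- stats::setNames(rules$geo, vapply(rules$geo, `[[`, character(1), "rule_id"))
  zm <- zone_metrics
  r <- rg$geo_proportion_range
  if (!is.null(r) && nrow(zm)) {
    bad <- !is.na(zm$value) & zm$units %in% "proportion" &
      (zm$value < 0 | zm$value > 1)
    for (i in which(bad))
      flags[[length(flags) + 1]] <- flag_row("metric", zone_id = zm$zone_id[i],
        metric_name = zm$metric_name[i], rule_id = r$rule_id,
        severity = r$severity, disposition = r$disposition,
        note = sprintf("proportion %g outside [0, 1]", zm$value[i]))
  }
  r <- rg$geo_beyond_prior
  if (!is.null(r) && nrow(zm)) {
    for (m in names(r$prior_max)) {
      bad <- zm$metric_name == m & !is.na(zm$value) & zm$value > r$prior_max[[m]]
      for (i in which(bad))
        flags[[length(flags) + 1]] <- flag_row("metric", zone_id = zm$zone_id[i],
          metric_name = m, rule_id = r$rule_id, severity = r$severity,
          disposition = r$disposition,
          note = sprintf("%g beyond prior maximum %g", zm$value[i], r$prior_max[[m]]))
    }
  }
  r <- rg$geo_false_na
  if (!is.null(r) && nrow(zm)) {
    bad <- is.na(zm$value) & (is.na(zm$flag) | zm$flag != "NO_DATA")
    for (i in which(bad))
      flags[[length(flags) + 1]] <- flag_row("metric", zone_id = zm$zone_id[i],
        metric_name = zm$metric_name[i], rule_id = r$rule_id,
        severity = r$severity, disposition = r$disposition,
        note = "value not available although source data cover the zone")
  }
  r <- rg$geo_depth_not_feasible
  if (!is.null(r) && !is.null(lake_attributes) &&
      all(c("meandepth", "maxdepth") %in% names(lake_attributes))) {
    la <- lake_attributes
    bad <- !is.na(la$meandepth) & !is.na(la$maxdepth) & la$meandepth > la$maxdepth
    for (i in which(bad))
      flags[[length(flags) + 1]] <- flag_row("lake", obs_id = la$lake_id[i],
        metric_name = "meandepth", rule_id = r$rule_id, severity = r$severity,
        disposition = r$disposition,
        note = sprintf("mean depth %g m > maximum depth %g m",
                       la$meandepth[i], la$maxdepth[i]))
  }
  if (length(flags)) unique(do.call(rbind, flags)) else flag_row("metric")[0, ]
}

#' Apply QAQC to a store, recording flags and auditable deletions
#'
#' Runs the limno rules over the store's live observations and the geo
#' rules over its zone metrics, appends only flags not already present
#' (idempotent), and marks egregious observations non-live. Deleted
#' observations keep their row and provenance; the audit FlagRecord is
#' the only path by which live counts decrease.
#'
#' @param store a `limno_store`.
#' @param vocab a `controlled_vocabulary`.
#' @param rules rule list from [load_qaqc_rules()].
#' @param lake_attributes optional lake depth attribute data.frame for
#'   the geo feasibility rule.
#' @return the store, invisibly; new flags are in `store$tables$flags`.
#' @export
qaqc_store <- function(store, vocab, rules = load_qaqc_rules(),
                       lake_attributes = NULL) {
  ob <- store$tables$observations
  live <- ob[ob$live, , drop = FALSE]
  lim <- apply_limno_rules(live, vocab, rules)
  geo <- apply_geo_rules(store$tables$zone_metrics, lake_attributes, rules)
  new <- rbind(lim$flags, geo)
  old <- store$tables$flags
  key <- function(f) paste(f$target_type, f$obs_id, f$zone_id, f$metric_name,
                           f$rule_id, sep = "|")
  new <- new[!key(new) %in% key(old), , drop = FALSE]
  if (nrow(new)) {
    new$flag_id <- as.integer(seq_len(nrow(new)) + nrow(old))
    store$tables$flags <- rbind(old, new)
  }
  store$tables$observations$live[
    store$tables$observations$obs_id %in% lim$deleted_obs_ids] <- FALSE
  invisible(store)
}

#' Summarize QAQC outcomes
#'
#' Per-rule and per-variable flag counts, the overall flag rate relative
#' to live observations, and the deletion count; optionally written as a
#' CSV plus a human-readable text report.
#'
#' @param store a `limno_store` after [qaqc_store()].
#' @param out_dir optional directory to write `qaqc_report.csv` and
#'   `qaqc_report.txt` into.
#' @return list with `by_rule`, `by_variable`, `n_flags`,
#'   `n_obs_flagged`, `n_deleted`, `n_live`, `flag_rate`.
#' @export
qaqc_report <- function(store, out_dir = NULL) {
  fl <- store$tables$flags
  ob <- store$tables$observations
  n_live <- sum(ob$live)
  obs_flags <- fl[fl$target_type == "observation", , drop = FALSE]
  by_rule <- as.data.frame(table(rule_id = fl$rule_id), stringsAsFactors = FALSE)
  names(by_rule) <- c("rule_id", "n_flags")
  vmap <- stats::setNames(ob$variable, ob$obs_id)
  by_var <- as.data.frame(table(variable = vmap[as.character(obs_flags$obs_id)]),
                          stringsAsFactors = FALSE)
  names(by_var) <- c("variable", "n_flags")
  n_deleted <- sum(!ob$live)
  n_obs_flagged <- length(unique(obs_flags$obs_id))
  rate <- if (n_live > 0) n_obs_flagged / n_live else 0
  rep <- list(by_rule = by_rule, by_variable = by_var,
              n_flags = nrow(fl), n_obs_flagged = n_obs_flagged,
              n_deleted = n_deleted, n_live = n_live, flag_rate = rate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(by_rule, file.path(out_dir, "qaqc_report.csv"),
                     row.names = FALSE)
    txt <- c("QAQC report",
             sprintf("live observations: %d", n_live),
             sprintf("observations flagged: %d (rate %.4f)", n_obs_flagged, rate),
             sprintf("observations deleted (egregious): %d", n_deleted),
             "", "flags by rule:",
             sprintf("  %-32s %d", by_rule$rule_id, by_rule$n_flags))
    writeLines(txt, file.path(out_dir, "qaqc_report.txt"))
  }
  rep
}
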