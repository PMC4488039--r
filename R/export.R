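# Versioned horizontal exports. The vertical store is transposed into
# flat files optimized for statistical use: a limno file with one row per
# (lake, date, depth class) and one column per variable, and one geo file
# per (theme, zone type) keyed by ZoneID so users can reassemble metrics
# onto lakes through the zone-membership table. Deleted values never
# appear; flagged values carry a parallel flag column. Every export gets
# a manifest and a user-documentation file and is reproducible
# byte-for-byte under a fixed clock.

#' Export the store to horizontal flat files
#'
#' Collision policy: when several live observations share the same
#' (lake, date, depth_code, variable) cell — e.g. two programs sampling
#' the same lake-day — the exported value is their median and the cell's
#' flag column records MULTI; the raw duplicates remain in the vertical
#' store. QAQC-flagged values are exported with their rule ids in the
#' flag column.
#'
#' @param store a `limno_store`.
#' @param out_dir output directory (created if needed).
#' @param variables canonical variable names to export (default: all in
#'   the store's vocabulary table). Unknown names are an error.
#' @param date_range optional c(min, max) ISO date strings, inclusive.
#' @param zone_types zone types whose geo metric files to export
#'   (default: all present).
#' @param version version row from [register_version()]; defaults to the
#'   store's latest registered version.
#' @return the export manifest (list), also written as manifest.json.
#' @export
export_flat <- function(store, out_dir, variables = NULL, date_range = NULL,
                        zone_types = NULL, version = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vars_known <- store$tables$variables$canonical_name
  if (is.null(variables)) variables <- vars_known
  unknown <- setdiff(variables, vars_known)
  if (length(unknown))
    stop("unknown variable(s) in selection: ", paste(unknown, collapse = ", "))
  if (is.null(version)) {
    vt <- store$tables$versions
    if (nrow(vt) == 0) stop("no version registered; call register_version() first")
    version <- vt[nrow(vt), , drop = FALSE]
  }
  ver <- version$version_string

  ob <- store$tables$observations
  ob <- ob[ob$live & ob$variable %in% variables, , drop = FALSE]
  if (!is.null(date_range))
    ob <- ob[ob$sample_date >= date_range[1] & ob$sample_date <= date_range[2], ,
             drop = FALSE]
  fl <- store$tables$flags
  ofl <- fl[fl$target_type == "observation", , drop = FALSE]
  obs_flag_map <- if (nrow(ofl))
    vapply(split(ofl$rule_id, ofl$obs_id),
           function(x) paste(sort(unique(x)), collapse = ";"), character(1))
  else character(0)

  key <- paste(ob$lake_id, ob$sample_date, ob$depth_code, sep = "|")
  rows <- unique(data.frame(lake_id = ob$lake_id, sample_date = ob$sample_date,
                            depth_code = ob$depth_code, key = key,
                            stringsAsFactors = FALSE))
  rows <- rows[order(rows$lake_id, rows$sample_date, rows$depth_code), , drop = FALSE]
  limno <- rows[, c("lake_id", "sample_date", "depth_code"), drop = FALSE]
  n_cells <- 0L
  for (v in sort(variables)) {
    sel <- ob$variable == v
    vals <- rep(NA_real_, nrow(rows))
    flags <- rep(NA_character_, nrow(rows))
    if (any(sel)) {
      sp <- split(seq_len(nrow(ob))[sel], key[sel])
      idx <- match(names(sp), rows$key)
      for (k in seq_along(sp)) {
        ii <- sp[[k]]
        vv <- ob$value[ii]
        fv <- obs_flag_map[as.character(ob$obs_id[ii])]
        fset <- unique(fv[!is.na(fv)])
        fcodes <- character(0)
        if (length(ii) > 1) fcodes <- "MULTI"
        fcodes <- c(fcodes, fset)
        vals[idx[k]] <- if (length(ii) > 1) stats::median(vv, na.rm = TRUE) else vv
        if (length(fcodes)) flags[idx[k]] <- paste(fcodes, collapse = ";")
      }
    }
    limno[[v]] <- vals
    limno[[paste0(v, "_flag")]] <- flags
    n_cells <- n_cells + sum(!is.na(vals))
  }
  limno_file <- sprintf("limno_limno_lake_%s.csv", ver)
  write_export_csv(limno, file.path(out_dir, limno_file))

  # geo files: one per (theme, zone_type), keyed by ZoneID
  zm <- store$tables$zone_metrics
  zd <- store$tables$zone_defs
  zm$zone_type <- zd$zone_type[match(zm$zone_id, zd$zone_id)]
  if (is.null(zone_types)) zone_types <- sort(unique(zm$zone_type))
  geo_files <- list()
  zm <- zm[zm$zone_type %in% zone_types, , drop = FALSE]
  if (nrow(zm)) {
    for (th in sort(unique(zm$theme))) {
      for (zt in sort(unique(zm$zone_type[zm$theme == th]))) {
        sub <- zm[zm$theme == th & zm$zone_type == zt, , drop = FALSE]
        zids <- sort(unique(sub$zone_id))
        wide <- data.frame(zone_id = zids, stringsAsFactors = FALSE)
        for (m in sort(unique(sub$metric_name))) {
          ss <- sub[sub$metric_name == m, , drop = FALSE]
          wide[[m]] <- ss$value[match(zids, ss$zone_id)]
          fg <- ss$flag[match(zids, ss$zone_id)]
          if (any(!is.na(fg))) wide[[paste0(m, "_flag")]] <- fg
        }
        f <- sprintf("geo_%s_%s_%s.csv", th, zt, ver)
        write_export_csv(wide, file.path(out_dir, f))
        geo_files[[f]] <- list(theme = th, zone_type = zt, columns = names(wide))
      }
    }
  }
  membership_file <- sprintf("geo_membership_all_%s.csv", ver)
  write_export_csv(store$tables$zone_membership, file.path(out_dir, membership_file))

  manifest <- list(
    version = ver, created_date = version$created_date,
    dataset_count = version$dataset_count,
    observation_count = n_cells,
    selection = list(variables = sort(variables),
                     date_range = date_range, zone_types = zone_types),
    limno_file = limno_file, limno_columns = names(limno),
    membership_file = membership_file,
    geo_files = geo_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# RFC-4180 CSV with "NA" as the missing token and deterministic number
# formatting (up to 15 significant digits), so identical stores export
# byte-identical files.
write_export_csv <- function(df, path) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- ifelse(is.na(df[[cn]]), NA,
                         format(df[[cn]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = TRUE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-version user documentation file
#'
#' Enumerates the version string, change notes, every exported file and
#' every column with its units and description (drawn from the
#' controlled vocabulary for variable columns). A variable column with no
#' vocabulary units or description is an error: documentation
#' completeness is mandatory.
#'
#' @param store a `limno_store`.
#' @param manifest manifest returned by [export_flat()].
#' @param vocab a `controlled_vocabulary`.
#' @param out_dir the export directory.
#' @return path to the documentation file, invisibly.
#' @export
write_user_doc <- function(store, manifest, vocab, out_dir) {
  vt <- store$tables$versions
  vrow <- vt[vt$version_string == manifest$version, , drop = FALSE]
  builtin <- c(
    lake_id = "Surrogate integer key of the lake (aggregated-lakes table)|id",
    sample_date = "Calendar date of the sample (ISO-8601)|date",
    depth_code = "Depth semantics: point, integrated, surface or unknown|code",
    zone_id = "ZoneID of the spatial extent|id",
    zone_type = "Type of the spatial extent|code",
    flag = "Membership flag|code")
  describe <- function(col) {
    base <- sub("_flag$", "", col)
    if (col %in% names(builtin)) {
      p <- strsplit(builtin[[col]], "|", fixed = TRUE)[[1]]
      return(c(p[1], p[2]))
    }
    if (endsWith(col, "_flag"))
      return(c(paste0("QAQC/collision flag codes for column ", base), "codes"))
    i <- match(base, vocab$variables$canonical_name)
    if (!is.na(i))
      return(c(vocab$variables$long_name[i], vocab$variables$canonical_units[i]))
    if (grepl("^prop_", col))
      return(c(paste0("Areal proportion of class ", sub("^prop_", "", col)),
               "proportion"))
    if (grepl("_(mean|min|max)$", col))
      return(c(paste0("Zonal ", sub("^.*_", "", col), " of ",
                      sub("_(mean|min|max)$", "", col)), "layer units"))
    stop("column '", col, "' lacks a vocabulary description/units; ",
         "user documentation must be complete")
  }
  lines <- c(
    paste0("Database export documentation — version ", manifest$version),
    paste0("Created: ", manifest$created_date),
    paste0("Source datasets loaded: ", manifest$dataset_count),
    paste0("Exported observation cells: ", manifest$observation_count),
    paste0("Change notes: ",
           if (nrow(vrow)) vrow$change_notes else ""),
    "")
  doc_file <- function(fname, cols) {
    out <- c(paste0("FILE ", fname))
    for (col in cols) {
      d <- describe(col)
      out <- c(out, sprintf("  %-24s [%s] %s", col, d[2], d[1]))
    }
    c(out, "")
  }
  lines <- c(lines, doc_file(manifest$limno_file, manifest$limno_columns))
  for (f in names(manifest$geo_files))
    lines <- c(lines, doc_file(f, manifest$geo_files[[f]]$columns))
  lines <- c(lines, doc_file(manifest$membership_file,
                             c("lake_id", "zone_id", "zone_type", "flag")))
  path <- file.path(out_dir, sprintf("user_documentation_%s.txt", manifest$version))
  writeLines(lines, path)
  invisible(path)
}

#' Reconstruct vertical observations from a horizontal export
#'
#' Inverse of the limno transposition: reads the manifest and limno flat
#' file back into (lake_id, sample_date, depth_code, variable, value)
#' tuples. Used to verify that the export conserves the exported cells
#' exactly.
#'
#' @param out_dir export directory containing manifest.json.
#' @return data.frame of tuples, one per non-NA cell.
#' @export
vertical_roundtrip <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::fromJSON(mf)
  lf <- file.path(out_dir, manifest$limno_file)
  if (!file.exists(lf)) stop("manifest names missing file: ", manifest$limno_file)
  df <- utils::read.csv(lf, stringsAsFactors = FALSE, na.strings = "NA",
                        colClasses = "character")
  if (!identical(names(df), as.character(manifest$limno_columns)))
    stop("limno file columns do not match the manifest")
  vars <- setdiff(names(df), c("lake_id", "sample_date", "depth_code"))
  vars <- vars[!endsWith(vars, "_flag")]
  out <- list()
  for (v in vars) {
    has <- !is.na(df[[v]])
    if (!any(has)) next
    out[[v]] <- data.frame(lake_id = as.integer(df$lake_id[has]),
                           sample_date = df$sample_date[has],
                           depth_code = df$depth_code[has], variable = v,
                           value = as.numeric(df[[v]][has]),
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lake_id = integer(), sample_date = character(),
                      depth_code = character(), variable = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$lake_id, res$sample_date, res$depth_code, res$variable), ]
}
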