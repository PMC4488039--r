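# Vector geoprocessing: census filtering of the waterbody layer, zone
# construction with ZoneIDs, lake-to-zone membership, and zonal
# summarization of categorical and continuous polygon layers. All layers
# share one projected CRS (metres). Zone and land-cover polygons must be
# convex (the clipping kernel is Sutherland–Hodgman); the fixtures module
# generates rectangles, and real-world non-convex zones would need to be
# pre-split into convex parts.

#' Filter a waterbody layer to the census lake population
#'
#' A census lake is a perennial body of relatively still water at or
#' above the minimum area (boundary inclusive, default 4 ha), excluding
#' entirely artificial waterbodies (sewage-treatment or aquaculture
#' ponds). Every exclusion is labeled TOO_SMALL, ARTIFICIAL or
#' NON_PERENNIAL.
#'
#' @param waterbodies layer data.frame with columns `source_polygon_id`,
#'   `fclass` (feature class), `perennial` (logical; assumed TRUE when
#'   absent), optional `name` and `area_ha`, plus a `geometry`
#'   list-column. When `area_ha` is absent it is computed from geometry;
#'   a body with neither area nor geometry is an error.
#' @param min_area_ha census minimum surface area, hectares (default 4).
#' @param excluded_classes feature classes treated as entirely
#'   artificial.
#' @return the input layer with logical `is_census` and character
#'   `excluded_reason` columns added.
#' @export
census_filter <- function(waterbodies, min_area_ha = 4,
                          excluded_classes = c("sewage treatment", "aquaculture")) {
  if (!"area_ha" %in% names(waterbodies)) {
    if (!"geometry" %in% names(waterbodies))
      stop("waterbodies lack both an area_ha attribute and geometry")
    waterbodies$area_ha <- vapply(waterbodies$geometry, poly_area_ha, numeric(1))
  }
  if (anyNA(waterbodies$area_ha)) stop("missing area attribute for some waterbodies")
  perennial <- if ("perennial" %in% names(waterbodies))
    waterbodies$perennial else rep(TRUE, nrow(waterbodies))
  fclass <- if ("fclass" %in% names(waterbodies))
    tolower(as.character(waterbodies$fclass)) else rep("lake", nrow(waterbodies))
  artificial <- fclass %in% tolower(excluded_classes)
  too_small <- waterbodies$area_ha < min_area_ha
  reason <- rep(NA_character_, nrow(waterbodies))
  # precedence: artificial > non-perennial > too small
  reason[too_small] <- "TOO_SMALL"
  reason[!perennial] <- "NON_PERENNIAL"
  reason[artificial] <- "ARTIFICIAL"
  waterbodies$is_census <- is.na(reason)
  waterbodies$excluded_reason <- reason
  waterbodies
}

#' Build shoreline buffer zones around census lakes
#'
#' For every lake and distance, the zone is the ring (lake polygon
#' dilated by the distance) minus the lake itself; its ZoneID is
#' `buffer{d}_{lake_id}`. Ring areas are reported exclusive of the lake.
#'
#' @param lakes census lake layer with `lake_id` and convex polygon
#'   `geometry`.
#' @param distances_m positive buffer distances, metres (default 100 and
#'   500).
#' @return list with `zone_defs` (zone_id, zone_type, buffer_distance_m,
#'   lake_id, area_ha of the ring) and `geometry` (named list of outer
#'   dilated polygons keyed by zone_id; the ring is outer minus the
#'   lake).
#' @export
build_buffer_zones <- function(lakes, distances_m = c(100, 500)) {
  stopifnot(all(distances_m > 0))
  defs <- list(); geoms <- list()
  for (i in seq_len(nrow(lakes))) {
    g <- lakes$geometry[[i]]
    if (is.null(dim(g)) || nrow(g) < 3) stop("non-polygonal lake geometry for lake ",
                                             lakes$lake_id[i])
    for (d in distances_m) {
      outer <- dilate_convex(g, d)
      zid <- sprintf("buffer%d_%d", as.integer(d), lakes$lake_id[i])
      defs[[length(defs) + 1]] <- data.frame(
        zone_id = zid, zone_type = sprintf("buffer%d", as.integer(d)),
        buffer_distance_m = d, lake_id = as.integer(lakes$lake_id[i]),
        area_ha = (poly_area(outer) - poly_area(g)) / 1e4,
        stringsAsFactors = FALSE)
      geoms[[zid]] <- outer
    }
  }
  list(zone_defs = do.call(rbind, defs), geometry = geoms)
}

#' Assign each lake to at most one zone per zone type
#'
#' Membership is by lake centroid containment, falling back to the
#' largest lake/zone intersection area when the centroid lies in no zone
#' of that type (so lakes straddling a boundary still receive an
#' assignment). Lakes matching no zone of a type are flagged MISSING.
#'
#' @param lakes census lake layer with `lake_id` and `geometry`.
#' @param zones zone layer: data.frame with `zone_id`, `zone_type` and a
#'   `geometry` list-column of convex polygons (non-buffer zones).
#' @return data.frame (lake_id, zone_id, zone_type, flag).
#' @export
assign_zone_membership <- function(lakes, zones) {
  out <- list()
  ztypes <- unique(zones$zone_type)
  for (i in seq_len(nrow(lakes))) {
    cent <- poly_centroid(lakes$geometry[[i]])
    for (zt in ztypes) {
      zs <- zones[zones$zone_type == zt, , drop = FALSE]
      hit <- which(vapply(zs$geometry, function(g) point_in_polygon(cent, g), logical(1)))
      zone_id <- NA_character_; flag <- NA_character_
      if (length(hit) >= 1) {
        zone_id <- zs$zone_id[hit[1]]
      } else {
        areas <- vapply(zs$geometry, function(g)
          intersection_area_convex(lakes$geometry[[i]], g), numeric(1))
        if (length(areas) && max(areas) > 0) {
          zone_id <- zs$zone_id[which.max(areas)]
        } else {
          flag <- "MISSING"
        }
      }
      out[[length(out) + 1]] <- data.frame(
        lake_id = as.integer(lakes$lake_id[i]), zone_id = zone_id,
        zone_type = zt, flag = flag, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(lake_id = integer(), zone_id = character(),
                      zone_type = character(), flag = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize a categorical polygon layer over a zone
#'
#' Computes, for each class present, the proportion of the zone's covered
#' area occupied by that class: area(zone ∩ class) / area(zone ∩ all
#' classes). A PARTIAL_COVERAGE flag is raised when the layer covers less
#' than the whole zone, NO_DATA when it covers none of it.
#'
#' @param zone list/one-row data.frame with `zone_id` and `geometry` (a
#'   convex polygon).
#' @param landcover layer data.frame with a class attribute column and
#'   `geometry` list-column.
#' @param class_attr name of the class attribute column (default
#'   "class").
#' @param theme metric theme label (default "landcover").
#' @param coverage_tol relative tolerance when comparing covered area to
#'   zone area (default 1e-9).
#' @return data.frame of ZoneMetrics (zone_id, theme, metric_name =
#'   `prop_<class>`, value, units = "proportion", flag).
#' @export
zonal_summary_categorical <- function(zone, landcover, class_attr = "class",
                                      theme = "landcover", coverage_tol = 1e-9) {
  zg <- if (is.data.frame(zone)) zone$geometry[[1]] else zone$geometry
  zid <- if (is.data.frame(zone)) zone$zone_id[1] else zone$zone_id
  za <- poly_area(zg)
  if (za <= 0) stop("zero-area zone: ", zid)
  classes <- as.character(landcover[[class_attr]])
  inter <- vapply(landcover$geometry, function(g)
    intersection_area_convex(g, zg), numeric(1))
  covered <- sum(inter)
  if (covered <= 0)
    return(data.frame(zone_id = zid, theme = theme, metric_name = "prop_NA",
                      value = NA_real_, units = "proportion", year = NA_integer_,
                      flag = "NO_DATA", stringsAsFactors = FALSE))
  by_class <- tapply(inter, classes, sum)
  by_class <- by_class[by_class > 0]
  flag <- if (covered < za * (1 - coverage_tol)) "PARTIAL_COVERAGE" else NA_character_
  data.frame(zone_id = zid, theme = theme,
             metric_name = paste0("prop_", names(by_class)),
             value = as.numeric(by_class) / covered,
             units = "proportion", year = NA_integer_, flag = flag,
             stringsAsFactors = FALSE)
}

#' Summarize a continuous polygon value layer over a zone
#'
#' Area-weighted mean (or min/max over intersecting patches) of a numeric
#' attribute carried by value polygons, within the zone.
#'
#' @inheritParams zonal_summary_categorical
#' @param values layer data.frame with a numeric attribute column and
#'   `geometry` list-column.
#' @param value_attr name of the numeric attribute column.
#' @param statistic one of "mean", "min", "max".
#' @param theme metric theme label (e.g. "climate", "topography").
#' @return one-row ZoneMetric data.frame.
#' @export
zonal_summary_continuous <- function(zone, values, value_attr,
                                     statistic = c("mean", "min", "max"),
                                     theme = "climate", coverage_tol = 1e-9) {
  statistic <- match.arg(statistic)
  zg <- if (is.data.frame(zone)) zone$geometry[[1]] else zone$geometry
  zid <- if (is.data.frame(zone)) zone$zone_id[1] else zone$zone_id
  za <- poly_area(zg)
  if (za <= 0) stop("zero-area zone: ", zid)
  v <- as.numeric(values[[value_attr]])
  inter <- vapply(values$geometry, function(g)
    intersection_area_convex(g, zg), numeric(1))
  covered <- sum(inter)
  metric <- paste0(value_attr, "_", statistic)
  if (covered <= 0)
    return(data.frame(zone_id = zid, theme = theme, metric_name = metric,
                      value = NA_real_, units = NA_character_, year = NA_integer_,
                      flag = "NO_DATA", stringsAsFactors = FALSE))
  val <- switch(statistic,
                mean = sum(v * inter) / covered,
                min = min(v[inter > 0]),
                max = max(v[inter > 0]))
  flag <- if (covered < za * (1 - coverage_tol)) "PARTIAL_COVERAGE" else NA_character_
  data.frame(zone_id = zid, theme = theme, metric_name = metric, value = val,
             units = NA_character_, year = NA_integer_, flag = flag,
             stringsAsFactors = FALSE)
}
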