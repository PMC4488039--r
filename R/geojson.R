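# GeoJSON feature-collection I/O.
#
# Layers are represented as a data.frame of feature properties with a
# `geometry` list-column: polygons as n x 2 vertex matrices (first vertex
# not repeated), linestrings as n x 2 matrices with attr "type" =
# "LineString", points as length-2 numeric vectors. Only single-ring
# polygons are supported (no holes, no multipolygons): the pipeline's
# fixtures and inputs are simple lake/zone/land-cover polygons.

#' Read a GeoJSON FeatureCollection into a layer data.frame
#'
#' @param path path to a GeoJSON file.
#' @return data.frame with one row per feature, a `geometry` list-column,
#'   and one column per property. The declared CRS, if present in a
#'   top-level `crs` member or `crs` foreign member, is attached as
#'   attribute "crs".
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geoms[[i]] <- geojson_geometry_to_matrix(f$geometry)
    props[[i]] <- f$properties
  }
  keys <- unique(unlist(lapply(props, names)))
  df <- as.data.frame(
    lapply(keys, function(k) {
      vals <- lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
      unlist(vals, use.names = FALSE)
    }),
    col.names = keys, stringsAsFactors = FALSE, optional = TRUE
  )
  if (length(feats) > 0 && ncol(df) == 0) df <- data.frame(row.names = seq_along(feats))
  df$geometry <- geoms
  crs <- NULL
  if (!is.null(gj$crs)) {
    crs <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
    if (is.null(crs)) crs <- as.character(gj$crs)[1]
  }
  attr(df, "crs") <- crs
  df
}

geojson_geometry_to_matrix <- function(g) {
  if (is.null(g)) return(NULL)
  coords_mat <- function(cc) {
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  }
  switch(g$type,
    Point = c(g$coordinates[[1]], g$coordinates[[2]]),
    LineString = {
      m <- coords_mat(g$coordinates)
      attr(m, "type") <- "LineString"
      m
    },
    Polygon = {
      ring <- g$coordinates[[1]]
      m <- coords_mat(ring)
      # GeoJSON rings repeat the first vertex; drop the closure
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    },
    stop("unsupported GeoJSON geometry type: ", g$type)
  )
}

matrix_to_geojson_geometry <- function(m) {
  if (is.null(dim(m))) {
    list(type = "Point", coordinates = c(m[1], m[2]))
  } else if (identical(attr(m, "type"), "LineString")) {
    list(type = "LineString",
         coordinates = lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))
  } else {
    ring <- rbind(m, m[1, ])
    list(type = "Polygon",
         coordinates = list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))))
  }
}

#' Write a layer data.frame as a GeoJSON FeatureCollection
#'
#' @param layer data.frame with a `geometry` list-column (see
#'   [read_geojson()]); any "crs" attribute is written as a `crs` member.
#' @param path output path.
#' @export
write_geojson <- function(layer, path) {
  props_cols <- setdiff(names(layer), "geometry")
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    pr <- as.list(layer[i, props_cols, drop = FALSE])
    pr <- lapply(pr, function(v) if (is.na(v)) NULL else v)
    pr <- pr[!vapply(pr, is.null, logical(1))]
    list(type = "Feature",
         properties = if (length(pr)) pr else structure(list(), names = character(0)),
         geometry = matrix_to_geojson_geometry(layer$geometry[[i]]))
  })
  out <- list(type = "FeatureCollection", features = feats)
  crs <- attr(layer, "crs")
  if (!is.null(crs))
    out$crs <- list(type = "name", properties = list(name = crs))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
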