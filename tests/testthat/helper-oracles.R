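# Shared fixtures and independent oracles.

square <- function(xmin, ymin, side) {
  cbind(c(xmin, xmin + side, xmin + side, xmin),
        c(ymin, ymin, ymin + side, ymin + side))
}

# Independent even-odd (ray crossing) point-in-polygon oracle.
pip_evenodd <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Brute-force boolean transitive closure over an edge list of node names.
closure_oracle <- function(edges, nodes) {
  n <- length(nodes)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) m[edges$from[k], edges$to[k]] <- TRUE
  repeat {
    m2 <- m | (m %*% m > 0)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# Independent connectivity classification from raw stream segments: a
# lake owns the nodes within snap distance of its centroid; classes come
# from direct in/out edges and the transitive closure.
connectivity_oracle <- function(streams, lakes, snap_m = 50) {
  cents <- t(vapply(lakes$geometry, limnopipe::poly_centroid, numeric(2)))
  nodes <- unique(c(streams$from_id, streams$to_id))
  coords <- rbind(
    unique(data.frame(id = streams$from_id, x = streams$from_x, y = streams$from_y)),
    unique(data.frame(id = streams$to_id, x = streams$to_x, y = streams$to_y)))
  coords <- coords[!duplicated(coords$id), ]
  owner <- rep(NA_character_, nrow(coords))
  for (i in seq_len(nrow(lakes))) {
    d <- sqrt((coords$x - cents[i, 1])^2 + (coords$y - cents[i, 2])^2)
    owner[d <= snap_m] <- paste0("L", lakes$lake_id[i])
  }
  rename <- stats::setNames(ifelse(is.na(owner), coords$id, owner), coords$id)
  ed <- data.frame(from = unname(rename[streams$from_id]),
                   to = unname(rename[streams$to_id]), stringsAsFactors = FALSE)
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  all_nodes <- unique(c(paste0("L", lakes$lake_id), ed$from, ed$to))
  reach <- if (nrow(ed)) closure_oracle(ed, all_nodes) else
    matrix(FALSE, length(all_nodes), length(all_nodes),
           dimnames = list(all_nodes, all_nodes))
  out <- character(nrow(lakes))
  for (i in seq_len(nrow(lakes))) {
    v <- paste0("L", lakes$lake_id[i])
    has_in <- any(ed$to == v)
    has_out <- any(ed$from == v)
    if (!has_in && !has_out) { out[i] <- "ISOLATED"; next }
    if (!has_in) { out[i] <- "HEADWATER"; next }
    ups <- all_nodes[reach[, v]]
    up_lakes <- setdiff(ups[startsWith(ups, "L")], v)
    out[i] <- if (length(up_lakes)) "DRAINAGE_UPSTREAM_LAKES" else "DRAINAGE"
  }
  data.frame(lake_id = lakes$lake_id, connectivity_class = out,
             stringsAsFactors = FALSE)
}

# Minimal consistent store with one lake, source, program and vocabulary.
make_tiny_store <- function(path = tempfile("store")) {
  store <- init_store(path, config = list(crs = "EPSG:5070",
                                          census_min_area_ha = 4))
  vocab <- load_vocabulary()
  add_variables(store, vocab)
  lakes <- data.frame(source_polygon_id = "WB0001", name = "Lake One",
                      area_ha = 25, is_census = TRUE,
                      excluded_reason = NA_character_,
                      stringsAsFactors = FALSE)
  lakes$geometry <- list(square(0, 0, 500))
  add_lakes(store, lakes)
  add_source(store, "srcA", "state", "Agency A",
             checklist = list(methods = TRUE, depth = TRUE, location = TRUE,
                              unaggregated = TRUE))
  add_program(store, "progA", "srcA")
  store
}

obs_row <- function(lake_id = 1L, variable = "tp", value = 10,
                    sample_date = "2010-06-01", depth_code = "surface",
                    sample_depth_m = NA_real_, censor_code = "none",
                    detection_limit = NA_real_, program_id = "progA",
                    source_id = "srcA", row_ref = 1L, col_ref = "v",
                    text = "10", units = "ug/L") {
  data.frame(lake_id = lake_id, program_id = program_id, variable = variable,
             value = value, sample_date = sample_date,
             sample_depth_m = sample_depth_m, depth_code = depth_code,
             censor_code = censor_code, detection_limit = detection_limit,
             method_code = NA_character_, source_id = source_id,
             source_row_ref = row_ref, source_column_ref = col_ref,
             original_value_text = text, original_units = units,
             stringsAsFactors = FALSE)
}
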