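# Hydrologic connectivity: lakes are placed on a directed stream network
# and classified by their position in the flowpath — isolated (no stream
# connections), headwater (outflow only), drainage (stream inflow but no
# census lake upstream), or drainage with upstream lakes.

#' Build a directed flow network from stream segments and census lakes
#'
#' Stream segments carry from/to node identifiers with node coordinates;
#' lakes are snapped to the nearest network node within `snap_m` of their
#' centroid (a lake may own several nodes). After collapsing each lake's
#' nodes the network must be acyclic; a cycle is an error naming its
#' members.
#'
#' @param streams data.frame with columns from_id, to_id, from_x, from_y,
#'   to_x, to_y (one row per directed segment, flow from -> to). May have
#'   zero rows.
#' @param lakes census lake layer with `lake_id` and `geometry`.
#' @param snap_m lake-to-node snap tolerance, metres (default 50).
#' @return a `flow_network`: list with `graph` (igraph, vertex attribute
#'   `lake_id` where a node belongs to a lake), `lake_nodes` (named list
#'   lake_id -> node ids), `lake_ids`.
#' @export
build_flow_network <- function(streams, lakes, snap_m = 50) {
  nodes <- unique(rbind(
    data.frame(id = as.character(streams$from_id), x = streams$from_x,
               y = streams$from_y, stringsAsFactors = FALSE),
    data.frame(id = as.character(streams$to_id), x = streams$to_x,
               y = streams$to_y, stringsAsFactors = FALSE)))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  lake_nodes <- stats::setNames(vector("list", nrow(lakes)),
                                as.character(lakes$lake_id))
  for (i in seq_len(nrow(lakes))) {
    if (nrow(nodes) == 0) break
    cent <- poly_centroid(lakes$geometry[[i]])
    d <- sqrt((nodes$x - cent[1])^2 + (nodes$y - cent[2])^2)
    near <- nodes$id[d <= snap_m]
    lake_nodes[[as.character(lakes$lake_id[i])]] <- near
  }
  # every lake gets a vertex; lakes off the network stay isolated vertices
  lake_vertices <- paste0("lake_", lakes$lake_id)
  stream_vertices <- setdiff(nodes$id, unlist(lake_nodes))
  node_owner <- rep(NA_character_, nrow(nodes))
  for (lid in names(lake_nodes))
    node_owner[nodes$id %in% lake_nodes[[lid]]] <- paste0("lake_", lid)
  vname <- function(node_id) {
    i <- match(node_id, nodes$id)
    ifelse(is.na(node_owner[i]), node_id, node_owner[i])
  }
  edges <- if (nrow(streams) > 0)
    data.frame(from = vname(as.character(streams$from_id)),
               to = vname(as.character(streams$to_id)),
               stringsAsFactors = FALSE) else
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # drop within-lake segments
  vertices <- data.frame(name = unique(c(lake_vertices, stream_vertices,
                                         edges$from, edges$to)),
                         stringsAsFactors = FALSE)
  vertices$lake_id <- NA_integer_
  is_lake <- startsWith(vertices$name, "lake_")
  vertices$lake_id[is_lake] <- as.integer(sub("^lake_", "", vertices$name[is_lake]))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      comp <- igraph::components(g, mode = "strong")
      names(comp$membership)[comp$membership %in% which(comp$csize > 1)]
    }, error = function(e) character(0))
    stop("flow network contains a cycle after lake collapse: ",
         paste(cyc, collapse = " -> "))
  }
  structure(list(graph = g, lake_nodes = lake_nodes,
                 lake_ids = as.integer(lakes$lake_id)),
            class = "flow_network")
}

#' Classify a lake's hydrologic connectivity
#'
#' ISOLATED: no stream in- or outflow. HEADWATER: outflow only. DRAINAGE:
#' stream inflow but no census lake reachable upstream.
#' DRAINAGE_UPSTREAM_LAKES: stream inflow with at least one census lake
#' upstream.
#'
#' @param lake_id a census lake id present in the network.
#' @param network a `flow_network` from [build_flow_network()].
#' @return character class label.
#' @export
classify_connectivity <- function(lake_id, network) {
  v <- paste0("lake_", lake_id)
  if (!v %in% igraph::V(network$graph)$name)
    stop("lake ", lake_id, " is not in the network")
  g <- network$graph
  indeg <- igraph::degree(g, v, mode = "in")
  outdeg <- igraph::degree(g, v, mode = "out")
  if (indeg == 0 && outdeg == 0) return("ISOLATED")
  if (indeg == 0) return("HEADWATER")
  up <- igraph::subcomponent(g, v, mode = "in")
  up_lakes <- setdiff(stats::na.omit(up$lake_id), lake_id)
  if (length(up_lakes) > 0) "DRAINAGE_UPSTREAM_LAKES" else "DRAINAGE"
}

#' Classify every lake in a network
#' @param network a `flow_network`.
#' @return data.frame (lake_id, connectivity_class).
#' @export
classify_all_lakes <- function(network) {
  data.frame(lake_id = network$lake_ids,
             connectivity_class = vapply(network$lake_ids, classify_connectivity,
                                         character(1), network = network),
             stringsAsFactors = FALSE)
}
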