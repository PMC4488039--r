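# Georeferencing: linking reported sampling coordinates to census lake
# polygons. Containment gives an automatic match; points that miss every
# polygon (shoreline fixes, boat-launch coordinates) are matched to the
# nearest polygon boundary within a tolerance and routed through an
# explicit human review queue, with exact-name evidence used only to
# break near-ties between adjacent lakes.

#' Match one sampling site to a census lake
#'
#' @param site list/one-row data.frame with `site_ref`, `x`, `y` and
#'   optionally `reported_name` (projected coordinates, metres).
#' @param lakes lake layer: data.frame with `lake_id`, optional `name`,
#'   and a `geometry` list-column of polygons (census lakes only).
#' @param tolerance_m maximum boundary distance for a BUFFER match
#'   (default 100 m).
#' @param tie_window_m two candidate distances closer than this are an
#'   ambiguous near-tie (default 1 m).
#' @return one-row data.frame: site_ref, lake_id (NA if unmatched),
#'   method (CONTAINS | BUFFER | NAME_ASSISTED | UNMATCHED), distance_m,
#'   needs_review, note.
#' @export
match_site_to_lake <- function(site, lakes, tolerance_m = 100,
                               tie_window_m = 1) {
  stopifnot(tolerance_m >= 0)
  pt <- c(site$x, site$y)
  if (!all(is.finite(pt))) stop("site coordinates must be finite")
  res <- function(lake_id, method, distance_m, needs_review, note = "") {
    data.frame(site_ref = as.character(site$site_ref),
               lake_id = if (is.null(lake_id)) NA_integer_ else as.integer(lake_id),
               method = method, distance_m = distance_m,
               needs_review = needs_review, note = note,
               stringsAsFactors = FALSE)
  }
  n <- nrow(lakes)
  if (n == 0) return(res(NULL, "UNMATCHED", NA_real_, TRUE, "no census lakes"))
  inside <- vapply(lakes$geometry, function(g) point_in_polygon(pt, g), logical(1))
  if (sum(inside) == 1)
    return(res(lakes$lake_id[inside], "CONTAINS", 0, FALSE))
  if (sum(inside) > 1)
    return(res(NULL, "UNMATCHED", 0, TRUE, "OVERLAP"))
  d <- vapply(lakes$geometry, function(g) dist_point_poly_boundary(pt, g), numeric(1))
  ord <- order(d, lakes$lake_id)  # lake_id as deterministic tie-break for ordering only
  d1 <- d[ord[1]]
  if (d1 > tolerance_m)
    return(res(NULL, "UNMATCHED", d1, TRUE, "beyond tolerance"))
  # ambiguity depends only on the distance gap, not on the tolerance, so
  # that the matched set grows monotonically with tolerance
  ambiguous <- n >= 2 && (d[ord[2]] - d1) < tie_window_m
  if (!ambiguous)
    return(res(lakes$lake_id[ord[1]], "BUFFER", d1, TRUE))
  # near-tie: name evidence may disambiguate
  cand <- ord[d[ord] - d1 < tie_window_m]
  rname <- site$reported_name
  if (!is.null(rname) && !is.na(rname) && nzchar(rname) && "name" %in% names(lakes)) {
    hits <- cand[!is.na(lakes$name[cand]) &
                   fold_term(lakes$name[cand]) == fold_term(rname)]
    if (length(hits) == 1)
      return(res(lakes$lake_id[hits], "NAME_ASSISTED", d[hits], TRUE,
                 "near-tie resolved by reported name"))
  }
  res(NULL, "UNMATCHED", d1, TRUE, "ambiguous near-tie, no name evidence")
}

#' Georeference a whole site table against the census lakes
#'
#' Applies [match_site_to_lake()] to every site and assembles the review
#' queue: every non-CONTAINS result. Observations may only be attached to
#' lakes through CONTAINS matches or review items a human has accepted
#' (see [apply_review_decisions()]).
#'
#' @param sites data.frame with columns source_id, site_ref, x, y and
#'   optionally reported_name; coordinates must be projected (metres) in
#'   the same CRS as the lakes. A `crs` attribute mismatch against the
#'   lake layer's is an error.
#' @param lakes census lake layer (see [match_site_to_lake()]).
#' @param tolerance_m buffer-match tolerance, metres.
#' @return list with `matches` (one row per site) and `review_queue`
#'   (subset needing review).
#' @export
georeference_dataset <- function(sites, lakes, tolerance_m = 100) {
  scrs <- attr(sites, "crs"); lcrs <- attr(lakes, "crs")
  if (!is.null(scrs) && !is.null(lcrs) && !identical(scrs, lcrs))
    stop("CRS mismatch: sites are ", scrs, " but lakes are ", lcrs)
  if (anyDuplicated(sites$site_ref))
    stop("duplicate site_ref within source: ",
         paste(unique(sites$site_ref[duplicated(sites$site_ref)]), collapse = ", "))
  rows <- lapply(seq_len(nrow(sites)), function(i)
    match_site_to_lake(as.list(sites[i, , drop = FALSE]), lakes, tolerance_m))
  matches <- do.call(rbind, rows)
  matches$source_id <- as.character(sites$source_id)
  matches <- matches[, c("source_id", "site_ref", "lake_id", "method",
                         "distance_m", "needs_review", "note")]
  list(matches = matches,
       review_queue = matches[matches$needs_review | matches$method == "UNMATCHED", ,
                              drop = FALSE])
}

#' Apply human review decisions to a match table
#'
#' Decisions accept or reject review-queue items; accepted matches become
#' attachable (needs_review dropped), rejected ones become UNMATCHED. The
#' decisions table itself is provenance and the reviewer is recorded in
#' the match note. Deciding a CONTAINS match is an error: automatic
#' containment matches are not reviewable.
#'
#' @param matches match table from [georeference_dataset()].
#' @param decisions data.frame with columns site_ref, lake_id (proposed),
#'   decision ("accept" or "reject"), reviewer, note; or a path to such a
#'   CSV.
#' @return updated match table.
#' @export
apply_review_decisions <- function(matches, decisions) {
  if (is.character(decisions))
    decisions <- utils::read.csv(decisions, stringsAsFactors = FALSE)
  if (nrow(decisions) == 0) return(matches)
  for (i in seq_len(nrow(decisions))) {
    d <- decisions[i, ]
    j <- which(matches$site_ref == as.character(d$site_ref))
    if (length(j) != 1)
      stop("decision references unknown or ambiguous site_ref: ", d$site_ref)
    if (matches$method[j] == "CONTAINS")
      stop("site ", d$site_ref, " is a CONTAINS match and not reviewable")
    if (d$decision == "accept") {
      matches$lake_id[j] <- as.integer(d$lake_id)
      matches$needs_review[j] <- FALSE
      matches$note[j] <- paste0("accepted by ", d$reviewer,
                                if (!is.null(d$note) && nzchar(d$note)) paste0(": ", d$note) else "")
    } else if (d$decision == "reject") {
      matches$lake_id[j] <- NA_integer_
      matches$method[j] <- "UNMATCHED"
      matches$needs_review[j] <- FALSE
      matches$note[j] <- paste0("rejected by ", d$reviewer)
    } else stop("unknown decision: ", d$decision)
  }
  matches
}
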