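# Seeded synthetic landscape and source-dataset generator with a
# known-truth ledger. The landscape emulates the pipeline's geospatial
# inputs: a waterbody layer with areas straddling the 4 ha census
# threshold and a fraction of artificial or non-perennial bodies, a
# directed stream network connecting a known subset of lakes, nested
# rectangular zone layers (state / county / hu4 / hu8) and a categorical
# land-cover tiling with exactly computable per-zone proportions. Source
# datasets come in three dialects mirroring the heterogeneity of real
# providers (a wide state-agency table, a long citizen-monitoring table,
# an idiosyncratic university table), with seeded coordinate
# displacements and seeded QAQC violations, all recorded in the ledger.

# Distance from an interior point to a convex polygon's boundary along a
# ray at `angle`; used to construct displaced sites at a known distance
# beyond the shoreline.
ray_boundary_distance <- function(poly, origin, angle) {
  d <- c(cos(angle), sin(angle))
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    e <- b - a
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-12) next
    t <- ((a[1] - origin[1]) * (-e[2]) - (a[2] - origin[2]) * (-e[1])) / den
    s <- (d[1] * (a[2] - origin[2]) - d[2] * (a[1] - origin[1])) / den
    if (t > 0 && s >= -1e-9 && s <= 1 + 1e-9) best <- min(best, t)
  }
  best
}

regular_polygon <- function(center, area, k = 8L, rot = 0) {
  # circumradius of a regular k-gon with the requested area
  r <- sqrt(2 * area / (k * sin(2 * pi / k)))
  th <- rot + 2 * pi * (seq_len(k) - 1) / k
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# exact overlap area of two axis-aligned rectangles (xmin,ymin,xmax,ymax)
rect_overlap_area <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

#' Generate a synthetic landscape with a known-truth ledger
#'
#' Lakes are convex polygons placed on a grid with generous spacing (so
#' displaced sampling sites can never fall near a neighboring lake);
#' about 30 % of bodies are below the 4 ha census threshold, 10 % are
#' artificial (sewage-treatment or aquaculture ponds) and 5 %
#' non-perennial. Census lakes are chained into stream flowpaths so that
#' all four connectivity classes occur, with the true class of every
#' lake recorded by construction.
#'
#' @param n_lakes number of waterbodies (default 30).
#' @param seed RNG seed; the whole landscape is reproducible from
#'   (parameters, seed).
#' @param extent_m optional square extent side; when given it must admit
#'   the grid packing, otherwise an error suggests a larger extent. By
#'   default the extent is computed from the packing.
#' @return list with layers `waterbodies`, `streams`, `zones`,
#'   `landcover` (data.frames; polygon layers carry `geometry`
#'   list-columns and a "crs" attribute) and `ledger` (list: per-lake
#'   truth table, per-zone land-cover proportions, zone rectangles).
#' @export
gen_landscape <- function(n_lakes = 30, seed = 1, extent_m = NULL) {
  stopifnot(n_lakes >= 1)
  set.seed(seed)
  crs <- "EPSG:5070"
  ncol_grid <- ceiling(sqrt(n_lakes))
  nrow_grid <- ceiling(n_lakes / ncol_grid)
  max_area_ha <- 80
  max_r <- sqrt(2 * max_area_ha * 1e4 / (8 * sin(pi / 4)))  # octagon circumradius
  cell <- 2 * max_r + 1300  # >= 600 m clearance beyond a 500 m displacement
  need <- cell * max(ncol_grid, nrow_grid)
  if (is.null(extent_m)) extent_m <- need
  if (extent_m < need)
    stop("infeasible packing: ", n_lakes, " lakes need an extent of at least ",
         ceiling(need), " m; increase extent_m")
  cell_x <- extent_m / ncol_grid
  cell_y <- extent_m / nrow_grid

  small <- stats::runif(n_lakes) < 0.3
  areas_ha <- ifelse(small, stats::runif(n_lakes, 0.8, 3.9),
                     exp(stats::runif(n_lakes, log(4), log(max_area_ha))))
  artificial <- stats::runif(n_lakes) < 0.10
  perennial <- stats::runif(n_lakes) >= 0.05
  fclass <- ifelse(artificial,
                   sample(c("sewage treatment", "aquaculture"), n_lakes, TRUE),
                   "lake")
  lake_names <- sprintf("Lake %s-%02d", LETTERS[(seq_len(n_lakes) - 1) %% 26 + 1],
                        seq_len(n_lakes))
  geoms <- vector("list", n_lakes)
  cents <- matrix(NA_real_, n_lakes, 2)
  for (i in seq_len(n_lakes)) {
    gx <- (i - 1) %% ncol_grid
    gy <- (i - 1) %/% ncol_grid
    center <- c((gx + 0.5) * cell_x, (gy + 0.5) * cell_y)
    k <- sample(6:10, 1)
    geoms[[i]] <- regular_polygon(center, areas_ha[i] * 1e4, k,
                                  rot = stats::runif(1, 0, 2 * pi))
    cents[i, ] <- center
  }
  waterbodies <- data.frame(source_polygon_id = sprintf("WB%04d", seq_len(n_lakes)),
                            name = lake_names, fclass = fclass,
                            perennial = perennial, area_ha = areas_ha,
                            stringsAsFactors = FALSE)
  waterbodies$geometry <- geoms
  attr(waterbodies, "crs") <- crs

  is_census <- areas_ha >= 4 & !artificial & perennial
  census_idx <- which(is_census)

  # stream network: chain census lakes into flowpaths; leave ~1/4 isolated
  conn_class <- rep("ISOLATED", n_lakes)
  streams <- list()
  jn <- 0L
  # junction nodes must stay well clear of every lake centroid, or the
  # network builder would snap them into the wrong lake
  raw_node <- function(x, y) {
    jn <<- jn + 1L
    list(id = sprintf("J%04d", jn), x = x, y = y)
  }
  node <- function(x, y) {
    while (min(sqrt((cents[, 1] - x)^2 + (cents[, 2] - y)^2)) < 600) {
      x <- x + 613; y <- y + 401
    }
    raw_node(x, y)
  }
  seg <- function(a, b)
    streams[[length(streams) + 1]] <<- data.frame(
      from_id = a$id, to_id = b$id, from_x = a$x, from_y = a$y,
      to_x = b$x, to_y = b$y, stringsAsFactors = FALSE)
  lake_node <- function(i) raw_node(cents[i, 1], cents[i, 2])
  if (length(census_idx) >= 2) {
    pool <- sample(census_idx)
    n_chain <- max(2, round(length(pool) * 0.75))
    chain_lakes <- pool[seq_len(n_chain)]
    # split into chains of 2-4 lakes
    chains <- split(chain_lakes, ceiling(seq_along(chain_lakes) / 3))
    for (ch in chains) {
      if (length(ch) == 1) {
        # single lake fed by a pure-stream source: DRAINAGE
        src <- node(cents[ch, 1] + 200, cents[ch, 2] + 200)
        ln <- lake_node(ch)
        seg(src, ln)
        out <- node(cents[ch, 1] - 200, cents[ch, 2] - 200)
        seg(ln, out)
        conn_class[ch] <- "DRAINAGE"
        next
      }
      head_has_source <- stats::runif(1) < 0.5
      prev <- NULL
      for (pos in seq_along(ch)) {
        i <- ch[pos]
        ln <- lake_node(i)
        if (pos == 1) {
          if (head_has_source) {
            src <- node(cents[i, 1] + 300, cents[i, 2] + 300)
            seg(src, ln)
            conn_class[i] <- "DRAINAGE"
          } else {
            conn_class[i] <- "HEADWATER"
          }
        } else {
          mid <- node((cents[ch[pos - 1], 1] + cents[i, 1]) / 2,
                      (cents[ch[pos - 1], 2] + cents[i, 2]) / 2)
          seg(prev, mid)
          seg(mid, ln)
          conn_class[i] <- "DRAINAGE_UPSTREAM_LAKES"
        }
        prev <- ln
      }
      outlet <- node(cents[ch[length(ch)], 1] - 300, cents[ch[length(ch)], 2] - 300)
      seg(prev, outlet)
    }
  }
  streams <- if (length(streams)) do.call(rbind, streams) else
    data.frame(from_id = character(), to_id = character(), from_x = numeric(),
               from_y = numeric(), to_x = numeric(), to_y = numeric(),
               stringsAsFactors = FALSE)
  conn_class[!is_census] <- NA_character_

  # nested rectangular zones: 2 states, 2x2 counties, 2 hu4, 4x4 hu8
  zone_grid <- function(prefix, nx, ny) {
    out <- list(); rects <- list()
    for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      zid <- sprintf("%s_%d_%d", prefix, ix, iy)
      r <- c((ix - 1) * extent_m / nx, (iy - 1) * extent_m / ny,
             ix * extent_m / nx, iy * extent_m / ny)
      df <- data.frame(zone_id = zid, zone_type = prefix, stringsAsFactors = FALSE)
      df$geometry <- list(rect_poly(r[1], r[2], r[3], r[4]))
      out[[zid]] <- df
      rects[[zid]] <- r
    }
    list(layer = do.call(rbind, out), rects = rects)
  }
  st <- zone_grid("state", 2, 1)
  co <- zone_grid("county", 2, 2)
  h4 <- zone_grid("hu4", 1, 2)
  h8 <- zone_grid("hu8", 4, 4)
  zones <- rbind(st$layer, co$layer, h4$layer, h8$layer)
  attr(zones, "crs") <- crs
  zone_rects <- c(st$rects, co$rects, h4$rects, h8$rects)

  # land cover: checkerboard of 4 classes, full coverage
  classes <- c("forest", "agriculture", "wetland", "urban")
  nlc <- 8
  lc <- list(); lc_rects <- list(); lc_classes <- character(0)
  for (ix in seq_len(nlc)) for (iy in seq_len(nlc)) {
    cl <- classes[((ix + iy) %% 4) + 1]
    r <- c((ix - 1) * extent_m / nlc, (iy - 1) * extent_m / nlc,
           ix * extent_m / nlc, iy * extent_m / nlc)
    df <- data.frame(class = cl, stringsAsFactors = FALSE)
    df$geometry <- list(rect_poly(r[1], r[2], r[3], r[4]))
    lc[[length(lc) + 1]] <- df
    lc_rects[[length(lc_rects) + 1]] <- r
    lc_classes <- c(lc_classes, cl)
  }
  landcover <- do.call(rbind, lc)
  attr(landcover, "crs") <- crs

  # ledger land-cover proportions per zone by exact rectangle arithmetic
  prop_rows <- list()
  for (zid in names(zone_rects)) {
    zr <- zone_rects[[zid]]
    by_class <- stats::setNames(numeric(length(classes)), classes)
    for (j in seq_along(lc_rects))
      by_class[lc_classes[j]] <- by_class[lc_classes[j]] +
        rect_overlap_area(zr, lc_rects[[j]])
    tot <- sum(by_class)
    for (cl in classes[by_class > 0])
      prop_rows[[length(prop_rows) + 1]] <- data.frame(
        zone_id = zid, class = cl, proportion = by_class[[cl]] / tot,
        stringsAsFactors = FALSE)
  }

  ledger <- list(
    lakes = data.frame(
      lake_index = seq_len(n_lakes),
      source_polygon_id = waterbodies$source_polygon_id,
      name = lake_names, area_ha = areas_ha, artificial = artificial,
      perennial = perennial, is_census = is_census,
      connectivity_class = conn_class, centroid_x = cents[, 1],
      centroid_y = cents[, 2], stringsAsFactors = FALSE),
    landcover_proportions = do.call(rbind, prop_rows),
    zone_rects = zone_rects,
    extent_m = extent_m, seed = seed, crs = crs)

  list(waterbodies = waterbodies, streams = streams, zones = zones,
       landcover = landcover, ledger = ledger)
}

style_specs <- function() {
  list(
    wide_state = list(
      provider_type = "state", date_format = "%m/%d/%Y",
      variables = list(
        list(col = "TP_MGL", canonical = "tp", unit = "mg/L"),
        list(col = "TN_MGL", canonical = "tn", unit = "mg/L"),
        list(col = "CHLA_UGL", canonical = "chla", unit = "ug/L"),
        list(col = "SECCHI_FT", canonical = "secchi", unit = "ft")),
      site_col = "SITE_ID", date_col = "SAMPLE_DATE"),
    long_citizen = list(
      provider_type = "citizen", date_format = "%d.%m.%Y",
      variables = list(
        list(term = "Total Phosphorus", canonical = "tp", unit = "ug/L"),
        list(term = "Secchi Depth", canonical = "secchi", unit = "m"),
        list(term = "Chlorophyll a", canonical = "chla", unit = "ug/L")),
      site_col = "lake", date_col = "date"),
    odd_university = list(
      provider_type = "university", date_format = "%Y%m%d",
      variables = list(
        list(col = "TP_umol", canonical = "tp", unit = "umol P/L"),
        list(col = "DOC_mgL", canonical = "doc", unit = "mg/L"),
        list(col = "Secchi_cm", canonical = "secchi", unit = "cm")),
      site_col = "StationCode", date_col = "Date"))
}

# plausible clean value ranges, canonical units, far inside [valid_min, valid_max]
true_value_for <- function(canonical) {
  switch(canonical,
         tp = stats::runif(1, 5, 150), tn = stats::runif(1, 200, 3000),
         chla = stats::runif(1, 1, 80), secchi = stats::runif(1, 0.5, 10),
         doc = stats::runif(1, 2, 20),
         stop("no value model for ", canonical))
}

#' Generate one synthetic source dataset in a provider dialect
#'
#' Emits a raw CSV-style table in one of three dialects (column names,
#' units, date formats and censor conventions differ per style), the
#' matching declarative mapping, and a truth ledger recording every true
#' canonical value, every site's coordinate displacement (drawn from a
#' mixture: exact centroid, shoreline-like 0--80 m beyond the boundary,
#' access-point-like 120--500 m beyond) and every injected QAQC
#' violation.
#'
#' @param landscape a landscape from [gen_landscape()].
#' @param style one of "wide_state", "long_citizen", "odd_university".
#' @param n_samples sampling events per site (default 5).
#' @param error_rate fraction of value cells perturbed into questionable
#'   QAQC violations (above the variable's plausible maximum but below
#'   its egregious threshold). Exactly `round(error_rate * n_cells)`
#'   cells are perturbed.
#' @param egregious_rate fraction of value cells perturbed above the
#'   egregious deletion threshold (default 0).
#' @param seed RNG seed.
#' @param censored_rate fraction of cells reported as below-detection
#'   (default 0; only styles with a censor convention use it).
#' @return list with `table` (raw data.frame of character columns),
#'   `mapping` (a `source_mapping`), `sites` (site table with projected
#'   coordinates and "crs" attribute), and `ledger` (true values, site
#'   displacements and expected match methods, injected violations).
#' @export
gen_source_dataset <- function(landscape, style = c("wide_state", "long_citizen",
                                                    "odd_university"),
                               n_samples = 5, error_rate = 0,
                               egregious_rate = 0, censored_rate = 0, seed = 1) {
  style <- match.arg(style)
  stopifnot(error_rate >= 0, error_rate <= 1, egregious_rate >= 0,
            censored_rate >= 0)
  set.seed(seed)
  spec <- style_specs()[[style]]
  source_id <- paste0("src_", style)
  led <- landscape$ledger$lakes
  census <- led[led$is_census, , drop = FALSE]
  if (nrow(census) == 0) stop("landscape has no census lakes to sample")
  n_sites <- min(nrow(census), max(3, round(nrow(census) * 0.7)))
  pick <- sort(sample(seq_len(nrow(census)), n_sites))
  site_rows <- census[pick, , drop = FALSE]

  # displacement mixture with expected georeferencing outcome
  kind <- sample(c("centroid", "shore", "access"), n_sites, TRUE,
                 prob = c(0.6, 0.25, 0.15))
  xs <- ys <- disp <- numeric(n_sites)
  expected <- character(n_sites)
  for (i in seq_len(n_sites)) {
    g <- landscape$waterbodies$geometry[[site_rows$lake_index[i]]]
    cent <- c(site_rows$centroid_x[i], site_rows$centroid_y[i])
    if (kind[i] == "centroid") {
      xs[i] <- cent[1]; ys[i] <- cent[2]; disp[i] <- 0
      expected[i] <- "CONTAINS"
    } else {
      ang <- stats::runif(1, 0, 2 * pi)
      beyond <- if (kind[i] == "shore") stats::runif(1, 5, 80)
                else stats::runif(1, 120, 500)
      rb <- ray_boundary_distance(g, cent, ang)
      xs[i] <- cent[1] + (rb + beyond) * cos(ang)
      ys[i] <- cent[2] + (rb + beyond) * sin(ang)
      disp[i] <- beyond
      expected[i] <- if (kind[i] == "shore") "BUFFER" else "UNMATCHED"
    }
  }
  site_refs <- sprintf("%s_S%03d", toupper(substr(style, 1, 2)), seq_len(n_sites))
  sites <- data.frame(source_id = source_id, site_ref = site_refs,
                      x = xs, y = ys, reported_name = site_rows$name,
                      stringsAsFactors = FALSE)
  attr(sites, "crs") <- landscape$ledger$crs

  dates <- sort(sample(seq(as.Date("2005-01-01"), as.Date("2011-12-31"), by = "day"),
                       n_samples))
  # build the clean long truth table first
  truth <- list()
  for (i in seq_len(n_sites)) for (d in seq_len(n_samples)) for (v in spec$variables) {
    truth[[length(truth) + 1]] <- data.frame(
      site_ref = site_refs[i], lake_index = site_rows$lake_index[i],
      sample_date = as.character(dates[d]), canonical = v$canonical,
      true_value = true_value_for(v$canonical), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  n_cells <- nrow(truth)

  vocab <- load_vocabulary()
  vars <- vocab$variables
  vmax <- stats::setNames(vars$valid_max, vars$canonical_name)
  emax <- stats::setNames(vars$egregious_max, vars$canonical_name)
  truth$injected <- "none"
  n_q <- round(error_rate * n_cells)
  n_e <- round(egregious_rate * n_cells)
  n_c <- round(censored_rate * n_cells)
  perturb <- sample(seq_len(n_cells), n_q + n_e + n_c)
  qi <- perturb[seq_len(n_q)]
  ei <- perturb[n_q + seq_len(n_e)]
  ci <- perturb[n_q + n_e + seq_len(n_c)]
  # questionable: between valid_max and egregious_max (flagged, kept)
  truth$true_value[qi] <- vmax[truth$canonical[qi]] * 1.5
  truth$injected[qi] <- "questionable"
  # egregious: beyond the deletion threshold
  truth$true_value[ei] <- emax[truth$canonical[ei]] * 2
  truth$injected[ei] <- "egregious"
  truth$injected[ci] <- "censored"

  fmt_date <- function(d) format(as.Date(d), spec$date_format)
  canon_units <- stats::setNames(vars$canonical_units, vars$canonical_name)
  to_source <- function(value, canonical, unit)
    convert_units(value, canon_units[[canonical]], unit, vocab)

  if (style %in% c("wide_state", "odd_university")) {
    tab <- list()
    tab[[spec$site_col]] <- rep(site_refs, each = n_samples)
    tab[[spec$date_col]] <- fmt_date(rep(dates, n_sites))
    key <- paste(tab[[spec$site_col]], rep(as.character(dates), n_sites))
    for (v in spec$variables) {
      tt <- truth[truth$canonical == v$canonical, , drop = FALSE]
      tkey <- paste(tt$site_ref, tt$sample_date)
      sv <- to_source(tt$true_value, v$canonical, v$unit)
      txt <- formatC(sv, format = "fg", digits = 6)
      cens <- tt$injected == "censored"
      txt[cens] <- paste0("<", formatC(to_source(2, v$canonical, v$unit),
                                       format = "fg", digits = 3))
      tab[[v$col]] <- txt[match(key, tkey)]
    }
    if (style == "odd_university") tab[["Depth_m"]] <- "1.0"
    tab <- as.data.frame(tab, stringsAsFactors = FALSE, check.names = FALSE,
                         optional = TRUE)
    columns <- list()
    columns[[spec$site_col]] <- list(role = "site_id")
    columns[[spec$date_col]] <- list(role = "date")
    if (style == "odd_university")
      columns[["Depth_m"]] <- list(role = "depth", unit = "m")
    for (v in spec$variables)
      columns[[v$col]] <- list(variable = v$canonical, unit = v$unit)
    mapping <- validate_mapping(list(
      source_id = source_id, orientation = "wide", aggregated = FALSE,
      date_format = spec$date_format, columns = columns,
      censor_conventions = list("<" = "below_detection")))
  } else {
    tt <- truth
    units <- vapply(tt$canonical, function(cn) {
      for (v in spec$variables) if (v$canonical == cn) return(v$unit)
      NA_character_
    }, character(1))
    terms <- vapply(tt$canonical, function(cn) {
      for (v in spec$variables) if (v$canonical == cn) return(v$term)
      NA_character_
    }, character(1))
    sv <- mapply(function(val, cn, u) to_source(val, cn, u),
                 tt$true_value, tt$canonical, units)
    txt <- formatC(sv, format = "fg", digits = 6)
    cens <- tt$injected == "censored"
    txt[cens] <- "<2"
    tab <- list()
    tab[[spec$site_col]] <- tt$site_ref
    tab[[spec$date_col]] <- fmt_date(tt$sample_date)
    tab[["parameter"]] <- unname(terms)
    tab[["reading"]] <- txt
    tab[["units"]] <- unname(units)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE, check.names = FALSE,
                         optional = TRUE)
    mapping <- validate_mapping(list(
      source_id = source_id, orientation = "long", aggregated = FALSE,
      date_format = spec$date_format,
      columns = list(
        lake = list(role = "site_id"), date = list(role = "date"),
        parameter = list(role = "variable_name"),
        reading = list(role = "value"),
        units = list(role = "unit")),
      censor_conventions = list("<" = "below_detection")))
  }

  ledger <- list(
    sites = data.frame(site_ref = site_refs,
                       lake_index = site_rows$lake_index,
                       displacement_m = disp, expected_method = expected,
                       stringsAsFactors = FALSE),
    values = truth,
    n_cells = n_cells, n_questionable = n_q, n_egregious = n_e,
    n_censored = n_c, provider_type = spec$provider_type,
    style = style, seed = seed)
  list(table = tab, mapping = mapping, sites = sites, ledger = ledger)
}
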