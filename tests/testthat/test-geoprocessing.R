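test_that("census filter is boundary-inclusive at 4 ha and labels exclusions", {
  wb <- data.frame(source_polygon_id = c("a", "b", "c", "d"),
                   fclass = c("lake", "lake", "sewage treatment", "lake"),
                   perennial = c(TRUE, TRUE, TRUE, FALSE),
                   area_ha = c(3.99, 4.0, 12, 10), stringsAsFactors = FALSE)
  out <- census_filter(wb)
  expect_equal(out$is_census, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$excluded_reason, c("TOO_SMALL", NA, "ARTIFICIAL", "NON_PERENNIAL"))
  expect_equal(sum(out$is_census), 1)
  # area computed from geometry when the attribute is absent
  wb2 <- data.frame(source_polygon_id = "g", fclass = "lake",
                    perennial = TRUE, stringsAsFactors = FALSE)
  wb2$geometry <- list(square(0, 0, 200))  # 4 ha exactly
  expect_true(census_filter(wb2)$is_census)
  expect_error(census_filter(data.frame(source_polygon_id = "h", fclass = "lake",
                                        perennial = TRUE)),
               "area")
})

test_that("buffer zones are rings with positive, distance-monotone areas", {
  lakes <- data.frame(lake_id = c(1L, 2L), stringsAsFactors = FALSE)
  lakes$geometry <- list(square(0, 0, 100), square(5000, 0, 300))
  buf <- build_buffer_zones(lakes, distances_m = c(100, 500))
  expect_equal(nrow(buf$zone_defs), 4)  # 2 lakes x 2 distances
  expect_equal(anyDuplicated(buf$zone_defs$zone_id), 0)
  expect_true(all(buf$zone_defs$area_ha > 0))
  expect_true("buffer100" %in% buf$zone_defs$zone_type)
  a100 <- buf$zone_defs$area_ha[buf$zone_defs$zone_id == "buffer100_1"]
  a500 <- buf$zone_defs$area_ha[buf$zone_defs$zone_id == "buffer500_1"]
  expect_true(a500 > a100)
  # ring excludes the lake: dilated minus lake area
  outer <- poly_area(buf$geometry[["buffer100_1"]])
  expect_equal(a100, (outer - 1e4) / 1e4)
})

test_that("zone membership uses centroids with largest-intersection fallback", {
  zones <- data.frame(zone_id = c("state_A", "state_B"),
                      zone_type = "state", stringsAsFactors = FALSE)
  zones$geometry <- list(square(0, 0, 10000), square(10000, 0, 10000))
  lakes <- data.frame(lake_id = c(1L, 2L), stringsAsFactors = FALSE)
  # lake 1 wholly in A; lake 2 straddles with 60% of area in A
  lakes$geometry <- list(square(2000, 2000, 1000),
                         cbind(c(9400, 10400, 10400, 9400),
                               c(2000, 2000, 3000, 3000)))
  mem <- assign_zone_membership(lakes, zones)
  expect_equal(mem$zone_id[mem$lake_id == 1], "state_A")
  # lake 2 centroid at x=9900 inside A; also the larger intersection
  expect_equal(mem$zone_id[mem$lake_id == 2], "state_A")
  # push lake 2's centroid into no zone (beyond B): fallback by area
  lakes$geometry[[2]] <- cbind(c(19400, 20400, 20400, 19400),
                               c(2000, 2000, 3000, 3000))
  mem <- assign_zone_membership(lakes, zones)
  expect_equal(mem$zone_id[mem$lake_id == 2], "state_B")  # 60% of area in B
  # empty zone set: everything flagged MISSING
  mem0 <- assign_zone_membership(lakes, zones[0, , drop = FALSE])
  expect_equal(nrow(mem0), 0)
  no_cover <- data.frame(zone_id = "z", zone_type = "county", stringsAsFactors = FALSE)
  no_cover$geometry <- list(square(50000, 50000, 100))
  memm <- assign_zone_membership(lakes, no_cover)
  expect_true(all(memm$flag == "MISSING"))
})

test_that("categorical zonal summaries are exact on constructed layers", {
  zone <- data.frame(zone_id = "z1", stringsAsFactors = FALSE)
  zone$geometry <- list(square(0, 0, 1000))
  # fully forested zone
  lc <- data.frame(class = "forest", stringsAsFactors = FALSE)
  lc$geometry <- list(square(-500, -500, 3000))
  zm <- zonal_summary_categorical(zone, lc)
  expect_equal(zm$value, 1.0)
  expect_true(is.na(zm$flag))
  # half forest / half agriculture, exact to 1e-9
  lc2 <- data.frame(class = c("forest", "agriculture"), stringsAsFactors = FALSE)
  lc2$geometry <- list(square(0, 0, 500) * c(1, 1), # placeholder replaced below
                       square(500, 0, 500))
  lc2$geometry <- list(cbind(c(0, 500, 500, 0), c(0, 0, 1000, 1000)),
                       cbind(c(500, 1000, 1000, 500), c(0, 0, 1000, 1000)))
  zm2 <- zonal_summary_categorical(zone, lc2)
  expect_equal(sort(zm2$value), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(zm2$value), 1, tolerance = 1e-9)
  # zone outside all land cover
  lc3 <- data.frame(class = "forest", stringsAsFactors = FALSE)
  lc3$geometry <- list(square(99000, 99000, 10))
  zm3 <- zonal_summary_categorical(zone, lc3)
  expect_equal(zm3$flag, "NO_DATA")
  expect_true(is.na(zm3$value))
  # partial coverage flagged
  zm4 <- zonal_summary_categorical(zone, data.frame(class = "forest",
    geometry = I(list(square(0, 0, 500)))))
  expect_equal(zm4$flag, "PARTIAL_COVERAGE")
  expect_error(zonal_summary_categorical(
    list(zone_id = "bad", geometry = square(0, 0, 0)), lc), "zero-area")
})

test_that("proportions are invariant to polygon order and to splitting a class", {
  zone <- data.frame(zone_id = "z", stringsAsFactors = FALSE)
  zone$geometry <- list(square(0, 0, 900))
  lc <- data.frame(class = c("forest", "urban", "urban"), stringsAsFactors = FALSE)
  lc$geometry <- list(cbind(c(0, 300, 300, 0), c(0, 0, 900, 900)),
                      cbind(c(300, 900, 900, 300), c(0, 0, 450, 450)),
                      cbind(c(300, 900, 900, 300), c(450, 450, 900, 900)))
  a <- zonal_summary_categorical(zone, lc)
  b <- zonal_summary_categorical(zone, lc[c(3, 1, 2), , drop = FALSE])
  expect_equal(a[order(a$metric_name), "value"], b[order(b$metric_name), "value"])
  expect_equal(sum(a$value), 1, tolerance = 1e-9)
  expect_equal(a$value[a$metric_name == "prop_forest"], 1 / 3, tolerance = 1e-9)
  # merging the two urban halves into one polygon changes nothing
  lc_merged <- data.frame(class = c("forest", "urban"), stringsAsFactors = FALSE)
  lc_merged$geometry <- list(lc$geometry[[1]],
                             cbind(c(300, 900, 900, 300), c(0, 0, 900, 900)))
  m <- zonal_summary_categorical(zone, lc_merged)
  expect_equal(a$value[order(a$metric_name)], m$value[order(m$metric_name)],
               tolerance = 1e-9)
})

test_that("continuous zonal summaries take area-weighted statistics", {
  zone <- data.frame(zone_id = "z", stringsAsFactors = FALSE)
  zone$geometry <- list(square(0, 0, 1000))
  vals <- data.frame(elev = c(2, 4), stringsAsFactors = FALSE)
  vals$geometry <- list(cbind(c(0, 500, 500, 0), c(0, 0, 1000, 1000)),
                        cbind(c(500, 1000, 1000, 500), c(0, 0, 1000, 1000)))
  expect_equal(zonal_summary_continuous(zone, vals, "elev", "mean")$value, 3)
  expect_equal(zonal_summary_continuous(zone, vals, "elev", "min")$value, 2)
  expect_equal(zonal_summary_continuous(zone, vals, "elev", "max")$value, 4)
  # uniform layer: mean equals the constant
  uni <- data.frame(elev = 7, stringsAsFactors = FALSE)
  uni$geometry <- list(square(-100, -100, 2000))
  expect_equal(zonal_summary_continuous(zone, uni, "elev", "mean")$value, 7)
  far <- data.frame(elev = 7, stringsAsFactors = FALSE)
  far$geometry <- list(square(90000, 90000, 10))
  expect_equal(zonal_summary_continuous(zone, far, "elev", "mean")$flag, "NO_DATA")
})
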