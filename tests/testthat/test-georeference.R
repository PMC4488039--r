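two_lakes <- function() {
  lakes <- data.frame(lake_id = c(1L, 2L), name = c("East Lake", "West Lake"),
                      stringsAsFactors = FALSE)
  lakes$geometry <- list(square(0, 0, 1000), square(2000, 0, 1000))
  lakes
}

test_that("containment, buffer and out-of-tolerance matches behave as specified", {
  lakes <- two_lakes()
  m <- match_site_to_lake(list(site_ref = "a", x = 500, y = 500), lakes)
  expect_equal(m$method, "CONTAINS")
  expect_equal(m$distance_m, 0)
  expect_equal(m$lake_id, 1L)
  expect_false(m$needs_review)
  # 40 m east of lake 1's boundary, tolerance 100 -> BUFFER under review
  m <- match_site_to_lake(list(site_ref = "b", x = 1040, y = 500), lakes,
                          tolerance_m = 100)
  expect_equal(m$method, "BUFFER")
  expect_equal(m$distance_m, 40)
  expect_equal(m$lake_id, 1L)
  expect_true(m$needs_review)
  # 500 m from both lakes with tolerance 100 -> UNMATCHED
  m <- match_site_to_lake(list(site_ref = "c", x = 1500, y = 500), lakes,
                          tolerance_m = 100)
  expect_equal(m$method, "UNMATCHED")
  expect_true(is.na(m$lake_id))
})

test_that("overlapping polygons and near-ties are routed to review", {
  lakes <- data.frame(lake_id = c(1L, 2L), name = c("A", "B"),
                      stringsAsFactors = FALSE)
  lakes$geometry <- list(square(0, 0, 1000), square(500, 0, 1000))
  m <- match_site_to_lake(list(site_ref = "x", x = 750, y = 500), lakes)
  expect_equal(m$method, "UNMATCHED")
  expect_equal(m$note, "OVERLAP")
  # two lakes 10 m apart, site midway: name evidence resolves the tie
  lakes$geometry <- list(square(0, 0, 1000), square(1010, 0, 1000))
  site <- list(site_ref = "y", x = 1005, y = 500, reported_name = "  b ")
  m <- match_site_to_lake(site, lakes, tolerance_m = 100)
  expect_equal(m$method, "NAME_ASSISTED")
  expect_equal(m$lake_id, 2L)
  expect_true(m$needs_review)
  # without a name the tie goes to review as UNMATCHED
  site$reported_name <- NULL
  m <- match_site_to_lake(site, lakes, tolerance_m = 100)
  expect_equal(m$method, "UNMATCHED")
  expect_match(m$note, "ambiguous")
})

test_that("dataset georeferencing enforces CRS and site uniqueness", {
  lakes <- two_lakes()
  attr(lakes, "crs") <- "EPSG:5070"
  sites <- data.frame(source_id = "s", site_ref = c("p", "q"),
                      x = c(500, 2500), y = c(500, 500),
                      stringsAsFactors = FALSE)
  attr(sites, "crs") <- "EPSG:4326"
  expect_error(georeference_dataset(sites, lakes), "CRS mismatch")
  attr(sites, "crs") <- "EPSG:5070"
  gr <- georeference_dataset(sites, lakes)
  expect_equal(nrow(gr$matches), 2)
  expect_equal(nrow(gr$review_queue), 0)  # both at centroids
  sites$site_ref <- c("p", "p")
  expect_error(georeference_dataset(sites, lakes), "duplicate site_ref")
})

test_that("matching is order-invariant and monotone in tolerance", {
  set.seed(21)
  lakes <- data.frame(lake_id = 1:5,
                      name = paste("Lake", 1:5), stringsAsFactors = FALSE)
  lakes$geometry <- lapply(0:4, function(i) square(i * 3000, 0, 1000))
  pts <- data.frame(x = runif(30, -500, 14500), y = runif(30, -500, 1500))
  for (tol in c(50, 200)) {
    base <- lapply(seq_len(30), function(i)
      match_site_to_lake(list(site_ref = i, x = pts$x[i], y = pts$y[i]),
                         lakes, tolerance_m = tol))
    perm <- sample(5)
    shuf <- lakes[perm, , drop = FALSE]
    again <- lapply(seq_len(30), function(i)
      match_site_to_lake(list(site_ref = i, x = pts$x[i], y = pts$y[i]),
                         shuf, tolerance_m = tol))
    expect_identical(do.call(rbind, base), do.call(rbind, again))
  }
  matched_at <- function(tol) {
    res <- vapply(seq_len(30), function(i)
      !is.na(match_site_to_lake(list(site_ref = i, x = pts$x[i], y = pts$y[i]),
                                lakes, tolerance_m = tol)$lake_id), logical(1))
    which(res)
  }
  m50 <- matched_at(50); m200 <- matched_at(200); m500 <- matched_at(500)
  expect_true(all(m50 %in% m200))
  expect_true(all(m200 %in% m500))
})

test_that("CONTAINS decisions agree with the even-odd oracle on random fixtures", {
  set.seed(31)
  for (rep in seq_len(30)) {
    k <- sample(2:4, 1)
    lakes <- data.frame(lake_id = seq_len(k), stringsAsFactors = FALSE)
    lakes$geometry <- lapply(seq_len(k), function(i)
      square((i - 1) * 2500 + runif(1, 0, 300), runif(1, 0, 300),
             runif(1, 400, 1200)))
    pt <- c(runif(1, -500, k * 2500), runif(1, -500, 1700))
    m <- match_site_to_lake(list(site_ref = "r", x = pt[1], y = pt[2]), lakes,
                            tolerance_m = 0.001)
    inside <- vapply(lakes$geometry, function(g) pip_evenodd(pt, g), logical(1))
    if (sum(inside) == 1) {
      expect_equal(m$method, "CONTAINS")
      expect_equal(m$lake_id, lakes$lake_id[inside])
    } else {
      expect_false(identical(m$method, "CONTAINS"))
    }
  }
})

test_that("review decisions transition matches and refuse CONTAINS targets", {
  lakes <- two_lakes()
  sites <- data.frame(source_id = "s", site_ref = c("in", "near", "far"),
                      x = c(500, 1040, 1500), y = c(500, 500, 500),
                      stringsAsFactors = FALSE)
  gr <- georeference_dataset(sites, lakes, tolerance_m = 100)
  expect_identical(gr$matches, apply_review_decisions(gr$matches,
    data.frame(site_ref = character(), lake_id = integer(),
               decision = character(), reviewer = character(),
               note = character())))
  dec <- data.frame(site_ref = "near", lake_id = 1L, decision = "accept",
                    reviewer = "rev1", note = "launch point", stringsAsFactors = FALSE)
  out <- apply_review_decisions(gr$matches, dec)
  i <- out$site_ref == "near"
  expect_false(out$needs_review[i])
  expect_equal(out$lake_id[i], 1L)
  expect_match(out$note[i], "accepted by rev1")
  rej <- data.frame(site_ref = "near", lake_id = 1L, decision = "reject",
                    reviewer = "rev2", note = "", stringsAsFactors = FALSE)
  out2 <- apply_review_decisions(gr$matches, rej)
  expect_equal(out2$method[out2$site_ref == "near"], "UNMATCHED")
  bad <- data.frame(site_ref = "in", lake_id = 1L, decision = "accept",
                    reviewer = "r", note = "", stringsAsFactors = FALSE)
  expect_error(apply_review_decisions(gr$matches, bad), "not reviewable")
})

test_that("seeded displacement fixtures land in the expected match classes", {
  ls <- gen_landscape(n_lakes = 16, seed = 8)
  src <- gen_source_dataset(ls, style = "wide_state", n_samples = 2, seed = 13)
  lakes <- census_filter(ls$waterbodies)
  lakes$lake_id <- seq_len(nrow(lakes))
  lakes <- lakes[lakes$is_census, , drop = FALSE]
  gr <- georeference_dataset(src$sites, lakes, tolerance_m = 100)
  led <- src$ledger$sites
  got <- gr$matches$method[match(led$site_ref, gr$matches$site_ref)]
  expect_identical(got, led$expected_method)
  # matched lake is the ledger's lake for every CONTAINS/BUFFER site
  ok <- got %in% c("CONTAINS", "BUFFER")
  expect_equal(gr$matches$lake_id[match(led$site_ref[ok], gr$matches$site_ref)],
               led$lake_index[ok])
  # review queue = exactly the non-CONTAINS sites
  expect_setequal(gr$review_queue$site_ref, led$site_ref[led$expected_method != "CONTAINS"])
})
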