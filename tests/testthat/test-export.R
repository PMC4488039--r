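export_fixture_store <- function() {
  store <- make_tiny_store()
  lakes2 <- data.frame(source_polygon_id = "WB0002", name = "Lake Two",
                       area_ha = 9, is_census = TRUE,
                       excluded_reason = NA_character_, stringsAsFactors = FALSE)
  lakes2$geometry <- list(square(5000, 0, 300))
  add_lakes(store, lakes2)
  store
}

test_that("a single observation exports to one row and one variable column", {
  store <- export_fixture_store()
  add_observations(store, obs_row(variable = "tp", value = 12))
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  mf <- export_flat(store, d, variables = "tp")
  df <- read.csv(file.path(d, mf$limno_file))
  expect_equal(nrow(df), 1)
  expect_equal(df$tp, 12)
  expect_equal(mf$observation_count, 1)
})

test_that("missing cells render as a single NA in the transposed table", {
  store <- export_fixture_store()
  # 2 lakes x 3 variables with one (lake 2, chla) missing: 5 values, 1 NA
  ob <- rbind(obs_row(lake_id = 1L, variable = "tp", value = 10, row_ref = 1L),
              obs_row(lake_id = 1L, variable = "tn", value = 500, row_ref = 2L),
              obs_row(lake_id = 1L, variable = "chla", value = 3, row_ref = 3L),
              obs_row(lake_id = 2L, variable = "tp", value = 20, row_ref = 4L),
              obs_row(lake_id = 2L, variable = "tn", value = 700, row_ref = 5L))
  add_observations(store, ob)
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  mf <- export_flat(store, d, variables = c("tp", "tn", "chla"))
  df <- read.csv(file.path(d, mf$limno_file), na.strings = "NA")
  vals <- df[, c("tp", "tn", "chla")]
  expect_equal(sum(is.na(vals)), 1)
  expect_true(is.na(df$chla[df$lake_id == 2]))
  expect_equal(mf$observation_count, 5)
})

test_that("unknown selection errors before writing; themes can be excluded", {
  store <- export_fixture_store()
  add_observations(store, obs_row())
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  expect_error(export_flat(store, d, variables = "nonexistent"), "unknown variable")
  expect_false(file.exists(file.path(d, "manifest.json")))
  # zone metrics present only for an excluded zone type -> no geo file
  store$tables$zone_defs <- data.frame(zone_id = "state_1", zone_type = "state",
                                       buffer_distance_m = NA_real_,
                                       lake_id = NA_integer_, stringsAsFactors = FALSE)
  store$tables$zone_metrics <- data.frame(
    zone_id = "state_1", theme = "landcover", metric_name = "prop_forest",
    value = 1, units = "proportion", year = NA_integer_, flag = NA_character_,
    stringsAsFactors = FALSE)
  mf <- export_flat(store, d, zone_types = character(0))
  expect_equal(length(mf$geo_files), 0)
  mf2 <- export_flat(store, d, zone_types = "state")
  expect_equal(length(mf2$geo_files), 1)
})

test_that("duplicate lake-date-variable cells export as median with MULTI flag", {
  store <- export_fixture_store()
  ob <- rbind(obs_row(variable = "tp", value = 10, row_ref = 1L),
              obs_row(variable = "tp", value = 30, row_ref = 2L),
              obs_row(variable = "tp", value = 14, row_ref = 3L))
  add_observations(store, ob)
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  mf <- export_flat(store, d, variables = "tp")
  df <- read.csv(file.path(d, mf$limno_file), na.strings = "NA")
  expect_equal(nrow(df), 1)
  expect_equal(df$tp, 14)  # median of 10, 30, 14
  expect_equal(df$tp_flag, "MULTI")
})

test_that("deleted observations never reach an export; flags ride along", {
  store <- export_fixture_store()
  ob <- rbind(obs_row(variable = "chla", value = 20000, row_ref = 1L),
              obs_row(variable = "chla", value = 5, sample_date = "2010-08-01",
                      row_ref = 2L),
              obs_row(variable = "tp", value = 5000, row_ref = 3L))
  add_observations(store, ob)
  qaqc_store(store, load_vocabulary())
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  mf <- export_flat(store, d)
  df <- read.csv(file.path(d, mf$limno_file), na.strings = "NA")
  expect_false(20000 %in% df$chla)
  expect_equal(sort(stats::na.omit(c(df$chla, df$tp))), c(5, 5000))
  expect_equal(df$tp_flag[!is.na(df$tp)], "limno_above_valid_max")
})

test_that("export round-trips to the vertical model and is byte-reproducible", {
  store <- export_fixture_store()
  set.seed(3)
  ob <- do.call(rbind, lapply(1:20, function(i)
    obs_row(lake_id = sample(1:2, 1), variable = sample(c("tp", "tn", "secchi"), 1),
            value = round(runif(1, 1, 100), 3),
            sample_date = sample(c("2010-06-01", "2010-07-01"), 1),
            row_ref = as.integer(i))))
  add_observations(store, ob)
  register_version(store, created_date = "2026-01-01")
  d1 <- tempfile("exp1"); d2 <- tempfile("exp2")
  mf <- export_flat(store, d1)
  export_flat(store, d2)
  # byte-identical re-export under the same version clock
  f1 <- file.path(d1, mf$limno_file); f2 <- file.path(d2, mf$limno_file)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # vertical -> horizontal -> vertical tuple equality (median collapses dupes)
  back <- vertical_roundtrip(d1)
  live <- store$tables$observations[store$tables$observations$live, ]
  key <- paste(live$lake_id, live$sample_date, live$depth_code, live$variable)
  want <- aggregate(live$value, by = list(key = key), FUN = stats::median)
  got_key <- paste(back$lake_id, back$sample_date, back$depth_code, back$variable)
  expect_setequal(got_key, want$key)
  expect_equal(back$value[order(got_key)], want$x[order(want$key)])
  expect_equal(nrow(back), mf$observation_count)  # transposition conservation
  # a corrupted cell is caught by comparing against the store
  txt <- paste(readLines(f1), collapse = "\n")
  txt <- sub("\"[0-9]+\\.[0-9]+\"", "\"999999\"", txt)
  writeLines(txt, f1)
  corrupted <- vertical_roundtrip(d1)
  expect_false(isTRUE(all.equal(sort(corrupted$value), sort(back$value))))
})

test_that("user documentation enumerates files and columns and demands completeness", {
  store <- export_fixture_store()
  add_observations(store, obs_row(variable = "tp", value = 10))
  register_version(store, created_date = "2026-01-01")
  d <- tempfile("exp")
  vocab <- load_vocabulary()
  mf <- export_flat(store, d, variables = c("tp", "secchi"))
  doc <- write_user_doc(store, mf, vocab, d)
  txt <- readLines(doc)
  expect_true(any(grepl(mf$limno_file, txt, fixed = TRUE)))
  expect_true(any(grepl("Total phosphorus", txt)))
  expect_true(any(grepl("ug/L", txt)))
  expect_true(any(grepl(mf$version, txt, fixed = TRUE)))
  # identical store re-export -> identical documentation
  d3 <- tempfile("exp3")
  mf2 <- export_flat(store, d3, variables = c("tp", "secchi"))
  doc2 <- write_user_doc(store, mf2, vocab, d3)
  expect_identical(readLines(doc2), txt)
  # a column with no vocabulary entry fails completeness
  mf$limno_columns <- c(mf$limno_columns, "mystery_column")
  expect_error(write_user_doc(store, mf, vocab, d), "lacks a vocabulary description")
})
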