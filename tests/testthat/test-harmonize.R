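wide_mapping <- function() validate_mapping(list(
  source_id = "srcW", orientation = "wide", aggregated = FALSE,
  date_format = "%Y-%m-%d",
  columns = list(
    site = list(role = "site_id"), date = list(role = "date"),
    tp_mgl = list(variable = "tp", unit = "mg/L"),
    secchi_m = list(variable = "secchi", unit = "m")),
  censor_conventions = list("<" = "below_detection")))

test_that("empty tables harmonize to empty results", {
  vocab <- load_vocabulary()
  h <- harmonize_table(data.frame(site = character(), date = character(),
                                  tp_mgl = character(), secchi_m = character()),
                       wide_mapping(), vocab)
  expect_equal(nrow(h$observations), 0)
  expect_equal(nrow(h$issues), 0)
})

test_that("wide tables transpose with unit conversion to canonical units", {
  vocab <- load_vocabulary()
  tab <- data.frame(site = c("S1", "S2"), date = c("2010-06-01", "2010-07-15"),
                    tp_mgl = c("0.025", "0.040"), secchi_m = c("3.2", "1.1"),
                    stringsAsFactors = FALSE)
  h <- harmonize_table(tab, wide_mapping(), vocab)
  expect_equal(nrow(h$observations), 4)  # 2 rows x 2 bound variable columns
  expect_equal(nrow(h$issues), 0)
  tp <- h$observations[h$observations$variable == "tp", ]
  expect_equal(sort(tp$value), c(25, 40))  # mg/L -> ug/L is x1000, by hand
  se <- h$observations[h$observations$variable == "secchi", ]
  expect_equal(sort(se$value), c(1.1, 3.2))
  expect_true(all(h$observations$censor_code == "none"))
  # provenance pointers resolve back to the original cell text
  for (i in seq_len(nrow(h$observations))) {
    o <- h$observations[i, ]
    expect_identical(o$original_value_text,
                     as.character(tab[o$source_row_ref, o$source_column_ref]))
  }
})

test_that("censor conventions translate '<' prefixed values to censored observations", {
  vocab <- load_vocabulary()
  tab <- data.frame(site = "S1", date = "2010-06-01", tp_mgl = "<0.005",
                    secchi_m = "", stringsAsFactors = FALSE)
  h <- harmonize_table(tab, wide_mapping(), vocab)
  expect_equal(nrow(h$observations), 1)
  o <- h$observations[1, ]
  expect_equal(o$censor_code, "below_detection")
  expect_equal(o$detection_limit, 5)  # 0.005 mg/L -> 5 ug/L
  expect_true(is.na(o$value))
  expect_identical(o$original_value_text, "<0.005")
})

test_that("long tables resolve variable terms via the vocabulary", {
  vocab <- load_vocabulary()
  mp <- validate_mapping(list(
    source_id = "srcL", orientation = "long", aggregated = FALSE,
    date_format = "%d.%m.%Y",
    columns = list(
      lake = list(role = "site_id"), date = list(role = "date"),
      parameter = list(role = "variable_name"),
      reading = list(role = "value"), units = list(role = "unit"))))
  tab <- data.frame(
    lake = c("L1", "L1", "L1"), date = rep("01.06.2010", 3),
    parameter = c("Total Phosphorus", "Secchi Depth", "unheard-of thing"),
    reading = c("12.5", "4.0", "7"), units = c("ug/L", "m", "ug/L"),
    stringsAsFactors = FALSE)
  h <- harmonize_table(tab, mp, vocab)
  expect_equal(nrow(h$observations), 2)
  expect_equal(nrow(h$issues), 1)
  expect_match(h$issues$problem, "unknown variable term")
  expect_setequal(h$observations$variable, c("tp", "secchi"))
  expect_equal(h$observations$sample_date, rep("2010-06-01", 2))
})

test_that("aggregated sources are rejected; unparseable cells become issues", {
  vocab <- load_vocabulary()
  mp <- wide_mapping()
  mp$aggregated <- TRUE
  expect_error(harmonize_table(data.frame(site = "S", date = "2010-01-01",
                                          tp_mgl = "1", secchi_m = "1"),
                               mp, vocab),
               "minimum dataset requirements")
  tab <- data.frame(site = c("S1", "S2"), date = c("2010-06-01", "not-a-date"),
                    tp_mgl = c("garbage", "0.02"), secchi_m = c("2.0", NA),
                    stringsAsFactors = FALSE)
  h <- harmonize_table(tab, wide_mapping(), vocab)
  # S1 tp fails parse (issue), S1 secchi fine, S2 tp has a bad date (issue)
  expect_equal(nrow(h$observations), 1)
  expect_equal(nrow(h$issues), 2)
  expect_setequal(h$issues$problem,
                  c("value failed numeric parse", "unparseable or missing date"))
})

test_that("cell conservation holds on generated source tables", {
  ls <- gen_landscape(n_lakes = 12, seed = 5)
  vocab <- load_vocabulary()
  for (style in c("wide_state", "long_citizen", "odd_university")) {
    src <- gen_source_dataset(ls, style = style, n_samples = 3,
                              error_rate = 0.05, seed = 9)
    h <- harmonize_table(src$table, src$mapping, vocab)
    bound_cells <- src$ledger$n_cells  # every generated cell is bound and non-null
    expect_equal(nrow(h$observations) + nrow(h$issues), bound_cells)
    expect_equal(nrow(h$issues), 0)
  }
})

test_that("harmonization is deterministic and respects row permutations", {
  ls <- gen_landscape(n_lakes = 10, seed = 3)
  vocab <- load_vocabulary()
  src <- gen_source_dataset(ls, style = "wide_state", n_samples = 3, seed = 4)
  h1 <- harmonize_table(src$table, src$mapping, vocab)
  h2 <- harmonize_table(src$table, src$mapping, vocab)
  expect_identical(h1, h2)
  # permuting input rows permutes observations identically (compare sorted)
  perm <- sample(nrow(src$table))
  hp <- harmonize_table(src$table[perm, ], src$mapping, vocab)
  key <- function(o) paste(o$site_ref, o$sample_date, o$variable)
  expect_identical(h1$observations$value[order(key(h1$observations))],
                   hp$observations$value[order(key(hp$observations))])
})

test_that("detection-limit policies retain or substitute half the limit", {
  vocab <- load_vocabulary()
  tab <- data.frame(site = "S1", date = "2010-06-01", tp_mgl = "<0.005",
                    secchi_m = "2", stringsAsFactors = FALSE)
  h <- harmonize_table(tab, wide_mapping(), vocab)
  keep <- apply_detection_limit_policy(h$observations, "retain")
  cens <- keep[keep$censor_code == "below_detection", ]
  expect_true(is.na(cens$value))
  expect_equal(cens$detection_limit, 5)
  expect_false(any(keep$dl_substituted))
  # non-censored observations are untouched by either policy
  expect_equal(keep$value[keep$censor_code == "none"], 2)
  half <- apply_detection_limit_policy(h$observations, "half_limit")
  censh <- half[half$censor_code == "below_detection", ]
  expect_equal(censh$value, 2.5)  # limit 5 / 2
  expect_true(censh$dl_substituted)
  # substitution without a limit is an error
  broken <- h$observations
  broken$detection_limit <- NA_real_
  expect_error(apply_detection_limit_policy(broken, "half_limit"), "no detection limit")
})
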