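# limnopipe

Building an integrated, multi-thematic lake water-quality database from
heterogeneous site-level sources is mostly a data-engineering problem:
dozens of agency, citizen-science and university datasets arrive in
incompatible schemas, units, date formats and detection-limit
conventions, and the lakes they describe must be tied to a *census*
population of lake polygons and characterized by the landscapes —
political units, hydrologic units, watersheds, shoreline buffers — they
sit in. **limnopipe** is a reusable, tested R implementation of that
workflow for ecoinformaticians and landscape limnologists:

- **Vertical observation store.** Every measurement is one row —
  `(lake, program, variable, date, depth, value)` — with cell-level
  provenance (source file, row, column, original text and units), so new
  variables never require schema changes and every value is auditable
  back to its source cell.
- **Controlled vocabulary and unit registry.** Source terminology is
  mapped to canonical variable names (17 water-quality variables —
  nutrients, clarity, carbon, chlorophyll — plus lake depth) and all
  values are converted to canonical units (e.g. µmol P/L → µg/L via
  molar mass). Harmonization is driven by declarative per-source mapping
  files: mappings are data, not code.
- **Georeferencing with a review queue.** A site's reported coordinate is
  matched to a census lake by polygon containment; points that miss every
  polygon (shoreline fixes, boat launches) match the nearest lake within
  a tolerance (default 100 m) and are queued for human review, with
  exact-name evidence used only to break near-ties.
- **Census filtering and zonal characterization.** A census lake is a
  perennial still-water body ≥ 4 ha (boundary-inclusive), excluding
  entirely artificial waterbodies. Lakes are assigned ZoneIDs at every
  spatial extent, land-cover composition and continuous layers are
  summarized per zone by exact vector overlay, and each lake's hydrologic
  connectivity is classified on the stream network:
  `ISOLATED | HEADWATER | DRAINAGE | DRAINAGE_UPSTREAM_LAKES`.
- **Two-tier QAQC.** Geo-tier rules only flag (not ecological, beyond
  prior studies, not feasible such as mean depth > max depth, falsely
  "not available"); limno-tier rules flag questionable values and delete
  only values beyond deliberately extreme per-variable thresholds — every
  deletion leaves an audit FlagRecord and keeps its provenance.
- **Versioned, documented exports.** The vertical store is transposed to
  horizontal flat files (one limno file keyed by lake/date/depth, one geo
  file per theme × zone type keyed by ZoneID), with a manifest, a
  machine-checked user-documentation file, and `MAJOR.DDD.PATCH` version
  strings where `DDD` is the zero-padded count of loaded source datasets.
- **Synthetic fixtures with a known-truth ledger.** A seeded generator
  emulates the whole input universe — lake polygons straddling the census
  threshold, stream networks with known connectivity, nested zones,
  land-cover tilings with exactly computable proportions, and three
  provider dialects with seeded coordinate displacements and seeded QAQC
  violations — so every stage is testable offline against ground truth.

## Worked example

```r
library(limnopipe)

root <- tempfile("demo"); dir.create(root)
cfg <- list(store = file.path(root, "store"),
            data_dir = file.path(root, "data"),
            crs = "EPSG:5070",
            fixtures = list(n_lakes = 24, seed = 42, n_samples = 4,
                            error_rate = 0.01),
            export = list(dir = file.path(root, "exports"),
                          created_date = "2026-01-01"))
run_pipeline(cfg)   # fixtures -> init -> ingest -> georef -> geo -> qaqc -> export

store <- open_store(cfg$store)
print(store)
#> <limno_store> at .../store
#>   lakes            24 rows
#>   sources          3 rows
#>   programs         3 rows
#>   variables        19 rows
#>   observations     304 rows
#>   flags            4 rows
#>   zone_defs        52 rows
#>   zone_metrics     80 rows
#>   zone_membership  56 rows
#>   site_matches     30 rows
#>   versions         1 rows

validate_integrity(store)   # 0 rows: every reference resolves
qaqc_report(store)[c("n_obs_flagged", "n_deleted", "flag_rate")]
#> $n_obs_flagged   [1] 4
#> $n_deleted       [1] 0
#> $flag_rate       [1] 0.01315789
```

Of the 24 generated waterbodies, those at least 4 ha, perennial and not
artificial became census lakes; 30 sampling sites across the three
synthetic providers were georeferenced (sites at lake centroids matched
by containment, displaced sites went to the review queue); 304
observations were harmonized to canonical units and attached; the 1 %
injected violations were flagged by the limno QAQC tier; and the export
directory contains the versioned flat files (`limno_limno_lake_1.003.0.csv`,
one `geo_landcover_*` file per zone type) plus
`user_documentation_1.003.0.txt` describing every file and column.

The same workflow runs from a shell via the thin wrapper in
`inst/scripts/limnopipe`:

```sh
Rscript inst/scripts/limnopipe all --config inst/extdata/demo_config.yaml
```

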