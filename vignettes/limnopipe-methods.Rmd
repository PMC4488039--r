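---
title: "Methods: harmonizing, georeferencing and characterizing lake water-quality data"
author: "limnopipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing, georeferencing and characterizing lake water-quality data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnopipe)
```

## The data model

limnopipe stores measurements *vertically*: one row per observation of
one variable on one lake on one date at one depth. The alternative — one
column per variable — breaks every time a new source contributes a new
parameter. The store is a set of relational tables (aggregated lakes,
sources, programs, variables, observations, flags, zone definitions,
zone metrics, zone membership, site matches, versions) linked by
surrogate keys; `validate_integrity()` enforces the link structure:
every foreign key resolves, keys are unique, censored values carry a
detection limit, census lakes satisfy the census invariants, and every
deleted observation has an audit flag. Because no embedded database
engine is assumed, persistence is deliberately plain text: one CSV per
table, the schema as SQL DDL (`store_schema_sql()`), a JSON manifest,
and geometries as GeoJSON. This keeps every artifact diffable and
inspectable, at the cost of multi-user access, which is out of scope.

Surrogate integer `lake_id`s are assigned in polygon-file order and the
source polygon identifier is always preserved, so lake identity is
traceable to the input layer. Dates are ISO-8601 calendar dates; time of
day, where a source reports it, survives only in the provenance text.
Depths are metres, positive downward; a missing depth is allowed only
with a depth code other than `point`.

## Harmonization

Each source ships with a *mapping*: a YAML file declaring orientation
(wide or long), the role of each column (`site_id`, `date`, `depth`,
`variable_name`, `value`, `unit`, `method`), per-column variable/unit
bindings for wide tables, the date format, censor-code conventions
(e.g. a `<` prefix means below detection) and whether the source is
pre-aggregated. Mappings are data, not code: the engine
(`harmonize_table()`) is the only import program, so every import is
reproducible from `(table, mapping, vocabulary)` and the mapping file
itself is provenance. Sources declaring `aggregated: true` are rejected
outright — means and medians cannot be un-aggregated, and accepting them
would poison the vertical model.

Variable terms resolve case-insensitively after whitespace/punctuation
folding; anything else must be an explicit synonym. This deliberately
refuses fuzzy matching: a false merge between, say, total and dissolved
phosphorus is far more damaging than a skipped row reported in the
issues table. Cells that fail numeric parsing, date parsing, unit
conversion or variable resolution become *issues*, never silent drops,
and the cell-conservation property (observations + issues = bound
non-null cells) is tested.

The unit registry is multiplicative within a dimension: each symbol
carries a factor to the dimension's reference unit, so conversion is
`x * f_from / f_to`, identical symbols return the value bit-for-bit, and
composition holds to 1e-9 relative tolerance. Molar nutrient units carry
the element's molar mass in their factor (µmol P/L → µg/L is × 30.97).
The registry trusts the mapping author to bind element-consistent units;
it does not model chemical speciation.

Censored values default to *retain-and-qualify*: the value stays absent,
the limit and qualifier are recorded. The optional half-limit policy
(`apply_detection_limit_policy(..., "half_limit")`) substitutes limit/2
and marks the substitution — the flag uses the questionable severity,
because a substitution is an estimate rather than an error. Substitution
without a recorded limit is an error, since detection limits are often
missing or change over time and silent defaults would be untraceable.

## Georeferencing

Reported coordinates frequently indicate the shoreline or an access
point rather than open water, so containment alone under-matches.
`match_site_to_lake()` proceeds: (1) inside exactly one census polygon →
`CONTAINS`, automatic; (2) otherwise the nearest polygon by boundary
distance within a tolerance (default **100 m**, the same order as a
shoreline buffer) → `BUFFER`, flagged for review; (3) if the two nearest
candidates are within a **1 m** tie window, an exactly matching reported
name (after case/whitespace folding) resolves the tie → `NAME_ASSISTED`,
still reviewed; (4) otherwise `UNMATCHED`. A point inside two
overlapping polygons is never guessed (`OVERLAP`, review). The tie test
depends only on the distance gap, not the tolerance, so the set of
matched sites grows monotonically with tolerance. Observations attach to
lakes only through `CONTAINS` matches or review items a human accepted
via `apply_review_decisions()`; the decisions table (site, proposed
lake, decision, reviewer) is part of provenance. Distances are planar
Euclidean in the declared projected CRS; matching in geographic degrees
is refused because degree distances are meaningless.

## Census filtering and geoprocessing

A census lake is a perennial, relatively still waterbody with surface
area ≥ **4 ha** (boundary-inclusive), excluding entirely artificial
classes (sewage-treatment and aquaculture ponds by default). Exclusions
are labeled `TOO_SMALL`, `ARTIFICIAL` or `NON_PERENNIAL` and retained.

No geometry engine is assumed: the package carries a small planar
toolkit — shoelace areas and centroids, winding-number containment,
point-to-segment distances, Sutherland–Hodgman clipping, convex
dilation. Two consequences matter to users:

- **Zone and land-cover polygons must be convex** (the clipping kernel
  clips against convex polygons only). Rectangular administrative and
  hydrologic-unit fixtures satisfy this; real-world non-convex zones
  would need pre-splitting into convex parts.
- **Buffers are approximate only at corners**: dilation is the Minkowski
  sum with a disc approximated by 64 chords, so a ring's area
  underestimates the exact `P·d + πd²` by < 0.2 %. Ring areas are
  strictly positive and increase monotonically with distance.

Zone membership uses the lake centroid, falling back to
largest-intersection area when the centroid lies in no zone of a type —
so lakes straddling a state boundary still receive a state. Zonal
summaries are exact vector overlays: categorical proportions are
`area(zone ∩ class) / area(zone ∩ all classes)` (summing to 1 under full
coverage to 1e-9, `PARTIAL_COVERAGE`/`NO_DATA` otherwise), continuous
summaries are area-weighted means or patch min/max.

### Connectivity

Lakes snap to stream-network nodes within **50 m** of their centroid
(default), each lake's nodes collapse to a single graph vertex, and the
collapsed directed graph must be acyclic. The four-class taxonomy
operationalizes position in the flowpath: `ISOLATED` (no stream edges),
`HEADWATER` (outflow only), `DRAINAGE` (stream inflow, no census lake
upstream), `DRAINAGE_UPSTREAM_LAKES` (≥ 1 census lake upstream,
transitively). Reachability uses igraph; tests check every label against
an independent transitive-closure oracle on random 20-node networks.
Finer connectivity metrics (e.g. wetland classes, flow accumulation) are
out of scope, as is DEM-based watershed delineation — watershed polygons
enter as just another zone layer.

## QAQC

Screening is scripted and rule-driven to remove observer bias and make
the procedure repeatable; statistical outlier detection is deliberately
*not* part of it. Two tiers:

- **Geo tier** (zone metrics, lake attributes): flags only, never edits.
  Categories: not ecologically sensible (a proportion outside [0, 1]),
  beyond prior studies (configured per-metric maxima), not technically
  feasible (mean depth > maximum depth), and falsely "not available" (a
  missing metric whose source layer covers the zone).
- **Limno tier** (observations): values beyond a variable's
  `egregious_max` are deleted — but the row, its provenance and an audit
  FlagRecord remain, so ever-ingested = live + audited deletions always
  holds. Values outside the plausible `[valid_min, valid_max]` range and
  dissolved fractions exceeding their total form within the same
  `(lake, date, depth)` sample are flagged questionable and kept.

All thresholds live in configuration (the vocabulary file), never in
code, and the shipped defaults are deliberately *extremely high* so that
real extreme values survive; they are stand-ins, since authoritative
per-variable thresholds are program-specific. Rule application is
idempotent (re-running adds no duplicate flags) and order-independent.
Cross-variable checks never interpolate across samples.

## Exports and versioning

`export_flat()` transposes live observations into one row per
`(lake, date, depth code)` with one column per variable plus a parallel
flag column; geo metrics export one file per theme × zone type keyed by
ZoneID, re-joinable through the membership table. `NA` is the missing
token; files are RFC-4180 CSV, UTF-8, with 15-significant-digit number
formatting so identical stores export byte-identical files under a fixed
`created_date`. When two programs sample the same lake-date, the cell
exports their median with a `MULTI` flag — raw duplicates remain in the
vertical store; pre-aggregated *input* is forbidden but an export
collision policy is unavoidable, and the median is robust to a single
discrepant duplicate. Version strings are `MAJOR.DDD.PATCH` with `DDD`
the zero-padded loaded-dataset count (40 datasets → `1.040.x`); this
reading of the version convention is a package choice. The
user-documentation writer refuses to emit a file whose columns it cannot
describe from the vocabulary — documentation completeness is enforced,
not aspirational. `vertical_roundtrip()` inverts the transposition and
is tested for exact tuple equality.

## The synthetic generator

`gen_landscape()` emulates the input universe: convex lake polygons on a
well-spaced grid with ~30 % of areas below the 4 ha threshold, ~10 %
artificial and ~5 % non-perennial; stream chains that realize all four
connectivity classes with the true class recorded by construction;
nested rectangular zones (2 states, 2×2 counties, 2 hu4, 4×4 hu8); and a
four-class land-cover checkerboard whose per-zone proportions the ledger
computes by independent rectangle arithmetic. `gen_source_dataset()`
emits three provider dialects — a wide state-agency table (mg/L, feet,
`%m/%d/%Y`), a long citizen table (synonym variable names, `<` censor
codes, `%d.%m.%Y`), an idiosyncratic university table (µmol P/L,
centimetres, `%Y%m%d`) — with site coordinates displaced by a mixture
(60 % exact centroid; 25 % shoreline-like, 5–80 m beyond the boundary;
15 % access-point-like, 120–500 m beyond), chosen so each displaced
site's match outcome is provable: a shoreline site is always within the
100 m tolerance, an access-point site always beyond it. Injected
violations are exact counts (`round(rate × cells)`) recorded per cell,
so recovery tests are equalities, not approximations.

What the generator does **not** emulate — and hence what passing tests
cannot show: raster land-cover/climate realism (value layers are
polygonal), non-convex or multi-part lake geometries, holes and islands,
statistical realism of limnological values beyond plausible ranges,
correlated variables, seasonal structure, or messy real-world encodings
(locale decimal commas, embedded notes). Real deployments should expect
more harmonization issues and more review-queue traffic than the
fixtures produce.

## Numerical choices and problem sizes

Containment treats boundary points as inside; clipping uses a 1e-12
side-test slack and discards intersections below 1e-12 area; coverage
comparisons use 1e-9 relative tolerance; unit round-trips are tested to
1e-9. The packaged tests run the complete pipeline on 16–48-lake
landscapes (plus a 520-waterbody landscape for the ~200-site
georeferencing check, 100 random containment fixtures and 50 random
20-node networks), sizes chosen so the whole suite exercises every stage
in well under a minute while keeping each oracle comparison exhaustive
at its scale. The demo workflow — fixtures through export on 24 lakes
and three sources — completes in a few seconds on one core.

## Known limitations

Convex-only clipping and single-ring polygons; no Shapefile reader
(GeoJSON only); no coordinate reprojection (all layers must share one
projected CRS, declared; mismatches are errors, not warnings); the store
is single-writer; the connectivity taxonomy ignores wetlands and
interbasin transfers; and the shipped vocabulary, thresholds and rule
set are starting points intended to be replaced by program-specific
configuration.
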