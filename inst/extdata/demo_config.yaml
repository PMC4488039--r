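# Demo pipeline configuration: synthetic fixtures through export.
# Paths are relative to the working directory the pipeline is run from.
store: demo/store
data_dir: demo/data
crs: "EPSG:5070"
census_min_area_ha: 4
tolerance_m: 100
run_log: demo/run.log
fixtures:
  n_lakes: 24
  seed: 42
  n_samples: 4
  error_rate: 0.01
  styles: [wide_state, long_citizen, odd_university]
export:
  dir: demo/exports
  major: 1
  patch: 0
  created_date: "2026-01-01"
  change_notes: "demo export from synthetic fixtures"
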