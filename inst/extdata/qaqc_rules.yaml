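# Two-tier QAQC rule set. Limno numeric thresholds (valid_min, valid_max,
# egregious_max) live with the controlled vocabulary, per variable; rules
# here reference them. Geo-tier rules only flag; the limno EGREGIOUS rule
# deletes but archives (audit FlagRecord retained).
limno:
  - rule_id: limno_egregious_max
    category: EGREGIOUS
    severity: egregious
    disposition: deleted
    description: value exceeds the variable's egregious_max threshold
  - rule_id: limno_above_valid_max
    category: QUESTIONABLE
    severity: questionable
    disposition: flagged
    description: value exceeds the variable's plausible maximum
  - rule_id: limno_below_valid_min
    category: QUESTIONABLE
    severity: questionable
    disposition: flagged
    description: value below the variable's plausible minimum (e.g. negative depth)
  - rule_id: limno_dissolved_exceeds_total
    category: INCONSISTENT
    severity: questionable
    disposition: flagged
    description: dissolved fraction exceeds the total form in the same sample
    pairs:
      - {dissolved: tdp, total: tp}
      - {dissolved: srp, total: tp}
      - {dissolved: tdn, total: tn}
      - {dissolved: doc, total: toc}
      - {dissolved: dkn, total: tkn}
geo:
  - rule_id: geo_proportion_range
    category: NOT_ECOLOGICAL
    severity: questionable
    disposition: flagged
    description: a proportion metric lies outside [0, 1]
  - rule_id: geo_depth_not_feasible
    category: NOT_FEASIBLE
    severity: questionable
    disposition: flagged
    description: lake mean depth exceeds lake maximum depth
  - rule_id: geo_beyond_prior
    category: BEYOND_PRIOR
    severity: questionable
    disposition: flagged
    description: metric exceeds the maximum reported by prior studies
    prior_max:
      elevation_mean: 4500
      precip_mean: 7000
      temp_mean: 35
  - rule_id: geo_false_na
    category: FALSE_NA
    severity: questionable
    disposition: flagged
    description: metric reported not-available although source data cover the zone
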