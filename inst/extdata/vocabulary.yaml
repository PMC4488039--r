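# Packaged controlled vocabulary: 17 water-quality variables plus lake
# depth. Threshold columns (valid_*, egregious_max) are QAQC
# configuration, deliberately set at extremely high levels so that real
# extreme values survive screening. This is a synthetic stand-in
# vocabulary: canonical names follow common limnological usage.
variables:
  - {canonical_name: tp,        long_name: "Total phosphorus",                  canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 3000,  egregious_max: 20000}
  - {canonical_name: tn,        long_name: "Total nitrogen",                    canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 30000, egregious_max: 200000}
  - {canonical_name: tkn,       long_name: "Total Kjeldahl nitrogen",           canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 30000, egregious_max: 200000}
  - {canonical_name: no2no3,    long_name: "Nitrate plus nitrite nitrogen",     canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 20000, egregious_max: 150000}
  - {canonical_name: no2,       long_name: "Nitrite nitrogen",                  canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 5000,  egregious_max: 50000}
  - {canonical_name: nh4,       long_name: "Ammonium nitrogen",                 canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 10000, egregious_max: 100000}
  - {canonical_name: srp,       long_name: "Soluble reactive phosphorus",       canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 2000,  egregious_max: 15000}
  - {canonical_name: tdp,       long_name: "Total dissolved phosphorus",        canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 2500,  egregious_max: 15000}
  - {canonical_name: tdn,       long_name: "Total dissolved nitrogen",          canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 25000, egregious_max: 150000}
  - {canonical_name: dkn,       long_name: "Dissolved Kjeldahl nitrogen",       canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 25000, egregious_max: 150000}
  - {canonical_name: ton,       long_name: "Total organic nitrogen",            canonical_units: "ug/L", category: nutrient,    valid_min: 0, valid_max: 25000, egregious_max: 150000}
  - {canonical_name: doc,       long_name: "Dissolved organic carbon",          canonical_units: "mg/L", category: carbon,      valid_min: 0, valid_max: 200,   egregious_max: 1000}
  - {canonical_name: toc,       long_name: "Total organic carbon",              canonical_units: "mg/L", category: carbon,      valid_min: 0, valid_max: 300,   egregious_max: 1500}
  - {canonical_name: chla,      long_name: "Chlorophyll a",                     canonical_units: "ug/L", category: chlorophyll, valid_min: 0, valid_max: 1500,  egregious_max: 10000}
  - {canonical_name: secchi,    long_name: "Secchi disk transparency depth",    canonical_units: "m",    category: clarity,     valid_min: 0, valid_max: 50,    egregious_max: 200}
  - {canonical_name: colora,    long_name: "Apparent color",                    canonical_units: "PCU",  category: clarity,     valid_min: 0, valid_max: 1000,  egregious_max: 10000}
  - {canonical_name: colort,    long_name: "True color",                        canonical_units: "PCU",  category: clarity,     valid_min: 0, valid_max: 1000,  egregious_max: 10000}
  - {canonical_name: maxdepth,  long_name: "Lake maximum depth",                canonical_units: "m",    category: depth,       valid_min: 0, valid_max: 500,   egregious_max: 2000}
  - {canonical_name: meandepth, long_name: "Lake mean depth",                   canonical_units: "m",    category: depth,       valid_min: 0, valid_max: 300,   egregious_max: 2000}
synonyms:
  "total phosphorus": tp
  "phosphorus, total": tp
  "tot p": tp
  "total p": tp
  "total nitrogen": tn
  "nitrogen, total": tn
  "tot n": tn
  "kjeldahl nitrogen": tkn
  "total kjeldahl nitrogen": tkn
  "nitrate-nitrite": no2no3
  "nitrate + nitrite": no2no3
  "no3no2": no2no3
  "nox": no2no3
  "nitrite": no2
  "ammonium": nh4
  "ammonia-n": nh4
  "ortho-phosphate": srp
  "orthophosphate": srp
  "soluble reactive phosphorus": srp
  "dissolved phosphorus": tdp
  "total dissolved phosphorus": tdp
  "total dissolved nitrogen": tdn
  "dissolved kjeldahl nitrogen": dkn
  "organic nitrogen": ton
  "dissolved organic carbon": doc
  "total organic carbon": toc
  "chlorophyll": chla
  "chlorophyll a": chla
  "chl-a": chla
  "secchi": secchi
  "secchi depth": secchi
  "secchi disk depth": secchi
  "transparency": secchi
  "apparent color": colora
  "true color": colort
  "max depth": maxdepth
  "maximum depth": maxdepth
  "mean depth": meandepth
units:
  - {symbol: "ug/L",      dimension: mass_concentration, factor: 1}
  - {symbol: "ug P/L",    dimension: mass_concentration, factor: 1}
  - {symbol: "ug N/L",    dimension: mass_concentration, factor: 1}
  - {symbol: "mg/L",      dimension: mass_concentration, factor: 1000}
  - {symbol: "mg P/L",    dimension: mass_concentration, factor: 1000}
  - {symbol: "mg N/L",    dimension: mass_concentration, factor: 1000}
  - {symbol: "ng/L",      dimension: mass_concentration, factor: 0.001}
  - {symbol: "ppm",       dimension: mass_concentration, factor: 1000}
  - {symbol: "ppb",       dimension: mass_concentration, factor: 1}
  - {symbol: "mg/m3",     dimension: mass_concentration, factor: 1}
  - {symbol: "umol P/L",  dimension: mass_concentration, factor: 30.97}
  - {symbol: "umol N/L",  dimension: mass_concentration, factor: 14.01}
  - {symbol: "m",         dimension: length, factor: 1}
  - {symbol: "cm",        dimension: length, factor: 0.01}
  - {symbol: "ft",        dimension: length, factor: 0.3048}
  - {symbol: "in",        dimension: length, factor: 0.0254}
  - {symbol: "km",        dimension: length, factor: 1000}
  - {symbol: "PCU",       dimension: color, factor: 1}
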