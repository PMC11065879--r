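# Synthetic crop archetypes: every generator default lives here so tests
# and documentation can cite exact parameters.
#
# Per-band trajectories are base + (peak - base) * g(t)^e, where g is a
# normalized double logistic (greenup midpoint sos50, senescence midpoint
# eos50, rates in days) and e is 1 for structural bands. The
# pigment-sensitive bands (red, RE1) use e = chl_exponent: high-chlorophyll
# crops (< 1) develop pigment absorption ahead of canopy structure, giving
# a concave TCARI/OSAVI curve; low-chlorophyll crops (> 1) lag, giving a
# convex one.
optical:
  cadence_days: 5
  first_doy: 92
  last_doy: 318
sar:
  cadence_days: 12
  vh_base_db: -22.0
  vh_range_db: 8.0
  vv_base_db: -14.0
  vv_range_db: 3.0
  noise_db: 0.5
base_reflectance:
  blue: 0.06
  green: 0.08
  red: 0.10
  re1: 0.12
  re2: 0.15
  re3: 0.17
  nir: 0.18
  swir1: 0.25
  swir2: 0.20
jitter:
  season_sd_days: 3.0
  vigor_sd: 0.05
crops:
  soybean:
    sos50: 160
    eos50: 265
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 0.35
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.03, green: 0.06, red: 0.030, re1: 0.09, re2: 0.34,
           re3: 0.38, nir: 0.48, swir1: 0.21, swir2: 0.13}
  corn:
    sos50: 150
    eos50: 262
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 0.35
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.03, green: 0.07, red: 0.040, re1: 0.10, re2: 0.25,
           re3: 0.35, nir: 0.40, swir1: 0.16, swir2: 0.08}
  rice:
    sos50: 155
    eos50: 280
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 0.35
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.03, green: 0.06, red: 0.040, re1: 0.10, re2: 0.26,
           re3: 0.31, nir: 0.40, swir1: 0.12, swir2: 0.06}
  peanut:
    sos50: 150
    eos50: 275
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 2.5
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.04, green: 0.08, red: 0.090, re1: 0.14, re2: 0.24,
           re3: 0.28, nir: 0.36, swir1: 0.22, swir2: 0.15}
  cotton:
    sos50: 155
    eos50: 285
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 2.5
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.04, green: 0.08, red: 0.085, re1: 0.15, re2: 0.23,
           re3: 0.27, nir: 0.35, swir1: 0.24, swir2: 0.17}
  potato:
    sos50: 145
    eos50: 260
    growth_rate: 8
    senescence_rate: 8
    chl_exponent: 2.5
    noise_sd: 0.012
    gap_prob: 0.2
    peak: {blue: 0.04, green: 0.07, red: 0.080, re1: 0.13, re2: 0.22,
           re3: 0.26, nir: 0.34, swir1: 0.20, swir2: 0.14}
  other:
    sos50: 140
    eos50: 280
    growth_rate: 12
    senescence_rate: 12
    chl_exponent: 1.8
    noise_sd: 0.015
    gap_prob: 0.2
    peak: {blue: 0.05, green: 0.08, red: 0.085, re1: 0.13, re2: 0.20,
           re3: 0.24, nir: 0.30, swir1: 0.23, swir2: 0.17}
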