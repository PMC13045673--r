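# Default synthetic-cohort configuration, calibrated to the published
# characteristics of a 206-patient European tertiary-care CRSwNP cohort.
#
# Continuous fields are calibrated to the published median and quartiles
# (the calibration anchors the theoretical median exactly and fits the
# spread to the quartiles); age and BMI use the published mean +/- SD;
# categorical and banded fields use the published frequencies. History
# bands reported as ">3" are stored as the value 4 (every bundled rule
# threshold is <= 2, so any value >= 4 is equivalent under every rule).
#
# NPS band notation in the source table is typographically ambiguous;
# the 0-2 / 3-4 / 5-6 / 7-8 reading used here is only approximately
# consistent with the separately published 44.3% share of NPS >= 4
# (it implies ~39%), with uniform sampling within a band.
#
# Missingness is missing-completely-at-random with per-field rates
# 1 - observed/206, the observed counts being the published per-field
# denominators. Fields without a published denominator are never masked.

# ("n" is quoted because bare n/y are YAML 1.1 boolean tokens)
"n": 206
seed: 1
marginals:
  age: {family: truncnorm, mean: 50.5, sd: 12.1, lower: 18, upper: 95, round: 0}
  sex: {family: categorical, levels: [male, female], probs: [0.600, 0.400]}
  bmi: {family: truncnorm, mean: 26.0, sd: 4.8, lower: 14, upper: 60, round: 1}
  smoking: {family: categorical, levels: [current, ex, never], probs: [0.133, 0.352, 0.516]}
  disease_duration: {family: lognormal, median: 11.0, q1: 4.0, q3: 21.0, round: 1}
  n_ess: {family: banded_count, bands: [[0], [1], [2], [3], [4]], probs: [0.319, 0.394, 0.138, 0.085, 0.064]}
  n_scs_past_year: {family: banded_count, bands: [[0], [1], [2], [3], [4]], probs: [0.478, 0.198, 0.154, 0.077, 0.093]}
  asthma: {family: bernoulli, p: 0.597}
  allergy: {family: bernoulli, p: 0.595}
  nerd: {family: bernoulli, p: 0.240}
  snot22: {family: scaled_beta, median: 37.0, q1: 18.5, q3: 59.0, lower: 0, upper: 110, round: 0}
  lund_mackay: {family: scaled_beta, median: 14.5, q1: 9.0, q3: 20.0, lower: 0, upper: 24, round: 0}
  vas_tss: {family: scaled_beta, median: 41.0, q1: 14.5, q3: 68.5, lower: 0, upper: 100, round: 0}
  vas_nb: {family: scaled_beta, median: 33.0, q1: 8.0, q3: 65.3, lower: 0, upper: 100, round: 0}
  vas_los: {family: scaled_beta, median: 62.5, q1: 14.5, q3: 98.8, lower: 0, upper: 100, round: 0}
  nps: {family: banded_count, bands: [[0, 1, 2], [3, 4], [5, 6], [7, 8]], probs: [0.456, 0.304, 0.215, 0.025]}
  bec: {family: lognormal, median: 379.0, q1: 200.0, q3: 600.0, round: 0}
  ige: {family: lognormal, median: 77.0, q1: 17.0, q3: 211.5, round: 1}
  biologic_initiated: {family: bernoulli, p: 0.18932}   # 39/206
  incs: {family: bernoulli, p: 0.503}
  ics: {family: bernoulli, p: 0.380}
loadings: {}          # per-field weights on the shared severity factor; default independence
missingness_observed: # published per-field denominators out of 206
  denominator: 206
  observed:
    n_ess: 195
    n_scs_past_year: 188
    nps: 158
    snot22: 191
    vas_tss: 199
    vas_nb: 196
    vas_los: 194
    bec: 153
    ige: 149
    asthma: 204
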