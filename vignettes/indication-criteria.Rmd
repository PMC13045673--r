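---
title: "Evaluating biologic-indication criteria on incomplete CRSwNP records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating biologic-indication criteria on incomplete CRSwNP records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsbiologic)
```

## The problem

International recommendations define when a patient with uncontrolled
severe chronic rhinosinusitis with nasal polyps (CRSwNP) is indicated
for a biologic. Applying such criteria to real-world registry data runs
into a structural difficulty: almost every input — endoscopy scores,
patient-reported symptom scales, blood values, treatment history — can
be missing for any given patient, and different criteria are missing for
different patients. Simply dropping incomplete records (complete-case
analysis) discards patients whose verdict is actually already decided by
the fields they *do* have: a patient with a nasal polyp score of 2 fails
the EUFOREA 2021 severity gate no matter what their missing SNOT-22
would have been.

`crsbiologic` makes this precise with three-valued logic and provides
everything around it: a validated record schema, the two bundled rule
sets, cohort-level reporting, an exact-test kernel, and a synthetic
cohort generator so the whole pipeline is testable without patient data.

## Three-valued evaluation and evaluability

Every leaf criterion maps a possibly-missing measurement to a *TriState*
TRUE / FALSE / UNKNOWN (in R: a logical with `NA` as UNKNOWN). All
bundled leaves are at-least comparisons (`threshold_test()`), plus one
recorded boolean (asthma). Connectives use **strong Kleene logic**:

* `kleene_and`: FALSE if either side is FALSE, TRUE if both TRUE,
  otherwise UNKNOWN;
* `kleene_or`: TRUE if either side is TRUE, FALSE if both FALSE,
  otherwise UNKNOWN;
* `at_least_k`: TRUE when the known TRUEs already reach *k*, FALSE when
  even counting every UNKNOWN as TRUE cannot reach *k*, else UNKNOWN.

These are exactly the three-way summaries of evaluating the tree under
*every completion* of the unknown leaves: the composite is TRUE iff all
completions are TRUE, FALSE iff none is. The test suite checks this
equivalence exhaustively — both bundled trees have seven leaves, so all
3^7 = 2187 tristate assignments are enumerated against a brute-force
completion oracle, on every node of the tree. Two consequences matter
for reporting:

* **Evaluability.** A patient is *evaluable* for a criterion iff its
  TriState is determinate. Denominators therefore vary by row, and a
  composite's denominator can legally *exceed* a component's: the OR of
  surgery history and steroid courses is decided for a patient with a
  recorded surgery and a missing steroid count.
* **Information monotonicity.** Kleene connectives are monotone in the
  information order (UNKNOWN below both truth values), so filling in a
  missing field can never flip a determinate verdict. This is asserted
  as a property test under random fill-ins.

The rule trees themselves are declarative data (`crit_threshold()`,
`crit_any()`, `crit_at_least()`, ...), serializable to JSON against a
schema shipped in `extdata/ruleset-schema.json`. The bundled sets are
`ruleset_euforea2021()` and `ruleset_epos2023()`; their constructors
accept cutoff overrides so users can express national reimbursement
variants (e.g. NPS ≥ 5, SNOT-22 ≥ 50) without touching the engine.

### Interpretation choices fixed by the package

Where the operationalization of the recommendations required a choice,
the package fixes it as follows:

* The 2021 steroid criterion ("≥ 1 course in the past 2 years") is
  evaluated on the recorded *past-year* count, the only window the data
  model carries.
* "Previous sinonasal surgery" and "history of endoscopic sinus
  surgery" are treated as the same field (`n_ess ≥ 1`).
* The asthma leaf uses the recorded asthma diagnosis, not inhaled
  corticosteroid use; the `ics` field exists but no bundled rule reads
  it.
* The smell criterion uses the VAS loss-of-smell surrogate at ≥ 52 mm
  (not 50), matching the adapted cutoff used with this instrument.
* Banded history answers (">3" surgeries or steroid courses) are stored
  as the integer 4. Every bundled threshold on these fields is ≤ 2, so
  any value ≥ 4 is equivalent under every rule and the convention is
  lossless for evaluation.

## Reporting conventions

All percentages are `100·n/d` rounded **half-up to one decimal**
(`percent()`), and every emitted table is checked internally: a
percentage that does not recompute from the counts printed beside it is
a hard error, not a formatting nuance. Patients with UNKNOWN composite
verdicts are excluded from cross-tabs, treatment gaps and concordance
(determinate-case analysis); the exclusion counts are reported in the
objects and in the pipeline manifest. Median/IQR summaries use linear
interpolation between order statistics (quantile type 7, positions
`p(n−1)+1`), the most common convention in statistical software.

The Fisher test (`fisher_exact_2x2()`) is a self-contained kernel: it
enumerates the full hypergeometric support of the top-left cell,
accumulates probabilities via `lchoose` so registry-scale counts cannot
overflow, and sums all tables whose probability is at most the observed
table's × (1 + 1e−7) — the probability-mass convention for two-sided
p-values. The unconditional odds ratio `ad/bc` is reported alongside
(blank when undefined). The suite verifies the kernel against a plain
factorial-formula oracle exhaustively for every 2×2 table with total
N ≤ 40, and against `stats::fisher.test` on random larger tables.

## The synthetic cohort generator

The generator emulates the *published marginal summaries* of a
206-patient European tertiary-care CRSwNP cohort; it does not, and
cannot, reproduce the unpublished joint distribution.

**Families.** Blood eosinophils, total IgE and disease duration are
log-normal (positive, right-skewed); SNOT-22, Lund-Mackay and the three
VAS scales are scaled-beta on their bounded ranges; age and BMI are
truncated normals from the published mean ± SD; surgery and steroid
counts and the nasal polyp score are banded-categorical with the
published band frequencies, sampled uniformly within a band. These are
the least-surprising two-parameter families honouring each field's
support when only a median/IQR or band table is published.

**Calibration.** `calibrate_quantiles()` fits each median/IQR-calibrated
family by anchoring the *theoretical median exactly* on the published
median (closed form for the log-normal, a constrained root-solve for the
scaled beta) and least-squares-fitting the remaining spread parameter to
the two quartiles (bounded search, tolerance 1e−6). The alternative — a
joint least-squares fit of both parameters to all three quantiles — was
rejected deliberately: with two parameters and three targets the fit
trades median error against quartile error, and for markedly asymmetric
IQRs (blood eosinophils: 379, IQR 200–600) it displaces the implied
median by ~5 %, while the median is precisely the quantity downstream
summaries report. With median anchoring the quartile misfit is absorbed
where it matters least.

**Dependence.** A single latent severity factor couples fields,
Gaussian-copula style: per patient `z ~ N(0,1)`, per field a loading
λ ∈ [−1, 1] and rank `u = Φ(λz + √(1−λ²)e)` pushed through the marginal
quantile function (monotone for every family, so positive loadings move
all loaded fields toward their severe end together). The default is
λ = 0 everywhere — the published data constrain only marginals, and the
near-multiplicative combination of the published type-2 component
frequencies (81.7 % and 44.3 % combining to ≈ 90.3 %) is consistent with
approximate independence. The treatment indicator is an independent
Bernoulli (p = 39/206) by default, so simulated prescription does not
track simulated indication; a loading can be set to change that.

**Missingness** is missing-completely-at-random with per-field rates
equal to one minus the published per-field observed fractions (e.g. the
nasal polyp score observed in 158 of 206 patients). No published
information supports an informative mechanism. Two published
denominators conflict for the steroid-course field (188 for the ≥ 1
cutoff, 182 for the ≥ 2 cutoff, a single underlying field); the default
uses 188. The NPS band notation in the source is typographically
ambiguous; the 0–2/3–4/5–6/7–8 reading used by the default configuration
implies ~39 % with NPS ≥ 4 versus the separately published 44.3 %, a
discrepancy flagged in the configuration file comments.

**What passing tests do and do not show.** Marginal-recovery tests (at
n = 20 000: continuous medians within 3 % of target, category
frequencies within 1.5 points) show the sampler is calibrated, not that
the synthetic cohort behaves like real patients jointly: real symptom
scales correlate, real missingness is likely informative, and composite
indication fractions depend on that joint structure. The generated
composite rates landing near the published ones is therefore a
plausibility check, not a validation. One discretization limit is noted:
an integer-valued Lund-Mackay score cannot have a sample median at the
half-integer target 14.5, so that field is checked to ±0.5 rather than
3 %.

## Numerical and degenerate-input choices

* Fisher two-sided mass comparison uses relative tolerance 1e−7;
  p-values are clamped to ≤ 1.
* Copula ranks are clamped to (1e−12, 1 − 1e−12) before the quantile
  transforms; sampled numerics are rounded to field-appropriate
  precision and clipped to the documented ranges, so generated cohorts
  always validate.
* Empty cohorts, all-UNKNOWN criteria and zero cross-tab margins yield
  blank percentages (with warnings where the caller should know), never
  division errors.
* `at_least_k` rejects k outside [1, n]; calibration rejects unordered
  or out-of-range quantile targets before any sampling.
* Masking and generation use separate seeds (the pipeline derives
  `seed + 1` for masking) so the two stages are independently
  reproducible; every report bundle's manifest records the full
  generator configuration for bit-identical re-runs.

## Problem sizes used by the test suite

Calibration checks generate one 20 000-patient cohort; engine/oracle
equivalence enumerates all 2187 leaf assignments per rule set times up
to 128 completions each; the Fisher kernel is verified on all 135 750
tables with N ≤ 40; property tests (monotonicity, determinism,
round-trips) use cohorts of 120–500 patients. These sizes give stable
stochastic margins (binomial standard error ≈ 0.35 percentage points for
a 60 % prevalence at n = 20 000) while keeping the default suite fast.

## Known limitations

* Only the index-date snapshot is modelled; no longitudinal diary data.
* The two criteria variants that require measurements outside the data
  model (tissue eosinophil counts, formal smell testing) are not
  implemented; patient-reported VAS smell is a proxy with imperfect
  correlation to olfactory tests.
* Published composite counts cannot be jointly reproduced from published
  marginals alone, and the package does not try.
* MCAR masking understates the structure of real-world missingness.
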