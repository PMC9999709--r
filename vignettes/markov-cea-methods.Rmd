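---
title: "Methods: a risk-stratified Markov model of primary CVD prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a risk-stratified Markov model of primary CVD prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irapen)
```

This vignette is the package's own account of the model it implements:
the structure and assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## The decision problem

A primary-health-care program screens adults from age 40 with a WHO/ISH
CVD risk chart and offers risk-stratified prevention: lifestyle
counseling plus medication packages that intensify with the 10-year CVD
risk band (low <10%, moderate 10–19%, high 20–29%, very high ≥30%; the
two published bands above 30% are merged because they are treated
identically). The comparator is no prevention: event-free people cost
nothing and receive nothing until a first CHD or stroke event. The
question is the incremental cost per QALY (and per life year) of the
program, per risk band, separately for people with and without diabetes.

Rather than one cohort with an average profile, the model follows one
**index cohort per band** — a hypothetical homogeneous cohort defined by
a representative risk-factor profile (`risk_profile()`, packaged in
`inst/extdata/index_cohorts.yaml`). This keeps the treatment package,
costs, and baseline hazard internally consistent for each band.

## Model structure

Four health states — event-free, CHD, stroke, dead — with annual cycles
over a 40-year horizon (entry at 40, life-table support to 80). The CHD
and stroke states are split into a first-year **tunnel sub-state** and a
chronic sub-state, because first-year costs and utilities differ sharply
from chronic ones. Survivors of a first event stay in that event state
until death: no second events, no CHD↔stroke transitions.

Within a cycle, from event-free, CHD event, stroke event and non-CVD
death compete as a mutually exclusive multinomial; the remainder stays
event-free. This is the simplest reading of a four-state diagram with no
stated within-cycle ordering; the engine validates that the three
probabilities never sum above 1 at any age (`validate_parameters()`
errors naming the age otherwise). All transitions and rewards occur at
cycle end and no half-cycle correction is applied — both arms share the
same structure and transition timing, so a half-cycle correction would
shift both arms' outcomes nearly identically and largely cancel in the
ICER. Cycle 0 accrues nothing.

Mortality is handled in three layers:

* **First-year case fatality.** 25% of CHD events are fatal in year one;
  60% of those deaths are prehospital and costless, the remaining 40%
  incur the full first-year CHD cost. About 25% of strokes are fatal in
  year one (published plausible range 0.22–0.34; the parameter is
  configurable); because half of fatal strokes occur within the first
  month, fatal strokes are costed at 40% of the first-year stroke cost.
  Fatal entrants contribute no QALY or LY in their event cycle (death at
  cycle end, consistent with cost-at-end timing).
* **Post-event fatality.** Event-state occupants face an annual
  cause-specific fatality combined independently with background
  mortality, `1 − (1 − p_fatal)(1 − q_bg)`.
* **Background mortality.** An age-indexed life table net of CHD/stroke
  deaths (`net_background_mortality()` subtracts the CVD-attributable
  share so the model's own event fatality is not double-counted).
  Everyone, post-event states included, faces it.

## Baseline risk

The packaged risk equation is the Framingham general cardiovascular
profile: sex-specific Cox survival form on log(age), log(total
cholesterol), log(HDL), log(SBP), smoking and diabetes, predicting total
10-year CVD risk. Coefficients live in a versioned YAML data file
(`load_risk_coefficients()`), never in code, so alternative published
sets can be swapped in. Two choices deserve note:

* **Annualization.** The conversion from 10-year to annual probability
  is not dictated by the risk chart; the package uses the constant-hazard
  form `p1 = 1 − (1 − p10)^(1/10)`, the standard monotone choice.
* **CHD:stroke split.** The packaged equation predicts combined CVD
  risk; it is split 3:1 into CHD and stroke components
  (`chd_stroke_split: 0.75`, configurable). Separate outcome-specific
  equations of the same shape can be supplied instead.
* **Age updating.** By default the 10-year risk is re-evaluated every
  cycle as the cohort ages (`risk$mode = "per_cycle"`); treatment
  relative risks stay constant. A `"fixed"` mode holds the entry-age
  incidence, which the synthetic scenarios use because their hazard is
  drawn, not profile-derived. Ages beyond the equation's validity range
  (30–74) are clamped to 74 — direct calls warn, the engine clamps
  silently for the oldest cycles.

The representative profile values were chosen once so that each of the
eight packaged profiles' computed risks falls inside its own published
band (e.g. the high-risk non-diabetic profile sits at SBP 178 within its
160–179 band; a mid-band value would classify as moderate under this
particular equation). The self-consistency is a permanent test.

## Intervention effect

Each cohort's package follows the program protocol: moderate risk
receives one antihypertensive (ACE inhibitor) + statin + lifestyle
counseling, high risk adds a thiazide, very high adds a beta-blocker;
diabetic cohorts add metformin (all bands — the low-risk diabetic cohort
receives metformin + lifestyle only) and a sulfonylurea (high/very
high). The low-risk non-diabetic cohort is screened only.

Per outcome, component relative risks multiply and the combined risk
reduction is attenuated by an overlap-correction factor of 0.8 —
`1 − (1 − ∏RRᵢ) × 0.8` — applied only when two or more components are
involved, reflecting that simultaneous risk-factor control achieves less
than the product of isolated effects suggests. Both counseling cost
lines (nutrition, psychiatric) map to the single published lifestyle
relative risk; lifestyle counseling participates in the product like any
other component, since no exclusion rule is published.

Adherence enters as a linear attenuation of the combined risk reduction,
`1 − a·(1 − RR)`: full adherence reproduces the base case, zero
adherence removes the effect. The published analyses run a 50% adherence
scenario without stating a mechanism; linear scaling is the simplest
monotone contract with those endpoints.

## Costs, utilities, discounting

Program costs per cohort-year come from the published cost table (2017
rial line items; their exact integer sums, the 2018 inflation adjustment
and the dollar conversion are all reproduced by `sum_cost_components()`
and `adjust_cost()`; the implied inflation factor 216540/165804 and
exchange rate 216540/5.16 IRR/USD are stored at full precision since
only they are consistent with the printed rows — one column's printed
total exceeds its component sum by 1 IRR, documented in the fixture).
The published cohort costs are for diabetic cohorts; non-diabetic cohort
costs are derived by removing the diabetes-medication cost (metformin
$16/yr from the published low-risk medication line; sulfonylurea assumed
$6/yr) and are tagged `"derived"` in provenance. The screening-only
low-risk non-diabetic cohort uses the published no-medication cost
($5.16/yr).

Event-state annual costs and utilities use the published first-year /
subsequent values (CHD $519/$173, stroke $5,691/$1,422; utilities CHD
0.67/0.82, stroke 0.33/0.52; event-free utility 1, dead 0). Event-free
status-quo occupancy and dying are costless. Costs and effects are both
discounted at 3.5%/year. Any cost item without a published standard
error gets SE = 0.1 × mean.

Reported tables show discounted costs and QALYs alongside
**undiscounted** life years, matching the published layout (undiscounted
LYs of ~30 against a 40-year horizon could not be discounted values,
whose ceiling is the 21.36 annuity factor). `accumulate_outcomes()`
returns both.

## Sensitivity analysis

**One-way (tornado).** Each scalar parameter is addressed by a
slash-path (`"treatments/statin/rr_chd"`), pushed to its bounds (95% CIs
for relative risks; mean ± 1.96 SE truncated to the parameter's domain
for costs and utilities; 50–100% for adherence) with everything else at
base, and ranked by full-precision ICER spread (rounded ICERs would
create rank ties). Restoring a parameter reproduces the base ICER
bit-exactly; undefined-ICER bounds are flagged and excluded from the
ordering.

**Probabilistic.** Gamma distributions for costs and beta for utilities
(method of moments), lognormal for relative risks inverted from their
95% CIs (`σ = (ln hi − ln lo)/(2 × 1.959964)`) — lognormal is the
standard positive-support model for ratio parameters, and the published
distribution list names only costs and utilities. Parameters are drawn
independently (no correlation structure is published); component
relative risks are sampled *before* the overlap combination so the
combined effect varies coherently per draw. Each parameter draws from
its own named RNG substream (seed derived from the parameter path), so
adding an assignment never perturbs other parameters' draws. Transition
baselines (incidences, fatalities, life table) are held fixed. Draws
breaking a structural invariant (e.g. first-year cost below chronic
cost) are redrawn, with a warning above a 1% redraw rate. Default 1,000
draws; zero-SE assignments collapse the PSA exactly onto the
deterministic result, which is a permanent test.

## Synthetic data: what it emulates and what it does not

The original analysis's transition probabilities (annual incidences per
cohort, background life table, post-event fatalities) live in an
unpublished supplementary file. The `synthetic_data` module generates
them with the structure the analysis assumes:

* **Life table**: Gompertz hazard, `qx = 1 − exp(−a·e^{b·age}(e^b−1)/b)`
  capped at 0.99. Defaults `a = 3.8e-5`, `b = 0.096` give a remaining
  life expectancy at 40 of ≈36 years — a realistic level for a
  population with life expectancy at birth in the mid-70s, used as a
  sanity anchor, not a calibration target. The background table removes
  a 35% CVD-attributable share via `net_background_mortality()`.
* **Incidence**: `make_scenario(seed, band)` draws a 10-year risk
  uniformly inside the band, annualizes, splits 3:1 CHD:stroke.
* **Post-event fatality**: 0.04/yr (CHD) and 0.08/yr (stroke), chosen
  once as plausible chronic-phase excess mortality; flagged synthetic.

Consequently the tests show that the *machinery* is correct — band
consistency, full parameter validation, exact recovery of the
generator's own inputs from simulated histories, agreement of the cohort
engine with an independent microsimulation — but **not** that the
absolute published costs/QALYs/LYs are reproduced; those depend on the
unpublished inputs and are out of scope by design. Assertions against
printed numbers are restricted to quantities that are pure arithmetic on
printed values (cost sums, conversions, ICERs from printed incremental
rows), guided by each parameter's provenance tag. Three printed
incremental cells differ from their printed arm differences by one unit
in the last printed digit (pre-rounding artifacts in the source tables);
the tests assert agreement to printed rounding and exactness of the
package's own delta arithmetic.

## Validation

`microsimulate()` is an independent individual-level implementation of
the same natural history and reward rules (its own per-individual
transition sampling and reward accumulation, sharing only the parameter
set and effective relative risks with the cohort engine). On seeded
scenarios at 10⁵ simulees the cohort trace agrees with the
microsimulation means within 3 Monte-Carlo standard errors for cost,
QALYs and LYs. Closed-form checks pin the accumulator: a hazard-free
cohort reproduces cost = C × Σ(1.035)⁻ᵗ (annuity factor 21.3551 over 40
years) and QALY = LY = horizon undiscounted. Structural properties —
occupancy conservation to 1e−12, monotone dead fraction, LY ≥ QALY,
discounted ≤ undiscounted, currency-scale equivariance of the ICER,
exact null-intervention identity — run as property-style tests over
seeded scenarios.

## Numerical and degenerate-input choices

* Risk bands are half-open `[a, b)` so every probability has exactly one
  band; "10–19%" is implemented as `[0.10, 0.20)`.
* ICERs are reported to whole dollars (matching the published tables);
  internal values keep full precision. `|ΔQALY| < 1e−9` ⇒ status
  undefined, never a division. The southwest quadrant (cheaper, less
  effective) reports the raw ratio with a dominated-direction warning;
  the base case never reaches it.
* Serialization is full-precision decimal JSON; `load_parameters()`
  (YAML or JSON) fills omitted sections from the packaged base case and
  re-validates everything, and a round trip is bit-stable.
* Problem sizes used by the shipped tests and scripts: 10⁵ simulees for
  microsimulation agreement, 10⁶ for parameter recovery, 1,000 PSA
  draws per cohort — sizes at which Monte-Carlo error is far below the
  effects being checked.

## Known limitations

* No second or recurrent CVD events (excluded for lack of data; the
  exclusion is conservative for the intervention, which delays first
  events), no cross-event transitions, no sub-annual cycles.
* The intervention effect is assumed equal across risk bands; this
  likely understates the benefit in high-risk and overstates it in
  low-risk groups.
* The treatment disutility of lifelong medication is not modeled.
* The horizon stops at 80 because the life-table support does; a
  lifetime horizon would likely improve the ICERs.
* Absolute monetary results inherit the synthetic transition inputs;
  only the printed-arithmetic quantities are exact reproductions.
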