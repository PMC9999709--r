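# irapen — Markov cohort cost-effectiveness model for risk-based CVD prevention

`irapen` implements a decision-analytic model of primary cardiovascular
disease (CVD) prevention delivered through a primary-health-care
essential-NCD program (IraPEN, the Iranian adaptation of the WHO PEN
package), compared with no prevention. It is written for health
economists and epidemiologists who want a tested, scriptable version of
the analysis: every model quantity is an exported, documented R function,
and the full workflow (base case, one-way and probabilistic sensitivity
analysis, internal validation) is reproduced by the numbered scripts
under `analysis/`.

## The model

Four hypothetical **index cohorts** enter at age 40, one per WHO/ISH
10-year CVD risk band — low (<10%), moderate (10–19%), high (20–29%),
very high (≥30%) — in two scenarios (with/without diabetes). Each cohort
moves through a four-state Markov model with annual cycles over a
40-year horizon:

```
event-free ──► CHD state ──► death
     │   └───► stroke state ──► death
     └───────────────────────► death (other causes)
```

* 10-year CVD risk comes from a Framingham-type general CVD equation
  (Cox survival form, sex-specific), converted to an annual probability
  under constant hazard, `p1 = 1 − (1 − p10)^(1/10)`, and split into CHD
  and stroke components.
* First post-event years are **tunnel states**: 25% of CHD events are
  fatal in the first year (60% prehospital and costless), ~25% of stroke
  events are fatal (fatal strokes incur 40% of the first-year cycle
  cost). Survivors stay in their event state until death; second events
  are not modeled.
* The intervention multiplies event probabilities by an effective
  relative risk built from the per-medication relative risks, combined
  with an overlap correction, `RR = 1 − (1 − RR₁·RR₂···RR_N) × 0.8`, and
  scaled linearly by adherence.
* Costs (USD, healthcare perspective) and utilities follow the published
  program tables; costs and effects are discounted at 3.5%/year; no
  half-cycle correction. The cost-effectiveness threshold is 1 × GDP per
  capita, **$4,091/QALY**.

The transition inputs the source program never published (background
life table net of CVD deaths, per-band annual incidences, post-event
fatalities) are produced by a first-class synthetic-data module
(`make_scenario()`, `make_life_table()`) and tagged `"synthetic"` in
each parameter set's provenance map, so tests restrict exact assertions
to printed values.

## Worked example

```r
library(irapen)

params <- paper_base_case("very_high", diabetic = FALSE)
res <- run_cea(params)
print(res)
#> Incremental cost-effectiveness result
#>   delta cost: $-184.16   delta QALY: 2.1063   delta LY: 1.7508
#>   status: dominant_cost_saving   ICER: $-87/QALY
#>   NMB at $4,091/QALY: $8800.93
```

The very-high-risk cohort gains 2.11 discounted QALYs per person and
*saves* money (negative incremental cost), so the intervention dominates
no prevention for this group. The screening-only low-risk cohort shows
the opposite boundary case:

```r
run_cea(paper_base_case("low", diabetic = FALSE))$status
#> [1] "undefined_zero_effect"
```

— screening costs accrue but no treatment is given, so the QALY gain is
exactly zero and the ICER is undefined. Absolute dollar values depend on
the synthetic transition inputs; the qualitative ordering (higher risk →
larger gains, high/very-high risk → cost-saving) is the model's robust
result.

The analysis workflow:

```sh
Rscript analysis/01_base_case.R           # all 8 cohorts, CE tables
Rscript analysis/02_one_way_sensitivity.R # tornado + 50%-adherence scenario
Rscript analysis/03_psa.R                 # 1,000-draw PSA, CE plane + CEAC
Rscript analysis/04_validation.R          # microsimulation + recovery checks
```

Each script writes CSV/JSON outputs and a run manifest under `results/`.

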