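# raschval

Rasch scale development and validation in R: a complete, tested pipeline
for building test-based assessments — calibration by joint maximum
likelihood, residual fit diagnostics, iterative item purification,
differential item functioning, strata-based reliability with raw-score
cutoffs, and a convergent/criterion validity battery — plus a synthetic
cohort generator with recoverable ground truth so every stage can be
verified by parameter recovery.

The motivating application is a battery of adolescent health literacy
assessments (functional, interactive and critical skills and their 23-item
composite), whose published raw-score cutoff bands ship as named presets.
The raw study responses are not deposited, so the package pairs the
analytic machinery with a generator that emulates the study's conditions:
355 persons, 23 mixed dichotomous/partial-credit items with difficulties
spanning −2.05 to +2.91 logits, and a left-skewed ability distribution.

## The models and statistics

* **Dichotomous Rasch model** `P(X=1) = exp(θ−b) / (1+exp(θ−b))` and
  **Masters partial credit model** `P(X=k) ∝ exp Σ_{j≤k}(θ − b − τ_j)`,
  estimated jointly over persons and items by alternating damped
  Newton-Raphson sweeps with mean item difficulty fixed at 0.
* **Fit:** outfit (mean z²) and infit (Σ W z² / Σ W) mean-squares with
  Wilson-Hilferty standardized forms; point-measure correlations; residual
  PCA first contrast (< 2 ⇒ unidimensional); residual correlations
  (< 0.50 ⇒ locally independent); test-characteristic-curve monotonicity.
* **Purification:** remove one item per round — worst outfit first, gated
  by mean-square > 1.5 *and* standardized outfit > 2 — recalibrating each
  round; negative point-measure-correlation items are always removed; one
  round of person-misfit removal kept only if item fit improves.
* **DIF:** anchored two-stage uniform contrasts with Welch t; flag iff
  |contrast| ≥ 0.5 logits and p < 0.01; Mantel-Haenszel cross-check.
* **Reliability & cutoffs:** item-separation reliability, KR-20/alpha, and
  the Wright strata walk (SEs inflated 10%, new level at twice the joint
  SE), giving `n²/(1+n²)` sample-independent reliability and raw-score
  cutoff bands.
* **Validity:** Pearson convergent correlations; criterion logistic
  regressions with Wald CIs on the per-point odds ratio; tie-corrected ROC
  areas converted to Cohen's d via `d = √2·Φ⁻¹(AUC)`.

## Worked example

Simulate a study-like cohort, run the full pipeline, and read off the
report bundle:

```r
library(raschval)

cohort <- generate_cohort(cohort_config(seed = 42))
bundle <- run_pipeline(run_config(cohort$responses, cohort$covariates,
                                  output_dir = "run42"))

bundle$reliability
#> $item_separation     0.986
#> $person_separation   0.854
#> $kr20                0.875
#> $sample_independent  0.941

bundle$strata
#> <strata_report> 4 level(s), sample-independent reliability 0.94
#>   Emerging: scores 0-10
#>   Expanding: scores 11-19
#>   Lower Bridging: scores 20-26
#>   Upper Bridging: scores 27-30

bundle$validity$summary[, c("measure", "estimate")]
#>                  measure estimate
#>             convergent_r    0.584
#>     beh_questions_online    1.122   # odds ratio per composite point
#>   beh_reads_instructions    1.151
```

The composite calibration separates four performance strata with
sample-independent reliability `4²/(1+4²) = 0.94`; a two-level scale gives
`2²/(1+2²) = 0.80`. Published bands are available directly:

```r
categorize(5, hl_cutoff_presets()$fhl)        # "Expanding"
categorize(28, hl_cutoff_presets()$composite) # "Upper Bridging"
```

A purification run on a cohort with six injected ability-independent noise
items removes exactly those six, one per round (see
`analysis/03_purify.R` for the full narrated run):

```r
co <- generate_cohort(purification_design("six_noise", seed = 911))
purify_items(co$responses)
#> <purification_trace> 7 round(s), 6 item(s) removed
#>   - N05 (outfit) ... - N03 (outfit)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of a complete
scale-development study over the simulated cohort, writing tables under
`results/`:

1. `01_simulate_cohort.R` — cohort, covariates, behaviors, screener
2. `02_calibrate.R` — per-scale and composite calibrations, item table
3. `03_purify.R` — misfit-injection purification studies
4. `04_dif.R` — gender / age-band / ethnicity invariance screens
5. `05_reliability_strata.R` — reliabilities, strata, cutoff scores
6. `06_validity.R` — convergent and criterion validity

Run them in order with `Rscript analysis/01_simulate_cohort.R`, etc.

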