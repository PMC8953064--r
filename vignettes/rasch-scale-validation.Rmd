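---
title: "Rasch scale development and validation with raschval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch scale development and validation with raschval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`raschval` implements the complete analytic pipeline used to develop and
validate test-based assessments with Rasch measurement models: calibration,
fit diagnostics and assumption checks, iterative item purification, a
one-round person-misfit procedure, uniform differential item functioning
(DIF), strata-based reliability with raw-score cutoffs, and a
convergent/criterion validity battery. A synthetic cohort generator with
fully recoverable ground truth makes every stage testable by parameter
recovery. The motivating application is a battery of adolescent health
literacy assessments — functional (FHL), interactive (IHL) and critical
(CHL) skills plus their composite — but nothing in the pipeline is specific
to that instrument.

## The measurement model

For a dichotomous item $i$ and person $n$ the Rasch model gives

$$P(X_{ni}=1) = \frac{e^{\theta_n - b_i}}{1 + e^{\theta_n - b_i}},$$

with person ability $\theta_n$ and item difficulty $b_i$ on a common logit
scale. Ordered polytomous items use Masters' partial credit model (PCM):

$$P(X_{ni}=k) \propto \exp\!\sum_{j \le k} (\theta_n - b_i - \tau_{ij}),
\qquad \tau_{i0} \equiv 0,$$

where the step thresholds $\tau_{ij}$ are item-specific and centered within
each item. With one step the PCM reduces exactly to the dichotomous model,
so both families share all downstream machinery through the expected score
$E_{ni}$ and model variance $W_{ni}$.

Three assumptions are screened at every stage: *unidimensionality* (first
principal component of the item-wise standardized-residual correlation
matrix below 2 items-worth of variance), *local independence* (all pairwise
residual correlations below 0.50 in absolute value; both signed extremes
are reported), and *monotonicity* (strictly ascending test characteristic
curve, checked on 201 grid points over $[-6, 6]$ — analytically guaranteed
for the model, so this guards implementation faults).

## Joint maximum likelihood estimation

`estimate_jmle()` maximizes the joint likelihood over persons and item
steps by alternating damped one-parameter Newton-Raphson sweeps:

* person update: $\theta_n \mathrel{+}= (r_n - \sum_i E_{ni}) / \sum_i W_{ni}$;
* step update for step $j$ of item $i$:
  $d_{ij} \mathrel{+}= (\sum_n P_{ni}(X \ge j) - \sum_n 1[x_{ni} \ge j]) /
  \sum_n P_{ni}(X\ge j)(1 - P_{ni}(X\ge j))$,

each move capped at 1 logit per sweep. After every sweep difficulties are
centered at zero (the identification constraint, matching the mixed-sign
difficulty tables the method reports) and the same shift is applied to the
person measures. Iteration stops when the largest parameter change falls
below `convergence_tol` (default 0.0001 logits) or after `max_iterations`
(default 200) sweeps; non-convergence is flagged, not hidden. At the
solution every retained person's and item's expected total equals its
observed total (`jmle_stationarity()` audits this).

Numerical choices worth knowing:

* **Extreme scores.** Persons with zero or perfect totals and items without
  two distinct observed scores carry no information about their own
  parameters under joint ML; they are removed before estimation (iterating
  until stable) and listed in the calibration. Measures for extreme *raw
  scores* in the score-to-measure table are extrapolated by adjusting the
  extreme score inward by 0.3 score points, the conventional practice.
* **Missing responses** are treated as not administered: skipped in every
  likelihood, expectation and fit sum, never imputed.
* **Standard errors** come from the information sums at the solution:
  $SE(\theta_n) = (\sum_i W_{ni})^{-1/2}$, step SEs from the step
  information, and the item difficulty SE as the delta-method SE of the
  mean of the estimated steps, $\sqrt{\sum_j SE(d_{ij})^2}/m_i$ — for
  dichotomous items this is exactly $(\sum_n W_{ni})^{-1/2}$.
* **Finite-test bias.** JMLE difficulty estimates are inflated by roughly
  $L/(L-1)$ for an $L$-item test. Standard practice in this software lineage is to use
  JMLE as-is, so no correction is applied by default; an optional
  `bias_correction` flag shrinks difficulties by $(L-1)/L$. Signed bias
  averaged over a centered bank is near zero either way; the inflation is
  visible only in the spread.
* Estimation is fully deterministic; seeds matter only for data generation.

The estimator was verified against an independent grid-search maximizer of
the same joint likelihood (person profiles solved by bisection): on every
estimable dichotomous margin class up to 5 persons by 4 items the two agree
within 0.01 logits. Margin classes whose likelihood peaks at the search
boundary (Guttman-separable patterns) have no finite maximizer and are
reported as inestimable.

## Fit statistics and purification

Standardized residuals $z_{ni} = (x_{ni} - E_{ni})/\sqrt{W_{ni}}$ feed two
mean-squares per item (and per person): *outfit*, the unweighted mean of
$z^2$, most sensitive to surprises far from the item's difficulty, and
*infit*, the information-weighted version $\sum W z^2 / \sum W$. Both have
expectation 1 under the model. Standardized forms use the Wilson-Hilferty
cube-root transformation with the model variance of the mean-square (the
convention of the standard Rasch software), so the sign of `zstd` tracks
the direction of departure from 1.

Purification applies the conventional rules: mean-squares in $[0.5, 1.5]$
indicate productive fit; an item is a removal candidate only when outfit
mean-square exceeds 1.5 *and* standardized outfit exceeds 2. Candidates are
removed one per round, worst first (ties by larger |zstd|, then item id),
with recalibration and fresh assumption checks between rounds — the
conservative reading of iterative removal. Items with negative
point-measure correlations (scores negatively correlated with person
measures, i.e. reverse polarity) are always removed; an item breaching both
rules is classified by its polarity, the more fundamental defect. Items
with outfit below 0.5 are noted as overfitting but never removed. A
keep-list lets substantive judgment override the statistics, and the loop
refuses to purify below 3 items.

The person procedure runs exactly once: persons with outfit above 2.0 are
removed, the model is refit, and the reduced dataset is kept only if item
fit strictly improves — fewer items outside the $[0.5, 1.5]$ outfit band,
with mean |item outfit zstd| breaking ties. Otherwise, or when removal
would leave fewer than 30 persons, the original data are retained. The 2.0
floor and the concrete definition of "improved" are package choices; the
source methodology names neither.

## Uniform DIF

`uniform_dif()` uses an anchored two-stage design: persons are measured
once in the pooled calibration; each item's overall difficulty is then
re-estimated within each group with persons (and PCM thresholds) anchored.
The contrast of the two group difficulties is tested with a Welch-style t
(Satterthwaite degrees of freedom), and an item is flagged only when
$|\text{contrast}| \ge 0.5$ logits *and* $p < 0.01$ — the joint
magnitude-and-significance rule, with the stringent per-test $\alpha$ serving
as the multiplicity allowance. Groups under 100 persons trigger a warning
(the size needed to detect 0.5-logit DIF reliably). A Mantel-Haenszel
cross-check stratified on rest-scores is provided for dichotomous items but
is not the primary flag source. Anchoring persons at pooled measures
absorbs a fraction of a true shift into the measures, so recovered
contrasts run some 15% shy of the generating shift on well-targeted items —
the operating characteristics (null flag rate $\le 2\%$, power $\ge 90\%$
for a 1-logit shift at 300 per group) absorb this. Only uniform
(constant-shift) DIF is in scope. The standard screens are gender, age band
(12–15 vs 16–18 years, the banding used when single-year samples are too
small), and ethnicity.

## Reliability, strata and cutoffs

Item-separation reliability is the proportion of observed item-difficulty
variance not attributable to estimation error (population-variance
convention), and KR-20 is computed in its coefficient-alpha generalization
(identical on dichotomous items). Because a skewed sample undermines
sample-dependent person reliability, the primary reliability summary is
Wright's sample-independent statistic $n^2/(1+n^2)$ for $n$ distinguishable
performance levels; person-separation reliability is reported as secondary.

The level count comes from a walk along the score-to-measure table with SEs
inflated by 10%: starting at the lowest attainable raw score, a new level
begins at the first score $s$ whose measure exceeds the *current level's
first score* (the anchor) by at least
$2\sqrt{SE^*(\text{anchor})^2 + SE^*(s)^2}$. Comparing to the level's
lowest score rather than the immediately previous one is the governing
interpretation of the "lowest and current raw scores" phrasing; both
endpoints use inflated SEs. Cutoffs are reported as inclusive raw-score
ranges. The published bands for the health literacy battery ship as named
presets (`hl_cutoff_presets()`): FHL Emerging 0–4 / Expanding 5–6, IHL 0–5
/ 6–10, CHL 0–8 / 9–14, composite Emerging 0–10 / Expanding 11–19 / Lower
Bridging 20–27 / Upper Bridging 28–30, plus the younger-group composite
variant with the Lower/Upper boundary at 26/27.

## Validity battery

Convergent validity is a pairwise-complete Pearson correlation between
summed scores. Criterion validity fits logistic regressions of each binary
health-literacy behavior on the score, controlling for demographics
(gender, age in years, ethnicity by default — the coding is a documented
package choice), reporting Wald 95% intervals on the per-point odds ratio
with separation detection. Effect sizes come from the tie-corrected
Mann-Whitney ROC area, converted to Cohen's d through the equal-variance
binormal relation $d = \sqrt{2}\,\Phi^{-1}(AUC)$ — the closed form
generating the published conversion tables; `table_snap = TRUE` rounds to 2
decimals to mimic table lookup. The 6-item screener used for convergent
anchoring is scored 0–6 and banded 0–1 / 2–3 / $\ge 4$.

## The synthetic cohort generator

`generate_cohort()` draws a full study-like dataset from known parameters
so every stage can be tested by recovery: cell-wise responses from the
model probabilities, demographic covariates, two criterion behaviors from a
logistic link on the summed score, and a convergent screener from a
noise-perturbed ability. The default configuration reproduces the
motivating study's conditions: 355 persons; 23 items with the published
difficulty spread ($-2.05$ to $+2.91$ logits; 16 dichotomous, 2
dichotomous + 5 partial-credit worth 12 points so the critical scale spans
0–14 and the composite 0–30); and a left-skewed ability distribution
implemented as a transparent two-normal mixture ($0.75\,N(1.3, 0.9^2) +
0.25\,N(-1, 1.1^2)$ — a health-class sample sitting about a logit above the
item centers with a low tail). Unpublished quantities were set once, by
calibration against published summaries: the PCM step spreads
($\pm 1$ and $\pm 1.6$ logits) so that estimated item SEs land in the
printed 0.09–0.30 range, and the screener noise (SD 0.8 on ability, with
difficulties 0.4–2.4 shifted hard relative to the focal items) so that
convergent correlations land near the published 0.44–0.56 band. At these
defaults the simulated pipeline reproduces the published *analysis
profile*: first-contrast eigenvalues near 1.4, two strata for the short
scales and four for the composite with reliabilities 0.80/0.94, and
composite behavior odds ratios near 1.15.

Injections with recoverable truth cover every failure mode the pipeline
screens for: uniform DIF shifts per grouping, misfitting persons (whole-row
random responders or careless tails), ability-independent noise items,
reverse-keyed items, and missingness.

**Power design of the injection studies.** A noise item whose responses are
Bernoulli(0.5) independent of ability is, perhaps surprisingly, *invisible*
to the outfit gate in a half-noise 12-item test: its expected squared
residual is $(0.25 + (\hat p - 0.5)^2)/(\hat p(1-\hat p))$, which only
exceeds 1.5 when many persons sit far from the item's estimated difficulty
— and noise contamination compresses the very ability estimates that would
create that distance, pinning the statistic near 1.1–1.3. A 50%-rate coin
flip is in fact the *least* detectable ability-independent noise. The
frozen injection designs (`purification_design()`) therefore use noise
with extreme marginal rates (0.07–0.93), the classic lucky-guess /
careless-error pattern outfit exists to catch, together with a wide ability
distribution ($N(0, 2^2)$) and good items spanning $\pm 1.2$ logits. Under
these conditions the removal loop deletes exactly the injected items
(6 of 12; 4 noise by outfit plus 1 reverse-keyed by negative polarity in
the 15-item design) in well over 90% of replicates, while model-consistent
cohorts lose essentially nothing.

**What passing these tests does and does not show.** The generator draws
independent cells from the fitted model family, so recovery results certify
the estimator, the decision rules and their operating characteristics — not
robustness to features real data may carry: classroom clustering,
curriculum-linked local dependence, multidimensionality beyond a single
planted contrast, non-uniform DIF, or systematically missing responses.
Category structures of the real polytomous items are unpublished, so the
generator's are configurable defaults.

## Problem sizes

The shipped tests and analysis scripts run the estimator at the study's own
scale (355 × 23) and at 500 × 20 for null-behavior checks, use 20-replicate
recovery and injection studies, 100-replicate DIF operating
characteristics at 300 per group, and the exhaustive small-matrix oracle
comparison up to 5 × 4. These sizes give Monte-Carlo error comfortably
inside every asserted band while keeping a full run in a few minutes.

## Known limitations

* Joint ML carries its well-known finite-test difficulty inflation; no
  correction is applied by default, matching standard practice with this
  software lineage.
* DIF contrasts from the anchored two-stage design are mildly attenuated;
  detection, not unbiased effect estimation, is the design goal.
* The person-misfit "improvement" criterion is necessarily a discrete
  proxy; other reasonable definitions could retain different datasets.
* Rating-scale (shared-threshold) models, marginal/conditional ML,
  multidimensional IRT and 2PL/3PL discrimination are out of scope.
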