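---
title: "Model and methods: a colorectal-cancer screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a colorectal-cancer screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cmost` simulates individual colorectal-cancer (CRC) life histories in
3-month steps from birth to death or age 100. Each individual carries a sex,
an individual adenoma-risk multiplier, a list of adenomas and a list of
preclinical cancers. Lesions live in one of 13 colonic segments (1 = rectum
… 6 = splenic/left flexure … 9 = hepatic flexure … 13 = cecum); the segment
is fixed for the lesion's lifetime and determines progression corrections
(rectum vs colon), endoscope reach and detection.

Within every quarter, events are resolved in a fixed order:

1. **Natural history.** A new stage-I adenoma appears with probability
   $a_0/(1+e^{-(a_1 y - a_2)})$ (age $y$ in years) times the male correction
   and the individual multiplier; its segment is drawn from a configurable
   location distribution. Each existing adenoma then experiences at most one
   of: *progression* (stage $+1$; stage VI progression is malignant
   transformation), *fast malignant transformation* (stages I–V), or
   *regression* (stage $-1$; a regressing stage-I adenoma disappears). The
   per-quarter probabilities are products of an age-dependent Gaussian base
   rate ($b_0 e^{-(b_1 y-b_2)^2}$ for stages I–IV, $c_0 e^{-(c_1 y-c_2)^2}$
   for V–VI and the fast route), a per-lesion multiplier, a per-stage
   constant, and sex/rectum corrections. Direct carcinomas without adenoma
   precursors arise at a constant per-segment rate, preferentially
   right-sided; this pathway stands in for serrated-pathway cancers whose
   precursors colonoscopy does not see. Finally preclinical cancers advance
   through stages 1–4 on a predefined dwell schedule and become symptomatic
   when their sojourn elapses.
2. **Endoscopy** — screening, surveillance, or the diagnostic colonoscopy a
   symptomatic cancer triggers.
3. **Treatment costs and death** — CRC death (restricted to 5 years after
   diagnosis, stage-specific), other-cause death from the life table, or
   death from an endoscopy complication.

Adenoma stages I–IV represent early adenomas (3/5/7/9 mm), V–VI advanced
adenomas (≥1 cm or villous; >2 cm). Cancer detection removes all malignant
disease ("curative treatment") and starts the 5-year treatment-cost and
survival clock; stage-specific 5-year survival is applied as a constant
quarterly hazard inside that window.

### Heterogeneity

Two anchored, piecewise-linear CDFs inject heterogeneity: one maps a uniform
quantile to an individual initiation multiplier (drawn once per person), one
to a per-adenoma aggressiveness multiplier (drawn once per lesion). The
early and advanced per-lesion CDFs are evaluated **comonotonically** — a
single aggressiveness quantile per adenoma feeds both curves. This is what
makes the median adenoma dwell time a usable calibration target: an
aggressive minority of lesions transits all six stages quickly (short
dwell), while the indolent majority carries the prevalence benchmarks.
With independent early/advanced draws (tried first) the dwell-time median
is locked near the population-average transit time and cannot be moved
without destroying the prevalence fit.

The individual-risk CDF is strongly right-skewed (default top 5% of the
population at ~6–18× average risk). Its shape is what produces realistic
adenoma multiplicity (~40% of carriers with ≥2 adenomas) and a synchronous
CRC fraction near 3.5% of diagnoses.

### Preclinical cancer

Sojourn time (cancer initiation → symptoms) is normal with mean 3 y and SD
0.5 y, rejected while non-positive and rounded to quarters (≥1). Quarter
rounding adds ~1/48 y² of variance, so the sampled SD is ≈0.505 — inside
every tolerance used here. The symptomatic stage is drawn from the
configured symptomatic stage distribution; the sojourn quarters are
partitioned multinomially over stages 1…s* with configurable weights
(default 0.50/0.25/0.15/0.10). The partition rule is modeling freedom: only
its two marginals (symptomatic and screen-detected stage distributions) are
benchmarked.

## Screening

*Colonoscopy*: insertion depth is categorical over the deepest segment
reached, 95% cecal intubation, the incomplete 5% spread uniformly over
segments 8–12. Per-stage adenoma detection defaults to 0.75/0.85/0.95
(early/larger-early/advanced), cancer 0.95, with a 0.9 multiplicative
penalty at the two flexures (magnitude not identified by any benchmark —
configurable). Detected adenomas are resected (polypectomy); detected
cancer starts treatment. Complications: major bleed 4, minor bleed 11,
mucosal burn 3, perforation 7 per 10,000, all doubled after polypectomy;
perforation carries a configurable case fatality (default 5%, in line with
published perforation outcomes). *Sigmoidoscopy* reaches segment 5–7 (mean
6 of 13), detects at 75% (early) / 87.5% (advanced and cancer) of
colonoscopy sensitivity, removes nothing, and refers any finding to
colonoscopy; complication probabilities are scaled by 0.1 (factor not
printed anywhere authoritative — configurable). *Stool tests* are a generic
per-lesion-class sensitivity/specificity interface with colonoscopy
referral on positivity.

Adherence is drawn once per individual ("consistent attender"); with
adherence 0 the screened arm is draw-for-draw identical to its baseline,
which the tests exploit. Surveillance follows the guideline rule table:
CRC → 1 y; advanced adenoma or ≥3 adenomas → 3 y; 1–2 small adenomas → 5 y;
nothing at a surveillance exam → back to routine screening; none past
age 85.

## Economics

Costs accrue for procedures, complications and three treatment phases:
initial (charged once in the diagnosis quarter), continuing (annual rate,
quarterly, until 5 y post-diagnosis) and terminal (annual rate over the 12
months before CRC death, replacing continuing; for rapid deaths terminal
dominates and initial is retained). Life-years are counted in quarters.
Both cost and life-year streams are discounted at 3%/year, end-of-year
convention, referenced to cohort birth. The reference point is configurable;
the cost-per-LYG ratio is invariant to it (both numerator and denominator
scale by the same factor), absolute discounted LYG are not — which is why
discounted LYG per 1000 is the quantity most sensitive to this convention.
Comparisons always run against a paired no-screening arm on common random
numbers.

## Calibration

The benchmark panel (91 points, 9 quantity families) tags each point to one
of four steps: I early adenoma (initiation sigmoid + male factor), II
advanced adenoma (early-progression Gaussian + male factor), III cancer
(advanced-progression Gaussian, fast-cancer scale, rectum and male
factors), IV direct cancer (one overall scale on a fixed right-skewed
segment profile). Each step runs a greedy multiplicative coordinate search
(×0.5/0.8/1.25/2, two sweeps) and a log-scale Nelder-Mead refinement on its
own benchmark subset; every objective evaluation simulates with a fixed
seed (common random numbers), so the objective is deterministic and the
accepted-value trajectory is monotone.

Design choices made where the design was open:

* **Relative squared error.** Benchmarks mix fractions, per-100k rates and
  a trial effect size; the objective is
  $\sum_i w_i ((\hat{y}_i - y_i)/y_i)^2$ with equal weights within a
  category and categories normalized to equal total weight.
* **Dwell-time penalty placement.** The median dwell (initiation →
  transformation, direct cancers excluded) is penalized quadratically
  *only* in the joint II+III fine-tune (weight 2). Placing the penalty
  inside the first-pass individual steps (tried first) let it dominate each
  step's small prevalence SSE and drove the parameters into a degenerate
  corner. Only the joint move — early and advanced Gaussians trading off —
  can change dwell while holding the prevalence benchmarks.
* **Joint fine-tune as block-coordinate rounds.** A single 12-parameter
  Nelder-Mead over the II+III groups stalls; the fine-tune instead
  alternates II-block and III-block refits (each greedy + simplex, dwell
  penalty active) for three rounds, exploiting the model's designed
  near-hierarchy.
* **Step IV sees step III's benchmarks.** Direct cancers add to total
  incidence, so fitting the trial benchmark with the direct scale alone can
  (and in testing did) satisfy the trial target by flooding the model with
  unpreventable cancers, wrecking the incidence fit. Step IV therefore
  optimizes the direct scale *and* the fast/adenomatous cancer scale
  against the union of the trial and incidence benchmark sets: adding
  direct cancers must be paid for elsewhere.
* **Step IV reduction.** A single scale on a fixed 13-segment right-skewed
  profile, not 13 free constants: one trial-reduction benchmark cannot
  identify 13 numbers.

Dwell variants 8/13/19 y are separate calibrations differing in the
penalty target. Variants below ~8 y fail: the prevalence benchmarks bound
how fast the adenoma stock can turn over, and `calibrate_full()` warns when
the realized median misses its target by more than 3 y.

## What the shipped fixtures are — and are not

The package ships synthetic stand-ins for inputs whose authoritative values
live in supplementary material not available here: the benchmark panel
(SEER-2005-09-style incidence/mortality, published-style adenoma
prevalence), a stylized 2008-US-style all-cause life table (Gompertz +
infant + young-adult components, $e_0$ = 76.2), and a 2012-Medicare-style
cost table. They are labelled synthetic in their documentation. A green
acceptance suite therefore establishes that the *machinery* reproduces the
published effect sizes when calibrated against a panel of this shape — not
that the shipped panel equals the original one. Quantities with explicit
fixture dependence (absolute costs per LYG most of all) inherit that
caveat.

A further structural limitation matters when comparing against randomized
screening trials: detection is an independent Bernoulli draw per lesion per
examination (no systematically missed lesions), any positive finding
triggers a full colonoscopy, and surveillance attendance is perfect for
consistent attenders. Together these place program effectiveness at the
optimistic end — the emulated one-time sigmoidoscopy trial produces a
larger intention-to-treat incidence reduction than observed trials report,
and colonoscopy-program incidence/mortality reductions sit above the range
published microsimulations give. The direct-cancer pathway cannot absorb
this: its per-segment rate is age-constant, so raising it to blunt
screening effectiveness floods the young-age incidence benchmarks (a trade
the calibration correctly refuses). Effect *magnitudes* should therefore be
read comparatively — between strategies, ages and intervals under the same
instrument assumptions — rather than as absolute forecasts; the *optima*
(best ages) are much more robust than the magnitudes.

Known limitations, deliberate non-goals: no serrated-adenoma lesion class
(folded into the direct pathway), no benign non-adenomatous polyps, no QALY
weighting, single-payer cost perspective, no GUI, no cluster scripts. The
direct-cancer rate is age-constant per segment; consequently the model
cannot reproduce very low CRC incidence below age ~40 simultaneously with a
substantial direct fraction, and the shipped benchmark panel starts at 40
where the screening questions live.

## Numerical conventions

Annual probabilities convert to quarterly as $p_q = 1-(1-p_a)^{1/4}$.
Per-quarter event probabilities are clipped at 1 with a counted warning.
Each lesion experiences at most one event per quarter (probabilities are
small). The engine's RNG is xoshiro256** with per-individual substreams
split between natural history and screening, so paired arms stay
synchronized until an intervention actually changes the colon; results are
bit-reproducible for a given `(params, plan, n, seed)` on any platform.
Natural (non-CRC) death ages are pre-drawn by inverting the quarterly
life-table CDF, which both pairs the competing-mortality draw across arms
and supplies the counterfactual death age used for years-lost accounting.
Lesion dynamics start at age 20; the first benchmarked quantity sits at 35.
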