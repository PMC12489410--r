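---
title: "From shared-plate food records to a weighted mixed-model method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shared-plate food records to a weighted mixed-model method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantifying what one person actually ate is hard in settings where meals
are served communally. An image-voice food record (IVFR) captures each
eating occasion as photographs plus a spoken description; trained
analysts later identify the foods against a food composition database
(FCD) and estimate portions. Three record features complicate the
arithmetic: food may be left over, servings may be *shared plates* eaten
by several people (only some of whom are study participants), and home
recipes change nutrient content through cooking. Once daily intakes
exist for two assessment methods — here an IVFR administered in two
separate weeks and interviewer-administered multiple-pass 24-hour
recalls in between — the methodological question is whether the two
methods agree (relative validity) and whether the IVFR agrees with
itself on repeat administration (test–retest reliability).

`sharedplate` implements both halves: the intake computation engine and
the statistical comparison, plus a synthetic-study generator that makes
the whole chain testable end to end without any field data.

## The intake engine

Every serving resolves to consumed grams, then to nutrients:

1. **Analyst reconciliation.** When a portion was estimated from an
   image, two blinded analysts each give a weight. If the relative
   difference $|a-b| / \bar{ab}$ is at most 25%, the portion is their
   arithmetic mean; above 25% a third analyst's review decides. The 25%
   trigger is the documented rule; the mean as the combination of two
   in-tolerance estimates and the mean-denominator for the relative
   difference are this package's choices (the natural symmetric ones).
2. **Imputation.** A portion that no analyst could resolve gets the
   median of resolved portions of the same item for the same participant
   (or the same household's shared servings), else the median across
   participants of the same type (mother or child), else a
   reference-portion default. Only directly resolved portions feed the
   medians, so imputation can never feed on its own output.
3. **Recipes.** A home recipe's per-100 g profile is
   $\sum_i \frac{g_i}{100}\, x_i \, r_i \times \frac{100}{W}$ over
   ingredients $i$ with per-100 g values $x_i$ and cooking retention
   factors $r_i$ (defaulting to 1 when no factor is tabulated). $W$ is
   the measured final prepared weight when recorded, otherwise the raw
   ingredient mass sum — no yield factors are invented. Profiles are
   built once per household and reused across its occasions.
4. **Leftovers and sharing.** Consumed = served − leftover (forced to
   the full amount or zero by the recorded consumption status). A shared
   serving's consumed total is divided evenly over the total eater count
   — participants and nonparticipants, adults and children alike — and
   each participating eater is assigned one share. Leftovers are
   subtracted from the shared total *before* the split, since attributing
   a communal leftover to individuals is impossible under even-split
   semantics.

Daily totals are summed per participant; per-period intakes are the
arithmetic mean over that period's 2–3 recorded days and form the
observation unit of the statistical model. The supervised practice day
is flagged in the records and always dropped. Breastmilk is out of
scope: only food and beverage servings are quantified, which is also why
a child with no recorded servings carries no intake data at all.

Participants enter the analysis only with at least 2 of the 3 recording
periods each having 2–3 recorded days. A "recorded day" is taken to be a
day with at least one serving that was not entirely unconsumed; the
boundary case (a day recorded but nothing eaten) is not specified by the
record format itself, and this reading keeps "has data" synonymous with
"contributes nonzero potential intake".

## The statistical model

For each role (mother/child) and nutrient separately, with $y_{ij}$ the
period-mean intake of participant $i$ in recording period $j$:

$$y_{ij} = \mu_{j} + a_i + b_{ij} + e_{ij}, \qquad
  a_i \sim N(0, \sigma_p^2),\; b_{ij} \sim N(0, \sigma_{pp}^2),\;
  e_{ij} \sim N(0, \sigma^2 / w_{ij}),$$

a fixed recording-period effect plus two random intercepts — one per
participant and one per period nested within participant — fitted by
REML (`lme4`). Unbalancedness is handled by the likelihood: participants
with only two periods contribute their available rows, and nothing is
imputed.

Intake data are strongly heteroscedastic: the residual spread grows with
the intake level. The weighting procedure estimates the residual SD as a
function of the predicted value and iterates:

* **M0** — unweighted fit;
* **M1** — weighted by $1/\mathrm{SD}^2$ from a *linear* regression of
  M0's absolute residuals on its predicted values;
* **M2** — second iteration: linear SD regression on M1's residuals;
* **M3** — second iteration: *cubic* SD regression on M1's residuals.

The reported model is the candidate whose standardized residuals
(residual/SD) show the least trend against the fitted values, measured
as the absolute Spearman correlation between |standardized residual| and
fitted value. This statistic is a quantitative stand-in for the visual
examination of standardized-residual plots that the procedure
classically relies on; exact ties (essentially only possible in
degenerate data) go to fewer weighting iterations, then lower polynomial
order. If every weighted fit fails, the unweighted model is reported and
annotated that no weighting was used.

Effect sizes are the three pairwise differences of the selected model's
weighted marginal means (test period 1 − recall, test period 2 − recall,
test period 1 − test period 2) with 95% Wald confidence intervals from
the fixed-effect covariance, plus one omnibus Wald chi-square p-value
for the period effect. A normal reference distribution is used
throughout; a small-sample degrees-of-freedom refinement (e.g.
Kenward–Roger) is a noted extension point, not implemented, and at the
default scale of ~100+ participants the difference is negligible.
Bland–Altman bias, limits of agreement and the Spearman trend screen are
reported per method pair but never gate the mixed-model path.

### Numerical choices

* *One observation per cell.* With period means as the observation unit,
  $b_{ij}$ and $e_{ij}$ are confounded: only their sum is identified.
  The fixed effects and their covariance — everything the effect sizes
  use — remain well defined; `lme4` resolves the variance split at a
  boundary and such boundary fits are treated as converged (only an
  optimizer failure flags non-convergence, so the unweighted fallback
  always exists). For the same reason, the residuals fed into the SD
  regressions are *cell-level* residuals $y_{ij} - \hat\mu_j - \hat a_i$
  (observation minus fixed effect minus participant BLUP), and the
  predicted values are $\hat\mu_j + \hat a_i$: conditional residuals
  including the cell-level intercept would be shrunk toward zero and the
  weighting machinery would see nothing.
* *SD floor.* The fitted SD line can go non-positive at the low end of
  the prediction range; SDs are floored at the larger of the 10th
  percentile of the absolute residuals and a small constant before
  inverting to weights.
* *Weight normalisation.* Weights are normalised to mean 1 and rounded
  to 12 significant digits, making the fit exactly invariant to any
  positive rescaling of the weights (only relative weights are
  meaningful).
* *Degenerate inputs.* Constant predicted values make the SD regression
  singular; the variance function then degrades to a constant SD.
  A nutrient with no variation at all (e.g. all-zero intakes) is
  reported as degenerate and skipped, without aborting other nutrients.
  An undefined Bland–Altman Spearman correlation (constant differences)
  is reported as 0 with an explicit flag.

## The synthetic study

The generator plays the role of the field study and fixes the
conditions everything is tested under. `generate_long()` draws directly
from the analysis model; its defaults encode a mother-like run: true
period means (1400, 1700, 1420) kcal — a systematic bias of roughly
−300 kcal for the test method against the recall period, near-zero
between test periods, matching the direction and order of magnitude the
method comparison is designed to detect (−150 kcal for the child
preset) — with $\sigma_p = 100$, $\sigma_{pp} = 50$ and residual SD
$50 + 0.1\,\mathrm{pred}$, a linear variance function so the weighting
machinery genuinely engages (a cubic option exists to exercise the
second iteration). The study scale is 148 households over three sites
with a 28% withdrawal rate (withdrawn households keep only their first
period), three periods of three nonconsecutive days including one
weekend day. Negative intake draws are truncated at zero and counted;
the config validator warns if a configuration implies more than 1%
truncation.

`generate_records()` emits a full record hierarchy — shared plates with
mixed participant/nonparticipant rosters, home recipes reused across
occasions, concordant and discordant analyst estimate pairs, leftovers,
occasional unconsumed servings, child-absent days, a training day — and
computes each participant-day's exact nutrient total analytically with
the same resolution rules the engine implements. Every analyst estimate
set in generated records resolves deterministically (the discordant
pairs carry a third-analyst decision), so this embedded truth is exact
and the engine can be held to agreement within 1e-9 relative error.
The method bias is carried by per-role, per-period portion scale
factors, so it propagates through servings, apportioning and the engine
rather than being painted onto outputs. Portion sizes and household
variation are lognormal with modest spreads chosen to give realistic
meal-to-meal variability at roughly the default energy scale.

What the generator does **not** emulate: real food-frequency patterns
or seasonality, misreporting behaviour, breastmilk, analyst
disagreement that stays unresolved (that path is exercised by
hand-built fixtures in the unit tests), or any image/voice processing —
portions enter as numbers. Passing tests therefore demonstrate that the
pipeline's arithmetic and inference behave as specified under the
declared generating model, not that any particular field dataset would
be free of bias.

### Problem sizes used in the checks

The statistical operating characteristics are verified by simulation at
n = 150 participants per replicate: confidence-interval coverage of the
three pairwise effects over 200 replicates (band 92–98%), type-I error
of the omnibus test under equal period means over 500 replicates (band
3–8%), and selection behaviour over 100 replicates (a weighted candidate
must win at least 80% of the time under strong heteroscedasticity,
SD = 10 + 0.3 pred, while under homoscedastic data all four candidates'
marginal means agree within 1%). The end-to-end engine identity is
checked at 30 households; the full pipeline example in the acceptance
script runs at the study scale of 148 households. These sizes are the
package's chosen verification conditions and keep the default test run
in the minutes range.

## Worked example

```{r, eval = FALSE}
library(sharedplate)

cfg <- run_config(out_dir = "study_run",
                  sim = sim_config(n_households = 148, seed = 1),
                  seed = 1,
                  nutrient_panels = list(mother = c("energy", "protein"),
                                         child = c("energy", "protein")))
res <- run_pipeline(cfg)
res$report$summary[, c("role", "nutrient", "p_value",
                       "diff_ivfr1_recall", "diff_ivfr2_recall",
                       "diff_ivfr1_ivfr2", "model")]
```

The summary has one row per role × nutrient, shaped like the classic
validity table: unadjusted per-period means and SDs, the omnibus
p-value, and the three pairwise differences of weighted marginal means
with their confidence bounds, plus which weighting candidate was
selected.

## Known limitations

* The even split weights children and adults identically when
  apportioning a shared plate; the record format does not carry
  age-specific consumption shares, and any other weighting would be an
  invention.
* Wald (normal) inference; no degrees-of-freedom correction for small
  samples.
* No multiplicity adjustment across nutrients — each nutrient's test
  stands alone, as is conventional for descriptive validity tables.
* The trend-statistic selection rule is a proxy for expert inspection of
  residual plots; with weak heteroscedasticity it can pick any of the
  four candidates, which is harmless precisely because the candidates
  then agree.
* Retention factors ship as a small illustrative table; real analyses
  should supply their own compilation.
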