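---
title: "Reproductive dynamics of a pelagic broadcast spawner: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproductive dynamics of a pelagic broadcast spawner: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pelagifec` implements the standard analysis chain for the reproductive
biology of a multiple-spawning pelagic fish with indeterminate annual
fecundity, built around South Pacific albacore tuna (*Thunnus alalunga*).
This vignette documents the models, the parameters that matter, the
synthetic-population generator used to validate every estimator, and the
design decisions taken where the methodology left genuine choices.

## The analysis chain

A sampling programme yields three tables: one fish per row (position, date,
fork length *FL* in cm, sex, gonad weight *GW* in g, optional whole weight
and age), a histology table with five categorical criteria per ovary, and
ovary-lobe subsamples for fecundity. The pipeline proceeds:

1. **Histological classification.** Each ovary is mapped by a deterministic
   decision table to one of eight development classes — immature (1),
   developing (2), spawning capable (3), spawning (4), regressing (5),
   regressed (6a, 6b) and regenerating (7) — from the most advanced group
   of oocytes (MAGO), postovulatory follicle (POF) stage, alpha/beta
   atresia, and maturity markers. Classes 3–7 are mature; 3–4 are active.
2. **Gonad index.** $GI = GW / FL^3 \times 10^4$, a size-standardised
   measure of gonad development; a screening aid only (histology is always
   authoritative), with females below $GI = 0.38$ uniformly immature and
   above $0.86$ uniformly mature in the data this pipeline targets.
3. **POF-method spawning fraction.** The daily spawning fraction $S$ of
   mature females is the proportion whose ovaries carry POFs of any stage
   younger than 24 h; the mean spawning interval is $1/S$ days. POFs
   resorb on a ~24-hour cycle, staged as new, <12 h, and 12–24 h.
4. **Gravimetric batch fecundity.** Per lobe,
   $\hat{B}_\text{lobe} = \frac{\text{count}}{\text{subsample weight}}
   \times \text{lobe weight}$, summed over the (one or two) available
   lobes. Relative batch fecundity is $B$ per gram of body weight.
5. **Model selection.** Each response (sex ratio, GI, oocyte diameter,
   proportion active, spawning fraction, batch fecundity) is modelled with
   additive fixed terms — factors, linear terms, or natural cubic splines
   of *FL*, age, month, latitude, longitude — plus a random fishing-set
   intercept, because fish from one gear deployment are not independent.
   Binomial-logit families for 0/1 responses, Gaussian otherwise.
   Candidates are ranked by the small-sample criterion
   $AIC_c = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}$ with Akaike weights
   $w_i \propto e^{-\Delta_i/2}$; models within $\Delta < 2$ of the best
   are treated as equally supported.
6. **Potential annual fecundity.** For an indeterminate spawner, monthly
   potential fecundity is $B_m \times S_m \times d_m$ (oocytes per batch
   times spawnings per day times days in month), summed over the year, and
   evaluated along a fork-length or age grid from the fitted surfaces.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Histology length threshold | 70 | cm FL | well below the ~80 cm minimum size at maturity; smaller females are reliably immature |
| Spawning latitude band | [-25, -10] | deg (negative south) | the band where active females occur; bounds inclusive |
| Peak spawning months | Oct–Dec | — | the austral spring/summer activity peak |
| GI screen thresholds | 0.38 / 0.86 | — | empirical all-immature / all-mature GI zones |
| POF "new" stage boundary | 4 | h | the staging literature does not quantify it; config constant, with the within-day stage ordering as the behavioural test |
| Spawning hour | 00:00 | local | spawning around midnight and the early morning hours |
| Length bin width | 5 | cm | the coarsest length-recording resolution in the data |
| Zone boundary | 25 | deg S | splits spawning-latitude from southern samples in class tallies |
| Days per month | calendar | d | see "Annual integrator" below; `fixed30` available |

## The annual integrator multiplies by days-in-month

The verbal description of annual fecundity — the product of batch fecundity
and spawning fraction in each month, summed across months — omits any time
unit. The spawning fraction is a *daily* rate, so summing twelve bare
products of batch size (~10^6) and fraction (≤ 0.75) could only reach
~10^6–10^7 eggs, while plausible annual outputs for this species are tens
to hundreds of millions. Multiplying by days in the month makes the units
coherent (spawnings per month × oocytes per spawning) and lands in the
right range: ~1.2 million oocytes per batch at a fraction of ~0.45
sustained over a year gives ~2×10^8. The integrator therefore uses
days-per-month by default, switchable to a fixed 30-day month
(`days_per_month = "fixed30"`) for sensitivity analyses.

## Decision-table edge cases

* **POF precedence.** Any POF stage forces class 4 regardless of atresia:
  a POF is direct evidence of a spawning event within the last day.
* **Hydrated or migratory-nucleus MAGO without POFs** is class 4 (spawning
  imminent) only while alpha atresia is below 50%; with ≥50% atresia the
  combination lies outside the decision table and is returned as
  `unclassifiable`, logged, and excluded from downstream proportions.
* **Advanced-yolked MAGO with ≥50% alpha atresia** is class 5 on the alpha
  criterion alone; the canonical table lists beta atresia as present in
  that row, but its absence does not block the class (the alpha level is
  the operative criterion).
* **Maturity markers** never exclude a class; they decide only between
  regenerating (7) and immature/developing (1/2).
* Class 2 (developing) is reported but treated as immature downstream.

Totality is tested over the full 5×4×4×2×2 = 320 criteria grid: every cell
yields a class or `unclassifiable`, never an error.

## The synthetic population

The generator emulates the statistical structure the analysis assumes, so
that every estimator can be validated against known truth:

* **Set-clustered sampling**: ~350 fishing sets of ~10 fish across ten
  regions with realistic latitude/longitude boxes and region weights
  (~3500 fish, matching the scale of the real sampling programme);
  sets south of 30°S sample juvenile grounds.
* **Sex and length**: length first (region-dependent), then sex with a
  length-dependent probability of being male, giving female-biased small
  fish and male-biased fish above ~95 cm.
* **Maturity**: logistic in length, L50 = 87 cm, slope 0.4 logit/cm.
* **Spawning dynamics**: monthly daily-spawning-fraction targets for
  mature females in the 10–25°S band (0.75 in Oct–Dec, ~0.05 in the
  austral winter), with a length effect (+0.06 logit/cm) and a set-level
  random intercept (SD 0.5) on the logit scale. The baseline logit of each
  month is calibrated by root finding so the *marginal* fraction over the
  realized pool equals the target exactly; recovery tests can therefore
  use plain binomial error bands.
* **Histology in reverse**: each fish's latent state (immature / active /
  spawned-within-24 h / regressing / regenerating) is converted to
  criteria by running the decision table backwards; on noiseless data the
  classifier is its exact inverse, which is tested. An optional
  `mis_rate` flips criteria at random to exercise robustness.
* **POF clock**: spawned fish get hours-since-midnight from their capture
  time and the POF stage the degeneration clock implies; MAGO progresses
  through the day (advanced yolked by day, migratory nucleus in the
  afternoon, hydrated at night).
* **Fecundity**: relative batch fecundity is normal with mean 64.4 and SD
  24.7 oocytes/g, truncated at zero; batch = relative fecundity × body
  weight from a length–weight power law; lobe subsamples are generated
  with Poisson counts at the ovary's oocyte density, so the gravimetric
  estimator is unbiased for the latent batch.
* **Ages** are assigned to a ~500-female subset (emulating partial otolith
  reading) via an inverted growth curve plus noise.

What it does **not** emulate: oceanographic realism (SST is a smooth
latitude/season function), reader disagreement in histology (beyond the
optional flip noise), gear selectivity by length, movement between months,
or fish-level persistent spawning heterogeneity. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
sampling structure — not robustness to every field complication.

## Numerical choices

* Splines are natural cubic bases (`splines::ns`) of the stated dimension
  with interior knots at quantiles of the observed values; knots are
  carried with each fit so prediction grids re-use the training basis.
  Month enters as a non-cyclic spline; a cyclic basis would be defensible
  but is not the default.
* Mixed models are fitted by maximum likelihood (never REML, so that
  AICc values are comparable across fixed-effect structures): `lme4::lmer`
  for Gaussian responses, `lme4::glmer` (Laplace approximation) for
  binomial ones, degenerating to `lm`/`glm` without a random term.
* The parameter count $k$ is the fitted degrees of freedom: fixed
  coefficients, plus one variance component per random term, plus the
  residual variance for Gaussian models.
* Predictions are population-level (random intercept at zero), inverse
  linked for binomial fits; grid points outside the training range are
  flagged as extrapolation; predicted batch sizes are floored at zero
  before integration.
* Intervals are rounded to one decimal place only at the reporting layer;
  internal values keep full precision.
* Degenerate inputs fail loudly: empty mature-female strata, zero spawning
  fraction (interval undefined, reported not thrown), constant spline
  inputs, $n \le k+1$ in AICc, mismatched month schedules.

## Problem sizes

The bundled analysis scripts and tests use a ~3500-fish default population;
parameter-recovery checks use ~5000 fish (500 sets), 200 × 10 clustered
Gaussian observations for variance-component recovery, and 50 simulation
replicates of n = 2000 for the model-form selection frequency. These sizes
give binomial/sampling errors comfortably inside the tested tolerances
while keeping a full run in minutes on one core.

## Known limitations

* The spawning-fraction denominator is mature females *sampled*; if
  availability varies with reproductive state within the band, the POF
  method inherits that bias (as in the field method).
* Annual fecundity extrapolates the fitted monthly surfaces to all twelve
  months; months with little fecundity sampling contribute little (the
  predicted fraction is near zero there), but the batch surface in those
  months is model-based, not observed.
* Binomial mixed models use the Laplace approximation; with very few fish
  per set its likelihood (hence AICc) is approximate.
* The GI screen thresholds and the 24-h POF window are taken as fixed
  biology, not re-estimated.

## A worked example

```{r example}
library(pelagifec)

fx <- fixture_small()
cls <- classify_histology(fx$histology)
d <- join_records(fx$samples, cls, fx$subsamples)

# POF method on a table where 9 of 20 mature females carry POFs
est <- spawning_fraction(tibble::tibble(
  sex = "female", mature = TRUE, latitude = -15, month = 11,
  pof_stage = rep(c("lt12h", "absent"), c(9, 11))))
est$fraction        # 0.45
est$interval_days   # 2.22 -> reported 2.2 days

# gravimetric batch fecundity, by hand: 120/0.06*300 + 100/0.05*250
batch_fecundity(fx$subsamples[fx$subsamples$fish_id == "A12", ])

# the full simulated workflow
bundle <- run_all(default_run_config())
bundle$spawning$peak
```
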