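---
title: "Analysing peripheral-nerve extracellular flux data with nerveflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing peripheral-nerve extracellular flux data with nerveflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerveflux)
library(dplyr)
```

## The assay and its model

Plate-based extracellular flux analysis records the oxygen consumption rate
(OCR, pmol O~2~/min) and extracellular acidification rate (ECAR, mpH/min) of
small tissue fragments — here 1.5 mm sciatic-nerve segments — while a fixed
sequence of mitochondrial effectors is injected. The canonical "mitostress"
schedule takes five basal readings at 6-minute intervals, then eight readings
after each of:

* **oligomycin A (Omy, 5 µM)** — blocks ATP synthase, so OCR falls to the
  proton-leak level;
* **FCCP (2.5 µM)** — uncouples the inner membrane, driving OCR to the
  maximal electron-transport capacity;
* **rotenone + antimycin A (Rot/AA, 5 µM each)** — block complexes I and
  III, leaving only non-mitochondrial oxygen consumption.

`injection_schedule()` encodes this design (29 readings by default) and
`phase_windows()` maps each phase to its inclusive 1-based reading range.
From one trace the seven classical parameters are extracted by
`compute_mitostress()`:

| parameter | definition |
|---|---|
| non-mitochondrial respiration (NMR) | minimum OCR over the Rot/AA window |
| basal respiration | last pre-Omy OCR − NMR |
| ATP-linked respiration | last pre-Omy OCR − minimum post-Omy OCR |
| proton leak | minimum post-Omy OCR − NMR |
| maximal respiration | maximum post-FCCP OCR − NMR |
| spare capacity (%) | 100 × maximal / basal |
| coupling efficiency (%) | 100 × ATP-linked / basal |

Two readings of these definitions were genuinely open and are resolved as
follows. "Last OCR before injection with Omy" is taken literally as the
single reading at index `n_basal` (the fifth), not a basal mean; a basal
mean would change every downstream level, and the single-reading form keeps
the energy-map coordinates and the basal metric consistent. Extrema are
searched over the *full* eight-reading window with no readings discarded
for mixing time, because the protocol records exactly eight readings per
phase and gives no discard rule. `ATP + leak = basal` holds exactly by
construction; both percentage metrics are undefined (returned missing, with
a reason) when basal ≤ 0. A missing reading inside a window makes the
metrics that need that window missing — traces are excluded, never repaired.

## Quality control

The study screened each trace visually for "an appropriate inhibitor
response". `qc_rules()` quantifies that screen with four configurable
checks on the raw (pre-adjustment) trace:

* `min(post-Omy)/last-basal ≤ 0.9` — OCR must actually fall after Omy;
* `max(post-FCCP)/min(post-Omy) ≥ 1.2` — FCCP must rescue OCR;
* `min(post-Rot/AA)/max(post-FCCP) ≤ 0.9` — Rot/AA must suppress it again;
* last-basal OCR ≥ 5 pmol O~2~/min — an absolute signal floor.

The three ratio checks make the decision invariant under rescaling of a
trace; only the absolute floor is scale-dependent. QC runs **before**
baseline adjustment so that the adjustment can never induce or mask an
exclusion, and Rot/AA-pretreated negative-control wells are exempt — their
whole purpose is to lack an inhibitor response. Failing wells stay in the
data, flagged, so reports can show what was excluded and why.

## Baseline adjustment

"Baseline-adjusted for each experimental group" is not defined
operationally in the assay software's terms, so `baseline_adjust()` offers
three modes and defaults to `group_offset`: within each group, every well's
trace is shifted additively so its last-basal reading equals the group mean
of last-basal readings. This choice keeps metrics in pmol O~2~/min (the
units the study reports), preserves the group's pointwise mean trace
exactly, and leaves all within-well differences — hence basal, ATP-linked,
leak, maximal, spare and coupling — unchanged. Two caveats are worth
stating plainly:

* NMR is a *level*, not a difference, so the per-well offset shifts it;
  only its group mean is preserved (offsets sum to zero within a group).
* Negative-control wells are adjusted as their own stratum, pooled across
  animals: their floor-level baselines would otherwise drag the offset
  computed for standard wells.

A `percent` mode (each well divided by its own last-basal × 100) is kept
for users who prefer Wave-style relative traces, and `none` for raw
analysis.

## MEF normalization

Because mitochondrial abundance can differ between lean and diabetic
nerves, flux is normalized to mitochondrial protein content rather than
total protein or tissue mass. From triplicate label-free proteomics per
animal, `compute_mef()` forms the **mitochondrial enrichment factor**: the
summed abundance of proteins in a mitochondrial annotation (a MitoCarta
3.0-style ID list) over total protein abundance, per sample, averaged over
an animal's replicates. The MEF is dimensionless, lies in [0, 1], and is
invariant under global rescaling of a sample — intensity units cancel.

`normalize_run()` applies per-animal factors. The default mode,
`relative_mef`, divides each animal's readings by `MEF / geometric-mean
MEF` of the cohort; the geometric mean makes the correction symmetric in
log space and leaves the cohort's geometric-mean basal OCR unchanged, so
adjusted rates stay in pmol O~2~/min at their familiar magnitude.
`absolute_mef` (divide by MEF itself) is available for rates per unit
mitochondrial-protein fraction, as are `total_protein` and `cs_activity`
divisors for laboratories without proteomics. Every mode is a per-well
positive scalar, so spare capacity, coupling efficiency and all
reference-based toxicity metrics are invariant under it. Factors are
per-animal, not per-well: the proteomics derive from a separate nerve
fragment, so fragment-level factors do not exist.

The pipeline order is fixed as **QC → baseline adjustment → normalization →
reference lines → metrics**. A consequence worth knowing: group-offset
alignment makes every included well's last-basal reading identical within
its group, and the subsequent per-animal division re-disperses those
levels. That residual dispersion is exactly what the basal z-score (below)
standardizes against; run with `norm_mode = "none"` there is no dispersion
and z-scores are reported missing with a warning.

## Reference lines and toxicity metrics

`build_reference_line()` averages baseline-adjusted, normalized traces
pointwise. The **positive** line comes from the standard wells of a
designated reference group (the lean control strain in the motivating
study; the label is a parameter, never hard-coded); the **negative** line
from the Rot/AA-pretreated wells of *all* animals, representing complete
inhibition. On top of these, `compute_mitotox()` scores every test well:

* `MTI_F = (test max FCCP − pos max FCCP) / (pos max FCCP − neg min FCCP)`
  — 0 at the positive maximum, −1 at the negative floor;
* `MTI_U = (test max of last-6 Omy readings − pos min Omy) /
  (pos max FCCP − pos min Omy)` — 0 fully coupled, 1 fully uncoupled;
* `z_basal`, `z_fccp` — the test well's last-basal reading (respectively
  FCCP-window maximum) standardized against the positive members.

Window extrema of the reference lines are taken on the **mean trace**
(literal reading of the definitions). The z-score reference statistics
cannot come from the averaged line — a mean trace has no across-sample SD
at a reading — so they are computed **across the positive member wells**
(per-well last-basal and FCCP-maximum distributions). This makes the
members' own z-scores average to exactly zero; the original study's
control-group z-means are slightly nonzero, which suggests a reference
subset that cannot be identified from the text, and no attempt is made to
match those values numerically.

## Statistics

Animals, not wells, are the statistical unit: `aggregate_by_animal()` pools
left- and right-nerve fragments by an arithmetic mean over included
standard wells (a side-stratified variant supports the left-vs-right
equivalence check). `compare_groups()` runs the unpaired two-tailed
Student's (pooled-variance) t-test per metric — Welch is one flag away —
and reports means ± SD across animals with significance tiers at
0.05/0.01/0.001. For the 2 × 2 genotype-by-week phenotype design
(`compare_two_factor()`), a two-way ANOVA is followed by Šídák-adjusted
simple-effect comparisons, one family of four. Hyperglycemia is classified
as random-fed blood glucose strictly above 16.7 mM (the murine renal
threshold), with values at the 33.3 mM meter ceiling flagged as censored.

## The synthetic-data generator

`simulate_plate()` exists so every stage can be validated against known
ground truth. Its model and defaults:

* **Kinetics.** Each well follows a piecewise exponential approach between
  phase plateaus `B, O, F, R`: within a phase with plateau `P` and entry
  level `L0`, the t-th reading sits at `P + (L0 − P)·exp(−τt)`. Defaults
  `B = 50.1, O = 35.5, F = 93.0, R = 18.7` pmol O~2~/min reproduce
  published 1.5 mm-fragment metrics (basal 31.4, ATP-linked 14.6, maximal
  74.3, NMR 18.7); basal ECAR defaults to 31.5 mpH/min. `τ = 1.0` per
  reading puts window extrema late in each eight-reading window, as in
  real traces. Plateaus are attained to relative accuracy
  `exp(−8τ)·span/level`; analyses that require attainment to 10⁻⁶ (e.g.
  the noise-free oracle comparison) use `τ = 3`, for which the residual is
  ~10⁻¹⁰.
* **Disease effect.** A genotype deficit multiplies the *above-floor*
  components `B − R`, `O − R`, `F − R` (and basal ECAR) by a common factor,
  default 0.85, leaving `R` fixed. This scales basal, ATP-linked, leak and
  maximal respiration by the factor while leaving spare capacity and
  coupling efficiency exactly unchanged — the published diabetic signature
  (group ratios ≈ 0.81–0.88 with identical spare capacity). A naive factor
  on the raw plateaus with `R` fixed would shift spare and coupling by
  6–10% and was rejected for that reason.
* **Between-animal variation.** One lognormal scale factor per animal
  (CV 0.10, matching across-animal SDs of ~10% in the published group
  means) multiplies all plateaus, so dimensionless metrics stay constant
  within a group. The factor also includes `MEF/mean-MEF`, coupling each
  animal's flux scale to its mitochondrial content (MEF ~ N(0.10, 0.02));
  MEF normalization then genuinely removes a real source of variance,
  which is visible as a large power gain in the group test.
* **Noise.** Every reading is multiplied by `1 + ε`, `ε ~ N(0, CV)` with
  CV 0.05: OCR spans roughly 10–90 pmol/min across phases and variability
  scales with signal, so multiplicative noise is the realistic choice. The
  underlying study publishes no noise model; these are stated assumptions.
* **Controls and failures.** One well per animal (the last fragment
  position) is the Rot/AA-pretreated negative control, pinned at `R` for
  all phases including basal. With probability `nonresponder_prob` a
  standard well ignores all injections (flat at `B`) to exercise QC; the
  default is 0, as the study excluded such wells rather than modelling
  them.
* **Phenotypes.** Blood glucose and body weight at weeks 6 and 15 are drawn
  from the published group means/SDs (glucose censored at the 33.3 mM
  meter limit). Week-15 body weights are not printed in the source; 26 g
  (lean) and 48 g (diabetic) are typical for these strains at that age.
* **Proteomics.** Per animal, three replicate samples of lognormal
  abundances over 200 protein IDs (20% annotated mitochondrial), with the
  mitochondrial block rescaled so the realized abundance share equals the
  drawn MEF exactly — MEF recovery is exact by construction, which is what
  makes it usable as an oracle.

What the generator does **not** emulate: instrument drift, plate-edge
effects, O~2~ diffusion physics, correlated noise between neighbouring
readings, and fragment-to-fragment heterogeneity within an animal beyond
independent reading noise. Passing tests on synthetic plates therefore
validate the *arithmetic and plumbing* of the pipeline, not robustness to
every failure mode of real instruments.

## Known numerical properties and limitations

* **Extremum-selection bias.** The classical metrics are minima/maxima over
  eight noisy readings. The minimum of several near-plateau readings under
  multiplicative noise is biased low (≈ −1.2 noise-SD), the maximum biased
  high, so basal, ATP-linked and maximal respiration are systematically
  overestimated relative to the true plateaus — at 5% reading noise and
  study-scale kinetics by roughly +3%, +15% and +8% respectively. This is
  a property of the published definitions, not of this implementation; it
  cancels in *between-group comparisons* (both groups share it nearly
  proportionally) and vanishes as noise → 0, but it means extremum metrics
  should not be read as unbiased plateau estimates. The acceptance suite
  keeps a strict plateau-recovery check in place, which documents this
  bias by failing; the dimensionless and differential contrasts are
  unaffected.
* **NMR under group-offset adjustment** shifts per well (group mean
  preserved), as discussed above.
* **z-scores need dispersion.** After group-offset alignment, basal
  dispersion across positive members exists only if some per-animal
  normalization follows; otherwise z-scores are reported missing.
* **Validation problem sizes.** The test suite uses cohorts of 2 groups ×
  4–6 animals × 10 wells for pipeline checks, 100 simulation seeds for
  recovery, 500 seeds for null calibration of the basal t-test (rejection
  rate 5% ± 2%), and 50 seeds for the directional disease-signature check;
  the full study scale (12 animals per group) is exercised by the
  acceptance script and the power check.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1) # two groups x 12 animals, study design
study <- simulate_study(cfg)

mef <- compute_mef(study$proteomics$abundance, study$proteomics$annotation)
res <- run_pipeline(study$plate,
                    factors = normalization_factors(mef),
                    positive_group = "BKS",
                    phenotypes = study$phenotypes)
res$comparisons # animal-level Student t per metric
build_report(res, "nerveflux_report")
plot_traces(res$plate)
plot_energy_map(res$animal_summaries)
```

Equivalent shell entry points (`simulate`, `qc`, `run-all`) live in
`inst/cli/nerveflux.R`.
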