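---
title: "Methods: quantitative analysis of ribosome-biogenesis RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of ribosome-biogenesis RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribohcs)
```

## The assay and its quantities

The screens this package analyzes follow newly made ribosomal subunits
through the cell. An inducible fluorescent ribosomal-protein reporter
(Rps2-YFP for the 40S pathway, Rpl29-GFP for 60S) or immunofluorescence
against a biogenesis factor (Enp1, Rio2) is imaged together with a DNA
stain in 96-well plates, three siRNAs per target gene, with three
negative-control wells (non-targeting siRNA) and three positive-control
wells (Crm1/exportin-1 siRNA, a strong nuclear-export block) on every
plate. In unperturbed cells the reporter is overwhelmingly cytoplasmic;
knockdowns that block biogenesis shift it to the nucleolus (early,
intranucleolar defects) or the nucleoplasm (late nuclear defects such as
export blocks).

Each readout has a fixed per-cell phenotype taxonomy
(`readout_classes()`), e.g. for Rps2-YFP: cytoplasmic, nucleoplasmic,
nucleolar, no-reporter, mitotic, debris. The pipeline turns classified
cells into screen-level calls through a small set of quantities:

* **Hit rate** — per well, the fraction of *reporter-positive interphase*
  cells carrying a defect phenotype. Mitotic cells, debris, and
  reporter-negative cells never enter the denominator. For Rps2-YFP the
  defect ("hit") classes are nucleolar *plus* nucleoplasmic — overall
  nuclear accumulation; for Rpl29-GFP, nuclear restriction; for nuclear
  Enp1, nucleoplasmic accumulation. A well with an empty denominator
  reports rate 0 and a flag, and a warning is raised.
* **Rank** — hit rates are not comparable across plates (staining,
  transfection efficiency), so each well is rescaled between its own
  plate's control levels: $rank = (h - h_{neg})/(h_{pos} - h_{neg})$,
  where $h_{neg}$ and $h_{pos}$ are the means of the *two highest* of the
  three negative and positive controls. Taking the two highest of three
  tolerates one failed control well. Ranks are deliberately not clipped
  to $[0,1]$. A plate whose positive level does not exceed its negative
  level is a failed plate: its sample wells are quarantined (no rank),
  not fatal to the run.
* **Candidate filter** — a target needs at least two siRNAs each with a
  hit rate *strictly* greater than twice the negative-control level of
  its own plate. This is the screen's defense against single-siRNA
  off-target effects.
* **Target rank and cutoff** — the mean of the two highest siRNA ranks
  (ties broken by rank, then hit rate, then siRNA id — a stable,
  documented order). High-confidence hits are candidates whose target
  rank strictly exceeds the readout cutoff: 0.2 (Rps2-YFP), 0.3
  (Enp1 IF), 0.25 (Rpl29-GFP).
* **Stage score** — for Rps2-YFP wells, the nucleoplasmic fraction of
  nuclear-phenotype cells, $np/(np + no)$: 0 means purely nucleolar
  accumulation (early defect), 1 purely nucleoplasmic (late defect). Per
  target, the score averages the ratios of the two siRNAs with the
  *highest hit rates* (selection by hit rate, not by rank — the two
  selections answer different questions, and a config switch in
  `target_stage_score()` vs the hit-calling path keeps both available);
  the absolute difference between the two ratios is reported as a
  quality measure. Wells without nuclear-phenotype cells have no defined
  ratio; these propagate as missing values, never as 0.
* **Cytoplasmic Enp1 and Rio2 (+LMB) calls** — there is no positive
  control that drives Enp1 or Rio2 into the cytoplasm, so these readouts
  cannot be rank-normalized. Absolute rates are used: the target
  statistic is the mean of the two highest per-siRNA rates, called
  against a strict threshold (default 0.2 for both; for cytoplasmic Enp1
  this threshold is an interpretation aligned with the analogous 20%
  rule of the Rio2 readout, and is configurable). Single-siRNA Rio2
  support is flagged rather than silently accepted.
* **Grouping** — targets scored in all three 40S readouts are sorted
  into a nuclear/cytoplasmic requirement taxonomy (`rps_grouping()`);
  the precedence is: cytoplasmic Enp1 + Rio2 → `cytoplasmic_both`
  (regardless of Rps2), then nuclear Rps2 + Rio2 → `mixed`, then
  Rps2 + nuclear Enp1 → `nuclear_both`, then single-readout groups.

All inequality comparisons in the calling rules (2× filter, rank
cutoffs, the 20% Rio2 rule, the growth threshold) are *strict*; wells or
targets exactly at a boundary do not pass, except the growth filter
where a well exactly at the threshold is retained (the rule excludes
wells strictly below it).

## Imaging: segmentation and the 30-feature vector

Nuclei are segmented from the DNA channel: Gaussian smoothing
(`smooth_sigma`, default 1 px — matched to the pixel-scale shot noise;
heavier smoothing systematically inflates masks), Otsu thresholding on
log intensity (robust when the background dominates the histogram) with
a configurable additive offset, hole filling, a distance-transform
watershed to split touching nuclei, and area bounds (default 30–2500
px²) to discard fragments and clumps. Labels are consecutive positive
integers, 0 is background, coordinates are pixel-centered with origin
top-left. Each nucleus then receives a cytoplasmic annulus (default
width 5 px at the simulated scale) truncated by Voronoi propagation
where neighbors collide, so annuli are disjoint from each other and from
all nuclei by construction.

The per-cell feature vector is fixed and versioned (`feature_names()`,
30 features): reporter intensity statistics in both compartments
(mean/median/integrated/SD, nuclear-to-cytoplasmic ratio), DNA-channel
mean and integrated intensity, nucleus morphology (area, perimeter,
eccentricity, solidity, extent, axes, form factor), five gray-level
co-occurrence texture measures of the nuclear reporter signal (contrast,
correlation, energy, homogeneity, entropy; 8 levels quantized over each
nucleus's own intensity range, so texture is invariant to linear
intensity scaling), the radial distribution of reporter over four
concentric depth rings (ring 1 innermost — nucleoli live there),
granularity at two structuring-element scales, the annulus area, and a
bright-speckle count. The exact composition is this package's design;
feature *categories* (intensity, morphology, texture) follow standard
high-content practice, and the fixed order is part of the schema so that
trained models detect mismatched inputs.

## The classifier

Phenotype classification uses a probability random forest (200 trees,
single-threaded, seeded — deterministic and serializable) over the
30-feature schema. Forests need no feature scaling, handle the mixed
feature types well, and produce usable class probabilities; the
algorithm of the original screen software is not published, so the model
family here is the package's own choice, fixed by configuration.
Predicted probabilities are renormalized to sum to 1; the predicted
class is the argmax with exact ties broken toward the earliest class in
the canonical readout order. Evaluation is stratified k-fold
cross-validation (default 5 folds, seeded assignment); the confusion
matrix aggregates held-out predictions only, and per-class one-vs-rest
ROC areas are computed from held-out probabilities, with 0.9 as the
conventional bar for an excellent per-class ranking. Mitotic and debris
classes are predicted like any other class and then used to exclude
cells from interphase denominators.

## The synthetic-data generator

The study's raw images are not redistributable, so validation runs on
synthetic screens with exported ground truth, at two fidelities:

* **Feature level** (fast): per well, a cell count is drawn from a
  negative binomial (mean = seeded density × growth multiplier,
  dispersion configurable, default size 10 — overdispersion is the norm
  in well-to-well counts); each cell's true class from the well's
  phenotype mix; optionally a feature vector from a per-class Gaussian
  model. The default class-mean geometry places classes at a chosen
  pairwise Mahalanobis separation (`default_feature_model()`).
* **Image level**: elliptical nuclei placed without overlap (touching
  pairs at a configurable rate, to exercise the watershed), nucleolar
  subregions in the inner half of each interphase nucleus, class-specific
  reporter placement (nucleolar concentration at a configured contrast
  factor, uniform nucleoplasmic fill, perinuclear ring, background-only),
  mitotic cells as small bright condensed-DNA objects, debris as dim
  fragments; Poisson shot noise plus Gaussian read noise on the 16-bit
  scale. Output is self-describing: multi-page TIFFs
  (`{plate}_{well}.tif`, page 1 DNA, page 2 reporter), a ground-truth
  CSV, a layout YAML and a JSON manifest.

Defaults emulate the screen design: 96-well plates, 3 + 3 controls,
3 siRNAs per target; baseline mix 0.90 cytoplasmic / 0.02 nucleoplasmic
/ 0.02 nucleolar / 0.03 no-reporter / 0.02 mitotic / 0.01 debris;
positive-control wells receive a Crm1-like nucleoplasmic-dominant mix
with a 0.8 growth multiplier. The assay's seeding densities are
1,250–1,750 cells per well; the number of cells actually imaged per well
after 72 h of RNAi is not knowable from the published record, so
`cells_per_well_mean` defaults to 1500 and is configuration, not a
claim. Validation screens in the test suite and acceptance script use
200–400 cells per well and 1–5 plates — sizes at which the binomial
noise of per-well fractions is far below every planted effect, so the
conclusions do not depend on the larger default.

Everything is a pure function of (configuration, seed): identical seeds
give bit-identical images, tables and hit lists.

What the generator does *not* emulate: optical point-spread functions,
illumination gradients, multi-field stitching, cell-cycle structure,
segmentation-adversarial morphologies, or correlated (off-target) siRNA
effects. Passing on synthetic data therefore demonstrates that the
statistics, rules and plumbing are correct and that segmentation and
classification work on well-behaved fields — not that the imaging stack
matches the original screen's images, whose exact feature definitions
and parameters are unpublished.

## Design choices on points the published record leaves open

* **Growth exclusion**: siRNAs with strong growth defects are excluded
  before ranking, but no threshold is published; the default is relative
  cell number < 0.3, configurable and logged per exclusion. The filter
  is applied per well (per siRNA); control wells are never excluded.
* **The 2× filter's negative-control summary**: taken as the same
  two-highest-negatives mean used for ranking (one consistent control
  level per plate); `neg_summary = "mean3"` switches to the mean of all
  three.
* **The 30th feature**: the feature list is anchored on the published
  categories; integrated DNA intensity completes it (a natural
  discriminator for mitotic cells).
* **Targets with two siRNAs** are scored from both; targets with fewer
  than two usable siRNAs after exclusion are "not evaluable", never
  "not hit".
* **Weak-phenotype annotation** (single siRNA at ≥ 7× the negative
  level) is an optional flag (`n_over_2x` and per-siRNA rates are
  reported for downstream annotation), not a call.

## Numerical conventions

Probability vectors must sum to 1 within 1e-9; covariance matrices must
be positive definite (checked by eigenvalue). Missing values (undefined
stage ratios, unranked wells of failed plates) propagate as `NA` and are
written to CSV as empty fields, never 0. Tables are UTF-8 CSV with "."
decimals and full-precision floats, so every writer round-trips through
its reader losslessly. All thresholds used by any call are recorded in
the JSON run manifest.

## Validation strategy

The test suite checks the calling rules against an independent
straight-line brute-force re-implementation on 1,000 randomized plates
(exact agreement), recovers planted hits (recall 1, false positives 0)
on 5-plate / 80-target / 10-planted-hit screens across 10 seeds,
separates planted nucleolar-defect from nucleoplasmic-defect targets at
the 0.5 stage-score threshold with zero overlap, verifies per-class ROC
areas above 0.9 at Mahalanobis class separation 4, and recovers ≥ 95% of
planted nuclei at Jaccard ≥ 0.8 on a 20-image rendered set. The
calling-rule replay on externally supplied per-well tables (the
published supplementary column layout) is validated on synthetic tables
written in that layout; replaying the actual published tables requires
those files, which are not redistributed with the package.

## Known limitations

Segmentation parameters are tuned to the generator's scale (20×-like,
nuclei ~10 px radius) and would need rescaling for other magnifications.
The classifier is only as good as its training annotations; the package
provides no annotation tooling. Hit calling is cutoff-based by design —
no p-values or multiple-testing control are computed, matching the
screen's decision rules rather than augmenting them.
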