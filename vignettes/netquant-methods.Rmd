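---
title: "Quantifying NETs in equine BALF: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NETs in equine BALF: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscope)
```

## The problem

Neutrophil extracellular traps (NETs) are webs of decondensed chromatin
expelled by activated neutrophils, carrying granule proteins such as
myeloperoxidase (MPO) and the chromatin-decondensation marker citrullinated
histone 3 (Cit-H3). In equine asthma, NETs in bronchoalveolar lavage fluid
(BALF) are a candidate marker separating the severe phenotype (labored
breathing at rest, high mucus scores, BALF neutrophilia above 20%) from the
moderate one. `netscope` packages the three complementary quantification
routes — fluorescence colocalization area on cytospins, cell-free DNA
(cf DNA) by intercalating dye, MPO-DNA complexes by ELISA — together with
the clinical classification rules and the statistics layer that turns
per-subject readouts into group comparisons, severity correlations and
ROC-based predictivity.

## Clinical classification

A BALF differential cytology (percent of total nucleated cells over five
populations, counted on 300 cells so values land on halves) flags asthma
when **any** granulocytic population is elevated: neutrophils > 5%,
eosinophils > 1% or mast cells > 2%. All cutoffs are strict — a horse at
exactly 5% neutrophils is not asthmatic by cytology. Among asthmatic
horses, *severe* requires labored breathing at rest, abnormal lung
auscultation (crackles, wheezes or increased lung sounds — curated to a
boolean, since source records are free text) or BALF neutrophilia > 20%;
everything else is *moderate*, and moderate cases split at 5% BALF
neutrophils into `neu_lo`/`neu_hi` (exactly 5 goes to `neu_hi`; the
published definitions use "< 5%" and "> 5%" and leave the boundary
unassigned, and no real record sits on it).

Enrollment labels can disagree with the cytology rule: two packaged healthy
controls run 5.5% and 8% neutrophils. `classify_cohort()` keeps an explicit
label and surfaces the disagreement as a warning rather than silently
reclassifying — the enrolling clinician saw information (history, repeat
lavages) the table does not carry. The pure rule is always available as
`classify_phenotype()`.

## Image-based NETs-area scoring

The quantification mirrors a simple, auditable script: binarize the green
(MPO) and red (Cit-H3) channels, intersect, measure.

* **Thresholding** is strict (`intensity > t`). The original thresholds
  were set manually per batch; the package accepts explicit numbers and
  offers Otsu's histogram split (256 bins, maximizing between-class
  variance) as a reproducible default. Otsu presumes a bimodal histogram:
  on a signal-free channel (negative controls) it will binarize noise, so
  manual cutoffs are the right choice there. This is a real limitation of
  automatic thresholding, not of the implementation.
* **Colocalization** is the pixelwise AND of the two masks. DAPI is
  deliberately **not** intersected: requiring the triple overlap suppresses
  genuine filamentous NETs (extracellular DNA stains weakly) while adding
  false positives near nuclei. An optional minimum object size
  (8-connectivity) exists but defaults to 0, since the original script
  applied no size filter.
* **Cell counting** takes 8-connected components of the binarized DAPI
  plane with area ≥ 30 px (a 20x-like floor that rejects debris). Touching
  nuclei are *not* declumped — the procedure counts objects, and the
  synthetic generator places non-touching nuclei so recovery tests can be
  exact.
* **Neutrophil identification**: a nucleus is MPO-positive when ≥ 10% of
  its footprint, dilated by 3 px to reach the cytoplasm, falls in the MPO
  mask. The 10%/3 px defaults are generous on purpose: a crisp cytoplasmic
  ring easily exceeds them, background does not.
* **Normalization**: colocalization area divided by cell count, or by
  neutrophil count; per-subject values are arithmetic means over fields
  (six per slide typically; any ≥ 1 accepted). A field with zero cells
  reports 0 for both normalized values (a blank field is evidence of
  absence, and a warning is raised if colocalization signal was present);
  positive area with zero detected neutrophils yields a *missing*
  per-neutrophil value — never an infinity — excluded from the subject
  mean. Areas are px² unless a pixel size is supplied (µm²); the area unit
  of the published figures is unstated, so both conventions are supported.

## Assay quantification

cf DNA uses a **linear** standard curve (OLS of readout on concentration)
over the 2-fold series 0.4 → 0.003125 µg/ml — eight points, derived from
the printed endpoints and configurable. The dye response is linear in this
range; a four-parameter logistic adds nothing but variance here. r² < 0.98
warns. Unknowns are inverted through the line; estimates outside the
calibrated span are returned but flagged, not clipped. When a plate carries
blank wells their mean is subtracted from standards and samples before
fitting (whether the original workflow blank-subtracted is unstated; the
choice is logged).

MPO-DNA ELISA values stay in OD units — no absolute calibrant exists — with
mean-blank subtraction floored at zero. The DNase-titration helper encodes
the plateau logic used to pick the digestion activity: OD rises with
activity (epitope accessibility), plateaus, then collapses as the complexes
degrade; the rule returns the lowest activity within 5% (relative,
configurable) of the maximum OD, which lands on 125 UI for the published
titration shape.

## Statistics

Every group is tested with Shapiro-Wilk at α = 0.05; parametric tests are
used only when **all** groups pass (per-group testing is the stricter and
more common reading; pooled testing is not stated anywhere). Two groups:
Student t (equal variances, as "unpaired Student t-test" implies) or
Mann-Whitney. More: one-way ANOVA with Tukey HSD, or Kruskal-Wallis with
Dunn pairwise z-tests (tie-corrected, Bonferroni-adjusted — the
multiple-testing rule is unstated, and Bonferroni is the conservative
default). The phrase "ANOVA with Kruskal-Wallis post hoc" in the source is
internally inconsistent and is implemented as Kruskal-Wallis + Dunn, with
the dispatched test recorded in every result. Stars follow *, P < 0.05;
**, P < 0.01; ***, P < 0.001.

Spearman correlation is the Pearson correlation of mid-ranks with the
large-sample t approximation for p (exact permutation p is out of scope;
cohort sizes here make the approximation adequate). ROC curves are
empirical, swept over all observed thresholds, and the AUC equals the
Mann-Whitney probability with ties counted ½. Orientation is explicit and
never auto-flipped, so a marker that is *lower* in the positive class
honestly reports AUC < 0.5 — the convention under which the published
moderate-asthma AUCs of 0.3613 and 0.3269 make sense. Correlations against
the weighted clinical score (WCS, 0–23) pool all subjects, with healthy
controls at score 0 when no score was recorded; NETs area/cell (not
per-neutrophil) feeds the severity correlation, matching the figure
labeled per-cell.

## The synthetic world

`generate_field()` paints what a 20x cytospin field shows: elliptical DAPI
nuclei (radii 4–7 px), cytoplasmic MPO annuli (3 px) for neutrophils, NET
filaments as smoothed random walks (length 40–120 px, width 3–4 px)
painted **identically** into MPO and Cit-H3 — the operational definition of
a double-positive structure — and "primed" neutrophils with nuclear Cit-H3
that, by construction, add to colocalization only where MPO was also
painted (in practice: nowhere, since MPO is cytoplasmic). Ground truth is
recorded before a Gaussian PSF (σ = 0.75 px) and additive Gaussian noise
(σ = 8 against signal 200 over background 10) are applied. The defaults
were calibrated once, per the stated 5%-recovery target, by sweeping PSF
and filament width: at σ_psf = 0.75 / width 3–4 px Otsu recovers painted
areas to ~1–2%, whereas σ_psf = 1 with 2–3 px filaments inflates thin-ridge
areas by ~65% (the threshold contour of a blurred thin ridge widens). The
field is 256 px square — a scaled-down field keeping the 50-field recovery
suite near a minute — with object densities scaled accordingly.

What a green test on this world does establish: the measurement chain
(threshold → intersect → label → count → normalize) is correct, unbiased at
the stated SNR, and deterministic under seed. What it does not establish:
robustness to real-microscopy nuisances — uneven illumination, autofluorescence,
touching or overlapping cells, out-of-focus filaments, channel bleed-through —
none of which are modeled beyond Gaussian blur and noise.

`generate_cohort()` draws the published group structure (12 healthy /
7 moderate / 14 severe) with cytologies that satisfy the validation
invariants and classify back to their intended groups by construction.
Readouts are lognormal (positive, right-skewed, as assay readouts are):
cf DNA log-means log(0.04)/log(0.06)/log(0.20) µg/ml (σ_log 0.5), MPO-DNA
OD 0.08 + lognormal with log-means log(0.05)/log(0.07)/log(0.55) (σ_log
0.4), and NETs area/cell zero-inflated — uniform on [0, 0.3] px²/cell for
healthy and moderate, plus a lognormal(log 8, 0.6) component for severe
only, encoding the finding that filamentous NETs appear only in severe
BALF. WCS is a monotone noisy function of group and neutrophilia (healthy
0, moderate ≤ 3, severe 4–23). The per-horse magnitudes of the source data
are **not** deposited, so these defaults are calibrated to ordering and
significance only — never to published figure values — and `effect_scale =
0` collapses every group onto the healthy distributions for null
simulations.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a cutoff is quoted; boundary cases are
  documented at each function.
* Otsu on a constant image warns and returns the constant (empty mask)
  rather than erroring: a blank channel is a legitimate negative control.
* Shapiro-Wilk on a constant vector is undefined; it is reported as
  non-normal (p = 0) with a warning, sending the dispatch to the
  nonparametric branch — the defensible direction.
* Connected components use 8-connectivity throughout (diagonal pixels of a
  thin diagonal filament belong together).
* Interpolation range flags use a 1e-8 relative guard so a standard's own
  readout never flags as out-of-range through float error.
* All randomness flows through explicit seeds; generation is byte-identical
  under a fixed seed, and `run_pipeline()` re-runs bit-identically.

## Known limitations

* No watershed declumping, no filament skeletonization or per-NET
  morphometry, and no automated "primed neutrophil" scoring (shown only
  qualitatively in the source).
* Images are single-plane grayscale (PGM I/O); multi-page TIFF and
  microscope vendor formats are out of scope in this environment.
* ELISA results are not comparable across plates (OD units, no inter-plate
  normalization), matching the source's reporting.
* The statistics layer reports no AUC confidence intervals and no exact
  small-sample Spearman p.
* One published narrative count (severe horses with both > 20% neutrophils
  and mucus ≥ 3/5, "all but one") is inconsistent with the printed table
  (two exceptions); the package follows the table and asserts nothing
  about the narrative count.
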