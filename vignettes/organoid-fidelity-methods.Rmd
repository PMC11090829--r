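---
title: "Scoring organoid fidelity from K8/K14 phenotype distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring organoid fidelity from K8/K14 phenotype distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsdfidelity)
```

## The problem and the model

Patient-derived organoids are only useful for drug-response prediction if
they carry forward the phenotypic mixture of the tumor they came from.
`jsdfidelity` treats that mixture as a probability distribution over a
one-dimensional phenotype axis — the per-section `log2(K8/K14)` positive-area
ratio, where K8 marks luminal and K14 basal/myoepithelial identity — and
scores any two conditions by how far apart their distributions sit.

Three ingredients define the score:

1. **Binning.** The 25th, 50th and 75th percentiles of a normal-breast
   reference cohort partition the log-ratio axis into four bins. Binning
   against a *fixed external* reference (rather than each sample's own
   quantiles) is what makes distributions comparable across patients and
   conditions; the reference itself lands uniformly in all four bins by
   construction.
2. **Divergence.** Conditions are compared with the Jensen–Shannon
   divergence in base 2, so the value is symmetric and bounded in
   $[0, 1]$: $\mathrm{JSD}(P,Q) = \tfrac12\sum_i p_i\log_2(p_i/m_i) +
   \tfrac12\sum_i q_i\log_2(q_i/m_i)$ with $M = \tfrac12(P+Q)$ and the
   convention $0\log 0 = 0$.
3. **Normalization.** Real tissue never attains disjoint support: all
   sections come from breast epithelium. The raw scale is therefore
   anchored at the most disparate comparison available in the reference
   data set — pooled ER+ vs pooled TNBC starting tissue, raw JSD 0.56 —
   giving $\mathrm{JSD}_{norm} = (1 - \mathrm{JSD}/0.56)\times 100$:
   100 means identical, 0 means "as different as two breast cohorts get",
   and slightly negative values are possible when a comparison exceeds the
   anchor. The anchor is configurable and can be re-derived for a new data
   set with `calibrate_norm_constant()`.

The base-2 choice deserves a note: with natural logarithms the divergence
is bounded by $\ln 2 \approx 0.693$, which would place the observed maximum
0.56 implausibly near the theoretical ceiling; base 2 bounds it at 1 and is
the convention adopted throughout, including the normalization.

A coverage rule guards against under-sampling: if the rarest bin in the
tumor cohorts has frequency $f$, the probability that $N$ sections all miss
it is $(1-f)^N$, so $n_{min} = \lceil \log(1-c)/\log(1-f)\rceil$ sections
give confidence $c$ of seeing it at least once. At the observed $f = 0.08$
and $c = 0.85$ this is 23 sections. Conditions below $n_{min}$ warn rather
than fail — small organoid harvests are a fact of life and the score is
still informative, just noisier.

## Image quantitation choices

The imaging front end makes four decisions a user should know about:

* **Thresholding** is Otsu's method on a 256-level histogram per channel,
  with a fixed-intensity override in the configuration. Otsu is the
  standard parameter-free choice for well-separated fluorescence and is the
  default precisely because it imports no tuned constant.
* **Thresholds are fitted on the parent image, then applied as fixed values
  to its tiles.** Per-tile Otsu degenerates on tiles that are mostly empty
  (the histogram loses its second mode), and a per-image threshold makes
  tile areas exactly additive — the sum of tile areas equals the parent's
  area, which the tests assert.
* **Tissue area** defaults to the union of the K8+ and K14+ masks, the most
  conservative definition available from the two mandatory channels; a
  dedicated tissue/nuclear channel can be configured instead. The 5% tissue
  filter is applied with strict inequality ("greater than 5%") to all
  quantified tiles by default, each tile judged against its own area
  (remainder tiles at image edges are smaller and are not penalized for it);
  a configuration flag restricts it to ST tiles only.
* **Tile size** defaults to `round(sqrt(mean organoid image area))` over the
  organoid images in the run, so ST sampling units match the organoid scale;
  it can be pinned explicitly. Tiles are enumerated row-major.

Small-object removal (default 25 px) and the nucleus-size window (50–5000
px) are exposed in the configuration; they are acquisition-dependent and no
universal value exists. Nucleus counting deliberately does not split
touching nuclei — at the section magnifications this pipeline targets,
component counting within a size window is adequate for *fractions* of
positive cells, which is the quantity used downstream.

## Binning conventions

* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), the common scientific-software default; the
  type is configurable.
* Bins are left-open, right-closed with bin 1 closed at the first quartile:
  $(-\infty, Q_{25}], (Q_{25}, Q_{50}], (Q_{50}, Q_{75}], (Q_{75}, \infty)$.
  Any single consistent closure works — the tests check shift-equivariance
  and exactly-one-bin membership — this one is simply fixed and documented.
* Zero areas: when either marker area is zero the ratio is undefined, so a
  1 px pseudocount is added to *both* areas (symmetric, hence no directional
  bias) and the record is flagged; sections with zero K8, zero K14 and zero
  tissue are rejected as carrying no phenotype signal.
* The reference scheme is fitted on all normal-tissue sections pooled, not
  per donor then averaged: the reference is meant to be one fixed ruler.

For within-group scores (e.g. "normal vs normal") two constructions exist
and the package provides both: `pooled` concatenates counts per group (and
is identically zero for a group against itself), while `mean_pairwise`
averages the JSD over distinct member pairs and is the construction that
yields a meaningful within-group disparity. Neither is asserted as uniquely
correct; group-level results should state which mode they used.

## The synthetic-data generator

No patient images are distributed with the package, so the generator stands
in for them at two levels, both fully seeded and deterministic:

* **Images** (`gen_section_image()`): random elliptical blobs per channel,
  grown until the requested positive-area fraction is hit *exactly* (the
  last blob is trimmed pixel-wise), rendered at constant foreground/
  background intensity plus Gaussian noise and clipped at zero. Ground-truth
  masks are returned alongside, so thresholding accuracy is measurable. The
  default recovery experiment uses noise at 10% of the foreground
  intensity; at that level Otsu recovers areas to within a few percent.
* **Cohorts** (`gen_cohort()`): the per-section log-ratio is a two-component
  normal mixture — a K14-rich component at mean −1.5 and a K8-rich one at
  +1.5, both SD 1 — with the K8-rich weight defining the subtype: 0.5
  (normal, centered), 0.8 (ER+, right-skewed), 0.2 (TNBC, left-skewed).
  Patients draw a mean offset (SD 0.3) before their sections; organoid
  cohorts are displaced by `culture_drift`; and drug selection is a signed
  delta on the mixture weight (`treatment_shift`), positive values modelling
  enrichment of a K8-rich resistant population. Defaults are 100 sections
  per patient and 7/7/6 patients for normal/ER+/TNBC, the scale of a
  realistic multi-patient imaging study, and were chosen (by closed-form
  calculation, see below) so that the qualitative orderings the method must
  detect hold in expectation: within-subtype similarity exceeds
  cross-subtype similarity, and ER+ vs TNBC is the most disparate pair.

`analytic_bin_probs()` is the generator's closed-form oracle: the exact
mixture mass per bin via the normal CDF, with the patient offset folded into
the component variances. Under the defaults it gives within-subtype
pairwise JSDs of roughly 0.01–0.03, normal-vs-tumor about 0.055 and ER+ vs
TNBC about 0.21 — the ordering the acceptance checks exercise empirically.

What the generator does *not* emulate: tissue texture, point-spread
blurring, spectral bleed-through, uneven illumination, or staining-batch
effects. Passing tests therefore demonstrate that the statistical machinery
is correct and that the imaging front end is robust to additive noise; they
do not certify performance on any particular microscope's output, for which
the fixed-threshold override and the configuration exist.

Draw order is patient-by-patient (offset, then that patient's sections), so
enlarging a cohort never perturbs the sections already generated — useful
when comparing runs at different cohort sizes.

## Companion statistics

Marker-redundancy checks use the Pearson product-moment correlation
("linear correlation" is read literally) with its two-sided test. Group
comparisons use the two-sided Mann–Whitney test: exact enumeration when the
combined sample is at most 16 without ties, the tie-corrected normal
approximation with continuity correction otherwise — exact where it is
cheap, standard elsewhere; the branches agree to ~0.01 in p at the cutoff.
Fold changes are ratios of group means (medians via `center = "median"`),
and no multiple-testing correction is applied by default, matching the
report-raw-p convention of the companion analyses; `p.adjust` can of course
be applied to the returned columns.

## Numerical details and degenerate inputs

* JSD terms with $p_i = 0$ contribute zero; bins empty in both
  distributions are skipped (so $m_i = 0$ never divides); the result is
  clipped to $[0,1]$ against floating-point drift and input vectors must
  sum to 1 within $10^{-9}$.
* `min_sections()` computes the closed form, then verifies
  $1-(1-f)^{n} \ge c$ and increments if rounding at the boundary undershot;
  $f = 1$ returns 1, $f = 0$ and $c = 1$ are errors (impossible coverage /
  unbounded sampling).
* A constant-intensity channel is a degenerate-threshold error under Otsu
  (but counts zero nuclei, where "no signal" is the correct answer).
* An all-identical reference yields a degenerate scheme with a warning;
  every value then falls in bin 1 or bin 4 by the closure convention.
* Quantitation is fully deterministic: identical images, parameters and
  seeds reproduce identical tables byte-for-byte.

## Problem sizes used in the tests

The shipped tests run the full pipeline at deliberately modest scale —
synthetic images of 150–300 px per side, cohorts of 3–7 patients with
20–100 sections, one 50,000-draw Monte-Carlo check of the analytic oracle,
and 50 images in the recovery experiment — sizes chosen so the whole suite
exercises every path in a few minutes on a laptop while keeping every
statistical check comfortably powered. The same properties hold at larger
sizes by construction (the convergence tests verify the $n^{-1/2}$
behaviour the generator is designed to have).

## Known limitations

* The method reduces phenotype to one marker ratio; phenotypes orthogonal
  to the K8/K14 axis are invisible to it. The machinery is
  marker-agnostic — any positive-area pair defines the same pipeline — but
  redundancy of extra markers should be established (see
  `marker_correlation()`) before trusting a two-marker summary.
* With four bins, the JSD between two conditions estimated from $n$
  sections each carries sampling noise of order $3/(4 n \ln 2)$; scores
  from conditions far below `min_sections()` should be read qualitatively.
* The normalization anchor is a property of the reference data set. Scores
  on a different tissue system should re-derive it rather than reuse 0.56.
* No confidence intervals are attached to JSD scores; the method is a
  point summary by design.
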