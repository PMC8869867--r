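---
title: "Quantifying the proteasome-to-autophagy switch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the proteasome-to-autophagy switch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteaphagy)
```

## Scope

Mantle-cell lymphoma lines that acquire resistance to the proteasome
inhibitor bortezomib reroute the degradation of ubiquitylated proteins from
the 26S proteasome to the autophagy–lysosome system, up to and including
autophagic degradation of proteasomes themselves (proteaphagy). Testing
that hypothesis quantitatively requires four unrelated kinds of analysis,
and this package implements all four as one pipeline:

1. **Ubiquitome quantification** — label-free spectral counting of TUBE
   (tandem ubiquitin-binding entity) pull-downs against GST resin
   controls, followed by a reproducibility-based two-fold differential
   filter.
2. **Functional-category summarization and enrichment** — mean abundance
   shifts per proteasome subcomplex (20S α, 20S β, 19S base, 19S lid) and
   autophagy stage (early signaling, autophagosome formation, lysosome
   fusion), with Fisher's exact enrichment tests.
3. **Co-localization** — puncta detection and ROI-restricted Manders
   coefficients for proteasome subunits versus autophagy markers in
   two-channel confocal planes, plus normalized line profiles.
4. **Drug-combination analysis** — annexin-V style event gating, the
   median-effect model, and Chou–Talalay combination indexes at constant
   dose ratios.

Every input can be simulated by the `generate_*` functions with known
ground truth, so each claim the pipeline makes is testable against a
planted answer.

## Spectral-count processing model

Counts are summed per matching peptide for each protein
(`aggregate_psm_counts()`; a peptide shared between proteins counts toward
every match, with a unique-peptides mode for the conservative alternative).
The mean of the GST control samples is then subtracted per protein
(`subtract_background()`); a paired mode subtracting control replicate *i*
from sample replicate *i* is available, but the mean is the default because
resin background is a property of the resin batch rather than of a
replicate. Subtracted values at or below the counting floor are raised to
one and the matrix is log2 transformed (`log2_with_floor()`). We floor the
whole interval below 1 — not only negative and zero values — because
fractional subtracted values in (0, 1) would otherwise produce negative
log2 abundances, and a background-corrected count below one specific
spectrum carries no more evidence than zero does. Finally, classical
quantile normalization (`quantile_normalize()`, delegating to
limma) forces all experimental columns onto the common rank-wise mean
distribution; ties are resolved by averaging tied ranks, and control
columns are excluded — they exist to define background, not abundance.

The stage tag on a `SpectralCountMatrix` enforces the order
raw → subtracted → log2 → normalized; applying a step out of order is an
error rather than a silent misuse.

A protein is *differential* when **every** replicate-pair log2 difference
exceeds +1 (enriched) or falls below −1 (reduced)
(`reproducible_differential()`). "More than two-fold" is read strictly: a
difference of exactly 1.0 log2 units fails. The default pairing is by
replicate index — the weakest reading of "reproduced in all replicas" —
with an all-pairs mode that is provably at least as stringent. No
multiple-testing correction is applied: the criterion is
reproducibility-based, not p-value-based, and the planted-truth
false-discovery proportion is surfaced by `recovery_report()` in
simulation instead.

## What the count generator emulates

`generate_tube_counts()` emulates a two-cell-line, three-replicate TUBE
design with matched GST controls. Its defaults are fixed once:

| parameter        | default | meaning                                                  |
|------------------|--------:|----------------------------------------------------------|
| `n_proteins`     |    1000 | pull-down depth of a typical TUBE–MS experiment          |
| `n_replicates`   |       3 | replicates per condition, plus 3 GST controls            |
| `frac_up`/`frac_down` | 0.05/0.05 | planted regulated fractions                        |
| `planted_log2fc` |       2 | four-fold planted shift                                  |
| `baseline_mean`  |     100 | median specific counts per protein                       |
| `baseline_sdlog` |       1 | log-normal abundance spread (95% range ≈ 13–740 counts)  |
| `dispersion`     |    0.03 | NB overdispersion; count CV ≈ 0.2 at 100 counts          |
| `background_mean`|       5 | nonspecific resin counts, present in every pull-down     |

Counts are negative-binomial (gamma–Poisson): variance = μ + 0.03 μ², the
Poisson limit as the overdispersion goes to zero. The log-normal abundance
spread matters more than it may look: if every protein sat at the same
baseline, the planted proteins would be the sole occupants of condition B's
extreme ranks and quantile normalization would compress their apparent fold
changes toward the null columns — a wide abundance distribution is what
makes rank-based normalization nearly neutral for scattered regulated
proteins, in simulation as in real data. Background counts are added to the
specific samples too, so that subtraction is meaningful, and planted set
sizes use round-half-away-from-zero of `frac × n`.

What the generator does **not** emulate: protein-correlated peptide
misassignment, database-search variability, missing-value censoring at the
identification step, and batch drifts between replicates. Passing the
recovery tests therefore shows the filter's behaviour under the stated
count model, not robustness to search-engine artefacts.

The validation suite and the acceptance script run the recovery analysis at
1000 proteins × 20 seeds with `baseline_mean = 400`, the depth at which the
~20% count CV it stipulates genuinely holds across the planted comparison
(at the four-fold-down side of a 100-count protein, Poisson noise alone
exceeds it); sensitivity is ~0.94 with a planted-truth FDP near zero.

## Category summaries and enrichment

`category_summary()` reports the arithmetic mean of member-protein values
per category and condition — the mean of all single values, with
many-to-many annotations contributing to every category they belong to.
`fisher_enrichment()` cross-classifies the protein universe (differential
vs not × in-category vs not) and reports the conventional two-sided
Fisher's exact p (sum of hypergeometric probabilities of tables at most as
probable as the one observed); the odds ratio is the sample `ad/bc` with
0.5 added to every cell when any cell is zero — reported alongside, never
used in the p-value. `heatmap_matrix()` optionally row-scales with the
sample standard deviation (as `scale()` does); constant rows map to zeros
rather than NaN so degenerate categories stay plottable.

## Co-localization

`detect_puncta()` thresholds a channel (Otsu by default, computed on the
channel rescaled to [0, 1]; fixed thresholds supported for
reproducibility), labels connected components with 8-connectivity, and
filters by area (default minimum 4 px, which removes single-pixel noise
excursions). A flat image under Otsu yields an empty ROI set with a
warning rather than an error. Within the union of the ROIs,
`manders()` computes M1 — the fraction of reference-channel intensity in
pixels where the partner channel exceeds its threshold — and the symmetric
M2, per ROI and pooled. We use thresholded Manders coefficients (not the
Costes automatic variant) restricted to puncta ROIs, with a whole-image
mode available by passing ROIs that cover the frame. Coefficients are
invariant under a simultaneous rescaling of a channel and its fixed
threshold, and always lie in [0, 1]. `line_profile()` uses bilinear
interpolation and normalizes each trace by its own maximum (a zero trace
stays zero).

The image generator places Gaussian puncta by rejection sampling with a
minimum pairwise center distance of 6 spot sigmas. At 3σ two spots'
thresholded supports merge into one connected component; 6σ is the
smallest round separation at which the detector can in principle resolve
every planted spot, which is the property the detection tests rely on.
Planted overlap is structural: `round(f × n)` spot centers appear in both
channels, and each channel carries `n` puncta in total, so the pooled M1
over reference ROIs converges to `f` when amplitudes are equal and the
background sits below threshold. Simulated images are single planes; the
package treats confocal stacks one slice at a time and does not segment
cells (one cropped cell per image is assumed).

## Median-effect model and combination index

Single agents follow the median-effect equation
`fa/(1−fa) = (D/Dm)^m`; `fit_median_effect()` linearizes it as
`log10(fa/(1−fa)) = m·log10 D − m·log10 Dm` and fits by least squares,
reporting `m`, `Dm` (the IC50) and the linear correlation of the fit.
Observations with fa at exactly 0 or 1 are rejected with a warning — the
generator clips its output to [0.005, 0.995] precisely so that the
linearization is defined, but real data must be handled by the caller.

`combination_index()` evaluates, at each requested effect level, the total
combination dose producing that effect, splits it by the fixed mixing
ratio, and sums the component doses relative to the single-agent
equipotent doses (the mutually exclusive Chou–Talalay form; the
non-exclusive form adds the cross term and is available by flag). CI < 1
flags cooperativity. `ci_analysis()` fits per replicate and summarizes CI
as mean ± SD, matching how combination indexes are conventionally reported
with a spread.

The dose-response generator plants the interaction directly in Loewe
terms: at every total dose it solves `dA/Dx_A(fa) + dB/Dx_B(fa) = α` for
the achieved effect, so α = 1 is exactly additive (the downstream CI
recovers 1 to fitting tolerance — the module's primary analytic check),
α < 1 synergistic, and when the two agents share a slope the combination
series is itself exactly median-effect linear.

Flow-cytometry events are a two-component log-normal mixture (unstained
around intensity 100, stained around 1000, σ_log = 0.25) with 10⁴ events
per experiment by default; `gate_apoptosis()` counts events above an
intensity gate, and the default gate in the pipeline (10^2.5, the
geometric midpoint) misclassifies a negligible fraction at that
separation.

## Statistics and reporting

`two_sample_ttest()` is the two-tailed unpaired t-test (pooled-variance
Student's by default, Welch by flag) via `stats::t.test`, with the
degenerate zero-variance cases defined explicitly (equal means → t = 0,
p = 1; unequal means → the p → 0 limit with a warning). Figure-legend
stars follow the 0.05/0.01/0.001/0.0001 convention
(`significance_stars()`); no multiplicity correction is applied anywhere,
as none is part of the procedure being implemented.

`run_pipeline()` executes simulate → quantify → differential → annotate →
coloc → ci, derives each generator's seed from the single global seed, and
writes one JSON report with the configuration echo, package version and
per-stage summaries. The report deliberately excludes the output directory
and any timestamps, so identical configuration and seed give byte-identical
reports wherever they are written; `validate_report()` checks the report
against the schema shipped in `inst/schema/` with a lightweight structural
validator.

## Problem sizes and limitations

The shipped validation suite uses 1000-protein count matrices (20 seeds),
256×256-pixel images (10–20 seeds per setting), five-dose three-to-four
replicate dose-response series, and 10⁴-event tables — sizes at which every
statistical property under test is already stable.

Known limitations: detection calls depend on configurable thresholds for
which no canonical rule exists, so absolute detected-set sizes are not
comparable across studies; quantile normalization slightly compresses
genuinely regulated proteins occupying extreme ranks (visible in simulation
as a sensitivity just below one); Manders coefficients are threshold
statistics and inherit the threshold's arbitrariness; and the combination
index presumes the median-effect model fits each series — `r` from
`fit_median_effect()` should be inspected before trusting a CI.
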