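---
title: "Methods: hotspot compartments, interaction graphs, and survival dichotomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot compartments, interaction graphs, and survival dichotomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hotspotr)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic benchmark does and does not establish. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The hotspot model

The analysis assumes a slide has been reduced to classified cell
centroids in micrometres. Cells are binned onto a lattice of
50×50 μm² grids (half-open intervals, so a cell exactly on a boundary
belongs to the next grid; the origin is the bounding-box minimum floored
to a multiple of the grid size, which makes results stable under
sub-grid translation of the input). A grid is *tissue* iff it contains
at least one cell of any class — including stromal cells, which join no
statistical channel but mark tissue presence. This matters because the
Getis–Ord reference population is, by default, the tissue grids only:
including acellular glass would deflate the global mean and inflate
hotspot calls. The choice is exposed (`population = "all"`) for
sensitivity analysis.

For a channel with grid counts $C_j$ the statistic of grid $i$ is

$$z_i = \frac{\sum_j W_{ij} C_j - \bar{C}\sum_j W_{ij}}
{S\sqrt{\left(n\sum_j W_{ij}^2 - (\sum_j W_{ij})^2\right)/(n-1)}}$$

with binary weights $W_{ij}=1$ for grids within Chebyshev distance 4
(the fourth-order queen neighborhood, a 9×9 window ≈ 450×450 μm²
context), $\bar{C}$ and $S$ the mean and *population* SD over the $n$
tissue grids. Two conventions were genuinely open, because the source
equations were not machine-readable:

* **Self-inclusion.** `include_self = TRUE` (the Gi\* convention) is the
  default and is recorded in output metadata; Gi (self excluded) is one
  flag away. On realistic lattices the two agree to well under one z
  unit because the window holds 81 grids.
* **Population.** Tissue grids only, as argued above; `n` counts the
  same population.

P values are one-sided upper tail of the standard normal — the analysis
looks for enrichment only, never cold spots — and are deliberately *not*
multiplicity-corrected across grids: the compartment definitions apply
the raw 0.05 threshold, and a tie at exactly 0.05 is non-significant
(strict `<`). Degenerate inputs: zero count variance yields undefined z
everywhere and an all-`NONE` labeling; a window that covers the whole
population has no contrast and is likewise non-significant.

Compartments follow from the two channels jointly: cancer-only
enrichment is a cancer hotspot (CH), lymphocyte-only enrichment a
peritumoral immune hotspot (IH~peri~), joint enrichment an intratumoral
immune hotspot (IH~intra~). The three slide scores are area ratios in
grid units: `S_intra/immune` (share of the immune-rich area interfacing
with tumor — the prognostic quantity), `S_intra/cancer`, and
`S_intra/tissue`. A score whose denominator is empty is returned as `NA`
with a recorded reason rather than silently 0.

## 2. Individual hotspots and TLS/LAG handling

Individual immune hotspots are 8-connected components of the *union* of
IH~peri~ and IH~intra~ grids; each grid keeps its sub-label afterwards.
Building components on the union, rather than per label, allows one
hotspot to span both compartments — which is exactly how tertiary
lymphoid structures straddling a tumor margin present. No minimum
component size is imposed.

Pathologist-annotated TLS (zoned aggregates with a germinal center) and
LAG (aggregates without one) arrive as polygons; a grid belongs to a
structure iff its center lies inside the polygon (even-odd rule —
unambiguous and area-faithful at 50 μm resolution). Annotated grids are
removed *before* segmentation and connectivity is recomputed, so an
annotation can split a hotspot in two; the alternative (post-hoc
masking) was rejected because it can leave a "component" whose remaining
grids are not mutually connected. Each structure is itself assigned to
the compartment covering the majority of its tissue grids, with an exact
peritumoral/intratumoral tie resolved to IH~intra~ and remaining ties by
IH~peri~ > CH > NONE precedence.

## 3. Interaction graphs

Within one hotspot, the six immune subsets' cells are joined by a
Delaunay triangulation (own Bowyer–Watson implementation; the test suite
holds it to an empty-circumcircle brute-force oracle), and edges longer
than 250 μm are discarded — beyond that distance adjacency in the
triangulation no longer plausibly reflects cellular interaction.
P40⁺ neoplastic cells are excluded from graphs. Exactly duplicated
coordinates (a real occurrence when detections collide) are collapsed to
one vertex with multiplicity retained, so triangulation sees a proper
point set while composition counts remain faithful. Fewer than three
non-collinear cells yield an empty, flagged edge set.

The interaction `f(a,b)` is the fraction of edges joining subsets a and
b among all edges of that hotspot. Same-type pairs count, giving 21
categories; under a label permutation null the fractions converge to the
finite-population expectation $2n_an_b/(n(n-1))$, which the acceptance
suite verifies. Shannon indices use the natural log (only orderings
matter downstream; the base is an argument), and diversity can be
computed over any non-negative weights — counts, densities or the
interaction fractions. The CD8⁺/CD4⁺FOXP3⁺ ratio is undefined (`NA`)
when the Treg count is zero: a pseudocount would fabricate a constant
the data do not contain, so such hotspots are excluded from ratio
analyses and the exclusion is visible. Group comparisons are two-sided
Wilcoxon tests (signed-rank when paired) with Benjamini–Hochberg
adjustment; the compartment logistic regressions code intratumoral = 1,
so a *negative* coefficient means an interaction is more frequent in
peritumoral hotspots. Complete separation is detected heuristically
(diverging coefficient or SE) and flagged `unstable` rather than
reported as a confident Wald p.

## 4. Registration

Serial sections are aligned by a least-squares affine fit to manually
chosen landmark pairs (≥ 3, non-collinear; exact interpolation at 3).
Registration quality is the target registration error — the mean
landmark residual as a percentage of the fixed image's diagonal — plus
the Pearson concordance of per-grid densities across modalities. TRE is
evaluated on the fitting landmarks by default, matching how a single
averaged error is conventionally reported; held-out evaluation is
available by passing different pairs. Coordinates are micrometres
throughout; pixel inputs are converted once at ingest via
`um_per_pixel`.

## 5. Survival dichotomization and validation

`optimal_cutpoint()` maximizes the two-group log-rank statistic over
candidate thresholds (midpoints of consecutive distinct score values —
the finest grid the data support) subject to `min_prop = 0.1` of
subjects per side. The reported p value is the naive log-rank p at the
maximum: it is *known to be anti-conservative* (the package's own null
simulations put the rejection rate far above 5%), which is precisely why
the repeated random-split routine exists — dichotomize on discovery,
test on validation, 100 times at 1:1, reporting the significant
fraction and the mean/SD/CI of validation p values. A conservative
Bonferroni-over-candidates correction is available as `p_method`.
Degenerate splits (a validation side with no subjects or no events) are
skipped and counted. Cox models use Efron tie handling, Wald intervals,
and flag monotone-likelihood covariates. The fast vectorized log-rank
scan is held to `survival::survdiff` at 1e-12 in the tests.

## 6. The synthetic world

The generator emulates the tissue geometry the analysis assumes: uniform
stromal background (tissue mass), disc-shaped cancer nests as Poisson
processes, immune infiltrates as Thomas cluster processes (Poisson
parents restricted to a region — nest interior, a 200 μm margin band, or
a distant field/disc — each with Poisson offspring displaced by an
isotropic Gaussian), and TLS-like aggregates with a B-cell-dominant core
and T-cell ring. Thomas was preferred over Matérn for its smooth
density; the margin band is the annulus [r, r + 200 μm] so peritumoral
infiltrates sit adjacent to, but outside, cancer hotspots. Each
compartment draws from its own RNG sub-stream keyed by the master seed,
so editing one compartment leaves the others' realizations untouched —
a property the tests assert.

No quantitative densities for "enriched" regions exist in the
literature the design follows; the defaults are this package's own
choices of realistic magnitudes and are claimed as nothing more:
stromal 1.5–2×10⁻³ cells/μm² (≈ 4–5 cells per 50 μm grid, a typical
nucleated-cell density), nest cancer intensity 4×10⁻³/μm², immune
fields κ = 6–8×10⁻⁵ parents/μm² with 40–60 offspring at σ = 50–60 μm
(peak lymphocyte densities comparable to cancer densities). The cohort
generator draws exponential survival whose log-hazard includes the
stored coefficient on the patient's true score plus mild age, stage and
pack-year effects (stage frequencies follow published NSCLC cohort
proportions); baseline hazard corresponds to a 1,000-day median with
administrative censoring uniform over 500–3,000 days (≈ 40% censoring).

What a green benchmark establishes: that the pipeline recovers *known*
generative structure — compartment masks (balanced accuracy > 0.9 at
default densities), permutation-null interaction fractions, simulated
cutpoints and hazard coefficients. What it does not establish: anything
about real H&E/IHC slides, whose cell-detection noise, staining
variability, tissue folds, and non-disc tumor geometry the generator
deliberately does not model, and nothing about the prognostic claims of
any particular cohort.

## 7. Known limitations

* The Getis–Ord self-inclusion and population conventions are defaults
  with flags, not ground truth; analyses should report them (they are
  stamped into the output config).
* The naive maximally selected p value is biased by construction; only
  the split-validated fraction should be interpreted inferentially.
* Bowyer–Watson uses double-precision circumcircle tests with an
  epsilon guard, adequate for cell coordinates but not adversarial
  inputs.
* The CLI is a thin dispatcher over the R API; it does not validate
  cross-file consistency (e.g. that annotations and cells share a
  frame) beyond what the underlying readers check.
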