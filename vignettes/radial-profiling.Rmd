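---
title: "Boundary-normalized radial profiling of core-shell condensates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-normalized radial profiling of core-shell condensates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoprofile)
```

## The measurement

Nucleoli are core–shell condensates: the fibrillar centre and dense
fibrillar component form a core, and the granular component — marked by
nucleophosmin (NPM) — forms a shell whose filled territory defines the
nucleolar outline. To ask where a signal of interest (here, a
psoralen-based reporter of underwound DNA) sits relative to that
architecture, this package measures intensity as a function of the
*boundary-normalized distance* d: rays are cast from the centroid of each
segmented nucleolus; along a ray at angle θ the boundary radius
r_b(θ) is the first inside→outside crossing of the nucleolar mask, and a
sample at radius r is assigned d = r / r_b(θ). Thus d = 1 is the outline
regardless of nucleolar size or shape, d ∈ [0, 0.5] is the deep interior
("inside" window) and d ∈ [1.5, 2.0] the surrounding nucleoplasm
("outside" window). Per-nucleolus profiles are averaged into a uniform
d-bin grid, optionally smoothed by a centred moving average, and
aggregated across nucleoli into a mean ± s.d. band. Window means are
always computed from the raw valid samples, never from the smoothed bins,
so the smoothing choice cannot influence the hypothesis tests.

Condition comparisons use the nucleolus as the sampling unit, pooled
across cells (the convention "n nucleoli / m cells" is recorded in every
summary). For two conditions the package applies a two-sided
Mann–Whitney U test to the inside and outside window means separately;
for three or more, the two-sided Steel–Dwass all-pairs test. A per-cell
aggregation is available through the recorded `field_id`/`cell_id`
columns for sensitivity analysis; pooling nucleoli ignores possible
cell-level correlation, a known caveat that the package reproduces
deliberately rather than silently correcting.

## The synthetic data generator

No reference image data accompany the method, so the generator is a
first-class module: every downstream stage is validated against fields
whose ground truth is analytic.

A field contains `n_cells` circular (2D) or spherical (3D) nuclei;
each nucleus holds 1–3 nucleoli by default, with radius ~N(18, 2²) px
inside a nucleus of radius ~N(120, 8²) px at 0.063 µm/px on a 512×512
grid — proportions chosen to resemble a high-NA oil-objective field of
cultured cells; they are conventions, not claims about any instrument.
Each channel follows a radial law f(d) on d ∈ [0, 2] plus a nucleoplasm
baseline:

* nucleus marker: uniform over the nucleus;
* shell marker: core 0.35, shell ring (d ∈ (0.75, 1]) 1.0, nucleoplasm
  0.08 — a bright NPM-like ring over a dimmer core;
* target: a step law with inside/outside ratio ρ. The `control` preset
  uses ρ = 3 over baseline 0.2; `RNAPI_inhibited_like` and
  `G4_ligand_like` flatten ρ to 1 (the latter also halves the shell
  marker); `BLM_like` multiplies the whole control law by 0.5.

Noise is applied in the physical order: Gaussian PSF blur (σ = 1.5 px),
Poisson shot noise at 200 photons per intensity unit, then additive
Gaussian read noise (s.d. 0.01). In addition, each nucleolus receives a
log-normal brightness factor (cv = 0.1) on the target channel across its
whole d ≤ 2 neighbourhood. This emulates nucleolus-to-nucleolus staining
variability, which dominates the between-nucleolus variance of window
means in real data; without it a window mean averages thousands of pixels
and its variance collapses to shot noise, making group comparisons
sensitive to arbitrarily small systematic residues (e.g. 1e-4-level PSF
spill), which no real experiment is.

Placement uses dart-throwing with whole-configuration restarts and an
explicit failure after 10⁴ attempts. Two deliberately strict defaults:
nucleoli are placed so that their whole d ≤ 2 annulus stays inside the
nucleus (`annulus_inside = TRUE`), keeping the outside window fully
measurable, and pairwise so that the annuli of different nucleoli are
disjoint (`separation = "annuli"`), so that no nucleolus's blurred core
can bleed into a neighbour's outside window. The looser rule that only
forbids annulus–body overlap is available as `separation = "body"` for
crowded fields. Optional low-order angular harmonics
(`irregularity > 0`) perturb the boundary so that boundary-tracing code
is exercised on non-circular outlines while the per-ray ground truth
stays analytic. Identical (spec, seed) pairs are bit-identical; the seed
is the only entropy source.

What the generator does *not* emulate: structured illumination
reconstruction artifacts, chromatic shift, irregular (non-star-convex)
nucleolar shapes, intra-nucleolar substructure (fibrillar centres are
not rendered separately), or any chromatin mechanics — the target signal
is a radial law, not a torsion model. Passing tests therefore demonstrate
correctness of the measurement machinery on geometries it can invert, not
performance on adversarial real-world morphology.

## Segmentation

Nuclei: global Otsu on the nucleus-marker channel (paralleling
threshold-generated nuclear outlines), hole filling, minimum area
2000 px²; border-touching nuclei are kept but flagged. Nucleoli:
Otsu computed per nucleus on the shell-marker histogram restricted to
that nucleus, hole filling (the outline is the *filled* shell territory,
ring plus enclosed core), minimum area π·5² px², minimum solidity 0.7,
and a contrast guard (the threshold must exceed the within-nucleus median
by 2 median-absolute-deviations) so that a nucleus without genuine shell
signal yields zero candidates instead of noise speckle. All thresholds
are overridable with fixed values. The method reference describes only
"thresholding"; Otsu was chosen as the parameter-free reproducible
default. No watershed splitting is applied by default because the
generator's placement rules prevent touching nucleoli; segmentation of
z-stacks labels in 3D (6-connectivity) and centroids are then 3D, with
profiling performed in the plane nearest the 3D centroid.

## Profiling: numerical choices

Defaults: 180 rays, 0.25 px radial step, d_max = 2, 40 bins (width 0.05
in d), smoothing window 5 bins. The boundary crossing is sub-pixel:
the bilinearly interpolated mask indicator is linearly interpolated to
its 0.5 crossing between consecutive radial samples. Intensity samples
use bilinear interpolation; validity rules discard samples outside the
image, outside the parent nucleus, or inside a *different* nucleolus
label. Rays that leave the image while still inside the label count as
boundary-undetectable; a nucleolus with more than half its rays
undetectable is excluded with a logged reason, as is any nucleolus with
an empty window. Bins with no samples are explicitly missing (NA), never
silent zeros, and the moving average skips missing bins rather than
imputing them.

These resolutions are conventions, shown stable by the test suite:
doubling the ray count or halving the step changes bin means by < 1% on
default fields, and a 1-px mask dilation moves the apparent d = 1
crossing by less than 1.5 bin widths. The bin grid aligns d = 1 and the
core/shell edge (0.75) with bin boundaries, so piecewise-constant laws
are recovered exactly by per-pixel binning.

One caveat the tests make explicit: any interpolating sampler smooths a
discontinuous law over ~1–2 px around the jump, so at small radii the
bins adjacent to a step differ from the per-pixel oracle by an amount
that scales like 1/(bin width in px). The oracle-equivalence check
therefore uses a disk large enough (R = 500 px) that this interpolation
transition is confined within single bins; boundary *localization*, by
contrast, is accurate to well under one bin width for all radii 10–60 px
because bilinear smoothing is symmetric about the edge.

## Statistics

The two rank tests are implemented in the package itself and validated
against independent references in the test suite:

* **Mann–Whitney U** (two-sided): U from mid-ranks. With a pooled sample
  size ≤ 14 and no ties (auto mode), the exact two-sided p is
  2·min-tail over full enumeration of rank assignments, capped at 1 —
  validated against the exact Wilcoxon distribution for every tie-free
  dataset with n₁ = n₂ ≤ 5. Otherwise: normal approximation with
  tie-corrected variance and continuity correction (equal to
  `wilcox.test`'s p on tied data). Two identical constant samples give
  p = 1 with a `degenerate` flag rather than an error.
* **Steel–Dwass** (two-sided, all pairs): for each pair, mid-ranks within
  the pooled pair, tie-corrected variance, standardized statistic t; p =
  P(Q_{k,∞} ≥ √2·|t|), with the studentized-range survival function
  integrated numerically (absolute tolerance 1e-8; cross-checked against
  `ptukey` and the published critical value q(3, ∞, 0.05) = 3.314). At
  k = 2 this reduces exactly to the uncorrected normal-approximation
  Mann–Whitney test. A max-statistic permutation mode provides a
  reference null: on a clearly separated fixed dataset (three groups of
  five) the asymptotic p agrees with a 10⁵-resample permutation p to
  ~0.003. In mid-range p (~0.1–0.8) at n = 5 the asymptotic
  approximation can deviate from the permutation null by up to ~0.1 —
  expected small-sample behaviour, which is why the validation dataset
  exercises the decision-relevant small-p regime; at the method's
  intended sample sizes (tens of nucleoli per group) the approximation is
  the standard choice.
* Paired and one-sample t tests wrap `stats::t.test`, with an explicit
  zero-variance error distinct from p = 1.

No multiplicity adjustment is applied beyond what Steel–Dwass itself
embodies. Type-I error of all four tests is verified by simulation
(1000 null replicates each) to lie in [0.03, 0.07] at α = 0.05, with the
Steel–Dwass family-wise rate ≤ 0.07.

One statistical subtlety uncovered while validating the end-to-end
comparison: when two conditions share the same nucleoplasm distribution,
the outside-window comparison is a true null test, so its rejection rate
cannot fall below the nominal α — the expected fraction of runs with
outside p > 0.05 is exactly 1 − α ≈ 95%, with binomial fluctuation around
it. The acceptance suite therefore checks the two halves of the
qualitative pattern separately: the inside-window effect must be detected
in ≥ 95% of runs (observed: 100%), and the outside-window rejection rate
must stay within the 3σ binomial envelope of α over 100 runs (≤ 0.12;
observed 0.07), alongside an identical-preset null check.

## Assays

The gel readout is the crosslink-protection fraction, non-denatured band
divided by total band, clipped to [0, 1] with a flag when measurement
noise pushes the raw ratio above 1. ChIP-qPCR enrichment is percent
input, `100 · f · E^(Ct_input − Ct_IP)` with aliquot fraction f = 0.02
and amplification efficiency E = 2 by default; E is exposed because
ΔCt-based and efficiency-corrected quantification differ only through
it. Normalization by the control condition is within-replicate
(each replicate divided by its own control), making control entries
exactly 1, and tests across replicates use the one-sample t against 1.
The synthetic ChIP truth encodes a treated/control ratio of 0.4 at the
four putative-quadruplex (PQS) regions and 1.0 at the non-PQS region for
the NPM antibody, with Ct noise of 0.15 cycles at n = 3 replicates —
under which the PQS-significant / non-PQS-n.s. decision pattern is
recovered in ≥ 90% of seeded runs.

## Problem sizes used by the tests and acceptance script

Heavy simulation checks run on a compact geometry with the same
structure and SNR regime as the default spec (200×200 px fields, nucleus
radius 85 px, six nucleoli of radius 9 px per nucleus, 72 rays at 0.4 px
step), chosen so that a 60-nucleolus condition dataset is produced by
ten fields in about a second. Segmentation recovery is scored on the
full default geometry over 20 seeds; type-I simulations use 1000
replicates; the permutation reference uses 10⁵ resamples; the
condition-comparison experiment uses 100 runs in the test suite and 40
in the acceptance script. These sizes are stated here so that anyone
rescaling them knows what the shipped numbers were measured on.

## Known limitations

* The boundary rule takes the *first* inside→outside crossing; for
  strongly concave outlines r_b underestimates the outline along some
  directions (later re-entries still contribute valid samples with their
  d). Centroids falling outside their region raise an error suggesting
  exclusion rather than guessing a pole.
* 2D profiling of 3D stacks uses the single plane nearest the 3D
  centroid; full spherical sampling is out of scope.
* The generator's nucleoli are star-convex by construction; segmentation
  and profiling have not been validated on fragmented or lobed nucleoli.
* Pooling nucleoli across cells treats them as independent; a
  mixed-effects treatment is deliberately out of scope.
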