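# nucleoprofile

Quantification of how a fluorescent signal distributes relative to
core–shell nuclear condensates (nucleoli), for microscopists analysing
multi-channel fluorescence images of nuclei. The motivating use case is
mapping torsionally underwound DNA — labelled by a biotinylated psoralen
intercalator — against the nucleolar architecture in which the fibrillar
centre and dense fibrillar component form a core and the granular
component (marked by nucleophosmin, NPM) forms a shell.

The package provides, end to end:

* a **synthetic image generator** with analytic ground truth: nuclei
  containing core–shell nucleoli whose per-channel intensities follow
  known radial laws, with Gaussian PSF blur, Poisson shot noise, Gaussian
  read noise and per-nucleolus brightness jitter;
* **threshold-based segmentation** of nuclei (global Otsu on the nuclear
  marker) and nucleoli (per-nucleus Otsu on the shell marker, hole-filled
  so the outline is the filled NPM territory);
* **boundary-normalized radial profiling**: for each nucleolus, rays are
  cast from the binary centroid; along a ray at angle θ, the boundary
  radius r_b(θ) is the first inside→outside crossing of the mask, and a
  sample at radius r gets the normalized distance

      d = r / r_b(θ)

  so that d = 1 is the nucleolar outline, d ∈ [0, 0.5] the deep interior
  ("inside") and d ∈ [1.5, 2.0] the surrounding nucleoplasm ("outside").
  Profiles are binned on a uniform d grid, optionally smoothed by a
  centred moving average, and aggregated across nucleoli (mean ± s.d.,
  with the nucleolus as the sampling unit);
* the **statistical layer** used for condition comparisons: a from-scratch
  two-sided Mann–Whitney U test (exact by enumeration for small tie-free
  samples; tie-corrected normal approximation with continuity correction
  otherwise), a from-scratch two-sided Steel–Dwass all-pairs test whose
  pairwise statistics are referred to the studentized range Q_{k,∞}
  (survival function integrated numerically to 1e-8), and paired /
  one-sample t tests;
* **assay helpers**: the crosslink-protection fraction
  (non-denatured band / total band) for gel assays, and ChIP-qPCR percent
  input, `%input = 100 · f · 2^(Ct_input − Ct_IP)` for an input aliquot
  fraction f (default 2%), with control-condition normalization and
  one-sample t tests against 1.

## Worked example

Simulate a control field, segment it, profile the target channel and
extract window means:

```r
library(nucleoprofile)

spec <- synthetic_spec(condition = "control", seed = 1)
sim  <- generate_field(spec)

nuclei   <- segment_nuclei(sim$field)
nucleoli <- segment_nucleoli(sim$field, nuclei)

pf <- profile_field(sim$field, nucleoli, nuclei, role = "target")
wm <- window_means_table(pf$profiles)
wm[, c("nucleolus_id", "inside_mean", "outside_mean")]
#>   nucleolus_id inside_mean outside_mean
#> 1            1       0.576        0.191
#> 2            2       0.587        0.194
```

The control preset draws the target signal with an inside/outside ratio
of 3 (nucleoplasm level 0.2, core level 0.6); the recovered window means
sit on those values up to noise. Comparing a control against an
"RNA-polymerase-I-inhibited"-like condition (core enrichment flattened
to ratio 1) over a few simulated fields:

```r
cfg <- run_config(conditions = c("control", "RNAPI_inhibited_like"),
                  n_fields = 4,
                  spec_args = list(nucleoli_per_nucleus = c(2, 3)),
                  seed = 42)
res <- run_pipeline(cfg, "out/")
res$stats[, c("window", "test", "statistic", "p_value")]
#>    window           test statistic p_value
#> 1  inside Mann-Whitney U        90 0.00028
#> 2 outside Mann-Whitney U        50 0.71330
```

The flattening is detected inside the nucleolus (p = 2.8e-4) and, as it
should be, not outside (p = 0.71): the nucleoplasm is identical in both
conditions. `out/` receives the per-nucleolus profile CSV, window-means
CSV, aggregated summary, stats table, label-mask TIFFs and a JSON
manifest; reruns with the same config and seed are byte-identical.

A thin command-line front end over the same functions is installed at
`inst/cli/nucleoprofile.R` (subcommands `simulate`, `segment`, `profile`,
`compare`, `assay-crosslink`, `assay-chip`, `run`, `lineprofile`).

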