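---
title: "Statistical methods behind immunosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind immunosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosig)
```

immunosig analyzes peptide immunoarray experiments: arrays of short
peptides probed with serum from two cohorts (here called *control* and
*treatment*), scanned to per-spot fluorescence intensities. This vignette
documents the statistical model, the estimators, the parameter choices and
their rationale, and the known limitations. It is a methods reference, not
a tutorial; the README walks through a worked example.

## Data model and assumptions

Each array file (GenePix GPR in ATF 1.0 form, or a plain four-column spot
CSV) yields per-spot foreground and local background medians, in relative
fluorescence units (RFU). The analysis assumes:

- Spots for the same peptide (replicates) are exchangeable up to spatial
  artifacts.
- Cohort membership is assigned per file at upload, not stored in the file.
- Measurements in different samples share a common peptide panel; a
  mismatched panel is an error, not something to reconcile silently.

## Intensity modes

Three per-spot intensity definitions are supported:

- **foreground**: the raw foreground median `f_l`.
- **background subtraction**: `f_l - b_l`, with `b_l` the spot's local
  background.
- **background scaling**: `f_s = f_l * b_m / b_l - b_m`, where `b_m` is the
  median background over the whole array.

Background scaling models the local background as a proxy for local
detector gain: dividing by `b_l` and re-multiplying by `b_m` equalizes a
multiplicative spatial gain before subtracting a common background level.
When `b_l = b_m` everywhere it reduces exactly to subtraction. Local
backgrounds are floored at `max(1, 1e-6 * b_m)` (with a warning) so a
zero-background spot cannot produce an infinite ratio. Negative corrected
intensities are retained: they are informative about the noise floor and
are handled downstream by rank-based testing.

## Replicate aggregation

Replicate spots are identified by a trailing replicate token on the spot ID
(pattern `([._]r?[0-9]+)$`) and grouped by peptide sequence. The aggregate
is the **median** (`aggregate = "median"`), chosen over the mean for
resistance to single-spot artifacts (dust, comets). A replicate coefficient
of variation is reported per peptide for quality control. `aggregate =
"none"` keeps every spot as its own feature.

## Cross-sample normalization

- **none**: intensities pass through unchanged.
- **quantile**: every sample's empirical distribution is mapped onto the
  average order-statistic distribution (via `limma::normalizeQuantiles`
  with `ties = TRUE`, so tied values receive the mean of the quantiles they
  span — ties in, ties out). Rank order within a sample is preserved by
  construction.
- **vsn**: a variance-stabilizing transformation
  `h_i(x) = arsinh((x - a_i) / b_i)` with one offset `a_i` and one scale
  `b_i > 0` per sample, appropriate when noise is multiplicative at high
  intensity and additive near the floor.

### VSN estimator and identifiability

The per-sample parameters are fit by maximizing a profile likelihood: for
parameter vector `(a, b)`, the transformed values are row-centered, and the
objective is

```
0.5 * n * log(rss / n) + 0.5 * sum(log((x - a)^2 + b^2))
```

(residual sum of squares of the row-centered transform plus the log of the
transform's Jacobian). Optimization is BFGS from moment-based starts
(`a0 = median`, `b0 = MAD`), followed by three least-trimmed-squares
refits that drop the 10% of peptides with the largest residuals
(`trim = 0.9`), which keeps a small fraction of truly differential
peptides from dragging the fit.

The scales `b_i` are identifiable only **up to one common factor**: a
global rescaling of all `b_i` is absorbed by the latent peptide means. The
fit is therefore gauge-fixed so that the geometric mean of the `b_i`
equals the geometric mean of the per-sample MADs, and any comparison
against known truth must compare `b_i` ratios, not absolute values. The
offsets obey `a_i ≈ offset_i + scale_i * c` for one common constant `c`.
The acceptance suite verifies recovery under this gauge to within 10%
relative error on data generated from the matching affine model.

## Differential reactivity screening

Each peptide is tested with a two-sided **Mann-Whitney U** (Wilcoxon
rank-sum) test comparing its per-sample intensities between cohorts. The
exact null distribution is used when the combined sample count is at most
12 and there are no ties; otherwise the normal approximation with tie and
continuity corrections. A peptide whose values are all identical across
both cohorts is reported with p = 1 and a warning rather than an error.
Effect size is the difference of cohort means (`delta_rfu`, treatment
minus control), reported alongside per-cohort means and variances.

P-values are corrected with the **Benjamini-Hochberg** step-up procedure.
The available FDR thresholds are 0.01, 0.05, 0.10, and 0.25.

Rank-based testing is used because array intensity distributions are
heavy-tailed and the per-cohort sample sizes (tens) are too small to lean
on normality; the cost is reduced power at very small n, which the package
warns about below 3 samples per cohort.

## Subset rules

Large panels cannot be plotted peptide-by-peptide, so heat maps, swarm
plots, and dendrograms operate on a restricted subset. The rank cutoff is
one of **20, 50, or 100** peptides; the direction restriction is `up`,
`down`, or `any`. Three lists are produced:

- `by_p`: lowest adjusted p-values (after the direction sign filter —
  a peptide with the "wrong" sign is excluded even if highly significant,
  because the user asked for one direction);
- `by_effect`: greatest effect sizes under `up`, least under `down`,
  largest `|delta|` under `any`;
- `by_both`: the `by_effect` ranking restricted to peptides with adjusted
  p below the FDR threshold (this list may be shorter than the cutoff).

Ties are broken by larger `|delta|`, then lexicographic spot ID, so
results are reproducible across platforms.

## Clustering and embedding

Samples are represented as points whose coordinates are peptide
intensities. The **dendrogram** uses the subset coordinates (default
`by_both`; configurable to `by_p` or `by_effect`), so with cutoff 20 each
sample is a 20-dimensional point. **k-means (k = 2)** and **PCA** use all
peptides with no subset restriction. Hierarchical clustering is UPGMA
(average linkage, Euclidean distance); two-group labels come from the
root bifurcation. Samples are pre-sorted lexicographically by ID before
clustering, which pins down the resolution of equal-height merges.
k-means uses Lloyd's algorithm with 10 seeded restarts; it is
deterministic given the run seed. Cluster quality is scored with
Davies-Bouldin, mean Silhouette width, and Calinski-Harabasz; indices
that are undefined for a degenerate clustering (coincident centroids,
all-singleton clusters) are reported as `NA`.

## Visualization data

All plot builders return tibbles, and rendering is a separate step
(`autoplot()` then `render()`), so every figure's underlying numbers are
exportable and testable. Boxplots use type-7 quartiles and Tukey 1.5 IQR
whiskers; band profiles show cohort means with plus/minus one standard
deviation (n-1) bands and an effect panel equal to the synoptic table's
`delta_rfu`; positional heatmaps and epitope maps order peptides from the
N- to the C-terminus; the epitope map stacks overlapping peptides into
lanes by greedy first-fit and colors segments on a diverging scale
symmetric about zero.

## The synthetic-data generator

`sim_spec()` / `simulate_experiment()` generate fixtures bottom-up:

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `protein_length` | 1273 | residues | a typical large viral surface protein |
| `peptide_length` / `overlap` | 15 / 11 | residues | the commercial array design emulated |
| `replicates` | 3 | spots | triplicate printing |
| `n_control` / `n_treatment` | 20 / 22 | samples | the emulated study's cohort sizes |
| `baseline_mean` | 1000 | RFU | mid-range scanner signal |
| `noise_sd` | 100 | RFU | additive scanner floor, 10% of baseline |
| `mult_cv` | 0.1 | log-sd | multiplicative spot-to-spot noise |
| `peptide_sdlog` | 0.5 | log-sd | wide spread of per-peptide reactivity |
| `differential_fraction` | 0.05 | — | a sparse reactive signature |
| `effect_size` | 4 | multiples of `noise_sd` | a clearly detectable spike |
| `background_mean` | 100 | RFU | 10% of baseline |
| `background_gradient` | 0.2 | — | a visible but moderate spatial artifact |

Signal is a per-peptide log-normal baseline times multiplicative noise
plus an additive Gaussian floor, with a treatment-only additive spike on
the differential peptides — the structure VSN assumes, which makes the
VSN recovery test well-posed. The spatial gradient multiplies **both** the
background and the foreground (a detector-gain model): that is precisely
the artifact background scaling removes and background subtraction does
not, so the generator encodes the motivation for Eq.-style scaling
structurally. Arrays are laid out replicate-major (the whole panel printed
once per replicate block), so a peptide's replicates sit at different
positions along the gradient. Intensities are rounded to whole RFU as a
scanner would report. The same spec and seed reproduce byte-identical
files.

The generator does **not** emulate sequence-dependent binding,
cross-reactivity between similar peptides, control spots, multi-block
print layouts, or scanner saturation.

## Problem sizes and reproducibility

The acceptance suite exercises the sizes its statements prescribe: 2,000
peptides (protein length 8011) with 10+10 samples for calibration and
power, 500 peptides (protein length 2011) for ranking and clustering
properties, and the generator defaults (15/11 tiling, triplicates, 20+22
samples) for design-emulation checks. Every stochastic stage takes an
explicit seed, run metadata records configuration, input digests and
package versions, and a rerun with identical inputs reproduces the
synoptic CSV byte for byte.

## Limitations

- Rank-based testing has limited power below roughly 5 samples per
  cohort; with 2+2 designs only extreme configurations reach p < 0.05.
- The VSN fit assumes the arsinh-affine noise model; data with strong
  rank-breaking distortions should use quantile normalization instead
  (the fit aborts with that suggestion if it fails to converge).
- Background scaling assumes local background is a valid gain proxy; on
  arrays where background is dominated by autofluorescence unrelated to
  gain, subtraction may be preferable.
- `delta_rfu` is a difference of means on the normalized scale; after
  VSN's arsinh transform it is a difference of transformed means, not RFU.
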