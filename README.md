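# immunosig

Differential reactivity analysis of peptide immunoarrays.

Peptide immunoarrays print thousands of short peptides — for example,
15-mers tiling a viral protein with 11-residue overlap, in triplicate —
and probe them with serum. Antibodies binding a peptide raise its
fluorescence, so the scanned intensities form an antibody reactivity
profile ("immunosignature") per sample. Given two cohorts of such arrays
(control and treatment), immunosig answers: *which peptides react
differently between the cohorts, do the samples separate into the two
groups on that basis, and where on the source protein do the reactive
peptides sit?*

The pipeline is deliberately conventional and fully testable:

1. **Ingest** GenePix results files (GPR/ATF 1.0) or four-column spot
   CSVs, with flag-based spot exclusion and strict schema validation.
2. **Spot intensity** as raw foreground, background subtraction
   (`f - b`), or background scaling (`f * b_m / b_l - b_m`, which removes
   a multiplicative spatial gain that subtraction leaves behind).
3. **Replicate aggregation** by median per peptide.
4. **Normalization** across arrays: none, quantile, or an arsinh
   variance-stabilizing transform (VSN) fit per sample.
5. **Screening**: two-sided Mann-Whitney U test per peptide, Benjamini-
   Hochberg FDR correction, effect size as difference of cohort means.
6. **Subsets** for plotting: the 20/50/100 top peptides by adjusted p, by
   effect size, or by effect size among the FDR-significant ("by both"),
   optionally restricted to up- or down-regulated peptides.
7. **Clustering**: UPGMA dendrogram on the subset coordinates, k-means
   (k = 2) and PCA on all peptides, with Davies-Bouldin, Silhouette, and
   Calinski-Harabasz quality indices.
8. **Visualization**: boxplots, mean-variance/median plots, heatmaps,
   swarm/strip plots, positional band profiles, and epitope maps — each
   built as a tibble first, rendered with `autoplot()`/`render()`.

A synthetic-data generator (`sim_spec()`, `simulate_experiment()`) writes
matched GPR/CSV fixture sets with known ground truth, so the whole
pipeline is exercisable offline. See the methods vignette
(`vignettes/immunosig-methods.Rmd`) for the statistical details and
parameter rationale.

## Worked example

Simulate a small experiment — a 403-residue protein tiled into 98
15-mers, triplicate spots, 6 control and 6 treatment sera, 5% of peptides
spiked in treatment — then run the synoptic stage:

```r
library(immunosig)

spec <- sim_spec(seed = 42, protein_length = 403,
                 n_control = 6, n_treatment = 6)
fix_dir <- file.path(tempdir(), "fixtures")
sim <- simulate_experiment(spec, fix_dir)

cfg <- run_config(
  control_files   = file.path(fix_dir, sim$manifest$control_files),
  treatment_files = file.path(fix_dir, sim$manifest$treatment_files),
  intensity = "background_scale", normalization = "quantile",
  cutoff = 20, direction = "up", fdr = 0.25, seed = 42)
res <- run_synoptic(cfg, file.path(tempdir(), "results"))

head(dplyr::arrange(tidy(res$table), p_adj), 5)
#>   spot_id control_mean treatment_mean delta_rfu   p_raw p_adj
#> 1 PEP0033         496.           850.      353. 0.00216 0.106
#> 2 PEP0093        1446.          1143.     -303. 0.00216 0.106
#> 3 PEP0011        1136.          1600.      464. 0.00433 0.115
#> 4 PEP0014         957.          1517.      560. 0.00470 0.115
#> 5 PEP0045        2583.          2790.      207. 0.00858 0.168
```

Four of the five top-ranked peptides are true spikes (the ground truth in
`sim$truth` marks PEP0011, PEP0014, PEP0033, PEP0045, PEP0085; PEP0093 is
a chance false positive, flagged by its *negative* delta). Note the
honest small-sample behavior: with 6+6 samples the smallest achievable
exact p is 0.00216, so after BH correction over 98 peptides nothing
clears FDR 0.05 — hence FDR 0.25 here. The "up and significant" subset
then holds the four real spikes:

```r
res$subsets$by_both
#> [1] "PEP0014" "PEP0011" "PEP0033" "PEP0045"
```

and the dendrogram built on those four coordinates separates the cohorts
perfectly at its first bifurcation, which the quality indices reflect:

```r
res$dendrogram$labels
#> C01 C02 C03 C04 C05 C06 T01 T02 T03 T04 T05 T06
#>   1   1   1   1   1   1   2   2   2   2   2   2
res$quality
#>   method    davies_bouldin silhouette calinski_harabasz
#> 1 kmeans             1.82       0.132              3.01
#> 2 upgma_cut          0.630      0.536             22.7
```

The output directory now contains `synoptic_results.csv` (one row per
peptide, per-sample normalized intensities plus the test statistics),
`cluster_quality.csv`, `run_metadata.json` (config, seed, input digests,
versions), and the rendered plots.

The targeted stage is stateless: it reads back only the synoptic CSV plus
a targeting file mapping spot IDs to protein coordinates:

```r
tgt <- file.path(tempdir(), "targeting.csv")
readr::write_csv(tibble::tibble(
  pathogen = "simvirus", protein = "antigen",
  start = sim$truth$start, end = sim$truth$end,
  spot_id = sim$truth$peptide_id), tgt)

pd <- run_targeted(file.path(tempdir(), "results", "synoptic_results.csv"),
                   tgt, plot = "epitope",
                   out_dir = file.path(tempdir(), "results"))
head(tibble::as_tibble(pd), 3)
#>   spot_id start   end  lane delta_rfu
#> 1 PEP0001     1    15     1      34.7
#> 2 PEP0002     5    19     2     -11.2
#> 3 PEP0003     9    23     3     -30.3
```

`targeted_epitope.png` shows each peptide as a segment at its protein
position, stacked into lanes and colored by effect on a diverging scale
symmetric about zero (here ±560 RFU); `targeted_epitope_data.csv` holds
the numbers behind it. The other targeted plots are `heatmap`
(position-ordered per-sample heatmap), `line` (cohort mean ± SD band
profile with an effect panel), and `strip` (one dot per sample per
peptide, in a fixed sample order).

A command-line wrapper with `synoptic`, `targeted`, and `fixtures`
subcommands is installed at `system.file("cli", "immunosig", package =
"immunosig")`.

## Running the tests

```r
# from the package directory, against the installed package
testthat::test_dir("tests/testthat", package = "immunosig",
                   load_package = "installed")
```

or `Rscript -e 'devtools::test()'` from a checkout.

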