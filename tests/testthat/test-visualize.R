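toy_targeting <- function(spot_id, start, end, protein = "spike",
                          pathogen = "virus") {
  tt <- tibble::tibble(pathogen = pathogen, protein = protein,
                       start = as.integer(start), end = as.integer(end),
                       spot_id = spot_id)
  structure(tt, class = c("targeting_table", class(tt)))
}

test_that("distribution summaries compute Tukey boxplot statistics", {
  mat <- toy_matrix(cbind(1:5, c(2, 2, 2, 2, 2)),
                    c("control", "treatment"))
  s <- build_distribution_summaries(mat)
  b1 <- s$boxplot[1, ]
  expect_equal(b1$middle, 3)
  expect_equal(b1$lower, 2)
  expect_equal(b1$upper, 4)
  expect_length(b1$outliers[[1]], 0)
  # constant sample: zero-height box, no outliers
  b2 <- s$boxplot[2, ]
  expect_equal(b2$lower, b2$upper)
  expect_equal(b2$ymin, b2$ymax)
  expect_length(b2$outliers[[1]], 0)
  # mean-variance/median cover all peptides per cohort with no filtering
  expect_equal(nrow(s$mean_variance), 2 * nrow(mat))
  expect_equal(nrow(s$mean_median), 2 * nrow(mat))
})

test_that("homoscedastic null data shows no mean-variance trend", {
  spec <- sim_spec(seed = 42, protein_length = 8011, n_control = 5,
                   n_treatment = 5, differential_fraction = 0,
                   peptide_sdlog = 0, mult_cv = 0, background_gradient = 0)
  pl <- run_sim_pipeline(spec, normalization = "none")
  s <- build_distribution_summaries(pl$matrix)
  mv <- s$mean_variance[s$mean_variance$cohort == "control", ]
  rho <- cor(mv$mean, mv$variance, method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("positional heatmap orders rows N- to C-terminus and copies values", {
  vals <- matrix(c(10, 20, 30, 11, 21, 31), nrow = 3)
  tab <- toy_synoptic(c("A", "B", "C"), delta_rfu = c(1, 2, 3),
                      p_adj = c(0.1, 0.2, 0.3), values = vals)
  tt <- toy_targeting(c("C", "A", "B"), start = c(9, 1, 5),
                      end = c(23, 15, 19))
  hm <- build_positional_heatmap(tab, tt)
  expect_equal(hm$start, c(1, 5, 9))
  expect_equal(hm$spot_id, c("A", "B", "C"))
  sids <- attr(tab, "samples")$sample_id
  for (sid in sids) {
    expect_equal(hm[[sid]], tab[[sid]][match(hm$spot_id, tab$spot_id)])
  }
  expect_error(build_positional_heatmap(tab,
                 toy_targeting("ZZ", 1, 15)), "ZZ",
               class = "immunosig_validation_error")
})

test_that("synoptic heatmap variant orders rows by subset rank", {
  tab <- toy_synoptic(sprintf("P%d", 1:6), delta_rfu = c(5, -2, 4, 1, -3, 2),
                      p_adj = c(0.01, 0.5, 0.02, 0.6, 0.03, 0.7))
  sub <- select_subset(tab, subset_spec(cutoff = 20, direction = "any",
                                        fdr = 0.05))
  hm <- build_synoptic_heatmap(tab, sub$by_p)
  expect_equal(hm$spot_id, sub$by_p)
  expect_equal(hm$rank, seq_along(sub$by_p))
})

test_that("band profile centers, bands, and effect match hand arithmetic", {
  vals <- cbind(c(2, 8), c(4, 10), c(5, 1), c(7, 5))
  tab <- toy_synoptic(c("A", "B"), delta_rfu = c(3, -6), p_adj = c(0.5, 0.5),
                      values = vals,
                      cohorts = c("control", "control", "treatment", "treatment"))
  tt <- toy_targeting(c("A", "B"), start = c(1, 5), end = c(15, 19))
  bp <- build_band_profile(tab, tt)
  expect_equal(bp$control_center[1], 3)
  expect_equal(bp$control_lower[1], 3 - sqrt(2))
  expect_equal(bp$control_upper[1], 3 + sqrt(2))
  expect_equal(bp$effect, tab$delta_rfu[match(bp$spot_id, tab$spot_id)])
  expect_true(all(bp$control_lower <= bp$control_center),
              all(bp$control_center <= bp$control_upper))

  # identical cohorts: effect panel identically zero
  same <- cbind(c(2, 8), c(4, 10), c(2, 8), c(4, 10))
  tab0 <- toy_synoptic(c("A", "B"), delta_rfu = c(0, 0), p_adj = c(1, 1),
                       values = same,
                       cohorts = c("control", "control", "treatment", "treatment"))
  expect_equal(build_band_profile(tab0, tt)$effect, c(0, 0))
})

test_that("strip data keeps one fixed global sample order across strips", {
  vals <- matrix(seq_len(15), nrow = 3)
  tab <- toy_synoptic(c("A", "B", "C"), delta_rfu = 1:3, p_adj = rep(0.5, 3),
                      values = vals,
                      cohorts = c("control", "control", "treatment",
                                  "treatment", "treatment"))
  tt <- toy_targeting(c("A", "C"), start = c(1, 200), end = c(15, 214))
  sd1 <- build_strip_data(tab, targeting = tt)
  ord <- attr(sd1, "sample_order")
  for (p in levels(sd1$peptide)) {
    expect_equal(sd1$sample_id[sd1$peptide == p], ord)
  }
  expect_equal(unique(sd1$cohort[sd1$dot_order <= 2]), "control")

  # shuffling synoptic row order leaves the strip sample order unchanged
  tab_shuf <- immunosig:::new_synoptic_table(
    tibble::as_tibble(tab)[c(3, 1, 2), ], attr(tab, "samples"))
  sd2 <- build_strip_data(tab_shuf, targeting = tt)
  expect_equal(attr(sd2, "sample_order"), ord)
  expect_equal(sd2$value[sd2$peptide == "A"], sd1$value[sd1$peptide == "A"])

  # single sample -> one dot per strip
  tab1 <- toy_synoptic(c("A", "B"), delta_rfu = c(0, 0), p_adj = c(1, 1),
                       values = cbind(c(1, 2), c(3, 4)))
  s1 <- build_strip_data(tab1, peptides = c("A", "B"))
  expect_equal(sum(s1$peptide == "A"), 2L)

  # multi-protein targeting is rejected for strips
  tt2 <- toy_targeting(c("A", "B"), start = c(1, 1), end = c(15, 15),
                       protein = c("spike", "nucleoprotein"))
  expect_error(build_strip_data(tab, targeting = tt2), "single protein",
               class = "immunosig_validation_error")
})

test_that("epitope maps stack overlapping peptides and use a symmetric scale", {
  tab <- toy_synoptic(sprintf("P%d", 1:4), delta_rfu = c(10, -40, 25, 5),
                      p_adj = rep(0.5, 4))
  tt <- toy_targeting(sprintf("P%d", 1:4), start = c(1, 5, 9, 13),
                      end = c(15, 19, 23, 27))
  em <- build_epitope_map(tab, tt)
  expect_equal(em$lane, 1:4)   # each 15-mer overlaps the next three
  expect_equal(attr(em, "color_limits"), c(-40, 40))
  expect_equal(attr(em, "index_range"), c(1, 27))

  # negating the effects mirrors the scale about zero
  tab_neg <- toy_synoptic(sprintf("P%d", 1:4), delta_rfu = -c(10, -40, 25, 5),
                          p_adj = rep(0.5, 4))
  em_neg <- build_epitope_map(tab_neg, tt)
  expect_equal(attr(em_neg, "color_limits"), attr(em, "color_limits"))
  expect_equal(em_neg$delta_rfu, -em$delta_rfu)

  # zero effect sits at the scale midpoint
  tab0 <- toy_synoptic("P1", delta_rfu = 0, p_adj = 1)
  em0 <- build_epitope_map(tab0, toy_targeting("P1", 1, 15))
  expect_equal(mean(attr(em0, "color_limits")), 0)
  expect_equal(em0$delta_rfu, 0)

  # a positional gap in the targeting is rejected (contiguity required)
  tt_sep <- toy_targeting(sprintf("P%d", 1:2), start = c(1, 40),
                          end = c(15, 54))
  expect_error(build_epitope_map(tab, tt_sep),
               class = "immunosig_validation_error")  # gap: not contiguous
})

test_that("rendering writes images without altering plot data", {
  tab <- toy_synoptic(sprintf("P%d", 1:4), delta_rfu = c(10, -40, 25, 5),
                      p_adj = rep(0.5, 4))
  tt <- toy_targeting(sprintf("P%d", 1:4), start = c(1, 5, 9, 13),
                      end = c(15, 19, 23, 27))
  em <- build_epitope_map(tab, tt)
  before <- tibble::as_tibble(em)
  dir <- withr::local_tempdir()
  for (fmt in c("png", "svg", "pdf")) {
    f <- file.path(dir, paste0("em.", fmt))
    render(em, f)
    expect_true(file.exists(f))
    expect_gt(file.size(f), 0)
  }
  expect_equal(tibble::as_tibble(em), before)

  bp <- build_band_profile(toy_synoptic(c("A", "B"), c(1, 2), c(0.5, 0.5),
                                        values = matrix(1:4, 2)),
                           toy_targeting(c("A", "B"), c(1, 5), c(15, 19)))
  f <- file.path(dir, "bp.png")
  render(bp, f)
  expect_gt(file.size(f), 0)

  expect_error(render(em, file.path(dir, "em.bmp")), "format",
               class = "immunosig_validation_error")
})
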