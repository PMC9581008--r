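test_that("protein tiling matches the window arithmetic", {
  w <- tile_protein(100, 15, 11)
  expect_equal(nrow(w), 23L)
  expect_equal(w$start[1], 1L)
  expect_equal(w$end[nrow(w)], 100L)
  expect_true(all(w$end - w$start + 1L == 15L))
  # consecutive windows overlap by the design overlap, except possibly the
  # appended terminal window
  ol <- w$end[-nrow(w)] - w$start[-1] + 1L
  expect_true(all(ol[-length(ol)] == 11L))

  # exact-fit lengths produce round window counts with no terminal patch
  w2000 <- tile_protein(8011, 15, 11)
  expect_equal(nrow(w2000), 2000L)
  expect_equal(w2000$end[2000], 8011L)
  expect_equal(nrow(tile_protein(2011, 15, 11)), 500L)

  expect_equal(nrow(tile_protein(15, 15, 11)), 1L)
  expect_error(tile_protein(10, 15, 11), class = "immunosig_validation_error")
})

test_that("simulated experiments are byte-identical under the same seed", {
  spec <- sim_spec(seed = 7, protein_length = 55, n_control = 2,
                   n_treatment = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(spec, d1)
  simulate_experiment(spec, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  expect_setequal(f1, c("C01.gpr", "C01.csv", "C02.gpr", "C02.csv",
                        "T01.gpr", "T01.csv", "T02.gpr", "T02.csv",
                        "manifest.json"))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the data files
  d3 <- withr::local_tempdir()
  simulate_experiment(sim_spec(seed = 8, protein_length = 55,
                               n_control = 2, n_treatment = 2), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "C01.gpr"))) ==
                 unname(tools::md5sum(file.path(d3, "C01.gpr"))))
})

test_that("matched GPR and CSV files parse to identical samples", {
  spec <- sim_spec(seed = 9, protein_length = 35, n_control = 1,
                   n_treatment = 1)
  d <- withr::local_tempdir()
  sim <- simulate_experiment(spec, d)
  g <- read_gpr(file.path(d, "C01.gpr"), sample_id = "C01",
                cohort = "control")
  s <- read_spot_csv(file.path(d, "C01.csv"), sample_id = "C01",
                     cohort = "control")
  expect_equal(g$spot_id, s$spot_id)
  expect_equal(g$sequence, s$sequence)
  expect_equal(g$foreground, s$foreground)
  expect_equal(g$background, s$background)
  # and both agree with the in-memory sample
  mem <- tibble::as_tibble(sim$samples[[1]])
  expect_equal(g$foreground, mem$foreground)
  expect_equal(g$background, mem$background)
})

test_that("the truth table marks the requested fraction with the stated effect", {
  spec <- sim_spec(seed = 10, protein_length = 2011, n_control = 1,
                   n_treatment = 1, differential_fraction = 0.1,
                   effect_size = 3, noise_sd = 100)
  sim <- simulate_samples(spec)
  expect_equal(nrow(sim$truth), 500L)
  expect_equal(sum(sim$truth$differential), 50L)
  expect_equal(unique(sim$truth$effect[sim$truth$differential]), 300)
  expect_equal(unique(sim$truth$effect[!sim$truth$differential]), 0)
  expect_equal(nchar(sim$truth$sequence), rep(15L, 500L))
  # every spot is printed in triplicate
  spots <- tibble::as_tibble(sim$samples[[1]])
  expect_equal(nrow(spots), 1500L)
  expect_true(all(table(spots$sequence[!duplicated(spots$spot_id)]) == 3L))
})

test_that("background scaling removes the spatial gain that subtraction leaves", {
  # flat true signal; any spatial trend in the corrected intensity is artifact
  spec <- sim_spec(seed = 11, protein_length = 2011, n_control = 1,
                   n_treatment = 1, differential_fraction = 0,
                   peptide_sdlog = 0, mult_cv = 0.02,
                   background_gradient = 0.5)
  sim <- simulate_samples(spec)
  spots <- tibble::as_tibble(sim$samples[[1]])
  pos <- seq_len(nrow(spots))
  b_m <- median(spots$background)
  sub <- compute_intensity(spots$foreground, spots$background, b_m,
                           "background_subtract")
  sca <- compute_intensity(spots$foreground, spots$background, b_m,
                           "background_scale")
  expect_gt(cor(sub, pos), 0.5)
  expect_lt(abs(cor(sca, pos)), 0.1)
})

test_that("the manifest records spec, cohorts, and ground truth", {
  spec <- sim_spec(seed = 12, protein_length = 55, n_control = 3,
                   n_treatment = 2, differential_fraction = 0.2)
  d <- withr::local_tempdir()
  sim <- simulate_experiment(spec, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$spec$seed, 12)
  expect_equal(man$spec$protein_length, 55)
  expect_equal(man$control_files, c("C01.gpr", "C02.gpr", "C03.gpr"))
  expect_equal(man$treatment_files, c("T01.gpr", "T02.gpr"))
  expect_equal(man$n_differential, sum(sim$truth$differential))
  expect_equal(man$truth$peptide_id, sim$truth$peptide_id)
  expect_equal(man$truth$differential, sim$truth$differential)
})

test_that("per-sample affine distortion is applied and validated", {
  aff <- list(c(0, 1), c(50, 2))
  spec <- sim_spec(seed = 13, protein_length = 35, n_control = 1,
                   n_treatment = 1, differential_fraction = 0,
                   sample_affine = aff)
  base <- sim_spec(seed = 13, protein_length = 35, n_control = 1,
                   n_treatment = 1, differential_fraction = 0)
  s_aff <- simulate_samples(spec)
  s_base <- simulate_samples(base)
  fg_aff <- tibble::as_tibble(s_aff$samples[[2]])$foreground
  fg_base <- tibble::as_tibble(s_base$samples[[2]])$foreground
  # affine applies before rounding, so allow 1 RFU of rounding slack
  expect_lte(max(abs(fg_aff - (50 + 2 * fg_base))), 2)

  expect_error(sim_spec(seed = 1, n_control = 2, n_treatment = 1,
                        sample_affine = list(c(0, 1))),
               class = "immunosig_validation_error")
})
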