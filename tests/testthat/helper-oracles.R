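# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# two-sided exact Mann-Whitney p by full enumeration of group assignments
enum_mw <- function(x, y) {
  m <- length(x); n <- length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    xs <- vals[idx]; ys <- vals[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# brute-force step-up BH: literal definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # running minimum from the largest rank down
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# build an array_sample directly from vectors
toy_sample <- function(spot_id, sequence, fg, bg, sample_id = "S1",
                       cohort = "control", flag = 0L) {
  spots <- tibble::tibble(spot_id = spot_id, sequence = sequence,
                          foreground = fg, background = bg,
                          flag = rep_len(flag, length(spot_id)))
  immunosig:::new_array_sample(spots, sample_id, cohort)
}

# build an intensity_matrix directly from a peptide x sample value matrix
toy_matrix <- function(vals, cohorts, peptide_ids = NULL) {
  stopifnot(ncol(vals) == length(cohorts))
  if (is.null(peptide_ids)) peptide_ids <- sprintf("P%02d", seq_len(nrow(vals)))
  sample_ids <- sprintf("%s%02d", ifelse(cohorts == "control", "C", "T"),
                        seq_along(cohorts))
  tab <- tibble::tibble(peptide_id = peptide_ids, sequence = peptide_ids)
  for (i in seq_along(sample_ids)) tab[[sample_ids[i]]] <- vals[, i]
  immunosig:::new_intensity_matrix(
    tab, tibble::tibble(sample_id = sample_ids, cohort = cohorts),
    list(intensity_mode = "foreground", aggregate = "median",
         normalization = "none"))
}

# build a synoptic_table directly from per-peptide statistics
toy_synoptic <- function(spot_id, delta_rfu, p_adj,
                         values = NULL, cohorts = c("control", "treatment")) {
  n <- length(spot_id)
  if (is.null(values)) {
    values <- matrix(rep(seq_len(n), length(cohorts)), nrow = n)
  }
  sample_ids <- sprintf("%s%02d", ifelse(cohorts == "control", "C", "T"),
                        seq_along(cohorts))
  tab <- tibble::tibble(spot_id = spot_id, sequence = spot_id)
  for (i in seq_along(sample_ids)) tab[[sample_ids[i]]] <- values[, i]
  ctrl <- values[, cohorts == "control", drop = FALSE]
  trt <- values[, cohorts == "treatment", drop = FALSE]
  tab$control_mean <- rowMeans(ctrl)
  tab$control_var <- apply(ctrl, 1, stats::var)
  tab$treatment_mean <- rowMeans(trt)
  tab$treatment_var <- apply(trt, 1, stats::var)
  tab$delta_rfu <- delta_rfu
  tab$p_raw <- p_adj
  tab$p_adj <- p_adj
  immunosig:::new_synoptic_table(
    tab, tibble::tibble(sample_id = sample_ids, cohort = cohorts))
}

# a small end-to-end simulated experiment, cached per test file run
run_sim_pipeline <- function(spec, normalization = "quantile",
                             mode = "foreground") {
  sim <- simulate_samples(spec)
  mat <- assemble_matrix(sim$samples, mode = mode)
  mat <- normalize_matrix(mat, method = normalization, seed = spec$seed)
  list(sim = sim, matrix = mat, table = build_synoptic_table(mat))
}

write_minimal_gpr <- function(path, rows,
                              cols = c("ID", "Name", "F635 Median",
                                       "B635 Median", "Flags")) {
  lines <- c("ATF\t1.0",
             sprintf("2\t%d", length(cols)),
             "\"Type=GenePix Results 3\"",
             "\"Wavelengths=635\"",
             paste(sprintf("\"%s\"", cols), collapse = "\t"),
             rows)
  writeLines(lines, path)
}
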