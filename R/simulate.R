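#' Specification of a simulated immunoarray experiment
#'
#' Defaults emulate the commercial pan-coronavirus array design and study
#' layout: 15-mer peptides tiled with 11 amino acid overlap along a source
#' protein, printed in triplicate, probed with 20 control and 22 treatment
#' sera. Signal is multiplicative log-normal on a per-peptide baseline with
#' an additive Gaussian scanner floor; the background carries a linear
#' spatial gradient and the same spatial gain multiplies the foreground
#' (detector-gain model), which is what background *scaling* corrects and
#' background *subtraction* does not.
#'
#' @param seed Integer seed; every draw is reproducible from it.
#' @param protein_length Length of the simulated source protein (residues).
#' @param peptide_length,overlap Tiling design (residues).
#' @param replicates Spots printed per peptide.
#' @param n_control,n_treatment Cohort sizes.
#' @param differential_fraction Fraction of peptides reactive in the
#'   treatment cohort.
#' @param effect_size Treatment shift on differential peptides, in
#'   multiples of `noise_sd`.
#' @param baseline_mean Mean true signal scale (RFU).
#' @param noise_sd Additive scanner noise standard deviation (RFU).
#' @param mult_cv Log-sd of the multiplicative signal noise.
#' @param peptide_sdlog Log-sd of the per-peptide baseline factor.
#' @param background_mean Mean local background (RFU).
#' @param background_gradient Amplitude of the linear spatial gain across
#'   the array (0 = spatially flat).
#' @param sample_affine Optional per-sample affine distortion: a list of
#'   `c(offset, scale)` pairs, one per sample (control block then
#'   treatment block), to exercise variance stabilizing normalization.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L, protein_length = 1273L, peptide_length = 15L,
                     overlap = 11L, replicates = 3L, n_control = 20L,
                     n_treatment = 22L, differential_fraction = 0.05,
                     effect_size = 4, baseline_mean = 1000, noise_sd = 100,
                     mult_cv = 0.1, peptide_sdlog = 0.5,
                     background_mean = 100, background_gradient = 0.2,
                     sample_affine = NULL) {
  stopifnot(overlap < peptide_length, replicates >= 1L, n_control >= 1L,
            n_treatment >= 1L, differential_fraction >= 0,
            differential_fraction <= 1)
  spec <- list(seed = as.integer(seed), protein_length = as.integer(protein_length),
               peptide_length = as.integer(peptide_length),
               overlap = as.integer(overlap), replicates = as.integer(replicates),
               n_control = as.integer(n_control),
               n_treatment = as.integer(n_treatment),
               differential_fraction = differential_fraction,
               effect_size = effect_size, baseline_mean = baseline_mean,
               noise_sd = noise_sd, mult_cv = mult_cv,
               peptide_sdlog = peptide_sdlog,
               background_mean = background_mean,
               background_gradient = background_gradient,
               sample_affine = sample_affine)
  if (!is.null(sample_affine) &&
      length(sample_affine) != spec$n_control + spec$n_treatment) {
    abort("sample_affine must have one (offset, scale) pair per sample.",
          class = "immunosig_validation_error")
  }
  structure(spec, class = "sim_spec")
}

#' Tile a protein with overlapping peptide windows
#'
#' Windows of `peptide_length` start at 1 and step by
#' `peptide_length - overlap`; if the final window falls short of the
#' C-terminus, one extra window ending exactly at `length` is appended so
#' the tail is covered.
#'
#' @param length Protein length (residues).
#' @param peptide_length,overlap Tiling design (residues).
#' @return A tibble of 1-based inclusive `start`/`end` positions.
#' @export
#' @examples
#' tile_protein(100, 15, 11)  # 23 windows
tile_protein <- function(length, peptide_length = 15L, overlap = 11L) {
  stopifnot(overlap < peptide_length)
  if (peptide_length > length) {
    abort("Peptide length exceeds the protein length.",
          class = "immunosig_validation_error")
  }
  step <- peptide_length - overlap
  starts <- seq.int(1L, length - peptide_length + 1L, by = step)
  ends <- starts + peptide_length - 1L
  if (ends[base::length(ends)] < length) {
    starts <- c(starts, length - peptide_length + 1L)
    ends <- c(ends, length)
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate an immunoarray experiment in memory
#'
#' Draws a random protein, tiles it per the spec, marks a random subset of
#' peptides as differentially reactive, and generates replicate spot-level
#' foreground/background intensities for every sample. Foreground values
#' carry the spatial gain that also shapes the background; intensities are
#' rounded to whole RFU as a scanner would report.
#'
#' @param spec A [sim_spec()].
#' @return A list: `samples` (list of `array_sample`), `truth` (tibble of
#'   `peptide_id`, `sequence`, `start`, `end`, `differential`, `effect`),
#'   `spec`.
#' @export
simulate_samples <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  protein <- paste(sample(AA20, spec$protein_length, replace = TRUE),
                   collapse = "")
  win <- tile_protein(spec$protein_length, spec$peptide_length, spec$overlap)
  n_pep <- nrow(win)
  pep_id <- sprintf("PEP%04d", seq_len(n_pep))
  pep_seq <- substring(protein, win$start, win$end)
  n_diff <- round(spec$differential_fraction * n_pep)
  diff_idx <- sort(sample.int(n_pep, n_diff))
  differential <- seq_len(n_pep) %in% diff_idx
  pep_factor <- rlnorm(n_pep, meanlog = 0, sdlog = spec$peptide_sdlog)

  n_s <- spec$n_control + spec$n_treatment
  sample_ids <- c(sprintf("C%02d", seq_len(spec$n_control)),
                  sprintf("T%02d", seq_len(spec$n_treatment)))
  cohorts <- rep(c("control", "treatment"),
                 c(spec$n_control, spec$n_treatment))

  # replicate-major layout: whole array printed once per replicate block,
  # so replicates of a peptide sit at different positions along the gradient
  n_spots <- n_pep * spec$replicates
  spot_pep <- rep(seq_len(n_pep), times = spec$replicates)
  spot_rep <- rep(seq_len(spec$replicates), each = n_pep)
  pos <- if (n_spots > 1L) (seq_len(n_spots) - 1) / (n_spots - 1) else 0
  gain <- 1 + spec$background_gradient * pos

  samples <- purrr::map(seq_len(n_s), function(i) {
    mu <- spec$baseline_mean * pep_factor +
      if (cohorts[i] == "treatment") {
        differential * spec$effect_size * spec$noise_sd
      } else 0
    signal <- mu[spot_pep] * exp(rnorm(n_spots, 0, spec$mult_cv))
    fg <- gain * signal + rnorm(n_spots, 0, spec$noise_sd)
    bg <- spec$background_mean * gain +
      rnorm(n_spots, 0, 0.05 * spec$background_mean)
    if (!is.null(spec$sample_affine)) {
      aff <- spec$sample_affine[[i]]
      fg <- aff[1] + aff[2] * fg
    }
    spots <- tibble::tibble(
      spot_id = sprintf("%s_r%d", pep_id[spot_pep], spot_rep),
      sequence = pep_seq[spot_pep],
      foreground = round(pmax(fg, 0)),
      background = round(pmax(bg, 0)),
      flag = 0L,
      block = 1L,
      row = ((seq_len(n_spots) - 1L) %/% 20L) + 1L,
      column = ((seq_len(n_spots) - 1L) %% 20L) + 1L
    )
    new_array_sample(spots, sample_ids[i], cohorts[i])
  })

  truth <- tibble::tibble(peptide_id = pep_id, sequence = pep_seq,
                          start = win$start, end = win$end,
                          differential = differential,
                          effect = ifelse(differential,
                                          spec$effect_size * spec$noise_sd, 0))
  list(samples = samples, truth = truth, spec = spec)
}

format_gpr_lines <- function(sample) {
  spots <- tibble::as_tibble(sample)
  header_records <- c("\"Type=GenePix Results 3\"", "\"Wavelengths=635\"")
  cols <- c("Block", "Row", "Column", "ID", "Name", "F635 Median",
            "B635 Median", "Flags")
  data <- sprintf("%d\t%d\t%d\t\"%s\"\t\"%s\"\t%d\t%d\t%d",
                  spots$block %||% 1L, spots$row %||% 1L,
                  spots$column %||% 1L, spots$spot_id, spots$sequence,
                  as.integer(spots$foreground), as.integer(spots$background),
                  spots$flag)
  c("ATF\t1.0",
    sprintf("%d\t%d", length(header_records), length(cols)),
    header_records,
    paste(sprintf("\"%s\"", cols), collapse = "\t"),
    data)
}

#' Write a simulated experiment to disk as matched GPR and CSV files
#'
#' For every sample, one GPR (ATF 1.0) file and one equivalent four-column
#' CSV are written, plus a `manifest.json` recording the spec, file lists
#' per cohort, and the ground-truth differential peptides. Re-running with
#' the same spec produces byte-identical files.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the simulation list from [simulate_samples()] with a
#'   `manifest` element appended.
#' @export
simulate_experiment <- function(spec, out_dir) {
  sim <- simulate_samples(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir),
          class = "immunosig_io_error")
  }
  files <- purrr::map_chr(sim$samples, function(s) {
    sid <- attr(s, "sample_id")
    gpr <- file.path(out_dir, paste0(sid, ".gpr"))
    csv <- file.path(out_dir, paste0(sid, ".csv"))
    readr::write_lines(format_gpr_lines(s), gpr)
    spots <- tibble::as_tibble(s)
    readr::write_csv(tibble::tibble(ID = spots$spot_id,
                                    Sequence = spots$sequence,
                                    Foreground = as.integer(spots$foreground),
                                    Background = as.integer(spots$background)),
                     csv, progress = FALSE)
    sid
  })
  cohorts <- purrr::map_chr(sim$samples, function(s) attr(s, "cohort"))
  manifest <- list(
    spec = unclass(sim$spec)[setdiff(names(sim$spec), "sample_affine")],
    sample_affine = sim$spec$sample_affine,
    control_files = paste0(files[cohorts == "control"], ".gpr"),
    treatment_files = paste0(files[cohorts == "treatment"], ".gpr"),
    n_differential = sum(sim$truth$differential),
    truth = sim$truth
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$manifest <- manifest
  invisible(sim)
}
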