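#' Configuration of a synoptic analysis run
#'
#' @param control_files,treatment_files Character vectors of input files
#'   (GPR or spot CSV; format detected per file by extension/content), one
#'   file per array, in upload order.
#' @param intensity Intensity mode, see [compute_intensity()].
#' @param aggregate Replicate handling, see [aggregate_replicates()].
#' @param normalization `"none"`, `"quantile"`, or `"vsn"`.
#' @param fdr,cutoff,direction Subset rules, see [subset_spec()].
#' @param seed Integer seed used for every stochastic stage (VSN fit,
#'   k-means restarts, plot jitter).
#' @param plots Which plot families to render: any of `"boxplot"`,
#'   `"mean_variance"`, `"mean_median"`, `"heatmap"`, `"swarm"`,
#'   `"dendrogram"`, `"cluster"`.
#' @param dendrogram_subset Which subset list feeds the dendrogram
#'   coordinates: `"by_both"` (default), `"by_p"`, or `"by_effect"`.
#' @param exclude_flagged Drop GPR spots with negative quality flags.
#' @param gpr_mapping A [column_mapping()] for GPR inputs.
#' @return A `run_config` list.
#' @export
run_config <- function(control_files, treatment_files,
                       intensity = c("background_scale", "foreground",
                                     "background_subtract"),
                       aggregate = c("median", "none"),
                       normalization = c("quantile", "none", "vsn"),
                       fdr = 0.05, cutoff = 50L,
                       direction = c("any", "up", "down"),
                       seed = 1L,
                       plots = c("boxplot", "mean_variance", "mean_median",
                                 "heatmap", "swarm", "dendrogram", "cluster"),
                       dendrogram_subset = c("by_both", "by_p", "by_effect"),
                       exclude_flagged = TRUE,
                       gpr_mapping = column_mapping()) {
  structure(list(control_files = control_files,
                 treatment_files = treatment_files,
                 intensity = match.arg(intensity),
                 aggregate = match.arg(aggregate),
                 normalization = match.arg(normalization),
                 fdr = fdr, cutoff = as.integer(cutoff),
                 direction = match.arg(direction), seed = as.integer(seed),
                 plots = plots,
                 dendrogram_subset = match.arg(dendrogram_subset),
                 exclude_flagged = exclude_flagged,
                 gpr_mapping = gpr_mapping),
            class = "run_config")
}

read_array_file <- function(path, cohort, config) {
  first <- readr::read_lines(path, n_max = 1L)
  if (grepl("^ATF", first)) {
    read_gpr(path, mapping = config$gpr_mapping,
             exclude_flagged = config$exclude_flagged, cohort = cohort)
  } else {
    read_spot_csv(path, cohort = cohort)
  }
}

#' Run the synoptic analysis stage
#'
#' The fixed pipeline: read every array file, compute spot intensities
#' under the selected mode, aggregate replicate spots, assemble the
#' peptide-by-sample matrix, normalize, test every peptide
#' (Mann-Whitney), adjust (Benjamini-Hochberg), form the rank-cutoff
#' subsets, cluster, and write the results: the synoptic CSV, the
#' cluster-quality table, the selected plots, and a run-metadata JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `synoptic_table`, the normalized
#'   `intensity_matrix`, the subset lists, cluster results, quality table,
#'   and the output directory.
#' @export
run_synoptic <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$control_files) < 1L) {
    abort("No control files supplied.", class = "immunosig_validation_error")
  }
  if (length(config$treatment_files) < 1L) {
    abort("No treatment files supplied.", class = "immunosig_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- c(
    purrr::map(config$control_files, read_array_file, cohort = "control",
               config = config),
    purrr::map(config$treatment_files, read_array_file, cohort = "treatment",
               config = config)
  )
  mat <- assemble_matrix(samples, mode = config$intensity,
                         aggregate = config$aggregate)
  mat <- normalize_matrix(mat, method = config$normalization,
                          seed = config$seed)
  table <- build_synoptic_table(mat)
  write_synoptic_csv(table, file.path(out_dir, "synoptic_results.csv"))
  spec <- subset_spec(cutoff = config$cutoff, direction = config$direction,
                      fdr = config$fdr)
  subsets <- select_subset(table, spec)

  vec_all <- sample_vectors(table)
  km <- kmeans2(vec_all, seed = config$seed)
  quality <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(method = "kmeans"),
                     quality_indices(vec_all, km$labels)))
  dendro <- NULL
  dsub <- subsets[[config$dendrogram_subset]]
  if (length(dsub) >= 1L) {
    vec_sub <- sample_vectors(table, peptides = dsub)
    dendro <- upgma_tree(vec_sub)
    quality <- dplyr::bind_rows(quality,
      dplyr::bind_cols(tibble::tibble(method = "upgma_cut"),
                       quality_indices(vec_sub, dendro$labels)))
  }
  readr::write_csv(quality, file.path(out_dir, "cluster_quality.csv"),
                   progress = FALSE)

  summaries <- build_distribution_summaries(mat)
  emit <- function(name, plot) {
    render(plot, file.path(out_dir, paste0(name, ".png")))
  }
  if ("boxplot" %in% config$plots) emit("boxplot", plot_boxplots(summaries))
  if ("mean_variance" %in% config$plots) {
    emit("mean_variance", plot_mean_spread(summaries, "variance"))
  }
  if ("mean_median" %in% config$plots) {
    emit("mean_median", plot_mean_spread(summaries, "median"))
  }
  if ("heatmap" %in% config$plots && length(subsets$by_p)) {
    emit("heatmap_by_p", autoplot(build_synoptic_heatmap(table, subsets$by_p)))
  }
  if ("swarm" %in% config$plots && length(subsets$by_p)) {
    emit("swarm_by_p",
         autoplot(build_strip_data(table, peptides = subsets$by_p),
                  seed = config$seed))
  }
  if ("dendrogram" %in% config$plots && !is.null(dendro)) {
    co <- attr(vec_all, "cohort")
    emit("dendrogram", plot_dendrogram(dendro, color_by_cohort = FALSE))
    emit("dendrogram_cohort",
         plot_dendrogram(dendro, color_by_cohort = TRUE, cohorts = co))
  }
  if ("cluster" %in% config$plots) {
    emb <- pca_embed(vec_all)
    emit("pca_kmeans", plot_pca(emb, labels = km$labels,
                                color_by_cohort = FALSE))
    emit("pca_kmeans_cohort", plot_pca(emb, labels = km$labels,
                                       color_by_cohort = TRUE))
  }

  metadata <- list(
    config = list(
      intensity = config$intensity, aggregate = config$aggregate,
      normalization = config$normalization, fdr = config$fdr,
      cutoff = config$cutoff, direction = config$direction,
      seed = config$seed, dendrogram_subset = config$dendrogram_subset,
      control_files = config$control_files,
      treatment_files = config$treatment_files
    ),
    input_digests = vapply(c(config$control_files, config$treatment_files),
                           function(f) unname(tools::md5sum(f)), ""),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("immunosig"))
  )
  jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = table, matrix = mat, subsets = subsets,
                 kmeans = km, dendrogram = dendro, quality = quality,
                 out_dir = out_dir))
}

#' Run a targeted visualization
#'
#' Stateless second stage: reads only the synoptic results CSV and the
#' targeting CSV, builds the requested plot's data, and writes both the
#' image and the plot data as CSV alongside it.
#'
#' @param synoptic_csv Path to the synoptic results CSV (layout of
#'   [write_synoptic_csv()]).
#' @param targeting_csv Path to the targeting file (see
#'   [read_targeting()]).
#' @param plot One of `"heatmap"`, `"line"`, `"strip"`, `"epitope"`.
#' @param out_dir Output directory.
#' @param seed Seed for strip-plot jitter.
#' @return Invisibly, the plot-data object.
#' @export
run_targeted <- function(synoptic_csv, targeting_csv,
                         plot = c("heatmap", "line", "strip", "epitope"),
                         out_dir, seed = 1L) {
  plot <- match.arg(plot)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_synoptic_csv(synoptic_csv)
  targeting <- read_targeting(targeting_csv,
                              require_contiguous = plot != "strip")
  pd <- switch(plot,
               heatmap = build_positional_heatmap(table, targeting),
               line = build_band_profile(table, targeting),
               strip = build_strip_data(table, targeting = targeting),
               epitope = build_epitope_map(table, targeting))
  p <- if (plot == "strip") autoplot(pd, seed = seed) else autoplot(pd)
  render(p, file.path(out_dir, paste0("targeted_", plot, ".png")))
  readr::write_csv(tibble::as_tibble(pd),
                   file.path(out_dir, paste0("targeted_", plot, "_data.csv")),
                   progress = FALSE)
  invisible(pd)
}
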