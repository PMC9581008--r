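#' Distribution summaries for the whole experiment
#'
#' Builds the data behind the synoptic distribution plots, always over all
#' peptides with no subset restriction:
#' \describe{
#'   \item{boxplot}{per sample: quartiles (linear interpolation), median,
#'     Tukey whiskers at 1.5 IQR, and outliers beyond them; control
#'     samples are styled red and treatment samples white when plotted.}
#'   \item{mean_variance}{per peptide within each cohort, to check for
#'     heteroscedasticity.}
#'   \item{mean_median}{per peptide within each cohort, to check for
#'     skew.}
#' }
#'
#' @param matrix An `intensity_matrix` (normalized or not).
#' @return A list of three tibbles: `boxplot` (sample_id, cohort, whisker
#'   and quartile columns, list-column `outliers`), `mean_variance`, and
#'   `mean_median` (cohort, peptide_id, and the two statistics).
#' @export
build_distribution_summaries <- function(matrix) {
  samples <- attr(matrix, "samples")
  vals <- intensity_values(matrix)
  box <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    v <- vals[, i]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    tibble::tibble(
      sample_id = samples$sample_id[i], cohort = samples$cohort[i],
      ymin = min(inside), lower = q[1], middle = q[2], upper = q[3],
      ymax = max(inside),
      outliers = list(v[v < lo_fence | v > hi_fence])
    )
  })
  per_cohort <- function(stat) {
    purrr::map_dfr(c("control", "treatment"), function(co) {
      m <- vals[, samples$cohort == co, drop = FALSE]
      tibble::tibble(cohort = co, peptide_id = matrix$peptide_id,
                     mean = rowMeans(m),
                     value = apply(m, 1, stat))
    })
  }
  mv <- per_cohort(var); names(mv)[names(mv) == "value"] <- "variance"
  mm <- per_cohort(median); names(mm)[names(mm) == "value"] <- "median"
  list(boxplot = box, mean_variance = mv, mean_median = mm)
}

match_targeting <- function(table, targeting, require_contiguous = TRUE) {
  validate_targeting(targeting, require_contiguous = require_contiguous)
  missing <- setdiff(targeting$spot_id, table$spot_id)
  if (length(missing)) {
    abort(sprintf("Targeting spot ID(s) absent from the synoptic table: %s.",
                  paste(head(missing, 10L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  idx <- match(targeting$spot_id, table$spot_id)
  dplyr::bind_cols(targeting[, c("pathogen", "protein", "start", "end", "spot_id")],
                   tibble::as_tibble(table)[idx, setdiff(names(table), "spot_id")])
}

#' Positional heatmap data (targeted)
#'
#' Per-sample normalized intensities for the targeted peptides, rows
#' ordered by start position along the source protein (N-terminus to
#' C-terminus), columns ordered control block then treatment block. Cell
#' values are taken verbatim from the synoptic table.
#'
#' @param table A `synoptic_table` (typically re-read from the synoptic
#'   CSV).
#' @param targeting A `targeting_table`; must cover a contiguous run of a
#'   single protein.
#' @return A `positional_heatmap` tibble: `spot_id`, `protein`, `start`,
#'   `end`, then one column per sample; sample metadata as attribute.
#' @export
build_positional_heatmap <- function(table, targeting) {
  samples <- attr(table, "samples")
  j <- match_targeting(table, targeting, require_contiguous = TRUE)
  j <- j[order(j$start, j$end), ]
  out <- j[, c("spot_id", "protein", "start", "end", samples$sample_id)]
  structure(out, class = c("positional_heatmap", class(out)),
            samples = samples)
}

#' Synoptic heatmap data (subset-ranked)
#'
#' The untargeted heatmap variant: rows are the peptides of a
#' [select_subset()] list, in subset rank order rather than protein
#' position.
#'
#' @param table A `synoptic_table`.
#' @param peptides Character vector of spot IDs in rank order (one element
#'   of a [select_subset()] result).
#' @return A `synoptic_heatmap` tibble: `spot_id`, `rank`, then one column
#'   per sample.
#' @export
build_synoptic_heatmap <- function(table, peptides) {
  samples <- attr(table, "samples")
  missing <- setdiff(peptides, table$spot_id)
  if (length(missing)) {
    abort(sprintf("Subset spot ID(s) absent from the synoptic table: %s.",
                  paste(head(missing, 10L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  idx <- match(peptides, table$spot_id)
  out <- dplyr::bind_cols(
    tibble::tibble(spot_id = peptides, rank = seq_along(peptides)),
    tibble::as_tibble(table)[idx, samples$sample_id])
  structure(out, class = c("synoptic_heatmap", class(out)), samples = samples)
}

#' Line-graph (immunosignature) band profile
#'
#' Per targeted peptide position: cohort mean as the line center, a band
#' of plus/minus one standard deviation (n-1), and an effect panel equal
#' to the treatment center minus the control center (identical to the
#' synoptic table's delta RFU at each peptide).
#'
#' @inheritParams build_positional_heatmap
#' @return A `band_profile` tibble: `spot_id`, `position` (peptide start),
#'   `control_center`, `control_lower`, `control_upper`,
#'   `treatment_center`, `treatment_lower`, `treatment_upper`, `effect`.
#' @export
build_band_profile <- function(table, targeting) {
  samples <- attr(table, "samples")
  j <- match_targeting(table, targeting, require_contiguous = TRUE)
  j <- j[order(j$start, j$end), ]
  ctrl_ids <- samples$sample_id[samples$cohort == "control"]
  trt_ids <- samples$sample_id[samples$cohort == "treatment"]
  xc <- as.matrix(j[, ctrl_ids]); xt <- as.matrix(j[, trt_ids])
  sd_row <- function(m) apply(m, 1, sd)
  out <- tibble::tibble(
    spot_id = j$spot_id, position = j$start,
    control_center = rowMeans(xc),
    control_lower = rowMeans(xc) - sd_row(xc),
    control_upper = rowMeans(xc) + sd_row(xc),
    treatment_center = rowMeans(xt),
    treatment_lower = rowMeans(xt) - sd_row(xt),
    treatment_upper = rowMeans(xt) + sd_row(xt)
  )
  out$effect <- out$treatment_center - out$control_center
  structure(out, class = c("band_profile", class(out)), samples = samples)
}

#' Strip/swarm plot data
#'
#' One strip per peptide; within every strip the dots appear in one fixed
#' global sample order (control block in upload order, then treatment
#' block), so the dot at position n is always the same sample across
#' strips, and each dot carries its cohort for color coding. Accepts an
#' arbitrary (not necessarily contiguous) peptide collection from a
#' single-protein targeting table, or an explicit `peptides` vector (the
#' synoptic swarm-plot case).
#'
#' @inheritParams build_positional_heatmap
#' @param targeting Optional `targeting_table` (contiguity not required).
#' @param peptides Optional character vector of spot IDs (used when
#'   `targeting` is `NULL`).
#' @return A `strip_data` tibble: `peptide` (ordered factor), `dot_order`,
#'   `sample_id`, `cohort`, `value`; the global sample order as attribute
#'   `"sample_order"`.
#' @export
build_strip_data <- function(table, targeting = NULL, peptides = NULL) {
  samples <- attr(table, "samples")
  if (!is.null(targeting)) {
    if (length(unique(targeting$protein)) > 1L) {
      abort(sprintf("Strip plots accept peptides from a single protein; found: %s.",
                    paste(unique(targeting$protein), collapse = ", ")),
            class = "immunosig_validation_error")
    }
    j <- match_targeting(table, targeting, require_contiguous = FALSE)
    ids <- j$spot_id[order(j$start, j$end)]
  } else if (!is.null(peptides)) {
    ids <- peptides
  } else {
    abort("Provide either a targeting table or a peptide vector.",
          class = "immunosig_validation_error")
  }
  missing <- setdiff(ids, table$spot_id)
  if (length(missing)) {
    abort(sprintf("Spot ID(s) absent from the synoptic table: %s.",
                  paste(head(missing, 10L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  idx <- match(ids, table$spot_id)
  long <- purrr::map_dfr(seq_along(ids), function(i) {
    tibble::tibble(
      peptide = ids[i],
      dot_order = seq_len(nrow(samples)),
      sample_id = samples$sample_id,
      cohort = samples$cohort,
      value = unlist(tibble::as_tibble(table)[idx[i], samples$sample_id],
                     use.names = FALSE)
    )
  })
  long$peptide <- factor(long$peptide, levels = ids)
  structure(long, class = c("strip_data", class(long)),
            sample_order = samples$sample_id)
}

#' Epitope map data
#'
#' Places each targeted peptide as a segment at its protein coordinates,
#' colored by its effect size (delta RFU) on a diverging scale symmetric
#' about zero, so the core reactive region of a set of overlapping
#' peptides stands out. Overlapping segments are stacked into lanes by
#' greedy first-fit in start order.
#'
#' @inheritParams build_positional_heatmap
#' @return An `epitope_map` tibble: `spot_id`, `start`, `end`, `lane`,
#'   `delta_rfu`; attributes `index_range` (min start, max end) and
#'   `color_limits` (symmetric about 0 at the largest absolute effect).
#' @export
build_epitope_map <- function(table, targeting) {
  j <- match_targeting(table, targeting, require_contiguous = TRUE)
  j <- j[order(j$start, j$end), ]
  lane_end <- numeric(0)
  lane <- integer(nrow(j))
  for (i in seq_len(nrow(j))) {
    free <- which(lane_end < j$start[i])
    if (length(free)) {
      lane[i] <- free[1]
    } else {
      lane_end <- c(lane_end, -Inf)
      lane[i] <- length(lane_end)
    }
    lane_end[lane[i]] <- j$end[i]
  }
  out <- tibble::tibble(spot_id = j$spot_id, start = j$start, end = j$end,
                        lane = lane, delta_rfu = j$delta_rfu)
  lim <- max(abs(out$delta_rfu))
  if (lim == 0) lim <- 1
  structure(out, class = c("epitope_map", class(out)),
            index_range = c(min(out$start), max(out$end)),
            color_limits = c(-lim, lim))
}
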