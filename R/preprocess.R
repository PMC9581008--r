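#' Spot intensity under a chosen intensity mode
#'
#' Converts a spot's raw foreground/background pair into the working
#' intensity. Three modes are supported:
#' \describe{
#'   \item{`foreground`}{the raw foreground, \eqn{f_l}.}
#'   \item{`background_subtract`}{\eqn{f_l - b_l}: removes the local
#'     optical background.}
#'   \item{`background_scale`}{\eqn{f_l \, b_m / b_l - b_m}: both
#'     intensities are first divided by the ratio of the local background
#'     \eqn{b_l} to the array-wide median background \eqn{b_m}, which
#'     additionally corrects spatially varying detector gain. When
#'     \eqn{b_l = b_m} this collapses to background subtraction.}
#' }
#' Negative results are retained, never clipped: clipping would distort
#' quantile normalization, and the downstream test is rank-based.
#'
#' @param f_l Foreground intensity (RFU), vectorized.
#' @param b_l Local background intensity (RFU), vectorized.
#' @param b_m Median background of the whole array (RFU, scalar).
#' @param mode One of `"foreground"`, `"background_subtract"`,
#'   `"background_scale"`.
#' @return Numeric vector of intensities (same length as `f_l`).
#' @details In scale mode, `b_l` is floored at `max(1, 1e-6 * b_m)` RFU to
#'   avoid division blow-up on zero-background spots; a warning reports how
#'   many spots were floored.
#' @export
#' @examples
#' compute_intensity(200, 50, 100, "background_scale")  # 300
compute_intensity <- function(f_l, b_l, b_m,
                              mode = c("foreground", "background_subtract",
                                       "background_scale")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(f_l)), all(is.finite(b_l)))
  switch(mode,
    foreground = f_l,
    background_subtract = f_l - b_l,
    background_scale = {
      stopifnot(is.finite(b_m))
      eps <- max(1, 1e-6 * b_m)
      n_floor <- sum(b_l < eps)
      if (n_floor > 0L) {
        warn(sprintf("%d spot(s) with background below %.3g RFU floored before scaling.",
                     n_floor, eps))
      }
      f_l * b_m / pmax(b_l, eps) - b_m
    })
}

#' Aggregate replicate spots to one value per peptide
#'
#' Arrays print each peptide in replicate (typically triplicate); replicate
#' spot intensities are collapsed to their median, which is robust to a
#' single bad spot. Grouping is by peptide sequence by default; set
#' `key = "spot_id"` with a `replicate_pattern` stripping the replicate
#' suffix to group by ID instead.
#'
#' @param spots A tibble with at least `spot_id`, `sequence`, and
#'   `intensity` columns.
#' @param method `"median"` (the only aggregation rule) or `"none"` to keep
#'   every spot as its own peptide entry (each spot is then tested
#'   independently downstream).
#' @param key Grouping key: `"sequence"` or `"spot_id"`.
#' @param replicate_pattern Regex removed from `spot_id` before grouping
#'   when `key = "spot_id"` (default strips a trailing `_r<k>` / `.<k>`
#'   replicate suffix).
#' @return A tibble with one row per peptide: `peptide_id`, `sequence`,
#'   `intensity` (the median), `n_replicates`, and `cv` (coefficient of
#'   variation across replicates, for QC).
#' @export
aggregate_replicates <- function(spots, method = c("median", "none"),
                                 key = c("sequence", "spot_id"),
                                 replicate_pattern = "([._]r?[0-9]+)$") {
  method <- match.arg(method)
  key <- match.arg(key)
  stopifnot(nrow(spots) >= 1L, "intensity" %in% names(spots))
  if (method == "none") {
    return(tibble::tibble(peptide_id = spots$spot_id, sequence = spots$sequence,
                          intensity = spots$intensity, n_replicates = 1L,
                          cv = NA_real_))
  }
  gkey <- if (key == "sequence") spots$sequence else sub(replicate_pattern, "", spots$spot_id)
  spots |>
    dplyr::mutate(.key = gkey) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      peptide_id = dplyr::first(sub(replicate_pattern, "", .data$spot_id)),
      sequence = dplyr::first(.data$sequence),
      intensity = median(.data$intensity),
      n_replicates = dplyr::n(),
      cv = ifelse(dplyr::n() > 1L & mean(.data$intensity) != 0,
                  sd(.data$intensity) / abs(mean(.data$intensity)), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$.key, unique(gkey))) |>
    dplyr::select("peptide_id", "sequence", "intensity", "n_replicates", "cv")
}

new_intensity_matrix <- function(values, samples, provenance) {
  stopifnot(all(c("peptide_id", "sequence") %in% names(values)),
            all(samples$sample_id %in% names(values)))
  ord <- order(match(samples$cohort, c("control", "treatment")))
  samples <- samples[ord, ]
  values <- values[, c("peptide_id", "sequence", samples$sample_id)]
  structure(values,
            class = c("intensity_matrix", class(tibble::tibble())),
            samples = samples, provenance = provenance)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  s <- attr(x, "samples"); p <- attr(x, "provenance")
  cat(sprintf("<intensity_matrix> %d peptides x %d samples (%d control, %d treatment)\n",
              nrow(x), nrow(s), sum(s$cohort == "control"), sum(s$cohort == "treatment")))
  cat(sprintf("  intensity: %s | aggregation: %s | normalization: %s\n",
              p$intensity_mode %||% "?", p$aggregate %||% "?",
              p$normalization %||% "none"))
  NextMethod()
}

#' Assemble the peptide-by-sample intensity matrix
#'
#' Applies the intensity mode to every spot of every array, aggregates
#' replicate spots, and joins the samples into one peptide-by-sample
#' matrix. Samples are ordered control block first, then treatment block,
#' each in upload order; peptide order follows the first sample.
#'
#' @param samples List of `array_sample` objects, each with a cohort of
#'   `"control"` or `"treatment"`.
#' @param mode Intensity mode, see [compute_intensity()].
#' @param aggregate Replicate handling, see [aggregate_replicates()].
#' @param key Replicate grouping key, see [aggregate_replicates()].
#' @return An `intensity_matrix`: a tibble with `peptide_id`, `sequence`,
#'   and one numeric column per sample; sample metadata and provenance are
#'   carried as attributes.
#' @export
assemble_matrix <- function(samples,
                            mode = c("foreground", "background_subtract",
                                     "background_scale"),
                            aggregate = c("median", "none"),
                            key = c("sequence", "spot_id")) {
  mode <- match.arg(mode); aggregate <- match.arg(aggregate)
  key <- match.arg(key)
  cohorts <- vapply(samples, function(s) attr(s, "cohort") %||% NA_character_, "")
  ids <- vapply(samples, function(s) attr(s, "sample_id"), "")
  if (anyNA(cohorts) || !all(cohorts %in% c("control", "treatment"))) {
    abort("Every sample must carry a cohort of 'control' or 'treatment'.",
          class = "immunosig_validation_error")
  }
  if (!any(cohorts == "control") || !any(cohorts == "treatment")) {
    abort("At least one control and one treatment sample are required.",
          class = "immunosig_validation_error")
  }
  if (anyDuplicated(ids)) {
    abort("Sample IDs must be unique across the experiment.",
          class = "immunosig_validation_error")
  }
  per_sample <- purrr::map(samples, function(s) {
    sp <- tibble::as_tibble(s)
    sp$intensity <- compute_intensity(sp$foreground, sp$background,
                                      attr(s, "median_background"), mode)
    aggregate_replicates(sp, method = aggregate, key = key)
  })
  ref <- per_sample[[1]]
  key_sets <- purrr::map(per_sample, "peptide_id")
  for (i in seq_along(key_sets)[-1]) {
    extra <- setdiff(key_sets[[i]], key_sets[[1]])
    missing <- setdiff(key_sets[[1]], key_sets[[i]])
    if (length(extra) || length(missing)) {
      abort(sprintf("Peptide sets differ between samples '%s' and '%s' (symmetric difference: %s).",
                    ids[1], ids[i],
                    paste(head(c(missing, extra), 20L), collapse = ", ")),
            class = "immunosig_validation_error")
    }
  }
  values <- tibble::tibble(peptide_id = ref$peptide_id, sequence = ref$sequence)
  for (i in seq_along(per_sample)) {
    values[[ids[i]]] <-
      per_sample[[i]]$intensity[match(ref$peptide_id, per_sample[[i]]$peptide_id)]
  }
  new_intensity_matrix(values,
                       tibble::tibble(sample_id = ids, cohort = cohorts),
                       list(intensity_mode = mode, aggregate = aggregate,
                            normalization = "none"))
}

intensity_values <- function(m) {
  s <- attr(m, "samples")
  as.matrix(m[, s$sample_id])
}

set_intensity_values <- function(m, vals) {
  s <- attr(m, "samples")
  for (i in seq_len(ncol(vals))) m[[s$sample_id[i]]] <- vals[, i]
  m
}
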