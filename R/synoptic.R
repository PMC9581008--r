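#' Mann-Whitney U test for one peptide
#'
#' Two-sided rank-sum test of whether the control and treatment intensity
#' distributions for a peptide differ. Uses the exact permutation null when
#' the combined sample size is at most 12 and there are no ties, and the
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x Control-cohort intensities.
#' @param y Treatment-cohort intensities.
#' @return A list with `u` (the U statistic of `x`, i.e. the number of
#'   (control, treatment) pairs where the control value wins) and `p`
#'   (two-sided p-value, capped at 1).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # exact p = 1/3
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(x) < 3L || length(y) < 3L) {
    warn("Cohort with fewer than 3 samples: the rank-sum test has negligible power.")
  }
  if (length(unique(c(x, y))) == 1L) {
    warn("All intensities identical across both cohorts; p = 1.")
    return(list(u = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(u = unname(res$statistic), p = min(unname(res$p.value), 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values `p * m / rank`, with the running-minimum
#' monotonicity enforcement, capped at 1; output order matches input
#' order. Thin validated wrapper over `p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  bad <- which(!is.finite(p_values) | p_values < 0 | p_values > 1)
  if (length(bad)) {
    abort(sprintf("p-values must lie in [0, 1]; offending index: %d (value %s).",
                  bad[1], format(p_values[bad[1]])),
          class = "immunosig_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

new_synoptic_table <- function(tab, samples) {
  structure(tab,
            class = c("synoptic_table", class(tibble::tibble())),
            samples = samples)
}

#' @export
print.synoptic_table <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("<synoptic_table> %d peptides, %d control + %d treatment samples\n",
              nrow(x), sum(s$cohort == "control"), sum(s$cohort == "treatment")))
  NextMethod()
}

#' Per-peptide differential reactivity table (synoptic analysis)
#'
#' For every peptide: cohort means and unbiased (n-1) variances, the effect
#' size delta RFU (treatment mean minus control mean), the Mann-Whitney
#' two-sided p-value, and the Benjamini-Hochberg adjusted p-value computed
#' jointly over all peptides. Per-sample normalized values are carried
#' alongside so the table is self-contained for targeted visualization.
#'
#' @param matrix A normalized `intensity_matrix`.
#' @return A `synoptic_table` tibble: `spot_id`, `sequence`, one column per
#'   sample, `control_mean`, `control_var`, `treatment_mean`,
#'   `treatment_var`, `delta_rfu`, `p_raw`, `p_adj`.
#' @export
build_synoptic_table <- function(matrix) {
  samples <- attr(matrix, "samples")
  vals <- intensity_values(matrix)
  ctrl <- samples$cohort == "control"
  trt <- samples$cohort == "treatment"
  stopifnot(any(ctrl), any(trt))
  xc <- vals[, ctrl, drop = FALSE]
  xt <- vals[, trt, drop = FALSE]
  tests <- purrr::map(seq_len(nrow(vals)), function(i) {
    suppressWarnings(mann_whitney_u(xc[i, ], xt[i, ]))
  })
  out <- tibble::tibble(spot_id = matrix$peptide_id, sequence = matrix$sequence)
  for (sid in samples$sample_id) out[[sid]] <- matrix[[sid]]
  out$control_mean <- rowMeans(xc)
  out$control_var <- apply(xc, 1, var)
  out$treatment_mean <- rowMeans(xt)
  out$treatment_var <- apply(xt, 1, var)
  out$delta_rfu <- out$treatment_mean - out$control_mean
  out$p_raw <- purrr::map_dbl(tests, "p")
  out$p_adj <- bh_adjust(out$p_raw)
  new_synoptic_table(out, samples)
}

#' Subset specification for synoptic heatmaps, swarm plots and dendrograms
#'
#' @param cutoff Rank cutoff: 20, 50, or 100 peptides.
#' @param direction `"up"` (treatment above control), `"down"`, or `"any"`.
#' @param fdr Tolerated false discovery rate: 0.01, 0.05, 0.10, or 0.25.
#'   The two larger thresholds suit screening, where false negatives cost
#'   more than false positives.
#' @return A `subset_spec` list.
#' @export
subset_spec <- function(cutoff = 50L, direction = c("down", "up", "any"),
                        fdr = 0.05) {
  direction <- match.arg(direction)
  if (!cutoff %in% c(20L, 50L, 100L)) {
    abort("Rank cutoff must be 20, 50, or 100.", class = "immunosig_validation_error")
  }
  if (!any(abs(fdr - c(0.01, 0.05, 0.10, 0.25)) < 1e-12)) {
    abort("FDR threshold must be 0.01, 0.05, 0.10, or 0.25.",
          class = "immunosig_validation_error")
  }
  structure(list(cutoff = as.integer(cutoff), direction = direction, fdr = fdr),
            class = "subset_spec")
}

#' Select peptide subsets for focused visualization
#'
#' Produces the three subsets driving heatmaps, swarm plots and
#' dendrograms, each truncated to the rank cutoff (shorter lists are legal
#' when fewer peptides qualify):
#' \describe{
#'   \item{`by_p`}{lowest adjusted p-values. Under direction `"up"` /
#'     `"down"` only peptides whose delta RFU has the matching sign are
#'     ranked; `"any"` ranks all peptides.}
#'   \item{`by_effect`}{largest (direction `"up"`), smallest (`"down"`), or
#'     largest-magnitude (`"any"`) delta RFU.}
#'   \item{`by_both`}{the `by_effect` ranking restricted to peptides with
#'     adjusted p below the FDR threshold.}
#' }
#' Ties are broken by larger `|delta RFU|`, then lexicographic spot ID, so
#' output is deterministic across platforms.
#'
#' @param table A `synoptic_table`.
#' @param spec A [subset_spec()].
#' @return A named list of three character vectors of spot IDs, with the
#'   spec attached as attribute `"spec"`.
#' @export
select_subset <- function(table, spec = subset_spec()) {
  stopifnot(nrow(table) >= 1L, inherits(spec, "subset_spec"))
  d <- tibble::tibble(spot_id = table$spot_id, delta = table$delta_rfu,
                      p_adj = table$p_adj)

  take <- function(df, ord_primary) {
    o <- order(ord_primary, -abs(df$delta), df$spot_id)
    df$spot_id[o][seq_len(min(spec$cutoff, nrow(df)))]
  }
  sign_pool <- switch(spec$direction,
                      up = d[d$delta > 0, ],
                      down = d[d$delta < 0, ],
                      any = d)
  by_p <- take(sign_pool, sign_pool$p_adj)
  effect_key <- function(df) switch(spec$direction,
                                    up = -df$delta, down = df$delta,
                                    any = -abs(df$delta))
  by_effect <- take(sign_pool, effect_key(sign_pool))
  sig_pool <- sign_pool[sign_pool$p_adj < spec$fdr, ]
  by_both <- take(sig_pool, effect_key(sig_pool))
  structure(list(by_p = by_p, by_effect = by_effect, by_both = by_both),
            spec = spec, class = "peptide_subset")
}

#' @rdname build_synoptic_table
#' @param x A `synoptic_table`.
#' @param ... Unused.
#' @method tidy synoptic_table
#' @export
tidy.synoptic_table <- function(x, ...) {
  tibble::as_tibble(x)[, c("spot_id", "sequence", synoptic_stat_cols)]
}

#' @rdname build_synoptic_table
#' @param fdr FDR threshold used for the significance count in `glance()`.
#' @method glance synoptic_table
#' @export
glance.synoptic_table <- function(x, fdr = 0.05, ...) {
  s <- attr(x, "samples")
  tibble::tibble(
    n_peptides = nrow(x),
    n_control = sum(s$cohort == "control"),
    n_treatment = sum(s$cohort == "treatment"),
    n_significant = sum(x$p_adj < fdr),
    fdr = fdr,
    min_p_adj = min(x$p_adj)
  )
}
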