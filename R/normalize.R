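#' Cross-sample normalization of an intensity matrix
#'
#' Dispatches to one of the three supported schemes: `"none"` (identity),
#' `"quantile"` (all samples forced onto the common distribution of
#' averaged order statistics), or `"vsn"` (per-sample affine calibration
#' followed by an arsinh transform that decouples variance from mean
#' intensity; see [vsn_normalize()]).
#'
#' @param matrix An `intensity_matrix` from [assemble_matrix()].
#' @param method `"none"`, `"quantile"`, or `"vsn"`.
#' @param seed Integer seed for the VSN fit (ignored otherwise).
#' @param ... Further arguments passed to [vsn_normalize()].
#' @return The normalized `intensity_matrix` (for `"vsn"`, the fit is
#'   attached as attribute `"vsn_fit"`).
#' @export
normalize_matrix <- function(matrix, method = c("none", "quantile", "vsn"),
                             seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         none = no_normalize(matrix),
         quantile = quantile_normalize(matrix),
         vsn = {
           res <- vsn_normalize(matrix, seed = seed, ...)
           out <- res$matrix
           attr(out, "vsn_fit") <- res$fit
           out
         })
}

#' Quantile normalization
#'
#' Every sample's sorted values are replaced by the vector of across-sample
#' means of the order statistics, preserving each sample's internal rank
#' order; afterwards all samples share one multiset of values. Ties within
#' a sample receive the mean of the reference quantiles they span, so the
#' result is stable under row permutation. The computation is delegated to
#' `limma::normalizeQuantiles()`.
#'
#' @param matrix An `intensity_matrix`.
#' @return The normalized `intensity_matrix`.
#' @export
quantile_normalize <- function(matrix) {
  vals <- intensity_values(matrix)
  if (ncol(vals) < 2L) {
    warn("Quantile normalization needs at least 2 samples; returning input unchanged.")
    return(no_normalize(matrix))
  }
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  out <- set_intensity_values(matrix, norm)
  prov <- attr(out, "provenance"); prov$normalization <- "quantile"
  attr(out, "provenance") <- prov
  out
}

#' No normalization
#'
#' Identity pass-through; only the provenance record is updated.
#'
#' @param matrix An `intensity_matrix`.
#' @return The same matrix with provenance method `"none"`.
#' @export
no_normalize <- function(matrix) {
  prov <- attr(matrix, "provenance"); prov$normalization <- "none"
  attr(matrix, "provenance") <- prov
  matrix
}

#' Variance stabilizing normalization (arsinh-affine calibration)
#'
#' Models each sample's measured intensities as an affine distortion of a
#' common latent scale and transforms
#' \deqn{h_{ij} = \mathrm{arsinh}\!\big((x_{ij} - a_i) / b_i\big),}
#' with one offset \eqn{a_i} and one positive scale \eqn{b_i} per sample,
#' fitted by maximum likelihood under the working model
#' \eqn{h_{ij} \sim N(\mu_j, \sigma^2)}. Because real experiments contain
#' differentially reactive peptides that violate this model, the fit is a
#' least-trimmed variant: after each full fit, the fraction `trim` of
#' peptides with the smallest residual sum of squares is retained and the
#' fit repeated, for a few rounds. The arsinh behaves like
#' \eqn{\log(2x/b)} for large intensities and is smooth and defined
#' through zero, so negative background-corrected values are handled.
#'
#' The scales \eqn{b_i} are identifiable only up to one common factor
#' (rescaling all of them is absorbed by the latent peptide means), so the
#' fit is reported in the gauge where the geometric mean of \eqn{b_i}
#' equals the geometric mean of the per-sample median absolute deviations
#' of the starting values, which also provides the initialization.
#'
#' @param matrix An `intensity_matrix` (values may be negative).
#' @param seed Integer seed (the trimmed refit subsamples deterministically;
#'   recorded in the fit).
#' @param trim Fraction of peptides retained in the trimmed refit
#'   (default 0.9).
#' @param max_iter Maximum optimizer iterations per round.
#' @param tol Relative convergence tolerance on the objective.
#' @return A list with `matrix` (transformed `intensity_matrix`) and `fit`
#'   (a `vsn_fit`: tibble of per-sample `a`, `b`, plus convergence info).
#' @export
vsn_normalize <- function(matrix, seed = 1L, trim = 0.9,
                          max_iter = 200L, tol = 1e-8) {
  x <- intensity_values(matrix)
  n_s <- ncol(x); n_p <- nrow(x)
  if (n_s < 2L) {
    abort("VSN requires at least 2 samples.", class = "immunosig_validation_error")
  }
  set.seed(seed)
  a0 <- apply(x, 2, median)
  b0 <- apply(x, 2, function(v) max(stats::mad(v), 1e-8))
  gauge <- exp(mean(log(b0)))

  nll <- function(par, xs) {
    a <- par[seq_len(n_s)]
    b <- exp(par[n_s + seq_len(n_s)])
    h <- asinh(sweep(sweep(xs, 2, a), 2, b, "/"))
    res <- h - rowMeans(h)
    rss <- sum(res^2)
    # profile normal likelihood plus the arsinh Jacobian term
    n <- length(h)
    0.5 * n * log(rss / n) -
      sum(-0.5 * log(sweep(xs, 2, a)^2 + rep(b, each = nrow(xs))^2))
  }

  keep <- seq_len(n_p)
  par <- c(a0, log(b0))
  conv <- FALSE; iters <- 0L
  for (round in 1:3) {
    opt <- optim(par, nll, xs = x[keep, , drop = FALSE], method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol))
    iters <- iters + opt$counts[["function"]]
    conv <- opt$convergence == 0L
    par <- opt$par
    if (trim < 1) {
      a <- par[seq_len(n_s)]; b <- exp(par[n_s + seq_len(n_s)])
      h <- asinh(sweep(sweep(x, 2, a), 2, b, "/"))
      pep_rss <- rowSums((h - rowMeans(h))^2)
      keep <- order(pep_rss)[seq_len(max(2L, floor(trim * n_p)))]
    }
  }
  if (!conv) {
    abort(sprintf("VSN fit did not converge after %d function evaluations; consider quantile normalization.", iters),
          class = "immunosig_convergence_error")
  }
  a <- par[seq_len(n_s)]
  b <- exp(par[n_s + seq_len(n_s)])
  # gauge-fix the common scale of b
  scale_fix <- gauge / exp(mean(log(b)))
  b <- b * scale_fix
  h <- asinh(sweep(sweep(x, 2, a), 2, b, "/"))
  out <- set_intensity_values(matrix, h)
  prov <- attr(out, "provenance"); prov$normalization <- "vsn"
  attr(out, "provenance") <- prov
  fit <- structure(
    tibble::tibble(sample_id = attr(matrix, "samples")$sample_id, a = a, b = b),
    class = c("vsn_fit", class(tibble::tibble())),
    converged = conv, iterations = iters, seed = seed, trim = trim)
  list(matrix = out, fit = fit)
}
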