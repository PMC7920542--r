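#' Across-subject coefficient of variation per connection
#'
#' Applies the per-subject normalization chain (fractional scaling,
#' symmetrization, log10 with zeros excluded) to each subject, then derives
#' for each pairwise connection the across-subject coefficient of variation
#' CV = sd/mean of the per-subject log-scale weights, restricted to the
#' subjects where the pair is defined. The scale matters: CV is computed on
#' the per-subject log10 weights, so a global rescaling of the raw counts
#' (which shifts the log weights) changes CV — this is the convention for
#' log-probability connectivity and is asserted in the tests.
#'
#' @param stack A `subject_stack`.
#' @param min_subjects Minimum contributing subjects for a pair to be
#'   defined (default 3).
#' @return A `variability_result`: list with `cv` (N x N), `mean`, `sd`,
#'   `n_contributing` (N x N counts), `defined`, `n_subjects` and the array
#'   of per-subject normalized matrices `fpt` (S x N x N).
#' @export
cv_matrix <- function(stack, min_subjects = 3L) {
  if (stack$n_subjects < 3L) stop("need at least 3 subjects")
  n <- stack$n
  fpt <- array(NA_real_, dim(stack$counts))
  for (s in seq_len(stack$n_subjects)) {
    f <- fpt_chain(connectome_matrix(stack$counts[s, , ], scale = "raw_counts"))
    v <- f$values
    v[!f$defined] <- NA_real_
    fpt[s, , ] <- v
  }
  n_contrib <- apply(!is.na(fpt), c(2, 3), sum)
  mu <- apply(fpt, c(2, 3), mean, na.rm = TRUE)
  sd_ <- apply(fpt, c(2, 3), stats::sd, na.rm = TRUE)
  defined <- n_contrib >= min_subjects & is.finite(mu) & mu != 0
  cv <- ifelse(defined, sd_ / mu, NA_real_)
  structure(list(cv = cv, mean = mu, sd = sd_, n_contributing = n_contrib,
                 defined = defined, n_subjects = stack$n_subjects, fpt = fpt),
            class = "variability_result")
}

#' Mask of the most consistent connections
#'
#' Selects the lower `quantile` of defined |CV| values — the connections
#' most consistent across subjects.
#'
#' @param vr A `variability_result` (or a bare numeric CV matrix).
#' @param quantile Lower quantile to keep, in (0, 1].
#' @return Logical N x N mask.
#' @export
consistency_mask <- function(vr, quantile = 0.2) {
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  cv <- if (inherits(vr, "variability_result")) vr$cv else vr
  defined <- is.finite(cv)
  if (sum(defined & upper.tri(cv)) < 5L) stop("CV defined on fewer than 5 pairs")
  acv <- abs(cv)
  thr <- stats::quantile(acv[defined & upper.tri(cv)], probs = quantile,
                         names = FALSE, type = 7)
  mask <- defined & acv <= thr
  mask | t(mask)
}

#' Correlation of two specific connections across subjects
#'
#' Pearson correlation across subjects of the per-subject normalized weight
#' at two parcel pairs (e.g. the left and right V1-V2 connections), with a
#' Fisher-z CI, plus the fold-range of the linear weight at each pair: the
#' ratio of the 97.5th to the 2.5th percentile of `10^Fpt` across subjects.
#'
#' @param vr A `variability_result` (carrying the per-subject matrices), or
#'   a `subject_stack` (the chain is then applied internally).
#' @param pair_a Integer vector `c(i, j)` of parcel indices.
#' @param pair_b Integer vector `c(i, j)`.
#' @param fold_probs Percentile pair defining the fold range.
#' @return List with `r`, `ci95`, `n`, `fold_range` (length 2: pair_a,
#'   pair_b).
#' @export
connection_pair_correlation <- function(vr, pair_a, pair_b,
                                        fold_probs = c(0.025, 0.975)) {
  if (inherits(vr, "subject_stack")) vr <- cv_matrix(vr)
  a <- vr$fpt[, pair_a[1], pair_a[2]]
  b <- vr$fpt[, pair_b[1], pair_b[2]]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 4L) stop("pairs share fewer than 4 defined subjects")
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (identical(pair_a, pair_b) || all(a == b)) {
      return(list(r = 1, ci95 = c(1, 1), n = length(a),
                  fold_range = fold_range_of(a, b, fold_probs)))
    }
    stop("zero variance at one of the pairs")
  }
  r <- stats::cor(a, b)
  list(r = r, ci95 = fisher_ci(r, length(a)), n = length(a),
       fold_range = fold_range_of(a, b, fold_probs))
}

fold_range_of <- function(a, b, probs) {
  fr <- function(x) {
    q <- stats::quantile(10^x, probs = probs, names = FALSE)
    q[2] / q[1]
  }
  c(fr(a), fr(b))
}
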