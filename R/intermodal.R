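#' Renormalize a connectivity matrix from another modality
#'
#' Applies the same fractional scaling and symmetrization used for the
#' tractography weights to an evoked-potential (CCEP) or resting-state
#' fMRI connectivity matrix. CCEP and dMRI weights are log10-transformed;
#' rs-fMRI weights are left on the linear scale because they are already
#' approximately normally distributed (if bimodal). Undefined entries
#' (missing sampling) propagate through both steps.
#'
#' @param M A `connectome_matrix` of non-negative modality weights
#'   (`raw_counts` or `modality_raw` scale).
#' @param modality `"dmri"`, `"ccep"` or `"rsfmri"`.
#' @param zero_policy Passed to [log10_transform()] for the logged
#'   modalities.
#' @return A symmetric `connectome_matrix`; scale `log10_fractional` for
#'   dmri/ccep, `fractional` for rsfmri.
#' @export
renormalize_modality <- function(M, modality = c("dmri", "ccep", "rsfmri"),
                                 zero_policy = "exclude") {
  modality <- match.arg(modality)
  raw <- if (M$scale == "raw_counts") M else
    cm_like(M, M$values, scale = "raw_counts")
  f <- symmetrize(suppressWarnings(fractional_scale(raw)))
  if (modality == "rsfmri") return(f)
  log10_transform(f, zero_policy = zero_policy)
}

#' Correlation between two modality matrices over shared pairs
#'
#' Pearson correlation over the intersection of defined off-diagonal pairs
#' (upper triangle, to avoid double counting on symmetric matrices), with a
#' Fisher-z CI.
#'
#' @param A,B `connectome_matrix` objects with the same parcel order.
#' @return List with `r`, `ci95`, `n_shared`.
#' @export
paired_correlation <- function(A, B) {
  if (A$n != B$n) stop("matrices differ in size")
  keep <- A$defined & B$defined & upper.tri(A$values)
  n <- sum(keep)
  if (n < 4L) stop("fewer than 4 shared defined pairs")
  x <- A$values[keep]; y <- B$values[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  list(r = r, ci95 = fisher_ci(r, n), n_shared = n)
}

#' Correlation between two connectomes over matched parcels
#'
#' Restricts both matrices to a set of name-matched parcels (the
#' cross-species use case: parcels shared between two atlases) and
#' correlates the defined shared pairs.
#'
#' @param A,B `connectome_matrix` objects with named rows/columns.
#' @param name_map Two-column data frame or matrix: names in `A`, names in
#'   `B`.
#' @return List with `r`, `p`, `ci95`, `n`.
#' @export
matched_parcel_correlation <- function(A, B, name_map) {
  name_map <- as.data.frame(name_map, stringsAsFactors = FALSE)
  if (nrow(name_map) == 0L) stop("empty name map")
  ia <- match(name_map[[1]], rownames(A$values))
  ib <- match(name_map[[2]], rownames(B$values))
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no matched parcels between the two matrices")
  ia <- ia[ok]; ib <- ib[ok]
  va <- A$values[ia, ia]; da <- A$defined[ia, ia]
  vb <- B$values[ib, ib]; db <- B$defined[ib, ib]
  keep <- da & db & upper.tri(va)
  n <- sum(keep)
  if (n < 4L) stop("fewer than 4 defined shared pairs after matching")
  x <- va[keep]; y <- vb[keep]
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, ci95 = fisher_ci(r, n), n = n)
}

#' Two-component Gaussian mixture fit with mode split
#'
#' Maximum-likelihood fit of a two-component Gaussian mixture (unequal
#' variances, EM) to linear-scale weights, used to characterize bimodal
#' resting-state connectivity distributions. Components are sorted by mean;
#' the split point is the midpoint of the two means, and membership masks
#' assign each value to the low or high mode by that split.
#'
#' @param values Numeric vector of linear-scale weights (NAs dropped).
#' @param seed Integer seed (EM initialization).
#' @param restarts Unused by the deterministic hierarchical initialization
#'   but retained for interface stability; extra random-start EM runs are
#'   attempted when the primary fit degenerates.
#' @return A `mixture_fit`: list with `mu` (ascending), `sigma` (sds),
#'   `variance`, `pi` (mixing proportions), `split_point`, `loglik`,
#'   `low_mode`/`high_mode` logical masks, `unimodal_flag` (TRUE when the
#'   mean separation is under 2 pooled sds), `n`.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm2_fit <- function(values, seed = 1L, restarts = 10) {
  x <- values[is.finite(values)]
  if (length(x) < 20L) stop("need at least 20 values")
  fit <- local_rng(seed, {
    init <- if (length(x) > 20000)
      list(subset = sample.int(length(x), 5000)) else NULL
    f <- tryCatch(mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                                 initialization = init),
                  error = function(e) NULL)
    if (is.null(f) || is.na(f$loglik)) {
      for (k in seq_len(restarts)) {
        init <- list(subset = sample.int(length(x), min(5000, length(x))))
        f <- tryCatch(mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE,
                                     initialization = init),
                      error = function(e) NULL)
        if (!is.null(f) && !is.na(f$loglik)) break
      }
    }
    f
  })
  if (!is.null(fit) && is.na(fit$loglik)) fit <- NULL
  if (is.null(fit)) stop("EM failed to fit a two-component mixture")
  mu <- as.numeric(fit$parameters$mean)
  var_ <- as.numeric(fit$parameters$variance$sigmasq)
  if (length(var_) == 1L) var_ <- rep(var_, 2)
  pi_ <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; var_ <- var_[ord]; pi_ <- pi_[ord]
  split <- mean(mu)
  structure(list(mu = mu, sigma = sqrt(var_), variance = var_, pi = pi_,
                 split_point = split, loglik = fit$loglik,
                 low_mode = values < split & is.finite(values),
                 high_mode = values >= split & is.finite(values),
                 unimodal_flag = diff(mu) < 2 * sqrt(mean(var_)),
                 n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: mu = %.4g / %.4g, pi = %.2f / %.2f, split = %.4g%s\n",
              x$mu[1], x$mu[2], x$pi[1], x$pi[2], x$split_point,
              if (x$unimodal_flag) " (flagged unimodal)" else ""))
  invisible(x)
}
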