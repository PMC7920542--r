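#' Fractionally scaled myelination-difference (hierarchy-similarity) matrix
#'
#' Cortical hierarchical level is indexed (inversely) by the T1w/T2w
#' myelination ratio. The pairwise absolute difference in myelination,
#' fractionally scaled exactly like the connectivity weights, yields a
#' hierarchy-similarity matrix: smaller values mean the two parcels sit at
#' closer hierarchical levels. Because fractional scaling normalizes by row
#' and column sums, the result is invariant to affine transforms of the
#' myelination vector.
#'
#' @param myelination Numeric per-parcel myelination indices (no NAs).
#' @param parcels Optional parcel names.
#' @return A `connectome_matrix` (scale `modality_raw`) of scaled |delta
#'   myelination|; entries undefined where the scaling denominator is zero
#'   (e.g. constant myelination).
#' @export
myelin_similarity <- function(myelination, parcels = NULL) {
  if (anyNA(myelination)) stop("missing myelination values")
  n <- length(myelination)
  dm <- abs(outer(myelination, myelination, "-"))
  raw <- connectome_matrix(dm, scale = "raw_counts", parcels = parcels)
  f <- suppressWarnings(fractional_scale(raw))
  cm_like(f, f$values, scale = "modality_raw", symmetric = FALSE,
          defined = f$defined)
}

#' Correlation between connectivity and hierarchy similarity over a scope
#'
#' Pearson correlation between the connectivity weights and the
#' hierarchy-similarity matrix over a set of parcel pairs: a whole
#' hemisphere, the callosal pairs, or the within-network pairs of one
#' network in one hemisphere. Hemispheres are analysed separately to avoid
#' the collinearity introduced by hemispheric homology. A negative
#' correlation means parcels at similar hierarchical levels tend to be more
#' connected.
#'
#' @param F A symmetric `connectome_matrix` of connectivity weights.
#' @param H The hierarchy-similarity `connectome_matrix` from
#'   [myelin_similarity()].
#' @param atlas A `parcel_atlas`.
#' @param scope `"left"`, `"right"`, `"callosal"`, or `"network"`.
#' @param network Network label, required when `scope = "network"`.
#' @param hemisphere Hemisphere for `scope = "network"`.
#' @return List with `r`, `ci95` (Fisher-z), `n`.
#' @export
network_hierarchy_correlation <- function(F, H, atlas,
                                          scope = c("left", "right",
                                                    "callosal", "network"),
                                          network = NULL,
                                          hemisphere = c("left", "right")) {
  scope <- match.arg(scope)
  mask <- if (scope == "network") {
    hemisphere <- match.arg(hemisphere)
    if (is.null(network)) stop("network label required for scope='network'")
    network_block_mask(atlas, network, hemisphere)
  } else {
    pair_subset_mask(atlas, scope)
  }
  keep <- F$defined & H$defined & mask & upper.tri(mask)
  n <- sum(keep)
  if (n < 4L) stop("fewer than 4 defined shared pairs in scope")
  x <- F$values[keep]; y <- H$values[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in scope")
  r <- stats::cor(x, y)
  list(r = r, ci95 = fisher_ci(r, n), n = n)
}

#' Parcel-wise correlation of connectivity with the myelination vector
#'
#' For each parcel, correlates its row of the connectome (self excluded,
#' homologs and callosal entries retained unless `callosal = FALSE`) with
#' the vector of myelination indices. P-values use the t-distribution and
#' are Bonferroni-multiplied by the number of parcels.
#'
#' @param F A symmetric `connectome_matrix`.
#' @param myelination Numeric per-parcel myelination vector.
#' @param atlas Optional `parcel_atlas` (needed when `callosal = FALSE`).
#' @param alpha Corrected significance level (default 0.05).
#' @param callosal Include callosal entries in the rows (default `TRUE`).
#' @return Data frame per parcel: `r`, `p`, `p_corrected`, `significant`,
#'   `sign`, `n`.
#' @export
parcelwise_myelin_correlation <- function(F, myelination, atlas = NULL,
                                          alpha = 0.05, callosal = TRUE) {
  n <- F$n
  if (length(myelination) != n) stop("myelination must have length ", n)
  keep_base <- F$defined
  if (!callosal) {
    if (is.null(atlas)) stop("atlas required when excluding callosal entries")
    keep_base <- keep_base & !pair_subset_mask(atlas, "callosal")
  }
  res <- lapply(seq_len(n), function(i) {
    keep <- keep_base[i, ]
    keep[i] <- FALSE
    x <- F$values[i, keep]; y <- myelination[keep]
    m <- length(x)
    if (m < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(r = NA_real_, p = NA_real_, n = m))
    }
    r <- stats::cor(x, y)
    tt <- r * sqrt((m - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = m - 2)
    data.frame(r = r, p = p, n = m)
  })
  out <- do.call(rbind, res)
  out$p_corrected <- pmin(1, out$p * n)
  out$significant <- !is.na(out$p_corrected) & out$p_corrected < alpha
  out$sign <- ifelse(is.na(out$r), NA, ifelse(out$r < 0, "negative", "positive"))
  out <- cbind(parcel_id = seq_len(n), out)
  if (!is.null(atlas)) out$name <- atlas$name
  out
}
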