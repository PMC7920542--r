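#' Fractional scaling of raw streamline counts
#'
#' Normalizes each pairwise count by the total number of streamlines that
#' either originate at the row parcel or terminate at the column parcel,
#' excluding within-parcel connections:
#' \deqn{F_{i,j} = \frac{C_{i,j}}{\sum_{x \ne i} C_{i,x} + \sum_{y \ne j} C_{y,j}}}
#' This is the normalization used for non-human-primate tracing data and is
#' invariant to a global rescaling of the counts.
#'
#' @param raw A `connectome_matrix` on the `raw_counts` scale.
#' @return A `connectome_matrix` on the `fractional` scale. Pairs whose
#'   denominator is zero (isolated parcels) become undefined, with a warning.
#' @export
fractional_scale <- function(raw) {
  stopifnot(inherits(raw, "connectome_matrix"))
  if (raw$scale != "raw_counts") stop("fractional_scale expects raw counts")
  if (raw$n < 2L) stop("need at least two parcels")
  v <- raw$values
  v[!raw$defined] <- 0
  diag(v) <- 0
  rs <- rowSums(v)           # sum over x != i of C[i, x]
  cs <- colSums(v)           # sum over y != j of C[y, j]
  den <- outer(rs, cs, "+")
  f <- ifelse(den > 0, v / den, NA_real_)
  defined <- raw$defined & den > 0
  iso <- rs == 0 & cs == 0      # parcel carries no streamlines at all
  if (any(iso) || any(raw$defined & den == 0)) {
    defined[iso, ] <- FALSE
    defined[, iso] <- FALSE
    warning("zero denominator (isolated parcel) for ",
            sum(raw$defined & !defined), " pairs; entries set undefined")
  }
  cm_like(raw, f, scale = "fractional", symmetric = FALSE, defined = defined)
}

#' Alternative streamline-count normalizations
#'
#' Besides fractional scaling, three simpler strategies normalize counts by
#' the number of samples drawn per seed voxel (and optionally seed/target
#' parcel areas): `samples` divides by the per-voxel sample count; the area
#' modes additionally divide by seed area or by the geometric mean of both
#' areas. On realistic data all four agree up to a near-monotone transform.
#'
#' @param raw A `connectome_matrix` of raw counts.
#' @param mode One of `"fractional"`, `"samples"`, `"samples_seed_area"`,
#'   `"samples_both_areas"`.
#' @param areas Numeric per-parcel areas (mm^2); required for the area modes.
#' @param samples_per_voxel Probabilistic-sampling constant (default 5000
#'   samples per seed voxel).
#' @return A `connectome_matrix`; `fractional` scale for mode `fractional`,
#'   otherwise `modality_raw`.
#' @export
alt_normalize <- function(raw, mode = c("fractional", "samples",
                                        "samples_seed_area", "samples_both_areas"),
                          areas = NULL, samples_per_voxel = 5000) {
  mode <- match.arg(mode)
  if (mode == "fractional") return(fractional_scale(raw))
  v <- raw$values
  if (mode != "samples") {
    if (is.null(areas)) stop("areas required for mode ", mode)
    areas <- as.numeric(areas)
    if (length(areas) != raw$n) stop("areas must have length ", raw$n)
    if (any(!is.finite(areas) | areas <= 0)) stop("areas must be positive")
  }
  out <- switch(mode,
    samples            = v / samples_per_voxel,
    samples_seed_area  = v / (samples_per_voxel * areas),
    samples_both_areas = v / (samples_per_voxel *
                              outer(sqrt(areas), sqrt(areas))))
  cm_like(raw, out, scale = "modality_raw", symmetric = FALSE)
}

#' Symmetrize a connectivity matrix
#'
#' Tractography computes A-to-B and B-to-A streamlines separately, creating
#' minor asymmetries; symmetry is enforced by the arithmetic mean of the two
#' directions. An entry is defined only when both directions are defined.
#'
#' @param F A `connectome_matrix` (applied after normalization).
#' @return A symmetric `connectome_matrix` on the same scale.
#' @export
symmetrize <- function(F) {
  stopifnot(inherits(F, "connectome_matrix"))
  v <- (F$values + t(F$values)) / 2
  defined <- F$defined & t(F$defined)
  v[!defined] <- NA_real_
  cm_like(F, v, symmetric = TRUE, defined = defined)
}

#' Log10 transform of fractional weights
#'
#' Fractional weights span several orders of magnitude and are approximately
#' lognormal; the log10 transform brings them close to Gaussian. Zeros are
#' not log-transformed (to avoid infinities): policy `exclude` marks them
#' undefined, policy `floor` substitutes a user floor value.
#'
#' @param F A `connectome_matrix` on the `fractional` scale.
#' @param zero_policy `"exclude"` or `"floor"`.
#' @param floor_value Log10 value substituted for zeros under `"floor"`.
#' @return A `connectome_matrix` on the `log10_fractional` scale.
#' @export
log10_transform <- function(F, zero_policy = c("exclude", "floor"),
                            floor_value = NULL) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(F, "connectome_matrix"))
  if (F$scale != "fractional") stop("log10_transform expects fractional scale")
  v <- F$values
  if (any(v[F$defined] < 0)) stop("negative fractional values")
  defined <- F$defined
  zero <- defined & v == 0
  out <- suppressWarnings(log10(v))
  if (zero_policy == "exclude") {
    defined <- defined & v > 0
  } else {
    if (is.null(floor_value)) stop("floor_value required for zero_policy='floor'")
    out[zero] <- floor_value
  }
  out[!defined] <- NA_real_
  cm_like(F, out, scale = "log10_fractional", defined = defined)
}

#' Full normalization chain for one raw-count matrix
#'
#' Fixed pipeline order: fractional scaling, then symmetrization, then log10.
#'
#' @param raw A `connectome_matrix` of raw counts.
#' @param zero_policy Passed to [log10_transform()].
#' @return A symmetric `connectome_matrix` on the `log10_fractional` scale.
#' @export
fpt_chain <- function(raw, zero_policy = "exclude") {
  log10_transform(symmetrize(fractional_scale(raw)), zero_policy = zero_policy)
}

#' Distribution moments with bootstrap confidence intervals
#'
#' Sample mean, standard deviation, moment skewness (g1) and non-excess
#' kurtosis (Gaussian reference value 3), each with a percentile bootstrap
#' 95\% CI. Because log10 of a fractional weight is negative, the summary
#' also reports the moments of the magnitudes |x|, the scale on which
#' group-level summaries of log-probability weights are conventionally
#' printed.
#'
#' @param values Numeric vector (NAs dropped).
#' @param bootstrap_iters Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A `moment_summary`: list with `mean`, `sd`, `skewness`,
#'   `kurtosis`, per-moment `ci95`, `magnitude` (same fields computed on
#'   |x|) and `n`.
#' @export
moments <- function(values, bootstrap_iters = 2000, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 values for kurtosis")
  pt <- moment_vec(values)
  boot <- local_rng(seed, {
    t(vapply(seq_len(bootstrap_iters), function(i) {
      moment_vec(values[sample.int(n, n, replace = TRUE)])
    }, numeric(4)))
  })
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  mag <- unname(moment_vec(abs(values)))
  pt <- unname(pt)
  structure(list(mean = pt[1], sd = pt[2], skewness = pt[3], kurtosis = pt[4],
                 ci95 = list(mean = ci[, 1], sd = ci[, 2],
                             skewness = ci[, 3], kurtosis = ci[, 4]),
                 magnitude = list(mean = mag[1], sd = mag[2],
                                  skewness = mag[3], kurtosis = mag[4]),
                 n = n),
            class = "moment_summary")
}

moment_vec <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  c(mean = m,
    sd = stats::sd(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
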