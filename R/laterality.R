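#' Ipsilateral-versus-contralateral differential connectome
#'
#' For every bilateral parcel-identity pair (p, q) of the 180 parcel names,
#' subtracts the mean of the two contralateral weights (left-right and
#' right-left) from the mean of the two ipsilateral weights (left-left and
#' right-right):
#' \deqn{D_{p,q} = \tfrac{1}{2}(F_{LL} + F_{RR}) - \tfrac{1}{2}(F_{LR} + F_{RL})}
#' Positive entries mark pairs dominated by within-hemisphere connectivity.
#'
#' @param F A symmetric N x N `connectome_matrix` (N even, left parcels
#'   first).
#' @param atlas A `parcel_atlas`.
#' @return An (N/2) x (N/2) numeric matrix; entries with any undefined
#'   constituent are `NA`.
#' @export
ipsi_contra_differential <- function(F, atlas) {
  n <- atlas_n(atlas)
  h <- n %/% 2L
  li <- hemisphere_index(atlas, "left")
  ri <- atlas$homolog_id[li]
  v <- F$values; v[!F$defined] <- NA_real_
  ll <- v[li, li]; rr <- v[ri, ri]
  lr <- v[li, ri]; rl <- v[ri, li]
  d <- (ll + rr) / 2 - (lr + rl) / 2
  dimnames(d) <- list(atlas$name[li], atlas$name[li])
  d
}

#' Bootstrap test of contralateral-homolog hyperconnectivity
#'
#' For each of the 180 bilateral parcel identities, compares the per-subject
#' connectivity to the contralateral homolog with the mean of that parcel's
#' other callosal connectivity. The per-parcel statistic (averaged over the
#' two hemispheric directions of the symmetrized matrix) is bootstrapped
#' over subjects; percentile CIs at the Bonferroni-corrected level
#' 1 - alpha/m classify each parcel as hyperconnected (CI entirely > 0),
#' hypoconnected (entirely < 0) or not significant.
#'
#' @param fpt S x N x N array of per-subject normalized weights (e.g. the
#'   `fpt` field of [cv_matrix()]), or a `subject_stack` (chain applied
#'   internally).
#' @param atlas A `parcel_atlas`.
#' @param iters Bootstrap iterations (default 2000).
#' @param alpha Family-wise error level (default 0.05).
#' @param correction `"bonferroni"` or `"none"`.
#' @param seed Integer seed.
#' @return A `homolog_test` data frame: per bilateral parcel `name`,
#'   `difference`, `ci_low`, `ci_high` (corrected), `class` in
#'   `{"hyper", "hypo", "ns"}`, `n_subjects`.
#' @export
homolog_test <- function(fpt, atlas, iters = 2000, alpha = 0.05,
                         correction = c("bonferroni", "none"), seed = 1L) {
  correction <- match.arg(correction)
  if (inherits(fpt, "subject_stack")) fpt <- cv_matrix(fpt)$fpt
  n <- atlas_n(atlas)
  h <- n %/% 2L
  li <- hemisphere_index(atlas, "left")
  ri <- atlas$homolog_id[li]
  ns <- dim(fpt)[1]
  if (ns < 10L) warning("fewer than 10 subjects; CIs will be unstable")
  # per subject, per bilateral parcel: homolog weight minus mean of the
  # other callosal weights in that parcel's row (both directions averaged)
  stat <- matrix(NA_real_, ns, h)
  for (s in seq_len(ns)) {
    lr <- fpt[s, li, ri, drop = TRUE]  # left row x right col quadrant
    rl <- fpt[s, ri, li, drop = TRUE]
    callosal <- (lr + t(rl)) / 2       # symmetric in parcel identity
    hom <- diag(callosal)
    others <- callosal
    diag(others) <- NA_real_
    stat[s, ] <- hom - rowMeans(others, na.rm = TRUE)
  }
  level <- if (correction == "bonferroni") alpha / h else alpha
  probs <- c(level / 2, 1 - level / 2)
  means <- colMeans(stat, na.rm = TRUE)
  idx <- local_rng(seed,
    matrix(sample.int(ns, ns * iters, replace = TRUE), iters, ns))
  ci <- apply(stat, 2, function(v) {
    bm <- rowMeans(matrix(v[idx], nrow(idx), ncol(idx)), na.rm = TRUE)
    stats::quantile(bm, probs = probs, names = FALSE)
  })
  cls <- ifelse(ci[1, ] > 0, "hyper", ifelse(ci[2, ] < 0, "hypo", "ns"))
  out <- data.frame(name = atlas$name[li], difference = means,
                    ci_low = ci[1, ], ci_high = ci[2, ], class = cls,
                    n_subjects = ns, stringsAsFactors = FALSE)
  class(out) <- c("homolog_test", "data.frame")
  out
}

#' @export
print.homolog_test <- function(x, ...) {
  tb <- table(factor(x$class, levels = c("hyper", "hypo", "ns")))
  cat(sprintf("homolog_test: %d hyper / %d hypo / %d ns of %d parcels\n",
              tb["hyper"], tb["hypo"], tb["ns"], nrow(x)))
  invisible(x)
}

#' Distance-binned within/between-network connectivity profile
#'
#' Bins pairwise connections by fiber tract length in fixed increments
#' (half-open bins [k*w, (k+1)*w) mm). Within each bin and subject, the
#' linear-scale weights of connections inside the parcel set (both parcels
#' in the set, same hemisphere) and between the set and the rest of the
#' cortex are averaged *before* being log10-transformed; the grand average
#' across subjects carries a Bonferroni-corrected percentile bootstrap CI.
#' The default parcel set is the combined language + auditory network.
#'
#' @param fpt S x N x N array of per-subject log10 weights, or a
#'   `subject_stack`.
#' @param lengths A `tract_lengths`.
#' @param atlas A `parcel_atlas`.
#' @param network_set Integer parcel ids defining the grouped network;
#'   default [language_auditory_parcels()].
#' @param bin_mm Bin width (default 15 mm).
#' @param iters Bootstrap iterations (default 2000).
#' @param seed Integer seed.
#' @return A `distance_bin_profile`: list with `edges`, and for each
#'   hemisphere a data frame of per-bin `within`, `between` grand-average
#'   log10 means, their corrected CIs, the `differential` trace
#'   (within - between) with its CI, and per-bin pair counts. Empty bins
#'   are `NA`.
#' @export
distance_binned_profile <- function(fpt, lengths, atlas, network_set = NULL,
                                    bin_mm = 15, iters = 2000, seed = 1L) {
  if (inherits(fpt, "subject_stack")) fpt <- cv_matrix(fpt)$fpt
  if (is.null(network_set)) network_set <- language_auditory_parcels(atlas)
  ns <- dim(fpt)[1]
  dmax <- max(lengths$lengths[lengths$defined])
  edges <- seq(0, bin_mm * ceiling(dmax / bin_mm), by = bin_mm)
  nb <- length(edges) - 1L
  bin_of <- findInterval(lengths$lengths, edges, rightmost.closed = FALSE,
                         left.open = FALSE)
  dim(bin_of) <- dim(lengths$lengths)
  res <- list(edges = edges)
  # number of hypotheses for Bonferroni: bins x 2 groups x 2 hemispheres
  m_corr <- nb * 4L
  probs <- c(0.05 / m_corr / 2, 1 - 0.05 / m_corr / 2)
  idx <- local_rng(seed,
    matrix(sample.int(ns, ns * iters, replace = TRUE), iters, ns))
  for (hemi in c("left", "right")) {
    hi <- hemisphere_index(atlas, hemi)
    in_set <- intersect(network_set, hi)
    sel_in <- atlas$parcel_id %in% in_set
    sel_hemi <- atlas$parcel_id %in% hi
    within_mask <- outer(sel_in, sel_in, "&")
    between_mask <- (outer(sel_in, sel_hemi & !sel_in, "&") |
                     outer(sel_hemi & !sel_in, sel_in, "&"))
    diag(within_mask) <- FALSE
    ut <- upper.tri(within_mask)
    per_subj <- function(mask) {
      keep <- mask & ut & lengths$defined
      bins <- bin_of[keep]
      sapply(seq_len(nb), function(b) {
        cells <- which(keep)[bins == b]
        if (!length(cells)) return(rep(NA_real_, ns))
        vapply(seq_len(ns), function(s) {
          v <- fpt[s, , ][cells]
          v <- v[is.finite(v)]
          if (!length(v)) NA_real_ else log10(mean(10^v))
        }, numeric(1))
      })
    }
    w_mat <- per_subj(within_mask)   # ns x nb
    b_mat <- per_subj(between_mask)
    grand <- function(mat) colMeans(mat, na.rm = TRUE)
    boot_ci <- function(mat) {
      apply(mat, 2, function(col) {
        if (all(is.na(col))) return(c(NA_real_, NA_real_))
        bm <- rowMeans(matrix(col[idx], nrow(idx), ncol(idx)), na.rm = TRUE)
        stats::quantile(bm, probs = probs, names = FALSE, na.rm = TRUE)
      })
    }
    wci <- boot_ci(w_mat); bci <- boot_ci(b_mat)
    dmat <- w_mat - b_mat
    dci <- boot_ci(dmat)
    counts_in <- sapply(seq_len(nb), function(b)
      sum(within_mask & ut & lengths$defined & bin_of == b))
    counts_bt <- sapply(seq_len(nb), function(b)
      sum(between_mask & ut & lengths$defined & bin_of == b))
    res[[hemi]] <- data.frame(
      bin_low = edges[-length(edges)], bin_high = edges[-1],
      within = grand(w_mat), within_lo = wci[1, ], within_hi = wci[2, ],
      between = grand(b_mat), between_lo = bci[1, ], between_hi = bci[2, ],
      differential = grand(dmat), diff_lo = dci[1, ], diff_hi = dci[2, ],
      n_within = counts_in, n_between = counts_bt)
  }
  class(res) <- "distance_bin_profile"
  res
}
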