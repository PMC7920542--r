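toy_atlas <- function(n) synthetic_atlas(n)

test_that("ipsi-contra differential matches hand arithmetic on a toy matrix", {
  at <- synthetic_atlas(40)
  n <- 40; h <- 20
  ipsi <- pair_subset_mask(at, "left") | pair_subset_mask(at, "right")
  v <- matrix(0.1, n, n)
  v[ipsi] <- 0.4
  diag(v) <- NA
  f <- connectome_matrix(v, scale = "modality_raw", symmetric = TRUE)
  d <- ipsi_contra_differential(f, at)
  off <- !diag(TRUE, h)
  expect_equal(unname(d[off]), rep(0.3, sum(off)))
  # identical quadrants give zero differential
  v2 <- matrix(0.2, n, n); diag(v2) <- NA
  d2 <- ipsi_contra_differential(
    connectome_matrix(v2, scale = "modality_raw", symmetric = TRUE), at)
  expect_equal(unname(d2[off]), rep(0, sum(off)))
  # undefined constituent -> undefined differential
  v3 <- v; v3[1, 2] <- NA; v3[2, 1] <- NA
  d3 <- ipsi_contra_differential(
    connectome_matrix(v3, scale = "modality_raw"), at)
  expect_true(is.na(d3[1, 2]))
})

test_that("synthetic ipsilateral dominance yields mostly positive differentials", {
  # distance-flat generator with only an ipsilateral advantage: the
  # differential recovers the planted advantage everywhere
  cfg <- synthetic_config(n_parcels = 60, n_subjects = 8, seed = 8,
                          lambda_mm = 1e6, callosal_lambda = 1e6,
                          homolog_boost = 0, ipsi_advantage = 0.3,
                          network_block_boost = 0,
                          language_longrange_boost = 0,
                          hierarchy_coupling = 0, myelin_coupling = 0,
                          motion_coef = 0, group_noise_sd = 0.05,
                          noise_sd = 0.05)
  ds2 <- generate_dataset(cfg)
  f2 <- fpt_chain(group_average(ds2$stack))
  d2 <- ipsi_contra_differential(f2, ds2$atlas)
  off2 <- !diag(TRUE, nrow(d2))
  expect_gt(mean(d2[off2] > 0, na.rm = TRUE), 0.99)
  expect_equal(median(d2[off2], na.rm = TRUE), 0.3, tolerance = 0.1)
  # realistic default study: ipsilateral connectivity still dominates
  ds <- mid_ds()
  fpt <- fpt_chain(group_average(ds$stack))
  d <- ipsi_contra_differential(fpt, ds$atlas)
  off <- !diag(TRUE, nrow(d))
  expect_gt(mean(d[off] > 0, na.rm = TRUE), 0.6)
})

test_that("homolog test classifies a planted boost and stays seed-stable", {
  base <- list(n_parcels = 60L, n_subjects = 30L,
               lambda_mm = 1e6, callosal_lambda = 1e6,
               ipsi_advantage = 0, network_block_boost = 0,
               language_longrange_boost = 0, hierarchy_coupling = 0,
               myelin_coupling = 0, motion_coef = 0,
               group_noise_sd = 0, callosal_noise_sd = 0, area_sdlog = 0)
  boosted <- cached("homolog_boosted", {
    cfg <- do.call(synthetic_config, c(base, homolog_boost = 0.5, seed = 61L))
    cv_matrix(generate_dataset(cfg)$stack)$fpt
  })
  at <- synthetic_atlas(60)
  ht <- homolog_test(boosted, at, iters = 500, seed = 1)
  expect_equal(unname(table(ht$class)["hyper"]), 30L)
  expect_true(all(ht$ci_low > 0))
  # classification is stable across bootstrap seeds
  ht2 <- homolog_test(boosted, at, iters = 500, seed = 99)
  expect_gte(sum(ht$class == ht2$class), 29L)
  # class invariant: CI sign determines the label
  expect_true(all((ht$class == "hyper") == (ht$ci_low > 0)))
  # null: no boost, no fixed pair effects
  nullfpt <- cached("homolog_null", {
    cfg0 <- do.call(synthetic_config, c(base, homolog_boost = 0, seed = 61L))
    cv_matrix(generate_dataset(cfg0)$stack)$fpt
  })
  ht0 <- homolog_test(nullfpt, at, iters = 500, seed = 1)
  expect_lte(sum(ht0$class != "ns"), 2L)
})

test_that("distance bins partition pairs and the null profile covers zero", {
  ds <- mid_ds()
  vr <- cached("mid_vr", cv_matrix(ds$stack))
  prof <- distance_binned_profile(vr$fpt, ds$lengths, ds$atlas,
                                  bin_mm = 15, iters = 200, seed = 2)
  # half-open 15-mm bins partition the observed range
  expect_equal(prof$edges[2] - prof$edges[1], 15)
  dmax <- max(ds$lengths$lengths[ds$lengths$defined])
  expect_gte(max(prof$edges), dmax)
  for (hemi in c("left", "right")) {
    pr <- prof[[hemi]]
    lang <- language_auditory_parcels(ds$atlas, hemi)
    sel <- ds$atlas$parcel_id %in% lang
    wmask <- outer(sel, sel, "&"); diag(wmask) <- FALSE
    n_within <- sum(wmask & upper.tri(wmask) & ds$lengths$defined)
    expect_equal(sum(pr$n_within), n_within)  # every pair in exactly one bin
  }
})

test_that("a targeted long-range within-network boost shows up in the right bins", {
  cfg <- synthetic_config(n_parcels = 200, n_subjects = 8, seed = 71,
                          language_longrange_threshold_mm = 100,
                          language_longrange_boost = 0.8,
                          homolog_boost = 0, ipsi_advantage = 0,
                          network_block_boost = 0, hierarchy_coupling = 0,
                          myelin_coupling = 0, motion_coef = 0,
                          group_noise_sd = 0.03, noise_sd = 0.05)
  ds <- generate_dataset(cfg)
  vr <- cv_matrix(ds$stack)
  prof <- distance_binned_profile(vr$fpt, ds$lengths, ds$atlas,
                                  bin_mm = 15, iters = 200, seed = 3)
  for (hemi in c("left", "right")) {
    pr <- prof[[hemi]]
    populated <- pr$n_within >= 3 & pr$n_between >= 3 &
      is.finite(pr$differential)
    short_bins <- populated & pr$bin_high <= 90
    long_bins <- populated & pr$bin_low >= 105
    expect_true(any(long_bins))
    expect_gt(min(pr$differential[long_bins]),
              max(pr$differential[short_bins]))
    # boosted bins are credibly positive
    expect_true(all(pr$diff_lo[long_bins] > 0))
  }
})

test_that("bin averaging happens on the linear scale before the log", {
  # Jensen: log10(mean(10^x)) >= mean(x); equality only for constant bins
  ds <- mid_ds()
  vr <- cached("mid_vr", cv_matrix(ds$stack))
  prof <- distance_binned_profile(vr$fpt, ds$lengths, ds$atlas,
                                  bin_mm = 15, iters = 50, seed = 4)
  # oracle for one populated bin and subject: within-language, left
  lang <- language_auditory_parcels(ds$atlas, "left")
  sel <- ds$atlas$parcel_id %in% lang
  wmask <- outer(sel, sel, "&"); diag(wmask) <- FALSE
  keep <- wmask & upper.tri(wmask) & ds$lengths$defined
  pr <- prof$left
  b <- which.max(pr$n_within)
  inbin <- keep & ds$lengths$lengths >= pr$bin_low[b] &
    ds$lengths$lengths < pr$bin_high[b]
  per_subject <- vapply(seq_len(dim(vr$fpt)[1]), function(s) {
    v <- vr$fpt[s, , ][inbin]
    v <- v[is.finite(v)]
    log10(mean(10^v))
  }, numeric(1))
  expect_equal(pr$within[b], mean(per_subject), tolerance = 1e-12)
  # and the linear-first mean dominates the mean of logs
  mean_of_logs <- mean(vapply(seq_len(dim(vr$fpt)[1]), function(s) {
    v <- vr$fpt[s, , ][inbin]
    mean(v[is.finite(v)])
  }, numeric(1)))
  expect_gte(pr$within[b], mean_of_logs)
})
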