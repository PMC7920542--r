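test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- tiny_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$stack$counts, d2$stack$counts)
  expect_identical(d1$truth$log_weights, d2$truth$log_weights)
  expect_identical(d1$modalities$ccep$values, d2$modalities$ccep$values)
  expect_identical(d1$modalities$rsfmri$values, d2$modalities$rsfmri$values)
  # a different seed changes the draw
  d3 <- generate_dataset(synthetic_config(n_parcels = 40L, n_subjects = 12L,
                                          seed = 43L))
  expect_false(identical(d1$stack$counts, d3$stack$counts))
})

test_that("geometry is mirror-symmetric with positive symmetric lengths", {
  cfg <- tiny_config()
  geom <- generate_geometry(cfg)
  L <- geom$lengths$lengths
  expect_true(all(L[geom$lengths$defined] > 0))
  expect_equal(L, t(L))
  # homologs are mirror images: within-hemisphere distance profiles match
  h <- cfg$n_parcels %/% 2
  expect_equal(L[1:h, 1:h], L[(h + 1):(2 * h), (h + 1):(2 * h)],
               tolerance = 1e-9)
  cents <- geom$centroids
  expect_equal(cents[1:h, 1], -cents[(h + 1):(2 * h), 1])
  expect_equal(cents[1:h, 2:3], cents[(h + 1):(2 * h), 2:3])
  # unit routing and no detour reduce to Euclidean distance
  cfg0 <- synthetic_config(n_parcels = 40L, n_subjects = 2L, seed = 42L,
                           routing_factor = 1, callosal_detour_mm = 0)
  geom0 <- generate_geometry(cfg0)
  eu <- as.matrix(dist(geom0$centroids))
  expect_equal(geom0$lengths$lengths, eu, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("boost-free truth is a pure exponential the decay fit recovers", {
  cfg <- synthetic_config(n_parcels = 100, n_subjects = 2, seed = 121,
                          homolog_boost = 0, ipsi_advantage = 0,
                          network_block_boost = 0,
                          language_longrange_boost = 0,
                          hierarchy_coupling = 0, myelin_coupling = 0,
                          callosal_lambda = 23.4, callosal_noise_sd = 0,
                          group_noise_sd = 0.05, motion_coef = 0)
  geom <- generate_geometry(cfg)
  truth <- generate_truth(cfg, geom)
  v <- truth$log_weights
  keep <- upper.tri(v) & is.finite(v)
  fit <- fit_exponential(10^v[keep], geom$lengths$lengths[keep])
  expect_lt(abs(fit$lambda_mm - 23.4) / 23.4, 0.02)
  # with all structure off and no scatter the relation is exact
  cfg0 <- synthetic_config(n_parcels = 60, n_subjects = 2, seed = 122,
                           homolog_boost = 0, ipsi_advantage = 0,
                           network_block_boost = 0,
                           language_longrange_boost = 0,
                           hierarchy_coupling = 0, myelin_coupling = 0,
                           callosal_lambda = 23.4, group_noise_sd = 0,
                           callosal_noise_sd = 0, motion_coef = 0)
  geom0 <- generate_geometry(cfg0)
  truth0 <- generate_truth(cfg0, geom0)
  v0 <- truth0$log_weights
  keep0 <- upper.tri(v0) & is.finite(v0)
  fit0 <- fit_exponential(10^v0[keep0], geom0$lengths$lengths[keep0])
  expect_equal(fit0$lambda_mm, 23.4, tolerance = 1e-4)
  expect_equal(fit0$r2, 1, tolerance = 1e-8)
})

test_that("homolog entries are the strongest callosal weights by construction", {
  ds <- tiny_ds()
  lw <- ds$truth$log_weights
  at <- ds$atlas
  cal <- pair_subset_mask(at, "callosal") & upper.tri(lw)
  hom <- homolog_mask(at) & upper.tri(lw)
  hom_mean <- mean(lw[hom & cal])
  other_mean <- mean(lw[cal & !hom])
  expect_gt(hom_mean, other_mean)
})

test_that("large counts concentrate subject weights at the truth", {
  cfg <- synthetic_config(n_parcels = 30, n_subjects = 3, seed = 123,
                          noise_sd = 0, subject_sd = 0, motion_coef = 0,
                          area_meanlog = log(3000))
  ds <- generate_dataset(cfg)
  f <- fpt_chain(connectome_matrix(ds$stack$counts[1, , ],
                                   scale = "raw_counts"))
  # compare against the fractional weights implied by the noiseless truth
  mu <- 10^ds$truth$log_weights
  diag(mu) <- 0
  voxels <- pmax(1, round(ds$truth$areas / cfg$voxel_area_mm2))
  counts_exp <- mu * matrix(cfg$samples_per_voxel * voxels, 30, 30)
  ftruth <- fpt_chain(connectome_matrix(counts_exp, scale = "raw_counts"))
  keep <- f$defined & ftruth$defined
  rel <- abs(10^f$values[keep] - 10^ftruth$values[keep]) /
    10^ftruth$values[keep]
  expect_lt(median(rel), 0.05)
})

test_that("motion coupling induces a negative lambda-motion correlation", {
  cfg <- synthetic_config(n_parcels = 60, n_subjects = 14, seed = 124,
                          motion_coef = 0.4,
                          homolog_boost = 0, ipsi_advantage = 0,
                          network_block_boost = 0,
                          language_longrange_boost = 0,
                          hierarchy_coupling = 0, myelin_coupling = 0,
                          callosal_lambda = 23.4, noise_sd = 0.1)
  ds <- generate_dataset(cfg)
  lam <- per_subject_lambda(ds$stack, ds$lengths)
  rel <- motion_lambda_relation(lam, ds$stack$motion_index)
  expect_lt(rel$r, -0.5)
})

test_that("modality emulation honours the missingness and mode settings", {
  ds <- tiny_ds()
  cfg <- tiny_config()
  cc <- ds$modalities$ccep
  off <- row(cc$values) != col(cc$values)
  miss_frac <- sum(!cc$defined & off) / sum(off)
  expect_equal(miss_frac, cfg$ccep_missing_fraction, tolerance = 0.02)
  # missingness is biased toward callosal pairs
  cal <- pair_subset_mask(ds$atlas, "callosal")
  miss <- !cc$defined & off
  expect_gt(sum(miss & cal) / sum(miss), sum(cal[off]) / sum(off))
  # no missingness when the fraction is zero
  cfg0 <- synthetic_config(n_parcels = 40L, n_subjects = 2L, seed = 42L,
                           ccep_missing_fraction = 0)
  ds0 <- generate_dataset(cfg0)
  expect_true(all(ds0$modalities$ccep$defined[off]))
  # rs-fMRI low mode sits at the configured proportion
  low <- ds$modalities$rsfmri_low_mode
  expect_equal(sum(low[upper.tri(low)]) / sum(upper.tri(low) & off),
               cfg$rsfmri_pi1, tolerance = 0.02)
})

test_that("well-separated rs-fMRI emulation is recovered by the mixture fit", {
  cfg <- synthetic_config(n_parcels = 120, n_subjects = 2, seed = 125,
                          rsfmri_sigma = 1e-8)
  ds <- generate_dataset(cfg)
  fit <- gmm2_fit(cm_values(ds$modalities$rsfmri, upper = TRUE), seed = 3)
  expect_lt(abs(fit$mu[1] - cfg$rsfmri_mu[1]) / cfg$rsfmri_mu[1], 0.05)
  expect_lt(abs(fit$mu[2] - cfg$rsfmri_mu[2]) / cfg$rsfmri_mu[2], 0.05)
  expect_lt(abs(fit$pi[1] - cfg$rsfmri_pi1) / cfg$rsfmri_pi1, 0.05)
})
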