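#' Configuration for the synthetic connectome generator
#'
#' Bundles every tunable of the generator with defaults chosen to emulate
#' the statistical structure of a group-average probabilistic-tractography
#' connectome: lognormally distributed pairwise weights decaying
#' exponentially with tract length (ipsilateral length constant 23.4 mm,
#' callosal 32.8 mm), ipsilateral dominance, contralateral-homolog
#' hyperconnectivity, 10-network block structure per hemisphere,
#' across-subject variability with Poisson counting noise at 5000 samples
#' per seed voxel, long-range hyperconnectivity of the combined
#' language+auditory network, myelination coupling, a CCEP-like matrix with
#' missing entries biased toward interhemispheric pairs, and a bimodal
#' rs-fMRI-like matrix.
#'
#' @param n_parcels Even parcel count (default 360).
#' @param n_subjects Cohort size (default 24).
#' @param lambda_mm Ipsilateral length constant, mm (default 23.4).
#' @param callosal_lambda Callosal length constant, mm (default 32.8).
#' @param alpha Scaling coefficient of the decay (fractional weight at
#'   d = 0; default 0.05).
#' @param homolog_boost Log10 boost on homolog pairs (default 0.5).
#' @param ipsi_advantage Log10 advantage of ipsilateral pairs (default
#'   0.15).
#' @param network_block_boost Log10 boost on within-network ipsilateral
#'   pairs (default 0.1).
#' @param noise_sd Pair-level log10 noise sd per subject (default 0.25).
#' @param noise_distance_coupling When nonzero, scales the per-subject
#'   pair noise by `1 + coupling * (1 - d/max(d))`, making short-range
#'   connections noisier across subjects (default 0, homoscedastic).
#' @param bilateral_noise_frac Fraction of the per-subject pair noise
#'   variance shared between a connection and its mirror image in the
#'   opposite hemisphere (default 0.7). This emulates the strong
#'   across-hemisphere covariance of individual connection strengths and
#'   makes homologous connections correlate across subjects at roughly
#'   this level.
#' @param group_noise_sd Pair-level log10 noise sd baked into the group
#'   truth (default 0.12; this is the scatter around the decay curve and
#'   sets the variance explained by the distance rule).
#' @param callosal_noise_sd Additional log10 scatter on interhemispheric
#'   pairs (default 0.1), emulating the lower consistency of callosal
#'   connectivity with the exponential expectation.
#' @param subject_sd Subject-level global log10 offset sd (default 0.1).
#' @param samples_per_voxel Probabilistic samples per seed voxel (5000).
#' @param area_meanlog,area_sdlog Lognormal parcel-area distribution, mm^2
#'   (defaults log(300), 0.4).
#' @param voxel_area_mm2 Interface area of one seed voxel (1.25 mm grid,
#'   default 1.5625).
#' @param language_longrange_threshold_mm,language_longrange_boost Distance
#'   threshold and log10 boost for long-range within-language/auditory
#'   connections (defaults 100 mm, 0.3).
#' @param myelin_coupling Strength of the negative loading of the
#'   designated (prefrontal) parcels' rows on the myelination vector
#'   (default 0.4 log10 units per myelination z-unit).
#' @param hierarchy_coupling Log10 penalty per unit |delta myelination| on
#'   ipsilateral pairs (default 0.3).
#' @param motion_coef Attenuation of long-range log10 weight per motion
#'   unit per 100 mm (default 0.02; set 0 to decouple).
#' @param rsfmri_mu Component means of the bimodal rs-fMRI-like weights
#'   (defaults 0.0011, 0.0017).
#' @param rsfmri_pi1 Low-mode proportion (default 0.63).
#' @param rsfmri_sigma Printed dispersion parameter 8.1e-8, interpreted per
#'   `rsfmri_sigma_is_variance`.
#' @param rsfmri_sigma_is_variance Interpret `rsfmri_sigma` as component
#'   variance (default `TRUE`, sd ~ 2.85e-4) rather than sd.
#' @param rsfmri_coupling Correlation-inducing loading of the rs-fMRI noise
#'   on the structural truth, in component sds (default 0.08, giving the
#'   weak structure-function correlation typical of resting-state data).
#' @param ccep_noise_sd Log10 noise added to the CCEP-like matrix (default
#'   1.7, chosen so the CCEP-dMRI correlation sits near the moderate values
#'   observed for stimulation-derived connectivity).
#' @param ccep_missing_fraction Fraction of pairs masked missing (0.3).
#' @param ccep_callosal_missing_bias Odds multiplier biasing missingness
#'   toward callosal pairs (default 3).
#' @param routing_factor Tract length = Euclidean distance x this (1.3).
#' @param callosal_detour_mm Additive interhemispheric detour (20).
#' @param seed Base seed; all stages derive their streams from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_parcels = 360L, n_subjects = 24L,
                             lambda_mm = 23.4, callosal_lambda = 32.8,
                             alpha = 0.05,
                             homolog_boost = 0.5, ipsi_advantage = 0.15,
                             network_block_boost = 0.1,
                             noise_sd = 0.25, noise_distance_coupling = 0,
                             bilateral_noise_frac = 0.7,
                             group_noise_sd = 0.12,
                             callosal_noise_sd = 0.1,
                             subject_sd = 0.1,
                             samples_per_voxel = 5000,
                             area_meanlog = log(300), area_sdlog = 0.4,
                             voxel_area_mm2 = 1.5625,
                             language_longrange_threshold_mm = 100,
                             language_longrange_boost = 0.3,
                             myelin_coupling = 0.4,
                             hierarchy_coupling = 0.3,
                             motion_coef = 0.02,
                             rsfmri_mu = c(0.0011, 0.0017),
                             rsfmri_pi1 = 0.63,
                             rsfmri_sigma = 8.1e-8,
                             rsfmri_sigma_is_variance = TRUE,
                             rsfmri_coupling = 0.08,
                             ccep_noise_sd = 1.7,
                             ccep_missing_fraction = 0.3,
                             ccep_callosal_missing_bias = 3,
                             routing_factor = 1.3,
                             callosal_detour_mm = 20,
                             seed = 1L) {
  if (n_parcels %% 2L != 0L) stop("n_parcels must be even")
  if (rsfmri_pi1 <= 0 || rsfmri_pi1 >= 1) stop("rsfmri_pi1 must be in (0,1)")
  if (ccep_missing_fraction >= 1) stop("ccep_missing_fraction must be < 1")
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Synthetic parcel atlas
#'
#' Builds a valid atlas for an arbitrary even parcel count: mirrored
#' hemispheres, 10 networks per hemisphere assigned in contiguous blocks
#' proportional to the real 10-network scheme. For 360 parcels the packaged
#' atlas is used instead so synthetic data keep the real parcel names.
#'
#' @param n_parcels Even parcel count.
#' @return A `parcel_atlas`.
#' @export
synthetic_atlas <- function(n_parcels) {
  if (n_parcels == 360L) return(load_atlas())
  h <- n_parcels %/% 2L
  if (h < 10L) stop("need at least 20 parcels for a 10-network scheme")
  labels <- c("Visual", "Somatomotor", "Cingulo-opercular", "Dorsal attention",
              "Language", "Frontoparietal", "Auditory", "Default mode",
              "Multimodal", "Orbito-affective")
  weights <- c(29, 19, 28, 12, 14, 22, 8, 40, 5, 3) / 180
  sizes <- pmax(1L, as.integer(floor(weights * h)))
  while (sum(sizes) < h) sizes[which.max(weights * h - sizes)] <-
    sizes[which.max(weights * h - sizes)] + 1L
  while (sum(sizes) > h) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  network <- rep(labels, times = sizes)
  df <- data.frame(
    parcel_id = seq_len(n_parcels),
    name = rep(sprintf("P%03d", seq_len(h)), 2),
    hemisphere = rep(c("left", "right"), each = h),
    network = rep(network, 2),
    display_order = seq_len(n_parcels),
    original_index = seq_len(n_parcels),
    stringsAsFactors = FALSE)
  as_parcel_atlas(df)
}

#' Generate mirrored hemispheric geometry and tract lengths
#'
#' Places parcels on two mirror-image ellipsoidal shells and derives fiber
#' tract lengths as Euclidean distance times a routing factor, plus an
#' additive detour for interhemispheric pairs. Homologs are exact mirror
#' images, so within-hemisphere distance profiles match across hemispheres.
#'
#' @param config A `synthetic_config`.
#' @return List with `lengths` (a `tract_lengths`), `centroids` (N x 3),
#'   and `atlas`.
#' @export
generate_geometry <- function(config) {
  n <- config$n_parcels
  h <- n %/% 2L
  atlas <- synthetic_atlas(n)
  semi <- c(55, 85, 60)
  centre <- c(35, 0, 0)
  pts <- local_rng(config$seed + 101L, {
    u <- matrix(stats::rnorm(3 * h), h, 3)
    u <- u / sqrt(rowSums(u^2))
    sweep(u, 2, semi, "*")
  })
  left <- sweep(pts, 2, c(-centre[1], centre[2], centre[3]), "+")
  left[, 1] <- -abs(left[, 1]) - 5  # keep the shell on its own side
  right <- left
  right[, 1] <- -left[, 1]          # mirror in x
  centroids <- rbind(left, right)
  if (any(stats::dist(centroids) < 1e-6)) stop("degenerate coincident centroids")
  eu <- as.matrix(stats::dist(centroids))
  callosal <- pair_subset_mask(atlas, "callosal")
  lengths <- eu * config$routing_factor + callosal * config$callosal_detour_mm
  diag(lengths) <- 0
  list(lengths = tract_lengths(lengths, parcels = atlas$name),
       centroids = centroids, atlas = atlas)
}

#' Generate the noiseless-plus-structure ground-truth connectome
#'
#' Builds the group-level log10 weight surface: exponential distance decay
#' (callosal pairs use the callosal length constant), plus the homolog,
#' ipsilateral, within-network and long-range language boosts, a
#' myelination vector with its couplings, and pair-level lognormal scatter.
#'
#' @param config A `synthetic_config`.
#' @param geometry Output of [generate_geometry()].
#' @return A `ground_truth` list: `log_weights` (symmetric N x N),
#'   `components` (named list of additive effect matrices), `myelination`,
#'   `areas`, `atlas`, `lengths`, `config`.
#' @export
generate_truth <- function(config, geometry) {
  atlas <- geometry$atlas
  n <- config$n_parcels
  d <- geometry$lengths$lengths
  callosal <- pair_subset_mask(atlas, "callosal")
  ipsi <- pair_subset_mask(atlas, "left") | pair_subset_mask(atlas, "right")
  lam <- matrix(config$lambda_mm, n, n)
  lam[callosal] <- config$callosal_lambda
  decay <- log10(config$alpha) - d / (lam * log(10))
  hom <- homolog_mask(atlas) * config$homolog_boost
  ips <- ipsi * config$ipsi_advantage
  net <- matrix(0, n, n)
  for (nw in unique(atlas$network)) {
    for (hemi in c("left", "right")) {
      net <- net + network_block_mask(atlas, nw, hemi) * config$network_block_boost
    }
  }
  lang <- language_auditory_parcels(atlas)
  in_lang <- atlas$parcel_id %in% lang
  lang_mask <- outer(in_lang, in_lang, "&") & ipsi &
    d > config$language_longrange_threshold_mm
  lng <- lang_mask * config$language_longrange_boost
  rngout <- local_rng(config$seed + 202L, {
    areas <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
    half <- n %/% 2L
    areas[(half + 1L):n] <- areas[seq_len(half)]  # homologs share area
    sensory <- atlas$network %in% c("Visual", "Somatomotor", "Auditory")
    myel <- 1.3 + 0.4 * sensory + stats::rnorm(n, 0, 0.15)
    z <- matrix(stats::rnorm(n * n, 0, config$group_noise_sd), n, n)
    scatter <- (z + t(z)) / sqrt(2)
    zc <- matrix(stats::rnorm(n * n, 0, config$callosal_noise_sd), n, n)
    scatter <- scatter + callosal * (zc + t(zc)) / sqrt(2)
    list(areas = areas, myel = myel, scatter = scatter)
  })
  myel <- rngout$myel
  hier <- -config$hierarchy_coupling * abs(outer(myel, myel, "-")) * ipsi
  # prefrontal territory: frontoparietal network plus the prefrontal
  # parcels of the default-mode network (when the real atlas is in use)
  prefrontal_dm <- c("a24", "d32", "p32", "10r", "47m", "8Av", "8Ad", "9m",
                     "8BL", "9p", "10d", "47l", "9a", "10v", "10pp", "OFC",
                     "47s")
  designated <- which(atlas$network == "Frontoparietal" |
                      atlas$name %in% prefrontal_dm)
  zmy <- as.numeric(scale(myel))
  myl <- matrix(0, n, n)
  myl[designated, ] <- myl[designated, ] -
    config$myelin_coupling * matrix(zmy, length(designated), n, byrow = TRUE)
  myl <- (myl + t(myl)) / 2
  components <- list(decay = decay, homolog = hom, ipsilateral = ips,
                     network = net, language_longrange = lng,
                     hierarchy = hier, myelin_rows = myl,
                     scatter = rngout$scatter)
  lw <- Reduce(`+`, components)
  lw <- (lw + t(lw)) / 2
  diag(lw) <- NA_real_
  structure(list(log_weights = lw, components = components,
                 myelination = myel, areas = rngout$areas,
                 designated_parcels = designated,
                 atlas = atlas, lengths = geometry$lengths,
                 centroids = geometry$centroids, config = config),
            class = "ground_truth")
}

#' Sample a multi-subject stack of streamline counts from the truth
#'
#' Each subject receives a global lognormal offset (subject effect) and
#' pair-level lognormal noise on the log10 weights; expected directional
#' streamline counts are the linear weights times the per-parcel number of
#' sampled streamlines (samples per voxel x seed voxels, voxels from the
#' parcel area), and observed counts are Poisson. Motion indices are drawn
#' per subject and, when `motion_coef > 0`, attenuate long-range weights.
#'
#' @param truth A `ground_truth`.
#' @param config Defaults to `truth$config`.
#' @return A `subject_stack` (with `motion_index` populated).
#' @export
sample_subjects <- function(truth, config = truth$config) {
  n <- config$n_parcels
  s <- config$n_subjects
  d <- truth$lengths$lengths
  voxels <- pmax(1, round(truth$areas / config$voxel_area_mm2))
  draws <- config$samples_per_voxel * voxels  # per seed parcel
  counts <- array(0, c(s, n, n))
  motion <- local_rng(config$seed + 303L, stats::rlnorm(s, 0, 0.5))
  local_rng(config$seed + 404L, {
    h <- n %/% 2L
    iL <- seq_len(h); iR <- h + iL
    for (k in seq_len(s)) {
      subj_eff <- stats::rnorm(1, 0, config$subject_sd)
      z <- matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
      noise <- (z + t(z)) / sqrt(2)
      fb <- config$bilateral_noise_frac
      if (fb > 0) {
        # mirror-shared component: a connection and its contralateral
        # image draw part of their subject-level deviation from one source
        zi <- matrix(stats::rnorm(h * h, 0, config$noise_sd), h, h)
        zi <- (zi + t(zi)) / sqrt(2)
        zc <- matrix(stats::rnorm(h * h, 0, config$noise_sd), h, h)
        zc <- (zc + t(zc)) / sqrt(2)
        shared <- matrix(0, n, n)
        shared[iL, iL] <- zi; shared[iR, iR] <- zi
        shared[iL, iR] <- zc; shared[iR, iL] <- t(zc)
        noise <- sqrt(1 - fb) * noise + sqrt(fb) * shared
      }
      if (config$noise_distance_coupling != 0) {
        dmax <- max(d)
        noise <- noise * (1 + config$noise_distance_coupling * (1 - d / dmax))
      }
      lw <- truth$log_weights + subj_eff + noise -
        config$motion_coef * motion[k] * d / 100
      mu <- 10^lw * matrix(draws, n, n)  # row parcel seeds the streamlines
      mu[!is.finite(mu)] <- 0
      counts[k, , ] <- stats::rpois(n * n, pmin(mu, 1e9))
    }
  })
  subject_stack(counts, motion_index = motion)
}

#' Emulate evoked-potential and resting-state modality matrices
#'
#' The CCEP-like matrix is the structural log-weight truth plus Gaussian
#' noise, with a configurable fraction of entries masked missing, the
#' missingness biased toward interhemispheric pairs (mimicking poor
#' interhemispheric stimulation sampling). The rs-fMRI-like matrix is a
#' two-component Gaussian mixture in linear space whose low mode is
#' assigned to the connections between the default-mode/frontoparietal
#' blocks and the rest of the cortex.
#'
#' @param truth A `ground_truth`.
#' @param config Defaults to `truth$config`.
#' @return List with `ccep` (`connectome_matrix`, log10 scale with missing
#'   mask), `rsfmri` (`connectome_matrix`, linear scale), and
#'   `rsfmri_low_mode` (logical matrix of planted low-mode pairs).
#' @export
emulate_modalities <- function(truth, config = truth$config) {
  n <- config$n_parcels
  atlas <- truth$atlas
  lw <- truth$log_weights
  sigma <- if (config$rsfmri_sigma_is_variance) sqrt(config$rsfmri_sigma) else
    config$rsfmri_sigma
  out <- local_rng(config$seed + 505L, {
    z <- matrix(stats::rnorm(n * n, 0, config$ccep_noise_sd), n, n)
    ccep_vals <- lw + (z + t(z)) / sqrt(2)
    callosal <- pair_subset_mask(atlas, "callosal")
    ut <- which(upper.tri(ccep_vals))
    odds <- ifelse(callosal[ut], config$ccep_callosal_missing_bias, 1)
    n_missing <- round(config$ccep_missing_fraction * length(ut))
    miss_ut <- if (n_missing > 0)
      sample(ut, n_missing, prob = odds) else integer(0)
    missing <- matrix(FALSE, n, n)
    missing[miss_ut] <- TRUE
    missing <- missing | t(missing)
    # rs-fMRI: rank pairs by low-mode affinity, take the configured fraction
    dmn <- atlas$network %in% c("Default mode", "Frontoparietal")
    between_block <- xor(matrix(dmn, n, n), matrix(dmn, n, n, byrow = TRUE))
    score <- between_block[ut] * 1 + stats::runif(length(ut), 0, 0.5)
    n_low <- round(config$rsfmri_pi1 * length(ut))
    low_ut <- ut[order(score, decreasing = TRUE)[seq_len(n_low)]]
    low <- matrix(FALSE, n, n)
    low[low_ut] <- TRUE
    low <- low | t(low)
    mu_mat <- ifelse(low, config$rsfmri_mu[1], config$rsfmri_mu[2])
    eps <- matrix(stats::rnorm(n * n, 0, sigma), n, n)
    eps <- (eps + t(eps)) / sqrt(2)
    lz <- as.numeric(scale(lw[is.finite(lw)]))
    zlw <- lw
    zlw[is.finite(lw)] <- lz
    zlw[!is.finite(lw)] <- 0
    rs_vals <- pmax(mu_mat + eps + config$rsfmri_coupling * sigma * zlw, 1e-9)
    list(ccep_vals = ccep_vals, missing = missing, rs_vals = rs_vals,
         low = low)
  })
  ccep_def <- !out$missing
  diag(ccep_def) <- FALSE
  ccep <- connectome_matrix(out$ccep_vals, scale = "log10_fractional",
                            symmetric = TRUE, defined = ccep_def,
                            parcels = atlas$name)
  rsf <- connectome_matrix(out$rs_vals, scale = "modality_raw",
                           symmetric = TRUE, parcels = atlas$name)
  list(ccep = ccep, rsfmri = rsf, rsfmri_low_mode = out$low)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running geometry, truth, subject sampling and
#' modality emulation under one configuration. Fully deterministic given
#' `(config, config$seed)`.
#'
#' @param config A `synthetic_config` (default [synthetic_config()]).
#' @return List with `atlas`, `lengths`, `truth`, `stack`, `modalities`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  geom <- generate_geometry(config)
  truth <- generate_truth(config, geom)
  stack <- sample_subjects(truth, config)
  modal <- emulate_modalities(truth, config)
  list(atlas = geom$atlas, lengths = geom$lengths, truth = truth,
       stack = stack, modalities = modal)
}
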