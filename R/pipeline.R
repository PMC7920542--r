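#' Run the full connectome analysis pipeline
#'
#' Orchestrates the stages in dependency order on either a synthetic study
#' (when `config` describes the generator) or user-supplied inputs: group
#' averaging, the normalization chain, distance-decay fits per hemispheric
#' subset, interindividual variability, the contralateral-homolog test, the
#' distance-binned language-network profile, hierarchy correlations, a
#' graph-metric density sweep, and the intermodal mixture fit. Each stage
#' writes delimited/JSON outputs under `out_dir` and is recorded, with
#' input digests and seeds, in a reproducibility manifest.
#'
#' @param config A `synthetic_config`, or a path to a YAML file whose keys
#'   mirror [synthetic_config()] arguments.
#' @param out_dir Output directory.
#' @param homolog_iters,profile_iters Bootstrap iterations for the
#'   laterality stages (default 2000).
#' @param sweep_densities,sweep_shuffles Graph-metric sweep grid and node
#'   shuffles (kept small by default; the sweep scales linearly in both).
#' @return A `run_manifest` list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = tempfile("cortconn_run_"),
                         homolog_iters = 2000, profile_iters = 2000,
                         sweep_densities = c(0.1, 0.2, 0.3),
                         sweep_shuffles = 10) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(synthetic_config, cfg_list)
  }
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(stage, ...) {
    stages[[stage]] <<- list(outputs = unname(c(...)))
  }

  ds <- generate_dataset(config)
  write_subject_stack(ds$stack, file.path(out_dir, "stack"), ds$lengths)
  note("simulate", file.path(out_dir, "stack"))

  grp <- group_average(ds$stack)
  fpt <- fpt_chain(grp)
  f_path <- file.path(out_dir, "fpt_group.csv")
  write_matrix(fpt, f_path)
  mom <- moments(cm_values(fpt, upper = TRUE), seed = config$seed + 1L)
  mom_path <- file.path(out_dir, "fpt_moments.json")
  jsonlite::write_json(
    list(signed = mom[c("mean", "sd", "skewness", "kurtosis")],
         magnitude = mom$magnitude, n_pairs = mom$n),
    mom_path, auto_unbox = TRUE, digits = NA)
  note("normalize", f_path, mom_path)

  fits <- lapply(c("all", "left", "right", "callosal"), function(ss)
    subset_fit(fpt, ds$lengths, ds$atlas, ss))
  names(fits) <- c("all", "left", "right", "callosal")
  decay_path <- file.path(out_dir, "decay_fits.json")
  jsonlite::write_json(
    lapply(fits, function(f) f[c("lambda_mm", "alpha", "r2", "ci95_lambda",
                                 "n_pairs", "subset")]),
    decay_path, auto_unbox = TRUE, digits = NA)
  note("fit_decay", decay_path)

  vr <- cv_matrix(ds$stack)
  cv_path <- file.path(out_dir, "cv.csv")
  write_matrix(connectome_matrix(vr$cv, scale = "modality_raw",
                                 defined = vr$defined,
                                 parcels = ds$atlas$name), cv_path)
  note("variability", cv_path)

  ht <- homolog_test(vr$fpt, ds$atlas, iters = homolog_iters,
                     seed = config$seed + 2L)
  ht_path <- file.path(out_dir, "homolog_test.csv")
  utils::write.csv(ht, ht_path, row.names = FALSE)
  prof <- distance_binned_profile(vr$fpt, ds$lengths, ds$atlas,
                                  iters = profile_iters,
                                  seed = config$seed + 3L)
  prof_path <- file.path(out_dir, "language_profile.json")
  jsonlite::write_json(list(edges = prof$edges, left = prof$left,
                            right = prof$right),
                       prof_path, auto_unbox = TRUE, digits = NA)
  note("laterality", ht_path, prof_path)

  H <- myelin_similarity(ds$truth$myelination, parcels = ds$atlas$name)
  hier <- list(
    left = network_hierarchy_correlation(fpt, H, ds$atlas, "left"),
    right = network_hierarchy_correlation(fpt, H, ds$atlas, "right"),
    callosal = network_hierarchy_correlation(fpt, H, ds$atlas, "callosal"))
  pw <- parcelwise_myelin_correlation(fpt, ds$truth$myelination, ds$atlas)
  hier_path <- file.path(out_dir, "hierarchy.json")
  jsonlite::write_json(
    list(scope_correlations = hier,
         parcelwise_significant = sum(pw$significant),
         parcelwise_negative = sum(pw$significant & pw$sign == "negative")),
    hier_path, auto_unbox = TRUE, digits = NA)
  note("hierarchy", hier_path)

  w <- fpt$values
  w[!fpt$defined] <- NA
  sweep <- metric_sweep(w, densities = sweep_densities,
                        node_shuffles = sweep_shuffles,
                        partition = paste(ds$atlas$network, ds$atlas$hemisphere),
                        seed = config$seed + 4L)
  sweep_path <- file.path(out_dir, "metric_sweep.csv")
  utils::write.csv(sweep, sweep_path, row.names = FALSE)
  note("netmetrics", sweep_path)

  gfit <- gmm2_fit(cm_values(ds$modalities$rsfmri, upper = TRUE),
                   seed = config$seed + 5L)
  cc <- paired_correlation(fpt, ds$modalities$ccep)
  rf <- paired_correlation(fpt, ds$modalities$rsfmri)
  inter_path <- file.path(out_dir, "intermodal.json")
  jsonlite::write_json(
    list(gmm = gfit[c("mu", "sigma", "pi", "split_point", "loglik")],
         r_dmri_ccep = cc, r_dmri_rsfmri = rf),
    inter_path, auto_unbox = TRUE, digits = NA)
  note("intermodal", inter_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cortconn")),
    config = unclass(config),
    seed = config$seed,
    stages = stages,
    digests = output_digests(stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$out_dir <- out_dir
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

output_digests <- function(stages) {
  files <- unlist(lapply(stages, `[[`, "outputs"), use.names = FALSE)
  files <- unlist(lapply(files, function(f) {
    if (dir.exists(f)) list.files(f, full.names = TRUE) else f
  }))
  md5 <- tools::md5sum(files)
  as.list(stats::setNames(unname(md5), basename(files)))
}

#' Verify a run against its manifest
#'
#' Recomputes the digests of the run's output files and warns about any
#' mismatch (tampered or regenerated outputs).
#'
#' @param manifest A `run_manifest` (or path to a `manifest.json` plus its
#'   run directory).
#' @param out_dir Run directory; defaults to the manifest's.
#' @return Logical: `TRUE` when all digests match, invisibly; mismatches
#'   raise a warning naming the files.
#' @export
verify_manifest <- function(manifest, out_dir = manifest$out_dir) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    class(manifest) <- "run_manifest"
  }
  digests <- output_digests(manifest$stages)
  old <- manifest$digests
  common <- intersect(names(digests), names(old))
  bad <- common[vapply(common, function(f)
    !identical(digests[[f]], old[[f]]), logical(1))]
  if (length(bad)) {
    warning("manifest digest mismatch for: ", paste(bad, collapse = ", "))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
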