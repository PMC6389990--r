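# End-to-end orchestration of the synthetic experiment: simulate -> decode
# under the six coordinate models -> permutation null -> model comparison ->
# ROI decoding -> searchlight RSA with group inference.

#' Experiment configuration
#'
#' Bundles the generator settings with the decoding and RSA parameters. The
#' master `seed` is split hierarchically (simulation, permutations, RSA), so
#' a configuration fully determines every number in the report, and stages
#' can be rerun in isolation with identical outcomes.
#'
#' @param sim A [sim_config()].
#' @param n_subjects Number of synthetic subjects (default 17).
#' @param k_stable Stability-selected voxel count for averaged decoding
#'   (default 500).
#' @param lambda Ridge policy: `"gcv"` or a fixed value.
#' @param n_permutations Decoding permutation iterations per subject
#'   (default 1000).
#' @param rsa_radius_mm Searchlight radius (default 7).
#' @param rsa_fwhm_mm Map- and variance-smoothing FWHM (default 6).
#' @param rsa_n_perm Sign-flip permutations for group inference
#'   (default 10000).
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), n_subjects = 17L,
                              k_stable = 500L, lambda = "gcv",
                              n_permutations = 1000L, rsa_radius_mm = 7,
                              rsa_fwhm_mm = 6, rsa_n_perm = 10000L,
                              seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  structure(list(
    sim = sim,
    n_subjects = assert_count(n_subjects, "n_subjects"),
    k_stable = assert_count(k_stable, "k_stable"),
    lambda = if (identical(lambda, "gcv")) "gcv" else as.numeric(lambda),
    n_permutations = assert_count(n_permutations, "n_permutations"),
    rsa_radius_mm = as.numeric(rsa_radius_mm),
    rsa_fwhm_mm = as.numeric(rsa_fwhm_mm),
    rsa_n_perm = assert_count(rsa_n_perm, "rsa_n_perm"),
    seed = assert_count(seed, "seed")
  ), class = "experiment_config")
}

#' Save / load an experiment configuration (YAML)
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   `experiment_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  lst <- unclass(config)
  lst$sim <- unclass(lst$sim)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- do.call(sim_config, lst$sim)
  lst$sim <- sim
  do.call(experiment_config, lst)
}

stage_message <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full synthetic experiment
#'
#' Simulates a multi-subject dataset, runs averaged-data decoding (target-word
#' coordinates), single-trial decoding under all six coordinate models,
#' pooled permutation nulls, across-subject model comparison, ROI decoding
#' restricted to each subject's informative voxels, and the searchlight RSA
#' with sign-flip group inference. All stages are deterministic under the
#' master seed. When `out_dir` is given, stage outputs are checkpointed there
#' as they complete.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory for checkpoint files.
#' @param verbose Print stage progress (default FALSE).
#' @return A list of class `semdec_report`; see [render_report()].
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 3L)
  sim_cfg <- config$sim
  sim_cfg$seed <- seeds[1L]
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  checkpoint <- function(tbl, name) {
    if (!is.null(out_dir)) {
      utils::write.table(tbl, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  stage_message(verbose, "simulating %d subject(s)", config$n_subjects)
  ds <- simulate_experiment(sim_cfg, config$n_subjects)

  Y_target <- design_matrix(ds$trials, "TARGET", ds$norms, ds$map, ds$space,
                            level = "target")
  Y_allfeat <- ds$target_coordinates
  trial_Y <- lapply(setNames(nm = coordinate_models()), function(m) {
    design_matrix(ds$trials, m, ds$norms, ds$map, ds$space, level = "trial")
  })

  acc_rows <- list()
  roi_rows <- list()
  null_acc <- list()
  z_maps <- matrix(NA_real_, nrow = ncol(ds$subjects[[1]]$betas),
                   ncol = config$n_subjects)
  model_sl <- model_rdm(design_matrix(ds$trials, "ALL_FEATURES", ds$norms,
                                      ds$map, ds$space, level = "trial"))
  perm_seeds <- derive_seeds(seeds[2L], config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    stack <- ds$subjects[[s]]
    stage_message(verbose, "subject %d: averaged decoding", s)
    avg_res <- decode_l2o_averaged(stack, Y_target, k = config$k_stable,
                                   lambda = config$lambda)
    acc_rows[[length(acc_rows) + 1L]] <-
      tibble(subject = s, analysis = "averaged", model = "TARGET",
             accuracy = glance(avg_res)$accuracy)

    stage_message(verbose, "subject %d: single-trial decoding (6 models)", s)
    st <- decode_l2o_single_trial(stack, trial_Y, lambda = config$lambda)
    for (m in names(st)) {
      acc_rows[[length(acc_rows) + 1L]] <-
        tibble(subject = s, analysis = "single_trial", model = m,
               accuracy = glance(st[[m]])$accuracy)
    }

    stage_message(verbose, "subject %d: permutation null (%d iter)", s,
                  config$n_permutations)
    pn <- permutation_null(stack, Y_target, analysis = "averaged",
                           n_iter = config$n_permutations,
                           seed = perm_seeds[s], k = config$k_stable,
                           lambda = config$lambda)
    null_acc[[s]] <- pn$accuracies$accuracy

    stage_message(verbose, "subject %d: ROI decoding", s)
    roi_res <- roi_decode(stack, ds$truths[[s]]$informative, Y_allfeat,
                          lambda = config$lambda)
    roi_rows[[s]] <- tibble(subject = s, analysis = "roi",
                            model = "ALL_FEATURES",
                            accuracy = glance(roi_res)$accuracy)

    stage_message(verbose, "subject %d: searchlight RSA", s)
    sl <- searchlight_rsa(stack, model_sl, radius_mm = config$rsa_radius_mm)
    z_maps[, s] <- smooth_within_mask(sl$z, stack$coords, stack$grid,
                                      stack$voxel_mm, config$rsa_fwhm_mm)
  }

  accuracies <- dplyr::bind_rows(acc_rows)
  checkpoint(accuracies, "accuracy_by_model")
  roi_tbl <- dplyr::bind_rows(roi_rows)
  checkpoint(roi_tbl, "roi_accuracy")

  null_vec <- unlist(null_acc)
  null_tbl <- tibble(iteration = seq_along(null_vec), accuracy = null_vec)
  null_threshold <- empirical_percentile(null_vec, 0.95)
  checkpoint(null_tbl, "permutation_null")

  st_acc <- accuracies[accuracies$analysis == "single_trial", ]
  comparison <- compare_models(st_acc[, c("subject", "model", "accuracy")])
  checkpoint(tidy(comparison), "model_comparison")

  stage_message(verbose, "group RSA inference (%d sign flips)", config$rsa_n_perm)
  stack1 <- ds$subjects[[1L]]
  group <- group_pseudo_t(z_maps, stack1$coords, stack1$grid, stack1$voxel_mm,
                          variance_fwhm_mm = config$rsa_fwhm_mm,
                          n_perm = config$rsa_n_perm, seed = seeds[3L])
  peaks <- cluster_table(group)
  checkpoint(peaks, "rsa_peaks")

  report <- structure(list(
    accuracies = accuracies,
    roi = roi_tbl,
    null = null_tbl,
    null_threshold = null_threshold,
    comparison = comparison,
    rsa_peaks = peaks,
    group = group,
    provenance = list(
      config = config,
      stage_seeds = seeds,
      package_version = as.character(utils::packageVersion("semdecode")),
      config_hash = rlang::hash(unclass(config)),
      table_hash = rlang::hash(list(accuracies, roi_tbl, null_tbl, peaks))
    )
  ), class = "semdec_report")
  report
}

#' @export
print.semdec_report <- function(x, ...) {
  cat(sprintf("<semdec_report: %d subject(s); averaged accuracy %.1f%%; null 95th pct %.1f%%; %d RSA cluster(s)>\n",
              x$provenance$config$n_subjects,
              mean(x$accuracies$accuracy[x$accuracies$analysis == "averaged"]),
              x$null_threshold, nrow(x$rsa_peaks)))
  invisible(x)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Render an experiment report to summary files
#'
#' Writes the per-subject accuracy table, the model-comparison table with
#' Bonferroni-corrected significance markers, the permutation-null summary,
#' the RSA peak table and a JSON overview, plus the configuration used.
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "semdec_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(report$accuracies, "accuracy_by_model")
  wr(report$roi, "roi_accuracy")
  cmp <- tidy(report$comparison)
  cmp$significance <- significance_stars(cmp$p_bonferroni)
  wr(cmp, "model_comparison")
  wr(report$comparison$ranking, "model_ranking")
  wr(report$null, "permutation_null")
  wr(report$rsa_peaks, "rsa_peaks")
  paths$config <- file.path(dir, "config.yaml")
  save_config(report$provenance$config, paths$config)
  paths$summary <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    mean_accuracy_by_model = split(
      report$accuracies$accuracy,
      paste(report$accuracies$analysis, report$accuracies$model, sep = ":")
    ) |> lapply(mean),
    null_threshold = report$null_threshold,
    n_rsa_clusters = nrow(report$rsa_peaks),
    rsa_fwe_threshold = report$group$threshold,
    provenance = report$provenance[c("package_version", "config_hash", "table_hash")]
  ), paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
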