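## End-to-end orchestration: simulate -> fit -> roi -> bins -> stats.
## Every stage reads its inputs from and writes its outputs to the run
## directory, so any stage can be re-run from disk and reproduces its outputs.

#' Pipeline configuration
#'
#' @param study An [study_spec()]; also the source of all simulation seeds.
#' @param fit An [fit_config()].
#' @param n_bins Number of equal-count bins (default 20).
#' @param responses Responses tabulated and tested in the density-bin
#'   analysis.
#' @param n_permutations Permutation iterations (default 10000).
#' @param n_replicates Bootstrap replicates (default 2000).
#' @return An object of class `oemri_pipeline_config`.
#' @export
pipeline_config <- function(study = study_spec(),
                            fit = fit_config(),
                            n_bins = 20,
                            responses = c("r1_air", "r1_o2", "delta_r1",
                                          "delta_r2star"),
                            n_permutations = 10000,
                            n_replicates = 2000) {
  structure(list(study = study, fit = fit, n_bins = as.integer(n_bins),
                 responses = responses,
                 n_permutations = as.integer(n_permutations),
                 n_replicates = as.integer(n_replicates),
                 stats_seed = (study$master_seed %% 2000000000L) + 77L),
            class = "oemri_pipeline_config")
}

log_line <- function(run_dir, ...) {
  cat(paste0(..., "\n"), file = file.path(run_dir, "log.txt"), append = TRUE)
}

write_table_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, run_dir) {
  study <- make_study(config$study, signals = TRUE)
  data_dir <- file.path(run_dir, "data")
  for (a in study) {
    write_image_series(a$series, data_dir)
    write_ground_truth(a$ground_truth, data_dir)
  }
  log_line(run_dir, "simulate: ", length(study), " animals, master_seed = ",
           config$study$master_seed)
  invisible(data_dir)
}

#' @rdname run_pipeline
#' @export
stage_fit <- function(config, run_dir) {
  data_dir <- file.path(run_dir, "data")
  maps_dir <- file.path(run_dir, "maps")
  ids <- list_animals(data_dir)
  report <- lapply(ids, function(id) {
    series <- read_image_series(data_dir, id)
    maps <- fit_maps(series, config$fit)
    write_parameter_maps(maps, maps_dir)
    n_mask <- sum(maps$mask)
    data.frame(animal_id = id, group = maps$group, n_mask = n_mask,
               n_valid = sum(maps$valid),
               fit_fail_rate = 1 - sum(maps$valid) / n_mask)
  })
  report <- do.call(rbind, report)
  write_table_csv(report, file.path(maps_dir, "fit_report.csv"))
  log_line(run_dir, "fit: ", nrow(report), " animals, mean fit-failure rate = ",
           format(mean(report$fit_fail_rate), digits = 4))
  invisible(maps_dir)
}

read_all_maps <- function(run_dir) {
  maps_dir <- file.path(run_dir, "maps")
  ids <- list_animals(maps_dir, kind = "maps")
  if (length(ids) == 0) stop("no fitted maps found under ", maps_dir, call. = FALSE)
  lapply(ids, function(id) read_parameter_maps(maps_dir, id))
}

#' @rdname run_pipeline
#' @export
stage_roi <- function(config, run_dir) {
  maps <- read_all_maps(run_dir)
  roi_dir <- file.path(run_dir, "roi")
  dir.create(roi_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- summarize_study(maps)
  write_table_csv(summaries, file.path(roi_dir, "roi_summaries.csv"))
  cmp_mean <- compare_groups(summaries, "mean")
  cmp_sd <- compare_groups(summaries, "sd")
  write_table_csv(cmp_mean, file.path(roi_dir, "group_means.csv"))
  write_table_csv(cmp_sd, file.path(roi_dir, "group_sds.csv"))
  jsonlite::write_json(list(mean_level = cmp_mean, sd_level = cmp_sd),
                       file.path(roi_dir, "group_tests.json"),
                       dataframe = "rows", digits = NA)
  log_line(run_dir, "roi: ", nrow(summaries), " animals summarised")
  invisible(roi_dir)
}

#' @rdname run_pipeline
#' @export
stage_bins <- function(config, run_dir) {
  maps <- read_all_maps(run_dir)
  bins_dir <- file.path(run_dir, "bins")
  dir.create(bins_dir, showWarnings = FALSE, recursive = TRUE)
  px <- build_pixel_table(maps)
  bt_density <- bin_table(px, "s0_air", config$n_bins, config$responses)
  bt_delivery <- bin_table(px, "delta_r2star", config$n_bins, "delta_r1")
  write_table_csv(bt_density, file.path(bins_dir, "density_bins.csv"))
  write_table_csv(bt_delivery, file.path(bins_dir, "delivery_bins.csv"))
  log_line(run_dir, "bins: ", nrow(px), " pixels into ", config$n_bins,
           " bins")
  invisible(bins_dir)
}

#' @rdname run_pipeline
#' @export
stage_stats <- function(config, run_dir) {
  maps <- read_all_maps(run_dir)
  stats_dir <- file.path(run_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE, recursive = TRUE)
  px <- build_pixel_table(maps)
  bins <- assign_bins(px$s0_air, config$n_bins)
  perm <- data.frame(bin = seq_len(config$n_bins))
  boot <- data.frame(bin = seq_len(config$n_bins))
  for (r in config$responses) {
    pr <- permutation_test_bins(px, bins, r, config$n_permutations,
                                seed = config$stats_seed)
    br <- bootstrap_bin_sd(px, bins, r, config$n_replicates,
                           seed = config$stats_seed + 1L)
    perm[[paste0("observed_diff_", r)]] <- pr$observed_diff
    perm[[paste0("p_", r)]] <- pr$p_value
    boot[[paste0("sd_control_", r)]] <- br$sd_control
    boot[[paste0("sd_challenged_", r)]] <- br$sd_challenged
  }
  write_table_csv(perm, file.path(stats_dir, "permutation_density.csv"))
  write_table_csv(boot, file.path(stats_dir, "bootstrap_density.csv"))
  log_line(run_dir, "stats: N = ", config$n_permutations, " permutations, ",
           config$n_replicates, " bootstrap replicates, seed = ",
           config$stats_seed)
  invisible(stats_dir)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, fit, roi, bins and stats in order, writing every
#' artifact into `run_dir` (NIfTI image series and maps, CSV summaries and
#' bin tables, permutation and bootstrap results, a structured log, and the
#' resolved configuration as JSON). A stage failure aborts with a
#' stage-tagged error; outputs of completed stages are preserved.
#'
#' @param config An [pipeline_config()].
#' @param run_dir Output directory; created if absent.
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "oemri_pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(run_dir, "log.txt"))
  jsonlite::write_json(resolved_config(config),
                       file.path(run_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- list(simulate = stage_simulate, fit = stage_fit, roi = stage_roi,
                 bins = stage_bins, stats = stage_stats)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, run_dir),
             error = function(e) {
               log_line(run_dir, nm, ": FAILED: ", conditionMessage(e))
               stop("[", nm, "] ", conditionMessage(e), call. = FALSE)
             })
  }
  invisible(run_dir)
}

resolved_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}
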