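## Whole-lung ROI summaries and group comparisons.

roi_parameters <- c("s0_air", "r1_air", "r1_o2", "delta_r1", "delta_r2star")

## Common accessor: the five analysis parameters plus the per-pixel validity
## mask, for fitted maps and ground-truth phantoms alike.
parameter_stack <- function(x) {
  if (inherits(x, "oemri_maps")) {
    gs <- x$protocol$gas_states
    list(params = list(s0_air = x$s0[[gs[1]]],
                       r1_air = x$r1[[gs[1]]],
                       r1_o2 = x$r1[[gs[2]]],
                       delta_r1 = x$delta_r1,
                       delta_r2star = x$delta_r2star),
         valid = x$mask & x$valid,
         group = x$group, animal_id = x$animal_id)
  } else if (inherits(x, "oemri_ground_truth")) {
    list(params = list(s0_air = x$s0_air,
                       r1_air = x$r1_air,
                       r1_o2 = x$r1_air + x$delta_r1,
                       delta_r1 = x$delta_r1,
                       delta_r2star = x$delta_r2star),
         valid = x$mask,
         group = x$group, animal_id = x$animal_id)
  } else {
    stop("expected an 'oemri_maps' or 'oemri_ground_truth' object", call. = FALSE)
  }
}

#' Whole-lung ROI summary for one animal
#'
#' Computes the unweighted mean and sample SD (n - 1 denominator) of each of
#' the five parameters (S0_air, R1_air, R1_O2, delta-R1, delta-R2*) over the
#' in-mask, fit-valid pixels.
#'
#' @param x An `oemri_maps` (fitted) or `oemri_ground_truth` object.
#' @param mask Optional logical matrix intersected with the object's own
#'   validity mask.
#' @return A one-row data frame: `animal_id`, `group`, `n_valid_pixels`, and
#'   `<parameter>_mean` / `<parameter>_sd` columns.
#' @export
summarize_roi <- function(x, mask = NULL) {
  st <- parameter_stack(x)
  valid <- st$valid
  if (!is.null(mask)) valid <- valid & mask
  out <- data.frame(animal_id = st$animal_id, group = st$group,
                    n_valid_pixels = sum(valid), stringsAsFactors = FALSE)
  if (out$n_valid_pixels == 0) {
    stop("no valid pixels in ROI for animal ", st$animal_id, call. = FALSE)
  }
  for (p in roi_parameters) {
    v <- st$params[[p]][valid]
    v <- v[!is.na(v)]
    out[[paste0(p, "_mean")]] <- mean(v)
    out[[paste0(p, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
  }
  out
}

#' ROI summaries for a list of animals
#'
#' @param objs List of `oemri_maps` / `oemri_ground_truth` objects, or the
#'   output of [make_study()] (in which case fitted maps are absent and the
#'   ground truth is summarised).
#' @return Data frame, one row per animal, as [summarize_roi()].
#' @export
summarize_study <- function(objs) {
  rows <- lapply(objs, function(o) {
    if (is.list(o) && !is.null(o$ground_truth) && is.null(o$maps)) {
      o <- o$ground_truth
    }
    summarize_roi(o)
  })
  do.call(rbind, rows)
}

#' Two-sample group comparison of ROI statistics
#'
#' Compares the per-animal ROI means (global-level analysis) or the
#' per-animal ROI SDs (heterogeneity analysis) between the control and
#' challenged groups with a two-tailed two-sample t-test per parameter.
#' Welch's test is the default; set `var_equal = TRUE` for the pooled-variance
#' Student test. The t statistic is oriented as challenged minus control.
#'
#' When both groups have zero variance the t-test is degenerate; the
#' comparison then reports `t = 0, p = 1` for equal means and
#' `t = +/-Inf, p = 0` otherwise.
#'
#' @param summaries Data frame from [summarize_study()]; both groups must be
#'   present with at least two animals each.
#' @param statistic `"mean"` (group means of animal-level means) or `"sd"`
#'   (group means of animal-level SDs).
#' @param var_equal Use the pooled-variance Student t-test.
#' @return Data frame with one row per parameter: group means and SDs of the
#'   chosen animal-level statistic, `t`, `df` and `p_value`.
#' @export
compare_groups <- function(summaries, statistic = c("mean", "sd"),
                           var_equal = FALSE) {
  statistic <- match.arg(statistic)
  g <- summaries$group
  if (length(unique(g)) < 2) {
    stop("both groups must be present; got a single-group study", call. = FALSE)
  }
  if (any(table(g) < 2)) {
    stop("each group needs at least 2 animals", call. = FALSE)
  }
  rows <- lapply(roi_parameters, function(p) {
    v <- summaries[[paste0(p, "_", statistic)]]
    x <- v[g == "challenged"]
    y <- v[g == "control"]
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal),
      error = function(e) {
        # zero within-group variance: no sampling noise, so any mean
        # difference is infinitely significant and none is null
        equal <- isTRUE(all.equal(mean(x), mean(y)))
        list(statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
             parameter = NA_real_, p.value = if (equal) 1 else 0)
      }
    )
    data.frame(parameter = p, statistic = statistic,
               mean_control = mean(y), sd_control = stats::sd(y),
               mean_challenged = mean(x), sd_challenged = stats::sd(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
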