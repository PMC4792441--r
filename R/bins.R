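## Equal-count binning of pooled lung pixels by density (S0_air) or by
## delta-R2*, and per-bin per-group means.

#' Pool all valid lung pixels of a study into one table
#'
#' @param objs List of `oemri_maps` / `oemri_ground_truth` objects (or
#'   [make_study()] output; ground truth is used when no fitted maps are
#'   given).
#' @return Data frame with one row per valid in-mask pixel: `animal_id`,
#'   `group`, and the five parameters. Animals contributing no valid pixel
#'   raise a warning and are skipped.
#' @export
build_pixel_table <- function(objs) {
  rows <- lapply(objs, function(o) {
    if (is.list(o) && !is.null(o$ground_truth) && is.null(o$maps) &&
        !inherits(o, c("oemri_maps", "oemri_ground_truth"))) {
      o <- o$ground_truth
    }
    st <- parameter_stack(o)
    keep <- st$valid
    for (p in roi_parameters) keep <- keep & !is.na(st$params[[p]])
    if (!any(keep)) {
      warning("animal ", st$animal_id, " has no valid pixels; skipped")
      return(NULL)
    }
    d <- data.frame(animal_id = st$animal_id, group = st$group,
                    stringsAsFactors = FALSE)
    d <- d[rep(1, sum(keep)), , drop = FALSE]
    for (p in roi_parameters) d[[p]] <- st$params[[p]][keep]
    rownames(d) <- NULL
    d
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no valid pixels in any animal", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Equal-count (quantile) bin assignment
#'
#' Rank-based assignment of pooled records to `n_bins` bins of equal count
#' (counts differ by at most one; when `n` is not divisible, the lowest bins
#' take the extra records). Ties are broken deterministically by record order
#' through a stable sort, so the assignment is well-defined even when all
#' values are equal — bin edges may then coincide, but counts stay balanced.
#'
#' @param values Numeric vector (e.g. pooled `s0_air` or `delta_r2star`).
#' @param n_bins Number of bins (default 20).
#' @return A list with `index` (bin id per record), `edges` (length
#'   `n_bins + 1`, non-decreasing; interior edges are midpoints between
#'   adjacent bins' extreme values), `counts`, and `n_bins`.
#' @export
assign_bins <- function(values, n_bins = 20) {
  n <- length(values)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (n < n_bins) stop("fewer records than bins", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  ord <- order(values, seq_len(n))  # stable: ties keep record order
  base <- as.integer(n %/% n_bins)
  counts <- rep.int(base, n_bins) + c(rep.int(1L, n %% n_bins),
                                      rep.int(0L, n_bins - n %% n_bins))
  index <- integer(n)
  index[ord] <- rep.int(seq_len(n_bins), counts)
  sorted <- values[ord]
  hi <- cumsum(counts)            # last rank of each bin
  edges <- c(sorted[1],
             (sorted[hi[-n_bins]] + sorted[hi[-n_bins] + 1L]) / 2,
             sorted[n])
  list(index = index, edges = edges, counts = counts, n_bins = as.integer(n_bins))
}

#' Per-bin per-group means of a response parameter
#'
#' For each bin, the mean of `response` over that bin's pixels, separately per
#' group. A group with no pixels in a bin carries `NA` there.
#'
#' @param table Pixel table from [build_pixel_table()].
#' @param bins Assignment from [assign_bins()].
#' @param response Parameter name (one of the pixel-table parameter columns).
#' @return Data frame: `bin`, `edge_low`, `edge_high`, `n_pixels`, per-group
#'   counts and means of the response.
#' @export
bin_group_means <- function(table, bins, response) {
  if (!response %in% names(table)) {
    stop("response '", response, "' not present in the pixel table", call. = FALSE)
  }
  if (length(bins$index) != nrow(table)) {
    stop("bin assignment does not match the pixel table", call. = FALSE)
  }
  f <- factor(bins$index, levels = seq_len(bins$n_bins))
  v <- table[[response]]
  out <- data.frame(bin = seq_len(bins$n_bins),
                    edge_low = bins$edges[-(bins$n_bins + 1)],
                    edge_high = bins$edges[-1],
                    n_pixels = as.integer(tabulate(f, bins$n_bins)))
  for (g in c("control", "challenged")) {
    sel <- table$group == g
    cnt <- tabulate(f[sel], bins$n_bins)
    s <- vapply(split(v[sel], f[sel]), sum, numeric(1))
    m <- ifelse(cnt > 0, s / cnt, NA_real_)
    out[[paste0("n_", g)]] <- as.integer(cnt)
    out[[paste0("mean_", g)]] <- m
  }
  out
}

#' Full bin-analysis table
#'
#' Convenience wrapper: assigns equal-count bins on the chosen variable over
#' the pooled pixels of both groups (default, which keeps per-bin group
#' contrasts well-defined) or per group's own quantiles (`mode =
#' "per_group"`, the presentation variant), then tabulates per-bin per-group
#' means of each response.
#'
#' @param table Pixel table from [build_pixel_table()].
#' @param binning_variable `"s0_air"` (density) or `"delta_r2star"`.
#' @param n_bins Number of bins (default 20).
#' @param responses Character vector of response parameters.
#' @param mode `"pooled"` (shared edges, default) or `"per_group"`.
#' @return Data frame with `bin`, edges/counts, and
#'   `mean_<group>_<response>` columns; the bin assignment is attached as the
#'   `"bins"` attribute (pooled mode only).
#' @export
bin_table <- function(table, binning_variable = c("s0_air", "delta_r2star"),
                      n_bins = 20,
                      responses = c("r1_air", "r1_o2", "delta_r1", "delta_r2star"),
                      mode = c("pooled", "per_group")) {
  binning_variable <- match.arg(binning_variable)
  mode <- match.arg(mode)
  if (mode == "pooled") {
    bins <- assign_bins(table[[binning_variable]], n_bins)
    out <- NULL
    for (r in responses) {
      bm <- bin_group_means(table, bins, r)
      if (is.null(out)) out <- bm[c("bin", "edge_low", "edge_high", "n_pixels",
                                    "n_control", "n_challenged")]
      out[[paste0("mean_control_", r)]] <- bm$mean_control
      out[[paste0("mean_challenged_", r)]] <- bm$mean_challenged
    }
    attr(out, "bins") <- bins
    attr(out, "binning_variable") <- binning_variable
    out
  } else {
    pieces <- lapply(c("control", "challenged"), function(g) {
      sub <- table[table$group == g, , drop = FALSE]
      bins <- assign_bins(sub[[binning_variable]], n_bins)
      d <- data.frame(bin = seq_len(n_bins), group = g,
                      edge_low = bins$edges[-(n_bins + 1)],
                      edge_high = bins$edges[-1],
                      n_pixels = bins$counts)
      f <- factor(bins$index, levels = seq_len(n_bins))
      for (r in responses) {
        d[[paste0("mean_", r)]] <- vapply(split(sub[[r]], f), mean, numeric(1))
      }
      d
    })
    out <- do.call(rbind, pieces)
    attr(out, "binning_variable") <- binning_variable
    out
  }
}

#' Plot per-bin group means against the binning variable
#'
#' Base-graphics rendering of a pooled-mode [bin_table()] column pair, with
#' optional resampling error bars and markers for bins whose permutation
#' p-value falls below 0.1.
#'
#' @param bt Pooled-mode [bin_table()].
#' @param response Response parameter to plot.
#' @param boot Optional [bootstrap_bin_sd()] result for error bars.
#' @param perm Optional [permutation_test_bins()] result; bins with
#'   `p < 0.1` are circled.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_bin_means <- function(bt, response, boot = NULL, perm = NULL, ...) {
  x <- (bt$edge_low + bt$edge_high) / 2
  yc <- bt[[paste0("mean_control_", response)]]
  yp <- bt[[paste0("mean_challenged_", response)]]
  ylim <- range(c(yc, yp), na.rm = TRUE)
  if (!is.null(boot)) {
    ylim <- range(c(yc - boot$sd_control, yc + boot$sd_control,
                    yp - boot$sd_challenged, yp + boot$sd_challenged),
                  na.rm = TRUE)
  }
  graphics::plot(x, yc, pch = 0, ylim = ylim,
                 xlab = attr(bt, "binning_variable"), ylab = response, ...)
  graphics::points(x, yp, pch = 15)
  if (!is.null(boot)) {
    graphics::arrows(x, yc - boot$sd_control, x, yc + boot$sd_control,
                     angle = 90, code = 3, length = 0.02)
    graphics::arrows(x, yp - boot$sd_challenged, x, yp + boot$sd_challenged,
                     angle = 90, code = 3, length = 0.02)
  }
  if (!is.null(perm)) {
    sig <- !is.na(perm$p_value) & perm$p_value < 0.1
    graphics::points(x[sig], pmax(yc, yp)[sig], pch = 1, cex = 2.2)
  }
  graphics::legend("topleft", legend = c("control", "challenged"),
                   pch = c(0, 15), bty = "n")
  invisible(bt)
}
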