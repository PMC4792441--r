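## Animal-level permutation test and animal bootstrap for binned group
## contrasts. Both work on per-animal-per-bin sufficient statistics (pixel
## sums and counts), so label permutations and animal resamples are cheap
## matrix operations against fixed bin edges.

## sums and counts of `response` per (bin, animal)
bin_animal_stats <- function(table, bins, response) {
  if (!response %in% names(table)) {
    stop("response '", response, "' not present in the pixel table", call. = FALSE)
  }
  if (length(bins$index) != nrow(table)) {
    stop("bin assignment does not match the pixel table", call. = FALSE)
  }
  animals <- unique(table$animal_id)
  grp <- table$group[match(animals, table$animal_id)]
  fb <- factor(bins$index, levels = seq_len(bins$n_bins))
  fa <- factor(table$animal_id, levels = animals)
  s <- tapply(table[[response]], list(fb, fa), sum, default = 0)
  cnt <- table(fb, fa)
  list(sums = unclass(s), counts = unclass(cnt),
       animals = animals, groups = grp, n_bins = bins$n_bins)
}

group_bin_means <- function(st, is_challenged) {
  w1 <- as.numeric(is_challenged); w0 <- 1 - w1
  m1 <- (st$sums %*% w1) / (st$counts %*% w1)
  m0 <- (st$sums %*% w0) / (st$counts %*% w0)
  cbind(control = m0[, 1], challenged = m1[, 1])
}

#' Animal-level permutation test for per-bin group differences
#'
#' Group labels are permuted among the animals (all pixels of an animal move
#' together) in `n_permutations` random relabelings; bin edges and the
#' observed differences stay fixed. Per bin, the two-tailed p-value is the
#' fraction of permutations whose absolute group mean difference strictly
#' exceeds the observed one (no +1 smoothing, so the resolution is
#' `1/n_permutations` and the minimum reportable p is 0). Permutations in
#' which a bin loses all pixels of one group are dropped for that bin;
#' `n_valid` reports the effective count.
#'
#' @param table Pixel table from [build_pixel_table()].
#' @param bins Assignment from [assign_bins()], computed once from the
#'   unpermuted data.
#' @param response Parameter to contrast.
#' @param n_permutations Number of random relabelings (default 10000).
#' @param seed Integer seed; the result is reproducible bit-for-bit.
#' @return Data frame: `bin`, `observed_diff` (challenged minus control),
#'   `p_value`, `n_valid`, `signif_0.1`; attributes `n_permutations`, `seed`.
#' @export
permutation_test_bins <- function(table, bins, response,
                                  n_permutations = 10000, seed = 1L) {
  st <- bin_animal_stats(table, bins, response)
  n_chal <- sum(st$groups == "challenged")
  n_ctrl <- sum(st$groups == "control")
  if (n_chal < 2 || n_ctrl < 2) {
    stop("each group needs at least 2 animals to permute", call. = FALSE)
  }
  n_animals <- length(st$animals)
  obs <- group_bin_means(st, st$groups == "challenged")
  observed_diff <- obs[, "challenged"] - obs[, "control"]

  W <- local_seed(seed, {
    w <- matrix(0, n_animals, n_permutations)
    for (j in seq_len(n_permutations)) {
      w[sample.int(n_animals, n_chal), j] <- 1
    }
    w
  })
  chal_mean <- (st$sums %*% W) / (st$counts %*% W)
  ctrl_mean <- (st$sums %*% (1 - W)) / (st$counts %*% (1 - W))
  diffs <- chal_mean - ctrl_mean                 # n_bins x n_permutations
  valid <- is.finite(diffs)
  exceed <- abs(diffs) > abs(observed_diff)      # recycled by column
  n_valid <- rowSums(valid)
  p <- rowSums(exceed & valid) / n_valid

  structure(
    data.frame(bin = seq_len(st$n_bins), observed_diff = observed_diff,
               p_value = p, n_valid = n_valid, signif_0.1 = p < 0.1),
    n_permutations = n_permutations, seed = seed, response = response
  )
}

#' Animal bootstrap SDs of per-bin group means
#'
#' Animals are resampled with replacement within each group; per replicate the
#' per-bin per-group means are recomputed against the fixed bin edges, and the
#' SD over replicates is returned. This estimates the between-animal sampling
#' variability of the binned curves, consistent with the exchangeability unit
#' of the permutation test.
#'
#' @param table Pixel table from [build_pixel_table()].
#' @param bins Assignment from [assign_bins()].
#' @param response Parameter to summarise.
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return Data frame: `bin`, `sd_control`, `sd_challenged`; attributes
#'   `n_replicates`, `seed`.
#' @export
bootstrap_bin_sd <- function(table, bins, response,
                             n_replicates = 2000, seed = 1L) {
  st <- bin_animal_stats(table, bins, response)
  out <- data.frame(bin = seq_len(st$n_bins))
  local_seed(seed, {
    for (g in c("control", "challenged")) {
      sel <- st$groups == g
      if (sum(sel) < 2) stop("each group needs at least 2 animals", call. = FALSE)
      ng <- sum(sel)
      # multiplicity of each animal in each replicate (uniform resampling)
      M <- stats::rmultinom(n_replicates, ng, rep(1 / ng, ng))
      means <- (st$sums[, sel, drop = FALSE] %*% M) /
        (st$counts[, sel, drop = FALSE] %*% M)
      out[[paste0("sd_", g)]] <- apply(means, 1, stats::sd, na.rm = TRUE)
    }
  })
  structure(out, n_replicates = n_replicates, seed = seed, response = response)
}
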