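test_that("Monte-Carlo permutation p matches exhaustive enumeration, 3 vs 2", {
  # toy fixed pixel values, single bin, all 10 label splits enumerable
  tab <- data.frame(
    animal_id = rep(c("a1", "a2", "a3", "b1", "b2"), each = 4),
    group = rep(c("control", "control", "control", "challenged", "challenged"),
                each = 4),
    delta_r1 = c(0.1, 0.2, 0.15, 0.12, 0.3, 0.25, 0.28, 0.31,
                 0.05, 0.1, 0.07, 0.09, 0.4, 0.38, 0.42, 0.36,
                 0.22, 0.19, 0.21, 0.2)
  )
  bins <- single_bin(tab$delta_r1)
  groups <- c(a1 = "control", a2 = "control", a3 = "control",
              b1 = "challenged", b2 = "challenged")
  p_exact <- exact_perm_p(tab$delta_r1, tab$animal_id, groups)
  n_perm <- 10000
  res <- permutation_test_bins(tab, bins, "delta_r1",
                               n_permutations = n_perm, seed = 99)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), max(3 * se, 3 / n_perm))
})

test_that("a null-centred observation yields p near 1", {
  # group means coincide (both 3) but relabelings almost always separate:
  # of the 20 label splits only the observed one and its mirror give 0,
  # so the exact two-tailed p is 0.9
  tab <- data.frame(
    animal_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    group = rep(c("control", "challenged"), each = 3),
    delta_r1 = c(1, 2, 6, 0, 4, 5)
  )
  res <- permutation_test_bins(tab, single_bin(tab$delta_r1), "delta_r1",
                               n_permutations = 4000, seed = 1)
  expect_equal(res$observed_diff, 0)
  expect_gt(res$p_value, 0.8)
  expect_lte(res$p_value, 1)
})

test_that("permutation results are seed-reproducible and label-symmetric", {
  st <- make_study(quick_study_spec(n_control = 4, n_challenged = 4,
                                    master_seed = 3), signals = FALSE)
  px <- build_pixel_table(st)
  bins <- assign_bins(px$s0_air, 5)
  r1 <- permutation_test_bins(px, bins, "delta_r1", 2000, seed = 7)
  r2 <- permutation_test_bins(px, bins, "delta_r1", 2000, seed = 7)
  expect_identical(r1, r2)
  # different seeds agree within Monte-Carlo noise
  r3 <- permutation_test_bins(px, bins, "delta_r1", 10000, seed = 8)
  r4 <- permutation_test_bins(px, bins, "delta_r1", 10000, seed = 9)
  se <- sqrt(pmax(r3$p_value * (1 - r3$p_value), 0.25 / 10000) / 10000)
  expect_true(all(abs(r3$p_value - r4$p_value) < 5 * se + 5 / 10000))
  # swapping which group is which leaves two-tailed p unchanged
  flipped <- px
  flipped$group <- ifelse(px$group == "control", "challenged", "control")
  r5 <- permutation_test_bins(flipped, bins, "delta_r1", 2000, seed = 7)
  r6 <- permutation_test_bins(px, bins, "delta_r1", 2000, seed = 7)
  expect_equal(r5$p_value, r6$p_value)
  expect_equal(r5$observed_diff, -r6$observed_diff)
})

test_that("permutation refuses undersized groups", {
  tab <- data.frame(animal_id = c("a", "a", "b", "b"),
                    group = c("control", "control", "challenged", "challenged"),
                    delta_r1 = 1:4)
  expect_error(permutation_test_bins(tab, single_bin(tab$delta_r1), "delta_r1",
                                     100, 1), "at least 2")
  expect_error(permutation_test_bins(tab, single_bin(tab$delta_r1), "nope",
                                     100, 1), "not present")
})

test_that("a group of identical animals bootstraps to SD 0", {
  tab <- data.frame(
    animal_id = rep(c("c1", "c2", "c3", "c4", "c5", "p1", "p2"), each = 2),
    group = rep(c(rep("control", 5), "challenged", "challenged"), each = 2),
    delta_r1 = c(rep(c(0.1, 0.3), 5), 0.2, 0.4, 0.5, 0.6)
  )
  res <- bootstrap_bin_sd(tab, single_bin(tab$delta_r1), "delta_r1",
                          n_replicates = 500, seed = 2)
  expect_equal(res$sd_control, 0)
  expect_gt(res$sd_challenged, 0)
})

test_that("bootstrap SD matches the analytic SD of a mean of animal means", {
  set.seed(5)
  n_animals <- 8
  m <- stats::rnorm(n_animals, 0.05, 0.02)  # per-animal means
  tab <- data.frame(
    animal_id = c(rep(paste0("c", seq_len(n_animals)), each = 30),
                  rep(c("p1", "p2"), each = 30)),
    group = c(rep("control", 30 * n_animals), rep("challenged", 60)),
    delta_r1 = c(rep(m, each = 30), stats::rnorm(60, 0.05, 0.02))
  )
  res <- bootstrap_bin_sd(tab, single_bin(tab$delta_r1), "delta_r1",
                          n_replicates = 4000, seed = 3)
  # resampling n animals with replacement: SD of the mean is sigma_pop/sqrt(n)
  analytic <- sqrt(mean((m - mean(m))^2) / n_animals)
  expect_lt(abs(res$sd_control - analytic) / analytic, 0.25)
})

test_that("default-study bin SDs are finite and positive (smoke)", {
  st <- make_study(quick_study_spec(master_seed = 12), signals = FALSE)
  px <- build_pixel_table(st)
  bins <- assign_bins(px$s0_air, 20)
  res <- bootstrap_bin_sd(px, bins, "delta_r1", n_replicates = 300, seed = 4)
  expect_true(all(is.finite(res$sd_control)))
  expect_true(all(is.finite(res$sd_challenged)))
  expect_true(all(res$sd_control > 0))
  expect_true(all(res$sd_challenged > 0))
})

test_that("permutation detects the low-density uptake deficit, not the null bins", {
  st <- make_study(study_spec(master_seed = 21), signals = FALSE)
  px <- build_pixel_table(st)
  bins <- assign_bins(px$s0_air, 20)
  res <- permutation_test_bins(px, bins, "delta_r1", 2000, seed = 5)
  expect_lt(res$p_value[1], 0.05)            # strong deficit in lowest bin
  crossing <- which.min(abs(res$observed_diff))
  expect_gt(res$p_value[crossing], 0.1)      # no signal where curves cross
})
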