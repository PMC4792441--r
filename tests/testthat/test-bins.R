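test_that("equal-count bins balance to within one pixel", {
  set.seed(1)
  # distinct values, divisible: exactly equal
  b <- assign_bins(rnorm(20000), 20)
  expect_true(all(b$counts == 1000))
  expect_true(all(tabulate(b$index, 20) == 1000))
  # non-divisible: a mix of 5s and 6s summing to n
  b2 <- assign_bins(runif(105), 20)
  expect_true(all(b2$counts %in% c(5L, 6L)))
  expect_identical(sum(b2$counts), 105L)
  # total tie: deterministic, still balanced
  b3 <- assign_bins(rep(1, 45), 4)
  expect_true(max(b3$counts) - min(b3$counts) <= 1)
  b3b <- assign_bins(rep(1, 45), 4)
  expect_identical(b3$index, b3b$index)
  # edges are sorted
  expect_true(all(diff(b$edges) >= 0))
  # errors
  expect_error(assign_bins(1:10, 20), "fewer records")
  expect_error(assign_bins(1:10, 1), "n_bins")
})

test_that("bin assignment is monotone in the values", {
  set.seed(2)
  v <- rnorm(377)
  b <- assign_bins(v, 20)
  expect_true(all(diff(b$index[order(v)]) >= 0))
  # every record's value lies within (or at) its bin's edges
  expect_true(all(v >= b$edges[b$index] - 1e-12))
  expect_true(all(v <= b$edges[b$index + 1] + 1e-12))
})

test_that("count-weighted mean of bin means recovers the pooled mean", {
  st <- make_study(quick_study_spec(n_control = 3, n_challenged = 3,
                                    master_seed = 6), signals = FALSE)
  px <- build_pixel_table(st)
  bins <- assign_bins(px$s0_air, 12)
  bm <- bin_group_means(px, bins, "delta_r1")
  for (g in c("control", "challenged")) {
    w <- bm[[paste0("n_", g)]]
    m <- bm[[paste0("mean_", g)]]
    pooled <- sum(w * m) / sum(w)
    expect_equal(pooled, mean(px$delta_r1[px$group == g]), tolerance = 1e-12)
  }
})

test_that("bin means lie on an exactly linear generating relationship", {
  # sd_delta_r1 = slope * sd_s0 leaves no residual: delta_r1 = a + b * s0
  spec <- quick_spec("control", seed = 8, sd_delta_r1 = 0.06 * 0.62,
                     density_uptake_slope = 0.06, uptake_delivery_slope = 0,
                     sd_delta_r2star = 0.205)
  gt <- make_phantom(spec)
  px <- build_pixel_table(list(gt))
  bins <- assign_bins(px$s0_air, 10)
  bm <- bin_group_means(px, bins, "delta_r1")
  s0_bin <- tapply(px$s0_air, bins$index, mean)
  pred <- 0.024 + 0.06 * (s0_bin - 3.29)
  expect_equal(as.numeric(bm$mean_control), as.numeric(pred), tolerance = 1e-10)
})

test_that("constant response gives constant bin means; empty groups give NA", {
  gt <- toy_ground_truth(c(5, 5, 5, 5, 5, 5), "control", "c1")
  px <- build_pixel_table(list(gt))
  bins <- assign_bins(px$s0_air, 3)
  bm <- bin_group_means(px, bins, "delta_r1")
  expect_true(all(bm$mean_control == 5))
  expect_true(all(is.na(bm$mean_challenged)))
  expect_true(all(bm$n_challenged == 0L))
})

test_that("pixel table pools animals and skips ones without valid pixels", {
  a <- toy_ground_truth(1:10, "control", "a")
  b <- toy_ground_truth(1:5, "challenged", "b")
  px <- build_pixel_table(list(a, b))
  expect_identical(nrow(px), 15L)
  expect_identical(sum(px$animal_id == "a"), 10L)
  # an animal whose mask is empty contributes nothing, with a warning
  c_empty <- toy_ground_truth(1:4, "control", "c")
  c_empty$mask[] <- FALSE
  expect_warning(px2 <- build_pixel_table(list(a, c_empty)), "no valid pixels")
  expect_identical(nrow(px2), 10L)
  expect_error(suppressWarnings(build_pixel_table(list(c_empty))), "no valid")
})

test_that("delivery-binned uptake recovers the generating coupling slope", {
  for (g in c("control", "challenged")) {
    spec <- phantom_spec(g, seed = 31)
    gt <- make_phantom(spec)
    px <- build_pixel_table(list(gt))
    bins <- assign_bins(px$delta_r2star, 20)
    bm <- bin_group_means(px, bins, "delta_r1")
    x <- tapply(px$delta_r2star, bins$index, mean)
    y <- bm[[paste0("mean_", g)]]
    slope <- stats::coef(stats::lm(y ~ x))[2]
    expect_lt(abs(slope - spec$uptake_delivery_slope) /
                spec$uptake_delivery_slope, 0.10)
    expect_gt(cor(x, y), 0.9)
  }
})

test_that("per-group quantile mode tabulates each group's own bins", {
  st <- make_study(quick_study_spec(n_control = 3, n_challenged = 3,
                                    master_seed = 2), signals = FALSE)
  px <- build_pixel_table(st)
  bt <- bin_table(px, "s0_air", n_bins = 8, responses = "delta_r1",
                  mode = "per_group")
  expect_identical(nrow(bt), 16L)
  expect_true(all(table(bt$group) == 8))
  # per-group counts are balanced within each group
  for (g in c("control", "challenged")) {
    cnt <- bt$n_pixels[bt$group == g]
    expect_true(max(cnt) - min(cnt) <= 1)
  }
})
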