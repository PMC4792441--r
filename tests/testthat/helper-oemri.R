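# small-grid templates and oracles shared across tests

quick_spec <- function(group, seed = 1L, ...) {
  phantom_spec(group, nx = 24, ny = 24, n_pixels_target = 120, seed = seed, ...)
}

quick_study_spec <- function(n_control = 9, n_challenged = 8, master_seed = 1L,
                             control = quick_spec("control"),
                             challenged = quick_spec("challenged"), ...) {
  study_spec(n_control = n_control, n_challenged = n_challenged,
             control = control, challenged = challenged,
             master_seed = master_seed, ...)
}

# trivial all-in-one bin assignment (the bin analysis with a single stratum)
single_bin <- function(values) {
  list(index = rep(1L, length(values)), edges = range(values),
       counts = length(values), n_bins = 1L)
}

# exhaustive-enumeration oracle for the animal-level permutation test:
# exact two-tailed p over all choose(n, n_challenged) label assignments
exact_perm_p <- function(pixel_values, animal_ids, groups_by_animal) {
  animals <- names(groups_by_animal)
  n_chal <- sum(groups_by_animal == "challenged")
  sums <- vapply(animals, function(a) sum(pixel_values[animal_ids == a]), 0)
  cnts <- vapply(animals, function(a) sum(animal_ids == a), 0)
  diff_for <- function(chal_idx) {
    ctrl_idx <- setdiff(seq_along(animals), chal_idx)
    sum(sums[chal_idx]) / sum(cnts[chal_idx]) -
      sum(sums[ctrl_idx]) / sum(cnts[ctrl_idx])
  }
  obs <- diff_for(which(groups_by_animal == "challenged"))
  splits <- utils::combn(length(animals), n_chal)
  perm_diffs <- apply(splits, 2, diff_for)
  mean(abs(perm_diffs) > abs(obs))
}

# minimal hand-built ground-truth object for toy ROI arithmetic
toy_ground_truth <- function(values, group = "control", animal_id = "toy") {
  n <- length(values)
  m <- matrix(values, nrow = n, ncol = 1)
  structure(
    list(s0_air = m, r1_air = m, delta_r1 = m, delta_r2star = m,
         mask = matrix(TRUE, n, 1), group = group, animal_id = animal_id),
    class = "oemri_ground_truth"
  )
}
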