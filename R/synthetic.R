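## Digital phantom generation and forward signal simulation.
##
## Units, fixed package-wide: inversion/echo times in the protocol unit
## (ms by default), R1 and delta-R1 in s^-1, delta-R2* in ms^-1.

#' Phantom template for one study group
#'
#' Describes the per-pixel parameter fields of a synthetic lung: mean and
#' within-animal SD of the density proxy S0_air, of the baseline relaxation
#' rate R1_air, of the oxygen-uptake contrast delta-R1 and of the
#' oxygen-delivery contrast delta-R2*, plus the two couplings that give the
#' fields their joint structure. The defaults reproduce the group-level
#' statistics of an elastase-challenged mouse emphysema study: a control lung
#' (higher, narrower density distribution) or a challenged lung (lower, wider
#' density; steeper density-uptake coupling, so low-density regions take up
#' less oxygen and high-density regions more).
#'
#' `density_uptake_slope` couples delta-R1 to local density (s^-1 per density
#' unit); `uptake_delivery_slope` is the generating slope of delta-R1 against
#' delta-R2* (s^-1 per ms^-1). Residual field SDs are derived so the marginal
#' SDs hit their targets exactly, which bounds the admissible slopes
#' (an error is raised when a coupling alone would exceed the target SD).
#'
#' @param group `"control"` or `"challenged"`; selects the default parameter
#'   set, any of which can be overridden.
#' @param nx,ny Grid size in pixels.
#' @param n_pixels_target Approximate total lung-mask size in pixels.
#' @param mean_s0_air,sd_s0_air Density proxy, arbitrary units.
#' @param mean_r1_air,sd_r1_air Baseline R1, s^-1.
#' @param mean_delta_r1,sd_delta_r1 Oxygen uptake contrast, s^-1.
#' @param mean_delta_r2star,sd_delta_r2star Oxygen delivery contrast, ms^-1.
#' @param density_uptake_slope s^-1 per density unit.
#' @param uptake_delivery_slope s^-1 per ms^-1; 0 disables the coupling.
#' @param spatial_correlation_length Gaussian smoothing length, pixels.
#' @param seed Integer seed for the phantom's random fields.
#' @return An object of class `oemri_phantom_spec`.
#' @export
phantom_spec <- function(group = c("control", "challenged"),
                         nx = 64, ny = 64, n_pixels_target = 1200,
                         mean_s0_air = NULL, sd_s0_air = NULL,
                         mean_r1_air = NULL, sd_r1_air = NULL,
                         mean_delta_r1 = NULL, sd_delta_r1 = NULL,
                         mean_delta_r2star = NULL, sd_delta_r2star = NULL,
                         density_uptake_slope = NULL,
                         uptake_delivery_slope = NULL,
                         spatial_correlation_length = 3,
                         seed = 1L) {
  group <- match.arg(group)
  d <- if (group == "control") {
    list(mean_s0_air = 3.29, sd_s0_air = 0.62,
         mean_r1_air = 0.557, sd_r1_air = 0.067,
         mean_delta_r1 = 0.024, sd_delta_r1 = 0.094,
         mean_delta_r2star = 0.071, sd_delta_r2star = 0.205,
         density_uptake_slope = 0.06, uptake_delivery_slope = 0.47)
  } else {
    list(mean_s0_air = 2.90, sd_s0_air = 0.66,
         mean_r1_air = 0.549, sd_r1_air = 0.081,
         mean_delta_r1 = 0.025, sd_delta_r1 = 0.110,
         mean_delta_r2star = 0.090, sd_delta_r2star = 0.267,
         density_uptake_slope = 0.16, uptake_delivery_slope = 0.42)
  }
  pick <- function(x, nm) if (is.null(x)) d[[nm]] else as.numeric(x)
  spec <- structure(
    list(group = group, nx = as.integer(nx), ny = as.integer(ny),
         n_pixels_target = as.integer(n_pixels_target),
         mean_s0_air = pick(mean_s0_air, "mean_s0_air"),
         sd_s0_air = pick(sd_s0_air, "sd_s0_air"),
         mean_r1_air = pick(mean_r1_air, "mean_r1_air"),
         sd_r1_air = pick(sd_r1_air, "sd_r1_air"),
         mean_delta_r1 = pick(mean_delta_r1, "mean_delta_r1"),
         sd_delta_r1 = pick(sd_delta_r1, "sd_delta_r1"),
         mean_delta_r2star = pick(mean_delta_r2star, "mean_delta_r2star"),
         sd_delta_r2star = pick(sd_delta_r2star, "sd_delta_r2star"),
         density_uptake_slope = pick(density_uptake_slope, "density_uptake_slope"),
         uptake_delivery_slope = pick(uptake_delivery_slope, "uptake_delivery_slope"),
         spatial_correlation_length = as.numeric(spatial_correlation_length),
         seed = as.integer(seed)),
    class = "oemri_phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "oemri_phantom_spec"))
  sds <- c(spec$sd_s0_air, spec$sd_r1_air, spec$sd_delta_r1, spec$sd_delta_r2star)
  if (anyNA(sds) || any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (spec$mean_s0_air <= 0 || spec$mean_r1_air <= 0) {
    stop("mean_s0_air and mean_r1_air must be > 0", call. = FALSE)
  }
  if (abs(spec$density_uptake_slope) * spec$sd_s0_air > spec$sd_delta_r1 + 1e-12) {
    stop("density_uptake_slope * sd_s0_air exceeds sd_delta_r1", call. = FALSE)
  }
  if (spec$uptake_delivery_slope != 0 &&
      spec$sd_delta_r1 / abs(spec$uptake_delivery_slope) > spec$sd_delta_r2star + 1e-12) {
    stop("sd_delta_r1 / uptake_delivery_slope exceeds sd_delta_r2star", call. = FALSE)
  }
  if (spec$spatial_correlation_length < 0) {
    stop("spatial_correlation_length must be >= 0", call. = FALSE)
  }
  spec
}

## run expr with a given RNG seed, restoring the caller's RNG state after
local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Two-ellipse lung mask; ellipse axes sized from the pixel target
## (aspect ratio 1.6, lungs side by side along x).
lung_mask <- function(nx, ny, n_pixels_target) {
  ratio <- 1.6
  a <- sqrt((n_pixels_target / 2) / (pi * ratio))
  b <- ratio * a
  cx <- c(0.30, 0.70) * (nx + 1)
  cy <- 0.5 * (ny + 1)
  if (cx[1] - a < 1 || cx[2] + a > nx || cy - b < 1 || cy + b > ny ||
      cx[1] + a >= cx[2] - a) {
    stop("grid too small to host n_pixels_target lung pixels", call. = FALSE)
  }
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  in1 <- ((x - cx[1]) / a)^2 + ((y - cy) / b)^2 <= 1
  in2 <- ((x - cx[2]) / a)^2 + ((y - cy) / b)^2 <= 1
  in1 | in2
}

## Spatially correlated standard field: Gaussian-smoothed white noise,
## standardised to mean 0 / SD 1 over the mask (exactly). Returns the zero
## field when the raw in-mask SD vanishes.
corr_field <- function(nx, ny, len, mask) {
  if (len > 0) {
    m <- as.integer(ceiling(3 * len))
    w <- matrix(stats::rnorm((nx + 2 * m) * (ny + 2 * m)), nx + 2 * m)
    k <- stats::dnorm(seq(-m, m), sd = len)
    k <- k / sum(k)
    s <- apply(w, 2, function(col) stats::filter(col, k, sides = 2))
    s <- t(apply(s, 1, function(row) stats::filter(row, k, sides = 2)))
    f <- s[(m + 1):(m + nx), (m + 1):(m + ny)]
  } else {
    f <- matrix(stats::rnorm(nx * ny), nx, ny)
  }
  standardize_in_mask(f, mask)
}

standardize_in_mask <- function(f, mask) {
  v <- f[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(matrix(0, nrow(f), ncol(f)))
  (f - mean(v)) / s
}

## residualise field `f` against `g` over the mask, restandardise
orthogonalize_in_mask <- function(f, g, mask) {
  gv <- g[mask]
  if (stats::sd(gv) < 1e-12) return(f)
  b <- stats::cov(f[mask], gv) / stats::var(gv)
  standardize_in_mask(f - b * g, mask)
}

#' Generate the ground-truth parameter maps of one synthetic animal
#'
#' Builds an ellipse-pair lung mask and, inside it, four spatially correlated
#' parameter fields: `s0_air` (density proxy) and `r1_air` (independent of
#' density, as baseline R1 shows no density dependence), `delta_r1` coupled to
#' density through `density_uptake_slope` plus an orthogonal residual field,
#' and `delta_r2star` coupled to `delta_r1` through `uptake_delivery_slope`.
#' Residual SDs are chosen so each field's in-mask SD equals its template SD
#' exactly (before the rare positivity clips). The oxygen-state relaxation
#' rate `r1_air + delta_r1` is clipped to stay positive.
#'
#' @param spec An [phantom_spec()].
#' @param animal_id Identifier string for the generated animal.
#' @return An object of class `oemri_ground_truth` with matrix fields
#'   `s0_air`, `r1_air`, `delta_r1`, `delta_r2star`, the logical `mask`,
#'   `group`, `animal_id` and the generating `spec`.
#' @export
make_phantom <- function(spec, animal_id = spec$group) {
  validate_phantom_spec(spec)
  nx <- spec$nx; ny <- spec$ny
  mask <- lung_mask(nx, ny, spec$n_pixels_target)
  len <- spec$spatial_correlation_length

  local_seed(spec$seed, {
    f_s0 <- corr_field(nx, ny, len, mask)
    f_r1 <- corr_field(nx, ny, len, mask)
    f_e1 <- orthogonalize_in_mask(corr_field(nx, ny, len, mask), f_s0, mask)

    s0_air <- spec$mean_s0_air + spec$sd_s0_air * f_s0
    s0_air <- pmax(s0_air, 0.05 * spec$mean_s0_air)
    r1_air <- pmax(spec$mean_r1_air + spec$sd_r1_air * f_r1, 0.01)

    sd_e1 <- sqrt(max(0, spec$sd_delta_r1^2 -
                        (spec$density_uptake_slope * spec$sd_s0_air)^2))
    delta_r1 <- spec$mean_delta_r1 +
      spec$density_uptake_slope * (s0_air - spec$mean_s0_air) +
      sd_e1 * f_e1
    delta_r1 <- pmax(delta_r1, 0.011 - r1_air)  # keep R1_O2 inside fit bounds

    if (spec$uptake_delivery_slope != 0) {
      coupled <- (delta_r1 - spec$mean_delta_r1) / spec$uptake_delivery_slope
      sd_coupled <- spec$sd_delta_r1 / abs(spec$uptake_delivery_slope)
    } else {
      coupled <- 0 * delta_r1
      sd_coupled <- 0
    }
    sd_e2 <- sqrt(max(0, spec$sd_delta_r2star^2 - sd_coupled^2))
    f_e2 <- orthogonalize_in_mask(corr_field(nx, ny, len, mask), delta_r1, mask)
    delta_r2star <- spec$mean_delta_r2star + coupled + sd_e2 * f_e2

    structure(
      list(s0_air = s0_air, r1_air = r1_air, delta_r1 = delta_r1,
           delta_r2star = delta_r2star, mask = mask,
           group = spec$group, animal_id = as.character(animal_id),
           spec = spec),
      class = "oemri_ground_truth"
    )
  })
}

#' Simulate a two-gas-state inversion-recovery image series
#'
#' Forward model of the SIR-UTE acquisition: at inversion time TI the
#' noiseless magnitude is `|S0 * (1 - B * exp(-R1 * TI))|` with inversion
#' efficiency `B` (2 for a perfect inversion). The oxygen state uses
#' `R1_O2 = R1_air + delta_r1` and `S0_O2 = S0_air * exp(-delta_r2star * TE)`,
#' so the oxygen-induced T2* shortening enters only through the oxygen-state
#' S0 — the air-state density estimate is unaffected by construction.
#' Magnitude noise is then added per the protocol's noise model (Gaussian
#' truncated at zero, or Rician); outside the lung mask only background noise
#' is present.
#'
#' @param gt An `oemri_ground_truth`.
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer seed for the noise draw.
#' @param inv_eff Inversion-efficiency factor B; default 2 (perfect inversion).
#' @return An `oemri_series`.
#' @export
simulate_signal <- function(gt, protocol = acquisition_protocol(), seed = 1L,
                            inv_eff = 2) {
  stopifnot(inherits(gt, "oemri_ground_truth"))
  validate_protocol(protocol)
  ti <- protocol$inversion_times
  te_ms <- if (protocol$ti_unit == "ms") protocol$echo_time else protocol$echo_time * 1000
  # R1 fields are s^-1; convert to the protocol time unit
  conv <- if (protocol$ti_unit == "ms") 1 / 1000 else 1

  s0 <- list(gt$s0_air * gt$mask,
             gt$s0_air * exp(-gt$delta_r2star * te_ms) * gt$mask)
  r1u <- list(gt$r1_air * conv, (gt$r1_air + gt$delta_r1) * conv)
  names(s0) <- names(r1u) <- protocol$gas_states

  nx <- nrow(gt$mask); ny <- ncol(gt$mask)
  sigma <- protocol$noise_sigma
  images <- local_seed(seed, {
    lapply(stats::setNames(protocol$gas_states, protocol$gas_states), function(g) {
      a <- array(0, dim = c(nx, ny, length(ti)))
      for (i in seq_along(ti)) {
        clean <- abs(s0[[g]] * (1 - inv_eff * exp(-r1u[[g]] * ti[i])))
        a[, , i] <- if (sigma == 0) {
          clean
        } else if (protocol$noise_model == "gaussian") {
          pmax(clean + stats::rnorm(nx * ny, sd = sigma), 0)
        } else {
          sqrt((clean + stats::rnorm(nx * ny, sd = sigma))^2 +
                 stats::rnorm(nx * ny, sd = sigma)^2)
        }
      }
      a
    })
  })
  image_series(images, protocol, gt$mask, gt$group, gt$animal_id)
}

#' Study design for a simulated two-group experiment
#'
#' @param n_control,n_challenged Group sizes; defaults 9 and 8, the
#'   post-exclusion analysis counts of the emulated study.
#' @param control,challenged Group [phantom_spec()] templates.
#' @param jitter_control,jitter_challenged Named numeric vectors giving the
#'   between-animal SD of the four template means (`s0_air`, `r1_air`,
#'   `delta_r1`, `delta_r2star`); defaults are the group SDs of the emulated
#'   study's global parameter table.
#' @param protocol An [acquisition_protocol()].
#' @param master_seed Integer; all per-animal seeds derive from it.
#' @return An object of class `oemri_study_spec`.
#' @export
study_spec <- function(n_control = 9, n_challenged = 8,
                       control = phantom_spec("control"),
                       challenged = phantom_spec("challenged"),
                       jitter_control = c(s0_air = 0.16, r1_air = 0.015,
                                          delta_r1 = 0.015, delta_r2star = 0.065),
                       jitter_challenged = c(s0_air = 0.23, r1_air = 0.019,
                                             delta_r1 = 0.018, delta_r2star = 0.058),
                       protocol = acquisition_protocol(),
                       master_seed = 1L) {
  stopifnot(n_control >= 0, n_challenged >= 0, n_control + n_challenged >= 1)
  validate_protocol(protocol)
  structure(
    list(n_control = as.integer(n_control),
         n_challenged = as.integer(n_challenged),
         control = validate_phantom_spec(control),
         challenged = validate_phantom_spec(challenged),
         jitter_control = jitter_control,
         jitter_challenged = jitter_challenged,
         protocol = protocol, master_seed = as.integer(master_seed)),
    class = "oemri_study_spec"
  )
}

jitter_template <- function(template, jitter) {
  nm <- c("s0_air", "r1_air", "delta_r1", "delta_r2star")
  eps <- stats::rnorm(length(nm), 0, jitter[nm])
  template$mean_s0_air <- max(template$mean_s0_air + eps[1], 0.2 * template$mean_s0_air)
  template$mean_r1_air <- max(template$mean_r1_air + eps[2], 0.05)
  template$mean_delta_r1 <- template$mean_delta_r1 + eps[3]
  template$mean_delta_r2star <- template$mean_delta_r2star + eps[4]
  template
}

#' Simulate a full two-group study
#'
#' Draws per-animal templates by jittering the group template means with the
#' configured between-animal SDs, generates each animal's ground-truth phantom
#' and (optionally) its noisy two-gas-state image series. All randomness
#' derives deterministically from `master_seed`.
#'
#' @param spec An [study_spec()].
#' @param signals If `FALSE`, skip the image simulation and return phantoms
#'   only (useful for analyses that work on ground truth).
#' @return A list with one element per animal: `list(ground_truth =, series =)`.
#' @export
make_study <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "oemri_study_spec"))
  n <- spec$n_control + spec$n_challenged
  groups <- rep(c("control", "challenged"), c(spec$n_control, spec$n_challenged))
  ids <- paste0(groups, "_", sprintf("%02d", c(seq_len(spec$n_control),
                                               seq_len(spec$n_challenged))))
  drawn <- local_seed(spec$master_seed, {
    templates <- lapply(seq_len(n), function(i) {
      g <- groups[i]
      jitter_template(spec[[g]], spec[[paste0("jitter_", g)]])
    })
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n), ncol = 2)
    list(templates = templates, seeds = seeds)
  })
  lapply(seq_len(n), function(i) {
    tpl <- drawn$templates[[i]]
    tpl$seed <- drawn$seeds[i, 1]
    gt <- make_phantom(tpl, animal_id = ids[i])
    # the study design assigns the label; the template only shapes the fields
    # (a null study can give both arms the same template)
    gt$group <- groups[i]
    series <- if (signals) {
      simulate_signal(gt, spec$protocol, seed = drawn$seeds[i, 2])
    }
    list(ground_truth = gt, series = series)
  })
}

#' Write / read a ground-truth bundle
#'
#' The four parameter maps are stacked along the third axis of one NIfTI
#' volume (order: s0_air, r1_air, delta_r1, delta_r2star), the mask written as
#' integer NIfTI, and group/animal id in a JSON sidecar.
#'
#' @param gt An `oemri_ground_truth`.
#' @param dir Output directory.
#' @return Sidecar path, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- gt$animal_id
  fields <- c("s0_air", "r1_air", "delta_r1", "delta_r2star")
  a <- array(0, dim = c(dim(gt$mask), length(fields)))
  for (i in seq_along(fields)) a[, , i] <- gt[[fields[i]]]
  RNifti::writeNifti(a, file.path(dir, paste0(id, "_truth.nii")), datatype = "double")
  RNifti::writeNifti(array(as.integer(gt$mask), dim = dim(gt$mask)),
                     file.path(dir, paste0(id, "_truth_mask.nii")), datatype = "int16")
  sidecar <- file.path(dir, paste0(id, "_truth.json"))
  write_sidecar(list(animal_id = id, group = gt$group, fields = fields), sidecar)
  invisible(sidecar)
}

#' @rdname write_ground_truth
#' @param animal_id Animal identifier (file prefix).
#' @export
read_ground_truth <- function(dir, animal_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(animal_id, "_truth.json")),
                              simplifyVector = TRUE)
  a <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_truth.nii"))))
  m <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_truth_mask.nii"))))
  gt <- list(mask = matrix(as.logical(m), nrow = dim(m)[1]))
  for (i in seq_along(meta$fields)) {
    gt[[meta$fields[i]]] <- matrix(as.numeric(a[, , i]), nrow = dim(a)[1])
  }
  gt$group <- meta$group
  gt$animal_id <- meta$animal_id
  structure(gt, class = "oemri_ground_truth")
}
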