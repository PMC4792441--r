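## Pixel-wise three-parameter inversion-recovery relaxometry.
##
## Model: S(TI) = | S0 * (1 - B * exp(-R1 * TI)) |, fitted on the magnitude
## directly (no polarity restoration). For S0 > 0 the model is linear in S0,
## so S0 is profiled out analytically and the optimiser works on (B, R1).

#' Configuration of the pixel-wise inversion-recovery fit
#'
#' @param r1_bounds Allowed R1 interval, s^-1.
#' @param inv_eff_bounds Allowed inversion-efficiency interval (dimensionless;
#'   2 is a perfect inversion).
#' @param s0_bounds Allowed S0 interval (lower bound exclusive at 0).
#' @param max_iterations Optimiser iteration cap per start.
#' @param tolerance Relative convergence tolerance of the optimiser.
#' @param n_multistart Number of initialisations per pixel: the canonical
#'   start (S0 from the signal maximum, R1 from the null-point heuristic
#'   TI_null = ln(2)/R1 at the minimum-signal TI, B = 2) plus log-spaced R1
#'   restarts across the bounds; lowest residual wins, ties broken by lowest
#'   R1.
#' @param residual_ceiling Maximum accepted sum of squared residuals; fits
#'   above it are flagged invalid.
#' @return An object of class `oemri_fit_config`.
#' @export
fit_config <- function(r1_bounds = c(0.01, 20),
                       inv_eff_bounds = c(0, 2.1),
                       s0_bounds = c(0, Inf),
                       max_iterations = 300,
                       tolerance = 1e-12,
                       n_multistart = 4,
                       residual_ceiling = Inf) {
  stopifnot(length(r1_bounds) == 2, diff(r1_bounds) > 0, r1_bounds[1] > 0,
            length(inv_eff_bounds) == 2, diff(inv_eff_bounds) > 0,
            inv_eff_bounds[1] >= 0,
            length(s0_bounds) == 2, diff(s0_bounds) > 0, s0_bounds[1] >= 0,
            max_iterations >= 1, tolerance > 0, n_multistart >= 1,
            residual_ceiling > 0)
  structure(list(r1_bounds = as.numeric(r1_bounds),
                 inv_eff_bounds = as.numeric(inv_eff_bounds),
                 s0_bounds = as.numeric(s0_bounds),
                 max_iterations = as.integer(max_iterations),
                 tolerance = as.numeric(tolerance),
                 n_multistart = as.integer(n_multistart),
                 residual_ceiling = as.numeric(residual_ceiling)),
            class = "oemri_fit_config")
}

#' Fit the three-parameter inversion-recovery model to one pixel
#'
#' Least-squares fit of `S(TI) = |S0 (1 - B exp(-R1 TI))|` within the
#' configured bounds. R1 is returned in s^-1 regardless of the protocol's
#' time unit. `fit_ok` is `FALSE` when the optimiser fails, any parameter
#' lands on a bound, or the residual exceeds the configured ceiling —
#' saturated fits are flagged, never clipped and accepted.
#'
#' @param signal Numeric vector of magnitudes, one per inversion time.
#' @param protocol An [acquisition_protocol()].
#' @param config An [fit_config()].
#' @return A list with `s0`, `inv_eff`, `r1` (s^-1), `residual` (sum of
#'   squared residuals) and `fit_ok`.
#' @export
fit_ir_pixel <- function(signal, protocol = acquisition_protocol(),
                         config = fit_config()) {
  validate_protocol(protocol)
  ti <- protocol$inversion_times
  if (length(signal) != length(ti)) {
    stop("signal length must equal the number of inversion times", call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal)) || any(signal < 0)) {
    stop("signal must be finite and nonnegative", call. = FALSE)
  }
  conv <- if (protocol$ti_unit == "ms") 1e-3 else 1  # s^-1 -> per TI unit
  fail <- list(s0 = NA_real_, inv_eff = NA_real_, r1 = NA_real_,
               residual = NA_real_, fit_ok = FALSE)
  if (all(signal == 0) || stats::sd(signal) == 0) return(fail)

  y <- signal
  yy <- sum(y^2)
  s0_lo <- config$s0_bounds[1]; s0_hi <- config$s0_bounds[2]
  profile_s0 <- function(g) {
    d <- sum(g * g)
    if (d < 1e-300) return(NA_real_)
    min(max(sum(y * g) / d, s0_lo), s0_hi)
  }
  obj <- function(p) {
    g <- abs(1 - p[1] * exp(-p[2] * ti))
    s0 <- profile_s0(g)
    if (!is.finite(s0)) return(yy)
    sum((y - s0 * g)^2)
  }

  lo <- c(config$inv_eff_bounds[1], config$r1_bounds[1] * conv)
  hi <- c(config$inv_eff_bounds[2], config$r1_bounds[2] * conv)
  b0 <- min(max(2, lo[1] + 1e-3), hi[1] - 1e-3)
  r1_hat <- min(max(log(2) / ti[which.min(y)], lo[2]), hi[2])

  # canonical start plus the best points of a coarse (B, R1) objective grid,
  # evaluated in one shot (the basis curves do not depend on the data)
  b_grid <- unique(pmin(pmax(c(0.6, 0.9, 1.2, 1.5, 1.8, 2.0, 2.05),
                             lo[1] + 1e-3), hi[1] - 1e-3))
  r1_grid <- exp(seq(log(lo[2] * 1.5), log(hi[2] / 1.5), length.out = 16))
  grid <- as.matrix(expand.grid(b = b_grid, r1 = r1_grid))
  G <- abs(1 - grid[, 1] * exp(-outer(grid[, 2], ti)))  # n_grid x n_TI
  score <- pmax(G %*% y, 0)^2 / pmax(rowSums(G^2), 1e-300)
  gobj <- yy - score  # profiled-S0 residual at each grid point
  ord <- order(gobj)
  n_extra <- max(config$n_multistart - 1L, 1L)
  picked <- integer(0)
  for (k in ord) {  # greedy, keeping starts in distinct basins
    if (length(picked) >= n_extra) break
    if (!length(picked) ||
        all(abs(log(grid[k, 2] / grid[picked, 2])) > 0.4 |
              abs(grid[k, 1] - grid[picked, 1]) > 0.25)) {
      picked <- c(picked, k)
    }
  }
  starts <- rbind(c(b0, r1_hat), grid[picked, , drop = FALSE])

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    ans <- tryCatch(
      stats::nlminb(starts[k, ], obj, lower = lo, upper = hi,
                    control = list(iter.max = config$max_iterations,
                                   eval.max = 4L * config$max_iterations,
                                   rel.tol = config$tolerance)),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    if (is.null(best) ||
        ans$objective < best$objective - 1e-12 ||
        (abs(ans$objective - best$objective) <= 1e-12 &&
         ans$par[2] < best$par[2])) {
      best <- ans
    }
  }
  if (is.null(best)) return(fail)

  b <- unname(best$par[1]); r1u <- unname(best$par[2])
  g <- abs(1 - b * exp(-r1u * ti))
  s0 <- profile_s0(g)
  residual <- best$objective
  at_bound <- function(x, l, u) {
    m <- 1e-7 * (1 + abs(x))
    (is.finite(l) && x - l < m) || (is.finite(u) && u - x < m)
  }
  # nlminb codes: 0 is clean convergence; "singular convergence" (7) is a
  # flat-valley stop at the optimum and is accepted; "false convergence" and
  # other failures are not.
  converged <- best$convergence == 0 ||
    isTRUE(grepl("singular convergence", best$message))
  ok <- converged &&
    is.finite(s0) && s0 > s0_lo && s0 < s0_hi &&
    !at_bound(b, lo[1], hi[1]) && !at_bound(r1u, lo[2], hi[2]) &&
    residual <= config$residual_ceiling
  list(s0 = s0, inv_eff = b, r1 = r1u / conv, residual = residual,
       fit_ok = isTRUE(ok))
}

#' Fit parameter maps for a whole image series
#'
#' Fits every in-mask pixel independently for each gas state, then derives
#' the oxygen-uptake map `delta_r1 = R1_O2 - R1_air` and the oxygen-delivery
#' map `delta_r2star = ln(S0_air / S0_O2) / TE` wherever both gas-state fits
#' succeeded. Out-of-mask pixels and failed fits carry `NA`; per-pixel
#' failures never abort the map.
#'
#' @param series An `oemri_series`.
#' @param config An [fit_config()].
#' @return An object of class `oemri_maps`: per-gas-state matrices `s0`,
#'   `r1`, `inv_eff`, `residual`, `fit_ok`, derived `delta_r1` (s^-1) and
#'   `delta_r2star` (ms^-1), the combined validity matrix `valid`, plus mask
#'   and metadata.
#' @export
fit_maps <- function(series, config = fit_config()) {
  validate_series(series)
  protocol <- series$protocol
  mask <- series$mask
  gs <- protocol$gas_states
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)

  blank <- function() matrix(NA_real_, nx, ny)
  maps <- list(s0 = list(), r1 = list(), inv_eff = list(),
               residual = list(), fit_ok = list())
  for (g in gs) {
    s0m <- blank(); r1m <- blank(); bm <- blank(); resm <- blank()
    okm <- matrix(FALSE, nx, ny)
    im <- series$images[[g]]
    ymat <- matrix(im, nx * ny, dim(im)[3])[idx, , drop = FALSE]
    for (j in seq_along(idx)) {
      f <- fit_ir_pixel(ymat[j, ], protocol, config)
      s0m[idx[j]] <- f$s0; r1m[idx[j]] <- f$r1; bm[idx[j]] <- f$inv_eff
      resm[idx[j]] <- f$residual; okm[idx[j]] <- f$fit_ok
    }
    maps$s0[[g]] <- s0m; maps$r1[[g]] <- r1m; maps$inv_eff[[g]] <- bm
    maps$residual[[g]] <- resm; maps$fit_ok[[g]] <- okm
  }

  valid <- maps$fit_ok[[gs[1]]] & maps$fit_ok[[gs[2]]]
  dr1 <- delta_r1(maps$r1[[gs[2]]], maps$r1[[gs[1]]])
  te_ms <- if (protocol$ti_unit == "ms") protocol$echo_time else protocol$echo_time * 1000
  dr2s <- delta_r2star(maps$s0[[gs[1]]], maps$s0[[gs[2]]], te_ms)
  dr1[!valid] <- NA_real_
  neg <- attr(dr2s, "negative")
  dr2s <- unflag(dr2s)
  dr2s[!valid] <- NA_real_

  structure(
    list(s0 = maps$s0, r1 = maps$r1, inv_eff = maps$inv_eff,
         residual = maps$residual, fit_ok = maps$fit_ok,
         delta_r1 = dr1, delta_r2star = dr2s,
         delta_r2star_negative = neg & valid, valid = valid,
         mask = mask, group = series$group, animal_id = series$animal_id,
         protocol = protocol),
    class = "oemri_maps"
  )
}

#' Oxygen-uptake map: delta-R1 = R1_O2 - R1_air
#'
#' Elementwise difference of the oxygen-state and air-state R1 maps (s^-1).
#' `NA` propagates; inputs must share their grid.
#'
#' @param r1_o2,r1_air Numeric scalars, vectors or matrices in s^-1.
#' @return The difference, same shape as the inputs.
#' @export
#' @examples
#' delta_r1(0.581, 0.557)  # 0.024 s^-1
delta_r1 <- function(r1_o2, r1_air) {
  if (!identical(dim(r1_o2), dim(r1_air)) ||
      length(r1_o2) != length(r1_air)) {
    stop("r1_o2 and r1_air must share their grid", call. = FALSE)
  }
  r1_o2 - r1_air
}

#' Oxygen-delivery map: delta-R2* = ln(S0_air / S0_O2) / TE
#'
#' Negative values are permitted (they indicate S0_O2 > S0_air) and flagged in
#' the `"negative"` attribute; pixels where either S0 is nonpositive are
#' marked invalid (`NA`) rather than aborting the map.
#'
#' @param s0_air,s0_o2 Fitted S0 maps (same grid), arbitrary units.
#' @param echo_time Echo time; with TE in ms the result is in ms^-1.
#' @return Map of delta-R2* with logical attributes `"negative"` and
#'   `"invalid"`.
#' @export
#' @examples
#' delta_r2star(1, exp(-0.045), 0.5)  # 0.090 ms^-1
delta_r2star <- function(s0_air, s0_o2, echo_time) {
  if (!identical(dim(s0_air), dim(s0_o2)) ||
      length(s0_air) != length(s0_o2)) {
    stop("s0_air and s0_o2 must share their grid", call. = FALSE)
  }
  if (!is.finite(echo_time) || echo_time <= 0) {
    stop("echo_time must be positive", call. = FALSE)
  }
  invalid <- !is.na(s0_air) & !is.na(s0_o2) & (s0_air <= 0 | s0_o2 <= 0)
  out <- s0_air + NA_real_  # keep shape
  ok <- !is.na(s0_air) & !is.na(s0_o2) & !invalid
  out[ok] <- log(s0_air[ok] / s0_o2[ok]) / echo_time
  structure(out,
            negative = !is.na(out) & out < 0,
            invalid = invalid)
}

## strip the flag attributes added by delta_r2star
unflag <- function(x) {
  attr(x, "negative") <- NULL
  attr(x, "invalid") <- NULL
  x
}

#' Write / read fitted parameter maps
#'
#' All real-valued maps are stacked along the third axis of one NIfTI volume
#' (layer order in the JSON sidecar); validity flags are written as an integer
#' NIfTI.
#'
#' @param maps An `oemri_maps`.
#' @param dir Output directory.
#' @return Sidecar path, invisibly.
#' @export
write_parameter_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- maps$animal_id
  gs <- maps$protocol$gas_states
  layers <- list()
  for (g in gs) {
    layers[[paste0("s0_", g)]] <- maps$s0[[g]]
    layers[[paste0("r1_", g)]] <- maps$r1[[g]]
    layers[[paste0("inv_eff_", g)]] <- maps$inv_eff[[g]]
    layers[[paste0("residual_", g)]] <- maps$residual[[g]]
  }
  layers$delta_r1 <- maps$delta_r1
  layers$delta_r2star <- maps$delta_r2star
  a <- array(NA_real_, dim = c(dim(maps$mask), length(layers)))
  for (i in seq_along(layers)) a[, , i] <- layers[[i]]
  RNifti::writeNifti(a, file.path(dir, paste0(id, "_maps.nii")), datatype = "double")
  fl <- array(0L, dim = c(dim(maps$mask), 4))
  fl[, , 1] <- as.integer(maps$mask)
  fl[, , 2] <- as.integer(maps$fit_ok[[gs[1]]])
  fl[, , 3] <- as.integer(maps$fit_ok[[gs[2]]])
  fl[, , 4] <- as.integer(maps$delta_r2star_negative)
  RNifti::writeNifti(fl, file.path(dir, paste0(id, "_maps_flags.nii")),
                     datatype = "int16")
  sidecar <- file.path(dir, paste0(id, "_maps.json"))
  write_sidecar(list(animal_id = id, group = maps$group,
                     layers = names(layers),
                     flags = c("mask", paste0("fit_ok_", gs), "delta_r2star_negative"),
                     protocol = protocol_to_list(maps$protocol)), sidecar)
  invisible(sidecar)
}

#' @rdname write_parameter_maps
#' @param animal_id Animal identifier (file prefix).
#' @export
read_parameter_maps <- function(dir, animal_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(animal_id, "_maps.json")),
                              simplifyVector = TRUE)
  protocol <- protocol_from_list(meta$protocol)
  gs <- protocol$gas_states
  a <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_maps.nii"))))
  fl <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_maps_flags.nii"))))
  nx <- dim(a)[1]
  layer <- function(nm) {
    matrix(as.numeric(a[, , match(nm, meta$layers)]), nrow = nx)
  }
  flag <- function(nm) {
    matrix(as.logical(fl[, , match(nm, meta$flags)]), nrow = nx)
  }
  maps <- list(s0 = list(), r1 = list(), inv_eff = list(),
               residual = list(), fit_ok = list())
  for (g in gs) {
    maps$s0[[g]] <- layer(paste0("s0_", g))
    maps$r1[[g]] <- layer(paste0("r1_", g))
    maps$inv_eff[[g]] <- layer(paste0("inv_eff_", g))
    maps$residual[[g]] <- layer(paste0("residual_", g))
    maps$fit_ok[[g]] <- flag(paste0("fit_ok_", g))
  }
  maps$delta_r1 <- layer("delta_r1")
  maps$delta_r2star <- layer("delta_r2star")
  maps$delta_r2star_negative <- flag("delta_r2star_negative")
  maps$mask <- flag("mask")
  maps$valid <- maps$fit_ok[[gs[1]]] & maps$fit_ok[[gs[2]]]
  maps$group <- meta$group
  maps$animal_id <- meta$animal_id
  maps$protocol <- protocol
  structure(maps, class = "oemri_maps")
}
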