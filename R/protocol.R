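#' Acquisition protocol for two-gas-state inversion-recovery lung imaging
#'
#' Bundles the fixed experimental constants of the segmented inversion-recovery
#' ultrashort echo-time (SIR-UTE) protocol: the inversion times sampled during
#' each gas state, the echo time used to convert the oxygen-induced signal
#' attenuation into a delta-R2* rate, the ordered gas-state labels, and the
#' magnitude-noise model used when simulating.
#'
#' @param inversion_times Numeric vector of inversion times, strictly
#'   increasing, all positive. Default: the seven-point schedule
#'   100, 400, 700, 1800, 3000, 4500, 6000 ms.
#' @param echo_time Echo time (TE), same time unit as `inversion_times`.
#'   Default 0.5 ms. Delta-R2* maps are reported in the reciprocal of this
#'   unit (ms^-1 for the default).
#' @param ti_unit Time unit of `inversion_times` and `echo_time`: `"ms"`
#'   (default) or `"s"`. Fitted R1 is always reported in s^-1 regardless.
#' @param gas_states Ordered pair of gas-state labels; first is the baseline
#'   (air), second the oxygen state.
#' @param noise_sigma Standard deviation of the simulated magnitude noise, in
#'   the arbitrary signal units of S0. Default 0.1645, i.e. SNR ~ 20 at the
#'   control-group mean density S0 = 3.29.
#' @param noise_model `"gaussian"` (additive, truncated at zero) or
#'   `"rician"`.
#' @return An object of class `oemri_protocol`.
#' @export
#' @examples
#' p <- acquisition_protocol()
#' p$inversion_times
acquisition_protocol <- function(inversion_times = c(100, 400, 700, 1800, 3000, 4500, 6000),
                                 echo_time = 0.5,
                                 ti_unit = c("ms", "s"),
                                 gas_states = c("air", "oxygen"),
                                 noise_sigma = 0.1645,
                                 noise_model = c("gaussian", "rician")) {
  p <- structure(
    list(
      inversion_times = as.numeric(inversion_times),
      echo_time = as.numeric(echo_time),
      ti_unit = match.arg(ti_unit),
      gas_states = as.character(gas_states),
      noise_sigma = as.numeric(noise_sigma),
      noise_model = match.arg(noise_model)
    ),
    class = "oemri_protocol"
  )
  validate_protocol(p)
}

#' Validate an acquisition protocol
#'
#' Checks the protocol invariants and returns the protocol unchanged when they
#' hold. At least four inversion times are required: the pixel fit has three
#' parameters and needs a residual degree of freedom.
#'
#' @param protocol An `oemri_protocol`.
#' @return `protocol`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "oemri_protocol"))
  ti <- protocol$inversion_times
  if (length(ti) < 4L) {
    stop("need at least 4 inversion times for a 3-parameter fit", call. = FALSE)
  }
  if (anyNA(ti) || any(ti <= 0)) {
    stop("inversion times must be positive and finite", call. = FALSE)
  }
  if (any(diff(ti) <= 0)) {
    stop("inversion times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(protocol$echo_time) || protocol$echo_time <= 0) {
    stop("echo_time must be positive", call. = FALSE)
  }
  if (length(protocol$gas_states) != 2L ||
      anyDuplicated(protocol$gas_states)) {
    stop("gas_states must be two distinct labels", call. = FALSE)
  }
  if (!is.finite(protocol$noise_sigma) || protocol$noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  protocol
}

#' @export
print.oemri_protocol <- function(x, ...) {
  cat("OE-MRI acquisition protocol\n")
  cat("  TI (", x$ti_unit, "): ", paste(x$inversion_times, collapse = ", "), "\n", sep = "")
  cat("  TE: ", x$echo_time, " ", x$ti_unit, "\n", sep = "")
  cat("  gas states: ", paste(x$gas_states, collapse = " -> "), "\n", sep = "")
  cat("  noise: ", x$noise_model, ", sigma = ", x$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' Construct a two-gas-state image series
#'
#' An image series holds one magnitude image per (gas state, inversion time)
#' pair for a single animal, together with the lung mask, group label and
#' acquisition protocol. Images are stored as arrays of dimension
#' `nx x ny x n_TI`, one array per gas state.
#'
#' @param images Named list, one element per gas state in
#'   `protocol$gas_states`, each an `nx x ny x n_TI` array of nonnegative
#'   magnitudes.
#' @param protocol An `oemri_protocol`.
#' @param mask Logical `nx x ny` matrix marking lung pixels.
#' @param group Group label, `"control"` or `"challenged"`.
#' @param animal_id Identifier string.
#' @return An object of class `oemri_series`.
#' @export
image_series <- function(images, protocol, mask, group, animal_id) {
  s <- structure(
    list(images = images, protocol = protocol, mask = mask,
         group = group, animal_id = as.character(animal_id)),
    class = "oemri_series"
  )
  validate_series(s)
}

#' Validate an image series
#'
#' @param series An `oemri_series`.
#' @return `series` if valid, otherwise an error.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "oemri_series"))
  validate_protocol(series$protocol)
  gs <- series$protocol$gas_states
  if (!identical(sort(names(series$images)), sort(gs))) {
    stop("images must be named by the protocol gas states", call. = FALSE)
  }
  if (!is.logical(series$mask) || length(dim(series$mask)) != 2L) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  n_ti <- length(series$protocol$inversion_times)
  for (g in gs) {
    im <- series$images[[g]]
    if (!identical(dim(im)[1:2], dim(series$mask)) ||
        length(dim(im)) != 3L || dim(im)[3] != n_ti) {
      stop("image array for state '", g, "' must be nx x ny x n_TI on the mask grid",
           call. = FALSE)
    }
    if (anyNA(im) || any(im < 0)) {
      stop("magnitude images must be nonnegative and finite", call. = FALSE)
    }
  }
  check_group_label(series$group)
  series
}

check_group_label <- function(group) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("control", "challenged")) {
    stop("group must be 'control' or 'challenged'", call. = FALSE)
  }
  invisible(group)
}

## ---- on-disk layout: NIfTI volumes + JSON sidecar --------------------------

protocol_to_list <- function(protocol) {
  unclass(protocol)
}

protocol_from_list <- function(x) {
  acquisition_protocol(
    inversion_times = x$inversion_times, echo_time = x$echo_time,
    ti_unit = x$ti_unit, gas_states = x$gas_states,
    noise_sigma = x$noise_sigma, noise_model = x$noise_model
  )
}

write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write an image series to disk
#'
#' Writes one NIfTI volume per gas state (inversion times stacked along the
#' third axis), the lung mask as an integer 0/1 NIfTI, and a JSON sidecar with
#' the protocol, group and animal id. Arrays are stored as 64-bit floats so
#' the round trip is lossless.
#'
#' @param series An `oemri_series`.
#' @param dir Output directory; created if absent. Files are prefixed with the
#'   animal id.
#' @return The sidecar path, invisibly.
#' @export
write_image_series <- function(series, dir) {
  validate_series(series)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- series$animal_id
  for (g in series$protocol$gas_states) {
    RNifti::writeNifti(series$images[[g]],
                       file.path(dir, paste0(id, "_", g, ".nii")),
                       datatype = "double")
  }
  RNifti::writeNifti(array(as.integer(series$mask), dim = dim(series$mask)),
                     file.path(dir, paste0(id, "_mask.nii")),
                     datatype = "int16")
  sidecar <- file.path(dir, paste0(id, ".json"))
  write_sidecar(list(animal_id = id, group = series$group,
                     protocol = protocol_to_list(series$protocol)), sidecar)
  invisible(sidecar)
}

#' Read an image series written by [write_image_series()]
#'
#' @param dir Directory containing the files.
#' @param animal_id Animal identifier (file prefix).
#' @return An `oemri_series`.
#' @export
read_image_series <- function(dir, animal_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(animal_id, ".json")),
                              simplifyVector = TRUE)
  protocol <- protocol_from_list(meta$protocol)
  mask_arr <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_mask.nii"))))
  mask <- matrix(as.logical(mask_arr), nrow = dim(mask_arr)[1])
  images <- lapply(stats::setNames(protocol$gas_states, protocol$gas_states), function(g) {
    a <- as.array(RNifti::readNifti(file.path(dir, paste0(animal_id, "_", g, ".nii"))))
    array(as.numeric(a), dim = dim(a))
  })
  image_series(images, protocol, mask, meta$group, meta$animal_id)
}

#' List animal ids present in a series/maps/ground-truth directory
#'
#' @param dir Directory written by [write_image_series()],
#'   [write_parameter_maps()] or [write_ground_truth()].
#' @param kind Which sidecars to list: image series (default), fitted maps,
#'   or ground-truth bundles.
#' @return Character vector of animal ids (JSON sidecar prefixes).
#' @export
list_animals <- function(dir, kind = c("series", "maps", "truth")) {
  kind <- match.arg(kind)
  f <- list.files(dir, pattern = "\\.json$")
  f <- switch(kind,
    series = f[!grepl("(_maps|_truth)\\.json$", f)],
    maps = f[grepl("_maps\\.json$", f)],
    truth = f[grepl("_truth\\.json$", f)]
  )
  suffix <- switch(kind, series = "", maps = "_maps", truth = "_truth")
  sort(sub(paste0(suffix, "\\.json$"), "", f))
}
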