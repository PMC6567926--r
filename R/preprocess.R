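#' Phase-retrieval parameters
#'
#' Parameters of the single-distance phase retrieval used for
#' propagation-based phase-contrast acquisitions: beam energy, propagation
#' (sample-to-detector) distance, detector pixel size and the assumed
#' delta/beta ratio of the tissue. The defaults for distance and
#' delta/beta are placeholders — they depend on the beamline geometry and
#' sample composition and must be set by the user.
#'
#' @param energy_keV X-ray energy in keV (default 65).
#' @param propagation_distance_m Sample-to-detector distance in metres.
#' @param pixel_size_um Detector pixel size in micrometres (default 47.7).
#' @param delta_beta_ratio Ratio of the refractive index decrement to the
#'   absorption index (delta/beta) assumed for the tissue.
#' @return An object of class `phase_params`.
#' @export
phase_params <- function(energy_keV = 65,
                         propagation_distance_m = 1,
                         pixel_size_um = 47.7,
                         delta_beta_ratio = 1000) {
  vals <- c(energy_keV, propagation_distance_m, pixel_size_um,
            delta_beta_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all phase parameters must be strictly positive", call. = FALSE)
  structure(list(energy_keV = energy_keV,
                 propagation_distance_m = propagation_distance_m,
                 pixel_size_um = pixel_size_um,
                 delta_beta_ratio = delta_beta_ratio),
            class = "phase_params")
}

# squared spatial frequency grid (cycles/m)^2 for an nr x nc FFT
freq_sq_grid <- function(nr, nc, pixel_size_m) {
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] /
    (nr * pixel_size_m)
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] /
    (nc * pixel_size_m)
  outer(fy^2, fx^2, `+`)
}

#' Single-distance phase retrieval (Paganin filter)
#'
#' Replaces each flat-field-normalized intensity slice by the
#' single-distance phase-retrieval result: the inverse Fourier transform
#' of `FT(I) / (1 + pi * lambda * z * (delta/beta) * |f|^2)` followed by
#' `-log`. The transfer function is 1 at zero frequency (DC preserving)
#' and decays at high frequency (low pass), so a uniform slice of
#' intensity 1 maps to 0 everywhere.
#'
#' @param intensity A [slice_stack()] of strictly positive
#'   (flat-field-normalized) intensity slices.
#' @param params A [phase_params()].
#' @param log_transform Apply the final `-log`? Disable to obtain the
#'   linear low-pass stage alone.
#' @return A `slice_stack` of retrieved (thickness-like) maps.
#' @export
paganin_filter <- function(intensity, params = phase_params(),
                           log_transform = TRUE) {
  stopifnot(inherits(intensity, "slice_stack"),
            inherits(params, "phase_params"))
  lambda_m <- 1.23984198e-9 / params$energy_keV  # hc/E
  px_m <- params$pixel_size_um * 1e-6
  coef <- pi * lambda_m * params$propagation_distance_m *
    params$delta_beta_ratio
  d <- slice_dim(intensity)
  H <- 1 / (1 + coef * freq_sq_grid(d[1], d[2], px_m))
  out <- lapply(intensity$slices, function(s) {
    if (log_transform && any(s <= 0))
      stop("intensity must be strictly positive (log undefined)",
           call. = FALSE)
    filt <- Re(fft(fft(s) * H, inverse = TRUE)) / length(s)
    if (log_transform) -log(pmax(filt, .Machine$double.eps)) else filt
  })
  slice_stack(out, voxel_size_um = intensity$voxel_size_um)
}

#' Normalize a slice stack to [0, 1]
#'
#' Linear rescale using the global stack minimum and maximum; order
#' preserving, and idempotent on stacks already spanning `[0, 1]`.
#'
#' @param stack A [slice_stack()] with non-constant values.
#' @return A `slice_stack` with values in `[0, 1]`.
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  rng <- range(unlist(lapply(stack$slices, range)))
  if (rng[1] == rng[2])
    stop("cannot normalize a constant stack", call. = FALSE)
  out <- lapply(stack$slices, function(s) (s - rng[1]) / diff(rng))
  slice_stack(out, voxel_size_um = stack$voxel_size_um)
}
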