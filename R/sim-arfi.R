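#' Isotropic Gaussian focal field
#'
#' A 3-D Gaussian bump on a regular grid: the standard stand-in for an
#' ultrasound focal spot, used both as a displacement field for MR-ARFI
#' simulation and as a volumetric heat source for bioheat runs.
#'
#' @param dim Integer grid dimensions (nx, ny, nz).
#' @param spacing_mm Voxel spacing, mm (scalar, isotropic).
#' @param center_mm Focus centre in mm from the grid origin (length 3).
#' @param fwhm_mm Full width at half maximum, mm.
#' @param peak Peak value at the centre (units are the caller's: um for
#'   displacement, W/cm2 for intensity).
#' @return A list of class `displacement_field`: `field` (3-D array),
#'   `spacing_mm`, `center_mm`, `fwhm_mm`, `peak`.
#' @export
gaussian_focus <- function(dim, spacing_mm, center_mm, fwhm_mm, peak) {
  stopifnot(length(dim) == 3, length(center_mm) == 3)
  stop_if_not_scalar_positive(fwhm_mm, "fwhm_mm")
  stop_if_not_scalar_positive(spacing_mm, "spacing_mm")
  extent <- (dim - 1) * spacing_mm
  if (any(center_mm < 0) || any(center_mm > extent)) {
    stop("`center_mm` lies outside the grid", call. = FALSE)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(k) ((seq_len(dim[k]) - 1) * spacing_mm -
                                   center_mm[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  structure(
    list(field = peak * exp(-r2 / (2 * sigma^2)),
         spacing_mm = spacing_mm, center_mm = center_mm,
         fwhm_mm = fwhm_mm, peak = peak),
    class = "displacement_field"
  )
}

#' Simulate a motion-encoded MR-ARFI phase-image pair
#'
#' Forward model of displacement encoding: two acquisitions with alternating
#' motion-encoding-gradient polarity acquire phase `+/- gamma*G*tau*D`, so
#' their difference is `2*gamma*G*tau*D`. Independent zero-mean Gaussian
#' phase noise is added to each acquisition and phases are wrapped to
#' (-pi, pi].
#'
#' @param field A `displacement_field` whose `field` holds displacement in
#'   micrometres (um), all values >= 0.
#' @param encoding An [encoding_params()].
#' @param noise_sd_rad Per-acquisition phase-noise SD, radians.
#' @param seed RNG seed.
#' @return A list of class `arfi_pair`: `phase_plus`, `phase_minus` (radian
#'   arrays), `encoding`, `spacing_mm`.
#' @export
simulate_arfi_pair <- function(field, encoding, noise_sd_rad = 0, seed = 1L) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(encoding, "encoding_params"))
  if (any(field$field < 0)) stop("`field` must be non-negative", call. = FALSE)
  if (noise_sd_rad < 0) stop("`noise_sd_rad` must be >= 0", call. = FALSE)
  d_m <- field$field * 1e-6
  half <- encoding$gamma_rad_s_T * encoding$G_T_per_m * encoding$tau_s * d_m
  with_rng_seed(seed, {
    noise_p <- if (noise_sd_rad > 0) {
      array(stats::rnorm(length(half), sd = noise_sd_rad), dim = dim(half))
    } else 0
    noise_m <- if (noise_sd_rad > 0) {
      array(stats::rnorm(length(half), sd = noise_sd_rad), dim = dim(half))
    } else 0
    wrap <- function(x) Arg(exp(1i * x))
    structure(
      list(phase_plus = wrap(half + noise_p),
           phase_minus = wrap(-half + noise_m),
           encoding = encoding, spacing_mm = field$spacing_mm),
      class = "arfi_pair"
    )
  })
}
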