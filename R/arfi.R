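#' Motion-encoding-gradient parameters
#'
#' Constants of the displacement-encoding relation
#' `D = delta_phi / (2 * gamma * G * tau)`. The gyromagnetic ratio defaults
#' to the proton value (gamma / 2pi = 42.58 MHz/T). The gradient-lobe
#' duration `tau` has no universal default: displacement in metres is
#' meaningless without it, so it must be supplied.
#'
#' @param G_T_per_m Motion-encoding gradient magnitude, tesla/metre
#'   (0.04 T/m in the acquisitions this pipeline targets).
#' @param tau_s Duration of each gradient lobe, seconds (required).
#' @param gamma_rad_s_T Gyromagnetic ratio, rad s^-1 T^-1.
#' @return An object of class `encoding_params`.
#' @export
encoding_params <- function(G_T_per_m = 0.04, tau_s,
                            gamma_rad_s_T = 2 * pi * 42.58e6) {
  if (missing(tau_s)) {
    stop("`tau_s` (gradient-lobe duration) must be supplied; ",
         "displacements cannot be scaled without it", call. = FALSE)
  }
  stop_if_not_scalar_positive(G_T_per_m, "G_T_per_m")
  stop_if_not_scalar_positive(tau_s, "tau_s")
  stop_if_not_scalar_positive(gamma_rad_s_T, "gamma_rad_s_T")
  structure(
    list(G_T_per_m = G_T_per_m, tau_s = tau_s,
         gamma_rad_s_T = gamma_rad_s_T),
    class = "encoding_params"
  )
}

#' Complex phase difference of an ARFI acquisition pair
#'
#' Computed through the complex representation,
#' `Arg(exp(i * (phase_plus - phase_minus)))`, so results wrap correctly to
#' (-pi, pi] and are invariant under adding 2*pi to either input.
#'
#' @param pair An `arfi_pair`.
#' @return Radian array of the same geometry.
#' @export
phase_difference <- function(pair) {
  stopifnot(inherits(pair, "arfi_pair"))
  if (!identical(dim(pair$phase_plus), dim(pair$phase_minus))) {
    stop("phase images have mismatched geometry", call. = FALSE)
  }
  Arg(exp(1i * (pair$phase_plus - pair$phase_minus)))
}

#' Per-voxel displacement from a phase-difference map
#'
#' `D = delta_phi / (2 * gamma * G * tau)`, metres.
#'
#' @param delta_phi Radian array (from [phase_difference()]).
#' @param encoding An [encoding_params()].
#' @param spacing_mm Voxel spacing carried through to the output.
#' @return A list of class `displacement_map`: `D_m` (metres), `D_um`
#'   (micrometres), `spacing_mm`, `encoding`.
#' @export
displacement_map <- function(delta_phi, encoding, spacing_mm = NA_real_) {
  stopifnot(inherits(encoding, "encoding_params"))
  D <- delta_phi / (2 * encoding$gamma_rad_s_T * encoding$G_T_per_m *
                      encoding$tau_s)
  structure(
    list(D_m = D, D_um = D * 1e6, spacing_mm = spacing_mm,
         encoding = encoding),
    class = "displacement_map"
  )
}

#' Maximum focal displacement
#'
#' Finds the maximum absolute displacement within a region of interest and
#' flags whether it is detectable above the background phase noise,
#' mirroring the exclusion of acquisitions whose focal spot cannot be
#' distinguished from noise. Because the statistic is a maximum over `n`
#' ROI voxels, the per-voxel `detect_k`-sigma rule is Bonferroni-corrected
#' for the ROI size: with per-voxel two-sided tail mass
#' `a = 2 pnorm(-detect_k)`, the map is detectable when
#' `max > sd * qnorm(1 - a / (2 n))`. A pure-noise ROI is then called
#' detectable with probability about `a`, independent of its size, while
#' genuine foci a few times above the noise floor still pass.
#'
#' @param map A `displacement_map`.
#' @param roi Logical array of the map's geometry (`TRUE` inside the ROI),
#'   or `NULL` for the whole volume.
#' @param detect_k Per-voxel sigma multiple before the ROI-size
#'   correction.
#' @return A list: `max_um`, `index` (voxel coordinates), `detectable`,
#'   `background_sd_um`.
#' @export
max_displacement <- function(map, roi = NULL, detect_k = 3) {
  stopifnot(inherits(map, "displacement_map"))
  D <- map$D_um
  if (is.null(roi)) roi <- array(TRUE, dim = dim(D))
  if (!identical(dim(roi), dim(D))) {
    stop("`roi` geometry does not match the map", call. = FALSE)
  }
  if (!any(roi)) stop("`roi` is empty", call. = FALSE)
  absD <- abs(D)
  absD[!roi] <- -Inf
  i <- which.max(absD)
  max_um <- abs(D[i])
  bg <- D[!roi]
  bg_sd <- if (length(bg) >= 2) stats::sd(bg) else stats::mad(D[roi])
  n_roi <- sum(roi)
  tail_mass <- 2 * stats::pnorm(-detect_k)
  z_star <- stats::qnorm(1 - tail_mass / (2 * n_roi))
  list(
    max_um = max_um,
    index = arrayInd(i, dim(D))[1, ],
    detectable = if (is.finite(bg_sd) && bg_sd > 0) {
      max_um > z_star * bg_sd
    } else max_um > 0,
    background_sd_um = bg_sd
  )
}

#' Write / read an ARFI phase pair as NIfTI + JSON sidecar
#'
#' Phase images go to float32 NIfTI volumes (radians); the encoding metadata
#' to a JSON sidecar with keys `G_T_per_m`, `tau_s`, `gamma_rad_s_T`,
#' `polarity`.
#'
#' @param pair An `arfi_pair`.
#' @param prefix Path prefix; writes `<prefix>_plus.nii`,
#'   `<prefix>_minus.nii`, `<prefix>.json`.
#' @export
write_arfi_pair <- function(pair, prefix) {
  sp <- if (is.na(pair$spacing_mm)) 1 else pair$spacing_mm
  RNifti::writeNifti(
    RNifti::asNifti(pair$phase_plus, datatype = "float",
                    pixdim = rep(sp, 3)),
    paste0(prefix, "_plus.nii")
  )
  RNifti::writeNifti(
    RNifti::asNifti(pair$phase_minus, datatype = "float",
                    pixdim = rep(sp, 3)),
    paste0(prefix, "_minus.nii")
  )
  jsonlite::write_json(
    list(G_T_per_m = pair$encoding$G_T_per_m,
         tau_s = pair$encoding$tau_s,
         gamma_rad_s_T = pair$encoding$gamma_rad_s_T,
         polarity = c("plus", "minus"),
         spacing_mm = sp),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_arfi_pair
#' @export
read_arfi_pair <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  plus <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_plus.nii"))),
                dim = dim(RNifti::readNifti(paste0(prefix, "_plus.nii"))))
  minus <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_minus.nii"))),
                 dim = dim(RNifti::readNifti(paste0(prefix, "_minus.nii"))))
  structure(
    list(phase_plus = plus, phase_minus = minus,
         encoding = encoding_params(meta$G_T_per_m, meta$tau_s,
                                    meta$gamma_rad_s_T),
         spacing_mm = meta$spacing_mm),
    class = "arfi_pair"
  )
}
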