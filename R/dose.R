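#' Sonication protocol parameters
#'
#' Pulse-timing and intensity parameters of the TUS protocol: 550 kHz
#' carrier, 1 ms pulses at a 2 ms pulse repetition interval (PRF 500 Hz),
#' 300 ms pulse trains repeated every second.
#'
#' @param f0_hz Fundamental frequency, Hz.
#' @param pulse_duration_s Pulse duration, s.
#' @param pri_s Pulse repetition interval, s.
#' @param train_duration_s Pulse-train duration, s.
#' @param train_interval_s Pulse-train repetition interval, s.
#' @param i_sppa_W_cm2 Spatial-peak pulse-average intensity, W/cm^2
#'   (optional).
#' @param pnp_MPa Peak negative pressure, MPa (optional).
#' @return An object of class `sonication_protocol`.
#' @export
sonication_protocol <- function(f0_hz = 550e3, pulse_duration_s = 1e-3,
                                pri_s = 2e-3, train_duration_s = 0.3,
                                train_interval_s = 1,
                                i_sppa_W_cm2 = NULL, pnp_MPa = NULL) {
  stop_if_not_scalar_positive(f0_hz, "f0_hz")
  stop_if_not_scalar_positive(pulse_duration_s, "pulse_duration_s")
  stop_if_not_scalar_positive(pri_s, "pri_s")
  stop_if_not_scalar_positive(train_duration_s, "train_duration_s")
  stop_if_not_scalar_positive(train_interval_s, "train_interval_s")
  if (pulse_duration_s > pri_s) {
    stop("`pulse_duration_s` must not exceed `pri_s`", call. = FALSE)
  }
  if (train_duration_s > train_interval_s) {
    stop("`train_duration_s` must not exceed `train_interval_s`",
         call. = FALSE)
  }
  structure(
    list(f0_hz = f0_hz, pulse_duration_s = pulse_duration_s, pri_s = pri_s,
         train_duration_s = train_duration_s,
         train_interval_s = train_interval_s,
         i_sppa_W_cm2 = i_sppa_W_cm2, pnp_MPa = pnp_MPa),
    class = "sonication_protocol"
  )
}

#' Duty-cycle arithmetic
#'
#' Within-train duty = pulse duration / PRI; train duty = train duration /
#' train interval; total duty = their product. The default protocol gives
#' 0.5, 0.3 and 0.15.
#'
#' @param p A [sonication_protocol()].
#' @return A list: `within_train`, `train`, `total` (fractions).
#' @export
duty_cycles <- function(p) {
  stopifnot(inherits(p, "sonication_protocol"))
  within <- p$pulse_duration_s / p$pri_s
  train <- p$train_duration_s / p$train_interval_s
  list(within_train = within, train = train, total = within * train)
}

#' Temporal-average intensity from pulse-average intensity
#'
#' `I_SPTA = I_SPPA x total duty cycle`.
#'
#' @param i_sppa_W_cm2 Spatial-peak pulse-average intensity, W/cm^2.
#' @param p A [sonication_protocol()].
#' @return I_SPTA, W/cm^2.
#' @export
ispta_from_isppa <- function(i_sppa_W_cm2, p) {
  if (i_sppa_W_cm2 < 0) stop("intensity must be >= 0", call. = FALSE)
  i_sppa_W_cm2 * duty_cycles(p)$total
}

#' Plane-wave intensity from peak pressure
#'
#' `I = p^2 / (2 rho c)`, converted to W/cm^2. A nominal mapping for
#' sanity-checking pressure/intensity pairs; hydrophone-calibrated values
#' should be preferred when available.
#'
#' @param pressure_MPa Peak pressure, MPa.
#' @param density_kg_m3 Medium density, kg/m^3.
#' @param sound_speed_m_s Speed of sound, m/s.
#' @return Intensity, W/cm^2.
#' @export
intensity_from_pressure <- function(pressure_MPa, density_kg_m3 = 1000,
                                    sound_speed_m_s = 1500) {
  if (pressure_MPa < 0) stop("pressure must be >= 0", call. = FALSE)
  stop_if_not_scalar_positive(density_kg_m3, "density_kg_m3")
  stop_if_not_scalar_positive(sound_speed_m_s, "sound_speed_m_s")
  (pressure_MPa * 1e6)^2 / (2 * density_kg_m3 * sound_speed_m_s) / 1e4
}

#' Volumetric heat source from acoustic intensity
#'
#' `Q = 2 alpha I`, optionally time-averaged over the protocol's total duty
#' cycle.
#'
#' @param intensity_W_cm2 Intensity field (scalar or array), W/cm^2.
#' @param alpha_Np_m Acoustic absorption coefficient, Np/m.
#' @param protocol Optional [sonication_protocol()]; when given, the source
#'   is scaled by the total duty cycle (time-averaged pulsing).
#' @return Volumetric source, W/m^3.
#' @export
heat_source_from_intensity <- function(intensity_W_cm2, alpha_Np_m,
                                       protocol = NULL) {
  stop_if_not_scalar_positive(alpha_Np_m, "alpha_Np_m")
  duty <- if (is.null(protocol)) 1 else duty_cycles(protocol)$total
  2 * alpha_Np_m * intensity_W_cm2 * 1e4 * duty
}
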