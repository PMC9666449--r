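#' Default electrode montage
#'
#' Eight subdermal needle electrodes: three over frontal cortex and five over
#' occipital cortex, tagged with hemisphere so laterality contrasts
#' (ipsilateral vs contralateral to sonication) can be formed.
#'
#' @return A data.frame with columns `name`, `region` (`"frontal"` /
#'   `"occipital"`) and `side` (`"left"` / `"right"`).
#' @export
default_montage <- function() {
  data.frame(
    name   = c("F1", "F2", "F3", "O1", "O2", "O3", "O4", "O5"),
    region = c(rep("frontal", 3), rep("occipital", 5)),
    side   = c("left", "right", "left", "left", "left", "right", "right", "left"),
    stringsAsFactors = FALSE
  )
}

#' Evoked-response template parameters
#'
#' The visual evoked potential is modelled as two Gaussian-windowed lobes: a
#' negative trough (N70) and a positive peak (P100). Latency defaults sit in
#' the middle of the detection windows used downstream (60-100 ms for N70,
#' 90-130 ms for P100), reflecting the latency shift expected under
#' anesthesia.
#'
#' @param n70_latency_ms N70 trough latency, ms post-stimulus.
#' @param n70_amplitude_uV N70 amplitude, microvolts (negative).
#' @param p100_latency_ms P100 peak latency, ms post-stimulus.
#' @param p100_amplitude_uV P100 amplitude, microvolts (positive).
#' @param width_ms Gaussian SD of each component lobe, ms.
#' @return An object of class `evoked_params`.
#' @export
evoked_params <- function(n70_latency_ms = 80, n70_amplitude_uV = -6,
                          p100_latency_ms = 110, p100_amplitude_uV = 9,
                          width_ms = 10) {
  if (n70_latency_ms < 60 || n70_latency_ms > 100) {
    stop("`n70_latency_ms` must lie in [60, 100] ms", call. = FALSE)
  }
  if (p100_latency_ms < 90 || p100_latency_ms > 130) {
    stop("`p100_latency_ms` must lie in [90, 130] ms", call. = FALSE)
  }
  if (n70_amplitude_uV > 0) stop("`n70_amplitude_uV` must be <= 0", call. = FALSE)
  if (p100_amplitude_uV < 0) stop("`p100_amplitude_uV` must be >= 0", call. = FALSE)
  stop_if_not_scalar_positive(width_ms, "width_ms")
  structure(
    list(
      n70_latency_ms = n70_latency_ms, n70_amplitude_uV = n70_amplitude_uV,
      p100_latency_ms = p100_latency_ms, p100_amplitude_uV = p100_amplitude_uV,
      width_ms = width_ms
    ),
    class = "evoked_params"
  )
}

#' Gamma-burst parameters
#'
#' Stimulus-locked gamma bursts with Gaussian envelopes. With the default
#' `phase = "random-per-trial"` each trial draws a fresh uniform phase so the
#' bursts cancel from the trial average and survive only in non-phase-locked
#' power; `phase = "locked"` makes them phase-locked instead.
#'
#' @param freq_hz Carrier frequency, Hz.
#' @param latencies_ms Envelope centre latencies, ms post-stimulus.
#' @param width_ms Envelope Gaussian SD, ms.
#' @param amplitude_uV Burst amplitude, microvolts.
#' @param phase `"random-per-trial"` or `"locked"`.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(freq_hz = 40, latencies_ms = c(90, 280),
                         width_ms = 25, amplitude_uV = 2,
                         phase = c("random-per-trial", "locked")) {
  phase <- match.arg(phase)
  stop_if_not_scalar_positive(freq_hz, "freq_hz")
  stop_if_not_scalar_positive(width_ms, "width_ms")
  if (amplitude_uV < 0) stop("`amplitude_uV` must be >= 0", call. = FALSE)
  structure(
    list(freq_hz = freq_hz, latencies_ms = latencies_ms, width_ms = width_ms,
         amplitude_uV = amplitude_uV, phase = phase),
    class = "gamma_params"
  )
}

#' Simulation configuration
#'
#' Bundles everything the EEG generator needs: montage, sampling rate, evoked
#' template, background-noise scale, gamma bursts, per-block evoked
#' suppression factors, TUS electromagnetic-artifact model, and blink
#' artifacts. A fixed `seed` makes the generated recording bit-identical
#' across runs.
#'
#' @param seed Integer RNG seed.
#' @param montage Electrode table as from [default_montage()].
#' @param fs_hz Sampling rate, Hz.
#' @param evoked [evoked_params()].
#' @param noise_scale_uV RMS of the 1/f background noise per channel,
#'   microvolts.
#' @param gamma_burst [gamma_params()], or `NULL` for none.
#' @param suppression Named numeric vector of per-block multiplicative
#'   factors in `[0, 1]` applied to the evoked amplitude (1 = no
#'   suppression); blocks not named default to 1.
#' @param tus_artifact_uV Amplitude of the broadband electromagnetic artifact
#'   gated by the 300 ms TUS pulse-train envelope, microvolts.
#' @param tus_artifact_decay_per_cm Exponential decay of the artifact with
#'   transducer distance (per cm).
#' @param tus_distance_cm Transducer distance used for the artifact scaling.
#' @param blink_rate Per-trial probability of a blink artifact.
#' @param blink_amplitude_uV Blink deflection amplitude on frontal channels.
#' @param occipital_gain Per-channel gain applied to the evoked template on
#'   occipital channels (recycled); frontal channels carry no evoked signal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       montage = default_montage(),
                       fs_hz = 1000,
                       evoked = evoked_params(),
                       noise_scale_uV = 5,
                       gamma_burst = gamma_params(),
                       suppression = c(LGN1 = 1, LGN2 = 1),
                       tus_artifact_uV = 4,
                       tus_artifact_decay_per_cm = 0.5,
                       tus_distance_cm = 0,
                       blink_rate = 0.01,
                       blink_amplitude_uV = 300,
                       occipital_gain = 1) {
  stopifnot(is.data.frame(montage),
            all(c("name", "region", "side") %in% names(montage)))
  stop_if_not_scalar_positive(fs_hz, "fs_hz")
  if (any(suppression < 0 | suppression > 1)) {
    stop("`suppression` factors must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(gamma_burst) && fs_hz <= 2 * gamma_burst$freq_hz) {
    stop("`fs_hz` must exceed twice the gamma carrier frequency", call. = FALSE)
  }
  if (noise_scale_uV < 0) stop("`noise_scale_uV` must be >= 0", call. = FALSE)
  structure(
    list(
      seed = as.integer(seed), montage = montage, fs_hz = fs_hz,
      evoked = evoked, noise_scale_uV = noise_scale_uV,
      gamma_burst = gamma_burst, suppression = suppression,
      tus_artifact_uV = tus_artifact_uV,
      tus_artifact_decay_per_cm = tus_artifact_decay_per_cm,
      tus_distance_cm = tus_distance_cm,
      blink_rate = blink_rate, blink_amplitude_uV = blink_amplitude_uV,
      occipital_gain = occipital_gain
    ),
    class = "sim_config"
  )
}
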