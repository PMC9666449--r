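#' Evoked-response template
#'
#' Two Gaussian-windowed lobes: a negative N70 trough and a positive P100
#' peak, sampled on a post-stimulus axis.
#'
#' @param evoked [evoked_params()].
#' @param fs_hz Sampling rate, Hz.
#' @param duration_ms Template length, ms post-stimulus.
#' @return Numeric vector of length `duration_ms / 1000 * fs_hz`, microvolts.
#' @export
evoked_template <- function(evoked, fs_hz = 1000, duration_ms = 500) {
  t_ms <- seq(0, duration_ms - 1000 / fs_hz, by = 1000 / fs_hz)
  evoked$n70_amplitude_uV * exp(-(t_ms - evoked$n70_latency_ms)^2 /
                                  (2 * evoked$width_ms^2)) +
    evoked$p100_amplitude_uV * exp(-(t_ms - evoked$p100_latency_ms)^2 /
                                     (2 * evoked$width_ms^2))
}

# 1/f (pink) noise by spectral shaping of white noise; unit RMS.
pink_noise <- function(n, fs_hz) {
  if (n < 2) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) / n * fs_hz
  f <- pmin(f, fs_hz - f)              # two-sided frequency axis
  amp <- ifelse(f > 0, 1 / sqrt(f), 0) # zero DC
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate a multi-electrode EEG recording
#'
#' Generates the voltage trace implied by an event schedule: a 1/f background
#' on every channel; the evoked template on occipital channels at each light
#' event, scaled by that block's suppression factor; stimulus-locked gamma
#' bursts (random or locked phase per trial); a broadband electromagnetic
#' artifact gated by the 300 ms TUS pulse-train envelope on TUS events,
#' attenuated exponentially with transducer distance; and occasional blink
#' artifacts on frontal channels. Bit-identical for a fixed config seed.
#'
#' @param events An `event_table` from [make_event_table()].
#' @param config A [sim_config()].
#' @param duration_s Recording length; defaults to 2 s past the last event.
#' @return An object of class `raw_eeg`: list with `data` (channels x
#'   samples matrix, microvolts, rownames = channel names), `fs_hz`,
#'   `montage`.
#' @export
simulate_eeg <- function(events, config, duration_s = NULL) {
  stopifnot(inherits(events, "event_table"), inherits(config, "sim_config"))
  fs <- config$fs_hz
  if (is.null(duration_s)) duration_s <- max(events$onset_s) + 2
  if (max(events$onset_s) + 1 > duration_s) {
    stop("events extend past the simulated duration", call. = FALSE)
  }
  n <- round(duration_s * fs)
  mont <- config$montage
  n_ch <- nrow(mont)
  occ <- which(mont$region == "occipital")
  fro <- which(mont$region == "frontal")
  gain <- rep_len(config$occipital_gain, length(occ))

  tmpl <- evoked_template(config$evoked, fs)
  L <- length(tmpl)
  tus_len <- round(0.3 * fs)           # 300 ms pulse-train envelope
  art_amp <- config$tus_artifact_uV *
    exp(-config$tus_artifact_decay_per_cm * config$tus_distance_cm)

  with_rng_seed(config$seed, {
    data <- matrix(0, n_ch, n, dimnames = list(mont$name, NULL))
    for (ch in seq_len(n_ch)) {
      data[ch, ] <- config$noise_scale_uV * pink_noise(n, fs)
    }

    gb <- config$gamma_burst
    if (!is.null(gb)) {
      t_ms <- seq(0, 500 - 1000 / fs, by = 1000 / fs)
      envs <- lapply(gb$latencies_ms, function(lat) {
        gb$amplitude_uV * exp(-(t_ms - lat)^2 / (2 * gb$width_ms^2))
      })
    }

    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      i0 <- round(ev$onset_s * fs) + 1L
      idx <- i0:(i0 + L - 1L)
      if (max(idx) > n) next

      if (ev$light_on) {
        s <- if (ev$block %in% names(config$suppression)) {
          config$suppression[[ev$block]]
        } else 1
        for (k in seq_along(occ)) {
          data[occ[k], idx] <- data[occ[k], idx] + s * gain[k] * tmpl
        }
        if (!is.null(gb) && gb$amplitude_uV > 0) {
          t_s <- (seq_len(L) - 1) / fs
          for (e in envs) {
            phi <- if (gb$phase == "random-per-trial") {
              stats::runif(1, 0, 2 * pi)
            } else 0
            burst <- e * cos(2 * pi * gb$freq_hz * t_s + phi)
            data[occ, idx] <- data[occ, idx] +
              matrix(burst, length(occ), L, byrow = TRUE)
          }
        }
        if (config$blink_rate > 0 && length(fro) > 0 &&
            stats::runif(1) < config$blink_rate) {
          blink <- config$blink_amplitude_uV *
            exp(-((seq_len(L) - 1) / fs * 1000 - 150)^2 / (2 * 50^2))
          data[fro, idx] <- data[fro, idx] +
            matrix(blink, length(fro), L, byrow = TRUE)
        }
      }

      if (ev$tus_on && art_amp > 0) {
        aidx <- i0:(i0 + tus_len - 1L)
        if (max(aidx) <= n) {
          burst <- art_amp * stats::rnorm(tus_len)
          data[, aidx] <- data[, aidx] +
            matrix(burst, n_ch, tus_len, byrow = TRUE)
        }
      }
    }

    structure(
      list(data = data, fs_hz = fs, montage = mont),
      class = "raw_eeg"
    )
  })
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  invisible(x)
}

#' Write / read a raw EEG recording as a delimited text matrix
#'
#' Channels as columns with a header row of channel names; one sample per
#' row. Channel region/side metadata travels in a JSON sidecar
#' (`<path>.json`).
#'
#' @param raw A `raw_eeg`.
#' @param path Output path (tab-separated text).
#' @export
write_eeg_matrix <- function(raw, path) {
  m <- t(raw$data)
  colnames(m) <- raw$montage$name
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = raw$fs_hz, montage = raw$montage),
    paste0(path, ".json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_eeg_matrix
#' @export
read_eeg_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(data = t(m), fs_hz = meta$fs_hz,
         montage = as.data.frame(meta$montage)),
    class = "raw_eeg"
  )
}
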