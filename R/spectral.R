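#' Complex Morlet wavelet family
#'
#' Fifty centre frequencies spanning 2-55 Hz with the cycle count rising
#' from 3 at the lowest to 10 at the highest frequency, trading temporal
#' precision at low frequencies for frequency precision at high ones.
#' Frequencies are linearly spaced by default (`spacing = "log"` available).
#' Each kernel is unit-energy normalized so power is comparable across
#' frequencies.
#'
#' @param fs_hz Sampling rate, Hz.
#' @param f_range Frequency range, Hz.
#' @param n_freqs Number of centre frequencies.
#' @param cycle_range Cycle count at the first and last frequency.
#' @param spacing `"linear"` or `"log"` frequency spacing.
#' @return An object of class `wavelet_family`: `freqs_hz`, `cycles`,
#'   `fs_hz`.
#' @export
build_wavelets <- function(fs_hz, f_range = c(2, 55), n_freqs = 50,
                           cycle_range = c(3, 10),
                           spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (n_freqs < 2) stop("`n_freqs` must be >= 2", call. = FALSE)
  if (f_range[1] <= 0 || f_range[2] <= f_range[1]) {
    stop("invalid frequency range", call. = FALSE)
  }
  if (f_range[2] >= fs_hz / 2) {
    stop("maximum frequency must be below fs/2", call. = FALSE)
  }
  if (cycle_range[1] < 3 || cycle_range[2] > 10 ||
      cycle_range[2] < cycle_range[1]) {
    stop("cycle counts must be non-decreasing within [3, 10]", call. = FALSE)
  }
  freqs <- if (spacing == "linear") {
    seq(f_range[1], f_range[2], length.out = n_freqs)
  } else {
    exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freqs))
  }
  structure(
    list(freqs_hz = freqs,
         cycles = seq(cycle_range[1], cycle_range[2], length.out = n_freqs),
         fs_hz = fs_hz),
    class = "wavelet_family"
  )
}

#' Morlet kernel for one frequency
#'
#' `w(t) = A exp(i 2 pi f t) exp(-t^2 / (2 sigma^2))` with
#' `sigma = cycles / (2 pi f)`, sampled over +/- 3.5 sigma and discretely
#' normalized to unit energy (`sum |w|^2 dt = 1`).
#'
#' @param f_hz Centre frequency, Hz.
#' @param cycles Cycle count.
#' @param fs_hz Sampling rate, Hz.
#' @return Complex vector of odd length.
#' @export
morlet_kernel <- function(f_hz, cycles, fs_hz) {
  sigma <- cycles / (2 * pi * f_hz)
  half <- ceiling(3.5 * sigma * fs_hz)
  t <- (-half:half) / fs_hz
  w <- exp(2i * pi * f_hz * t) * exp(-t^2 / (2 * sigma^2))
  w / sqrt(sum(Mod(w)^2) / fs_hz)
}

# FFT-based wavelet convolution of a trials x time matrix.
# Edge handling: each trial is padded by reflecting one maximal wavelet
# half-support at both ends before convolution; output is sampled on the
# original time axis (optionally decimated).
# Returns trials x freqs x time array of complex coefficients' power.
trial_power_stack <- function(x, family, decim = 1L) {
  if (is.vector(x)) x <- matrix(x, 1)
  n_trials <- nrow(x)
  T <- ncol(x)
  fs <- family$fs_hz
  kernels <- mapply(morlet_kernel, family$freqs_hz, family$cycles,
                    MoreArgs = list(fs_hz = fs), SIMPLIFY = FALSE)
  halves <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  P <- min(max(halves), T - 1L)
  Lmax <- max(lengths(kernels))
  N <- stats::nextn(T + 2L * P + Lmax - 1L, 2)
  Kf <- vapply(seq_along(kernels), function(j) {
    stats::fft(c(kernels[[j]], complex(N - length(kernels[[j]]))))
  }, complex(N))
  t_idx <- seq(1L, T, by = decim)
  out <- array(0, dim = c(n_trials, length(kernels), length(t_idx)))
  for (i in seq_len(n_trials)) {
    xi <- x[i, ]
    xp <- c(rev(xi[seq_len(P)]), xi, rev(xi[(T - P + 1L):T]))
    Xf <- stats::fft(c(xp, numeric(N - length(xp))))
    for (j in seq_along(kernels)) {
      y <- stats::fft(Xf * Kf[, j], inverse = TRUE) / N
      # 'same' alignment: kernel centre at sample halves[j] + 1
      start <- halves[j] + P + 1L
      out[i, j, ] <- Mod(y[start + t_idx - 1L])^2
    }
  }
  out
}

new_spectrogram <- function(power, family, time_ms, kind, units = "raw",
                            baseline_window = NULL, n_trials = NA_integer_) {
  structure(
    list(power = power, freqs_hz = family$freqs_hz, time_ms = time_ms,
         kind = kind, units = units, baseline_window = baseline_window,
         n_trials = n_trials),
    class = "spectrogram"
  )
}

#' Total spectral power
#'
#' Morlet convolution of every trial, squared magnitude, averaged over
#' trials.
#'
#' @param x Trials x time matrix (one channel or a channel average, e.g.
#'   from [channel_matrix()]).
#' @param family A [build_wavelets()] family.
#' @param time_ms Epoch time axis, ms.
#' @param decim Keep every `decim`-th time sample of the output.
#' @return A `spectrogram` of kind `"total"`, raw units (uV^2).
#' @export
total_power <- function(x, family, time_ms, decim = 1L) {
  stack <- trial_power_stack(x, family, decim)
  new_spectrogram(apply(stack, c(2, 3), mean), family,
                  time_ms[seq(1, length(time_ms), by = decim)],
                  kind = "total", n_trials = nrow(x))
}

#' Non-phase-locked (NPL) spectral power
#'
#' The trial-averaged evoked response is subtracted from every trial in the
#' time domain; each residual trial is then decomposed and the spectra
#' averaged. Activity with a reproducible phase across trials cancels in the
#' subtraction, so only induced (trial-varying-phase) power survives.
#'
#' @inheritParams total_power
#' @return A `spectrogram` of kind `"npl"`, raw units.
#' @export
npl_power <- function(x, family, time_ms, decim = 1L) {
  if (is.vector(x) || nrow(x) < 2) {
    stop("NPL power is undefined for fewer than 2 trials", call. = FALSE)
  }
  resid <- sweep(x, 2, colMeans(x))
  stack <- trial_power_stack(resid, family, decim)
  new_spectrogram(apply(stack, c(2, 3), mean), family,
                  time_ms[seq(1, length(time_ms), by = decim)],
                  kind = "npl", n_trials = nrow(x))
}

#' Phase-locked (PL) spectral power
#'
#' Elementwise `total - NPL`. Floating-point subtraction can leave
#' microscopically negative values; they are reported as-is here and clipped
#' at zero by [db_baseline()].
#'
#' @param total,npl `spectrogram`s of kinds `"total"` and `"npl"` on
#'   identical axes.
#' @return A `spectrogram` of kind `"pl"`, raw units.
#' @export
pl_power <- function(total, npl) {
  stopifnot(inherits(total, "spectrogram"), inherits(npl, "spectrogram"))
  if (!isTRUE(all.equal(total$freqs_hz, npl$freqs_hz)) ||
      !isTRUE(all.equal(total$time_ms, npl$time_ms))) {
    stop("total and NPL spectrograms have mismatched axes", call. = FALSE)
  }
  out <- total
  out$power <- total$power - npl$power
  out$kind <- "pl"
  out
}

#' Decibel change relative to the pre-stimulus baseline
#'
#' `10 * log10(power / baseline)` with the baseline taken as the
#' per-frequency mean power over the -150 to 0 ms pre-stimulus window
#' (closed-open, so the t = 0 onset sample is excluded).
#' Negative raw values (possible for PL maps through floating-point
#' subtraction) are clipped at zero first; the clip count is attached as an
#' attribute.
#'
#' @param spec A raw-units `spectrogram`.
#' @param window_ms Baseline window, ms.
#' @return A `spectrogram` in dB units.
#' @export
db_baseline <- function(spec, window_ms = c(-150, 0)) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$units != "raw") stop("spectrogram is already baselined", call. = FALSE)
  idx <- which(spec$time_ms >= window_ms[1] & spec$time_ms < window_ms[2])
  if (length(idx) == 0) stop("baseline window outside the time axis", call. = FALSE)
  p <- spec$power
  n_clip <- sum(p < 0)
  p[p < 0] <- 0
  base <- rowMeans(p[, idx, drop = FALSE])
  if (any(base <= 0)) {
    stop("non-positive baseline power at some frequency", call. = FALSE)
  }
  out <- spec
  out$power <- 10 * log10(p / base)
  out$units <- "dB"
  out$baseline_window <- window_ms
  attr(out, "n_clipped") <- n_clip
  out
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> kind=%s units=%s %d freqs (%.3g-%.3g Hz) x %d times\n",
              x$kind, x$units, length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), length(x$time_ms)))
  invisible(x)
}
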