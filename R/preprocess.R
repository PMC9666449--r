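#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward per channel
#' (`signal::filtfilt`), so component latencies are preserved. The 2-50 Hz
#' default covers the evoked response and the beta/gamma bands analysed
#' downstream while removing DC drift and line-frequency content.
#'
#' @param raw A `raw_eeg`.
#' @param low_hz,high_hz Passband edges, Hz.
#' @param order Butterworth order (of the analogue prototype).
#' @return A filtered `raw_eeg` with identical metadata.
#' @export
eeg_bandpass <- function(raw, low_hz = 2, high_hz = 50, order = 4) {
  stopifnot(inherits(raw, "raw_eeg"))
  fs <- raw$fs_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("need 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- raw
  for (ch in seq_len(nrow(raw$data))) {
    out$data[ch, ] <- signal::filtfilt(bf, raw$data[ch, ])
  }
  out
}

#' Section a recording into stimulus-locked epochs
#'
#' One epoch per event, spanning `pre_ms` before to `post_ms` after stimulus
#' onset as the closed-open window `[-pre_ms, post_ms)`; at 1000 Hz the
#' default 200/800 ms window gives exactly 1000 samples with the sample at
#' t = 0 being the onset sample. Events too close to a record edge are
#' skipped with a warning rather than failing the run.
#'
#' @param raw A `raw_eeg`.
#' @param events An `event_table`.
#' @param pre_ms,post_ms Window extent, ms.
#' @return An object of class `epoched_eeg`: `data` (trials x channels x
#'   time array), `fs_hz`, `time_ms`, `labels` (data.frame `onset_s`,
#'   `block`, `condition`, `light_on`, `tus_on`), `accepted` (logical
#'   rejection mask, `TRUE` = kept), `montage`.
#' @export
eeg_epoch <- function(raw, events, pre_ms = 200, post_ms = 800) {
  stopifnot(inherits(raw, "raw_eeg"), inherits(events, "event_table"))
  fs <- raw$fs_hz
  n <- ncol(raw$data)
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  len <- pre + post

  onset_idx <- round(events$onset_s * fs) + 1L
  ok <- onset_idx - pre >= 1L & onset_idx + post - 1L <= n
  if (any(!ok)) {
    warning(sprintf("skipping %d event(s) too close to the record edge",
                    sum(!ok)), call. = FALSE)
  }
  keep <- which(ok)
  if (length(keep) == 0) stop("no epochable events", call. = FALSE)

  data <- array(NA_real_, dim = c(length(keep), nrow(raw$data), len),
                dimnames = list(NULL, rownames(raw$data), NULL))
  for (j in seq_along(keep)) {
    i0 <- onset_idx[keep[j]]
    data[j, , ] <- raw$data[, (i0 - pre):(i0 + post - 1L)]
  }
  structure(
    list(data = data, fs_hz = fs,
         time_ms = epoch_time_ms(pre_ms, post_ms, fs),
         labels = as.data.frame(events)[keep, , drop = FALSE],
         accepted = rep(TRUE, length(keep)),
         montage = raw$montage),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf(
    "<epoched_eeg> %d trials (%d accepted) x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], sum(x$accepted), dim(x$data)[2], dim(x$data)[3], x$fs_hz))
  invisible(x)
}

#' Flag trials with large voltage deflections
#'
#' A trial is rejected when its absolute voltage exceeds `threshold_uV` on
#' any channel anywhere in the epoch. Voltage data are never modified; only
#' the `accepted` mask changes.
#'
#' @param epochs An `epoched_eeg`.
#' @param threshold_uV Rejection threshold, microvolts.
#' @return The `epoched_eeg` with an updated mask.
#' @export
reject_amplitude_artifacts <- function(epochs, threshold_uV = 100) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  if (!is.numeric(threshold_uV) || length(threshold_uV) != 1L ||
      is.na(threshold_uV) || threshold_uV <= 0) {
    stop("`threshold_uV` must be a single positive number", call. = FALSE)
  }
  peak <- apply(abs(epochs$data), 1, max)
  epochs$accepted <- epochs$accepted & (peak <= threshold_uV)
  epochs
}

#' Equalize trial counts across cells
#'
#' Retains, for each block x condition cell, the chronologically first `n`
#' accepted trials so every cell contributes the same trial count to
#' averages; cells with fewer than `n` accepted trials keep all of them with
#' a warning. With `method = "sample"` a seeded random subsample is taken
#' instead.
#'
#' @param epochs An `epoched_eeg`.
#' @param n Trials retained per cell.
#' @param method `"first"` (default) or `"sample"`.
#' @param seed Seed for `method = "sample"`.
#' @return The `epoched_eeg` with surplus trials marked not accepted.
#' @export
equalize_trials <- function(epochs, n = 250, method = c("first", "sample"),
                            seed = 1L) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  method <- match.arg(method)
  cell <- interaction(epochs$labels$block, epochs$labels$condition, drop = TRUE)
  for (cl in levels(cell)) {
    idx <- which(cell == cl & epochs$accepted)
    if (length(idx) < n) {
      warning(sprintf("cell %s has only %d accepted trials (< %d); keeping all",
                      cl, length(idx), n), call. = FALSE)
      next
    }
    keep <- if (method == "first") idx[seq_len(n)] else {
      with_rng_seed(seed, sort(sample(idx, n)))
    }
    epochs$accepted[setdiff(idx, keep)] <- FALSE
  }
  epochs
}

#' Subset epochs by label
#'
#' @param epochs An `epoched_eeg`.
#' @param block,condition Optional label filters.
#' @param accepted_only Drop rejected trials.
#' @return An `epoched_eeg` containing the matching trials.
#' @export
epoch_subset <- function(epochs, block = NULL, condition = NULL,
                         accepted_only = TRUE) {
  keep <- rep(TRUE, dim(epochs$data)[1])
  if (!is.null(block)) keep <- keep & epochs$labels$block %in% block
  if (!is.null(condition)) keep <- keep & epochs$labels$condition %in% condition
  if (accepted_only) keep <- keep & epochs$accepted
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep, , drop = FALSE]
  out$accepted <- epochs$accepted[keep]
  out
}

#' Extract one channel (or a channel average) as a trials x time matrix
#'
#' @param epochs An `epoched_eeg`.
#' @param channels Channel names or indices; averaged when several.
#' @return A trials x time numeric matrix.
#' @export
channel_matrix <- function(epochs, channels) {
  if (is.character(channels)) {
    channels <- match(channels, epochs$montage$name)
    if (anyNA(channels)) stop("unknown channel name", call. = FALSE)
  }
  x <- epochs$data[, channels, , drop = FALSE]
  if (length(channels) > 1) {
    apply(x, c(1, 3), mean)
  } else {
    matrix(x, dim(x)[1], dim(x)[3])
  }
}
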