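#' Trial-averaged evoked response for one cell
#'
#' Per-channel mean over accepted trials of the requested block x condition
#' cell.
#'
#' @param epochs An `epoched_eeg`.
#' @param block,condition Cell labels (`NULL` = all).
#' @return An object of class `erp`: `voltage` (channels x time matrix,
#'   microvolts), `time_ms`, `n_trials`, `block`, `condition`, `montage`.
#' @export
average_evoked <- function(epochs, block = NULL, condition = NULL) {
  sub <- epoch_subset(epochs, block = block, condition = condition)
  if (dim(sub$data)[1] == 0) {
    stop(sprintf("no accepted trials in cell block=%s condition=%s",
                 paste(block, collapse = "/"),
                 paste(condition, collapse = "/")), call. = FALSE)
  }
  structure(
    list(voltage = apply(sub$data, c(2, 3), mean),
         time_ms = sub$time_ms, n_trials = dim(sub$data)[1],
         block = block, condition = condition, montage = sub$montage),
    class = "erp"
  )
}

#' N70/P100 peak-to-peak quantification
#'
#' For each electrode the N70 amplitude is the minimum voltage in its
#' detection window and the P100 amplitude the maximum in its window (40 ms
#' windows accommodate the latency shift under anesthesia); the peak-to-peak
#' amplitude is their difference. Ties resolve to the earliest latency. The
#' electrode mean is taken after per-electrode quantification.
#'
#' @param erp An `erp`.
#' @param n70_window_ms,p100_window_ms Detection windows, ms.
#' @param electrodes Electrode names to quantify (default: occipital).
#' @return An object of class `vep_measure`: `per_electrode` (data.frame
#'   `electrode`, `n70_uV`, `n70_ms`, `p100_uV`, `p100_ms`, `p2p_uV`),
#'   `mean_p2p_uV`, plus the cell labels.
#' @export
peak_to_peak <- function(erp, n70_window_ms = c(60, 100),
                         p100_window_ms = c(90, 130), electrodes = NULL) {
  stopifnot(inherits(erp, "erp"))
  t <- erp$time_ms
  for (w in list(n70_window_ms, p100_window_ms)) {
    if (w[1] < min(t) || w[2] > max(t)) {
      stop("detection window outside the epoch time range", call. = FALSE)
    }
  }
  if (is.null(electrodes)) {
    electrodes <- erp$montage$name[erp$montage$region == "occipital"]
    if (length(electrodes) == 0) electrodes <- erp$montage$name
  }
  rows <- lapply(electrodes, function(el) {
    ch <- match(el, erp$montage$name)
    v <- erp$voltage[ch, ]
    iw_n <- which(t >= n70_window_ms[1] & t <= n70_window_ms[2])
    iw_p <- which(t >= p100_window_ms[1] & t <= p100_window_ms[2])
    i_n <- iw_n[which.min(v[iw_n])]      # which.min/max take the first tie
    i_p <- iw_p[which.max(v[iw_p])]
    data.frame(electrode = el,
               n70_uV = v[i_n], n70_ms = t[i_n],
               p100_uV = v[i_p], p100_ms = t[i_p],
               p2p_uV = v[i_p] - v[i_n])
  })
  per <- do.call(rbind, rows)
  stopifnot(all(per$n70_ms >= n70_window_ms[1] & per$n70_ms <= n70_window_ms[2]),
            all(per$p100_ms >= p100_window_ms[1] & per$p100_ms <= p100_window_ms[2]))
  structure(
    list(per_electrode = per, mean_p2p_uV = mean(per$p2p_uV),
         block = erp$block, condition = erp$condition,
         n_trials = erp$n_trials),
    class = "vep_measure"
  )
}

#' Normalize per-block peak-to-peak amplitudes to baseline
#'
#' Divides each block's electrode-mean peak-to-peak amplitude by the
#' Baseline block's value for the same recording (average-then-normalize);
#' `per_electrode = TRUE` instead normalizes each electrode by its own
#' baseline before averaging.
#'
#' @param measures Named list of `vep_measure`, one per block.
#' @param baseline_block Name of the baseline entry.
#' @param per_electrode Normalize per electrode before averaging.
#' @return A data.frame: `block`, `p2p_uV`, `p2p_norm`.
#' @export
normalize_to_baseline <- function(measures, baseline_block = "Baseline",
                                  per_electrode = FALSE) {
  if (!baseline_block %in% names(measures)) {
    stop(sprintf("baseline block '%s' missing from `measures`",
                 baseline_block), call. = FALSE)
  }
  base <- measures[[baseline_block]]
  if (base$mean_p2p_uV <= 0) {
    stop("baseline peak-to-peak amplitude must be > 0", call. = FALSE)
  }
  norm_one <- function(m) {
    if (per_electrode) {
      r <- m$per_electrode$p2p_uV / base$per_electrode$p2p_uV
      mean(r)
    } else {
      m$mean_p2p_uV / base$mean_p2p_uV
    }
  }
  data.frame(
    block = names(measures),
    p2p_uV = vapply(measures, function(m) m$mean_p2p_uV, numeric(1)),
    p2p_norm = vapply(measures, norm_one, numeric(1)),
    row.names = NULL
  )
}

#' Laterality index of evoked suppression
#'
#' Percent reduction of the mean peak-to-peak amplitude on occipital
#' electrodes ipsilateral to the sonicated side relative to the
#' contralateral side: `100 * (1 - ipsi / contra)`.
#'
#' @param measure A `vep_measure` with per-electrode values.
#' @param montage Electrode table with `name`, `region`, `side`.
#' @param sonicated_side `"left"` or `"right"`.
#' @return Percent reduction (positive = ipsilateral smaller).
#' @export
laterality_index <- function(measure, montage, sonicated_side) {
  stopifnot(inherits(measure, "vep_measure"))
  sonicated_side <- match.arg(sonicated_side, c("left", "right"))
  per <- merge(measure$per_electrode, montage,
               by.x = "electrode", by.y = "name")
  per <- per[per$region == "occipital", , drop = FALSE]
  ipsi <- per$p2p_uV[per$side == sonicated_side]
  contra <- per$p2p_uV[per$side != sonicated_side]
  if (length(ipsi) == 0 || length(contra) == 0) {
    stop("need at least one occipital electrode on each side", call. = FALSE)
  }
  100 * (1 - mean(ipsi) / mean(contra))
}

#' Display-only moving-average smoother
#'
#' 15-point centred moving average used when plotting evoked traces; never
#' applied before quantification.
#'
#' @param v Numeric vector.
#' @param k Window length (odd).
#' @return Smoothed vector of the same length (edges use shrinking windows).
#' @export
smooth_for_display <- function(v, k = 15) {
  h <- floor(k / 2)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
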