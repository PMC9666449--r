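BLOCK_LABELS <- c("Baseline", "LGN1", "LGN2", "Ctrl1", "Ctrl2", "Ctrl3")
CONDITION_LABELS <- c("no-stim", "light", "tus", "light+tus")

#' Build the block/condition event schedule
#'
#' Reproduces the experimental timeline: a 5-min Baseline block of light-only
#' stimulation, then 20-min sonication blocks each split into `n_sections`
#' one-minute sections containing four 15-s conditions (no-stim, light-only,
#' TUS-only, light+TUS). Stimulus repetition is 1 Hz within every condition,
#' so each 15-s condition holds 15 events and each 20-min block holds
#' 20 x 15 = 300 light-only events.
#'
#' Every 1-Hz event is emitted as a row, including the no-stim condition
#' (with both flags off) so that stimulus-free epochs are addressable.
#'
#' @param blocks Character vector of block labels, a subset of
#'   `c("Baseline", "LGN1", "LGN2", "Ctrl1", "Ctrl2", "Ctrl3")`.
#' @param n_sections Sections per sonication block (each 1 min); 20 gives
#'   the full 20-min block.
#' @param baseline_min Duration of the Baseline block in minutes.
#' @param gap_s Fixed gap between blocks, seconds.
#' @param t0_s Start time of the first block, seconds (kept > 0 so the very
#'   first stimulus has pre-stimulus history).
#' @return A data.frame of class `event_table` with columns `onset_s`,
#'   `block`, `condition`, `light_on`, `tus_on`.
#' @export
make_event_table <- function(blocks, n_sections = 20, baseline_min = 5,
                             gap_s = 30, t0_s = 2) {
  if (length(blocks) == 0) stop("`blocks` must be non-empty", call. = FALSE)
  unknown <- setdiff(blocks, BLOCK_LABELS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown block label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  stop_if_not_scalar_positive(n_sections, "n_sections")

  t <- t0_s
  rows <- list()
  for (b in blocks) {
    if (b == "Baseline") {
      # continuous light-only stimulation at 1 Hz
      n <- baseline_min * 60
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = t + seq_len(n) - 1,
        block = b, condition = "light",
        light_on = TRUE, tus_on = FALSE,
        stringsAsFactors = FALSE
      )
      t <- t + n + gap_s
    } else {
      for (s in seq_len(n_sections) - 1L) {
        for (ci in seq_along(CONDITION_LABELS)) {
          cond <- CONDITION_LABELS[ci]
          onset <- t + s * 60 + (ci - 1L) * 15 + 0:14
          rows[[length(rows) + 1L]] <- data.frame(
            onset_s = onset,
            block = b, condition = cond,
            light_on = cond %in% c("light", "light+tus"),
            tus_on = cond %in% c("tus", "light+tus"),
            stringsAsFactors = FALSE
          )
        }
      }
      t <- t + n_sections * 60 + gap_s
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(diff(out$onset_s) > 0))
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write / read an event table as TSV
#'
#' Columns: `onset_s`, `block`, `condition`, `light_on`, `tus_on`.
#' @param events An `event_table`.
#' @param path File path.
#' @return `read_event_table` returns an `event_table`.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$light_on <- as.logical(out$light_on)
  out$tus_on <- as.logical(out$tus_on)
  class(out) <- c("event_table", "data.frame")
  out
}
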