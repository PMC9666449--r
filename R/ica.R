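# Symmetric FastICA (tanh contrast) on whitened data. Deterministic given
# the seed used for the random orthogonal initialization.
fastica_symm <- function(Z, seed = 1L, max_iter = 200, tol = 1e-6) {
  k <- nrow(Z)
  W <- with_rng_seed(seed, {
    M <- matrix(stats::rnorm(k * k), k, k)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                       k, k) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  n <- ncol(Z)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / n - diag(Gp, k, k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Blind source separation of epoched EEG
#'
#' Independence-maximizing decomposition (FastICA, tanh contrast) of the
#' accepted trials, concatenated in time. Intended for TUS-containing
#' conditions, where the electromagnetic transducer artifact mixes into all
#' channels; light-only conditions are analysed without component cleaning.
#'
#' @param epochs An `epoched_eeg` with at least 2 channels.
#' @param n_components Number of components (default = channel count).
#' @param seed Seed for the (random) unmixing initialization.
#' @return An object of class `component_decomposition`: `mixing`
#'   (channels x components), `unmixing` (components x channels), `sources`
#'   (components x concatenated samples), `center` (channel means),
#'   `scores` (filled by [score_and_flag_components()]), `flagged`.
#' @export
decompose_components <- function(epochs, n_components = NULL, seed = 1L) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  n_ch <- dim(epochs$data)[2]
  if (n_ch < 2) stop("need >= 2 channels for component decomposition",
                     call. = FALSE)
  keep <- which(epochs$accepted)
  if (length(keep) < 2) stop("need >= 2 accepted trials", call. = FALSE)
  n_t <- dim(epochs$data)[3]
  # channels x (trials * time), trial-concatenated
  X <- matrix(aperm(epochs$data[keep, , , drop = FALSE], c(2, 3, 1)),
              n_ch, length(keep) * n_t)
  center <- rowMeans(X)
  Xc <- X - center
  C <- (Xc %*% t(Xc)) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  k <- if (is.null(n_components)) n_ch else min(n_components, n_ch)
  if (any(e$values[seq_len(k)] < 1e-12 * e$values[1])) {
    dep <- qr(t(Xc), tol = 1e-7)
    bad <- epochs$montage$name[setdiff(seq_len(n_ch),
                                       dep$pivot[seq_len(dep$rank)])]
    stop(sprintf("rank-deficient data; dependent channel(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  K <- diag(1 / sqrt(e$values[seq_len(k)]), k, k) %*%
    t(e$vectors[, seq_len(k), drop = FALSE])
  Z <- K %*% Xc
  W <- fastica_symm(Z, seed = seed)
  unmixing <- W %*% K                       # components x channels
  sources <- unmixing %*% Xc                # components x samples
  mixing <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k) %*% t(W)  # channels x components
  structure(
    list(mixing = mixing, unmixing = unmixing, sources = sources,
         center = center, n_trials = length(keep), n_time = n_t,
         trial_index = keep, fs_hz = epochs$fs_hz,
         scores = NULL, flagged = rep(FALSE, k)),
    class = "component_decomposition"
  )
}

# mean power spectral density of a component over trial segments
component_psd <- function(src, n_trials, n_time, fs) {
  seg <- matrix(src, n_time, n_trials)
  P <- abs(stats::mvfft(seg))^2
  psd <- rowMeans(P)
  freq <- (seq_len(n_time) - 1) / n_time * fs
  list(freq = freq[seq_len(floor(n_time / 2))],
       psd = psd[seq_len(floor(n_time / 2))])
}

#' Score components and flag artifacts
#'
#' Per component three numeric criteria replace the supervised inspection
#' used in practice: (a) the fraction of 2-50 Hz band power falling in the
#' 20-40 Hz muscle/artifact band; (b) a spatial-concentration index
#' (max |mixing weight| / sum |mixing weights|), standing in for the visual
#' topographic-map criterion; and (c) the coefficient of variation of
#' per-trial band power over time (spectral-fluctuation index). A component
#' exceeding any threshold is flagged unless its trial-averaged time course
#' resembles the grand-average evoked response (|r| above the protection
#' threshold), in which case it is never removed.
#'
#' @param decomp A `component_decomposition`.
#' @param epochs The `epoched_eeg` it was fitted to.
#' @param band_ratio_max Threshold on (a), in (0, 1).
#' @param concentration_max Threshold on (b), in (0, 1).
#' @param cv_max Threshold on (c), > 0.
#' @param erp_protect_r Protection threshold on |ERP correlation|, in (0, 1).
#' @return The decomposition with `scores` (data.frame) and `flagged` set.
#' @export
score_and_flag_components <- function(decomp, epochs,
                                      band_ratio_max = 0.5,
                                      concentration_max = 0.8,
                                      cv_max = 1.0,
                                      erp_protect_r = 0.6) {
  stopifnot(inherits(decomp, "component_decomposition"))
  for (v in c(band_ratio_max, concentration_max, erp_protect_r)) {
    if (v <= 0 || v >= 1) {
      stop("fractional thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  stop_if_not_scalar_positive(cv_max, "cv_max")

  fs <- decomp$fs_hz
  k <- nrow(decomp$sources)
  nt <- decomp$n_time

  # grand-average evoked response: channel mean over accepted trials
  ga <- colMeans(apply(epochs$data[decomp$trial_index, , , drop = FALSE],
                       c(1, 3), mean))

  band_ratio <- cv <- erp_sim <- conc <- numeric(k)
  for (j in seq_len(k)) {
    src <- decomp$sources[j, ]
    ps <- component_psd(src, decomp$n_trials, nt, fs)
    in_band <- ps$freq >= 20 & ps$freq <= 40
    total <- ps$freq >= 2 & ps$freq <= 50
    band_ratio[j] <- sum(ps$psd[in_band]) / sum(ps$psd[total])
    seg <- matrix(src, nt, decomp$n_trials)
    pow <- colMeans(seg^2)
    cv[j] <- stats::sd(pow) / mean(pow)
    avg <- rowMeans(seg)
    erp_sim[j] <- abs(stats::cor(avg, ga))
    w <- abs(decomp$mixing[, j])
    conc[j] <- max(w) / sum(w)
  }
  flagged <- (band_ratio > band_ratio_max | cv > cv_max |
                conc > concentration_max) & erp_sim < erp_protect_r
  decomp$scores <- data.frame(
    component = seq_len(k), band_ratio_20_40 = band_ratio,
    spectral_cv = cv, concentration = conc, erp_similarity = erp_sim,
    flagged = flagged
  )
  decomp$flagged <- flagged
  decomp
}

#' Reconstruct epochs with flagged components removed
#'
#' Projects each trial onto the component basis, zeroes flagged components,
#' and back-projects. With no component flagged this is the identity to
#' numerical tolerance.
#'
#' @param epochs The `epoched_eeg`.
#' @param decomp A scored `component_decomposition`.
#' @return A cleaned `epoched_eeg`.
#' @export
remove_components <- function(epochs, decomp) {
  stopifnot(inherits(epochs, "epoched_eeg"),
            inherits(decomp, "component_decomposition"))
  if (all(decomp$flagged)) {
    stop("all components flagged; refusing to return empty data",
         call. = FALSE)
  }
  if (!any(decomp$flagged)) return(epochs)
  P <- decomp$mixing[, decomp$flagged, drop = FALSE] %*%
    decomp$unmixing[decomp$flagged, , drop = FALSE]
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    x <- epochs$data[i, , ]
    out$data[i, , ] <- x - P %*% (x - decomp$center)
  }
  out
}
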