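# dB map of a mean power vector (freqs x time flattened), per-frequency
# baseline over the given column indices.
db_of_mean <- function(p, n_freq, base_cols) {
  dim(p) <- c(n_freq, length(p) / n_freq)
  p[p < 0] <- 0
  base <- rowMeans(p[, base_cols, drop = FALSE])
  10 * log10(sweep(p, 1, base, "/"))
}

#' Permutation difference-map statistics on spectrograms
#'
#' Observed map: dB spectrogram of condition A minus condition B (each
#' baselined to its own pre-stimulus window). The null is built by shuffling
#' trial-condition labels `n_perm` times and recomputing the difference;
#' the two-sided pixelwise p-value uses the add-one convention
#' `p = (1 + #\{|null| >= |obs|\}) / (n_perm + 1)`. No multiple-comparison
#' correction is applied. The permutation stream is attached to a canonical
#' ordering of the pooled trials, so exchanging A and B negates the
#' difference map and leaves the p-map unchanged.
#'
#' @param trials_a,trials_b Trials x time matrices for the two conditions.
#' @param family A [build_wavelets()] family.
#' @param time_ms Epoch time axis, ms.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level for the mask.
#' @param seed RNG seed (permutations are deterministic given it).
#' @param baseline_ms dB baseline window.
#' @param decim Time-axis decimation of the maps.
#' @param kind `"total"` or `"npl"`: decompose raw trials or their
#'   ERP-subtracted residuals (ERP computed per condition).
#' @return An object of class `diff_map_result`: `diff` (dB, freqs x time),
#'   `p`, `mask` (p < alpha), `freqs_hz`, `time_ms`, `alpha`, `n_perm`,
#'   `seed`.
#' @export
permutation_diff_map <- function(trials_a, trials_b, family, time_ms,
                                 n_perm = 1000, alpha = 0.05, seed = 1L,
                                 baseline_ms = c(-150, 0), decim = 1L,
                                 kind = c("total", "npl")) {
  kind <- match.arg(kind)
  if (nrow(trials_a) < 2 || nrow(trials_b) < 2) {
    stop("need >= 2 trials per condition", call. = FALSE)
  }
  if (n_perm < 100) {
    stop("`n_perm` must be >= 100 for a stable tail", call. = FALSE)
  }
  if (kind == "npl") {
    trials_a <- sweep(trials_a, 2, colMeans(trials_a))
    trials_b <- sweep(trials_b, 2, colMeans(trials_b))
  }
  na <- nrow(trials_a)
  nb <- nrow(trials_b)
  n <- na + nb
  stack <- trial_power_stack(rbind(trials_a, trials_b), family, decim)
  n_freq <- dim(stack)[2]
  t_out <- time_ms[seq(1, length(time_ms), by = decim)]
  base_cols <- which(t_out >= baseline_ms[1] & t_out < baseline_ms[2])
  if (length(base_cols) == 0) {
    stop("baseline window outside the time axis", call. = FALSE)
  }
  M <- n_freq * dim(stack)[3]
  P <- matrix(stack, n, M)            # trials x (freq*time)

  mean_a <- colMeans(P[seq_len(na), , drop = FALSE])
  mean_b <- colMeans(P[na + seq_len(nb), , drop = FALSE])
  obs <- db_of_mean(mean_a, n_freq, base_cols) -
    db_of_mean(mean_b, n_freq, base_cols)

  # canonical pooled order: invariant to the A/B argument order
  key <- P %*% rep(1, M)
  ord <- order(key, P[, 1], P[, min(2, M)])
  Pc <- P[ord, , drop = FALSE]
  tot <- colSums(Pc)

  W <- with_rng_seed(seed, {
    w <- matrix(0, n, n_perm)
    for (k in seq_len(n_perm)) w[sample(n, na), k] <- 1
    w
  })
  SA <- crossprod(Pc, W)              # M x n_perm sums of permuted "A"
  exceed <- matrix(0L, n_freq, M / n_freq)
  absobs <- abs(obs)
  for (k in seq_len(n_perm)) {
    d <- db_of_mean(SA[, k] / na, n_freq, base_cols) -
      db_of_mean((tot - SA[, k]) / nb, n_freq, base_cols)
    exceed <- exceed + (abs(d) >= absobs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  structure(
    list(diff = obs, p = p, mask = p < alpha,
         freqs_hz = family$freqs_hz, time_ms = t_out,
         alpha = alpha, n_perm = n_perm, seed = seed, kind = kind,
         n_trials = c(a = na, b = nb)),
    class = "diff_map_result"
  )
}

# one- or two-sample t statistic with degenerate (zero-variance) cases
# resolved by convention: t = 0 when the effect is exactly 0, +/-Inf
# otherwise, so one-tailed p reaches 0.5 / the bound.
t_stat_p <- function(x, y = NULL, paired = FALSE, mu = 0,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (paired) {
    stopifnot(length(x) == length(y))
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2) stop("need n >= 2", call. = FALSE)
    se <- stats::sd(x) / sqrt(n)
    eff <- mean(x) - mu
    df <- n - 1
    t <- if (se == 0) {
      if (eff == 0) 0 else sign(eff) * Inf
    } else eff / se
  } else {
    if (length(x) < 2 || length(y) < 2) {
      stop("need n >= 2 per group", call. = FALSE)
    }
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    eff <- mean(x) - mean(y) - mu
    if (vx + vy == 0) {
      t <- if (eff == 0) 0 else sign(eff) * Inf
      df <- length(x) + length(y) - 2
    } else {
      t <- eff / sqrt(vx + vy)
      df <- (vx + vy)^2 /
        (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))   # Welch
    }
  }
  p <- switch(alternative,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p)
}

#' The study's planned t-test comparisons
#'
#' Three designs over a tidy table of normalized peak-to-peak amplitudes
#' (columns `experiment`, `group`, `block`, `p2p_norm`, with groups
#' `"LGN-TUS"` and `"ActiveSham"`), all one-tailed in the direction of
#' suppression:
#' \describe{
#'   \item{`baseline_vs_lgn_paired`}{Baseline vs the LGN-sonication block
#'     within LGN-TUS experiments, paired by experiment (baseline >
#'     sonication).}
#'   \item{`lgn_vs_sham_unpaired`}{LGN-block values in the LGN-TUS group vs
#'     the corresponding block in the sham group (LGN < sham; Welch).}
#'   \item{`laterality_one_sample`}{One-sample test of laterality percents
#'     (in `p2p_norm`) against 0 (reduction > 0).}
#' }
#'
#' @param vep_table Tidy data.frame as above.
#' @param design One of the three designs.
#' @param lgn_block,sham_block Block labels entering the comparison.
#' @return A one-row data.frame: `design`, `t`, `df`, `p`, `n`.
#' @export
vep_t_tests <- function(vep_table,
                        design = c("baseline_vs_lgn_paired",
                                   "lgn_vs_sham_unpaired",
                                   "laterality_one_sample"),
                        lgn_block = "LGN1", sham_block = lgn_block) {
  design <- match.arg(design)
  res <- switch(
    design,
    baseline_vs_lgn_paired = {
      d <- vep_table[vep_table$group == "LGN-TUS", ]
      wide <- merge(d[d$block == "Baseline", c("experiment", "p2p_norm")],
                    d[d$block == lgn_block, c("experiment", "p2p_norm")],
                    by = "experiment", suffixes = c("_base", "_lgn"))
      r <- t_stat_p(wide$p2p_norm_base, wide$p2p_norm_lgn, paired = TRUE,
                    alternative = "greater")
      c(r, n = nrow(wide))
    },
    lgn_vs_sham_unpaired = {
      x <- vep_table$p2p_norm[vep_table$group == "LGN-TUS" &
                                vep_table$block == lgn_block]
      y <- vep_table$p2p_norm[vep_table$group == "ActiveSham" &
                                vep_table$block == sham_block]
      r <- t_stat_p(x, y, alternative = "less")
      c(r, n = length(x) + length(y))
    },
    laterality_one_sample = {
      x <- vep_table$p2p_norm
      r <- t_stat_p(x, mu = 0, alternative = "greater")
      c(r, n = length(x))
    }
  )
  data.frame(design = design, t = res$t, df = res$df, p = res$p, n = res$n)
}

#' Displacement / suppression dose-response correlation
#'
#' Correlates per-experiment maximum MR-ARFI displacement with the
#' baseline-normalized evoked amplitude during sonication. Under
#' suppression, larger displacement implies a smaller normalized amplitude,
#' so the expected correlation is negative. Both Pearson's r and Spearman's
#' rho are reported.
#'
#' @param displacement_um Maximum displacement per experiment, micrometres.
#' @param p2p_norm Normalized peak-to-peak amplitude per experiment.
#' @return A data.frame: `method`, `estimate`, `p`, `n`.
#' @export
dose_response <- function(displacement_um, p2p_norm) {
  stopifnot(length(displacement_um) == length(p2p_norm))
  if (length(displacement_um) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (any(!is.finite(displacement_um)) || any(!is.finite(p2p_norm))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(displacement_um) == 0 || stats::sd(p2p_norm) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  pe <- stats::cor.test(displacement_um, p2p_norm, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(displacement_um, p2p_norm, method = "spearman")
  )
  data.frame(
    method = c("pearson", "spearman"),
    estimate = c(unname(pe$estimate), unname(sp$estimate)),
    p = c(pe$p.value, sp$p.value),
    n = length(displacement_um)
  )
}
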