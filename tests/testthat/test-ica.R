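# two-source mixture with ground truth for recovery tests
mixture_epochs <- function(n_trials = 20, n_time = 1000, seed = 4) {
  tusvep:::with_rng_seed(seed, {
    n <- n_trials * n_time
    s1 <- sin(2 * pi * 7 * (seq_len(n)) / 1000)
    s2 <- sign(sin(2 * pi * 0.9 * seq_len(n) / 1000)) * runif(n)
    A <- matrix(c(1, 0.4, 0.3, 1), 2, 2)
    X <- A %*% rbind(s1, s2)
    data <- array(NA_real_, c(n_trials, 2, n_time))
    for (i in seq_len(n_trials)) {
      data[i, , ] <- X[, ((i - 1) * n_time + 1):(i * n_time)]
    }
    list(epochs = make_epochs(data, conditions = "tus",
                              montage = default_montage()[4:5, ]),
         s1 = s1, s2 = s2, X = X)
  })
}

test_that("independent sources are recovered from a two-channel mixture", {
  mx <- mixture_epochs()
  dec <- decompose_components(mx$epochs, seed = 2)
  S <- dec$sources
  r1 <- max(abs(cor(S[1, ], mx$s1)), abs(cor(S[2, ], mx$s1)))
  r2 <- max(abs(cor(S[1, ], mx$s2)), abs(cor(S[2, ], mx$s2)))
  expect_gt(r1, 0.95)
  expect_gt(r2, 0.95)
})

test_that("mixing %*% sources reconstructs the input and the seed fixes the fit", {
  mx <- mixture_epochs()
  dec <- decompose_components(mx$epochs, seed = 2)
  rec <- dec$center + dec$mixing %*% dec$sources
  expect_lt(max(abs(rec - mx$X)) / max(abs(mx$X)), 1e-6)
  dec2 <- decompose_components(mx$epochs, seed = 2)
  expect_identical(dec$sources, dec2$sources)
})

test_that("degenerate inputs are refused", {
  one_ch <- make_epochs(array(rnorm(10 * 100), c(10, 1, 100)),
                        montage = default_montage()[1, , drop = FALSE])
  expect_error(decompose_components(one_ch), ">= 2 channels")

  # duplicated channel -> rank deficient, named in the error
  base <- matrix(rnorm(5 * 100), 5, 100)
  data <- array(NA_real_, c(5, 2, 100))
  for (i in 1:5) data[i, , ] <- rbind(base[i, ], base[i, ])
  dup <- make_epochs(data, montage = default_montage()[4:5, ])
  expect_error(decompose_components(dup), "rank-deficient")
})

# three-source scene: evoked component, ongoing alpha, 30 Hz muscle artifact
scored_scene <- function(artifact_freq = 30, seed = 6) {
  n_trials <- 30
  n_time <- 1000
  t_ms <- seq(-200, 799)
  tusvep:::with_rng_seed(seed, {
    erp <- evoked_template(evoked_params(), 1000)
    s_erp <- as.vector(replicate(n_trials, {
      v <- numeric(n_time)
      v[t_ms >= 0 & t_ms < 500] <- erp
      v + 0.05 * rnorm(n_time)
    }))
    s_alpha <- sin(2 * pi * 9 * seq_len(n_trials * n_time) / 1000) +
      0.05 * rnorm(n_trials * n_time)
    # artifact bursts only in some trials -> large spectral fluctuation
    s_art <- as.vector(vapply(seq_len(n_trials), function(i) {
      amp <- if (i %% 3 == 0) 3 else 0
      amp * sin(2 * pi * artifact_freq * seq_len(n_time) / 1000 +
                  runif(1, 0, 2 * pi)) + 0.05 * rnorm(n_time)
    }, numeric(n_time)))
    A <- matrix(c(1.0, 0.8, 0.6,
                  0.5, 1.0, 0.7,
                  0.9, 0.1, 0.05), 3, 3)
    X <- A %*% rbind(s_erp, s_alpha, s_art)
    data <- array(NA_real_, c(n_trials, 3, n_time))
    for (i in seq_len(n_trials)) {
      data[i, , ] <- X[, ((i - 1) * n_time + 1):(i * n_time)]
    }
    make_epochs(data, conditions = "light+tus",
                montage = default_montage()[c(4, 5, 6), ])
  })
}

test_that("scoring flags the 20-40 Hz artifact component and protects the evoked one", {
  ep <- scored_scene()
  dec <- decompose_components(ep, seed = 3)
  dec <- score_and_flag_components(dec, ep)
  sc <- dec$scores
  # the component most correlated with the grand-average ERP is protected
  erp_comp <- which.max(sc$erp_similarity)
  expect_gt(sc$erp_similarity[erp_comp], 0.6)
  expect_false(sc$flagged[erp_comp])
  # exactly one component (the 30 Hz burst source) is flagged
  expect_equal(sum(sc$flagged), 1)
  flagged <- which(sc$flagged)
  expect_gt(sc$band_ratio_20_40[flagged], 0.5)
})

test_that("removing the flagged component suppresses artifact power >= 10-fold", {
  ep <- scored_scene()
  dec <- decompose_components(ep, seed = 3)
  dec <- score_and_flag_components(dec, ep)
  clean <- remove_components(ep, dec)
  # 25-35 Hz band power across channels, before vs after
  band_power <- function(e) {
    x <- e$data[, 1, ]
    ps <- abs(stats::mvfft(t(x)))^2
    f <- (seq_len(ncol(x)) - 1) / ncol(x) * 1000
    mean(ps[f >= 25 & f <= 35, ])
  }
  expect_gt(band_power(ep) / band_power(clean), 10)
})

test_that("component removal is identity with no flags and refuses to drop everything", {
  ep <- scored_scene()
  dec <- decompose_components(ep, seed = 3)
  dec$flagged <- rep(FALSE, length(dec$flagged))
  expect_identical(remove_components(ep, dec), ep)
  dec$flagged <- rep(TRUE, length(dec$flagged))
  expect_error(remove_components(ep, dec), "all components")
})

test_that("score thresholds are validated", {
  ep <- scored_scene()
  dec <- decompose_components(ep, seed = 3)
  expect_error(score_and_flag_components(dec, ep, band_ratio_max = 1.5),
               "\\(0, 1\\)")
})

test_that("a pure 20-40 Hz band oscillation scores a band ratio near 1 and is flagged", {
  # evoked source + random-phase 30 Hz source: the grand average is the
  # evoked response, so the protection rule leaves the oscillation exposed
  n_trials <- 30
  n_time <- 1000
  t_ms <- seq(-200, 799)
  erp <- evoked_template(evoked_params(), 1000)
  tusvep:::with_rng_seed(8, {
    s_erp <- as.vector(replicate(n_trials, {
      v <- numeric(n_time)
      v[t_ms >= 0 & t_ms < 500] <- erp
      v + 0.05 * rnorm(n_time)
    }))
    s_osc <- as.vector(vapply(seq_len(n_trials), function(i) {
      3 * sin(2 * pi * 30 * seq_len(n_time) / 1000 + runif(1, 0, 2 * pi)) +
        0.05 * rnorm(n_time)
    }, numeric(n_time)))
  })
  X <- matrix(c(1, 0.5, 0.2, 1), 2, 2) %*% rbind(s_erp, s_osc)
  data <- array(NA_real_, c(n_trials, 2, n_time))
  for (i in seq_len(n_trials)) {
    data[i, , ] <- X[, ((i - 1) * n_time + 1):(i * n_time)]
  }
  ep <- make_epochs(data, conditions = "tus",
                    montage = default_montage()[4:5, ])
  dec <- decompose_components(ep, seed = 1)
  dec <- score_and_flag_components(dec, ep)
  osc_comp <- which.max(dec$scores$band_ratio_20_40)
  expect_gt(dec$scores$band_ratio_20_40[osc_comp], 0.95)
  expect_true(dec$scores$flagged[osc_comp])
})
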