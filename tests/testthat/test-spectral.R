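test_that("the default family spans 2-55 Hz in 50 steps with 3-10 cycles", {
  fam <- build_wavelets(1000)
  expect_length(fam$freqs_hz, 50)
  expect_equal(fam$freqs_hz[1], 2)
  expect_equal(fam$freqs_hz[50], 55)
  expect_equal(fam$cycles[1], 3)
  expect_equal(fam$cycles[50], 10)
  expect_true(all(diff(fam$freqs_hz) > 0))
  expect_error(build_wavelets(1000, n_freqs = 1), ">= 2")
  expect_error(build_wavelets(100, f_range = c(2, 55)), "fs/2")
  expect_error(build_wavelets(1000, cycle_range = c(1, 10)), "cycle")
})

test_that("kernels have temporal SD cycles/(2 pi f) and unit energy", {
  fs <- 1000
  for (p in list(c(5, 3), c(20, 6), c(55, 10))) {
    w <- morlet_kernel(p[1], p[2], fs)
    t <- (seq_along(w) - (length(w) + 1) / 2) / fs
    g <- Mod(w)^2
    sd_t <- sqrt(sum(t^2 * g) / sum(g))
    # |w|^2 is Gaussian with SD sigma/sqrt(2)
    expect_equal(sd_t, p[2] / (2 * pi * p[1]) / sqrt(2), tolerance = 1e-3)
    expect_equal(sum(Mod(w)^2) / fs, 1, tolerance = 1e-6)
  }
})

test_that("total power peaks at the bin nearest a pure tone and scales quadratically", {
  fam <- build_wavelets(1000)
  tm <- seq(-200, 799)
  x <- matrix(rep(sin(2 * pi * 10 * tm / 1000), 4), 4, 1000, byrow = TRUE)
  tot <- total_power(x, fam, tm)
  mid <- 300:700
  peak_bin <- which.max(rowMeans(tot$power[, mid]))
  nearest <- which.min(abs(fam$freqs_hz - 10))
  expect_lte(abs(peak_bin - nearest), 1)

  expect_equal(max(total_power(matrix(0, 2, 1000), fam, tm)$power), 0)

  tot2 <- total_power(2 * x, fam, tm)
  expect_equal(tot2$power, 4 * tot$power)
})

test_that("NPL power vanishes for identical trials and ignores common waveforms", {
  fam <- build_wavelets(1000, n_freqs = 10)
  tm <- seq(-200, 799)
  x <- matrix(rep(sin(2 * pi * 8 * tm / 1000), 5), 5, 1000, byrow = TRUE)
  npl <- npl_power(x, fam, tm)
  tot <- total_power(x, fam, tm)
  expect_lt(max(npl$power) / max(tot$power), 1e-10)

  y <- pink_trials(5, seed = 3)
  common <- 10 * cos(2 * pi * 5 * tm / 1000)
  npl_a <- npl_power(y, fam, tm)
  npl_b <- npl_power(sweep(y, 2, common, "+"), fam, tm)
  expect_equal(npl_a$power, npl_b$power, tolerance = 1e-10)

  expect_error(npl_power(y[1, , drop = FALSE], fam, tm), "2 trials")
})

test_that("PL + NPL reconstructs total exactly and axis mismatches are refused", {
  fam <- build_wavelets(1000, n_freqs = 10)
  tm <- seq(-200, 799)
  x <- pink_trials(6, seed = 9)
  tot <- total_power(x, fam, tm)
  npl <- npl_power(x, fam, tm)
  pl <- pl_power(tot, npl)
  err <- abs((pl$power + npl$power) - tot$power)
  expect_lt(max(err / pmax(tot$power, .Machine$double.xmin)),
            4 * .Machine$double.eps)
  expect_equal(pl$kind, "pl")

  fam2 <- build_wavelets(1000, n_freqs = 8)
  npl2 <- npl_power(x, fam2, tm)
  expect_error(pl_power(tot, npl2), "mismatched axes")
})

test_that("phase-locked oscillations land in PL, random-phase ones in NPL", {
  fam <- build_wavelets(1000, n_freqs = 25)
  tm <- seq(-200, 799)
  env <- exp(-(tm - 300)^2 / (2 * 40^2))
  mk <- function(locked, n = 40) {
    tusvep:::with_rng_seed(5, {
      t(vapply(seq_len(n), function(i) {
        phi <- if (locked) 0 else runif(1, 0, 2 * pi)
        env * cos(2 * pi * 40 * tm / 1000 + phi) + 0.1 * rnorm(1000)
      }, numeric(1000)))
    })
  }
  i40 <- which.min(abs(fam$freqs_hz - 40))
  t300 <- which.min(abs(tm - 300))
  at <- function(s) s$power[i40, t300]

  xr <- mk(locked = FALSE)
  tot_r <- total_power(xr, fam, tm)
  npl_r <- npl_power(xr, fam, tm)
  pl_r <- pl_power(tot_r, npl_r)
  expect_gt(at(npl_r) / max(at(pl_r), 1e-12), 10)

  xl <- mk(locked = TRUE)
  tot_l <- total_power(xl, fam, tm)
  npl_l <- npl_power(xl, fam, tm)
  pl_l <- pl_power(tot_l, npl_l)
  expect_gt(at(pl_l) / at(npl_l), 10)
})

test_that("PL power of random-phase oscillations decreases with trial count", {
  fam <- build_wavelets(1000, n_freqs = 5, f_range = c(20, 50))
  tm <- seq(-200, 799)
  i40 <- which.min(abs(fam$freqs_hz - 40))
  t300 <- which.min(abs(tm - 300))
  pl_at <- function(n, seed) {
    x <- tusvep:::with_rng_seed(seed, {
      t(vapply(seq_len(n), function(i) {
        cos(2 * pi * 40 * tm / 1000 + runif(1, 0, 2 * pi))
      }, numeric(1000)))
    })
    tot <- total_power(x, fam, tm)
    pl <- pl_power(tot, npl_power(x, fam, tm))
    pl$power[i40, t300]
  }
  v <- c(pl_at(50, 1), pl_at(200, 2), pl_at(800, 3))
  expect_true(all(diff(v) < 0))
  expect_lt(v[3] / v[1], 0.25)   # ~1/n scaling
})

test_that("dB baselining maps ratios to decibels and is scale invariant", {
  fam <- build_wavelets(1000, n_freqs = 3)
  tm <- seq(-200, 799)
  spec <- tusvep:::new_spectrogram(matrix(5, 3, 1000), fam, tm, "total")
  db <- db_baseline(spec)
  expect_equal(max(abs(db$power)), 0)

  p <- matrix(2, 3, 1000)
  p[, tm >= 0] <- 4    # doubled post-stimulus
  spec2 <- tusvep:::new_spectrogram(p, fam, tm, "total")
  db2 <- db_baseline(spec2)
  expect_equal(db2$power[1, 600], 10 * log10(2), tolerance = 1e-12)

  p3 <- p
  p3[, tm >= 0] <- 1   # halved
  db3 <- db_baseline(tusvep:::new_spectrogram(p3, fam, tm, "total"))
  expect_equal(db3$power[1, 600], -10 * log10(2), tolerance = 1e-12)

  db_scaled <- db_baseline(tusvep:::new_spectrogram(7 * p, fam, tm, "total"))
  expect_equal(db_scaled$power, db2$power)

  expect_error(db_baseline(tusvep:::new_spectrogram(matrix(0, 3, 1000),
                                                    fam, tm, "total")),
               "non-positive")
  expect_error(db_baseline(db2), "already")
})
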