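test_that("averaging returns the template for identical or cancelling trials", {
  tmpl <- sin(seq(0, 2 * pi, length.out = 1000))
  data <- array(NA_real_, c(10, 1, 1000))
  for (i in 1:10) data[i, 1, ] <- tmpl
  ep <- make_epochs(data, montage = default_montage()[4, , drop = FALSE])
  erp <- average_evoked(ep, block = "LGN1", condition = "light")
  expect_equal(erp$voltage[1, ], tmpl)
  expect_equal(erp$n_trials, 10)

  eps <- 0.5 * rep(c(1, -1), 5)
  for (i in 1:10) data[i, 1, ] <- tmpl + eps[i]
  ep2 <- make_epochs(data, montage = default_montage()[4, , drop = FALSE])
  expect_equal(average_evoked(ep2)$voltage[1, ], tmpl)
})

test_that("averaging a cell with no accepted trials fails, naming the cell", {
  ep <- make_epochs(array(0, c(4, 1, 100)),
                    montage = default_montage()[4, , drop = FALSE])
  expect_error(average_evoked(ep, block = "Ctrl1"), "Ctrl1")
  ep$accepted[] <- FALSE
  expect_error(average_evoked(ep), "no accepted trials")
})

test_that("averaging noise attenuates as 1/sqrt(n)", {
  n <- 250
  sigma <- 2
  tmpl <- c(numeric(200), evoked_template(evoked_params(), 1000),
            numeric(300))
  data <- array(NA_real_, c(n, 1, 1000))
  tusvep:::with_rng_seed(13, {
    for (i in seq_len(n)) {
      data[i, 1, ] <- tmpl + rnorm(1000, sd = sigma)
    }
  })
  ep <- make_epochs(data, montage = default_montage()[4, , drop = FALSE])
  erp <- average_evoked(ep)
  resid <- erp$voltage[1, ] - tmpl
  expect_equal(sqrt(mean(resid^2)), sigma / sqrt(n), tolerance = 0.15)
})

erp_from_trace <- function(v) {
  structure(
    list(voltage = matrix(v, 1, length(v)),
         time_ms = seq(-200, 799)[seq_along(v)], n_trials = 1,
         block = "LGN1", condition = "light",
         montage = default_montage()[4, , drop = FALSE]),
    class = "erp"
  )
}

test_that("peak-to-peak picks window extrema: constructed case gives 12 uV", {
  t_ms <- seq(-200, 799)
  v <- numeric(1000)
  v[t_ms == 80] <- -5
  v[t_ms == 110] <- 7
  m <- peak_to_peak(erp_from_trace(v))
  expect_equal(m$per_electrode$p2p_uV, 12)
  expect_equal(m$per_electrode$n70_ms, 80)
  expect_equal(m$per_electrode$p100_ms, 110)

  expect_equal(peak_to_peak(erp_from_trace(numeric(1000)))$mean_p2p_uV, 0)
})

test_that("extrema outside the detection windows are ignored", {
  t_ms <- seq(-200, 799)
  v <- tusvep:::with_rng_seed(5, rnorm(1000))
  v[t_ms == 300] <- -50   # global min outside both windows
  v[t_ms == 400] <- 60    # global max outside both windows
  m <- peak_to_peak(erp_from_trace(v))
  # brute-force oracle restricted to the window indices
  n70 <- min(v[t_ms >= 60 & t_ms <= 100])
  p100 <- max(v[t_ms >= 90 & t_ms <= 130])
  expect_equal(m$per_electrode$n70_uV, n70)
  expect_equal(m$per_electrode$p100_uV, p100)
  expect_equal(m$per_electrode$p2p_uV, p100 - n70)
})

test_that("reported latencies always fall inside their windows", {
  tusvep:::with_rng_seed(77, {
    for (rep in 1:20) {
      m <- peak_to_peak(erp_from_trace(rnorm(1000, sd = 5)))
      expect_true(m$per_electrode$n70_ms >= 60 && m$per_electrode$n70_ms <= 100)
      expect_true(m$per_electrode$p100_ms >= 90 && m$per_electrode$p100_ms <= 130)
    }
  })
})

test_that("windows outside the epoch are refused", {
  expect_error(peak_to_peak(erp_from_trace(numeric(500)),
                            p100_window_ms = c(900, 940)), "window")
})

test_that("scaling all trials scales p2p linearly and leaves normalization fixed", {
  tmpl <- evoked_template(evoked_params(), 1000)
  v <- c(numeric(200), tmpl)[1:1000]
  m1 <- peak_to_peak(erp_from_trace(v))
  m3 <- peak_to_peak(erp_from_trace(3 * v))
  expect_equal(m3$mean_p2p_uV, 3 * m1$mean_p2p_uV)
  norm <- normalize_to_baseline(list(Baseline = m3, LGN1 = m3))
  expect_equal(norm$p2p_norm, c(1, 1))
})

test_that("baseline normalization divides by the baseline cell", {
  mk <- function(p2p) {
    structure(list(per_electrode = data.frame(electrode = "O1",
                                              n70_uV = -p2p / 2, n70_ms = 80,
                                              p100_uV = p2p / 2, p100_ms = 110,
                                              p2p_uV = p2p),
                   mean_p2p_uV = p2p), class = "vep_measure")
  }
  norm <- normalize_to_baseline(list(Baseline = mk(10), LGN1 = mk(5)))
  expect_equal(norm$p2p_norm[norm$block == "LGN1"], 0.5)
  expect_equal(norm$p2p_norm[norm$block == "Baseline"], 1.0)
  expect_error(normalize_to_baseline(list(Baseline = mk(0), LGN1 = mk(5))),
               "> 0")
})

test_that("laterality index reflects the ipsi/contra amplitude ratio", {
  mont <- default_montage()
  mk_sides <- function(left, right) {
    occ <- mont[mont$region == "occipital", ]
    p2p <- ifelse(occ$side == "left", left, right)
    structure(list(per_electrode = data.frame(electrode = occ$name,
                                              n70_uV = -p2p / 2, n70_ms = 80,
                                              p100_uV = p2p / 2, p100_ms = 110,
                                              p2p_uV = p2p),
                   mean_p2p_uV = mean(p2p)), class = "vep_measure")
  }
  expect_equal(laterality_index(mk_sides(10, 10), mont, "left"), 0)
  expect_equal(laterality_index(mk_sides(5, 10), mont, "left"), 50)
  expect_equal(laterality_index(mk_sides(10, 5), mont, "right"), 50)
  no_left <- mont[mont$side == "right" | mont$region == "frontal", ]
  m <- mk_sides(5, 10)
  m$per_electrode <- m$per_electrode[m$per_electrode$electrode %in%
                                       no_left$name, ]
  expect_error(laterality_index(m, mont[mont$name %in% no_left$name, ],
                                "left"), "each side")
})

test_that("side-specific suppression is recovered as a laterality percent", {
  # ipsilateral (left) occipital gain 0.4, contralateral 1.0 -> ~60%
  mont <- default_montage()
  occ <- mont$region == "occipital"
  gain <- ifelse(mont$side[occ] == "left", 0.4, 1.0)
  cfg <- sim_config(seed = 15, noise_scale_uV = 1, blink_rate = 0,
                    occipital_gain = gain)
  ev <- make_event_table("LGN1", n_sections = 4)
  raw <- simulate_eeg(ev, cfg)
  ep <- eeg_epoch(eeg_bandpass(raw), ev)
  m <- peak_to_peak(average_evoked(ep, "LGN1", "light"))
  expect_equal(laterality_index(m, mont, "left"), 60, tolerance = 0.1)
})

test_that("display smoothing is a centred moving average and is display-only", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(smooth_for_display(v, k = 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(length(smooth_for_display(rnorm(100))), 100)
})
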