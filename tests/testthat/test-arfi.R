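enc3 <- encoding_params(tau_s = 3e-3)

test_that("encoding parameters are validated and tau is mandatory", {
  expect_error(encoding_params(G_T_per_m = 0.04), "tau_s")
  expect_error(encoding_params(G_T_per_m = -1, tau_s = 1e-3), "G_T_per_m")
  expect_error(encoding_params(tau_s = 0), "tau_s")
  expect_equal(enc3$gamma_rad_s_T, 2 * pi * 42.58e6)
})

test_that("phase differences are computed on the circle", {
  mk_pair <- function(p, m) {
    structure(list(phase_plus = p, phase_minus = m, encoding = enc3,
                   spacing_mm = 1), class = "arfi_pair")
  }
  z <- array(0, c(2, 2, 1))
  expect_equal(phase_difference(mk_pair(z, z)), z)
  # +3 vs -3 rad wraps to -(2 pi - 6), not +6
  p <- array(3, c(1, 1, 1)); m <- array(-3, c(1, 1, 1))
  expect_equal(phase_difference(mk_pair(p, m))[1], Arg(exp(6i)))
  expect_equal(phase_difference(mk_pair(p, m))[1], 6 - 2 * pi)
  # invariance under adding 2 pi to both inputs
  a <- array(runif(8, -pi, pi), c(2, 2, 2))
  b <- array(runif(8, -pi, pi), c(2, 2, 2))
  expect_equal(phase_difference(mk_pair(a + 2 * pi, b + 2 * pi)),
               phase_difference(mk_pair(a, b)), tolerance = 1e-12)
  expect_error(phase_difference(mk_pair(z, array(0, c(3, 2, 1)))),
               "geometry")
})

test_that("displacement matches scalar arithmetic to 1e-12 relative", {
  # worked value: 0.0642 rad with G = 0.04 T/m, tau = 3 ms -> ~1 um
  d <- displacement_map(array(0.0642, c(1, 1, 1)), enc3)
  oracle <- 0.0642 / (2 * 2 * pi * 42.58e6 * 0.04 * 3e-3)
  expect_equal(d$D_m[1], oracle, tolerance = 1e-12)
  expect_equal(d$D_um[1], 1.0, tolerance = 1e-3)

  tusvep:::with_rng_seed(17, {
    for (i in 1:25) {
      dphi <- runif(1, -3, 3)
      G <- runif(1, 0.005, 0.08)
      tau <- runif(1, 5e-4, 8e-3)
      enc <- encoding_params(G_T_per_m = G, tau_s = tau)
      got <- displacement_map(array(dphi, c(1, 1, 1)), enc)$D_m[1]
      want <- dphi / (2 * 2 * pi * 42.58e6 * G * tau)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("displacement is linear in phase and inverse in G and tau", {
  dphi <- array(0.1, c(1, 1, 1))
  d1 <- displacement_map(dphi, enc3)$D_m[1]
  expect_equal(displacement_map(2 * dphi, enc3)$D_m[1], 2 * d1)
  enc_2tau <- encoding_params(tau_s = 6e-3)
  expect_equal(displacement_map(dphi, enc_2tau)$D_m[1], d1 / 2)
  enc_2G <- encoding_params(G_T_per_m = 0.08, tau_s = 3e-3)
  expect_equal(displacement_map(dphi, enc_2G)$D_m[1], d1 / 2)
  expect_equal(displacement_map(array(0, c(2, 2, 1)), enc3)$D_m,
               array(0, c(2, 2, 1)))
})

test_that("the simulator/estimator round trip recovers the field at zero noise", {
  field <- gaussian_focus(c(15, 15, 15), 1, c(7, 7, 7), 4, peak = 1.0)
  pair <- simulate_arfi_pair(field, enc3, noise_sd_rad = 0, seed = 1)
  expect_identical(pair$phase_plus, -pair$phase_minus)
  dm <- displacement_map(phase_difference(pair), enc3)
  expect_lt(max(abs(dm$D_m - field$field * 1e-6)), 1e-9)
  # forward formula: phase-difference peak = 2 gamma G tau x 1 um
  expect_equal(max(phase_difference(pair)),
               2 * enc3$gamma_rad_s_T * 0.04 * 3e-3 * 1e-6,
               tolerance = 1e-10)
})

test_that("simulated pairs are deterministic and noise is zero-mean", {
  field <- gaussian_focus(c(11, 11, 11), 1, c(5, 5, 5), 4, peak = 0.5)
  p1 <- simulate_arfi_pair(field, enc3, noise_sd_rad = 0.05, seed = 4)
  p2 <- simulate_arfi_pair(field, enc3, noise_sd_rad = 0.05, seed = 4)
  expect_identical(p1$phase_plus, p2$phase_plus)

  flat <- gaussian_focus(c(21, 21, 21), 1, c(10, 10, 10), 4, peak = 0)
  pn <- simulate_arfi_pair(flat, enc3, noise_sd_rad = 0.05, seed = 8)
  dphi <- phase_difference(pn)
  se <- sd(dphi) / sqrt(length(dphi))
  expect_lt(abs(mean(dphi)), 3 * se)
})

test_that("gaussian focus has the stated peak, FWHM and integral", {
  f <- gaussian_focus(c(21, 21, 21), 1, c(10, 10, 10), fwhm_mm = 6, peak = 2)
  expect_equal(f$field[11, 11, 11], 2)
  expect_equal(f$field[14, 11, 11], 1)    # half maximum at fwhm/2 = 3 mm
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(sum(f$field), 2 * (sigma * sqrt(2 * pi))^3 / 1,
               tolerance = 1e-3)
  expect_error(gaussian_focus(c(21, 21, 21), 1, c(30, 10, 10), 6, 1),
               "outside")
  expect_error(gaussian_focus(c(21, 21, 21), 1, c(10, 10, 10), -1, 1),
               "fwhm")
})

test_that("max displacement respects the ROI and the detectability criterion", {
  field <- gaussian_focus(c(21, 21, 21), 1, c(10, 10, 10), 4, peak = 2)
  dm <- displacement_map(
    phase_difference(simulate_arfi_pair(field, enc3, 0, seed = 1)), enc3)
  mx <- max_displacement(dm)
  expect_equal(mx$max_um, 2, tolerance = 1e-9)
  expect_equal(mx$index, c(11, 11, 11))

  # ROI excluding the focus returns the in-ROI maximum
  roi <- array(FALSE, c(21, 21, 21))
  roi[1:4, , ] <- TRUE
  mx2 <- max_displacement(dm, roi)
  expect_lt(mx2$max_um, 0.1)
  expect_true(mx2$index[1] <= 4)

  # pure noise -> not detectable at 3 x background SD
  flat <- gaussian_focus(c(21, 21, 21), 1, c(10, 10, 10), 4, peak = 0)
  dn <- displacement_map(
    phase_difference(simulate_arfi_pair(flat, enc3, 0.05, seed = 2)), enc3)
  roi_c <- array(FALSE, c(21, 21, 21))
  roi_c[8:14, 8:14, 8:14] <- TRUE
  expect_false(max_displacement(dn, roi_c)$detectable)
  # strong focus in the same noise is detectable
  dg <- displacement_map(
    phase_difference(simulate_arfi_pair(field, enc3, 0.005, seed = 2)), enc3)
  expect_true(max_displacement(dg, roi_c)$detectable)

  expect_error(max_displacement(dm, array(FALSE, c(21, 21, 21))), "empty")
})

test_that("phase pairs survive a NIfTI + JSON round trip", {
  field <- gaussian_focus(c(9, 9, 9), 1, c(4, 4, 4), 3, peak = 1)
  pair <- simulate_arfi_pair(field, enc3, noise_sd_rad = 0.01, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "arfi")
  write_arfi_pair(pair, prefix)
  back <- read_arfi_pair(prefix)
  expect_equal(back$phase_plus, pair$phase_plus, tolerance = 1e-6)
  expect_equal(back$phase_minus, pair$phase_minus, tolerance = 1e-6)
  expect_equal(back$encoding$tau_s, 3e-3)
  dm1 <- displacement_map(phase_difference(pair), enc3)
  dm2 <- displacement_map(phase_difference(back), back$encoding)
  expect_equal(dm2$D_um, dm1$D_um, tolerance = 1e-5)
})
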