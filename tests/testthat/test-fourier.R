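test_that("forward_spectrum rejects non-square and odd-sided images", {
  expect_error(forward_spectrum(gray_image(matrix(1, 8, 10))), "square")
  expect_error(forward_spectrum(gray_image(matrix(1, 9, 9))), "even")
})

test_that("a constant image transforms to a DC-only spectrum", {
  sp <- forward_spectrum(gray_image(matrix(3, 128, 128)))
  mag <- power_spectrum(sp)$magnitudes
  expect_equal(mag[65, 65], 3 * 128^2)
  mag[65, 65] <- 0
  expect_lt(max(mag), 1e-6 * 3 * 128^2)
})

test_that("spectral peaks of the reference sines land at the analytic bins", {
  # round(omega * N / (2*pi)): 8 for omega = 0.4, 1 for omega = 0.05
  for (case in list(list(om = 0.4, k = 8), list(om = 0.05, k = 1))) {
    mag <- power_spectrum(forward_spectrum(
      make_plane_wave(128, case$om, case$om)))$magnitudes
    mag[65, 65] <- -Inf
    ord <- arrayInd(order(mag, decreasing = TRUE)[1:2], dim(mag)) - 65
    got <- ord[order(ord[, 1]), ]
    expect_equal(got, rbind(c(-case$k, -case$k), c(case$k, case$k)))
  }
})

test_that("Parseval's identity holds to 1e-10 on random images", {
  for (n in c(16, 64, 256)) {
    img <- random_image(n, seed = n)
    sp <- forward_spectrum(img)
    lhs <- sum(as.matrix(img)^2)
    rhs <- sum(Mod(sp$coeffs)^2) / n^2
    expect_lt(abs(lhs - rhs) / lhs, 1e-10)
  }
})

test_that("forward transform agrees with the naive O(N^4) DFT oracle", {
  img <- random_image(16, seed = 7)
  got <- forward_spectrum(img)$coeffs
  want <- naive_centered_dft(as.matrix(img))
  expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-8)
})

test_that("inverse transform round-trips the input within 1e-8", {
  for (seed in 1:3) {
    img <- random_image(32, seed)
    back <- inverse_spectrum(forward_spectrum(img))
    expect_lt(max(abs(back - as.matrix(img))), 1e-8)
  }
})

test_that("power spectrum of a real image is point-symmetric off Nyquist", {
  img <- random_image(32, seed = 11)
  mag <- power_spectrum(forward_spectrum(img))$magnitudes
  sub <- mag[2:32, 2:32]  # drop the Nyquist row/column (index 1)
  flipped <- sub[31:1, 31:1]  # (u, v) -> (-u, -v) about DC
  expect_equal(sub, flipped, tolerance = 1e-12)
})

test_that("band mask counts match the lattice oracle and the printed 912", {
  mask <- band_mask(128, band_spec(1 / 4, 1 / 16))
  expect_identical(sum(mask), 912L)
  expect_identical(sum(mask), count_band_bins(128, 1 / 4, 1 / 16))
  # membership region is exactly 4 <= max(|u|,|v|) <= 15
  u <- matrix(rep(-64:63, each = 128), 128, 128)
  v <- matrix(rep(-64:63, times = 128), 128, 128)
  m <- pmax(abs(u), abs(v))
  expect_identical(mask, m >= 4 & m < 16)
})

test_that("nested half-open bands partition the non-DC spectrum", {
  n <- 64
  b_hi <- band_mask(n, band_spec(1, 1 / 4))
  b_mid <- band_mask(n, band_spec(1 / 4, 1 / 16))
  b_lo <- band_mask(n, band_spec(1 / 16, 0))
  expect_false(any(b_hi & b_mid) || any(b_mid & b_lo) || any(b_hi & b_lo))
  all_nondc <- matrix(TRUE, n, n); all_nondc[n / 2 + 1, n / 2 + 1] <- FALSE
  expect_identical(b_hi | b_mid | b_lo, all_nondc)
  # full band covers every non-DC bin on its own
  expect_identical(band_mask(n, band_spec(1, 0)), all_nondc)
})

test_that("invalid band fractions are rejected", {
  expect_error(band_spec(1 / 16, 1 / 4), "smaller")
  expect_error(band_spec(0, 0), "\\(0, 1]")
})

test_that("full-band reconstruction with DC restores the input", {
  img <- random_image(32, seed = 3)
  rec <- reconstruct_from_band(forward_spectrum(img), band_spec(1, 0),
                               keep_dc = TRUE)
  expect_lt(max(abs(rec - as.matrix(img))), 1e-8)
})

test_that("the scoring band reconstructs the fast sine but not the slow one", {
  band <- band_spec(1 / 4, 1 / 16)
  fast <- make_plane_wave(128, 0.4, 0.4)
  slow <- make_plane_wave(128, 0.05, 0.05)
  r_fast <- reconstruct_from_band(forward_spectrum(fast), band)
  r_slow <- reconstruct_from_band(forward_spectrum(slow), band)
  expect_gte(cor(as.vector(as.matrix(fast)), as.vector(r_fast)), 0.9)
  expect_lte(cor(as.vector(as.matrix(slow)), as.vector(r_slow)), 0.2)
})

test_that("circular window leaves constants alone and zeroes the oracle count", {
  const <- gray_image(matrix(5, 32, 32))
  expect_equal(as.matrix(circular_window(const, "mean")), matrix(5, 32, 32))
  expect_equal(as.matrix(circular_window(const, "zero"))[16, 16], 5)
  ones <- gray_image(matrix(1, 128, 128))
  zeroed <- sum(as.matrix(circular_window(ones, "zero")) == 0)
  expect_identical(zeroed, 128L * 128L - count_disc_pixels(128))
})

test_that("circular windowing suppresses cross-shaped axis leakage", {
  # sharp-edged half-bright square ROI
  m <- matrix(0.2, 128, 128)
  m[33:96, 33:96] <- 1
  img <- gray_image(m)
  axis_mag <- function(im) {
    mag <- power_spectrum(forward_spectrum(im))$magnitudes
    sum(mag[65, -65]) + sum(mag[-65, 65])  # u = 0 and v = 0 axes, DC dropped
  }
  expect_lt(axis_mag(circular_window(img)), axis_mag(img))
})

test_that("unknown circular-window fill strategies are rejected", {
  expect_error(circular_window(gray_image(matrix(1, 16, 16)), "wrap"))
})

test_that("plane-wave fitting recovers the exact angular frequencies", {
  f <- fit_plane_wave(make_plane_wave(128, 0.4, 0.4))
  expect_equal(f$omega_x, 0.4, tolerance = 1e-6)
  expect_equal(f$omega_y, 0.4, tolerance = 1e-6)
  f <- fit_plane_wave(make_plane_wave(128, 0.05, 0.05, phase = 0.7,
                                      offset = 2, amplitude = 0.5))
  expect_equal(f$omega_x, 0.05, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(f$offset, 2, tolerance = 1e-6)
})
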