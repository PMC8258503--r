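#' Centered 2-D discrete Fourier transform of an image
#'
#' Computes the unnormalized forward DFT of a square, even-sided image and
#' shifts it so the zero-frequency (DC) bin sits at centered index (0, 0),
#' i.e. matrix position (N/2 + 1, N/2 + 1) in 1-based R indexing. Centered
#' integer frequencies run u, v in \[-N/2, N/2 - 1\], u along columns
#' (x-frequency) and v along rows (y-frequency). The convention is the
#' unnormalized forward transform with the 1/N^2 factor on the inverse, so
#' Parseval's identity reads sum(img^2) == sum(|F|^2) / N^2.
#'
#' @param img a [gray_image()] (or numeric matrix), square with even side.
#' @return a `complex_spectrum`: list with `coeffs` (centered complex matrix)
#'   and `n` (side length).
#' @seealso [power_spectrum()], [inverse_spectrum()], [reconstruct_from_band()]
#' @examples
#' sp <- forward_spectrum(make_plane_wave(n = 64, omega_x = 0.4, omega_y = 0.4))
#' Mod(sp$coeffs[33, 33])  # DC bin
#' @export
forward_spectrum <- function(img) {
  m <- as.matrix(img)
  assert_square_even(m)
  f <- fftshift2(stats::fft(img_matrix(m)))
  structure(list(coeffs = f, n = nrow(m)), class = "complex_spectrum")
}

#' Inverse transform of a centered spectrum
#'
#' @param spec a `complex_spectrum` from [forward_spectrum()] (possibly with
#'   coefficients zeroed out by band masking).
#' @return numeric matrix: the real part of the inverse DFT. A warning is
#'   raised if the imaginary residual exceeds 1e-8 of the largest magnitude,
#'   which cannot happen for conjugate-symmetric spectra.
#' @export
inverse_spectrum <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  n <- spec$n
  z <- stats::fft(ifftshift2(spec$coeffs), inverse = TRUE) / n^2
  peak <- max(Mod(z))
  if (peak > 0 && max(abs(Im(z))) > 1e-8 * peak) {
    warning("inverse transform has a non-negligible imaginary residual")
  }
  Re(z)
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf("<complex_spectrum> %d x %d bins, centered (DC at (0,0))\n",
              x$n, x$n))
  invisible(x)
}

#' Power spectrum (bin-wise magnitude) of a centered spectrum
#'
#' The power spectrum is the magnitude |F(u,v)| of each DFT coefficient; each
#' bin measures the strength of one spatial frequency and orientation. For a
#' real source image it is point-symmetric about DC on the sub-grid that
#' excludes the Nyquist row and column.
#'
#' @param spec a `complex_spectrum`.
#' @return a `power_spectrum`: list with `magnitudes` (centered nonnegative
#'   matrix) and `n`.
#' @export
power_spectrum <- function(spec) {
  stopifnot(inherits(spec, "complex_spectrum"))
  structure(list(magnitudes = Mod(spec$coeffs), n = spec$n),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d x %d bins, total magnitude %.4g\n",
              x$n, x$n, sum(x$magnitudes)))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, main = "log power spectrum", ...) {
  plot.gray_image(gray_image(log1p(x$magnitudes)), main = main, ...)
  invisible(x)
}

#' Concentric-square frequency band
#'
#' A band is the square annulus between two centered squares in frequency
#' space, given by side-length fractions of the full spectrum. A bin with
#' centered integer frequencies (u, v) belongs to the band iff
#' `f_inner * N/2 <= max(|u|, |v|) < f_outer * N/2`; the DC bin never
#' belongs. The outer bound is exclusive except at `f_outer = 1`, where the
#' band closes over the Nyquist row/column so that the full band covers every
#' non-DC bin. Half-open bounds make nested bands tile the spectrum exactly.
#'
#' The default band (1/4, 1/16) is the annulus between concentric squares of
#' side N/4 and N/16 — at N = 128 the centered indices 4 <= max(|u|,|v|) <= 15,
#' the frequency range occupied by intact foot-process periodicity.
#'
#' @param f_outer outer side-length fraction in (0, 1].
#' @param f_inner inner side-length fraction in \[0, 1), strictly below
#'   `f_outer`.
#' @return a `band_spec` list.
#' @export
band_spec <- function(f_outer = 1 / 4, f_inner = 1 / 16) {
  f_outer <- as.numeric(f_outer); f_inner <- as.numeric(f_inner)
  if (!(f_outer > 0 && f_outer <= 1)) {
    stop("`f_outer` must lie in (0, 1]", call. = FALSE)
  }
  if (!(f_inner >= 0 && f_inner < 1)) {
    stop("`f_inner` must lie in [0, 1)", call. = FALSE)
  }
  if (f_inner >= f_outer) {
    stop("`f_inner` must be strictly smaller than `f_outer`", call. = FALSE)
  }
  structure(list(f_outer = f_outer, f_inner = f_inner), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> concentric-square annulus (%g, %g)\n",
              x$f_outer, x$f_inner))
  invisible(x)
}

#' Boolean membership mask of a frequency band
#'
#' @param n spectrum side length (even, >= 8).
#' @param band a [band_spec()].
#' @return logical n x n matrix in the centered layout, `TRUE` exactly where
#'   the band-membership rule holds; the DC bin is always `FALSE`.
#' @examples
#' sum(band_mask(128, band_spec(1 / 4, 1 / 16)))  # 912 bins
#' @export
band_mask <- function(n, band = band_spec()) {
  n <- as.integer(n)
  if (n < 8L || n %% 2L != 0L) {
    stop("`n` must be even and at least 8", call. = FALSE)
  }
  if (!inherits(band, "band_spec")) band <- do.call(band_spec, as.list(band))
  u <- centered_freq(n)
  m <- outer(abs(u), abs(u), pmax)  # max(|v|, |u|) with v on rows
  mask <- m >= band$f_inner * n / 2
  if (band$f_outer < 1) {
    mask <- mask & (m < band$f_outer * n / 2)
  }
  mask[n / 2 + 1, n / 2 + 1] <- FALSE  # DC never in any band
  mask
}

#' Band-limited inverse-FT reconstruction
#'
#' Zeroes every coefficient outside the band (DC included unless `keep_dc`)
#' and inverse-transforms, returning the real part. This is the operation
#' that shows which image structure a frequency region carries: a texture
#' whose periodicity falls inside the band is reconstructed, everything else
#' is suppressed.
#'
#' @param spec a `complex_spectrum`.
#' @param band a [band_spec()].
#' @param keep_dc keep the DC coefficient (restores the mean intensity).
#' @return numeric matrix (may contain negative values once DC is dropped).
#' @export
reconstruct_from_band <- function(spec, band = band_spec(), keep_dc = FALSE) {
  stopifnot(inherits(spec, "complex_spectrum"))
  mask <- band_mask(spec$n, band)
  if (isTRUE(keep_dc)) mask[spec$n / 2 + 1, spec$n / 2 + 1] <- TRUE
  masked <- spec$coeffs
  masked[!mask] <- 0 + 0i
  inverse_spectrum(structure(list(coeffs = masked, n = spec$n),
                             class = "complex_spectrum"))
}

#' Circular spatial window
#'
#' Replaces pixels at Euclidean distance > N/2 from the image centre
#' ((N-1)/2, (N-1)/2) in 0-based coordinates. Square ROI borders put
#' cross-shaped leakage on the frequency axes; cutting the ROI into a disc
#' before the FFT suppresses it. The default fill is the mean intensity
#' inside the disc, which avoids reintroducing a step edge at the disc
#' boundary; zero fill is available.
#'
#' @param img a square [gray_image()] or matrix.
#' @param fill `"mean"` (in-disc mean, default) or `"zero"`.
#' @return a `gray_image` with the out-of-disc pixels replaced.
#' @export
circular_window <- function(img, fill = c("mean", "zero")) {
  fill <- match.arg(fill)
  m <- as.matrix(img)
  if (nrow(m) != ncol(m)) stop("image must be square", call. = FALSE)
  n <- nrow(m)
  ctr <- (n - 1) / 2
  d2 <- outer((seq_len(n) - 1 - ctr)^2, (seq_len(n) - 1 - ctr)^2, `+`)
  outside <- d2 > (n / 2)^2
  vals <- img_matrix(as_gray_image(m))
  vals[outside] <- if (fill == "mean") mean(vals[!outside]) else 0
  gray_image(vals, pixel_size = attr(img, "pixel_size") %||% 32.27)
}

#' Recover plane-wave angular frequencies from an image
#'
#' Locates the dominant non-DC spectral peak and refines the per-axis angular
#' frequency (radians per pixel) by least squares on the plane-wave model
#' `z = offset + a sin(wx x + wy y) + b cos(wx x + wy y)`: for fixed (wx, wy)
#' the model is linear in (offset, a, b) and solved exactly, and the profiled
#' residual sum of squares is minimised over (wx, wy) by Nelder-Mead started
#' at the peak's bin frequency. The peak bin quantises frequency to 2*pi/N;
#' the fit removes that quantisation.
#'
#' @param img square even-sided image containing a single dominant plane wave.
#' @return list with `omega_x`, `omega_y` (radians per pixel, sign fixed so
#'   the leading nonzero component is positive), `amplitude`, `phase`,
#'   `offset`, `peak_bin` (centered indices of the seeding peak) and `rss`.
#' @examples
#' fit_plane_wave(make_plane_wave(n = 128, omega_x = 0.4, omega_y = 0.4))$omega_x
#' @export
fit_plane_wave <- function(img) {
  m <- as.matrix(img)
  assert_square_even(m)
  n <- nrow(m)
  mag <- power_spectrum(forward_spectrum(m))$magnitudes
  mag[n / 2 + 1, n / 2 + 1] <- -Inf
  idx <- arrayInd(which.max(mag), dim(mag))
  v <- idx[1] - 1 - n / 2
  u <- idx[2] - 1 - n / 2
  if (u < 0 || (u == 0 && v < 0)) {  # conjugate pair: keep the +u half
    u <- -u; v <- -v
  }
  x <- matrix(rep(0:(n - 1), each = n), n, n)   # column coordinate
  y <- matrix(rep(0:(n - 1), times = n), n, n)  # row coordinate
  z <- as.vector(img_matrix(as_gray_image(m)))
  rss_of <- function(w) {
    th <- as.vector(w[1] * x + w[2] * y)
    X <- cbind(1, sin(th), cos(th))
    fit <- stats::lm.fit(X, z)
    sum(fit$residuals^2)
  }
  w0 <- 2 * pi * c(u, v) / n
  opt <- stats::optim(w0, rss_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  th <- as.vector(opt$par[1] * x + opt$par[2] * y)
  beta <- stats::lm.fit(cbind(1, sin(th), cos(th)), z)$coefficients
  list(omega_x = opt$par[1], omega_y = opt$par[2],
       amplitude = unname(sqrt(beta[2]^2 + beta[3]^2)),
       phase = unname(atan2(beta[3], beta[2])),
       offset = unname(beta[1]),
       peak_bin = c(u = u, v = v),
       rss = opt$value)
}

# ---- internal helpers --------------------------------------------------

# centered integer frequencies for an even side: -n/2 .. n/2-1, DC at n/2+1
centered_freq <- function(n) seq_len(n) - 1L - n %/% 2L

# swap quadrants so DC moves from [1,1] to [n/2+1, n/2+1]; even sides only,
# where the shift is an involution (ifftshift2 == fftshift2)
fftshift2 <- function(m) {
  n <- nrow(m)
  ord <- c((n / 2 + 1):n, 1:(n / 2))
  m[ord, ord]
}
ifftshift2 <- fftshift2

`%||%` <- function(a, b) if (is.null(a)) b else a
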