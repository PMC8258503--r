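# Independent oracles the tests check the package against. These stay
# deliberately naive (direct sums, enumeration) and share no code with the
# implementation.

# O(N^4) naive centered DFT: F(u, v) = sum_xy z(x, y) exp(-2*pi*i*(ux + vy)/N)
naive_centered_dft <- function(m) {
  n <- nrow(m)
  freqs <- seq_len(n) - 1 - n / 2
  out <- matrix(0 + 0i, n, n)
  for (iu in seq_len(n)) {
    for (iv in seq_len(n)) {
      u <- freqs[iu]; v <- freqs[iv]
      acc <- 0 + 0i
      for (x in 0:(n - 1)) {
        for (y in 0:(n - 1)) {
          acc <- acc + m[y + 1, x + 1] * exp(-2i * pi * (u * x + v * y) / n)
        }
      }
      out[iv, iu] <- acc
    }
  }
  out
}

# lattice count of bins with f_inner*N/2 <= max(|u|,|v|) < f_outer*N/2
count_band_bins <- function(n, f_outer, f_inner) {
  cnt <- 0L
  for (u in (-n / 2):(n / 2 - 1)) {
    for (v in (-n / 2):(n / 2 - 1)) {
      m <- max(abs(u), abs(v))
      if (m > 0 && m >= f_inner * n / 2 && m < f_outer * n / 2) cnt <- cnt + 1L
    }
  }
  cnt
}

# lattice count of pixels inside the disc of radius n/2 about ((n-1)/2, (n-1)/2)
count_disc_pixels <- function(n) {
  cnt <- 0L
  for (x in 0:(n - 1)) {
    for (y in 0:(n - 1)) {
      if ((x - (n - 1) / 2)^2 + (y - (n - 1) / 2)^2 <= (n / 2)^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# per-bin sector classification by explicit angle arithmetic (DC, Nyquist
# row/column and bins beyond radius n/2 excluded, as in the contract)
oracle_sector_table <- function(n) {
  freqs <- seq_len(n) - 1 - n / 2
  out <- matrix(NA_real_, n, n)
  for (iu in seq_len(n)) {
    for (iv in seq_len(n)) {
      u <- freqs[iu]; v <- freqs[iv]
      if (u == -n / 2 || v == -n / 2 || (u == 0 && v == 0)) next
      if (u^2 + v^2 > (n / 2)^2) next
      ang <- atan2(v, u) * 180 / pi
      ang <- ang %% 360
      s <- 0
      repeat {  # find s with ang in [45s - 22.5, 45s + 22.5) mod 360
        lo <- (45 * s - 22.5) %% 360; hi <- (45 * s + 22.5) %% 360
        inside <- if (lo < hi) ang >= lo && ang < hi else ang >= lo || ang < hi
        if (inside) break
        s <- s + 1
      }
      out[iv, iu] <- s
    }
  }
  out
}

# exact Mann-Whitney two-sided p by full enumeration of rank assignments
enumerate_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# concentric-ring (isotropic) phantom
ring_phantom <- function(n = 128, period = 12) {
  ctr <- (n - 1) / 2
  r <- sqrt(outer((0:(n - 1) - ctr)^2, (0:(n - 1) - ctr)^2, `+`))
  gray_image(1 + 0.8 * sin(2 * pi * r / period))
}

random_image <- function(n, seed) {
  set.seed(seed)
  gray_image(matrix(stats::runif(n * n), n, n))
}
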