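# Low-level signal synthesis and analytic-signal helpers shared by the
# synthetic-data generators and the spectral metrics.

#' Colored (1/f) noise with an exact aperiodic exponent
#'
#' Shapes the spectrum of white Gaussian noise with an `f^(exponent/2)`
#' amplitude filter, so the resulting power spectral density follows
#' `P(f) ~ f^exponent` exactly (in expectation). The output is standardized
#' to unit standard deviation.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param exponent aperiodic exponent (negative; -1 is pink, -2 brown).
#' @param f_min frequencies below this are held at the `f_min` gain to avoid
#'   unbounded DC power (Hz).
#' @param random_phase with `TRUE` (default) the spectral amplitudes are set
#'   exactly to the target law and only the phases are random (surrogate
#'   construction), so the realized spectrum carries no amplitude
#'   fluctuations and the aperiodic slope is exactly controlled; with
#'   `FALSE` the law shapes complex Gaussian spectral coefficients.
#' @return numeric vector of length `n`, sd 1.
#' @export
one_over_f_noise <- function(n, fs, exponent = -2, f_min = 0.5,
                             random_phase = TRUE) {
  if (n < 4) stop("invalid parameter: n too small")
  m <- stats::nextn(n, c(2, 3))          # pad to a fast FFT length
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror for the negative frequencies
  g <- pmax(f, f_min)^(exponent / 2)
  g[1] <- 0                             # remove DC
  x <- if (random_phase) shaped_random_phase_noise(m, g)[seq_len(n)]
       else shaped_gaussian_noise(m, g)[seq_len(n)]
  x / stats::sd(x)
}

# surrogate synthesis: exact spectral amplitude profile g, uniform random
# phases; Hermitian-symmetrized so the inverse transform is real
shaped_random_phase_noise <- function(m, g) {
  X <- complex(length.out = m)
  if (m %% 2 == 0) {
    half <- m %/% 2
    ph <- stats::runif(half - 1, 0, 2 * pi)
    X[2:half] <- exp(1i * ph)
    X[m:(half + 2)] <- Conj(X[2:half])
    X[half + 1] <- sample(c(-1, 1), 1)
  } else {
    k <- (m - 1) %/% 2
    ph <- stats::runif(k, 0, 2 * pi)
    X[2:(k + 1)] <- exp(1i * ph)
    X[m:(k + 2)] <- Conj(X[2:(k + 1)])
  }
  X <- X * g
  Re(stats::fft(X, inverse = TRUE)) / sqrt(m)
}

# band-limited unit-sd Gaussian noise via hard spectral masking: gives
# exactly controllable band content for the generators
band_limited_noise <- function(n, fs, lo, hi) {
  m <- stats::nextn(n, c(2, 3))
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(f >= lo & f <= hi)
  x <- shaped_gaussian_noise(m, g)[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# two independent band-limited unit-sd noises from one inverse FFT: with an
# unsymmetrized iid complex-Gaussian spectrum shaped by the (symmetric) mask,
# the real and imaginary parts of the inverse transform are independent real
# Gaussian processes with the same spectrum
band_limited_noise_pair <- function(n, fs, lo, hi) {
  m <- stats::nextn(n, c(2, 3))
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(f >= lo & f <= hi)
  X <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * g
  y <- stats::fft(X, inverse = TRUE)[seq_len(n)] / sqrt(m)
  norm <- function(v) { s <- stats::sd(v); if (s == 0) v else v / s }
  list(norm(Re(y)), norm(Im(y)))
}

# Gaussian noise with spectral amplitude shape g (length m, symmetric in
# frequency), synthesized directly in the frequency domain: one inverse FFT
# instead of forward + inverse. Equivalent in law to masking white noise.
shaped_gaussian_noise <- function(m, g) {
  X <- complex(length.out = m)
  if (m %% 2 == 0) {
    half <- m %/% 2
    z <- complex(real = stats::rnorm(half - 1),
                 imaginary = stats::rnorm(half - 1))
    X[2:half] <- z
    X[m:(half + 2)] <- Conj(z)
    X[half + 1] <- stats::rnorm(1) * sqrt(2)   # Nyquist bin
  } else {
    k <- (m - 1) %/% 2
    z <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k))
    X[2:(k + 1)] <- z
    X[m:(k + 2)] <- Conj(z)
  }
  X <- X * g
  Re(stats::fft(X, inverse = TRUE)) / sqrt(m)
}

# zero-phase band isolation by spectral masking (padded FFT); used on the
# long multichannel envelope paths where IIR filtering per channel-band is
# needlessly slow. Returns the band component of each row of `data`.
fft_bandpass_rows <- function(data, fs, lo, hi) {
  n <- ncol(data)
  m <- stats::nextn(n, c(2, 3))
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- as.numeric(f >= lo & f <= hi)
  out <- data
  nch <- nrow(data)
  ch <- 1L
  while (ch <= nch) {
    if (ch + 1L <= nch) {
      # two real channels per complex FFT: the symmetric mask keeps the
      # real/imaginary packing separable
      X <- stats::fft(complex(real = c(data[ch, ], numeric(m - n)),
                              imaginary = c(data[ch + 1L, ], numeric(m - n))))
      y <- stats::fft(X * mask, inverse = TRUE)[seq_len(n)] / m
      out[ch, ] <- Re(y)
      out[ch + 1L, ] <- Im(y)
      ch <- ch + 2L
    } else {
      X <- stats::fft(c(data[ch, ], numeric(m - n)))
      out[ch, ] <- Re(stats::fft(X * mask, inverse = TRUE))[seq_len(n)] / m
      ch <- ch + 1L
    }
  }
  out
}

# analytic signal via the frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# instantaneous phase of the band-limited component of x
instantaneous_phase <- function(x, fs = NULL, band = NULL, order = 3) {
  if (!is.null(band)) {
    bf <- signal::butter(order, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  Arg(analytic_signal(x))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used by the synthetic generators to lock
#' spike phases to an oscillation band with concentration `kappa`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 is the circular uniform).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("invalid parameter: kappa must be >= 0")
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
    return(wrap_angle(th + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    fz <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - fz)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(fz)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(th) {
  out <- (th + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# mean resultant length of the von Mises law, I1(kappa)/I0(kappa)
vonmises_resultant <- function(kappa) {
  if (kappa < 1e-12) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

# cosine-tapered gate over sample indices i0:i1 with ramp_n samples per edge
taper_gate <- function(n, i0, i1, ramp_n) {
  g <- numeric(n)
  len <- i1 - i0 + 1L
  ramp_n <- min(ramp_n, floor(len / 2))
  core <- rep(1, len)
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    core[seq_len(ramp_n)] <- ramp
    core[(len - ramp_n + 1):len] <- rev(ramp)
  }
  g[i0:i1] <- core
  g
}
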