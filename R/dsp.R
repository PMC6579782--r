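# Internal DSP primitives: Butterworth design in zero-pole-gain form,
# zero-phase cascaded-biquad filtering, FFT analytic signal, 1/f noise and
# a von Mises sampler. Filtering is done in second-order sections because
# the transfer-function polynomial of a 4th-order Butterworth at the 0.1 Hz
# high-pass edge (normalized cutoff 4e-4 at 500 Hz) is numerically
# ill-conditioned in direct form.

# Digital Butterworth in zpk form via bilinear transform of the analog
# prototype; validated against signal::butter's frequency response.
butterZpk <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fc < fs / 2)
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # analog prototype poles
  wc <- 2 * fs * tan(pi * fc / fs)                # prewarped cutoff
  if (type == "low") {
    p <- wc * pa; z <- complex(0); g <- wc^n
  } else {
    p <- wc / pa; z <- rep(0 + 0i, n); g <- 1
  }
  fs2 <- 2 * fs
  g <- g * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, n - length(zd)))
  list(z = zd, p = pd, g = g)
}

# Group conjugate pole/zero pairs into biquads; overall gain on the first.
zpk2sos <- function(zpk) {
  p <- zpk$p[order(abs(Im(zpk$p)), Re(zpk$p))]
  z <- zpk$z[order(abs(Im(zpk$z)), Re(zpk$z))]
  n <- length(p)
  sos <- list()
  i <- 1
  while (i <= n - 1) {
    sos[[length(sos) + 1]] <- list(
      b = Re(c(1, -(z[i] + z[i + 1]), z[i] * z[i + 1])),
      a = Re(c(1, -(p[i] + p[i + 1]), p[i] * p[i + 1])))
    i <- i + 2
  }
  if (n %% 2 == 1)
    sos[[length(sos) + 1]] <- list(b = Re(c(1, -z[n])), a = Re(c(1, -p[n])))
  sos[[1]]$b <- sos[[1]]$b * zpk$g
  sos
}

# Second-order IIR notch (RBJ biquad), quality factor Q.
notchSos <- function(f0, fs, Q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, Q > 0)
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  list(list(b = c(1, -2 * cos(w0), 1) / (1 + al),
            a = c(1 + al, -2 * cos(w0), 1 - al) / (1 + al)))
}

# Frequency response of an SOS cascade on the length-N DFT grid.
sosFreqResponse <- function(sos, N) {
  w <- 2 * pi * (seq_len(N) - 1) / N
  e1 <- exp(-1i * w); e2 <- e1 * e1
  H <- rep(1 + 0i, N)
  for (s in sos) {
    b <- s$b; a <- s$a
    if (length(b) == 2) { b <- c(b, 0); a <- c(a, 0) }
    H <- H * (b[1] + b[2] * e1 + b[3] * e2) / (a[1] + a[2] * e1 + a[3] * e2)
  }
  H
}

# Zero-phase filtering of each column of X through a cascade of
# second-order sections: the forward-backward magnitude-squared response
# |H(w)|^2 is applied spectrally after odd-reflection end padding. This is
# the steady-state result of a forward-backward (filtfilt) pass, but free
# of the seconds-long IIR edge transients a 0.1 Hz high-pass produces in
# the time domain; padding is sized from the slowest pole's time constant
# and rounded up to an FFT-friendly length.
sosFiltfiltMat <- function(sos, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("signal too short to filter")
  rmax <- max(vapply(sos, function(s)
    max(Mod(polyroot(rev(s$a)))), numeric(1)))
  tau <- if (rmax >= 1) n else -1 / log(min(rmax, 1 - 1e-12))
  minPad <- min(n - 1, max(24, ceiling(4 * tau)))
  N <- stats::nextn(n + 2 * minPad, c(2, 3, 5))
  padTot <- min(N - n, 2 * (n - 1))
  npadL <- padTot %/% 2
  npadR <- padTot - npadL
  # even (mirror) reflection: value-continuous at both boundaries and free
  # of the DC step an odd reflection adds when the signal ends off-zero
  top <- X[(npadL + 1):2, , drop = FALSE]
  bot <- X[(n - 1):(n - npadR), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  if (nrow(Xp) < N) Xp <- rbind(Xp, matrix(rep(Xp[nrow(Xp), ], each = N - nrow(Xp)),
                                           N - nrow(Xp), ncol(Xp)))
  H2 <- Mod(sosFreqResponse(sos, N))^2
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * H2, inverse = TRUE)) / N
  Y[(npadL + 1):(npadL + n), , drop = FALSE]
}

sosFiltfilt <- function(sos, x) drop(sosFiltfiltMat(sos, matrix(x, ncol = 1)))

# Analytic signal of each column (Marple one-sided spectrum method).
analyticSignalMat <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  S <- stats::mvfft(X) * h
  stats::mvfft(S, inverse = TRUE) / n
}

# 1/f ("pink") background noise, one column per series, each standardized to
# zero mean and unit SD. Spectral-synthesis method: amplitude proportional to
# f^(-1/2) (power ~ 1/f), random phases, Hermitian-symmetrized spectrum.
pinkNoiseMat <- function(n, m) {
  stopifnot(n >= 4)
  nf <- (n - 1) %/% 2
  amp <- (seq_len(nf))^(-0.5)
  S <- matrix(0 + 0i, n, m)
  S[2:(nf + 1), ] <- amp * matrix(complex(real = stats::rnorm(nf * m),
                                          imaginary = stats::rnorm(nf * m)), nf, m)
  if (n %% 2 == 0) S[n / 2 + 1, ] <- (n / 2)^(-0.5) * stats::rnorm(m)
  S[n:(n - nf + 1), ] <- Conj(S[2:(nf + 1), ])
  x <- Re(stats::mvfft(S, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# von Mises(0, kappa) sampler, Best & Fisher (1979) wrapped-Cauchy rejection.
rVonMises <- function(n, kappa) {
  stopifnot(kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    v <- f[acc]
    if (length(v)) {
      sgn <- sign(stats::runif(length(v)) - 0.5)
      sgn[sgn == 0] <- 1
      out[(got + 1):(got + length(v))] <- sgn * acos(pmax(-1, pmin(1, v)))
      got <- got + length(v)
    }
  }
  out
}

# FNV-1a hash of a character string, as hex; used for run provenance.
fnv1aHex <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    h <- ((h %% 256) * 16777216 + h * 403) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
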