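# Shared fixture builders: analytic signals with known rate/depth, built
# in code at test time.

# Triaxial record whose z axis carries the acceleration of a sinusoidal
# displacement of given rate (min^-1) and peak-to-peak depth (mm).
sinusoid_accel <- function(rate_min, depth_mm, duration = 60, fs = 100,
                           gravity = 9.81, phase = 0) {
  f0 <- rate_min / 60
  amp <- (2 * pi * f0)^2 * (depth_mm / 2) / 1000  # m/s^2
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  z <- amp * cos(2 * pi * f0 * tt + phase) + gravity
  accel_record(cbind(0 * tt, 0 * tt, z), fs = fs)
}

# Scalar analysis window holding a sum of cosines (freqs Hz, amps, phases)
cosine_window <- function(freqs, amps, phases = 0 * freqs, Tw = 3, fs = 100) {
  tt <- (seq_len(round(Tw * fs)) - 1) / fs
  x <- rep(0, length(tt))
  for (i in seq_along(freqs))
    x <- x + amps[i] * cos(2 * pi * freqs[i] * tt + phases[i])
  analysis_window(x, fs = fs)
}

# Rotate a triaxial record rigidly by `deg` about the y axis
rotate_record <- function(accel, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              nrow = 3, byrow = TRUE)
  out <- accel
  out$samples <- accel$samples %*% t(R)
  out
}

# Brute-force independent spectrum oracle: magnitude of the zero-padded
# DFT of the mean-removed, Hamming-tapered segment, computed directly
# from the definition at one frequency index (0-based).
oracle_dft_mag <- function(x, bin, n_fft = 2048) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- (x - mean(x)) * w
  t <- 0:(n - 1)
  Mod(sum(xw * exp(-2i * pi * bin * t / n_fft)))
}

# Independent exact Mann-Whitney oracle by full enumeration
oracle_mwu_exact <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(utils::combn(N, n), 2, function(idx) sum(r[idx])) -
    n * (n + 1) / 2
  p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  list(U = u_obs, p = p)
}
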