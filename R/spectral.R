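# Core method: model the acceleration within a short analysis interval as
# an almost-periodic signal,
#     a(t) = sum_{k=1..N} A_k cos(2 pi k f_cc t + theta_k)   [m/s^2]
# estimate f_cc and the first N harmonics from a Hamming-windowed,
# zero-padded FFT, convert them to displacement harmonics through the
# second-derivative relation
#     S_k = 1000 * A_k / (2 pi k f_cc)^2  [mm],  phi_k = theta_k + pi,
# reconstruct one displacement cycle, and report
#     rate = 60 * f_cc  [min^-1],  depth = max s(t) - min s(t)  [mm].
# No integration of the acceleration is ever performed, so the estimates
# cannot drift.

#' Spectral analysis configuration
#'
#' @param n_fft FFT length with zero padding (default 2048).
#' @param n_harmonics number of harmonics N modelling the waveform
#'   (default 3).
#' @param band `(f_min, f_max)` in Hz, the search band for the
#'   fundamental. The default 0.6–3.5 Hz spans 36–210 min^-1, covering
#'   guideline-relevant compression rates with margin.
#' @param harmonic_halfwidth half-width in Hz of the search interval
#'   around each expected harmonic location `k * fcc`. `NULL` (default)
#'   means `max(1.5 * fs / n_fft, 0.1 * fcc)`, tolerating jitter-broadened
#'   peaks.
#' @param subharmonic_ratio if a local spectral peak near `fcc / 2` has at
#'   least this fraction of the main peak's magnitude, `fcc / 2` is taken
#'   as the fundamental. Guards against locking onto the 2nd harmonic of
#'   pulse-like compression waveforms. Must be in (0, 1).
#' @param refine_peak refine the fundamental beyond FFT-bin resolution by
#'   three-point parabolic interpolation around the winning bin (default
#'   `TRUE`). Bin-resolution read-off (`FALSE`) is available; note that
#'   the bin error enters the depth quadratically through the
#'   `1 / fcc^2` displacement conversion.
#' @param noise_floor_mult a candidate peak must exceed this multiple of
#'   the median in-band magnitude, otherwise "no periodicity detected".
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(n_fft = 2048, n_harmonics = 3,
                            band = c(0.6, 3.5), harmonic_halfwidth = NULL,
                            subharmonic_ratio = 0.3, refine_peak = TRUE,
                            noise_floor_mult = 5) {
  stopifnot(n_fft >= 8, n_harmonics >= 1,
            length(band) == 2, band[1] > 0, band[1] < band[2],
            subharmonic_ratio > 0, subharmonic_ratio < 1,
            noise_floor_mult > 0)
  structure(list(n_fft = as.integer(n_fft),
                 n_harmonics = as.integer(n_harmonics),
                 band = as.numeric(band),
                 harmonic_halfwidth = harmonic_halfwidth,
                 subharmonic_ratio = subharmonic_ratio,
                 refine_peak = isTRUE(refine_peak),
                 noise_floor_mult = noise_floor_mult),
            class = "spectral_config")
}

#' Analysis window
#'
#' A scalar acceleration segment of duration `Tw` seconds, the unit over
#' which one feedback value is computed.
#'
#' @param samples numeric vector, scalar acceleration in m/s^2.
#' @param fs sampling rate in Hz.
#' @param start window start time in s.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(samples, fs, start = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 8L) stop("analysis window needs at least 8 samples")
  if (any(!is.finite(samples))) stop("analysis window samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  structure(list(samples = samples, fs = fs, start = start,
                 Tw = length(samples) / fs),
            class = "analysis_window")
}

#' Extract a scalar analysis window from a triaxial record
#'
#' The method operates on a scalar acceleration signal; this selects how
#' the three accelerometer axes are combined.
#'
#' * `"principal"` (default): per-channel mean removed, then the segment
#'   is projected onto the direction of maximal variance within the
#'   window. Rotation-invariant, so an 18-degree sensor tilt needs no
#'   special handling. The sign is fixed deterministically: the earliest
#'   sample whose magnitude reaches half the segment maximum is made
#'   positive.
#' * `"x"`, `"y"`, `"z"`: a fixed axis, mean removed.
#' * `"magnitude"`: the Euclidean norm of the three axes, mean removed
#'   (rectifies the waveform; provided for comparison only).
#'
#' @param accel an [accel_record()].
#' @param start window start in seconds (relative to `t0`).
#' @param Tw window duration in seconds.
#' @param mode axis-combination mode.
#' @return An [analysis_window()].
#' @export
project_axes <- function(accel, start, Tw,
                         mode = c("principal", "x", "y", "z", "magnitude")) {
  stopifnot(inherits(accel, "accel_record"))
  mode <- match.arg(mode)
  fs <- accel$fs
  i0 <- floor(start * fs) + 1L
  n <- round(Tw * fs)
  if (Tw <= 0 || i0 < 1L || i0 + n - 1L > n_samples(accel))
    stop("analysis window exceeds record bounds")
  seg <- accel$samples[i0:(i0 + n - 1L), , drop = FALSE]

  if (mode %in% c("x", "y", "z")) {
    j <- match(mode, c("x", "y", "z"))
    s <- seg[, j] - mean(seg[, j])
  } else if (mode == "magnitude") {
    s <- sqrt(rowSums(seg^2))
    s <- s - mean(s)
  } else {
    ctr <- sweep(seg, 2, colMeans(seg))
    cv <- crossprod(ctr) / max(1, n - 1)
    if (sum(diag(cv)) <= .Machine$double.eps)
      stop_no_activity()
    v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    s <- as.numeric(ctr %*% v)
    # deterministic sign: earliest sample reaching half max magnitude is positive
    amax <- max(abs(s))
    if (amax <= .Machine$double.eps) stop_no_activity()
    first <- which(abs(s) >= amax / 2)[1]
    if (s[first] < 0) s <- -s
  }
  if (max(abs(s)) <= .Machine$double.eps) stop_no_activity()
  analysis_window(s, fs = fs, start = start)
}

stop_no_activity <- function() {
  stop(structure(class = c("cpr_no_activity", "error", "condition"),
                 list(message = "no compression activity in window",
                      call = sys.call(-1))))
}

stop_no_periodicity <- function() {
  stop(structure(class = c("cpr_no_periodicity", "error", "condition"),
                 list(message = "no periodicity detected in window",
                      call = sys.call(-1))))
}

#' Hamming-windowed, zero-padded spectrum of an analysis window
#'
#' Removes the segment mean, applies a Hamming taper, zero-pads to
#' `n_fft` points and returns the one-sided FFT. The taper's coherent
#' gain (`sum(w)`) is recorded so that harmonic amplitudes can be read
#' off in physical units: a unit cosine contributes a main-lobe peak of
#' magnitude `sum(w) / 2`.
#'
#' @param win an [analysis_window()].
#' @param cfg a [spectral_config()].
#' @return An object of class `cpr_spectrum` with elements `spectrum`
#'   (complex, bins 0..n_fft/2), `freq` (Hz), `coherent_sum`, `fs`,
#'   `n` (segment length), `df` (bin spacing in Hz).
#' @export
window_and_spectrum <- function(win, cfg = spectral_config()) {
  stopifnot(inherits(win, "analysis_window"))
  n <- length(win$samples)
  if (n > cfg$n_fft)
    stop(sprintf("window length %d exceeds n_fft = %d; increase n_fft",
                 n, cfg$n_fft))
  w <- as.numeric(signal::hamming(n))
  xw <- (win$samples - mean(win$samples)) * w
  X <- stats::fft(c(xw, rep(0, cfg$n_fft - n)))
  half <- seq_len(cfg$n_fft %/% 2 + 1L)
  df <- win$fs / cfg$n_fft
  structure(list(spectrum = X[half], freq = (half - 1L) * df,
                 coherent_sum = sum(w), fs = win$fs, n = n, df = df),
            class = "cpr_spectrum")
}

# largest local magnitude maximum among bins idx (indices into spec$freq).
# strict = TRUE returns NA when no interior local maximum exists;
# otherwise falls back to the global max in the range (amplitude read-off
# of a known harmonic tolerates lying on a lobe shoulder).
local_peak <- function(mag, idx, strict = FALSE) {
  if (length(idx) == 0L) return(NA_integer_)
  if (length(idx) <= 2L)
    return(if (strict) NA_integer_ else idx[which.max(mag[idx])])
  inner <- idx[-c(1L, length(idx))]
  is_loc <- mag[inner] >= mag[inner - 1L] & mag[inner] >= mag[inner + 1L]
  cand <- inner[is_loc]
  if (length(cand) == 0L)
    return(if (strict) NA_integer_ else idx[which.max(mag[idx])])
  cand[which.max(mag[cand])]
}

#' Estimate the fundamental compression frequency
#'
#' Picks the largest-magnitude bin inside the configured search band,
#' then applies a subharmonic check: if a local peak near half that
#' frequency (still inside the band) reaches
#' `subharmonic_ratio` of the main peak's magnitude, the halved frequency
#' is taken as the fundamental — pulse-like compression waveforms can
#' carry more energy in their 2nd harmonic than in the fundamental. With
#' `refine_peak`, a three-point parabolic fit around the winning bin
#' refines the frequency beyond bin resolution.
#'
#' @param spec a `cpr_spectrum` from [window_and_spectrum()].
#' @param cfg a [spectral_config()].
#' @return Fundamental frequency `fcc` in Hz.
#' @export
estimate_fundamental <- function(spec, cfg = spectral_config()) {
  stopifnot(inherits(spec, "cpr_spectrum"))
  mag <- Mod(spec$spectrum)
  in_band <- which(spec$freq >= cfg$band[1] & spec$freq <= cfg$band[2])
  if (length(in_band) == 0L) stop("fundamental search band contains no FFT bins")
  ipk <- in_band[which.max(mag[in_band])]
  if (mag[ipk] < 1e-9 ||
      mag[ipk] < cfg$noise_floor_mult * spectrum_noise_floor(spec, cfg))
    stop_no_periodicity()

  # subharmonic check: a genuine local peak near half the winning
  # frequency, separated from the main peak by a real spectral valley
  # (guards against the mainlobe skirt of short windows, which reaches
  # fcc/2 at Tw = 2 s without being a peak)
  f_half <- spec$freq[ipk] / 2
  hw <- harm_halfwidth(cfg, spec$df, f_half)
  sub_idx <- in_band[spec$freq[in_band] >= f_half - hw &
                     spec$freq[in_band] <= f_half + hw]
  isub <- local_peak(mag, sub_idx, strict = TRUE)
  if (!is.na(isub) && mag[isub] >= cfg$subharmonic_ratio * mag[ipk]) {
    valley <- min(mag[isub:ipk])
    if (valley < 0.5 * mag[isub]) ipk <- isub
  }

  if (cfg$refine_peak && ipk > 1L && ipk < length(mag)) {
    fcc <- spec$freq[ipk] + parabolic_offset(mag, ipk) * spec$df
  } else {
    fcc <- spec$freq[ipk]
  }
  fcc
}

# Robust noise-floor estimate: median magnitude above the highest
# possible harmonic location (3 x band top), where no compression content
# can live. Inside the search band the mainlobes of short windows can
# cover most bins, which would inflate an in-band median. Falls back to
# the in-band median when the record leaves no room above the band.
spectrum_noise_floor <- function(spec, cfg) {
  lo <- 3 * cfg$band[2]
  idx <- which(spec$freq > lo)
  if (length(idx) < 16L)
    idx <- which(spec$freq >= cfg$band[1] & spec$freq <= cfg$band[2])
  stats::median(Mod(spec$spectrum[idx]))
}

harm_halfwidth <- function(cfg, df, fcc) {
  if (!is.null(cfg$harmonic_halfwidth)) return(cfg$harmonic_halfwidth)
  max(1.5 * df, 0.1 * fcc)
}

parabolic_offset <- function(mag, i) {
  a <- mag[i - 1L]; b <- mag[i]; cc <- mag[i + 1L]
  den <- a - 2 * b + cc
  if (abs(den) < .Machine$double.eps) return(0)
  delta <- 0.5 * (a - cc) / den
  max(-0.5, min(0.5, delta))
}

#' Harmonic set
#'
#' Fundamental frequency plus the first N harmonic amplitudes and phases
#' of the acceleration model, together with the displacement harmonics
#' derived from the second-derivative relation
#' `S_k = 1000 * A_k / (2 pi k fcc)^2` (mm) and `phi_k = theta_k + pi`.
#'
#' @param fcc fundamental frequency in Hz (> 0).
#' @param A amplitudes `A_k` in m/s^2 (k = 1..N, all >= 0).
#' @param theta phases `theta_k` in rad.
#' @return An object of class `harmonic_set` with fields `fcc`, `N`, `A`,
#'   `theta`, `S` (mm), `phi` (rad, wrapped to `[0, 2*pi)`).
#' @export
harmonic_set <- function(fcc, A, theta) {
  stopifnot(is.finite(fcc), fcc > 0, length(A) == length(theta), all(A >= 0))
  k <- seq_along(A)
  S <- 1000 * A / (2 * pi * k * fcc)^2
  phi <- (theta + pi) %% (2 * pi)
  structure(list(fcc = fcc, N = length(A), A = as.numeric(A),
                 theta = as.numeric(theta), S = S, phi = phi),
            class = "harmonic_set")
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("<harmonic_set> fcc = %.4f Hz (%.1f min^-1), N = %d\n",
              x$fcc, 60 * x$fcc, x$N))
  for (k in seq_len(x$N))
    cat(sprintf("  k=%d: A = %.4f m/s^2, theta = %+.3f rad, S = %.3f mm\n",
                k, x$A[k], x$theta[k], x$S[k]))
  invisible(x)
}

#' Estimate the first N harmonics from a spectrum
#'
#' For each `k = 1..N`, locates the local magnitude maximum within
#' `harmonic_halfwidth` of `k * fcc`, reads the acceleration amplitude as
#' `2 * |X| / sum(w)` (undoing the Hamming coherent gain) and the phase
#' as the complex argument at that bin. Harmonics whose expected location
#' is at or above Nyquist, or whose peak does not rise above the spectrum
#' noise floor, are zeroed.
#'
#' @param spec a `cpr_spectrum`.
#' @param fcc fundamental frequency in Hz.
#' @param cfg a [spectral_config()].
#' @return A [harmonic_set()].
#' @export
estimate_harmonics <- function(spec, fcc, cfg = spectral_config()) {
  stopifnot(inherits(spec, "cpr_spectrum"), is.finite(fcc), fcc > 0)
  mag <- Mod(spec$spectrum)
  # harmonics must clear both the broadband noise floor and the Hamming
  # sidelobe level (~ -43 dB) of the strongest component
  floor_mag <- max(3 * spectrum_noise_floor(spec, cfg), 0.01 * max(mag))
  A <- numeric(cfg$n_harmonics)
  theta <- numeric(cfg$n_harmonics)
  for (k in seq_len(cfg$n_harmonics)) {
    fk <- k * fcc
    if (fk >= spec$fs / 2) next
    hw <- harm_halfwidth(cfg, spec$df, fcc)
    idx <- which(spec$freq >= fk - hw & spec$freq <= fk + hw)
    i <- local_peak(mag, idx)
    if (is.na(i)) next
    if (k > 1L && mag[i] <= floor_mag) next  # below noise floor: zeroed
    A[k] <- 2 * mag[i] / spec$coherent_sum
    # re-reference the phase to the window centre: the symmetric taper
    # carries linear phase -2*pi*f*(n-1)/(2*fs), which at bin-quantized
    # frequencies would skew the relative harmonic phases and distort the
    # reconstructed cycle shape
    theta[k] <- Arg(spec$spectrum[i]) +
      2 * pi * spec$freq[i] * (spec$n - 1) / (2 * spec$fs)
  }
  theta <- ((theta + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
  harmonic_set(fcc, A, theta)
}

#' Reconstruct one displacement cycle from a harmonic set
#'
#' Evaluates `s(t) = sum_k S_k cos(2 pi k fcc t + phi_k)` (mm) over one
#' full period on a uniform grid.
#'
#' @param h a [harmonic_set()].
#' @param samples_per_cycle grid resolution (default 256).
#' @return Numeric vector of displacements in mm with attribute `t`
#'   (seconds within the cycle).
#' @export
reconstruct_cycle <- function(h, samples_per_cycle = 256) {
  stopifnot(inherits(h, "harmonic_set"))
  t <- seq(0, 1 / h$fcc, length.out = samples_per_cycle + 1L)[seq_len(samples_per_cycle)]
  s <- rep(0, samples_per_cycle)
  for (k in seq_len(h$N))
    s <- s + h$S[k] * cos(2 * pi * k * h$fcc * t + h$phi[k])
  attr(s, "t") <- t
  s
}

#' Rate and depth feedback for one analysis window
#'
#' Runs the full spectral chain on a scalar window: Hamming window +
#' zero-padded FFT, fundamental estimation, harmonic estimation,
#' displacement-cycle reconstruction, and finally
#' `rate = 60 * fcc` (min^-1), `depth = max(s) - min(s)` (mm).
#'
#' @param win an [analysis_window()].
#' @param cfg a [spectral_config()].
#' @return A [feedback_estimate()] with `source = "spectral"`.
#' @export
feedback_from_window <- function(win, cfg = spectral_config()) {
  spec <- window_and_spectrum(win, cfg)
  fcc <- estimate_fundamental(spec, cfg)
  h <- estimate_harmonics(spec, fcc, cfg)
  cyc <- reconstruct_cycle(h)
  feedback_estimate(rate = 60 * fcc, depth = max(cyc) - min(cyc),
                    window_start = win$start, Tw = win$Tw,
                    source = "spectral")
}

#' Analyze a full record in consecutive windows
#'
#' Divides the record into non-overlapping consecutive analysis intervals
#' of duration `Tw` starting at `0, Tw, 2*Tw, ...` (any trailing partial
#' interval is discarded) and computes one feedback estimate per window.
#' Windows without detectable compression activity or periodicity yield a
#' gap row (`NA` rate/depth with the failure reason in `status`), never a
#' fabricated value.
#'
#' @param accel an [accel_record()] (already preprocessed).
#' @param Tw analysis-interval duration in seconds.
#' @param cfg a [spectral_config()].
#' @param mode axis-combination mode, see [project_axes()].
#' @return A data.frame with columns `window_start`, `Tw`, `rate`,
#'   `depth`, `status` (`"ok"` or the failure reason), `source`.
#' @export
analyze_session <- function(accel, Tw, cfg = spectral_config(),
                            mode = "principal") {
  stopifnot(inherits(accel, "accel_record"), Tw > 0)
  dur <- record_duration(accel)
  if (dur < Tw) stop("record shorter than one analysis interval")
  n_win <- floor(dur / Tw + 1e-9)
  starts <- (seq_len(n_win) - 1L) * Tw
  rows <- lapply(starts, function(st) {
    est <- tryCatch({
      win <- project_axes(accel, st, Tw, mode = mode)
      feedback_from_window(win, cfg)
    }, cpr_no_activity = function(e) e, cpr_no_periodicity = function(e) e)
    if (inherits(est, "condition")) {
      data.frame(window_start = st, Tw = Tw, rate = NA_real_,
                 depth = NA_real_, status = conditionMessage(est),
                 source = "spectral", stringsAsFactors = FALSE)
    } else {
      data.frame(window_start = st, Tw = Tw, rate = est$rate,
                 depth = est$depth, status = "ok", source = "spectral",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
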