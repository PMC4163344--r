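#' Low-pass filter a record (3rd-order Butterworth)
#'
#' Suppresses high-frequency noise before analysis. Each channel is
#' filtered independently with a digital Butterworth low-pass filter.
#' By default the filter is applied forward and backward (zero-phase),
#' which doubles the attenuation and introduces no group delay, keeping
#' method and reference windows aligned in offline evaluation. Set
#' `zero_phase = FALSE` for a causal single pass, as a real-time device
#' would apply.
#'
#' @param record an [accel_record()] or [disp_record()].
#' @param cutoff_hz cut-off frequency in Hz (default 15).
#' @param order filter order (default 3).
#' @param zero_phase apply forward-backward filtering (default `TRUE`).
#' @return A record of the same type, same length and sampling rate.
#' @export
lowpass_record <- function(record, cutoff_hz = 15, order = 3, zero_phase = TRUE) {
  stopifnot(inherits(record, "cpr_record"))
  if (record$fs <= 2 * cutoff_hz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz cut-off (need fs > %g)",
                 record$fs, cutoff_hz, 2 * cutoff_hz))
  bf <- signal::butter(order, cutoff_hz / (record$fs / 2), type = "low")
  apply_fn <- function(x) {
    if (length(x) == 0L) return(x)
    if (zero_phase) filtfilt_padded(bf, x)
    else as.numeric(signal::filter(bf, x))
  }
  out <- record
  if (is.matrix(record$samples)) {
    out$samples <- apply(record$samples, 2, apply_fn)
    if (!is.matrix(out$samples))  # single-row records
      out$samples <- matrix(out$samples, nrow = 1,
                            dimnames = list(NULL, colnames(record$samples)))
  } else {
    out$samples <- apply_fn(record$samples)
  }
  out
}

# zero-phase filtering with odd-reflection padding at both ends so that
# step-like record boundaries (e.g. the constant gravity component) do
# not ring into the first and last analysis windows
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (max(length(bf$b), length(bf$a)) - 1L) * 30L)
  if (npad < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad, by = -1L)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(bf, y))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(npad + 1L):(npad + n)]
}

#' Resample a record to a new sampling rate
#'
#' The record is assumed to be band-limited below `fs_out / 2` already
#' (normally by [lowpass_record()]), so no further anti-alias filtering
#' is applied: integer decimation factors reduce to exact polyphase
#' subsampling, and non-integer ratios use Hann-windowed sinc
#' interpolation onto the output grid. Duration is preserved to within
#' one output sample.
#'
#' @param record an [accel_record()] or [disp_record()].
#' @param fs_out target sampling rate in Hz (default 100).
#' @return A record of the same type with `fs = fs_out`.
#' @export
resample_record <- function(record, fs_out = 100) {
  stopifnot(inherits(record, "cpr_record"))
  if (!is.finite(fs_out) || fs_out <= 0) stop("fs_out must be > 0")
  if (isTRUE(all.equal(fs_out, record$fs))) return(record)
  n_in <- n_samples(record)
  n_out <- floor(n_in * fs_out / record$fs)
  ratio <- record$fs / fs_out
  res_fn <- function(x) resample_vector(x, ratio, n_out)
  out <- record
  if (is.matrix(record$samples)) {
    out$samples <- vapply(seq_len(ncol(record$samples)), function(j)
      res_fn(record$samples[, j]), numeric(n_out))
    if (!is.matrix(out$samples))
      out$samples <- matrix(out$samples, nrow = n_out)
    colnames(out$samples) <- colnames(record$samples)
  } else {
    out$samples <- res_fn(record$samples)
  }
  out$fs <- fs_out
  out
}

resample_vector <- function(x, ratio, n_out, taps = 16L) {
  n <- length(x)
  if (abs(ratio - round(ratio)) < 1e-9) {   # exact polyphase subsampling
    idx <- 1L + round(ratio) * (seq_len(n_out) - 1L)
    return(x[idx])
  }
  pos <- 1 + ratio * (seq_len(n_out) - 1)   # fractional input positions
  base <- floor(pos)
  frac <- pos - base
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  for (m in (-taps + 1L):taps) {
    i <- base + m
    u <- frac - m                 # offset in input samples
    w <- hann_sinc(u, taps)
    ok <- i >= 1L & i <= n
    y[ok] <- y[ok] + w[ok] * x[i[ok]]
    wsum[ok] <- wsum[ok] + w[ok]  # renormalise near the edges
  }
  y / wsum
}

hann_sinc <- function(u, taps) {
  s <- ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u))
  s * 0.5 * (1 + cos(pi * u / taps)) * (abs(u) <= taps)
}

#' Standard signal conditioning chain
#'
#' Low-pass filters at `cutoff_hz` and resamples to `fs_out` — the
#' conditioning applied to every record before analysis.
#'
#' @inheritParams lowpass_record
#' @inheritParams resample_record
#' @return A conditioned record.
#' @export
preprocess_record <- function(record, cutoff_hz = 15, fs_out = 100,
                              zero_phase = TRUE) {
  resample_record(lowpass_record(record, cutoff_hz = cutoff_hz,
                                 zero_phase = zero_phase),
                  fs_out = fs_out)
}
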