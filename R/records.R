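#' Triaxial acceleration record
#'
#' A uniformly sampled sternal acceleration time-series. The three columns
#' are the accelerometer axes (ax, ay, az) in m/s^2; `fs` is the sampling
#' rate in Hz and `t0` the time of the first sample in seconds.
#'
#' @param samples numeric matrix (or coercible) with 3 columns, in m/s^2.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds.
#' @param meta optional [session_meta()] describing the recording session.
#' @return An object of class `accel_record`.
#' @export
accel_record <- function(samples, fs, t0 = 0, meta = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("accel_record requires exactly three channels (ax, ay, az)")
  if (nrow(samples) < 1L)
    stop("accel_record requires at least one sample")
  storage.mode(samples) <- "double"
  colnames(samples) <- c("ax", "ay", "az")
  new_record(samples, fs, t0, meta, "accel_record")
}

#' Chest displacement record
#'
#' A uniformly sampled compression-depth (CD) signal in mm. Zero is the
#' resting chest position; positive values mean the chest is compressed.
#' Negative values (recoil overshoot) are permitted.
#'
#' @param samples numeric vector of displacements in mm.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds.
#' @param meta optional [session_meta()].
#' @return An object of class `disp_record`.
#' @export
disp_record <- function(samples, fs, t0 = 0, meta = NULL) {
  samples <- as.numeric(samples)
  new_record(samples, fs, t0, meta, "disp_record")
}

new_record <- function(samples, fs, t0, meta, cls) {
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate fs must be a single finite value > 0")
  if (any(!is.finite(samples)))
    stop("record samples must all be finite")
  if (!is.null(meta) && !inherits(meta, "session_meta"))
    stop("meta must be a session_meta object")
  structure(
    list(samples = samples, fs = fs, t0 = as.numeric(t0), meta = meta),
    class = c(cls, "cpr_record")
  )
}

#' Session metadata
#'
#' Describes one recording session: who compressed, the targeted rate and
#' depth, and whether the accelerometer was aligned with the chest normal
#' (`regular`) or misaligned (`tilt`, canonically by 18 degrees).
#'
#' @param rescuer_id label for the rescuer.
#' @param target_rate targeted compression rate in min^-1.
#' @param target_depth targeted compression depth in mm.
#' @param session_kind `"regular"` or `"tilt"`.
#' @param tilt_deg sensor misalignment in degrees; defaults to 0 for
#'   regular sessions and 18 for tilt sessions. Other angles are allowed
#'   for extended experiments.
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(rescuer_id = NA_character_, target_rate = NA_real_,
                         target_depth = NA_real_,
                         session_kind = c("regular", "tilt"),
                         tilt_deg = NULL) {
  session_kind <- match.arg(session_kind)
  if (is.null(tilt_deg))
    tilt_deg <- if (session_kind == "tilt") 18 else 0
  structure(
    list(rescuer_id = as.character(rescuer_id),
         target_rate = as.numeric(target_rate),
         target_depth = as.numeric(target_depth),
         session_kind = session_kind,
         tilt_deg = as.numeric(tilt_deg)),
    class = "session_meta"
  )
}

#' Number of samples in a record
#' @param x a `cpr_record`.
#' @return integer sample count.
#' @export
n_samples <- function(x) {
  if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
}

#' Record duration in seconds
#' @param x a `cpr_record`.
#' @return duration `n_samples(x) / fs` in seconds.
#' @export
record_duration <- function(x) n_samples(x) / x$fs

#' Sample times of a record
#' @param x a `cpr_record`.
#' @return numeric vector `t0 + (0:(n-1))/fs`.
#' @export
record_times <- function(x) x$t0 + (seq_len(n_samples(x)) - 1L) / x$fs

#' @export
print.cpr_record <- function(x, ...) {
  kind <- if (inherits(x, "accel_record")) "acceleration (m/s^2, 3 axes)"
          else "chest displacement (mm)"
  cat(sprintf("<%s> %s: %d samples @ %g Hz (%.2f s)\n",
              class(x)[1], kind, n_samples(x), x$fs, record_duration(x)))
  if (!is.null(x$meta))
    cat(sprintf("  session: %s, target %g min^-1 x %g mm, tilt %g deg\n",
                x$meta$session_kind, x$meta$target_rate,
                x$meta$target_depth, x$meta$tilt_deg))
  invisible(x)
}

#' Per-window feedback estimate
#'
#' One (rate, depth) feedback value for a single analysis window, with the
#' window bounds and the provenance of the estimate.
#'
#' @param rate compression rate in min^-1 (> 0).
#' @param depth compression depth in mm (>= 0).
#' @param window_start window start time in s.
#' @param Tw window duration in s.
#' @param source one of `"spectral"`, `"reference"`, `"baseline"`.
#' @return An object of class `feedback_estimate`.
#' @export
feedback_estimate <- function(rate, depth, window_start, Tw,
                              source = c("spectral", "reference", "baseline")) {
  source <- match.arg(source)
  if (!is.finite(rate) || rate <= 0) stop("rate must be finite and > 0")
  if (!is.finite(depth) || depth < 0) stop("depth must be finite and >= 0")
  structure(
    list(rate = rate, depth = depth, window_start = window_start,
         Tw = Tw, source = source),
    class = "feedback_estimate"
  )
}

#' @export
print.feedback_estimate <- function(x, ...) {
  cat(sprintf("<feedback_estimate:%s> window [%.2f, %.2f) s: rate %.1f min^-1, depth %.1f mm\n",
              x$source, x$window_start, x$window_start + x$Tw, x$rate, x$depth))
  invisible(x)
}
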