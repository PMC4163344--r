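# Gold-standard side of the evaluation: compressions are annotated in the
# displacement (CD) signal with a fixed-threshold peak detector, and
# per-window reference feedback is aggregated from the annotations.

#' Detect compressions in a displacement record
#'
#' Finds local maxima of the CD signal exceeding a fixed depth threshold,
#' enforcing a refractory period between accepted peaks (taller peaks
#' win). The peak depth is the sample value at the maximum, i.e. the
#' displacement from the resting chest position.
#'
#' @param cd a [disp_record()] (already preprocessed).
#' @param threshold_mm minimum peak depth in mm (default 15).
#' @param refractory_s minimum separation between accepted peaks in
#'   seconds (default 0.25, a 240 min^-1 ceiling).
#' @return A data.frame of class `compression_annotations` with columns
#'   `peak_time` (s) and `peak_depth` (mm), ordered by time.
#' @export
detect_compressions <- function(cd, threshold_mm = 15, refractory_s = 0.25) {
  stopifnot(inherits(cd, "disp_record"))
  x <- cd$samples
  n <- length(x)
  empty <- data.frame(peak_time = numeric(0), peak_depth = numeric(0))
  class(empty) <- c("compression_annotations", "data.frame")
  if (n < 3L) return(empty)
  # local maxima: >= left neighbour, > right neighbour (left edge of plateaus)
  i <- 2:(n - 1L)
  is_pk <- x[i] >= x[i - 1L] & x[i] > x[i + 1L] & x[i] > threshold_mm
  pk <- i[is_pk]
  if (length(pk) == 0L) return(empty)
  # refractory: accept taller peaks first, reject any within refractory_s
  ord <- pk[order(x[pk], decreasing = TRUE)]
  min_gap <- refractory_s * cd$fs
  kept <- integer(0)
  for (p in ord) {
    if (length(kept) == 0L || all(abs(kept - p) >= min_gap))
      kept <- c(kept, p)
  }
  kept <- sort(kept)
  out <- data.frame(peak_time = cd$t0 + (kept - 1L) / cd$fs,
                    peak_depth = x[kept])
  class(out) <- c("compression_annotations", "data.frame")
  out
}

#' Reference feedback for one analysis window
#'
#' Aggregates annotated compressions whose peaks fall inside the
#' half-open window `[window_start, window_start + Tw)`:
#' `rate = 60 / agg(inter-peak intervals)` and `depth = agg(peak depths)`,
#' with `agg` the mean by default (median available). At least two peaks
#' are required.
#'
#' @param annotations output of [detect_compressions()].
#' @param window_start window start in s.
#' @param Tw window duration in s.
#' @param agg `"mean"` (default) or `"median"`.
#' @return A [feedback_estimate()] with `source = "reference"`.
#' @export
reference_feedback <- function(annotations, window_start, Tw,
                               agg = c("mean", "median")) {
  agg <- match.arg(agg)
  aggfun <- if (agg == "mean") mean else stats::median
  sel <- annotations$peak_time >= window_start &
         annotations$peak_time < window_start + Tw
  tt <- annotations$peak_time[sel]
  dd <- annotations$peak_depth[sel]
  if (length(tt) < 2L)
    stop(structure(class = c("cpr_insufficient_reference", "error", "condition"),
                   list(message = "insufficient reference compressions in window",
                        call = sys.call())))
  feedback_estimate(rate = 60 / aggfun(diff(tt)), depth = aggfun(dd),
                    window_start = window_start, Tw = Tw,
                    source = "reference")
}

#' Reference feedback over consecutive windows
#'
#' Applies [reference_feedback()] on the same non-overlapping window grid
#' used by [analyze_session()], emitting gap rows where a window holds
#' fewer than two annotated compressions.
#'
#' @param annotations output of [detect_compressions()].
#' @param duration record duration in s (defines how many windows fit).
#' @param Tw window duration in s.
#' @param agg aggregation rule, see [reference_feedback()].
#' @return A data.frame with columns `window_start`, `Tw`, `rate`,
#'   `depth`, `status`, `source`.
#' @export
reference_session <- function(annotations, duration, Tw, agg = "mean") {
  stopifnot(Tw > 0, duration >= Tw)
  n_win <- floor(duration / Tw + 1e-9)
  starts <- (seq_len(n_win) - 1L) * Tw
  rows <- lapply(starts, function(st) {
    est <- tryCatch(reference_feedback(annotations, st, Tw, agg = agg),
                    cpr_insufficient_reference = function(e) e)
    if (inherits(est, "condition")) {
      data.frame(window_start = st, Tw = Tw, rate = NA_real_,
                 depth = NA_real_, status = conditionMessage(est),
                 source = "reference", stringsAsFactors = FALSE)
    } else {
      data.frame(window_start = st, Tw = Tw, rate = est$rate,
                 depth = est$depth, status = "ok", source = "reference",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
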