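# Evaluation protocol: pair spectral-method and reference estimates per
# analysis window, then RMSE as a function of the interval length,
# Bland-Altman 95% limits of agreement at Tw = 3 s, per-condition
# median (5-95 percentile) summaries with Mann-Whitney U comparisons,
# and a naive double-integration baseline demonstrating the displacement
# drift the spectral method avoids.

#' Pair method and reference window estimates
#'
#' Joins two window tables produced on the same grid (same `Tw`, same
#' window starts). Only windows where both sources produced an estimate
#' become pairs; the number of excluded (gapped) windows per source is
#' attached as attribute `exclusions`.
#'
#' @param method data.frame from [analyze_session()].
#' @param reference data.frame from [reference_session()].
#' @return A data.frame of class `paired_feedback` with columns
#'   `window_start`, `Tw`, `method_rate`, `ref_rate`, `method_depth`,
#'   `ref_depth`.
#' @export
pair_windows <- function(method, reference) {
  if (nrow(method) != nrow(reference) ||
      (nrow(method) > 0 &&
       (!isTRUE(all.equal(method$window_start, reference$window_start)) ||
        !isTRUE(all.equal(method$Tw, reference$Tw)))))
    stop("method and reference were not computed on the same window grid")
  ok <- method$status == "ok" & reference$status == "ok"
  out <- data.frame(window_start = method$window_start[ok],
                    Tw = method$Tw[ok],
                    method_rate = method$rate[ok],
                    ref_rate = reference$rate[ok],
                    method_depth = method$depth[ok],
                    ref_depth = reference$depth[ok])
  attr(out, "exclusions") <- c(method = sum(method$status != "ok"),
                               reference = sum(reference$status != "ok"))
  class(out) <- c("paired_feedback", "data.frame")
  out
}

#' Root-mean-square error
#'
#' @param differences non-empty numeric vector of errors.
#' @return `sqrt(mean(differences^2))`.
#' @export
rmse <- function(differences) {
  if (length(differences) == 0L) stop("rmse of an empty vector")
  sqrt(mean(differences^2))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference (method minus reference); the 95% limits
#' of agreement are `bias +/- 1.96 * sd(differences)` (sample sd, n - 1).
#'
#' @param pairs a `paired_feedback` data.frame, or a numeric vector of
#'   differences.
#' @param quantity `"rate"` or `"depth"` (ignored when `pairs` is already
#'   a vector of differences).
#' @return A list of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, `sd`, `n`, plus `means` and `diffs` for plotting.
#' @export
bland_altman <- function(pairs, quantity = c("rate", "depth")) {
  if (is.data.frame(pairs)) {
    quantity <- match.arg(quantity)
    m <- pairs[[paste0("method_", quantity)]]
    r <- pairs[[paste0("ref_", quantity)]]
    d <- m - r
    mn <- (m + r) / 2
  } else {
    d <- as.numeric(pairs)
    mn <- rep(NA_real_, length(d))
    quantity <- "difference"
  }
  if (length(d) < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd = s, n = length(d),
                 quantity = quantity, means = mn, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman:%s> n = %d, bias = %+.3f, 95%% LOA = [%+.3f, %+.3f]\n",
              x$quantity, x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a [bland_altman()] result built from paired feedback.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = sprintf("mean of method and reference (%s)", x$quantity),
                 ylab = "method - reference", pch = 20, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. `U` is the number of (x, y) pairs
#' with `x > y` (ties counting one half). The two-sided p-value is exact
#' — full enumeration of all `choose(n + m, n)` group assignments of the
#' observed (possibly tied) ranks — whenever `min(n, m) <= 8` and the
#' enumeration stays below `max_enumeration`; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param max_enumeration enumeration budget for the exact path.
#' @return A list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, max_enumeration = 5e5) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (min(n, m) <= 8L && choose(N, n) <= max_enumeration) {
    us <- utils::combn(N, n, FUN = function(idx) sum(r[idx])) - n * (n + 1) / 2
    p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
    list(U = U, p = p, method = "exact")
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- U - mu
    z <- z - sign(z) * 0.5  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sig2)))
    list(U = U, p = p, method = "normal")
  }
}

#' Naive double-integration baseline
#'
#' Cumulative trapezoidal integration of the acceleration, twice, with
#' zero initial conditions and no drift compensation — the conventional
#' way accelerometer devices reconstruct the displacement, included to
#' demonstrate the drift that the spectral method avoids. A constant
#' acceleration offset `b` produces a terminal drift of
#' `1000 * b * t^2 / 2` mm.
#'
#' @param win an [analysis_window()] (scalar acceleration, m/s^2).
#' @return Numeric vector: displacement trace in mm, same length as the
#'   window.
#' @export
naive_double_integration <- function(win) {
  stopifnot(inherits(win, "analysis_window"))
  tt <- (seq_along(win$samples) - 1L) / win$fs
  v <- pracma::cumtrapz(tt, win$samples)
  s <- pracma::cumtrapz(tt, as.numeric(v))
  as.numeric(s) * 1000
}

#' Stream a benchmark design into window-level paired estimates
#'
#' For each record of the design: generate the session, condition both
#' signals ([preprocess_record()]), run the spectral method
#' ([analyze_session()]) and the reference annotator
#' ([detect_compressions()] + [reference_session()]) on the same
#' non-overlapping grid for every requested `Tw`, and pair the windows.
#' Records are generated one at a time and discarded, so the full
#' 320-record grid fits comfortably in memory.
#'
#' @param design a [benchmark_design()].
#' @param tws analysis-interval durations in s (default `c(2, 3, 4, 5)`).
#' @param cfg a [spectral_config()].
#' @param mode axis-combination mode for [project_axes()].
#' @param fs_out analysis sampling rate (default 100).
#' @param threshold_mm reference peak-detection threshold (default 15).
#' @param ... simulation overrides forwarded to [design_row_config()].
#' @return A data.frame: one row per paired window, with the design
#'   identifiers (`record_id`, `rescuer_id`, `session_kind`,
#'   `target_rate`, `target_depth`), `Tw`, `window_start`, and the four
#'   estimate columns of [pair_windows()].
#' @export
evaluate_benchmark <- function(design, tws = c(2, 3, 4, 5),
                               cfg = spectral_config(), mode = "principal",
                               fs_out = 100, threshold_mm = 15, ...) {
  out <- vector("list", nrow(design) * length(tws))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    ses <- generate_session(design_row_config(row, ...),
                            rescuer_id = row$rescuer_id)
    accel <- preprocess_record(ses$accel, fs_out = fs_out)
    cd <- preprocess_record(ses$cd, fs_out = fs_out)
    ann <- detect_compressions(cd, threshold_mm = threshold_mm)
    dur <- record_duration(accel)
    for (Tw in tws) {
      meth <- analyze_session(accel, Tw, cfg = cfg, mode = mode)
      ref <- reference_session(ann, dur, Tw)
      pr <- pair_windows(meth, ref)
      if (nrow(pr) == 0L) next
      k <- k + 1L
      out[[k]] <- cbind(data.frame(record_id = row$record_id,
                                   rescuer_id = row$rescuer_id,
                                   session_kind = row$session_kind,
                                   target_rate = row$target_rate,
                                   target_depth = row$target_depth,
                                   stringsAsFactors = FALSE),
                        as.data.frame(pr))
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' RMSE versus analysis-interval duration
#'
#' Pools the window-level rate and depth errors (method minus reference)
#' of [evaluate_benchmark()] output per session kind and `Tw`.
#'
#' @param pairs output of [evaluate_benchmark()].
#' @return A data.frame with columns `Tw`, `session_kind`, `n_windows`,
#'   `rate_rmse` (min^-1), `depth_rmse` (mm).
#' @export
rmse_vs_tw <- function(pairs) {
  sp <- split(pairs, list(pairs$Tw, pairs$session_kind), drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(Tw = d$Tw[1], session_kind = d$session_kind[1],
               n_windows = nrow(d),
               rate_rmse = rmse(d$method_rate - d$ref_rate),
               depth_rmse = rmse(d$method_depth - d$ref_depth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$session_kind, out$Tw), ]
  rownames(out) <- NULL
  out
}

#' Per-condition summary of mean rate and depth per record
#'
#' For each record, the mean method and reference rate and depth over its
#' windows at one `Tw`; then, per targeted condition and session kind,
#' the median and 5-95 percentiles (linear interpolation) of those
#' per-record means for both sources, with a Mann-Whitney U comparison of
#' method versus reference. Rate conditions group by target rate, depth
#' conditions by target depth — the unit is the record, not the window.
#'
#' @param pairs output of [evaluate_benchmark()]; only rows with the
#'   requested `Tw` are used.
#' @param Tw analysis-interval duration to summarize at (default 3).
#' @return A data.frame with one row per (quantity, target, session
#'   kind): `n_records`, reference and method `median`, `p5`, `p95`, and
#'   the Mann-Whitney `p_value`.
#' @export
summarize_by_condition <- function(pairs, Tw = 3) {
  d <- pairs[abs(pairs$Tw - Tw) < 1e-9, ]
  if (nrow(d) == 0L) stop("no pairs at the requested Tw")
  per_rec <- do.call(rbind, lapply(split(d, d$record_id), function(r) {
    data.frame(record_id = r$record_id[1], session_kind = r$session_kind[1],
               target_rate = r$target_rate[1], target_depth = r$target_depth[1],
               method_rate = mean(r$method_rate), ref_rate = mean(r$ref_rate),
               method_depth = mean(r$method_depth), ref_depth = mean(r$ref_depth),
               stringsAsFactors = FALSE)
  }))
  q <- function(x) stats::quantile(x, c(0.5, 0.05, 0.95), names = FALSE, type = 7)
  one <- function(recs, mcol, rcol, quantity, target) {
    qm <- q(recs[[mcol]]); qr <- q(recs[[rcol]])
    data.frame(quantity = quantity, target = target,
               session_kind = recs$session_kind[1], n_records = nrow(recs),
               ref_median = qr[1], ref_p5 = qr[2], ref_p95 = qr[3],
               method_median = qm[1], method_p5 = qm[2], method_p95 = qm[3],
               p_value = mann_whitney_u(recs[[mcol]], recs[[rcol]])$p,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (sk in unique(per_rec$session_kind)) {
    prs <- per_rec[per_rec$session_kind == sk, ]
    for (tr in sort(unique(prs$target_rate)))
      rows[[length(rows) + 1L]] <-
        one(prs[prs$target_rate == tr, ], "method_rate", "ref_rate", "rate", tr)
    for (td in sort(unique(prs$target_depth)))
      rows[[length(rows) + 1L]] <-
        one(prs[prs$target_depth == td, ], "method_depth", "ref_depth", "depth", td)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
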