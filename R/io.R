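# CSV dialect: leading comment-style header lines "# key=value" (fs_hz
# required; t0_s, rescuer_id, session_kind, tilt_deg, target_rate,
# target_depth optional), then a column-header row ("t,ax,ay,az" for
# acceleration, "t,cd_mm" for displacement), then numeric rows. UTF-8,
# '.' decimal separator, LF line endings. The time column is written for
# human inspection only and ignored on read: fs and t0 are authoritative.

ACCEL_COLS <- c("t", "ax", "ay", "az")
DISP_COLS  <- c("t", "cd_mm")

#' Read an acceleration or displacement record from CSV
#'
#' Parses the package's self-describing CSV dialect (see
#' [write_record()]). The sampling rate is taken from the `fs_hz` header
#' key; the time column in the file is ignored.
#'
#' @param path path to a CSV file.
#' @param kind `"accel"` (3 data channels) or `"displacement"` (1 channel).
#' @return An [accel_record()] or [disp_record()], with any session
#'   metadata found in the header attached as `meta`.
#' @export
read_record <- function(path, kind = c("accel", "displacement")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_hdr <- 0L
  while (n_hdr < length(lines) && startsWith(lines[n_hdr + 1L], "#"))
    n_hdr <- n_hdr + 1L
  keys <- parse_header_keys(lines[seq_len(n_hdr)])
  if (is.null(keys$fs_hz))
    stop("format error: missing required header line '# fs_hz=<value>' in ", path)
  fs <- suppressWarnings(as.numeric(keys$fs_hz))
  if (is.na(fs)) stop("format error: non-numeric fs_hz header in ", path)
  t0 <- if (!is.null(keys$t0_s)) as.numeric(keys$t0_s) else 0

  want <- if (kind == "accel") ACCEL_COLS else DISP_COLS
  if (n_hdr >= length(lines))
    stop("format error: no column-header row in ", path)
  cols <- strsplit(trimws(lines[n_hdr + 1L]), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(cols), want))
    stop(sprintf("format error in %s line %d: expected columns '%s', found '%s'",
                 path, n_hdr + 1L, paste(want, collapse = ","),
                 lines[n_hdr + 1L]))

  body <- lines[-seq_len(n_hdr + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    dat <- matrix(numeric(0), ncol = length(want))
  } else {
    parts <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(want)))
      stop(sprintf("parse error in %s data row %d: expected %d fields, found %d",
                   path, which(nf != length(want))[1], length(want),
                   nf[which(nf != length(want))[1]]))
    dat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                  ncol = length(want), byrow = TRUE)
    if (any(is.na(dat))) {
      bad <- which(apply(is.na(dat), 1, any))[1]
      stop(sprintf("parse error in %s data row %d: non-numeric value", path, bad))
    }
  }

  meta <- header_meta(keys)
  if (kind == "accel") {
    if (nrow(dat) < 1L)
      stop("parse error: acceleration record in ", path, " has no data rows")
    accel_record(dat[, 2:4, drop = FALSE], fs = fs, t0 = t0, meta = meta)
  } else {
    disp_record(dat[, 2], fs = fs, t0 = t0, meta = meta)
  }
}

parse_header_keys <- function(hlines) {
  keys <- list()
  for (i in seq_along(hlines)) {
    txt <- trimws(sub("^#", "", hlines[i]))
    if (!nzchar(txt)) next
    kv <- strsplit(txt, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("format error in header line %d: expected '# key=value', found '%s'",
                   i, hlines[i]))
    keys[[trimws(kv[1])]] <- trimws(kv[2])
  }
  keys
}

header_meta <- function(keys) {
  known <- c("rescuer_id", "session_kind", "tilt_deg", "target_rate", "target_depth")
  if (!any(known %in% names(keys))) return(NULL)
  session_meta(
    rescuer_id   = keys$rescuer_id %||% NA_character_,
    target_rate  = as.numeric(keys$target_rate %||% NA),
    target_depth = as.numeric(keys$target_depth %||% NA),
    session_kind = keys$session_kind %||% "regular",
    tilt_deg     = if (!is.null(keys$tilt_deg)) as.numeric(keys$tilt_deg) else NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a record to CSV
#'
#' Writes the dialect read by [read_record()]: `# key=value` header lines
#' (always `fs_hz` and `t0_s`, plus session metadata when present), a
#' column-header row, and one numeric row per sample with 12 significant
#' digits, so that a write/read round trip reproduces the samples to
#' better than 1e-9.
#'
#' @param record an [accel_record()] or [disp_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "cpr_record"))
  hdr <- c(sprintf("# fs_hz=%s", fmt_num(record$fs)),
           sprintf("# t0_s=%s", fmt_num(record$t0)))
  m <- record$meta
  if (!is.null(m)) {
    hdr <- c(hdr,
             sprintf("# rescuer_id=%s", m$rescuer_id),
             sprintf("# session_kind=%s", m$session_kind),
             sprintf("# tilt_deg=%s", fmt_num(m$tilt_deg)),
             sprintf("# target_rate=%s", fmt_num(m$target_rate)),
             sprintf("# target_depth=%s", fmt_num(m$target_depth)))
  }
  tt <- record_times(record)
  if (inherits(record, "accel_record")) {
    colrow <- paste(ACCEL_COLS, collapse = ",")
    body <- if (n_samples(record) > 0)
      paste(fmt_num(tt), fmt_num(record$samples[, 1]),
            fmt_num(record$samples[, 2]), fmt_num(record$samples[, 3]),
            sep = ",")
    else character(0)
  } else {
    colrow <- paste(DISP_COLS, collapse = ",")
    body <- if (n_samples(record) > 0)
      paste(fmt_num(tt), fmt_num(record$samples), sep = ",")
    else character(0)
  }
  con <- file(path, open = "wb")  # binary mode => LF endings everywhere
  on.exit(close(con))
  writeLines(c(hdr, colrow, body), con, sep = "\n")
  invisible(path)
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 12, width = 1)
  gsub(" ", "", out, fixed = TRUE)
}
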