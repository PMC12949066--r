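# Beat-interval (R-R) preprocessing: artifact correction, gap interpolation,
# exclusion bookkeeping and uniform 1 Hz heart-rate resampling.

#' Construct an R-R interval series
#'
#' An `rr_series` holds one subject's beat-to-beat intervals for one recording
#' session, together with the task-phase windows needed downstream. Timestamps
#' are seconds from session start and mark the *end* of each interval, so
#' consecutive timestamps differ by the preceding interval.
#'
#' @param subject_id Opaque subject identifier.
#' @param beats `data.frame` with columns `t` (seconds, strictly increasing)
#'   and `rr` (milliseconds, positive).
#' @param phase_marks `data.frame` with columns `phase`
#'   (one of `"baseline"`, `"story"`, `"discussion"`, `"other"`), `start_s`,
#'   `end_s`. Windows must be ordered and non-overlapping. May be empty.
#' @param session_id Opaque session identifier.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(subject_id, beats, phase_marks = NULL,
                      session_id = "s1") {
  stopifnot(is.data.frame(beats), all(c("t", "rr") %in% names(beats)))
  if (nrow(beats) == 0L) stop("rr_series: empty beat table")
  if (any(!is.finite(beats$rr)) || any(beats$rr <= 0))
    stop("rr_series: rr intervals must be positive and finite")
  if (is.unsorted(beats$t, strictly = TRUE))
    stop("rr_series: timestamps must be strictly increasing")
  if (is.null(phase_marks)) {
    phase_marks <- data.frame(phase = character(), start_s = numeric(),
                              end_s = numeric())
  } else {
    stopifnot(all(c("phase", "start_s", "end_s") %in% names(phase_marks)))
    if (nrow(phase_marks) > 1L) {
      o <- order(phase_marks$start_s)
      phase_marks <- phase_marks[o, , drop = FALSE]
      if (any(phase_marks$start_s[-1L] <
              phase_marks$end_s[-nrow(phase_marks)]))
        stop("rr_series: phase windows overlap")
    }
    bad <- !phase_marks$phase %in% c("baseline", "story", "discussion", "other")
    if (any(bad))
      stop("rr_series: unknown phase label(s): ",
           paste(unique(phase_marks$phase[bad]), collapse = ", "))
  }
  structure(list(subject_id = subject_id, session_id = session_id,
                 beats = beats[, c("t", "rr")], phase_marks = phase_marks),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject %s, session %s: %d beats over %.1f s\n",
              x$subject_id, x$session_id, nrow(x$beats),
              diff(range(x$beats$t))))
  if (nrow(x$phase_marks))
    cat("  phases:", paste(sprintf("%s [%g, %g]", x$phase_marks$phase,
                                   x$phase_marks$start_s,
                                   x$phase_marks$end_s), collapse = "; "),
        "\n")
  invisible(x)
}

new_preprocess_report <- function(subject_id, n_beats_in, n_modified,
                                  reasons = character()) {
  fraction <- if (n_beats_in > 0) n_modified / n_beats_in else NA_real_
  structure(list(subject_id = subject_id,
                 n_beats_in = n_beats_in,
                 n_modified = n_modified,
                 fraction_modified = fraction,
                 excluded = isTRUE(fraction >= 0.10),
                 reasons = reasons),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "<preprocess_report> %s: %d beats in, %d modified (%.1f%%) -> %s\n",
    x$subject_id, x$n_beats_in, x$n_modified, 100 * x$fraction_modified,
    if (x$excluded) "EXCLUDED" else "retained"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Read a beat-interval export file
#'
#' Reads the tabular R-R exports produced by chest-strap loggers: one beat per
#' row, interval in milliseconds, optionally with an explicit timestamp
#' column. When no timestamp column is present, timestamps are reconstructed
#' as the cumulative sum of intervals (each beat stamped at the end of its
#' interval).
#'
#' @param path Path to the export file.
#' @param dialect List describing the format: `sep` (default `","`), `header`
#'   (default `TRUE`), `rr_col` (name or index of the interval column, default
#'   the first column), `t_col` (optional timestamp column, seconds).
#' @param subject_id,session_id Identifiers attached to the series; default
#'   the file name.
#' @param phase_marks Optional phase window table (see [rr_series()]).
#' @return An [rr_series()].
#' @export
read_rr_export <- function(path, dialect = list(),
                           subject_id = basename(path), session_id = "s1",
                           phase_marks = NULL) {
  if (!file.exists(path)) stop("read_rr_export: no such file: ", path)
  sep <- dialect$sep %||% ","
  header <- dialect$header %||% TRUE
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop("read_rr_export: empty file: ", path)
  rr_col <- dialect$rr_col %||% 1L
  rr_chr <- raw[[rr_col]]
  rr <- suppressWarnings(as.numeric(rr_chr))
  if (any(is.na(rr))) {
    bad <- which(is.na(rr))[1L]
    stop(sprintf(
      "read_rr_export: non-numeric rr value %s at data line %d of %s",
      dQuote(rr_chr[bad]), bad + as.integer(header), path))
  }
  if (!is.null(dialect$t_col)) {
    t <- suppressWarnings(as.numeric(raw[[dialect$t_col]]))
    if (any(is.na(t))) {
      bad <- which(is.na(t))[1L]
      stop(sprintf(
        "read_rr_export: non-numeric timestamp at data line %d of %s",
        bad + as.integer(header), path))
    }
  } else {
    t <- cumsum(rr) / 1000
  }
  rr_series(subject_id, data.frame(t = t, rr = rr), phase_marks,
            session_id = session_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove beat-interval outliers
#'
#' Drops every beat whose interval differs from the previous *retained*
#' interval by strictly more than `threshold` (relative change). Comparing
#' against the last retained beat means a run of artifactual values is removed
#' in full instead of only its first element. The first beat is always kept.
#' Removed beats leave gaps that [interpolate_gaps()] fills afterwards.
#'
#' @param series An [rr_series()].
#' @param threshold Relative change above which a beat is an outlier
#'   (default 0.30; a change of exactly 30\% is retained).
#' @return `list(series = <rr_series>, report = <preprocess_report>)` where
#'   `n_modified` counts removed beats.
#' @export
correct_outliers <- function(series, threshold = 0.30) {
  stopifnot(inherits(series, "rr_series"))
  if (!(threshold > 0 && threshold < 1))
    stop("correct_outliers: threshold must lie in (0, 1)")
  rr <- series$beats$rr
  n <- length(rr)
  keep <- logical(n)
  keep[1L] <- TRUE
  prev <- rr[1L]
  if (n > 1L) for (i in 2L:n) {
    if (abs(rr[i] - prev) / prev <= threshold) {
      keep[i] <- TRUE
      prev <- rr[i]
    }
  }
  out <- series
  out$beats <- series$beats[keep, , drop = FALSE]
  rownames(out$beats) <- NULL
  n_removed <- sum(!keep)
  rep <- new_preprocess_report(
    series$subject_id, n, n_removed,
    reasons = if (n_removed)
      sprintf("%d beat(s) removed by the %.0f%% outlier rule",
              n_removed, 100 * threshold))
  list(series = out, report = rep)
}

#' Fill long inter-beat gaps by linear interpolation
#'
#' Any gap between consecutive retained beats exceeding `max_gap_s` seconds is
#' filled with synthetic beats whose intervals ramp linearly between the two
#' flanking intervals; synthesized beat spacing equals the interpolated
#' interval itself. Gaps at the series boundary have no flanking value and are
#' left unfilled (noted in the report). Synthesized beats count as modified
#' data.
#'
#' @param series An [rr_series()].
#' @param max_gap_s Gap length (s) above which interpolation kicks in
#'   (default 2).
#' @return `list(series, report)`; `report$n_modified` counts synthesized
#'   beats (denominated by the *input* beat count).
#' @export
interpolate_gaps <- function(series, max_gap_s = 2.0) {
  stopifnot(inherits(series, "rr_series"))
  t <- series$beats$t
  rr <- series$beats$rr
  n <- length(t)
  reasons <- character()
  if (n < 2L) {
    return(list(series = series,
                report = new_preprocess_report(series$subject_id, n, 0L)))
  }
  gaps <- diff(t)
  fill_idx <- which(gaps > max_gap_s)
  pieces <- vector("list", length(fill_idx))
  n_new <- 0L
  for (k in seq_along(fill_idx)) {
    i <- fill_idx[k]
    t0 <- t[i]; t1 <- t[i + 1L]
    rr0 <- rr[i]; rr1 <- rr[i + 1L]
    # walk forward; each synthetic beat is spaced by the rr interpolated at
    # its own timestamp (solve T = prev + line(T)/1000, linear in T)
    tt <- numeric(); vv <- numeric()
    slope <- (rr1 - rr0) / (t1 - t0)
    cur <- t0
    repeat {
      nxt <- (cur + (rr0 - t0 * slope) / 1000) / (1 - slope / 1000)
      step <- nxt - cur
      if (nxt >= t1 - step / 2) break
      tt <- c(tt, nxt)
      vv <- c(vv, step * 1000)
      cur <- nxt
    }
    pieces[[k]] <- data.frame(t = tt, rr = vv)
    n_new <- n_new + length(tt)
  }
  if (n_new > 0L) {
    beats <- rbind(series$beats, do.call(rbind, pieces))
    beats <- beats[order(beats$t), , drop = FALSE]
    rownames(beats) <- NULL
    series$beats <- beats
    reasons <- c(reasons, sprintf(
      "%d beat(s) synthesized across %d gap(s) > %g s",
      n_new, length(fill_idx), max_gap_s))
  }
  # boundary gaps relative to phase windows cannot be filled (one flank only)
  if (nrow(series$phase_marks)) {
    for (j in seq_len(nrow(series$phase_marks))) {
      w <- series$phase_marks[j, ]
      inw <- series$beats$t >= w$start_s & series$beats$t <= w$end_s
      if (!any(inw)) next
      lead <- min(series$beats$t[inw]) - w$start_s
      tail_ <- w$end_s - max(series$beats$t[inw])
      if (lead > max_gap_s)
        reasons <- c(reasons, sprintf(
          "unfilled %.1f s boundary gap at start of phase %s", lead, w$phase))
      if (tail_ > max_gap_s)
        reasons <- c(reasons, sprintf(
          "unfilled %.1f s boundary gap at end of phase %s", tail_, w$phase))
    }
  }
  list(series = series,
       report = new_preprocess_report(series$subject_id, n, n_new, reasons))
}

#' Full beat-interval preprocessing
#'
#' Applies [correct_outliers()] then [interpolate_gaps()] and merges the two
#' reports under the study's counting convention: modified data = removed
#' beats + synthesized beats, denominated by the original beat count. A
#' subject is flagged excluded when the modified fraction reaches 10\%.
#'
#' @inheritParams correct_outliers
#' @inheritParams interpolate_gaps
#' @param exclude_at Modified-data fraction at or above which the recording is
#'   excluded (default 0.10).
#' @return `list(series, report)` with the combined report.
#' @export
preprocess_rr <- function(series, threshold = 0.30, max_gap_s = 2.0,
                          exclude_at = 0.10) {
  n_in <- nrow(series$beats)
  step1 <- correct_outliers(series, threshold)
  step2 <- interpolate_gaps(step1$series, max_gap_s)
  n_mod <- step1$report$n_modified + step2$report$n_modified
  rep <- new_preprocess_report(series$subject_id, n_in, n_mod,
                               c(step1$report$reasons, step2$report$reasons))
  rep$excluded <- rep$fraction_modified >= exclude_at
  if (rep$excluded)
    rep$reasons <- c(rep$reasons, sprintf(
      "excluded: %.1f%% of beats changed (limit %.0f%%)",
      100 * rep$fraction_modified, 100 * exclude_at))
  list(series = step2$series, report = rep)
}

#' Resample instantaneous heart rate onto a uniform grid
#'
#' Converts the beat-interval series within one phase window to instantaneous
#' heart rate (60000 / rr ms, in bpm) at beat times and interpolates onto a
#' uniform grid (default 1 Hz). Interpolation is monotone piecewise cubic
#' (Fritsch-Carlson), which cannot overshoot the beat-wise values; samples
#' outside the span of observed beats take the nearest observed rate and are
#' flagged invalid in `valid_mask`.
#'
#' @param series A preprocessed [rr_series()].
#' @param phase Phase label to extract; must be present in `phase_marks`.
#' @param rate Target sampling rate in Hz (default 1).
#' @param hr_bounds Plausibility range in bpm; values outside trigger a
#'   warning only (default `c(40, 220)`).
#' @return An object of class `uniform_hr`: list with `subject_id`,
#'   `phase_label`, `t0_s`, `rate`, `t` (absolute seconds), `hr` (bpm),
#'   `valid_mask`.
#' @export
resample_heart_rate <- function(series, phase, rate = 1.0,
                                hr_bounds = c(40, 220)) {
  stopifnot(inherits(series, "rr_series"))
  pm <- series$phase_marks
  w <- pm[pm$phase == phase, , drop = FALSE]
  if (nrow(w) == 0L)
    stop("resample_heart_rate: phase not present: ", phase)
  w <- w[1L, ]
  inw <- series$beats$t >= w$start_s & series$beats$t <= w$end_s
  if (sum(inw) < 10L)
    stop(sprintf(
      "resample_heart_rate: phase %s has %d beats (< 10), insufficient data",
      phase, sum(inw)))
  tb <- series$beats$t[inw]
  hrb <- 60000 / series$beats$rr[inw]
  grid <- seq(w$start_s, w$end_s, by = 1 / rate)
  f <- stats::splinefun(tb, hrb, method = "monoH.FC")
  hr <- f(grid)
  inside <- grid >= tb[1L] & grid <= tb[length(tb)]
  # constant extrapolation at the edges, flagged invalid
  hr[grid < tb[1L]] <- hrb[1L]
  hr[grid > tb[length(tb)]] <- hrb[length(hrb)]
  if (any(hr < hr_bounds[1L] | hr > hr_bounds[2L]))
    warning(sprintf(
      "resample_heart_rate: %s/%s has samples outside [%g, %g] bpm",
      series$subject_id, phase, hr_bounds[1L], hr_bounds[2L]))
  structure(list(subject_id = series$subject_id, phase_label = phase,
                 t0_s = w$start_s, rate = rate, t = grid, hr = hr,
                 valid_mask = inside),
            class = "uniform_hr")
}

#' @export
print.uniform_hr <- function(x, ...) {
  cat(sprintf(
    "<uniform_hr> %s/%s: %d samples at %g Hz, mean %.1f bpm\n",
    x$subject_id, x$phase_label, length(x$hr), x$rate, mean(x$hr)))
  invisible(x)
}

report_as_row <- function(rep) {
  data.frame(subject_id = rep$subject_id, n_beats_in = rep$n_beats_in,
             n_modified = rep$n_modified,
             fraction_modified = rep$fraction_modified,
             excluded = rep$excluded,
             reasons = paste(rep$reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}
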