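# Windowed high-frequency heart-rate-variability power from the R-R
# tachogram: 120 s windows shifted by 60 s, Hann-tapered periodogram of the
# 4 Hz resampled, detrended tachogram, integrated over 0.15-0.4 Hz.

#' One-sided power spectral density of a tapered, detrended tachogram window
#'
#' Internal workhorse shared by [hf_hrv_windows()] and its tests' oracle
#' comparisons. Linear detrend, Hann taper with power-loss compensation
#' (division by the mean squared taper), one-sided periodogram density in
#' ms^2/Hz so that the integral over frequency approximates the variance of
#' the detrended signal.
#'
#' @param x Numeric vector (evenly sampled tachogram values, ms).
#' @param fs Sampling rate (Hz).
#' @param taper `"hann"` (default) or `"none"`.
#' @return `data.frame(freq, psd)` for frequencies `fs/n * (1:(n/2))`.
#' @export
tachogram_psd <- function(x, fs, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  stopifnot(n >= 8L)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)) else
    rep(1, n)
  y <- x * w
  X <- stats::fft(y)
  half <- seq_len(floor(n / 2))
  psd <- 2 * Mod(X[half + 1L])^2 / (fs * n * mean(w^2))
  data.frame(freq = half * fs / n, psd = psd)
}

#' Integrate a power spectral density over a frequency band
#'
#' Each periodogram bin is treated as covering `[f - df/2, f + df/2)`; bins
#' fully inside the band contribute `psd * df`, boundary bins are weighted by
#' their overlap fraction with the band.
#'
#' @param psd `data.frame(freq, psd)` as returned by [tachogram_psd()].
#' @param band Length-2 numeric, band edges in Hz.
#' @return Band power (units of `psd` times Hz; ms^2 for a tachogram).
#' @export
band_power <- function(psd, band) {
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  df <- psd$freq[2L] - psd$freq[1L]
  lo <- psd$freq - df / 2
  hi <- psd$freq + df / 2
  overlap <- pmax(0, pmin(hi, band[2L]) - pmax(lo, band[1L]))
  sum(psd$psd * overlap)
}

#' Windowed high-frequency HRV power
#'
#' Slides a 120 s window in 60 s steps across one task phase of a
#' preprocessed beat-interval series and, per window, resamples the tachogram
#' at `resample_hz`, detrends it linearly, applies a Hann taper, and
#' integrates the one-sided periodogram over the high-frequency band
#' (0.15-0.4 Hz). Both the raw power (ms^2) and its natural logarithm -- the
#' usual modelling scale for HF HRV -- are returned.
#'
#' Windows in which unfilled gaps (inter-beat spacings above `max_gap_s`)
#' cover more than 20\% of the window are marked invalid.
#'
#' @param series A preprocessed [rr_series()].
#' @param phase Phase label present in the series' `phase_marks`.
#' @param band High-frequency band in Hz (default `c(0.15, 0.4)`).
#' @param window_s,shift_s Window length and shift in seconds (defaults
#'   120 and 60).
#' @param resample_hz Tachogram resampling rate for spectral estimation
#'   (default 4 Hz; independent of the 1 Hz grid used for synchrony).
#' @param max_gap_s Inter-beat spacing treated as an unfilled gap (default 2).
#' @return `data.frame` with one row per window: `subject_id`, `phase`,
#'   `window_index`, `t_start_s`, `t_end_s`, `hf_power`, `hf_log`, `valid`.
#' @export
hf_hrv_windows <- function(series, phase, band = c(0.15, 0.4),
                           window_s = 120, shift_s = 60, resample_hz = 4,
                           max_gap_s = 2.0) {
  stopifnot(inherits(series, "rr_series"))
  pm <- series$phase_marks
  w <- pm[pm$phase == phase, , drop = FALSE]
  if (nrow(w) == 0L) stop("hf_hrv_windows: phase not present: ", phase)
  w <- w[1L, ]
  L <- w$end_s - w$start_s
  if (L < window_s)
    stop(sprintf("hf_hrv_windows: phase %s lasts %.0f s (< %g s window)",
                 phase, L, window_s))
  n_win <- floor((L - window_s) / shift_s) + 1L
  rows <- vector("list", n_win)
  tb_all <- series$beats$t
  rr_all <- series$beats$rr
  for (k in seq_len(n_win)) {
    t0 <- w$start_s + (k - 1L) * shift_s
    t1 <- t0 + window_s
    inw <- tb_all >= t0 & tb_all <= t1
    tb <- tb_all[inw]
    rr <- rr_all[inw]
    valid <- TRUE
    hf <- NA_real_
    if (length(tb) >= 8L) {
      gaps <- diff(tb)
      uncovered <- sum(gaps[gaps > max_gap_s])
      lead <- tb[1L] - t0
      tail_ <- t1 - tb[length(tb)]
      uncovered <- uncovered + max(0, lead - max_gap_s) +
        max(0, tail_ - max_gap_s)
      if (uncovered > 0.2 * window_s) valid <- FALSE
    } else valid <- FALSE
    if (valid) {
      grid <- seq(t0, t1, by = 1 / resample_hz)
      tach <- stats::approx(tb, rr, xout = grid, rule = 2)$y
      psd <- tachogram_psd(tach, resample_hz)
      hf <- band_power(psd, band)
    }
    rows[[k]] <- data.frame(
      subject_id = series$subject_id, phase = phase, window_index = k,
      t_start_s = t0, t_end_s = t1, hf_power = hf,
      hf_log = if (is.na(hf) || hf <= 0) NA_real_ else log(hf),
      valid = valid, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
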