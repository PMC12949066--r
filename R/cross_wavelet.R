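# Continuous Morlet wavelet transform, dyadic cross-wavelet power,
# band-wise 20 s interval maxima (HF / LF synchrony) and pooled z-scoring.

#' Wavelet analysis settings
#'
#' Settings for the continuous Morlet transform used by the synchrony chain.
#' The frequency grid is geometric, `voices` scales per octave, spanning at
#' least `freq_range` (defaults cover both analysis bands, 0.031-0.5 Hz, at
#' 1 Hz sampling). Signals are zero-padded to `pad_factor` times the next
#' power of two before the FFT, and the cone of influence (the e-folding time
#' of the wavelet envelope at each scale) is computed for masking.
#'
#' @param omega0 Morlet center-frequency parameter (default 6, the field
#'   standard: admissible and near-analytic).
#' @param voices Scales per octave (default 12).
#' @param freq_range Frequency coverage in Hz (default `c(0.031, 0.5)`).
#' @param pad_factor Zero-padding multiplier on the next power of two
#'   (default 2; pushes circular wrap-around leakage below numerical
#'   tolerance).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(omega0 = 6, voices = 12,
                         freq_range = c(0.031, 0.5), pad_factor = 2) {
  stopifnot(omega0 > 0, voices >= 1, length(freq_range) == 2L,
            freq_range[1L] > 0, freq_range[1L] < freq_range[2L])
  structure(list(omega0 = omega0, voices = voices, freq_range = freq_range,
                 pad_factor = pad_factor),
            class = "wavelet_spec")
}

# scale <-> Fourier frequency conversion for the Morlet wavelet
morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

wavelet_freq_grid <- function(spec) {
  ff <- spec$freq_range
  n_oct <- log2(ff[2L] / ff[1L])
  j <- 0:ceiling(n_oct * spec$voices)
  freqs <- ff[2L] * 2^(-j / spec$voices)
  if (freqs[length(freqs)] > ff[1L] * (1 + 1e-12)) freqs <- c(freqs, ff[1L])
  freqs
}

cwt_input <- function(hr, dt) {
  if (inherits(hr, "uniform_hr")) {
    list(x = hr$hr, dt = 1 / hr$rate, times = hr$t)
  } else {
    if (is.null(dt)) stop("cwt: dt required for a plain numeric vector")
    list(x = as.numeric(hr), dt = dt, times = (seq_along(hr) - 1L) * dt)
  }
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform of a uniformly sampled heart-rate
#' trajectory (mean-centered internally) with the analytic Morlet mother
#' wavelet in the standard normalisation, where the discrete transform at
#' scale \eqn{s} equals
#' \deqn{W_b(s) = \sum_m x_m \sqrt{dt/s}\, \psi_0^*((m-b)\,dt/s),}
#' \eqn{\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}}. The
#' companion [cwt_morlet_direct()] evaluates that sum literally and serves as
#' the independent oracle in the test suite.
#'
#' @param hr A `uniform_hr` object (see [resample_heart_rate()]) or a plain
#'   numeric vector (then `dt` must be supplied).
#' @param spec A [wavelet_spec()].
#' @param dt Sampling interval in seconds (taken from `hr` when it is a
#'   `uniform_hr`).
#' @return An object of class `cwt`: `coef` (complex matrix, frequencies x
#'   times, frequencies descending), `freqs`, `scales`, `times` (absolute
#'   seconds), `coi_freq` (per-time lowest reliable frequency), `dt`, `spec`.
#' @export
cwt_morlet <- function(hr, spec = wavelet_spec(), dt = NULL) {
  inp <- cwt_input(hr, dt)
  x <- inp$x; dt <- inp$dt; times <- inp$times
  n <- length(x)
  freqs <- wavelet_freq_grid(spec)
  fourier_factor <- morlet_fourier_factor(spec$omega0)
  scales <- 1 / (freqs * fourier_factor)
  if (n * dt < 2 * sqrt(2) * max(scales))
    stop(sprintf(
      "cwt_morlet: %.0f s signal is shorter than twice the largest wavelet support (%.0f s)",
      n * dt, 2 * sqrt(2) * max(scales)))
  x <- x - mean(x)
  npad <- spec$pad_factor * 2^ceiling(log2(n))
  xpad <- c(x, rep(0, npad - n))
  Xf <- stats::fft(xpad)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * 2 * pi / (npad * dt)
  coef <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    # periodized spectrum of the *sampled* analytic Morlet: scales near the
    # Nyquist frequency alias, and the discrete kernel must reflect that to
    # agree with direct time-domain convolution
    psi_hat <- 0
    for (m in -1:1)
      psi_hat <- psi_hat +
        exp(-0.5 * (s * (omega + m * 2 * pi / dt) - spec$omega0)^2)
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-0.25) * psi_hat
    wj <- stats::fft(Xf * psi_hat, inverse = TRUE) / npad
    coef[j, ] <- wj[seq_len(n)]
  }
  tt <- times - times[1L]
  edge <- pmin(tt, (n - 1L) * dt - tt)
  coi_period <- fourier_factor * sqrt(2) * pmax(edge, dt / 2)
  structure(list(coef = coef, freqs = freqs, scales = scales, times = times,
                 coi_freq = 1 / coi_period, dt = dt, spec = spec),
            class = "cwt")
}

#' Brute-force Morlet transform by direct convolution
#'
#' Literal O(n^2)-per-scale evaluation of the convolution sum documented in
#' [cwt_morlet()], kept free of FFTs so it can serve as an independent
#' reference on short signals.
#'
#' @inheritParams cwt_morlet
#' @return Same structure as [cwt_morlet()].
#' @export
cwt_morlet_direct <- function(hr, spec = wavelet_spec(), dt = NULL) {
  inp <- cwt_input(hr, dt)
  x <- inp$x; dt <- inp$dt; times <- inp$times
  n <- length(x)
  x <- x - mean(x)
  freqs <- wavelet_freq_grid(spec)
  fourier_factor <- morlet_fourier_factor(spec$omega0)
  scales <- 1 / (freqs * fourier_factor)
  coef <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  m <- seq_len(n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (b in m) {
      eta <- (m - b) * dt / s
      psi <- pi^(-0.25) * exp(1i * spec$omega0 * eta - 0.5 * eta^2)
      coef[j, b] <- sqrt(dt / s) * sum(x * Conj(psi))
    }
  }
  tt <- times - times[1L]
  edge <- pmin(tt, (n - 1L) * dt - tt)
  coi_period <- fourier_factor * sqrt(2) * pmax(edge, dt / 2)
  structure(list(coef = coef, freqs = freqs, scales = scales, times = times,
                 coi_freq = 1 / coi_period, dt = dt, spec = spec),
            class = "cwt")
}

#' Cross-wavelet power of two transforms
#'
#' Pointwise `|W_a * Conj(W_b)|`; the magnitude discards relative phase, so
#' in-phase and anti-phase co-oscillation score identically and the operation
#' is exactly symmetric in dyad member order.
#'
#' @param a,b `cwt` objects on identical time and scale grids.
#' @param dyad_id,phase_label Identifiers carried through to the output.
#' @return An object of class `xwt_spectrum`: `power` (non-negative matrix,
#'   frequencies x times), `freqs`, `times`, `coi_freq`, `dt`, `dyad_id`,
#'   `phase_label`.
#' @export
cross_power <- function(a, b, dyad_id = NA_character_,
                        phase_label = NA_character_) {
  stopifnot(inherits(a, "cwt"), inherits(b, "cwt"))
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9 ||
      length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-12)
    stop("cross_power: time/scale grids of the two transforms differ")
  structure(list(power = Mod(a$coef * Conj(b$coef)),
                 freqs = a$freqs, times = a$times,
                 coi_freq = pmin(a$coi_freq, b$coi_freq), dt = a$dt,
                 dyad_id = dyad_id, phase_label = phase_label),
            class = "xwt_spectrum")
}

#' Band-wise interval maxima of cross-wavelet power
#'
#' Reduces a cross-wavelet spectrum to one value per consecutive
#' non-overlapping `interval_s` interval (aligned to the start of the
#' spectrum): the maximum power over all time points in the interval and all
#' frequency bins whose center lies inside `band`. With `coi_mask = TRUE`
#' (default) samples below the cone of influence are excluded; an interval
#' whose band block is entirely masked yields `NA`.
#'
#' @param spectrum An `xwt_spectrum` from [cross_power()].
#' @param band Frequency band in Hz, e.g. `c(0.125, 0.5)` (HF) or
#'   `c(0.031, 0.125)` (LF).
#' @param interval_s Interval length in seconds (default 20).
#' @param coi_mask Exclude samples outside the cone of influence
#'   (default TRUE).
#' @return Numeric vector of per-interval maxima (length
#'   `floor(duration / interval_s)`).
#' @export
band_interval_max <- function(spectrum, band, interval_s = 20,
                              coi_mask = TRUE) {
  stopifnot(inherits(spectrum, "xwt_spectrum"), length(band) == 2L)
  if (band[1L] < min(spectrum$freqs) * (1 - 1e-9) ||
      band[2L] > max(spectrum$freqs) * (1 + 1e-9))
    stop("band_interval_max: band outside the spectrum's frequency coverage")
  in_band <- spectrum$freqs >= band[1L] & spectrum$freqs <= band[2L]
  pow <- spectrum$power[in_band, , drop = FALSE]
  if (coi_mask) {
    mask <- outer(spectrum$freqs[in_band], spectrum$coi_freq, `<`)
    pow[mask] <- NA_real_
  }
  rel_t <- spectrum$times - spectrum$times[1L]
  n_int <- floor((rel_t[length(rel_t)] + spectrum$dt) / interval_s)
  vapply(seq_len(n_int), function(k) {
    sel <- rel_t >= (k - 1L) * interval_s & rel_t < k * interval_s
    block <- pow[, sel, drop = FALSE]
    if (all(is.na(block))) NA_real_ else max(block, na.rm = TRUE)
  }, numeric(1))
}

#' Build a per-dyad synchrony series for one phase
#'
#' Convenience wrapper: cross-wavelet power of two heart-rate trajectories
#' followed by HF and LF interval maxima.
#'
#' @param hr_a,hr_b `uniform_hr` objects for the two dyad members, same phase.
#' @param dyad_id Dyad identifier.
#' @param spec A [wavelet_spec()].
#' @param hf_band,lf_band Analysis bands in Hz.
#' @param interval_s Interval length (default 20 s).
#' @param coi_mask Passed to [band_interval_max()].
#' @return `data.frame(dyad_id, phase, interval_index, hf_raw, lf_raw)`.
#' @export
synchrony_series <- function(hr_a, hr_b, dyad_id, spec = wavelet_spec(),
                             hf_band = c(0.125, 0.5),
                             lf_band = c(0.031, 0.125), interval_s = 20,
                             coi_mask = TRUE) {
  stopifnot(hr_a$phase_label == hr_b$phase_label)
  wa <- cwt_morlet(hr_a, spec)
  wb <- cwt_morlet(hr_b, spec)
  xp <- cross_power(wa, wb, dyad_id, hr_a$phase_label)
  hf <- band_interval_max(xp, hf_band, interval_s, coi_mask)
  lf <- band_interval_max(xp, lf_band, interval_s, coi_mask)
  data.frame(dyad_id = dyad_id, phase = hr_a$phase_label,
             interval_index = seq_along(hf), hf_raw = hf, lf_raw = lf,
             stringsAsFactors = FALSE)
}

#' Truncate synchrony series and z-score across the pooled sample
#'
#' Equalises task length across groups by keeping the first `story_min`
#' minutes of every story series and `discussion_min` minutes of every
#' discussion series (series from other phases are kept whole), then
#' z-scores each band against the mean and standard deviation pooled over all
#' retained dyads, phases, and intervals, so that per band the pooled mean is
#' 0 and the pooled SD is 1. Series shorter than their target are dropped
#' with a warning.
#'
#' @param synchrony `data.frame` as produced by row-binding
#'   [synchrony_series()] results; must contain `dyad_id`, `phase`,
#'   `interval_index`, `hf_raw`, `lf_raw`.
#' @param story_min,discussion_min Target lengths in minutes (defaults 8
#'   and 10).
#' @param interval_s Interval length used to convert minutes to bins
#'   (default 20 s).
#' @return The truncated table with added columns `hf_z`, `lf_z`.
#' @export
truncate_and_zscore <- function(synchrony, story_min = 8, discussion_min = 10,
                                interval_s = 20) {
  need <- c("dyad_id", "phase", "interval_index", "hf_raw", "lf_raw")
  stopifnot(all(need %in% names(synchrony)))
  bins_target <- function(phase) {
    switch(phase, story = story_min * 60 / interval_s,
           discussion = discussion_min * 60 / interval_s, Inf)
  }
  keep <- rep(TRUE, nrow(synchrony))
  key <- interaction(synchrony$dyad_id, synchrony$phase, drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    tgt <- bins_target(synchrony$phase[rows[1L]])
    if (is.finite(tgt) && length(rows) < tgt) {
      warning(sprintf(
        "truncate_and_zscore: dropping %s/%s (%d of %d required intervals)",
        synchrony$dyad_id[rows[1L]], synchrony$phase[rows[1L]],
        length(rows), tgt))
      keep[rows] <- FALSE
    } else if (is.finite(tgt)) {
      ord <- rows[order(synchrony$interval_index[rows])]
      keep[ord[-seq_len(tgt)]] <- FALSE
    }
  }
  out <- synchrony[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$hf_z <- zscore_pooled(out$hf_raw)
  out$lf_z <- zscore_pooled(out$lf_raw)
  out
}

zscore_pooled <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  sdv <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0)
    stop("zscore_pooled: pooled standard deviation is zero or undefined")
  (x - mu) / sdv
}
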