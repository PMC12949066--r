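# Shared fixture builders. Everything is generated in code; nothing binary.

# rr_series with constant intervals covering [0, dur_s]
constant_rr <- function(rr_ms = 800, dur_s = 160, phase = "story",
                        subject_id = "sX") {
  n <- ceiling(dur_s * 1000 / rr_ms)
  rr <- rep(rr_ms, n)
  rr_series(subject_id, data.frame(t = cumsum(rr) / 1000, rr = rr),
            data.frame(phase = phase, start_s = 0, end_s = dur_s))
}

# beats emitted from a time-varying rr function (ms), iterative emission
emitted_rr <- function(rr_fun, dur_s, phase = "story", subject_id = "sX") {
  t <- numeric(0)
  cur <- rr_fun(0) / 1000
  while (cur <= dur_s) {
    t <- c(t, cur)
    cur <- cur + rr_fun(cur) / 1000
  }
  rr <- diff(c(0, t)) * 1000
  rr_series(subject_id, data.frame(t = t, rr = rr),
            data.frame(phase = phase, start_s = 0, end_s = dur_s))
}

# write a one-column rr export CSV, return the path
write_rr_file <- function(rr, header = FALSE, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  path <- file.path(dir, "rr.csv")
  if (header) writeLines(c("rr_ms", rr), path) else
    writeLines(as.character(rr), path)
  path
}

# raw (untapered) one-sided periodogram band power of an evenly sampled
# signal -- the independent spectral oracle used against tachogram_psd
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2))
  freq <- half * fs / n
  psd <- 2 * Mod(X[half + 1L])^2 / (fs * n)
  sum(psd[freq >= band[1L] & freq <= band[2L]]) * fs / n
}

# a tiny deterministic two-subject coupled pair: shared sinusoidal drive at
# drive_hz added to both members' heart-rate processes, beats by
# integrate-and-fire; returns list of two rr_series covering one story phase
coupled_pair <- function(drive_hz, drive_amp, dur_s = 480, fs = 4,
                         base = c(80, 76), noise_sd = 0.5) {
  nt <- ceiling(dur_s * fs) + 1L
  tt <- (0:(nt - 1)) / fs
  drive <- drive_amp * sin(2 * pi * drive_hz * tt + stats::runif(1, 0, 2 * pi))
  lapply(1:2, function(i) {
    rate <- base[i] + drive + stats::rnorm(nt, 0, noise_sd)
    cum <- c(0, cumsum((rate[-1L] + rate[-nt]) / 2 / 60) / fs)
    bt <- stats::approx(cum, tt, xout = seq_len(floor(cum[nt])))$y
    rr <- diff(c(0, bt)) * 1000
    rr_series(paste0("p", i), data.frame(t = cumsum(rr) / 1000, rr = rr),
              data.frame(phase = "story", start_s = 0, end_s = dur_s))
  })
}

# mean band synchrony (raw interval maxima) of a pair of rr series
pair_band_mean <- function(pair, band, spec = wavelet_spec()) {
  hr <- lapply(pair, resample_heart_rate, phase = "story")
  xp <- cross_power(cwt_morlet(hr[[1]], spec), cwt_morlet(hr[[2]], spec))
  mean(band_interval_max(xp, band), na.rm = TRUE)
}
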