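test_that("read_rr_export reconstructs cumulative timestamps", {
  path <- write_rr_file(c(800, 810, 805))
  s <- read_rr_export(path, dialect = list(header = FALSE))
  expect_s3_class(s, "rr_series")
  expect_equal(s$beats$rr, c(800, 810, 805))
  expect_equal(s$beats$t, c(0.800, 1.610, 2.415))
})

test_that("read_rr_export honours an explicit timestamp column", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rr.csv")
  writeLines(c("t_s,rr_ms", "0.5,700", "1.2,710", "1.9,705"), path)
  s <- read_rr_export(path, dialect = list(rr_col = "rr_ms", t_col = "t_s"))
  expect_equal(s$beats$t, c(0.5, 1.2, 1.9))
  expect_equal(s$beats$rr, c(700, 710, 705))
})

test_that("read_rr_export reports the offending line and rejects empty files", {
  path <- write_rr_file(c("800", "oops", "805"))
  expect_error(read_rr_export(path, dialect = list(header = FALSE)),
               "line 2")
  empty <- file.path(withr::local_tempdir(), "empty.csv")
  file.create(empty)
  expect_error(read_rr_export(empty, dialect = list(header = FALSE)))
})

test_that("correct_outliers drops beats deviating > 30% from last retained", {
  s <- rr_series("a", data.frame(t = cumsum(c(800, 810, 1200, 805)) / 1000,
                                 rr = c(800, 810, 1200, 805)))
  res <- correct_outliers(s)
  expect_equal(res$series$beats$rr, c(800, 810, 805))
  expect_equal(res$report$n_modified, 1L)
  expect_equal(res$report$n_beats_in, 4L)
})

test_that("a change of exactly 30% is retained (strict inequality)", {
  s <- rr_series("a", data.frame(t = c(0.8, 1.84), rr = c(800, 1040)))
  res <- correct_outliers(s)
  expect_equal(res$series$beats$rr, c(800, 1040))
  expect_equal(res$report$n_modified, 0L)
})

test_that("runs of artifacts are removed in full (last-retained comparison)", {
  rr <- c(800, 1200, 1150, 820)
  s <- rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr))
  res <- correct_outliers(s)
  expect_equal(res$series$beats$rr, c(800, 820))
})

test_that("correct_outliers is idempotent and validates its threshold", {
  set.seed(42)
  rr <- 800 * exp(cumsum(stats::rnorm(200, 0, 0.08)))
  s <- rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr))
  once <- correct_outliers(s)
  twice <- correct_outliers(once$series)
  expect_equal(twice$series$beats, once$series$beats)
  expect_equal(twice$report$n_modified, 0L)
  expect_error(correct_outliers(s, threshold = 0), "threshold")
  expect_error(correct_outliers(s, threshold = 1.2), "threshold")
})

test_that("interpolate_gaps fills long gaps with a linear rr ramp", {
  s <- rr_series("a", data.frame(t = c(1.0, 6.0), rr = c(800, 900)))
  res <- interpolate_gaps(s)
  beats <- res$series$beats
  expect_gt(nrow(beats), 2L)
  expect_equal(res$report$n_modified, nrow(beats) - 2L)
  # oracle: every synthesized rr must equal the straight line between the
  # flanking beats evaluated at its own timestamp
  mid <- beats[beats$t > 1 & beats$t < 6, ]
  expected <- 800 + (mid$t - 1) / 5 * 100
  expect_equal(mid$rr, expected, tolerance = 1e-10)
  # and beat spacing must equal the interpolated interval
  expect_equal(diff(beats$t[-nrow(beats)]),
               head(beats$rr[-1], -1) / 1000, tolerance = 1e-10)
})

test_that("interpolate_gaps leaves short-gap series untouched and notes boundary gaps", {
  rr <- rep(800, 20)
  s <- rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr))
  res <- interpolate_gaps(s)
  expect_identical(res$series$beats, s$beats)
  expect_equal(res$report$n_modified, 0L)

  sb <- rr_series("b", data.frame(t = c(10, 10.8), rr = c(800, 800)),
                  data.frame(phase = "story", start_s = 0, end_s = 20))
  resb <- interpolate_gaps(sb)
  expect_identical(resb$series$beats, sb$beats)
  expect_true(any(grepl("boundary gap", resb$report$reasons)))
})

test_that("combined report counts removed + synthesized beats and applies the 10% rule", {
  # 10 beats, one spike: removal changes 1/10 of the data -> excluded
  # (spike height chosen so the removal gap stays <= 2 s: no resynthesis)
  rr <- c(rep(800, 5), 1100, rep(800, 4))
  s <- rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr))
  res <- preprocess_rr(s)
  expect_true(res$report$excluded)
  expect_equal(res$report$fraction_modified, 0.1)
  # conservation: n_out = n_in - removed + synthesized
  removed <- correct_outliers(s)$report$n_modified
  synthesized <- res$report$n_modified - removed
  expect_equal(nrow(res$series$beats), 10L - removed + synthesized)
})

test_that("exclusion boundary is exact at fraction 0.10", {
  base <- rep(800, 10000)
  spike_at <- function(k) {
    rr <- base
    rr[seq(5, by = 10, length.out = k)] <- 1100
    rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr))
  }
  res_below <- preprocess_rr(spike_at(999))   # fraction 0.0999
  res_at <- preprocess_rr(spike_at(1000))     # fraction 0.1000
  expect_equal(res_below$report$fraction_modified, 0.0999)
  expect_false(res_below$report$excluded)
  expect_equal(res_at$report$fraction_modified, 0.1)
  expect_true(res_at$report$excluded)
})

test_that("resample_heart_rate maps constant rr to constant bpm", {
  s <- constant_rr(750, dur_s = 60)
  hr <- resample_heart_rate(s, "story")
  expect_equal(unique(round(hr$hr, 9)), 80)
  expect_length(hr$hr, 61L)
})

test_that("resampled hr stays within the beat-wise value range", {
  rr <- rep(c(600, 1000), 60)
  s <- rr_series("a", data.frame(t = cumsum(rr) / 1000, rr = rr),
                 data.frame(phase = "story", start_s = 0, end_s = 90))
  hr <- resample_heart_rate(s, "story")
  expect_true(all(hr$hr >= 60 - 1e-9 & hr$hr <= 100 + 1e-9))
})

test_that("1 Hz resampling preserves a 0.25 Hz rr modulation", {
  s <- emitted_rr(function(t) 800 + 60 * sin(2 * pi * 0.25 * t),
                  dur_s = 256)
  hr <- resample_heart_rate(s, "story")
  x <- hr$hr - mean(hr$hr)
  n <- length(x)
  X <- Mod(stats::fft(x))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) / n
  expect_lt(abs(freqs[which.max(X)] - 0.25), 1.5 / n)
})

test_that("resample_heart_rate needs a phase window and enough beats", {
  s <- constant_rr(800, dur_s = 60)
  expect_error(resample_heart_rate(s, "discussion"), "phase")
  few <- rr_series("a", data.frame(t = cumsum(rep(800, 5)) / 1000,
                                   rr = rep(800, 5)),
                   data.frame(phase = "story", start_s = 0, end_s = 10))
  expect_error(resample_heart_rate(few, "story"), "insufficient")
})
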