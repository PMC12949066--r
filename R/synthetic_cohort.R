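# Fully seeded synthetic study generator: classroom groups, friendship
# networks, questionnaires, and coupled cardiac beat series with known
# (planted) dyadic coupling structure, so that the whole analysis chain can
# be validated end to end without any external data.

#' Synthetic cohort configuration
#'
#' All knobs of the generator, with defaults emulating the study population:
#' groups of 4-6 classmates, ~28\% mutual and ~14\% one-sided friendships,
#' a 5-minute baseline, 9-minute story and 11-minute discussion, and cardiac
#' rate processes with respiratory-band (RSA, ~0.25 Hz) and low-frequency
#' (~0.1 Hz) oscillations plus 1/f noise. Dyadic coupling is a shared
#' band-limited drive added to both members' rate processes: its
#' low-frequency weight is raised for friends (`kappa_lf_friend` vs
#' `kappa_lf_nonfriend`) and its high-frequency weight grows with the dyad's
#' planted negative affect (`beta_hf_negaffect`), so the analysis chain
#' should find higher LF synchrony in friends and higher HF synchrony under
#' negative affect.
#'
#' @param n_groups Number of groups.
#' @param group_size_range Inclusive group-size range (default 4-6).
#' @param p_mutual,p_one_sided Per-dyad friendship probabilities (defaults
#'   0.28 and 0.14).
#' @param gender_ratio Probability a subject is female (default 0.5).
#' @param seed Integer seed; fully determines every output.
#' @param phase_durations Named list of phase lengths in seconds (defaults
#'   baseline 300, story 540, discussion 660).
#' @param cardiac Named list: `mean_hr_bpm`, `sd_hr_bpm`, `rsa_freq_hz`,
#'   `rsa_amp`, `lf_freq_hz`, `lf_amp`, `noise_sd`, `sim_hz`.
#' @param coupling Named list: `kappa_lf_friend`, `kappa_lf_nonfriend`,
#'   `kappa_hf_base`, `beta_hf_negaffect`, plus the drive bands
#'   `lf_drive_band`, `hf_drive_band`.
#' @param effects Named list of planted questionnaire effects:
#'   `closeness_friend` (IOS shift for friends), `liking_friend`,
#'   `est_noise_sd` (affect estimation noise, controls empathic accuracy)
#'   and the nominal planted regression coefficients
#'   `lf_mutual` / `hf_valence` used by [score_recovery()].
#' @param artifact_spike,artifact_dropout Per-beat artifact probabilities
#'   (defaults 0, i.e. clean recordings).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_groups = 30,
                          group_size_range = c(4L, 6L),
                          p_mutual = 0.28, p_one_sided = 0.14,
                          gender_ratio = 0.5, seed = 1L,
                          phase_durations = list(baseline = 300, story = 540,
                                                 discussion = 660),
                          cardiac = list(), coupling = list(),
                          effects = list(),
                          artifact_spike = 0, artifact_dropout = 0) {
  cardiac_def <- list(mean_hr_bpm = 82, sd_hr_bpm = 6, rsa_freq_hz = 0.25,
                      rsa_amp = 2.5, lf_freq_hz = 0.1, lf_amp = 2.0,
                      noise_sd = 1.0, sim_hz = 4)
  coupling_def <- list(kappa_lf_friend = 1.15, kappa_lf_nonfriend = 0.6,
                       kappa_hf_base = 0.8, beta_hf_negaffect = 0.42,
                       lf_drive_band = c(0.05, 0.10),
                       hf_drive_band = c(0.20, 0.30))
  effects_def <- list(closeness_friend = 2.0, liking_friend = 0.5,
                      est_noise_sd = 0.8, lf_mutual = 0.24,
                      hf_valence = -0.09)
  cfg <- list(n_groups = n_groups,
              group_size_range = as.integer(group_size_range),
              p_mutual = p_mutual, p_one_sided = p_one_sided,
              gender_ratio = gender_ratio, seed = as.integer(seed),
              phase_durations = phase_durations,
              cardiac = utils::modifyList(cardiac_def, cardiac),
              coupling = utils::modifyList(coupling_def, coupling),
              effects = utils::modifyList(effects_def, effects),
              artifact_spike = artifact_spike,
              artifact_dropout = artifact_dropout)
  if (p_mutual < 0 || p_one_sided < 0 || p_mutual + p_one_sided > 1)
    stop("cohort_config: friendship probabilities must be in [0,1] and sum <= 1")
  if (cfg$group_size_range[1L] < 2L || cfg$group_size_range[2L] > 12L)
    stop("cohort_config: group_size_range must lie within [2, 12]")
  structure(cfg, class = "cohort_config")
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate the synthetic roster
#'
#' Groups, subjects (gender, age, height, weight, circular seat position)
#' and the per-dyad friendship network: each unordered within-group pair is
#' mutual with `p_mutual`, one-sided with `p_one_sided` (direction assigned
#' symmetrically at random), else unconnected. Anthropometrics follow
#' plausible distributions for 10-13-year-olds (age ~ N(11.3, 0.7) clipped
#' to 10-13; height ~ N(1.50, 0.08) m; weight from BMI ~ N(18.5, 2.5)).
#'
#' @param config A [cohort_config()]; the seed fully determines the roster.
#' @return `list(subjects = <data.frame>, dyads = <data.frame>,
#'   nominations = <data.frame>)`.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  size_choices <- seq(config$group_size_range[1L],
                      config$group_size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), config$n_groups,
                                   replace = TRUE)]
  subs <- list(); dyads <- list(); noms <- list()
  for (g in seq_len(config$n_groups)) {
    n <- sizes[g]
    gid <- sprintf("g%02d", g)
    ids <- sprintf("%s_s%d", gid, seq_len(n))
    age <- clip(stats::rnorm(n, 11.3, 0.7), 10, 13)
    height <- clip(stats::rnorm(n, 1.50, 0.08), 1.25, 1.80)
    bmi_true <- clip(stats::rnorm(n, 18.5, 2.5), 13, 30)
    subs[[g]] <- data.frame(
      subject_id = ids, group_id = gid,
      gender = ifelse(stats::runif(n) < config$gender_ratio,
                      "female", "male"),
      age = round(age, 1), height_m = round(height, 2),
      weight_kg = round(bmi_true * height^2, 1),
      seat = seq_len(n), stringsAsFactors = FALSE)
    pairs <- utils::combn(ids, 2)
    status <- sample(c("mutual", "one_sided", "none"), ncol(pairs),
                     replace = TRUE,
                     prob = c(config$p_mutual, config$p_one_sided,
                              1 - config$p_mutual - config$p_one_sided))
    flip <- stats::runif(ncol(pairs)) < 0.5
    dyads[[g]] <- data.frame(
      dyad_id = sprintf("%s_d%02d", gid, seq_len(ncol(pairs))),
      group_id = gid, member_a = pairs[1L, ], member_b = pairs[2L, ],
      friendship = status, stringsAsFactors = FALSE)
    nm <- list()
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      if (status[k] == "mutual") {
        nm[[length(nm) + 1L]] <- data.frame(subject_id = c(a, b),
                                            nominee_id = c(b, a))
      } else if (status[k] == "one_sided") {
        who <- if (flip[k]) a else b
        whom <- if (flip[k]) b else a
        nm[[length(nm) + 1L]] <- data.frame(subject_id = who,
                                            nominee_id = whom)
      }
    }
    noms[[g]] <- if (length(nm)) do.call(rbind, nm) else
      data.frame(subject_id = character(), nominee_id = character())
  }
  subjects <- do.call(rbind, subs)
  subjects$bmi <- round(bmi(subjects$weight_kg, subjects$height_m), 2)
  list(subjects = subjects, dyads = do.call(rbind, dyads),
       nominations = do.call(rbind, noms))
}

#' Generate synthetic questionnaire tables
#'
#' Self-reported affect comes from a latent bivariate (valence, arousal)
#' state per subject; other-estimates equal the target's latent state plus
#' estimation noise (`effects$est_noise_sd`), which controls empathic
#' accuracy. IOS closeness and the eight liking items are shifted upward for
#' friends by the planted `closeness_friend` / `liking_friend` effects. All
#' values are rounded and clipped to their instrument ranges.
#'
#' @param roster Output of [generate_roster()].
#' @param config The same [cohort_config()].
#' @return `list(affect, ios, liking, group_feelings)` of tidy data frames.
#' @export
generate_questionnaires <- function(roster, config) {
  set.seed(config$seed + 1L)
  subj <- roster$subjects
  n <- nrow(subj)
  lat_val <- clip(stats::rnorm(n, 2.2, 0.6), 1, 3)
  lat_aro <- clip(stats::rnorm(n, 2.0, 0.6), 1, 3)
  names(lat_val) <- names(lat_aro) <- subj$subject_id
  grid <- function(x) as.integer(clip(round(x), 1, 3))

  affect <- list(); ios <- list(); liking <- list()
  es <- config$effects
  friend_level <- function(a, b) {
    d <- roster$dyads
    row <- d[(d$member_a == a & d$member_b == b) |
             (d$member_a == b & d$member_b == a), ]
    if (!nrow(row)) return(0)
    switch(row$friendship[1L], mutual = 1, one_sided = 0.5, none = 0)
  }
  for (i in seq_len(n)) {
    id <- subj$subject_id[i]
    mates <- subj$subject_id[subj$group_id == subj$group_id[i] &
                             subj$subject_id != id]
    # self-report at T1 (the modelled timepoint)
    affect[[length(affect) + 1L]] <- data.frame(
      reporter_id = id, target_id = id, timepoint = "T1",
      valence = grid(lat_val[id]), arousal = grid(lat_aro[id]),
      stringsAsFactors = FALSE)
    for (m in mates) {
      fl <- friend_level(id, m)
      # estimate of the mate's affect at T1
      affect[[length(affect) + 1L]] <- data.frame(
        reporter_id = id, target_id = m, timepoint = "T1",
        valence = grid(lat_val[m] + stats::rnorm(1, 0, es$est_noise_sd)),
        arousal = grid(lat_aro[m] + stats::rnorm(1, 0, es$est_noise_sd)),
        stringsAsFactors = FALSE)
      for (tp in c("T0", "T1")) {
        ios[[length(ios) + 1L]] <- data.frame(
          rater_id = id, target_id = m, timepoint = tp,
          ios = as.integer(clip(round(
            2 + es$closeness_friend * fl + stats::rnorm(1, 0, 1)), 0, 6)),
          stringsAsFactors = FALSE)
      }
      lat_like <- 2.8 + es$liking_friend * fl + stats::rnorm(1, 0, 0.35)
      for (tp in c("T0", "T4")) {
        resp <- clip(round(lat_like + stats::rnorm(8, 0, 0.45)), 1, 4)
        # negatively framed items are answered on the reversed key
        resp[7:8] <- 5 - resp[7:8]
        liking[[length(liking) + 1L]] <- data.frame(
          rater_id = id, target_id = m, timepoint = tp,
          item = LIKING_ITEMS, response = as.integer(resp),
          stringsAsFactors = FALSE)
      }
    }
  }
  gf <- data.frame(
    subject_id = subj$subject_id,
    safe = as.integer(clip(round(stats::rnorm(n, 3.2, 0.7)), 1, 4)),
    content = as.integer(clip(round(stats::rnorm(n, 3.0, 0.7)), 1, 4)),
    stressed = as.integer(clip(round(stats::rnorm(n, 1.8, 0.7)), 1, 4)),
    stringsAsFactors = FALSE)
  list(affect = do.call(rbind, affect), ios = do.call(rbind, ios),
       liking = do.call(rbind, liking), group_feelings = gf,
       latent = data.frame(subject_id = subj$subject_id,
                           valence = lat_val, arousal = lat_aro,
                           stringsAsFactors = FALSE))
}

#' Planted ground truth for one synthetic cohort
#'
#' Derives each dyad's coupling weights from the roster and questionnaires:
#' the low-frequency drive weight steps up with friendship (none <
#' one-sided < mutual), the high-frequency weight grows linearly with the
#' dyad's negative affect (`(6 - valence_sum)/4`, in `[0, 1]`). Also records
#' the nominal planted regression coefficients used by [score_recovery()].
#'
#' @param roster,questionnaires,config Generator outputs and configuration.
#' @return An object of class `synthetic_truth`: `dyads` (per-dyad coupling
#'   table) and `planted` (per-coefficient truth table).
#' @export
cohort_truth <- function(roster, questionnaires, config) {
  d <- roster$dyads
  cp <- config$coupling
  aff <- questionnaires$affect
  self <- aff[aff$reporter_id == aff$target_id & aff$timepoint == "T1", ]
  val <- stats::setNames(self$valence, self$reporter_id)
  fl <- c(none = 0, one_sided = 0.5, mutual = 1)[d$friendship]
  valence_sum <- val[d$member_a] + val[d$member_b]
  negaffect <- (6 - valence_sum) / 4
  d$kappa_lf <- cp$kappa_lf_nonfriend +
    (cp$kappa_lf_friend - cp$kappa_lf_nonfriend) * fl
  d$kappa_hf <- pmax(0, cp$kappa_hf_base + cp$beta_hf_negaffect * negaffect)
  d$valence_sum <- as.numeric(valence_sum)
  planted <- data.frame(
    outcome = c("lf_z", "hf_z", "lf_z", "hf_z", "lf_z", "hf_z"),
    term = c("friendshipmutual", "valence_sum", "liking_sum", "liking_sum",
             "empathic_accuracy", "affect_coherence"),
    value = c(config$effects$lf_mutual, config$effects$hf_valence,
              0, 0, 0, 0),
    sign_only = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  structure(list(dyads = d, planted = planted), class = "synthetic_truth")
}

# unit-variance Gaussian noise band-limited to `band` (Hz) via FFT masking
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  W[f < band[1L] | f > band[2L]] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

# 1/f (pink) noise, unit variance
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1))
  f <- pmin(f, n - f)
  W <- W / sqrt(pmax(f, 1))
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate coupled beat-interval recordings
#'
#' Builds each subject's instantaneous heart-rate process (baseline level +
#' RSA sinusoid + LF sinusoid + pink noise + the shared band-limited drives
#' of every dyad the subject belongs to, weighted by the planted couplings)
#' and converts it to a beat point process by integrate-and-fire: a beat is
#' emitted each time the integrated rate accumulates one full cycle.
#' Optional artifact injection multiplies random intervals by 1.6 (spikes)
#' or merges neighbouring intervals (dropouts) to exercise preprocessing.
#'
#' @param roster Output of [generate_roster()].
#' @param truth Output of [cohort_truth()].
#' @param config The [cohort_config()].
#' @return Named list of [rr_series()] objects, one per subject, with phase
#'   marks for baseline, story and discussion.
#' @export
generate_coupled_rr <- function(roster, truth, config) {
  set.seed(config$seed + 2L)
  cd <- config$cardiac
  pd <- config$phase_durations
  total_s <- pd$baseline + pd$story + pd$discussion
  fs <- cd$sim_hz
  nt <- ceiling(total_s * fs) + 1L
  tt <- (0:(nt - 1)) / fs
  phase_marks <- data.frame(
    phase = c("baseline", "story", "discussion"),
    start_s = c(0, pd$baseline, pd$baseline + pd$story),
    end_s = c(pd$baseline, pd$baseline + pd$story, total_s))
  subj <- roster$subjects
  dy <- truth$dyads
  # one shared drive pair per dyad
  drives <- lapply(seq_len(nrow(dy)), function(k) {
    list(lf = bandlimited_noise(nt, fs, config$coupling$lf_drive_band),
         hf = bandlimited_noise(nt, fs, config$coupling$hf_drive_band))
  })
  out <- list()
  for (i in seq_len(nrow(subj))) {
    id <- subj$subject_id[i]
    base <- stats::rnorm(1, cd$mean_hr_bpm, cd$sd_hr_bpm)
    f_rsa <- cd$rsa_freq_hz * stats::runif(1, 0.85, 1.15)
    f_lf <- cd$lf_freq_hz * stats::runif(1, 0.85, 1.15)
    rate <- base +
      cd$rsa_amp * sin(2 * pi * f_rsa * tt + stats::runif(1, 0, 2 * pi)) +
      cd$lf_amp * sin(2 * pi * f_lf * tt + stats::runif(1, 0, 2 * pi)) +
      cd$noise_sd * pink_noise(nt)
    in_d <- which(dy$member_a == id | dy$member_b == id)
    for (k in in_d)
      rate <- rate + dy$kappa_lf[k] * drives[[k]]$lf +
        dy$kappa_hf[k] * drives[[k]]$hf
    if (any(rate <= 0))
      stop("generate_coupled_rr: rate process went non-positive; ",
           "reduce amplitudes/couplings in the config")
    # integrate-and-fire: beat each time the integral of rate/60 gains 1
    # (cumulative trapezoid so cum[i] is the integral up to tt[i])
    cum <- c(0, cumsum((rate[-1L] + rate[-nt]) / 2 / 60) / fs)
    n_beats <- floor(cum[nt])
    beat_t <- stats::approx(cum, tt, xout = seq_len(n_beats))$y
    rr <- diff(c(0, beat_t)) * 1000
    if (config$artifact_spike > 0) {
      hit <- stats::runif(length(rr)) < config$artifact_spike
      rr[hit] <- rr[hit] * 1.6
    }
    if (config$artifact_dropout > 0) {
      hit <- which(stats::runif(length(rr)) < config$artifact_dropout)
      hit <- hit[hit < length(rr)]
      if (length(hit)) {
        rr[hit] <- rr[hit] + rr[hit + 1L]
        rr <- rr[-(hit + 1L)]
      }
    }
    out[[id]] <- rr_series(id, data.frame(t = cumsum(rr) / 1000, rr = rr),
                           phase_marks, session_id = "synthetic")
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_roster()], [generate_questionnaires()], [cohort_truth()]
#' and [generate_coupled_rr()] under the configuration's seed.
#'
#' @param config A [cohort_config()].
#' @return `list(config, roster, questionnaires, truth, rr)`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  roster <- generate_roster(config)
  quest <- generate_questionnaires(roster, config)
  truth <- cohort_truth(roster, quest, config)
  rr <- generate_coupled_rr(roster, truth, config)
  list(config = config, roster = roster, questionnaires = quest,
       truth = truth, rr = rr)
}

#' Score parameter recovery against the planted truth
#'
#' For every planted coefficient, collects the matching term across a list
#' of replicate fits and reports bias, RMSE, 95\%-interval coverage of the
#' planted value, and the sign-detection rate (proportion of replicates in
#' which the estimate carries the planted sign; `NA` for null effects).
#'
#' @param fits List of replicates; each element a named list of `mm_fit`
#'   objects keyed by outcome (e.g. `list(hf_z = ..., lf_z = ...)`).
#' @param truth A `synthetic_truth` (its `planted` table drives the report).
#' @return `data.frame` with one row per planted coefficient.
#' @export
score_recovery <- function(fits, truth) {
  stopifnot(inherits(truth, "synthetic_truth"), length(fits) >= 1L)
  rows <- lapply(seq_len(nrow(truth$planted)), function(i) {
    pl <- truth$planted[i, ]
    est <- lower <- upper <- numeric(0)
    for (rep in fits) {
      fit <- rep[[pl$outcome]]
      if (is.null(fit)) stop("score_recovery: no fit for outcome ",
                             pl$outcome)
      co <- fit$coefficients
      j <- match(pl$term, co$term)
      if (is.na(j)) stop("score_recovery: term not in fit: ", pl$term)
      est <- c(est, co$estimate[j])
      lower <- c(lower, co$lower[j]); upper <- c(upper, co$upper[j])
    }
    data.frame(outcome = pl$outcome, term = pl$term, value = pl$value,
               n_reps = length(est), mean_estimate = mean(est),
               bias = mean(est) - pl$value,
               rmse = sqrt(mean((est - pl$value)^2)),
               coverage = mean(lower <= pl$value & pl$value <= upper),
               sign_rate = if (pl$value != 0)
                 mean(sign(est) == sign(pl$value)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
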