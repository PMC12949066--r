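# End-to-end orchestration: declarative JSON run config, stage drivers that
# connect the preprocessing, spectral, wavelet, measures and modelling
# modules, and CSV/JSON artifact output.

#' Preprocess a collection of beat-interval recordings
#'
#' Applies [preprocess_rr()] to every series, returning the cleaned series
#' (excluded subjects dropped) and the combined report table.
#'
#' @param rr_list Named list of [rr_series()] objects.
#' @param threshold,max_gap_s,exclude_at See [preprocess_rr()].
#' @return `list(series = <named list>, reports = <data.frame>)`.
#' @export
preprocess_cohort <- function(rr_list, threshold = 0.30, max_gap_s = 2.0,
                              exclude_at = 0.10) {
  res <- lapply(rr_list, preprocess_rr, threshold = threshold,
                max_gap_s = max_gap_s, exclude_at = exclude_at)
  reports <- do.call(rbind, lapply(res, function(r) report_as_row(r$report)))
  rownames(reports) <- NULL
  series <- lapply(res, `[[`, "series")
  keep <- !reports$excluded
  list(series = series[keep], reports = reports)
}

#' Windowed HF HRV for a cohort
#'
#' @param series Named list of preprocessed [rr_series()].
#' @param phases Phases to analyse (default baseline, story, discussion).
#' @param ... Passed to [hf_hrv_windows()].
#' @return Long data frame of HRV windows with a `time` column (window index
#'   within phase).
#' @export
compute_hrv_table <- function(series,
                              phases = c("baseline", "story", "discussion"),
                              ...) {
  rows <- list()
  for (s in series) {
    for (ph in phases) {
      tab <- tryCatch(hf_hrv_windows(s, ph, ...), error = function(e) NULL)
      if (!is.null(tab)) rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  out$time <- out$window_index
  out
}

#' Dyadic synchrony table for a cohort
#'
#' For every dyad whose two members both survived preprocessing, resamples
#' both heart-rate trajectories at 1 Hz per phase, computes cross-wavelet
#' power and band-wise 20 s maxima, then truncates and z-scores the pooled
#' collection.
#'
#' @param series Named list of preprocessed [rr_series()].
#' @param dyads Data frame with `dyad_id`, `group_id`, `member_a`,
#'   `member_b`.
#' @param phases Phases to analyse (default story and discussion).
#' @param spec A [wavelet_spec()].
#' @param coi_mask,interval_s Passed to [synchrony_series()].
#' @param story_min,discussion_min Passed to [truncate_and_zscore()].
#' @return Z-scored synchrony table with `group_id` and a `time` column
#'   (interval index within phase).
#' @export
compute_synchrony_table <- function(series, dyads,
                                    phases = c("story", "discussion"),
                                    spec = wavelet_spec(), coi_mask = TRUE,
                                    interval_s = 20, story_min = 8,
                                    discussion_min = 10) {
  hr_cache <- new.env(parent = emptyenv())
  get_cwt <- function(id, ph) {
    key <- paste(id, ph)
    if (!is.null(hr_cache[[key]])) return(hr_cache[[key]])
    s <- series[[id]]
    if (is.null(s)) return(NULL)
    w <- tryCatch(cwt_morlet(resample_heart_rate(s, ph), spec),
                  error = function(e) NULL)
    hr_cache[[key]] <- w
    w
  }
  rows <- list()
  for (k in seq_len(nrow(dyads))) {
    for (ph in phases) {
      wa <- get_cwt(dyads$member_a[k], ph)
      wb <- get_cwt(dyads$member_b[k], ph)
      if (is.null(wa) || is.null(wb)) next
      xp <- cross_power(wa, wb, dyads$dyad_id[k], ph)
      hf <- band_interval_max(xp, c(0.125, 0.5), interval_s, coi_mask)
      lf <- band_interval_max(xp, c(0.031, 0.125), interval_s, coi_mask)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = dyads$dyad_id[k], group_id = dyads$group_id[k],
        phase = ph, interval_index = seq_along(hf), hf_raw = hf,
        lf_raw = lf, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("compute_synchrony_table: no analysable dyads")
  sync <- do.call(rbind, rows)
  out <- truncate_and_zscore(sync, story_min, discussion_min, interval_s)
  out$time <- out$interval_index
  out
}

#' Subject-level covariate table
#'
#' Joins roster covariates with T1 self-reported affect and group-related
#' feelings into the layout the individual HRV model consumes.
#'
#' @param roster,questionnaires Generator outputs (or equivalents read from
#'   file).
#' @return Data frame keyed by `subject_id`.
#' @export
build_subject_table <- function(roster, questionnaires) {
  subj <- roster$subjects
  aff <- questionnaires$affect
  self1 <- aff[aff$reporter_id == aff$target_id & aff$timepoint == "T1", ]
  gf <- questionnaires$group_feelings
  out <- merge(subj, self1[, c("reporter_id", "valence", "arousal")],
               by.x = "subject_id", by.y = "reporter_id", all.x = TRUE)
  out <- merge(out, gf, by = "subject_id", all.x = TRUE)
  names(out)[names(out) == "safe"] <- "safe_group"
  names(out)[names(out) == "content"] <- "content_group"
  names(out)[names(out) == "stressed"] <- "stressed_group"
  out
}

#' Model table for the dyadic synchrony analysis
#'
#' @param sync_table Output of [compute_synchrony_table()].
#' @param dyad_table Output of [build_dyad_table()].
#' @return Merged long table ready for [fit_model()] with a
#'   [synchrony_model_spec()].
#' @export
build_synchrony_model_table <- function(sync_table, dyad_table) {
  merge(sync_table, dyad_table, by = c("dyad_id", "group_id"))
}

#' Model table for the individual HF HRV analysis
#'
#' @param hrv_table Output of [compute_hrv_table()].
#' @param subject_table Output of [build_subject_table()].
#' @return Merged long table ready for [fit_model()] with an
#'   [hrv_model_spec()].
#' @export
build_hrv_model_table <- function(hrv_table, subject_table) {
  out <- merge(hrv_table, subject_table, by = "subject_id")
  out[!is.na(out$hf_log), , drop = FALSE]
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run config not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(
    out_dir = "dyadsync_run",
    seed = 1L,
    preprocessing = list(threshold = 0.30, max_gap_s = 2.0,
                         exclude_at = 0.10),
    hrv = list(band = c(0.15, 0.4), window_s = 120, shift_s = 60,
               resample_hz = 4),
    wavelet = list(omega0 = 6, voices = 12, freq_range = c(0.031, 0.5),
                   hf_band = c(0.125, 0.5), lf_band = c(0.031, 0.125),
                   interval_s = 20, story_min = 8, discussion_min = 10,
                   coi_mask = TRUE),
    models = list(run = TRUE, screening_alpha = 0.05))
  cfg <- utils::modifyList(defaults, config)
  wb <- cfg$wavelet
  if (is.null(wb$hf_band) || is.null(wb$lf_band) ||
      length(wb$hf_band) != 2L || length(wb$lf_band) != 2L)
    stop("run config: wavelet block must declare hf_band and lf_band")
  if (wb$hf_band[2L] > wb$freq_range[2L] ||
      wb$lf_band[1L] < wb$freq_range[1L])
    stop("run config: analysis bands exceed the wavelet frequency coverage")
  pp <- cfg$preprocessing
  if (pp$threshold <= 0 || pp$threshold >= 1 || pp$exclude_at <= 0 ||
      pp$exclude_at > 1 || pp$max_gap_s <= 0)
    stop("run config: preprocessing thresholds out of range")
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic cohort (when the config carries a
#' `synthetic` block) or on files named in an `input` block, writing all
#' stage outputs, a manifest, and -- when ground truth exists -- a recovery
#' report into `out_dir`. Reruns with the same config are deterministic.
#'
#' @param config Path to a JSON run config or an equivalent named list.
#'   Recognised blocks: `synthetic` (fields of [cohort_config()]),
#'   `preprocessing`, `hrv`, `wavelet`, `models`, plus `out_dir` and `seed`.
#' @return Invisibly, a list with all in-memory stage products.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on.exit(if (!identical(stage, "done"))
    writeLines(paste("FAILED at stage:", stage),
               file.path(cfg$out_dir, "FAILED")), add = TRUE)

  stage <- "inputs"
  if (!is.null(cfg$synthetic)) {
    sc_args <- cfg$synthetic
    sc_args$seed <- sc_args$seed %||% cfg$seed
    cohort <- generate_cohort(do.call(cohort_config, sc_args))
    rr <- cohort$rr
    roster <- cohort$roster
    quest <- cohort$questionnaires
    truth <- cohort$truth
  } else if (!is.null(cfg$input)) {
    inp <- cfg$input
    roster <- list(
      subjects = utils::read.csv(inp$subjects, stringsAsFactors = FALSE),
      dyads = utils::read.csv(inp$dyads, stringsAsFactors = FALSE),
      nominations = utils::read.csv(inp$nominations,
                                    stringsAsFactors = FALSE))
    quest <- list(
      affect = utils::read.csv(inp$affect, stringsAsFactors = FALSE),
      ios = utils::read.csv(inp$ios, stringsAsFactors = FALSE),
      liking = utils::read.csv(inp$liking, stringsAsFactors = FALSE),
      group_feelings = utils::read.csv(inp$group_feelings,
                                       stringsAsFactors = FALSE))
    pm <- utils::read.csv(inp$phases, stringsAsFactors = FALSE)
    rr <- lapply(stats::setNames(nm = roster$subjects$subject_id),
                 function(id) {
      path <- file.path(inp$rr_dir, paste0(id, ".csv"))
      read_rr_export(path, dialect = inp$dialect %||% list(),
                     subject_id = id,
                     phase_marks = pm[pm$subject_id == id | pm$subject_id ==
                                        "*", c("phase", "start_s", "end_s")])
    })
    truth <- NULL
  } else stop("run config needs a 'synthetic' or an 'input' block")

  stage <- "preprocess"
  pp <- cfg$preprocessing
  prep <- preprocess_cohort(rr, pp$threshold, pp$max_gap_s, pp$exclude_at)
  utils::write.csv(prep$reports,
                   file.path(cfg$out_dir, "preprocess_reports.csv"),
                   row.names = FALSE)

  stage <- "hrv"
  hrv_tab <- compute_hrv_table(prep$series, band = cfg$hrv$band,
                               window_s = cfg$hrv$window_s,
                               shift_s = cfg$hrv$shift_s,
                               resample_hz = cfg$hrv$resample_hz)
  utils::write.csv(hrv_tab, file.path(cfg$out_dir, "hrv_windows.csv"),
                   row.names = FALSE)

  stage <- "synchrony"
  wb <- cfg$wavelet
  sync_tab <- compute_synchrony_table(
    prep$series, roster$dyads,
    spec = wavelet_spec(wb$omega0, wb$voices, wb$freq_range),
    coi_mask = isTRUE(wb$coi_mask), interval_s = wb$interval_s,
    story_min = wb$story_min, discussion_min = wb$discussion_min)
  utils::write.csv(sync_tab, file.path(cfg$out_dir, "synchrony.csv"),
                   row.names = FALSE)

  stage <- "measures"
  dyad_tab <- build_dyad_table(roster, quest)
  subj_tab <- build_subject_table(roster, quest)
  utils::write.csv(dyad_tab, file.path(cfg$out_dir, "dyads.csv"),
                   row.names = FALSE)
  utils::write.csv(subj_tab, file.path(cfg$out_dir, "subjects.csv"),
                   row.names = FALSE)

  fits <- NULL
  if (isTRUE(cfg$models$run)) {
    stage <- "models"
    model_tab <- build_synchrony_model_table(sync_tab, dyad_tab)
    fits <- list(
      hf_z = fit_model(synchrony_model_spec("hf_z"), model_tab),
      lf_z = fit_model(synchrony_model_spec("lf_z"), model_tab))
    for (nm in names(fits))
      utils::write.csv(fits[[nm]]$coefficients,
                       file.path(cfg$out_dir,
                                 paste0("model_", nm, "_coefficients.csv")),
                       row.names = FALSE)
    meta <- lapply(fits, function(f)
      list(loglik = f$loglik, n_obs = f$n_obs, n_units = f$n_units,
           ar1_phi = f$ar1_phi, marginal_r2 = f$marginal_r2,
           variance_components = f$variance_components))
    jsonlite::write_json(meta, file.path(cfg$out_dir, "model_meta.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(truth)) {
      stage <- "recovery"
      recov <- score_recovery(list(fits), truth)
      utils::write.csv(recov, file.path(cfg$out_dir, "recovery.csv"),
                       row.names = FALSE)
      jsonlite::write_json(truth$dyads,
                           file.path(cfg$out_dir, "truth_dyads.json"),
                           digits = NA)
    }
  }

  stage <- "manifest"
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    seed = cfg$seed,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(
      cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE))) %% 2^31,
    stages = c("preprocess", "hrv", "synchrony", "measures",
               if (isTRUE(cfg$models$run)) "models"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  unlink(file.path(cfg$out_dir, "FAILED"))
  stage <- "done"
  invisible(list(config = cfg, reports = prep$reports, hrv = hrv_tab,
                 synchrony = sync_tab, dyads = dyad_tab,
                 subjects = subj_tab, fits = fits))
}
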