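# Multilevel models for repeated physiological outcomes: ICCs, covariate
# screening, stepwise structure selection, REML fits with AR(1) residuals,
# and fixed-effects variance-explained summaries. Estimation is delegated to
# nlme (lme/gls + corAR1); everything around it is package code.

#' Intraclass correlations from a null random-intercept model
#'
#' Fits an intercept-only model with nested random intercepts for the
#' requested grouping levels and reports, per level, its variance component
#' as a percentage of the total (all components plus residual).
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column.
#' @param levels Character vector of grouping columns, outermost first
#'   (e.g. `c("group_id", "subject_id")`).
#' @return `data.frame(level, variance, icc_pct)` with a final `residual`
#'   row (`icc_pct` for the residual is its share too).
#' @export
icc_components <- function(data, outcome, levels) {
  stopifnot(outcome %in% names(data), all(levels %in% names(data)))
  y <- data[[outcome]]
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("icc_components: outcome has zero variance")
  for (l in levels) data[[l]] <- factor(data[[l]])
  rnd <- stats::as.formula(paste0("~ 1 | ", paste(levels, collapse = "/")))
  fit <- nlme::lme(stats::as.formula(paste(outcome, "~ 1")), random = rnd,
                   data = data, method = "REML", na.action = stats::na.omit)
  vc <- extract_varcomp(fit)
  total <- sum(vc$variance)
  vc$icc_pct <- 100 * vc$variance / total
  vc
}

# variance components (one per random level + residual) from an lme fit
extract_varcomp <- function(fit) {
  vc <- nlme::VarCorr(fit)
  rows <- rownames(vc)
  keep <- grepl("^\\(Intercept\\)$|^Residual$|^[^=(]", rows) &
    !grepl("=", rows)
  est <- suppressWarnings(as.numeric(vc[, "Variance"]))
  lvl_names <- character(0); lvl_var <- numeric(0)
  current <- NULL
  for (i in seq_along(rows)) {
    r <- rows[i]
    if (grepl("=", r)) {                      # "group_id =" header row
      current <- sub(" =.*$", "", r)
    } else if (r == "Residual") {
      lvl_names <- c(lvl_names, "residual"); lvl_var <- c(lvl_var, est[i])
    } else if (is.finite(est[i])) {
      nm <- if (r == "(Intercept)") current %||% r else
        paste0(current %||% "", ":", r)
      lvl_names <- c(lvl_names, nm); lvl_var <- c(lvl_var, est[i])
    }
  }
  # single-level fits have no header rows
  if (!length(lvl_names) || !"residual" %in% lvl_names) {
    s <- summary(fit)
    lvl_var <- c(as.numeric(nlme::VarCorr(fit)[, "Variance"]))
    lvl_names <- rownames(nlme::VarCorr(fit))
    lvl_names[lvl_names == "(Intercept)"] <-
      attr(fit$modelStruct$reStruct, "names")[1L] %||% "(Intercept)"
    lvl_names[lvl_names == "Residual"] <- "residual"
    keep <- is.finite(lvl_var)
    lvl_names <- lvl_names[keep]; lvl_var <- lvl_var[keep]
  }
  data.frame(level = lvl_names, variance = lvl_var,
             stringsAsFactors = FALSE)
}

#' Screen candidate covariates against an outcome
#'
#' Tests each candidate's marginal association with the outcome (Pearson
#' correlation for numeric candidates, one-way ANOVA F-test for categorical
#' ones) and retains those with `p < alpha`. Constant candidates are skipped
#' with a warning. Every decision is logged.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate column names.
#' @param alpha Inclusion threshold (default 0.05).
#' @return `list(included = <character>, log = <data.frame>)`; the log has
#'   columns `candidate`, `test`, `statistic`, `p_value`, `included`.
#' @export
screen_covariates <- function(data, outcome, candidates, alpha = 0.05) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  y <- data[[outcome]]
  rows <- lapply(candidates, function(cn) {
    x <- data[[cn]]
    cc <- stats::complete.cases(x, y)
    x2 <- x[cc]; y2 <- y[cc]
    if (length(unique(x2)) < 2L) {
      warning("screen_covariates: skipping constant candidate ", cn)
      return(data.frame(candidate = cn, test = "skipped (constant)",
                        statistic = NA_real_, p_value = NA_real_,
                        included = FALSE, stringsAsFactors = FALSE))
    }
    if (is.numeric(x2)) {
      ct <- stats::cor.test(x2, y2)
      data.frame(candidate = cn, test = "pearson_r",
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 included = ct$p.value < alpha, stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(y2 ~ factor(x2))
      an <- stats::anova(fit)
      data.frame(candidate = cn, test = "anova_F",
                 statistic = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L],
                 included = an[["Pr(>F)"]][1L] < alpha,
                 stringsAsFactors = FALSE)
    }
  })
  log <- do.call(rbind, rows)
  list(included = log$candidate[log$included], log = log)
}

#' Specify a multilevel model
#'
#' Describes one model of the repeated-measures outcome: fixed terms (with
#' reference levels for the dummy-coded factors), nested random intercepts
#' for group and measurement unit (subject or dyad), an optional random slope
#' for time within the unit, and an AR(1) residual correlation indexed by
#' observation order within unit and phase.
#'
#' @param outcome Outcome column (e.g. `"hf_log"`, `"hf_z"`, `"lf_z"`).
#' @param fixed Character vector of fixed-effect terms (column names or
#'   interaction terms like `"friendship:gender_combo"`).
#' @param group,unit Grouping columns (outer, inner).
#' @param slope Optional column for a random slope within `unit` (usually
#'   `"time"`).
#' @param ar1 Include an AR(1) residual correlation within unit-phase
#'   (default TRUE).
#' @param references Named list of factor reference levels, e.g.
#'   `list(phase = "story", friendship = "none", gender_combo = "mixed")`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed, group = "group_id", unit,
                       slope = NULL, ar1 = TRUE, references = list()) {
  structure(list(outcome = outcome, fixed = fixed, group = group,
                 unit = unit, slope = slope, ar1 = ar1,
                 references = references),
            class = "model_spec")
}

apply_references <- function(data, references) {
  for (nm in names(references)) {
    if (!nm %in% names(data)) next
    f <- factor(data[[nm]])
    if (!references[[nm]] %in% levels(f))
      stop(sprintf("reference level %s absent from %s",
                   references[[nm]], nm))
    data[[nm]] <- stats::relevel(f, ref = references[[nm]])
  }
  data
}

# AR(1) position: observation order within unit, with a large jump between
# phases so cross-phase correlation is effectively zero
ar1_position <- function(data) {
  ph <- if ("phase" %in% names(data)) as.integer(factor(data$phase)) else 1L
  tm <- if ("time" %in% names(data)) data$time else
    stats::ave(seq_len(nrow(data)), data$phase, FUN = seq_along)
  as.integer(round(ph * 100000 + tm))
}

#' Fit a multilevel model with AR(1) residuals
#'
#' REML fit (via [nlme::lme()]) of a [model_spec()]: nested random
#' intercepts for group and unit, optional random slope for time within
#' unit, AR(1) correlation within unit-phase. Returns a tidy coefficient
#' table with 95\% intervals and p-values, variance components, the AR(1)
#' parameter, level ICCs, marginal R-squared, and the underlying `lme` fit.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with all referenced columns; rows with missing
#'   values in used columns are dropped.
#' @param method `"REML"` (default, for reported fits) or `"ML"` (for
#'   likelihood-ratio comparisons).
#' @return An object of class `mm_fit`.
#' @export
fit_model <- function(spec, data, method = "REML") {
  stopifnot(inherits(spec, "model_spec"))
  used <- unique(c(spec$outcome, all.vars(stats::reformulate(spec$fixed)),
                   spec$group, spec$unit, spec$slope,
                   intersect(c("phase", "time"), names(data))))
  used <- intersect(used, names(data))
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), ,
               drop = FALSE]
  data <- apply_references(data, spec$references)
  data[[spec$group]] <- factor(data[[spec$group]])
  data[[spec$unit]] <- factor(data[[spec$unit]])
  data$.ar1_pos <- ar1_position(data)
  fixed_fml <- stats::reformulate(spec$fixed, response = spec$outcome)
  # rank check on the fixed design
  X <- stats::model.matrix(fixed_fml, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fit_model: rank-deficient fixed design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  random <- if (is.null(spec$slope)) {
    stats::as.formula(paste0("~ 1 | ", spec$group, "/", spec$unit))
  } else {
    rl <- list(stats::as.formula("~ 1"),
               stats::as.formula(paste("~", spec$slope)))
    names(rl) <- c(spec$group, spec$unit)
    rl
  }
  corr <- if (spec$ar1)
    nlme::corAR1(form = stats::as.formula(
      paste0("~ .ar1_pos | ", spec$group, "/", spec$unit))) else NULL
  fit <- tryCatch(
    nlme::lme(fixed_fml, random = random, data = data, method = method,
              correlation = corr, na.action = stats::na.omit,
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE)),
    error = function(e) stop("fit_model: lme failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  tt <- summary(fit)$tTable
  ci <- tryCatch(nlme::intervals(fit, which = "fixed")$fixed,
                 error = function(e) NULL)
  if (is.null(ci)) {
    crit <- stats::qt(0.975, tt[, "DF"])
    ci <- cbind(lower = tt[, "Value"] - crit * tt[, "Std.Error"],
                est. = tt[, "Value"],
                upper = tt[, "Value"] + crit * tt[, "Std.Error"])
  }
  coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      lower = ci[, "lower"], upper = ci[, "upper"],
                      p_value = tt[, "p-value"], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vc <- extract_varcomp(fit)
  phi <- if (spec$ar1)
    unname(stats::coef(fit$modelStruct$corStruct,
                       unconstrained = FALSE)[1L]) else NA_real_
  icc <- vc
  icc$icc_pct <- 100 * icc$variance / sum(icc$variance)
  r2 <- marginal_r2_lme(fit, data, fixed_fml)
  structure(list(model = fit, spec = spec, data = data,
                 coefficients = coefs, variance_components = vc,
                 ar1_phi = phi, icc_by_level = icc, marginal_r2 = r2,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(data),
                 n_units = length(unique(data[[spec$unit]]))),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s on %d obs / %d %s units; marginal R2 = %.3f",
              x$spec$outcome, x$n_obs, x$n_units, x$spec$unit,
              x$marginal_r2), "\n")
  if (is.finite(x$ar1_phi)) cat(sprintf("  AR(1) phi = %.3f\n", x$ar1_phi))
  print(transform(x$coefficients,
                  estimate = round(estimate, 3), lower = round(lower, 3),
                  upper = round(upper, 3), p_value = round(p_value, 4)))
  invisible(x)
}

marginal_r2_lme <- function(fit, data, fixed_fml) {
  X <- stats::model.matrix(fixed_fml, data)
  beta <- nlme::fixef(fit)
  pred <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
  v_fix <- stats::var(pred)
  vc <- extract_varcomp(fit)
  v_fix / (v_fix + sum(vc$variance))
}

#' Marginal R-squared of a fitted multilevel model
#'
#' Proportion of total outcome variance attributable to the fixed effects:
#' variance of the fixed-effect predictions over (fixed + all random
#' components + residual). With `semi_partial = TRUE`, additionally returns
#' each term's drop-one contribution (full marginal R-squared minus the
#' marginal R-squared of the model refit without that term).
#'
#' @param fit An `mm_fit`.
#' @param semi_partial Also compute per-term semi-partial values
#'   (default FALSE; refits the model once per term).
#' @return A single proportion, or with `semi_partial = TRUE` a list
#'   `(marginal, semi_partial)`.
#' @export
marginal_r2 <- function(fit, semi_partial = FALSE) {
  stopifnot(inherits(fit, "mm_fit"))
  if (!semi_partial) return(fit$marginal_r2)
  terms <- fit$spec$fixed
  sp <- vapply(terms, function(tm) {
    spec2 <- fit$spec
    spec2$fixed <- setdiff(terms, tm)
    if (!length(spec2$fixed)) spec2$fixed <- "1"
    fit$marginal_r2 - fit_model(spec2, fit$data)$marginal_r2
  }, numeric(1))
  list(marginal = fit$marginal_r2, semi_partial = sp)
}

#' Variance explained at each random level relative to an intercept-only fit
#'
#' Refits the model with the same random structure but intercept-only fixed
#' effects and reports, per random level, the proportional reduction in its
#' variance component attributable to the fixed effects (negative reductions
#' are truncated at 0).
#'
#' @param fit An `mm_fit`.
#' @return `data.frame(level, var_null, var_full, pct_explained)`.
#' @export
variance_explained_by_level <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  spec0 <- fit$spec
  spec0$fixed <- "1"
  fit0 <- fit_model(spec0, fit$data)
  v0 <- fit0$variance_components
  v1 <- fit$variance_components
  m <- merge(v0, v1, by = "level", suffixes = c("_null", "_full"))
  m$pct_explained <- pmax(0, 100 * (1 - m$variance_full / m$variance_null))
  m[order(match(m$level, v0$level)), ]
}

#' Stepwise selection of the random/correlation structure
#'
#' Walks a declared sequence of nested model candidates (each a function of
#' the data returning a fitted `lme`/`gls` object, fitted with ML) and keeps
#' a step when its likelihood-ratio test against the last accepted model is
#' significant at `alpha`. A step that fails to converge is skipped and the
#' predecessor retained. Every step is logged with the LR statistic, degrees
#' of freedom and p-value.
#'
#' @param data Data frame passed to each candidate fitter.
#' @param steps Named list of functions `function(data) -> fit`; the first is
#'   the null model and is always accepted.
#' @param alpha Significance level for each likelihood-ratio test
#'   (default 0.05).
#' @return `list(chosen = <name>, fit = <model>, log = <data.frame>)`.
#' @export
select_structure <- function(data, steps, alpha = 0.05) {
  stopifnot(length(steps) >= 2L, !is.null(names(steps)))
  fits <- list()
  current <- steps[[1L]](data)
  chosen <- names(steps)[1L]
  log <- data.frame(step = names(steps)[1L], lr_stat = NA_real_,
                    df = NA_integer_, p_value = NA_real_, accepted = TRUE,
                    note = "null model", stringsAsFactors = FALSE)
  for (k in 2L:length(steps)) {
    nm <- names(steps)[k]
    cand <- tryCatch(steps[[k]](data), error = function(e) e)
    if (inherits(cand, "error")) {
      warning(sprintf("select_structure: step %s failed (%s); kept %s",
                      nm, conditionMessage(cand), chosen))
      log <- rbind(log, data.frame(step = nm, lr_stat = NA_real_,
                                   df = NA_integer_, p_value = NA_real_,
                                   accepted = FALSE,
                                   note = "non-convergence, skipped",
                                   stringsAsFactors = FALSE))
      next
    }
    ll0 <- stats::logLik(current); ll1 <- stats::logLik(cand)
    df <- attr(ll1, "df") - attr(ll0, "df")
    lr <- as.numeric(2 * (ll1 - ll0))
    p <- if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_
    accepted <- isTRUE(p < alpha)
    if (accepted) { current <- cand; chosen <- nm }
    log <- rbind(log, data.frame(step = nm, lr_stat = lr, df = df,
                                 p_value = p, accepted = accepted, note = "",
                                 stringsAsFactors = FALSE))
  }
  list(chosen = chosen, fit = current, log = log)
}

#' Canonical synchrony model specification
#'
#' The dyadic synchrony model: outcome `hf_z` or `lf_z` on task phase
#' (reference story), time within phase, gender combination (reference
#' mixed), friendship status (reference none), closeness and liking sums,
#' affect coherence, arousal and valence sums, and empathic accuracy, with
#' random intercepts for group and dyad and AR(1) residuals. The HF model
#' carries a random slope for time within dyad.
#'
#' @param outcome `"hf_z"` or `"lf_z"`.
#' @param extra Additional fixed terms (e.g. interaction strings).
#' @param slope Random-slope column; defaults to `"time"` for `hf_z`,
#'   `NULL` for `lf_z`.
#' @return A [model_spec()].
#' @export
synchrony_model_spec <- function(outcome = c("lf_z", "hf_z"), extra = NULL,
                                 slope = if (outcome[1L] == "hf_z") "time") {
  outcome <- match.arg(outcome)
  model_spec(
    outcome = outcome,
    fixed = c("phase", "time", "gender_combo", "friendship",
              "closeness_sum", "liking_sum", "affect_coherence",
              "arousal_sum", "valence_sum", "empathic_accuracy", extra),
    group = "group_id", unit = "dyad_id", slope = slope, ar1 = TRUE,
    references = list(phase = "story", friendship = "none",
                      gender_combo = "mixed"))
}

#' Canonical individual HF HRV model specification
#'
#' Log HF power on task phase (reference baseline), time within phase, the
#' screened covariates, post-discussion affect and group-related feelings,
#' with random intercepts for group and subject, a random slope for time,
#' and AR(1) residuals.
#'
#' @param covariates Screened covariate columns to include (default age and
#'   BMI).
#' @return A [model_spec()].
#' @export
hrv_model_spec <- function(covariates = c("age", "bmi")) {
  model_spec(
    outcome = "hf_log",
    fixed = c("phase", "time", covariates, "arousal", "valence",
              "content_group", "safe_group", "stressed_group"),
    group = "group_id", unit = "subject_id", slope = "time", ar1 = TRUE,
    references = list(phase = "baseline"))
}
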