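# Questionnaire-derived individual and dyadic variables: affect-grid
# metrics, friendship status, closeness/liking aggregates, covariates.

# maximal distance on the 3x3 affect grid: sqrt((3-1)^2 + (3-1)^2)
DIST_MAX <- sqrt(8)

check_grid <- function(valence, arousal, what) {
  ok <- function(v) length(v) == 1L && !is.na(v) && v %in% 1:3
  if (!ok(valence) || !ok(arousal))
    stop(sprintf("%s: valence/arousal must be integers in 1..3 (got %s, %s)",
                 what, format(valence), format(arousal)))
}

#' Affect coherence of two simultaneous self-reports
#'
#' Recoded Euclidean closeness of two people's affect-grid coordinates:
#' `dist_max - sqrt((v_a - v_b)^2 + (r_a - r_b)^2)` with
#' `dist_max = sqrt(8) ~ 2.83`, the largest distance on the 3x3 grid. Higher
#' values mean more similar simultaneous affect; identical reports score
#' `dist_max`, diagonally opposite corners score 0.
#'
#' @param valence_a,arousal_a,valence_b,arousal_b Grid coordinates, integers
#'   in 1..3.
#' @return Value in `[0, sqrt(8)]`.
#' @export
affect_coherence <- function(valence_a, arousal_a, valence_b, arousal_b) {
  check_grid(valence_a, arousal_a, "affect_coherence")
  check_grid(valence_b, arousal_b, "affect_coherence")
  DIST_MAX - sqrt((valence_a - valence_b)^2 + (arousal_a - arousal_b)^2)
}

#' Empathic accuracy of one affect estimate
#'
#' Recoded Euclidean closeness of a reporter's estimate of a target's affect
#' to the target's actual self-report:
#' `dist_max - sqrt((v_est - v_real)^2 + (r_est - r_real)^2)`. A perfect
#' estimate scores `sqrt(8) ~ 2.83`; the dyad-level sum of both members'
#' accuracies therefore ranges over `[0, 5.66]`.
#'
#' @param valence_est,arousal_est The estimate's grid coordinates (1..3).
#' @param valence_real,arousal_real The target's actual self-report (1..3).
#' @return Value in `[0, sqrt(8)]`.
#' @export
empathic_accuracy <- function(valence_est, arousal_est,
                              valence_real, arousal_real) {
  check_grid(valence_est, arousal_est, "empathic_accuracy")
  check_grid(valence_real, arousal_real, "empathic_accuracy")
  DIST_MAX - sqrt((valence_est - valence_real)^2 +
                  (arousal_est - arousal_real)^2)
}

#' Dyadic friendship status from nomination lists
#'
#' A dyad is a mutual friendship when both members nominated each other,
#' one-sided when exactly one did, and `none` otherwise. Self-nominations are
#' ignored; nominations of unknown ids are skipped with a warning when a
#' roster is supplied.
#'
#' @param nominations Named list mapping each subject id to the character
#'   vector of ids they nominated as friends.
#' @param dyad Character vector of the two member ids.
#' @param roster Optional character vector of valid subject ids.
#' @return One of `"none"`, `"one_sided"`, `"mutual"`.
#' @export
friendship_status <- function(nominations, dyad, roster = NULL) {
  stopifnot(length(dyad) == 2L, dyad[1L] != dyad[2L])
  get_noms <- function(id) {
    noms <- nominations[[id]]
    if (is.null(noms)) return(character())
    noms <- setdiff(noms, id)
    if (!is.null(roster)) {
      unknown <- setdiff(noms, roster)
      if (length(unknown)) {
        warning(sprintf("friendship_status: %s nominated unknown id(s): %s",
                        id, paste(unknown, collapse = ", ")))
        noms <- intersect(noms, roster)
      }
    }
    noms
  }
  ab <- dyad[2L] %in% get_noms(dyad[1L])
  ba <- dyad[1L] %in% get_noms(dyad[2L])
  if (ab && ba) "mutual" else if (ab || ba) "one_sided" else "none"
}

#' Dyadic closeness sum (IOS)
#'
#' Each rater's Inclusion-of-the-Other-in-the-Self score (0-6) is averaged
#' over the two assessments bracketing the discussion (T0 and T1, using
#' whichever are available); the dyad value is the sum of the two rater
#' means, range 0-12. If a rater is missing both timepoints the dyad value is
#' `NA`.
#'
#' @param ios_a,ios_b Numeric vectors of up to two IOS values (T0, T1; `NA`
#'   allowed) for the two raters, each rating the other member.
#' @return Value in `[0, 12]`, or `NA`.
#' @export
closeness_sum <- function(ios_a, ios_b) {
  rater_mean <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    if (any(x < 0 | x > 6)) stop("closeness_sum: IOS values must be in 0..6")
    mean(x)
  }
  rater_mean(ios_a) + rater_mean(ios_b)
}

LIKING_ITEMS <- c("nice", "fair", "interesting", "smart", "cool",
                  "ready_to_help", "boring", "mean")
LIKING_REVERSE <- c("boring", "mean")

#' Recode reverse-keyed Likert items
#'
#' Maps `x -> 5 - x` on a 1-4 scale; applying it twice restores the input.
#'
#' @param x Numeric vector of item responses in 1..4.
#' @return Recoded vector.
#' @export
recode_reverse <- function(x) {
  if (any(!is.na(x) & (x < 1 | x > 4)))
    stop("recode_reverse: items must be coded 1..4")
  5 - x
}

#' Dyadic liking sum
#'
#' Eight trait ratings (nice, fair, interesting, smart, cool, ready to help,
#' boring, mean) on a 1-4 Likert scale; the negatively framed items
#' (`reverse_items`) are recoded `5 - x`. Per rater and timepoint, the item
#' mean is taken (a timepoint with more than two missing items is dropped);
#' per rater, the T0/T4 means are averaged; the dyad value is the sum of the
#' two rater values, range 2-8.
#'
#' @param items_a,items_b For each rater, a list of up to two numeric item
#'   vectors (named or ordered `T0`, `T4`), values 1-4 with `NA` for missing.
#' @param reverse_items Names or indices of reverse-keyed items (default
#'   `c("boring", "mean")`, positions 7 and 8 when unnamed).
#' @return Value in `[2, 8]`, or `NA` when a rater has no usable timepoint.
#' @export
liking_sum <- function(items_a, items_b, reverse_items = LIKING_REVERSE) {
  rater_value <- function(tp_list) {
    tp_means <- vapply(tp_list, function(items) {
      if (is.null(items)) return(NA_real_)
      items <- as.numeric(unlist(items))
      if (length(items) != 8L)
        stop("liking_sum: each timepoint needs 8 item responses")
      idx <- if (is.character(reverse_items))
        match(reverse_items, LIKING_ITEMS) else as.integer(reverse_items)
      items[idx] <- recode_reverse(items[idx])
      if (sum(is.na(items)) > 2L) return(NA_real_)
      mean(items, na.rm = TRUE)
    }, numeric(1))
    tp_means <- tp_means[!is.na(tp_means)]
    if (!length(tp_means)) NA_real_ else mean(tp_means)
  }
  rater_value(items_a) + rater_value(items_b)
}

#' Cronbach's alpha
#'
#' Internal consistency of an item battery:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`.
#'
#' @param item_matrix Numeric matrix, raters in rows, items in columns.
#' @param use Passed to [stats::var()] for missing-data handling (default
#'   `"everything"`; use `"pairwise.complete.obs"` for pairwise deletion).
#' @return Alpha (at most 1; can be negative), or `NA` when the total
#'   variance is zero.
#' @export
cronbach_alpha <- function(item_matrix, use = "everything") {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  if (k < 2L || nrow(item_matrix) < 2L)
    stop("cronbach_alpha: need at least 2 items and 2 raters")
  v_items <- sum(apply(item_matrix, 2L, stats::var, use = use))
  v_total <- stats::var(rowSums(item_matrix), use = use)
  if (!is.finite(v_total) || v_total == 0) return(NA_real_)
  k / (k - 1) * (1 - v_items / v_total)
}

#' Dyadic affect sums
#'
#' The dyad's total affective valence and arousal: plain sums of the two
#' members' post-discussion self-reports, each in 2-6.
#'
#' @param self_a,self_b Length-2 numeric `c(valence, arousal)` self-reports
#'   (1..3) of the two members at the same timepoint.
#' @return `list(valence_sum, arousal_sum)`; both `NA` when either report is
#'   missing.
#' @export
dyadic_sums <- function(self_a, self_b) {
  if (anyNA(self_a) || anyNA(self_b))
    return(list(valence_sum = NA_real_, arousal_sum = NA_real_))
  check_grid(self_a[1L], self_a[2L], "dyadic_sums")
  check_grid(self_b[1L], self_b[2L], "dyadic_sums")
  list(valence_sum = self_a[1L] + self_b[1L],
       arousal_sum = self_a[2L] + self_b[2L])
}

#' Gender combination of a dyad
#'
#' @param gender_a,gender_b `"female"` or `"male"`.
#' @return `"female_female"`, `"male_male"`, or `"mixed"` (the modelling
#'   reference level).
#' @export
gender_combo <- function(gender_a, gender_b) {
  g <- sort(c(gender_a, gender_b))
  if (identical(g, c("female", "female"))) "female_female"
  else if (identical(g, c("male", "male"))) "male_male"
  else "mixed"
}

#' Seating relation of a dyad in a circle
#'
#' Circular seat distance 1 is `adjacent`; the maximal circular distance
#' (`floor(n/2)`) is `across`; anything in between is `non_adjacent`.
#'
#' @param seat_a,seat_b Integer seat indices (1..`n_seats`).
#' @param n_seats Number of seats in the circle.
#' @return One of `"adjacent"`, `"across"`, `"non_adjacent"`.
#' @export
seating_relation <- function(seat_a, seat_b, n_seats) {
  stopifnot(n_seats >= 3L, seat_a != seat_b)
  d <- abs(seat_a - seat_b)
  d <- min(d, n_seats - d)
  if (d == 1L) "adjacent"                       # adjacency wins ties (n = 3)
  else if (d == floor(n_seats / 2)) "across"
  else "non_adjacent"
}

#' Body mass index
#'
#' @param weight_kg,height_m Weight (kg) and height (m).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) weight_kg / height_m^2

#' Assemble the dyad-level measures table
#'
#' Combines the roster and tidy questionnaire tables into one row per
#' within-group dyad: friendship status, gender combination, seating
#' relation, closeness and liking sums, affect coherence, dyadic valence and
#' arousal sums, and the dyadic empathic-accuracy sum. Dyads with missing
#' constituent reports carry `NA` in the affected columns.
#'
#' @param roster `list(subjects, dyads, nominations)` as produced by
#'   [generate_roster()] or read from file; `subjects` needs `subject_id`,
#'   `group_id`, `gender`, `seat`; `dyads` needs `dyad_id`, `group_id`,
#'   `member_a`, `member_b`.
#' @param questionnaires `list(affect, ios, liking)` tidy tables (see
#'   [generate_questionnaires()] for the layouts).
#' @return Data frame with one row per dyad.
#' @export
build_dyad_table <- function(roster, questionnaires) {
  subj <- roster$subjects
  dy <- roster$dyads
  noms <- split(roster$nominations$nominee_id,
                factor(roster$nominations$subject_id,
                       levels = subj$subject_id))
  aff <- questionnaires$affect
  ios <- questionnaires$ios
  lik <- questionnaires$liking
  self1 <- aff[aff$reporter_id == aff$target_id & aff$timepoint == "T1", ]
  rownames(self1) <- self1$reporter_id
  est1 <- aff[aff$reporter_id != aff$target_id & aff$timepoint == "T1", ]

  get_ios <- function(rater, target)
    vapply(c("T0", "T1"), function(tp) {
      v <- ios$ios[ios$rater_id == rater & ios$target_id == target &
                   ios$timepoint == tp]
      if (length(v)) v[1L] else NA_real_
    }, numeric(1))
  get_items <- function(rater, target)
    lapply(c("T0", "T4"), function(tp) {
      sub <- lik[lik$rater_id == rater & lik$target_id == target &
                 lik$timepoint == tp, ]
      if (!nrow(sub)) return(NULL)
      sub$response[match(LIKING_ITEMS, sub$item)]
    })
  get_est <- function(rater, target) {
    sub <- est1[est1$reporter_id == rater & est1$target_id == target, ]
    if (!nrow(sub)) return(NULL)
    c(sub$valence[1L], sub$arousal[1L])
  }
  one_acc <- function(rater, target) {
    e <- get_est(rater, target)
    if (is.null(e) || !target %in% rownames(self1)) return(NA_real_)
    s <- self1[target, ]
    empathic_accuracy(e[1L], e[2L], s$valence, s$arousal)
  }

  rows <- lapply(seq_len(nrow(dy)), function(k) {
    a <- dy$member_a[k]; b <- dy$member_b[k]
    sa <- subj[subj$subject_id == a, ]; sb <- subj[subj$subject_id == b, ]
    n_seats <- sum(subj$group_id == dy$group_id[k])
    coher <- val_sum <- aro_sum <- NA_real_
    if (a %in% rownames(self1) && b %in% rownames(self1)) {
      ra <- self1[a, ]; rb <- self1[b, ]
      coher <- affect_coherence(ra$valence, ra$arousal,
                                rb$valence, rb$arousal)
      ds <- dyadic_sums(c(ra$valence, ra$arousal), c(rb$valence, rb$arousal))
      val_sum <- ds$valence_sum; aro_sum <- ds$arousal_sum
    }
    acc_a <- one_acc(a, b); acc_b <- one_acc(b, a)
    data.frame(
      dyad_id = dy$dyad_id[k], group_id = dy$group_id[k],
      member_a = a, member_b = b,
      friendship = friendship_status(noms, c(a, b),
                                     roster = subj$subject_id),
      gender_combo = gender_combo(sa$gender, sb$gender),
      seating = seating_relation(sa$seat, sb$seat, n_seats),
      closeness_sum = closeness_sum(get_ios(a, b), get_ios(b, a)),
      liking_sum = liking_sum(get_items(a, b), get_items(b, a)),
      affect_coherence = coher, valence_sum = val_sum,
      arousal_sum = aro_sum,
      empathic_accuracy = acc_a + acc_b,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
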