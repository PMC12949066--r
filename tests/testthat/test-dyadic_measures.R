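test_that("affect coherence reproduces the grid constants", {
  expect_equal(affect_coherence(2, 2, 2, 2), sqrt(8))
  expect_equal(affect_coherence(1, 1, 3, 3), 0)
  expect_equal(affect_coherence(1, 3, 3, 3), sqrt(8) - 2)
  expect_error(affect_coherence(0, 2, 2, 2), "1..3")
  expect_error(affect_coherence(2, 2, 2, 4), "1..3")
})

test_that("affect coherence is symmetric and bounded over all 81 grid pairs", {
  grid <- expand.grid(va = 1:3, aa = 1:3, vb = 1:3, ab = 1:3)
  vals <- mapply(affect_coherence, grid$va, grid$aa, grid$vb, grid$ab)
  swapped <- mapply(affect_coherence, grid$vb, grid$ab, grid$va, grid$aa)
  expect_equal(vals, swapped)
  expect_true(all(vals >= 0 & vals <= sqrt(8) + 1e-12))
})

test_that("empathic accuracy scores estimates against actual reports", {
  expect_equal(empathic_accuracy(3, 1, 3, 1), sqrt(8))
  expect_equal(empathic_accuracy(1, 1, 3, 3), 0)
  expect_equal(empathic_accuracy(2, 3, 2, 1), sqrt(8) - 2)
  # dyad sum of two perfect estimates attains the 5.66 table maximum
  expect_equal(empathic_accuracy(2, 2, 2, 2) + empathic_accuracy(1, 3, 1, 3),
               2 * sqrt(8))
})

test_that("friendship status covers mutual, one-sided, none and is order-invariant", {
  noms <- list(A = c("B", "C"), B = "A", C = character(), D = "A")
  expect_equal(friendship_status(noms, c("A", "B")), "mutual")
  expect_equal(friendship_status(noms, c("B", "A")), "mutual")
  expect_equal(friendship_status(noms, c("A", "C")), "one_sided")
  expect_equal(friendship_status(noms, c("A", "D")), "one_sided")
  expect_equal(friendship_status(noms, c("B", "C")), "none")
})

test_that("friendship status ignores self-nominations and warns on unknown ids", {
  noms <- list(A = c("A", "B"), B = c("A", "ghost"))
  expect_warning(st <- friendship_status(noms, c("A", "B"),
                                         roster = c("A", "B")),
                 "ghost")
  expect_equal(st, "mutual")
})

test_that("closeness sums rater means over T0/T1", {
  expect_equal(closeness_sum(c(3, 3), c(1, 2)), 4.5)
  expect_equal(closeness_sum(c(6, 6), c(6, 6)), 12)
  expect_equal(closeness_sum(c(4, NA), c(2, 2)), 6)
  expect_true(is.na(closeness_sum(c(NA, NA), c(2, 2))))
  expect_error(closeness_sum(c(7, 2), c(1, 1)), "0..6")
})

test_that("liking sum recodes, averages items and timepoints, then sums raters", {
  best <- c(4, 4, 4, 4, 4, 4, 1, 1)    # reverse items answered low
  worst <- c(1, 1, 1, 1, 1, 1, 4, 4)
  expect_equal(liking_sum(list(best, best), list(best, best)), 8)
  expect_equal(liking_sum(list(worst, worst), list(worst, worst)), 2)
  a <- c(3, 3, 3, 3, 3, 3, 2, 2)       # recodes to all 3s -> rater 3.0
  expect_equal(liking_sum(list(a, a), list(best, best)), 7)
  # a timepoint with > 2 missing items is dropped for that rater
  holes <- c(4, 4, 4, NA, NA, NA, 1, 1)
  expect_equal(liking_sum(list(holes, best), list(best, best)), 8)
  expect_true(is.na(liking_sum(list(holes, holes), list(best, best))))
})

test_that("reverse coding is involutive", {
  x <- c(1, 2, 3, 4, NA)
  expect_equal(recode_reverse(recode_reverse(x)), x)
  expect_error(recode_reverse(c(0, 5)), "1..4")
})

test_that("cronbach alpha hits its closed forms", {
  set.seed(10)
  base <- rnorm(200)
  perfect <- cbind(base, base, base)
  expect_equal(cronbach_alpha(perfect), 1)
  # two-item closed form 4c/(v1 + v2 + 2c) from the same sample moments
  x <- rnorm(500); y <- 0.6 * x + rnorm(500, 0, 0.8)
  m <- cbind(x, y)
  cc <- stats::cov(x, y)
  expect_equal(cronbach_alpha(m),
               4 * cc / (stats::var(x) + stats::var(y) + 2 * cc),
               tolerance = 1e-12)
  expect_true(is.na(cronbach_alpha(matrix(1, 5, 3))))
  expect_error(cronbach_alpha(matrix(1, 1, 3)), "at least")
})

test_that("independent equal-variance items give alpha near zero", {
  set.seed(11)
  m <- matrix(rnorm(1000 * 8), ncol = 8)
  expect_lt(abs(cronbach_alpha(m)), 0.1)
})

test_that("dyadic affect sums add the two members' reports", {
  s <- dyadic_sums(c(3, 3), c(3, 3))
  expect_equal(s$valence_sum, 6)
  expect_equal(s$arousal_sum, 6)
  expect_equal(dyadic_sums(c(2, 1), c(3, 1))$valence_sum, 5)
  expect_equal(dyadic_sums(c(2, 1), c(3, 1))$arousal_sum, 2)
  expect_true(is.na(dyadic_sums(c(NA, 2), c(3, 3))$valence_sum))
})

test_that("gender combination and seating relation are classified correctly", {
  expect_equal(gender_combo("female", "male"), "mixed")
  expect_equal(gender_combo("male", "female"), "mixed")
  expect_equal(gender_combo("female", "female"), "female_female")
  expect_equal(seating_relation(1, 2, 5), "adjacent")
  expect_equal(seating_relation(1, 5, 5), "adjacent")   # circular wrap
  expect_equal(seating_relation(1, 3, 6), "non_adjacent")
  expect_equal(seating_relation(1, 4, 6), "across")
  expect_equal(seating_relation(2, 4, 4), "across")
})

test_that("bmi is weight over height squared", {
  expect_equal(bmi(50, 1.5), 50 / 2.25)
})

test_that("build_dyad_table assembles a consistent dyad row", {
  roster <- list(
    subjects = data.frame(subject_id = c("A", "B", "C"), group_id = "g1",
                          gender = c("female", "male", "female"),
                          seat = 1:3, stringsAsFactors = FALSE),
    dyads = data.frame(dyad_id = c("d1", "d2", "d3"), group_id = "g1",
                       member_a = c("A", "A", "B"),
                       member_b = c("B", "C", "C"),
                       stringsAsFactors = FALSE),
    nominations = data.frame(subject_id = c("A", "B"),
                             nominee_id = c("B", "A"),
                             stringsAsFactors = FALSE))
  affect <- rbind(
    data.frame(reporter_id = c("A", "B", "C"),
               target_id = c("A", "B", "C"), timepoint = "T1",
               valence = c(2, 3, 1), arousal = c(2, 3, 1)),
    data.frame(reporter_id = c("A", "B"), target_id = c("B", "A"),
               timepoint = "T1", valence = c(3, 2), arousal = c(3, 2)))
  ios <- expand.grid(rater_id = c("A", "B"), target_id = c("A", "B"),
                     timepoint = c("T0", "T1"), stringsAsFactors = FALSE)
  ios <- ios[ios$rater_id != ios$target_id, ]
  ios$ios <- 4
  lik <- do.call(rbind, lapply(c("T0", "T4"), function(tp)
    data.frame(rater_id = c(rep("A", 8), rep("B", 8)),
               target_id = c(rep("B", 8), rep("A", 8)), timepoint = tp,
               item = rep(dyadsync:::LIKING_ITEMS, 2),
               response = rep(c(4, 4, 4, 4, 4, 4, 1, 1), 2),
               stringsAsFactors = FALSE)))
  tab <- build_dyad_table(roster, list(affect = affect, ios = ios,
                                       liking = lik))
  d1 <- tab[tab$dyad_id == "d1", ]
  expect_equal(d1$friendship, "mutual")
  expect_equal(d1$gender_combo, "mixed")
  expect_equal(d1$closeness_sum, 8)
  expect_equal(d1$liking_sum, 8)
  expect_equal(d1$affect_coherence, sqrt(8) - sqrt(2))
  expect_equal(d1$valence_sum, 5)
  expect_equal(d1$empathic_accuracy, 2 * sqrt(8))  # both estimates perfect
  d2 <- tab[tab$dyad_id == "d2", ]
  expect_equal(d2$friendship, "none")
  expect_true(is.na(d2$closeness_sum))   # C never rated anyone
})

test_that("all dyadic variables respect their instrument ranges on a generated cohort", {
  cfg <- cohort_config(n_groups = 6, seed = 21)
  roster <- generate_roster(cfg)
  quest <- generate_questionnaires(roster, cfg)
  tab <- build_dyad_table(roster, quest)
  ok <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  expect_true(ok(tab$closeness_sum, 0, 12))
  expect_true(ok(tab$liking_sum, 2, 8))
  expect_true(ok(tab$affect_coherence, 0, sqrt(8)))
  expect_true(ok(tab$valence_sum, 2, 6))
  expect_true(ok(tab$arousal_sum, 2, 6))
  expect_true(ok(tab$empathic_accuracy, 0, 2 * sqrt(8)))
  expect_true(all(tab$friendship %in% c("none", "one_sided", "mutual")))
})
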