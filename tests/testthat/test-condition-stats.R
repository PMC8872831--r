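test_that("Spearman correlation matches hand-computed values", {
  expect_equal(rank_correlation(1:10, 1:10)$rho, 1)
  expect_equal(rank_correlation(1:10, 10:1)$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 = (4, 1, 1)
  expect_equal(rank_correlation(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:3, 1:4), "equal length")
})

test_that("KS statistic equals the ECDF supremum distance", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3)
})

test_that("signed-rank Z matches the exhaustive sign-flip enumeration for small n", {
  expect_error(wilcoxon_paired(1:5, 1:5), "degenerate")

  a <- c(1, 2, 3, 4, 5); b <- a + 1
  expect_lt(wilcoxon_paired(a, b)$Z, 0)
  expect_equal(wilcoxon_paired(b, a)$Z, -wilcoxon_paired(a, b)$Z)

  set.seed(42)
  for (i in 1:12) {
    n <- sample(10:12, 1)
    x <- round(stats::rnorm(n), 1)
    y <- round(stats::rnorm(n), 1)
    if (all(x == y)) next
    res <- wilcoxon_paired(x, y)
    expect_lt(abs(res$p - exact_signed_rank_p(x - y)), 0.06)
    # the same normal approximation as the reference implementation
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = FALSE))
    expect_equal(res$p, wt$p.value, tolerance = 1e-8)
  }
})

test_that("agreement reproduces the validation-session summary figures", {
  tab <- synthetic_ratings_table()
  expect_equal(nrow(tab), 208)

  ag <- agreement(tab)
  expect_equal(ag$percent, 95.7)
  expect_equal(ag$matched, 199)
  expect_equal(ag$total, 208)
  by_stim <- ag$by_stimulus
  expect_equal(by_stim$percent[by_stim$group == "word"], 100)
  expect_equal(by_stim$percent[by_stim$group == "vowel"], 91.3)
  by_cond <- ag$by_condition
  expect_equal(by_cond$percent[by_cond$group == "hypernasal"], 92.0)
  expect_equal(by_cond$percent[by_cond$group == "normal"], 90.7)

  kept <- tab[!tab$word %in% excluded_words(), ]
  agk <- agreement(kept)
  expect_equal(agk$percent, 96.9)
  expect_equal(agk$matched, 154)
  expect_equal(agk$total, 159)

  # permutation invariance over row order
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(agreement(shuffled)$percent, ag$percent)

  all_match <- data.frame(word = "bee", stimulus_type = "vowel",
                          intended = "hypernasal", verdict = "present")
  expect_equal(agreement(all_match)$percent, 100)
})

test_that("could-not-tell counts as disagreement", {
  tab <- data.frame(word = "x", stimulus_type = "vowel",
                    intended = c("hypernasal", "normal"),
                    verdict = c("could_not_tell", "could_not_tell"))
  expect_equal(agreement(tab)$matched, 0)
})

test_that("Cohen's kappa matches hand computation and edge cases", {
  perfect <- data.frame(verdict_first = c("present", "absent", "present"),
                        verdict_repeat = c("present", "absent", "present"))
  expect_equal(cohens_kappa(perfect)$kappa, 1)

  # 2x2 table [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  tab22 <- data.frame(
    verdict_first = rep(c("present", "present", "absent", "absent"),
                        c(20, 5, 10, 15)),
    verdict_repeat = rep(c("present", "absent", "present", "absent"),
                         c(20, 5, 10, 15)))
  expect_equal(cohens_kappa(tab22)$kappa, 0.4)

  # agreement exactly at chance
  chance <- data.frame(
    verdict_first = rep(c("present", "present", "absent", "absent"),
                        c(25, 25, 25, 25)),
    verdict_repeat = rep(c("present", "absent", "present", "absent"),
                         c(25, 25, 25, 25)))
  expect_equal(cohens_kappa(chance)$kappa, 0)

  # repeat pairs of the synthetic session: 94 % agreement, kappa 0.88
  pairs <- repeat_pairs(synthetic_ratings_table())
  expect_equal(nrow(pairs), 52)
  kp <- cohens_kappa(pairs)
  expect_equal(round(100 * kp$p_o), 94)
  expect_equal(round(kp$kappa, 2), 0.88)
})

test_that("logistic calibration evaluates, fits and guards degenerate data", {
  # direct evaluation of the calibration line at nasalance 60
  expect_equal(logistic_probability(60, b0 = -4.2588, b1 = 0.0863),
               0.7149, tolerance = 1e-4)
  expect_equal(-(-4.2588) / 0.0863, 49.3488, tolerance = 1e-4)

  # parameter recovery from a known generating model
  set.seed(99)
  n <- 2000
  x <- stats::runif(n, 10, 90)
  y <- stats::runif(n) < stats::plogis(-4.2588 + 0.0863 * x)
  fit <- fit_logistic(x, y)
  se <- summary(fit$fit)$coefficients[, 2]
  expect_lt(abs(fit$b0 - (-4.2588)), 3 * se[1])
  expect_lt(abs(fit$b1 - 0.0863), 3 * se[2])
  expect_equal(fit$halfway, -fit$b0 / fit$b1)
  expect_lt(fit$p, 0.01)

  expect_error(fit_logistic(x, rep(1, n)), "both rating classes")
  sep_x <- c(1:10, 61:70)
  sep_y <- sep_x > 50
  expect_error(fit_logistic(sep_x, sep_y), "separation")
})

test_that("correlation report partitions pairs and reproduces the reference tables", {
  f <- default_grid()$frequencies
  set.seed(5)
  vals <- stats::runif(355, 0.5, 2)
  same <- lapply(c(rep("hypernasal", 3), rep("normal", 3)), function(cond)
    transfer_function(f, vals, 11, condition = cond, harmonics_removed = TRUE))
  cr <- correlation_report(same)
  expect_equal(nrow(cr$within), 6)
  expect_equal(nrow(cr$across), 9)
  expect_true(all(cr$within$rho == 1))
  expect_true(all(cr$across$rho == 1))
  expect_equal(cr$within_range, 0)

  unflagged <- same
  unflagged[[1]]$harmonics_removed <- FALSE
  expect_error(correlation_report(unflagged), "harmonics removed")

  # printed worked example: dawn within-HN pairs and across pairs
  within <- reference_within_correlations()
  dawn <- within[within$vowel == "dawn", ]
  expect_equal(round(mean(as.numeric(dawn[c("hn1_hn2", "hn1_hn3", "hn2_hn3")])), 2),
               0.87)
  expect_equal(round(mean(reference_across_correlations_dawn()$rho), 2), 0.71)

  all_within <- as.matrix(within[, -1])
  expect_equal(max(all_within) - min(all_within), 0.18)
})

test_that("difference spectrum is zero for identical groups and checks axes", {
  f <- default_grid()$frequencies
  mk <- function(v, cond) transfer_function(f, v, 11, condition = cond,
                                            harmonics_removed = TRUE)
  set.seed(2)
  v <- stats::runif(355, 0.5, 2)
  ds <- difference_spectrum(list(mk(v, "hypernasal")), list(mk(v, "normal")))
  expect_true(all(ds$values == 0))

  short <- transfer_function(f[1:100], v[1:100], 11, condition = "normal",
                             harmonics_removed = TRUE)
  expect_error(difference_spectrum(list(mk(v, "hypernasal")), list(short)),
               "frequency axis")
  raw <- transfer_function(f, v, 11, condition = "normal")
  expect_error(difference_spectrum(list(mk(v, "hypernasal")), list(raw)),
               "harmonics removed")
  expect_error(band_mean(ds, 10, 20), "no frequency bins")
})
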