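# Validation and condition-comparison statistics: rank correlation within and
# across speech conditions, distribution tests, rater agreement, logistic
# calibration of perceptual ratings against nasalance, and condition
# difference spectra.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the t
#' approximation (never the exact permutation distribution).
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
rank_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("'a' and 'b' must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("rank correlation is undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value is
#' asymptotic.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Signed-rank test applied pairwise (here typically bin-wise to two transfer
#' functions): zero differences are dropped, tied absolute differences get
#' average ranks, and the Z statistic uses the normal approximation with tie
#' correction (no continuity correction). Positive Z means `a` tends to exceed
#' `b`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return List with `Z`, `p` (two-sided) and `n` (non-zero differences).
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stop("degenerate test: zero variance")
  z <- (w_plus - mu) / sqrt(sigma2)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Rater agreement with intended condition
#'
#' A presentation matches when the intended condition and the verdict agree
#' (`hypernasal` with `present`, `normal` with `absent`); a
#' `could_not_tell` verdict never matches. Percentages are rounded to one
#' decimal.
#'
#' @param table Ratings data frame with columns `word`, `stimulus_type`
#'   (`"word"` or `"vowel"`), `intended` (`"normal"` / `"hypernasal"`) and
#'   `verdict` (`"present"` / `"absent"` / `"could_not_tell"`).
#' @return List with `percent`, `matched`, `total`, plus data frames
#'   `by_stimulus` and `by_condition` (vowel stimuli only) with the same
#'   three columns per group.
#' @export
agreement <- function(table) {
  if (nrow(table) == 0L) stop("ratings table is empty")
  matched <- (table$intended == "hypernasal" & table$verdict == "present") |
    (table$intended == "normal" & table$verdict == "absent")
  pct <- function(m) round(100 * sum(m) / length(m), 1)
  summarize_by <- function(groups) {
    do.call(rbind, lapply(split(seq_along(matched), groups), function(i)
      data.frame(group = groups[i[1L]], percent = pct(matched[i]),
                 matched = sum(matched[i]), total = length(i))))
  }
  vowels <- table$stimulus_type == "vowel"
  by_condition <- if (any(vowels)) {
    vm <- matched[vowels]
    vi <- table$intended[vowels]
    do.call(rbind, lapply(split(seq_along(vm), vi), function(i)
      data.frame(group = vi[i[1L]], percent = pct(vm[i]),
                 matched = sum(vm[i]), total = length(i))))
  } else NULL
  list(percent = pct(matched),
       matched = sum(matched),
       total = length(matched),
       by_stimulus = summarize_by(table$stimulus_type),
       by_condition = by_condition)
}

#' Cohen's kappa over repeat ratings
#'
#' Chance-corrected agreement over the full three-way verdict set
#' (`present` / `absent` / `could_not_tell`): `kappa = (p_o - p_e) /
#' (1 - p_e)` with expected agreement from the marginal products.
#'
#' @param pairs Data frame with columns `verdict_first` and `verdict_repeat`.
#' @return List with `kappa`, `p_o` (observed agreement) and `p_e`.
#' @export
cohens_kappa <- function(pairs) {
  if (nrow(pairs) < 2L) stop("need at least two repeat pairs")
  lev <- c("present", "absent", "could_not_tell")
  f <- factor(pairs$verdict_first, levels = lev)
  r <- factor(pairs$verdict_repeat, levels = lev)
  tab <- table(f, r)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) stop("kappa is undefined: expected agreement is 1")
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e)
}

#' Logistic calibration of perceptual ratings against nasalance
#'
#' One-predictor binomial logistic regression (maximum likelihood via IRLS,
#' coefficient tolerance 1e-8) of the binary "rated hypernasal" outcome on
#' percent nasalance. The halfway point `-b0 / b1` is the nasalance at which
#' the predicted probability is 0.5.
#'
#' @param nasalance Numeric vector of percent nasalance values.
#' @param rated_hypernasal Logical/0-1 vector of the same length.
#' @return An object of class `logistic_fit`: list with `b0`, `b1`,
#'   `halfway`, `p` (Wald p-value of the slope) and the underlying `glm` fit.
#' @export
fit_logistic <- function(nasalance, rated_hypernasal) {
  y <- as.integer(rated_hypernasal)
  if (length(nasalance) != length(y))
    stop("'nasalance' and 'rated_hypernasal' must have equal length")
  if (length(unique(y)) < 2L)
    stop("both rating classes must be present")
  fit <- suppressWarnings(
    stats::glm(y ~ nasalance, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- stats::fitted(fit)
  if (all(mu > 1 - 1e-8 | mu < 1e-8))
    stop("perfect separation: logistic coefficients are unbounded")
  b <- stats::coef(fit)
  if (b[2L] == 0) stop("slope is zero; halfway point undefined")
  structure(list(b0 = unname(b[1L]), b1 = unname(b[2L]),
                 halfway = unname(-b[1L] / b[2L]),
                 p = summary(fit)$coefficients[2L, 4L],
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: logit(p) = %.4f + %.4f * nasalance; halfway %.2f%% (slope p = %.3g)>\n",
              x$b0, x$b1, x$halfway, x$p))
  invisible(x)
}

#' Predicted probability from a logistic calibration
#'
#' Evaluates `plogis(b0 + b1 * nasalance)` for a fit or for explicit
#' coefficients.
#'
#' @param nasalance Percent nasalance value(s).
#' @param fit A [fit_logistic()] result, or `NULL` when `b0`/`b1` are given.
#' @param b0,b1 Explicit coefficients (used when `fit` is `NULL`).
#' @return Predicted probability of being rated hypernasal.
#' @export
logistic_probability <- function(nasalance, fit = NULL, b0 = NULL, b1 = NULL) {
  if (!is.null(fit)) { b0 <- fit$b0; b1 <- fit$b1 }
  stats::plogis(b0 + b1 * nasalance)
}

#' Within/across-condition correlation report
#'
#' Takes the six transfer functions of one vowel (three takes per speech
#' condition, all with harmonics removed) and computes every pairwise Spearman
#' correlation: three within-hypernasal pairs, three within-normal pairs, and
#' nine across-condition pairs, with the per-group means and the min/max/range
#' of the within-condition coefficients. Report means are rounded to two
#' decimals, as is conventional for these tables.
#'
#' @param tfs List of six [transfer_function()]s with `condition` labels
#'   (three `"hypernasal"`, three `"normal"`), all flagged
#'   `harmonics_removed`.
#' @return An object of class `correlation_report`: list with data frames
#'   `within` and `across` (pair labels, `rho`, `p`), the rounded means
#'   `mean_within_hn`, `mean_within_n`, `mean_across`, and `within_min`,
#'   `within_max`, `within_range`.
#' @export
correlation_report <- function(tfs) {
  if (length(tfs) != 6L) stop("need exactly six transfer functions (3 takes x 2 conditions)")
  conds <- vapply(tfs, function(tf) tf$condition %||% NA_character_, character(1))
  if (sum(conds == "hypernasal", na.rm = TRUE) != 3L ||
      sum(conds == "normal", na.rm = TRUE) != 3L)
    stop("need three 'hypernasal' and three 'normal' transfer functions")
  if (!all(vapply(tfs, function(tf) tf$harmonics_removed, logical(1))))
    stop("all transfer functions must have harmonics removed first")
  hn <- which(conds == "hypernasal")
  nm <- which(conds == "normal")
  label <- function(i) {
    k <- if (conds[i] == "hypernasal") match(i, hn) else match(i, nm)
    paste0(if (conds[i] == "hypernasal") "HN" else "N", k)
  }
  pair_rows <- function(idx_pairs) {
    do.call(rbind, lapply(idx_pairs, function(pr) {
      rc <- rank_correlation(tfs[[pr[1L]]]$values, tfs[[pr[2L]]]$values)
      data.frame(pair = paste(label(pr[1L]), label(pr[2L]), sep = "-"),
                 rho = rc$rho, p = rc$p)
    }))
  }
  within <- pair_rows(c(utils::combn(hn, 2, simplify = FALSE),
                        utils::combn(nm, 2, simplify = FALSE)))
  across <- pair_rows(unlist(lapply(nm, function(i)
    lapply(hn, function(j) c(i, j))), recursive = FALSE))
  w_hn <- within$rho[1:3]
  w_n <- within$rho[4:6]
  structure(list(within = within, across = across,
                 mean_within_hn = round(mean(w_hn), 2),
                 mean_within_n = round(mean(w_n), 2),
                 mean_across = round(mean(across$rho), 2),
                 within_min = min(within$rho),
                 within_max = max(within$rho),
                 within_range = max(within$rho) - min(within$rho)),
            class = "correlation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report: within HN %.2f, within N %.2f, across %.2f; within range %.2f>\n",
    x$mean_within_hn, x$mean_within_n, x$mean_across, x$within_range))
  invisible(x)
}

#' Condition difference spectrum
#'
#' Per-bin difference between the mean hypernasal and the mean normal
#' transfer function: a negative value means the normal condition has the
#' greater value at that frequency.
#'
#' @param hn,nm Lists of [transfer_function()]s sharing one frequency axis,
#'   all flagged `harmonics_removed`.
#' @param scope `"per-vowel"` or `"pooled"` tag recorded on the result.
#' @return An object of class `difference_spectrum`: list with `frequencies`,
#'   `values` (mean hypernasal minus mean normal) and `scope`.
#' @export
difference_spectrum <- function(hn, nm, scope = c("per-vowel", "pooled")) {
  scope <- match.arg(scope)
  all_tf <- c(hn, nm)
  if (length(hn) == 0L || length(nm) == 0L)
    stop("both condition groups must be non-empty")
  f <- all_tf[[1L]]$frequencies
  for (tf in all_tf) {
    if (!isTRUE(all.equal(tf$frequencies, f)))
      stop("all transfer functions must share one frequency axis")
    if (!tf$harmonics_removed)
      stop("all transfer functions must have harmonics removed first")
  }
  mean_vals <- function(tfl)
    rowMeans(vapply(tfl, function(tf) tf$values, numeric(length(f))))
  structure(list(frequencies = f,
                 values = mean_vals(hn) - mean_vals(nm),
                 scope = scope),
            class = "difference_spectrum")
}

#' Band mean of a difference spectrum
#'
#' Mean difference value over a frequency band (inclusive edges).
#'
#' @param ds A [difference_spectrum()].
#' @param low,high Band edges in Hz.
#' @return Single numeric band mean.
#' @export
band_mean <- function(ds, low, high) {
  stopifnot(inherits(ds, "difference_spectrum"))
  sel <- ds$frequencies >= low & ds$frequencies <= high
  if (!any(sel)) stop("band contains no frequency bins")
  mean(ds$values[sel])
}
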