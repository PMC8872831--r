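# Loaders for the reference correlation tables shipped with the package:
# Spearman coefficients between repeated nostril-resonance transfer-function
# measurements from a single-speaker validation dataset (ten vowels, three
# takes per speech condition). Used by the worked examples and the
# reproduction checks.

ref_csv <- function(name)
  utils::read.csv(system.file("extdata", name, package = "nrmd",
                              mustWork = TRUE))

#' Within-condition reference correlations
#'
#' Spearman correlation coefficients between the three take pairs of each
#' speech condition (hypernasal takes HN1-HN3, normal takes N1-N3) for ten
#' vowels, from the single-speaker validation dataset shipped with the
#' package.
#'
#' @return Data frame with columns `vowel`, `hn1_hn2`, `hn1_hn3`, `hn2_hn3`,
#'   `n1_n2`, `n1_n3`, `n2_n3`.
#' @export
reference_within_correlations <- function()
  ref_csv("within_condition_correlations.csv")

#' Across-condition reference correlations for "dawn"
#'
#' The nine across-condition Spearman coefficients (each normal take against
#' each hypernasal take) for the vowel in "dawn".
#'
#' @return Data frame with columns `pair` and `rho`.
#' @export
reference_across_correlations_dawn <- function()
  ref_csv("dawn_across_correlations.csv")

#' Per-vowel reference correlation means
#'
#' Mean within-condition and across-condition Spearman coefficients per
#' vowel.
#'
#' @return Data frame with columns `vowel`, `mean_within_hn`,
#'   `mean_within_n`, `mean_across`.
#' @export
reference_correlation_means <- function()
  ref_csv("across_condition_means.csv")
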