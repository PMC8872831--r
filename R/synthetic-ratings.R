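# Synthetic reconstruction of the perceptual-rating session.
#
# The per-token expert ratings of the single-speaker validation study are not
# distributed, so this module constructs a deterministic SYNTHETIC session
# whose marginal counts match every reported summary figure: 208
# presentations (156 unique tokens + 52 repeats, split evenly between whole
# words and isolated vowels); all whole-word presentations rated correctly;
# nine vowel mismatches on barn (x3), book (x2), burn (x2), bun and dune
# split 4 hypernasal / 5 normal; and 52 repeat pairs of which 49 agree. It
# is a stand-in for the study table, not the study table itself.

.words <- c("bee", "den", "bell", "ban", "barn", "dawn", "doll",
            "bow", "boot", "dune", "bun", "burn", "book")
.high_nasalance_words <- c("ban", "barn", "bun")

# Tokens repeated for intra-rater reliability, by group and condition.
.repeat_tokens <- list(
  word = list(
    hypernasal = c("ban_1", "ban_2", "ban_3", "barn_1", "barn_2", "bun_1",
                   "bee_1", "bell_1", "den_1", "doll_1", "boot_1", "bow_1",
                   "dawn_1"),
    normal = c("ban_1", "ban_2", "barn_1", "barn_2", "bun_1", "bee_1",
               "bell_1", "den_1", "doll_1", "boot_1", "bow_1", "dawn_1",
               "dune_1")),
  vowel = list(
    hypernasal = c("barn_2", "bee_1", "den_1", "bell_1", "boot_1", "dune_1",
                   "doll_1", "bow_1", "burn_1", "book_1", "dawn_1"),
    normal = c("barn_1", "dune_2", "bee_1", "den_1", "bell_1", "boot_1",
               "doll_1", "bow_1", "burn_1", "book_1", "dawn_1", "bee_2",
               "den_2", "bell_2", "boot_2")))

# Verdict overrides (everything else is rated as intended). Keys are
# group_word_condition_take:presentation.
.verdict_overrides <- c(
  "vowel_barn_hypernasal_1:first"  = "could_not_tell",
  "vowel_barn_hypernasal_2:first"  = "absent",
  "vowel_barn_hypernasal_2:repeat" = "present",
  "vowel_barn_normal_1:first"      = "present",
  "vowel_barn_normal_1:repeat"     = "absent",
  "vowel_book_hypernasal_3:first"  = "could_not_tell",
  "vowel_book_normal_2:first"      = "could_not_tell",
  "vowel_burn_hypernasal_2:first"  = "absent",
  "vowel_burn_normal_3:first"      = "present",
  "vowel_bun_normal_1:first"       = "could_not_tell",
  "vowel_dune_normal_2:first"      = "present",
  "vowel_dune_normal_2:repeat"     = "absent")

#' Synthetic perceptual-rating session
#'
#' Deterministically constructs a synthetic listening-test table: 13 CVC
#' words x 2 speech conditions x 3 takes, presented both as whole words and
#' as isolated vowels (156 unique tokens), with 26 tokens per stimulus group
#' repeated for intra-rater reliability (208 presentations in all). Verdicts
#' are the intended condition except for nine vowel-token mismatches and
#' three repeat disagreements, so the table reproduces the summary figures of
#' the validation study it stands in for (95.7 % overall agreement, 100 %
#' for words, 91.3 % for vowels, 96.9 % after excluding the three
#' high-nasalance words, 94 % repeat agreement, kappa 0.88).
#'
#' @return Data frame with columns `token_id`, `word`, `stimulus_type`
#'   (`"word"` / `"vowel"`), `take`, `intended`, `verdict` and `is_repeat`.
#' @seealso [repeat_pairs()], [agreement()], [cohens_kappa()]
#' @export
synthetic_ratings_table <- function() {
  grid <- expand.grid(take = 1:3,
                      intended = c("hypernasal", "normal"),
                      word = .words,
                      stimulus_type = c("vowel", "word"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tok <- paste(g$word, g$take, sep = "_")
    token_id <- paste(g$stimulus_type, g$word, g$intended, g$take, sep = "_")
    repeated <- tok %in% .repeat_tokens[[g$stimulus_type]][[g$intended]]
    pres <- if (repeated) c("first", "repeat") else "first"
    do.call(rbind, lapply(pres, function(p) {
      key <- paste0(token_id, ":", p)
      verdict <- if (key %in% names(.verdict_overrides))
        unname(.verdict_overrides[[key]])
      else if (g$intended == "hypernasal") "present" else "absent"
      data.frame(token_id = token_id, word = g$word,
                 stimulus_type = g$stimulus_type, take = g$take,
                 intended = g$intended, verdict = verdict,
                 is_repeat = (p == "repeat"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract repeat pairs from a ratings table
#'
#' Pairs the first and repeat presentation of every repeated token, the input
#' for [cohens_kappa()].
#'
#' @param table A ratings table in the [synthetic_ratings_table()] layout.
#' @return Data frame with columns `token_id`, `verdict_first`,
#'   `verdict_repeat`.
#' @export
repeat_pairs <- function(table) {
  firsts <- table[!table$is_repeat, ]
  reps <- table[table$is_repeat, ]
  m <- match(reps$token_id, firsts$token_id)
  if (anyNA(m)) stop("repeat presentation without a first presentation")
  data.frame(token_id = reps$token_id,
             verdict_first = firsts$verdict[m],
             verdict_repeat = reps$verdict,
             stringsAsFactors = FALSE)
}

#' Words excluded for high normal-condition nasalance
#'
#' The three words whose normal-condition nasalance exceeds the expected
#' normal range (anticipatory articulation of the nasal consonant) and which
#' are therefore excluded from the condition-comparison analyses.
#'
#' @return Character vector of word names.
#' @export
excluded_words <- function() .high_nasalance_words

#' Recording plan for one word
#'
#' The alternating measurement schedule used for every word: within each of
#' three takes, four recordings (acoustic then resonance setup, normal then
#' hypernasal condition), giving 12 measurements per word.
#'
#' @return Data frame with columns `recording`, `take`, `setup`,
#'   `condition`.
#' @export
recording_plan <- function() {
  plan <- expand.grid(condition = c("normal", "hypernasal"),
                      setup = c("acoustic", "resonance"),
                      take = 1:3,
                      stringsAsFactors = FALSE)
  data.frame(recording = seq_len(nrow(plan)),
             take = plan$take, setup = plan$setup,
             condition = plan$condition, stringsAsFactors = FALSE)
}
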