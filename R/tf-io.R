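# Transfer-function interchange: CSV of (frequency_hz, ratio) plus a JSON
# sidecar carrying the metadata (window count, condition label, flags).
# Plain text keeps the measurement inspectable; round-trips are lossless at
# full double precision.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a transfer function
#'
#' Writes the ratio values as a two-column CSV (`frequency_hz`, `ratio`) with
#' 17 significant digits, and the metadata (`n_windows`, `condition`,
#' `harmonics_removed`) as a JSON sidecar next to it (same name, `.json`).
#'
#' @param tf A [transfer_function()].
#' @param path Output CSV path (should end in `.csv`).
#' @return `path`, invisibly.
#' @export
write_tf <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  df <- data.frame(frequency_hz = sprintf("%.17g", tf$frequencies),
                   ratio = sprintf("%.17g", tf$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(n_windows = tf$n_windows,
               condition = tf$condition,
               harmonics_removed = tf$harmonics_removed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a transfer function
#'
#' Reads a CSV written by [write_tf()] together with its JSON sidecar. A
#' missing sidecar yields `n_windows = 1`, no condition and
#' `harmonics_removed = FALSE`.
#'
#' @param path CSV path.
#' @return A [transfer_function()].
#' @export
read_tf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("frequency_hz", "ratio") %in% names(df)))
    stop(sprintf("malformed transfer-function CSV (need frequency_hz, ratio columns): %s",
                 path))
  if (nrow(df) == 0L || anyNA(df$frequency_hz) || anyNA(df$ratio))
    stop(sprintf("malformed transfer-function CSV (non-numeric or empty): %s", path))
  meta <- list(n_windows = 1L, condition = NULL, harmonics_removed = FALSE)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    m <- jsonlite::read_json(sp)
    meta$n_windows <- m$n_windows %||% 1L
    meta$condition <- m$condition
    meta$harmonics_removed <- isTRUE(m$harmonics_removed)
  }
  transfer_function(df$frequency_hz, df$ratio, meta$n_windows,
                    condition = meta$condition,
                    harmonics_removed = meta$harmonics_removed)
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines (one per line, `#` comments allowed); values
#' that look numeric are coerced.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("malformed config line '%s' in %s", ln, path))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
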