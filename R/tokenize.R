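#' Tokenizer configuration
#'
#' Settings controlling how raw note text is split into tokens. Tokenization
#' is deterministic: the same text and configuration always yield the same
#' token sequence.
#'
#' @param lowercase Lowercase all tokens (default `TRUE`).
#' @param split_punctuation Detach punctuation characters into their own
#'   single-character tokens (default `TRUE`). Tokens mixing letters and
#'   digits, such as drug doses (`"10mg"`), are left intact because they
#'   contain no punctuation.
#' @param keep_numbers Keep tokens consisting entirely of digits
#'   (default `TRUE`); when `FALSE` they are dropped after splitting.
#' @return An object of class `tokenizer_config`.
#' @examples
#' tokenize("Pt developed abd pain.", tokenizer_config())
#' @export
tokenizer_config <- function(lowercase = TRUE, split_punctuation = TRUE,
                             keep_numbers = TRUE) {
  stopifnot(is.logical(lowercase), is.logical(split_punctuation),
            is.logical(keep_numbers))
  structure(list(lowercase = lowercase,
                 split_punctuation = split_punctuation,
                 keep_numbers = keep_numbers),
            class = "tokenizer_config")
}

#' Tokenize a piece of text
#'
#' Splits text on whitespace, optionally detaching punctuation into separate
#' tokens and lowercasing. Empty text yields a zero-length character vector.
#' The function is idempotent on its own output re-joined with single spaces
#' (with lowercasing enabled).
#'
#' @param text A single character string.
#' @param config A [tokenizer_config()].
#' @return Character vector of tokens (possibly empty). Tokens are non-empty
#'   and contain no internal whitespace.
#' @export
tokenize <- function(text, config = tokenizer_config()) {
  stopifnot(inherits(config, "tokenizer_config"))
  if (length(text) != 1L || is.na(text)) stop("`text` must be a single string")
  if (config$lowercase) text <- tolower(text)
  if (config$split_punctuation) {
    text <- gsub("([[:punct:]])", " \\1 ", text)
  }
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (!config$keep_numbers) toks <- toks[!grepl("^[0-9]+$", toks)]
  toks
}
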