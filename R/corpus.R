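#' Construct a single note document
#'
#' A document is one clinical note: its raw text lines, the token lines
#' derived from them (one token vector per raw line), optional patient
#' metadata and an optional flat sequence of pre-annotated concept
#' identifiers (e.g. terminology codes produced by an upstream
#' named-entity pipeline).
#'
#' @param doc_id Unique document identifier (string).
#' @param text Raw note text; lines are split on `"\n"`. Alternatively pass
#'   `raw_lines` directly.
#' @param patient_id Optional patient identifier.
#' @param date Optional ISO-8601 date string or `Date`.
#' @param note_type Optional note type label.
#' @param concepts Optional character vector of concept tokens.
#' @param raw_lines Optional character vector of raw lines (overrides `text`).
#' @param tokenizer A [tokenizer_config()].
#' @return An object of class `ehr_document` with fields `doc_id`,
#'   `patient_id`, `date`, `note_type`, `raw_lines`, `token_lines`
#'   (list parallel to `raw_lines`; blank lines give empty token vectors)
#'   and `concept_tokens`.
#' @export
ehr_document <- function(doc_id, text = NULL, patient_id = NULL, date = NULL,
                         note_type = NULL, concepts = NULL, raw_lines = NULL,
                         tokenizer = tokenizer_config()) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id))
    stop("`doc_id` must be a non-empty string")
  if (is.null(raw_lines)) {
    if (is.null(text)) text <- ""
    raw_lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    if (length(raw_lines) == 0L) raw_lines <- ""
  }
  token_lines <- lapply(raw_lines, tokenize, config = tokenizer)
  if (!is.null(date)) date <- as.character(date)
  structure(list(doc_id = doc_id,
                 patient_id = if (is.null(patient_id)) NA_character_ else as.character(patient_id),
                 date = if (is.null(date)) NA_character_ else date,
                 note_type = if (is.null(note_type)) NA_character_ else as.character(note_type),
                 raw_lines = as.character(raw_lines),
                 token_lines = token_lines,
                 concept_tokens = if (is.null(concepts)) NULL else as.character(concepts)),
            class = "ehr_document")
}

#' @export
print.ehr_document <- function(x, ...) {
  cat(sprintf("<ehr_document %s: %d lines, %d tokens%s%s>\n", x$doc_id,
              length(x$raw_lines), sum(lengths(x$token_lines)),
              if (!is.na(x$patient_id)) paste0(", patient ", x$patient_id) else "",
              if (!is.null(x$concept_tokens))
                sprintf(", %d concepts", length(x$concept_tokens)) else ""))
  invisible(x)
}

#' Construct a corpus of documents
#'
#' A corpus is an ordered collection of [ehr_document()]s together with the
#' active token layer. Iteration order is stable and equals insertion order.
#'
#' @param documents List of `ehr_document` objects with unique `doc_id`s.
#' @param layer Which token stream analyses use: `"word"` (tokens from the
#'   raw lines) or `"concept"` (the pre-annotated concept layer). Selecting
#'   the concept layer on a corpus where some document lacks concepts is an
#'   error at access time.
#' @return An object of class `ehr_corpus`.
#' @export
ehr_corpus <- function(documents, layer = c("word", "concept")) {
  layer <- match.arg(layer)
  if (!is.list(documents) || !all(vapply(documents, inherits, TRUE, "ehr_document")))
    stop("`documents` must be a list of ehr_document objects")
  ids <- vapply(documents, `[[`, "", "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate doc_id in corpus: ", dup[1L])
  names(documents) <- ids
  structure(list(documents = documents, layer = layer), class = "ehr_corpus")
}

#' @export
length.ehr_corpus <- function(x) length(x$documents)

#' @export
`[.ehr_corpus` <- function(x, i) ehr_corpus(x$documents[i], layer = x$layer)

#' @export
print.ehr_corpus <- function(x, ...) {
  npat <- length(unique(stats::na.omit(corpus_patients(x))))
  cat(sprintf("<ehr_corpus: %d documents, %d patients, layer=%s, %d tokens>\n",
              length(x), npat, x$layer,
              sum(vapply(x$documents, function(d) sum(lengths(d$token_lines)), 0))))
  invisible(x)
}

#' Document ids / patient ids of a corpus
#' @param corpus An `ehr_corpus`.
#' @return Character vector, in corpus order.
#' @export
corpus_ids <- function(corpus) {
  unname(vapply(corpus$documents, `[[`, "", "doc_id"))
}

#' @rdname corpus_ids
#' @export
corpus_patients <- function(corpus) {
  unname(vapply(corpus$documents, `[[`, "", "patient_id"))
}

#' Set the active token layer of a corpus
#' @param corpus An `ehr_corpus`.
#' @param layer `"word"` or `"concept"`.
#' @export
set_layer <- function(corpus, layer = c("word", "concept")) {
  layer <- match.arg(layer)
  if (layer == "concept" &&
      any(vapply(corpus$documents, function(d) is.null(d$concept_tokens), TRUE)))
    stop("corpus has documents without a concept layer")
  corpus$layer <- layer
  corpus
}

# Flat token stream of one document for a layer.
doc_tokens <- function(doc, layer = "word") {
  if (layer == "word") return(unlist(doc$token_lines, use.names = FALSE))
  if (is.null(doc$concept_tokens))
    stop("document ", doc$doc_id, " has no concept layer")
  doc$concept_tokens
}

# Token lines of one document for a layer; the concept layer is a single
# line because it carries no line structure (all concept analyses are
# count-based).
doc_token_lines <- function(doc, layer = "word") {
  if (layer == "word") return(doc$token_lines)
  list(doc_tokens(doc, "concept"))
}

#' Read a corpus from disk
#'
#' Two on-disk layouts are supported. `jsonl`: one JSON object per line with
#' keys `doc_id`, `text` and optional `patient_id`, `date`, `note_type`,
#' `concepts` (array of strings). `textdir`: a directory of `.txt` files
#' (`doc_id` = file name without extension) with an optional `metadata.tsv`
#' carrying columns `doc_id`, `patient_id`, `date`, `note_type`.
#'
#' @param path Path to the JSONL file or the directory.
#' @param format `"jsonl"` or `"textdir"`.
#' @param tokenizer A [tokenizer_config()].
#' @return An [ehr_corpus()] with documents in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "textdir"),
                        tokenizer = tokenizer_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    docs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e)
                        stop("malformed JSONL record at line ", i, ": ",
                             conditionMessage(e)))
      if (is.null(rec$doc_id) || is.null(rec$text))
        stop("malformed JSONL record at line ", i,
             ": missing doc_id or text")
      docs[[i]] <- ehr_document(doc_id = rec$doc_id, text = rec$text,
                                patient_id = rec$patient_id, date = rec$date,
                                note_type = rec$note_type,
                                concepts = rec$concepts,
                                tokenizer = tokenizer)
    }
  } else {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files found under ", path)
    meta <- NULL
    meta_path <- file.path(path, "metadata.tsv")
    if (file.exists(meta_path)) {
      meta <- utils::read.delim(meta_path, colClasses = "character")
      rownames(meta) <- meta$doc_id
    }
    docs <- lapply(files, function(f) {
      id <- sub("\\.txt$", "", basename(f))
      m <- if (!is.null(meta) && id %in% rownames(meta)) meta[id, ] else NULL
      ehr_document(doc_id = id,
                   text = paste(readLines(f, warn = FALSE), collapse = "\n"),
                   patient_id = m$patient_id, date = m$date,
                   note_type = m$note_type, tokenizer = tokenizer)
    })
  }
  ehr_corpus(docs)
}

#' Write a corpus as JSONL
#'
#' One JSON object per document, preserving ids, metadata, raw lines and
#' concept tokens, so that `read_corpus()` round-trips them exactly.
#'
#' @param corpus An `ehr_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (d in corpus$documents) {
    rec <- list(doc_id = d$doc_id,
                text = paste(d$raw_lines, collapse = "\n"))
    if (!is.na(d$patient_id)) rec$patient_id <- d$patient_id
    if (!is.na(d$date)) rec$date <- d$date
    if (!is.na(d$note_type)) rec$note_type <- d$note_type
    if (!is.null(d$concept_tokens)) rec$concepts <- d$concept_tokens
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
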