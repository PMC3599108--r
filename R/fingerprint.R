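#' Fingerprints of one text line
#'
#' Length-`n` character substrings of a line. `"full"` fingerprinting takes
#' every window: a line of `m` characters yields `m - n + 1` fingerprints.
#' `"selective"` fingerprinting takes consecutive non-overlapping windows
#' from the start of the line, `floor(m / n)` of them; a trailing remainder
#' shorter than `n` is discarded. Lines shorter than `n` yield none. No
#' fingerprint ever spans a line boundary.
#'
#' @param line A single string.
#' @param n Granularity in characters (>= 2).
#' @param scheme `"selective"` (default) or `"full"`.
#' @return Character vector of substrings (possibly with duplicates; set
#'   semantics are applied at the document level).
#' @examples
#' line_fingerprints("abcdefgh", 3, "full")      # 6 windows
#' line_fingerprints("abcdefgh", 3, "selective") # "abc", "def"
#' @export
line_fingerprints <- function(line, n, scheme = c("selective", "full")) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 2)
  m <- nchar(line)
  if (m < n) return(character())
  starts <- if (scheme == "full") seq_len(m - n + 1L)
            else seq.int(1L, by = n, length.out = m %/% n)
  substring(line, starts, starts + n - 1L)
}

#' Corpus reduction configuration
#'
#' Parameters of the fingerprint-based greedy sub-corpus construction.
#'
#' @param cutoff Maximum allowed fingerprint similarity in `[0, 1]` between
#'   a retained document and any other retained document.
#' @param n Fingerprint granularity in characters (default 20: long enough
#'   to be specific, short enough that typical note lines of 40-80
#'   characters yield two or more selective fingerprints).
#' @param scheme `"selective"` (default) or `"full"` fingerprinting.
#' @param order Order in which documents are visited: `"input"` (corpus
#'   order), `"date"` (ascending date, input order breaking ties) or
#'   `"random"` (seeded shuffle).
#' @param seed Integer seed used when `order = "random"`.
#' @param hash Hash fingerprints with a stable 64-bit hash (default `TRUE`);
#'   `FALSE` keeps raw substrings (useful for inspection and testing).
#' @return An object of class `reduction_config`.
#' @export
reduction_config <- function(cutoff, n = 20, scheme = c("selective", "full"),
                             order = c("input", "date", "random"), seed = 1,
                             hash = TRUE) {
  scheme <- match.arg(scheme); order <- match.arg(order)
  stopifnot(cutoff >= 0, cutoff <= 1, n >= 2)
  structure(list(cutoff = cutoff, n = as.integer(n), scheme = scheme,
                 order = order, seed = seed, hash = hash),
            class = "reduction_config")
}

#' Fingerprint profile of a document
#'
#' The set (duplicates removed) of line fingerprints over all raw lines of
#' the document, optionally hashed. A document whose lines are all shorter
#' than `n` has an empty profile.
#'
#' @param doc An `ehr_document`.
#' @param config A [reduction_config()].
#' @return An object of class `fingerprint_profile` with fields `doc_id`,
#'   `fingerprints` (character vector, unique), `n` and `scheme`.
#' @export
document_fingerprints <- function(doc, config) {
  stopifnot(inherits(config, "reduction_config"))
  fps <- unlist(lapply(doc$raw_lines, line_fingerprints,
                       n = config$n, scheme = config$scheme),
                use.names = FALSE)
  if (is.null(fps)) fps <- character()
  fps <- unique(fps)
  if (config$hash && length(fps)) fps <- unique(fnv1a64_cpp(fps))
  structure(list(doc_id = doc$doc_id, fingerprints = fps,
                 n = config$n, scheme = config$scheme),
            class = "fingerprint_profile")
}

#' Fingerprint similarity of document B to document A
#'
#' The number of fingerprints shared by A and B divided by the number of
#' fingerprints of A. Note the asymmetry: this is the similarity *of B to
#' A*. Profiles must have been built with the same granularity and scheme.
#'
#' @param b,a `fingerprint_profile` objects.
#' @return Ratio in `[0, 1]`; 0 when A's profile is empty.
#' @export
fingerprint_similarity <- function(b, a) {
  stopifnot(inherits(a, "fingerprint_profile"),
            inherits(b, "fingerprint_profile"))
  if (a$n != b$n || a$scheme != b$scheme)
    stop("profiles built with different granularity or scheme")
  if (!length(a$fingerprints)) return(0)
  length(intersect(b$fingerprints, a$fingerprints)) / length(a$fingerprints)
}

#' Greedy controlled-redundancy sub-corpus construction
#'
#' Visits documents one by one (in the configured order) and adds each to
#' the output corpus unless it shares too many fingerprints with a document
#' already retained: a candidate is rejected iff some retained document `d`
#' has `shared / |FP(candidate)| > cutoff` or `shared / |FP(d)| > cutoff`
#' (the rejection test is applied in both directions, so the final set is
#' guaranteed pairwise below the cutoff both ways). Retained documents are
#' indexed by an inverted fingerprint index, so each candidate is scored
#' against only the documents it shares at least one fingerprint with.
#'
#' @param corpus An `ehr_corpus`.
#' @param config A [reduction_config()].
#' @return A list with components `corpus` (the retained sub-corpus, in
#'   visit order) and `report`, an object of class `reduction_report` with
#'   fields `retained_ids`, `rejected` (data frame `doc_id`,
#'   `blocking_doc_id`, `similarity` — the largest offending ratio and the
#'   retained document attaining it) and `counts`.
#' @export
reduce_corpus <- function(corpus, config) {
  stopifnot(inherits(corpus, "ehr_corpus"), inherits(config, "reduction_config"))
  n <- length(corpus)
  ord <- switch(config$order,
    input = seq_len(n),
    date = {
      dates <- vapply(corpus$documents, `[[`, "", "date")
      if (anyNA(dates)) stop("order = 'date' requires a date on every document")
      order(as.Date(dates), seq_len(n))
    },
    random = with_seed(config$seed, sample.int(n)))

  profiles <- lapply(corpus$documents, document_fingerprints, config = config)
  index <- new.env(parent = emptyenv(), hash = TRUE)  # fingerprint -> retained idx
  retained <- integer(0)
  rej_id <- rej_block <- character(0); rej_sim <- numeric(0)

  for (i in ord) {
    fps <- profiles[[i]]$fingerprints
    shared <- integer(0)  # counts named by retained index
    if (length(fps)) {
      posting <- unlist(lapply(fps, function(f)
        if (!is.null(index[[f]])) index[[f]] else integer(0)), use.names = FALSE)
      if (length(posting)) shared <- table(posting)
    }
    blocked <- FALSE
    if (length(shared)) {
      ridx <- as.integer(names(shared))
      s <- as.numeric(shared)
      sim_cand <- if (length(fps)) s / length(fps) else rep(0, length(s))
      sim_ret <- s / vapply(profiles[ridx], function(p)
        max(length(p$fingerprints), 1L), 0)
      worst <- pmax(sim_cand, sim_ret)
      if (any(worst > config$cutoff)) {
        blocked <- TRUE
        k <- which.max(worst)
        rej_id <- c(rej_id, profiles[[i]]$doc_id)
        rej_block <- c(rej_block, profiles[[ridx[k]]]$doc_id)
        rej_sim <- c(rej_sim, worst[k])
      }
    }
    if (!blocked) {
      retained <- c(retained, i)
      for (f in fps) index[[f]] <- c(index[[f]], i)
    }
  }

  out <- ehr_corpus(corpus$documents[retained], layer = corpus$layer)
  report <- structure(list(
    retained_ids = corpus_ids(out),
    rejected = data.frame(doc_id = rej_id, blocking_doc_id = rej_block,
                          similarity = rej_sim, stringsAsFactors = FALSE),
    counts = c(input_docs = n, retained_docs = length(retained)),
    config = config), class = "reduction_report")
  list(corpus = out, report = report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report: %d of %d documents retained (cutoff %.2f, n=%d, %s)>\n",
              x$counts["retained_docs"], x$counts["input_docs"],
              x$config$cutoff, x$config$n, x$config$scheme))
  invisible(x)
}

#' Last-note-per-patient metadata baseline
#'
#' Keeps exactly one note per patient: the one with the latest date, ties
#' broken by the latest position in the corpus. This is the metadata-based
#' mitigation baseline; it guarantees a redundancy-free corpus at the cost
#' of discarding most of the data.
#'
#' @param corpus An `ehr_corpus` whose documents all carry `patient_id` and
#'   `date`.
#' @return An `ehr_corpus` with one document per patient, in input order.
#' @export
last_note_baseline <- function(corpus) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  pats <- corpus_patients(corpus)
  if (anyNA(pats)) stop("every document needs a patient_id")
  dates <- vapply(corpus$documents, `[[`, "", "date")
  missing <- which(is.na(dates))
  if (length(missing))
    stop("document ", corpus_ids(corpus)[missing[1L]], " has no date")
  d <- as.Date(dates)
  keep <- vapply(split(seq_along(d), pats), function(ix) {
    ix[max(which(d[ix] == max(d[ix])))]
  }, 0L)
  ehr_corpus(corpus$documents[sort(keep)], layer = corpus$layer)
}
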