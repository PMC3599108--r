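# Internal: adjacent in-line token pairs of one document for the active
# layer. Bigrams never cross a line boundary; the concept layer, having no
# line structure, is treated as one line.
doc_bigrams <- function(doc, layer = "word") {
  lines <- doc_token_lines(doc, layer)
  w1 <- character(0); w2 <- character(0)
  for (tl in lines) {
    if (length(tl) >= 2L) {
      w1 <- c(w1, tl[-length(tl)])
      w2 <- c(w2, tl[-1L])
    }
  }
  list(w1 = w1, w2 = w2)
}

#' Corpus-wide bigram contingency counts
#'
#' Counts adjacent in-line token pairs over the corpus. When a vocabulary
#' is given, a bigram is counted only if both of its words belong to it,
#' and the total `npp` counts only the counted bigrams — this is the
#' vocabulary-control device for comparing corpora of different sizes
#' (only word types present in the smaller corpus are considered).
#'
#' @param corpus An `ehr_corpus`.
#' @param vocab Optional character vector restricting both bigram slots.
#' @return An object of class `bigram_table`: `n11` (data frame `w1`, `w2`,
#'   `n11`), `n1p` / `np1` (named counts of each word as left/right
#'   element), `npp` (total counted bigram tokens).
#' @export
bigram_counts <- function(corpus, vocab = NULL) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  parts <- lapply(corpus$documents, doc_bigrams, layer = corpus$layer)
  w1 <- unlist(lapply(parts, `[[`, "w1"), use.names = FALSE)
  w2 <- unlist(lapply(parts, `[[`, "w2"), use.names = FALSE)
  if (!is.null(vocab)) {
    keep <- w1 %in% vocab & w2 %in% vocab
    w1 <- w1[keep]; w2 <- w2[keep]
  }
  if (length(w1)) {
    key <- paste(w1, w2, sep = "\r")
    tab <- table(key)
    kk <- strsplit(names(tab), "\r", fixed = TRUE)
    n11 <- data.frame(w1 = vapply(kk, `[[`, "", 1L),
                      w2 = vapply(kk, `[[`, "", 2L),
                      n11 = as.integer(tab),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    n11 <- data.frame(w1 = character(), w2 = character(), n11 = integer(),
                      stringsAsFactors = FALSE)
  }
  n1p <- tapply(n11$n11, n11$w1, sum)
  np1 <- tapply(n11$n11, n11$w2, sum)
  structure(list(n11 = n11,
                 n1p = as.integer(n1p) |> stats::setNames(names(n1p)),
                 np1 = as.integer(np1) |> stats::setNames(names(np1)),
                 npp = sum(n11$n11)),
            class = "bigram_table")
}

#' @export
print.bigram_table <- function(x, ...) {
  cat(sprintf("<bigram_table: %d bigram types, %d bigram tokens>\n",
              nrow(x$n11), x$npp))
  invisible(x)
}

# Internal vectorized scorers over parallel count vectors. Ratios are
# formed as products of exact integer counts before dividing, so uniform
# duplication of the corpus (all counts scaled by K) leaves every score
# bit-identical.
pmi_score <- function(n11, n1p, np1, npp) {
  log2((n11 * npp) / (n1p * np1))
}

tmi_score <- function(n11, n1p, np1, npp) {
  n12 <- n1p - n11; n21 <- np1 - n11; n22 <- npp - n1p - np1 + n11
  cell <- function(nij, ni, nj) {
    term <- (nij / npp) * log2((nij * npp) / (ni * nj))
    ifelse(nij > 0, term, 0)
  }
  cell(n11, n1p, np1) + cell(n12, n1p, npp - np1) +
    cell(n21, npp - n1p, np1) + cell(n22, npp - n1p, npp - np1)
}

#' Association score of one bigram
#'
#' Pointwise mutual information, `PMI = log2(n11 * npp / (n1p * np1))`, or
#' true mutual information, the mutual information of the full 2x2
#' contingency table: `TMI = sum_ij (nij/npp) * log2(nij * npp / (ni. *
#' n.j))`, with empty cells contributing 0. Both use log base 2.
#'
#' @param table A [bigram_counts()] result.
#' @param bigram Character vector of length 2, `c(w1, w2)`, with
#'   `n11 >= 1` in the table.
#' @param measure `"pmi"` or `"tmi"`.
#' @return The score (numeric scalar).
#' @export
score_bigram <- function(table, bigram, measure = c("pmi", "tmi")) {
  measure <- match.arg(measure)
  stopifnot(inherits(table, "bigram_table"), length(bigram) == 2L)
  if (table$npp == 0) stop("empty bigram table (npp = 0)")
  row <- table$n11$w1 == bigram[1L] & table$n11$w2 == bigram[2L]
  if (!any(row)) stop("bigram not present in table: ",
                      paste(bigram, collapse = " "))
  n11 <- table$n11$n11[row]
  n1p <- table$n1p[[bigram[1L]]]; np1 <- table$np1[[bigram[2L]]]
  if (measure == "pmi") pmi_score(n11, n1p, np1, table$npp)
  else tmi_score(n11, n1p, np1, table$npp)
}

#' Extract collocations from a corpus
#'
#' Scores every bigram with the chosen association measure and keeps either
#' those at or above a score threshold or the `top_n` best (ties broken by
#' score, then count, then lexicographically — deterministic). For corpora
#' with patient ids, each collocation is annotated with its patient
#' support: the number of distinct patients whose notes contain the bigram
#' as an adjacent in-line pair. Low support flags likely copy-paste
#' artifacts.
#'
#' @param corpus An `ehr_corpus`.
#' @param measure `"pmi"` or `"tmi"`.
#' @param threshold Keep bigrams with score >= threshold (give exactly one
#'   of `threshold` / `top_n`).
#' @param top_n Keep the `top_n` highest-scoring bigrams.
#' @param min_count Minimum bigram count to be scored (default 1).
#' @param vocab Optional vocabulary restriction, as in [bigram_counts()].
#' @return A data frame of class `collocations` with columns `w1`, `w2`,
#'   `measure`, `score`, `count` and `patient_support` (`NA` when the
#'   corpus has no patient ids), ordered best first.
#' @export
extract_collocations <- function(corpus, measure = c("pmi", "tmi"),
                                 threshold = NULL, top_n = NULL,
                                 min_count = 1, vocab = NULL) {
  measure <- match.arg(measure)
  if (is.null(threshold) == is.null(top_n))
    stop("give exactly one of `threshold` or `top_n`")
  tab <- bigram_counts(corpus, vocab = vocab)
  out <- data.frame(w1 = character(), w2 = character(),
                    measure = character(), score = numeric(),
                    count = integer(), patient_support = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("collocations", "data.frame")
  if (nrow(tab$n11) == 0L) return(out)
  d <- tab$n11[tab$n11$n11 >= min_count, , drop = FALSE]
  if (nrow(d) == 0L) return(out)
  n1p <- unname(tab$n1p[d$w1]); np1 <- unname(tab$np1[d$w2])
  d$score <- if (measure == "pmi") pmi_score(d$n11, n1p, np1, tab$npp)
             else tmi_score(d$n11, n1p, np1, tab$npp)
  ord <- order(-d$score, -d$n11, d$w1, d$w2)
  d <- d[ord, , drop = FALSE]
  if (!is.null(threshold)) d <- d[d$score >= threshold, , drop = FALSE]
  else d <- utils::head(d, top_n)
  if (nrow(d) == 0L) return(out)
  support <- bigram_patient_support(corpus, d$w1, d$w2)
  out <- data.frame(w1 = d$w1, w2 = d$w2, measure = measure,
                    score = d$score, count = d$n11,
                    patient_support = support,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("collocations", "data.frame")
  out
}

# Distinct-patient support of each (w1, w2) bigram, NA when no patient ids.
bigram_patient_support <- function(corpus, w1, w2) {
  if (!length(w1)) return(integer(0))
  pats <- corpus_patients(corpus)
  if (all(is.na(pats))) return(rep(NA_integer_, length(w1)))
  per_doc <- lapply(seq_along(corpus$documents), function(i) {
    bg <- doc_bigrams(corpus$documents[[i]], layer = corpus$layer)
    if (!length(bg$w1)) return(NULL)
    data.frame(key = unique(paste(bg$w1, bg$w2, sep = "\r")),
               patient = unname(pats[i]), stringsAsFactors = FALSE)
  })
  seen <- unique(do.call(rbind, per_doc))
  counts <- tapply(seen$patient, seen$key,
                   function(p) length(unique(p[!is.na(p)])))
  res <- counts[paste(w1, w2, sep = "\r")]
  as.integer(ifelse(is.na(res), 0L, res))
}

#' Patient-support summary of a collocation list
#'
#' Summarizes how broadly the extracted collocations are supported across
#' patients. A collocation appearing in the notes of three patients or
#' fewer is counted as low-support — the signature of evidence created by
#' copy-paste rather than by independent use.
#'
#' @param collocations A [extract_collocations()] result.
#' @param corpus The `ehr_corpus` the collocations came from (used to
#'   (re)compute support when the list lacks it).
#' @return An object of class `support_stats`: `n_collocations`,
#'   `mean_patients` and `frac_low_support` (fraction with support <= 3;
#'   0 for an empty list).
#' @export
support_stats <- function(collocations, corpus) {
  stopifnot(inherits(collocations, "data.frame"))
  n <- nrow(collocations)
  if (n == 0L)
    return(structure(list(n_collocations = 0L, mean_patients = NaN,
                          frac_low_support = 0), class = "support_stats"))
  sup <- collocations$patient_support
  if (is.null(sup) || anyNA(sup))
    sup <- bigram_patient_support(corpus, collocations$w1, collocations$w2)
  structure(list(n_collocations = n,
                 mean_patients = mean(sup),
                 frac_low_support = mean(sup <= 3)),
            class = "support_stats")
}

#' @export
print.support_stats <- function(x, ...) {
  cat(sprintf("<support_stats: %d collocations, mean %.1f patients, %.1f%% supported by <=3 patients>\n",
              x$n_collocations, x$mean_patients, 100 * x$frac_low_support))
  invisible(x)
}
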