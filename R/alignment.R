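#' Alignment scoring parameters
#'
#' Scoring scheme for token-level local alignment. Defaults reward a match
#' with +2 and penalize mismatches and (linear) gaps with -1. In repeated
#' mode segments are extracted while their score is at least
#' `min_segment_score`; the default of 4 requires at least two consecutive
#' matching tokens, which suppresses single shared-token noise.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param gap Linear gap score (<= 0).
#' @param min_segment_score Minimum score for a segment to be extracted in
#'   repeated mode (> 0).
#' @param repeated Extract multiple non-overlapping local alignments
#'   (default `TRUE`): copy-paste produces several shared segments which a
#'   single local alignment would miss.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1, gap = -1,
                              min_segment_score = 4, repeated = TRUE) {
  stopifnot(match > 0, mismatch <= 0, gap <= 0, min_segment_score > 0)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 min_segment_score = min_segment_score, repeated = repeated),
            class = "alignment_scoring")
}

#' Local alignment of two token sequences
#'
#' Smith-Waterman local alignment on token sequences. With
#' `scoring$repeated = FALSE` the single best local alignment is returned.
#' With the default repeated mode, the best alignment is extracted, its
#' spans are masked in both sequences, and the search repeats while the
#' best score is at least `min_segment_score`; matched tokens accumulate
#' over the extracted segments. Masked spans cannot be re-aligned, so
#' `matched_tokens <= min(length(a), length(b))`.
#'
#' @param a,b Character vectors of tokens.
#' @param scoring An [alignment_scoring()].
#' @return An object of class `alignment_result`: `matched_tokens` (count
#'   of aligned identical-token columns), `score` (summed segment scores)
#'   and `segments` (matrix of half-open token intervals `start_a`,
#'   `end_a`, `start_b`, `end_b`, 1-based).
#' @examples
#' a <- c("pt", "developed", "abd", "pain", "and", "acute", "cholecystitis")
#' b <- c("pt", "developed", "acute", "abd", "pain", "and", "cholecystitis")
#' align_local(a, b)$matched_tokens
#' @export
align_local <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "alignment_scoring"))
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0L || length(b) == 0L) {
    res <- list(matched_tokens = 0L, score = 0,
                segments = matrix(integer(), 0, 4,
                                  dimnames = list(NULL, c("start_a", "end_a",
                                                          "start_b", "end_b"))))
    return(structure(res, class = "alignment_result"))
  }
  lev <- unique(c(a, b))
  res <- sw_align_cpp(match(a, lev), match(b, lev),
                      scoring$match, scoring$mismatch, scoring$gap,
                      scoring$min_segment_score, scoring$repeated)
  structure(res, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: %d matched tokens in %d segment(s), score %g>\n",
              x$matched_tokens, nrow(x$segments), x$score))
  invisible(x)
}

#' Shared-word identity of two token sequences
#'
#' Bag-of-words (order-free) overlap: the Jaccard index of the two token
#' type sets. Two sentences containing the same words in different order
#' score 1 here even when their sequence alignment is partial.
#'
#' @param a,b Character vectors of tokens.
#' @return Fraction in `[0, 1]`.
#' @export
shared_word_identity <- function(a, b) {
  ta <- unique(as.character(a)); tb <- unique(as.character(b))
  if (!length(ta) && !length(tb)) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Pairwise redundancy between two documents
#'
#' Aligns the flattened token streams of two documents and normalizes the
#' matched-token count by each document's length. `redundancy_a` is the
#' fraction of `a`'s tokens aligned, `redundancy_b` likewise for `b`, and
#' `redundancy_sym` is their mean — the "percentage of alignment" of the
#' pair. A zero-length document has redundancy 0 in its direction.
#'
#' @param a,b `ehr_document` objects.
#' @param scoring An [alignment_scoring()].
#' @param layer Token layer to align: `"word"` or `"concept"`.
#' @return Named numeric vector `c(redundancy_a, redundancy_b,
#'   redundancy_sym)`, each in `[0, 1]`.
#' @export
pair_redundancy <- function(a, b, scoring = alignment_scoring(),
                            layer = "word") {
  ta <- doc_tokens(a, layer); tb <- doc_tokens(b, layer)
  m <- align_local(ta, tb, scoring)$matched_tokens
  ra <- if (length(ta)) m / length(ta) else 0
  rb <- if (length(tb)) m / length(tb) else 0
  c(redundancy_a = ra, redundancy_b = rb, redundancy_sym = (ra + rb) / 2)
}

#' Corpus-level redundancy profile
#'
#' Samples unordered document pairs — either notes of the same patient or
#' notes of two distinct patients — and measures alignment redundancy for
#' each pair. Pairs are drawn uniformly without replacement (all eligible
#' pairs when fewer exist than requested). The symmetric redundancy is
#' summarized as a decile histogram over `[0, 0.1), ..., [0.9, 1.0]` and a
#' mean.
#'
#' @param corpus An `ehr_corpus`; `same_patient` grouping requires patient
#'   ids.
#' @param grouping `"same_patient"` or `"cross_patient"`.
#' @param pair_sample Number of pairs to sample (>= 1).
#' @param seed Integer seed for the pair sample.
#' @param scoring An [alignment_scoring()].
#' @return An object of class `redundancy_profile`: `pair_records` (data
#'   frame with columns `doc_a`, `doc_b`, `redundancy_a`, `redundancy_b`,
#'   `redundancy_sym`), `histogram` (10 decile counts summing to the number
#'   of pairs) and `mean_sym`.
#' @export
redundancy_profile <- function(corpus, grouping = c("same_patient",
                                                    "cross_patient"),
                               pair_sample = 2000, seed = 1,
                               scoring = alignment_scoring()) {
  grouping <- match.arg(grouping)
  stopifnot(pair_sample >= 1)
  pats <- corpus_patients(corpus)
  n <- length(corpus)
  if (grouping == "same_patient") {
    if (all(is.na(pats))) stop("same_patient grouping requires patient ids")
    pairs <- do.call(rbind, lapply(split(seq_len(n), pats), function(ix) {
      if (length(ix) < 2L) return(NULL)
      t(utils::combn(ix, 2L))
    }))
  } else {
    if (n >= 2L) {
      pairs <- t(utils::combn(seq_len(n), 2L))
      keep <- !is.na(pats[pairs[, 1L]]) & !is.na(pats[pairs[, 2L]]) &
        pats[pairs[, 1L]] != pats[pairs[, 2L]]
      pairs <- pairs[keep, , drop = FALSE]
    } else pairs <- NULL
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no eligible document pairs for grouping ", grouping)
  if (nrow(pairs) > pair_sample) {
    pick <- with_seed(seed, sample.int(nrow(pairs), pair_sample))
    pairs <- pairs[pick, , drop = FALSE]
  }
  ids <- corpus_ids(corpus)
  rec <- vapply(seq_len(nrow(pairs)), function(k) {
    pair_redundancy(corpus$documents[[pairs[k, 1L]]],
                    corpus$documents[[pairs[k, 2L]]],
                    scoring, layer = corpus$layer)
  }, numeric(3L))
  records <- data.frame(doc_a = ids[pairs[, 1L]], doc_b = ids[pairs[, 2L]],
                        redundancy_a = rec[1L, ], redundancy_b = rec[2L, ],
                        redundancy_sym = rec[3L, ],
                        stringsAsFactors = FALSE, row.names = NULL)
  brk <- seq(0, 1, by = 0.1)
  hist_counts <- table(cut(records$redundancy_sym, breaks = brk,
                           include.lowest = TRUE, right = FALSE))
  structure(list(pair_records = records,
                 histogram = as.integer(hist_counts),
                 mean_sym = mean(records$redundancy_sym),
                 grouping = grouping),
            class = "redundancy_profile")
}

#' @export
print.redundancy_profile <- function(x, ...) {
  cat(sprintf("<redundancy_profile (%s): %d pairs, mean symmetric redundancy %.1f%%>\n",
              x$grouping, nrow(x$pair_records), 100 * x$mean_sym))
  labs <- sprintf("[%.1f,%.1f%s", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1),
                  c(rep(")", 9), "]"))
  cat(paste(sprintf("  %s %d", labs, x$histogram), collapse = "\n"), "\n")
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
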