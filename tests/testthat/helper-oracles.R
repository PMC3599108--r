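# Independent reference implementations used to check the package's
# optimized code paths, plus small corpus builders.

# Naive full-matrix Smith-Waterman (single best local alignment, linear
# gaps) in plain R. Traceback prefers diagonal, then up (gap in b), then
# left, matching the documented convention of align_local().
sw_oracle <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  la <- length(a); lb <- length(b)
  H <- matrix(0, la + 1, lb + 1)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(la) + 1L) {   # same strictly-greater scan order as the
    for (j in seq_len(lb) + 1L) { # compiled implementation
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best == 0) return(list(score = 0, matched_tokens = 0L))
  i <- bi; j <- bj
  matched <- 0L
  while (i > 1 && j > 1 && H[i, j] > 0) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    if (H[i, j] == H[i - 1, j - 1] + s) {
      if (a[i - 1] == b[j - 1]) matched <- matched + 1L
      i <- i - 1L; j <- j - 1L
    } else if (H[i, j] == H[i - 1, j] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = best, matched_tokens = matched)
}

# Substring-set oracle for document fingerprinting (unhashed).
fingerprint_set_oracle <- function(raw_lines, n, scheme) {
  out <- character()
  for (line in raw_lines) {
    m <- nchar(line)
    if (m < n) next
    starts <- if (scheme == "full") 1:(m - n + 1)
              else if (m %/% n > 0) (0:(m %/% n - 1)) * n + 1 else integer(0)
    for (s in starts) out <- c(out, substr(line, s, s + n - 1))
  }
  unique(out)
}

# Quadratic sequential oracle for the greedy reduction: every candidate is
# compared against every retained document, both directions, no index.
reduce_oracle <- function(corpus, config) {
  profiles <- lapply(corpus$documents, document_fingerprints, config = config)
  stopifnot(config$order == "input")
  retained <- integer(0)
  for (i in seq_along(profiles)) {
    ok <- TRUE
    for (r in retained) {
      s_cand <- fingerprint_similarity(profiles[[r]], profiles[[i]])
      s_ret <- fingerprint_similarity(profiles[[i]], profiles[[r]])
      if (s_cand > config$cutoff || s_ret > config$cutoff) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, i)
  }
  corpus_ids(corpus)[retained]
}

# Brute-force cell-by-cell 2x2 mutual information in log2.
tmi_oracle <- function(n11, n1p, np1, npp) {
  cells <- matrix(c(n11, n1p - n11, np1 - n11, npp - n1p - np1 + n11), 2, 2)
  rows <- rowSums(cells); cols <- colSums(cells)
  total <- 0
  for (i in 1:2) for (j in 1:2) {
    if (cells[i, j] > 0)
      total <- total + (cells[i, j] / npp) *
        log2((cells[i, j] * npp) / (rows[i] * cols[j]))
  }
  total
}

# Shorthand document/corpus builders.
doc_from_tokens <- function(id, lines, patient_id = NULL, date = NULL, ...) {
  ehr_document(id, text = paste(vapply(lines, paste, "", collapse = " "),
                                collapse = "\n"),
               patient_id = patient_id, date = date, ...)
}

corpus_of <- function(...) ehr_corpus(list(...))

random_token_seq <- function(len, alphabet) {
  sample(alphabet, len, replace = TRUE)
}

subset_patients <- function(corpus, patients) {
  corpus[which(corpus_patients(corpus) %in% patients)]
}
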