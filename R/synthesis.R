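#' Configuration for the synthetic EHR-note generator
#'
#' Parameters of a patient-note simulator with controllable copy-paste
#' redundancy, standing in for protected clinical corpora. Defaults are
#' calibrated to the redundancy regime reported for informative clinical
#' notes: mean same-patient alignment redundancy around 30% and
#' cross-patient redundancy in the low single digits (driven only by
#' shared common words). Because copying chains through successive notes,
#' redundancy between non-adjacent note pairs decays roughly like
#' `copy_fraction^gap`, so the per-note `copy_fraction` (0.55) sits above
#' the corpus-mean redundancy it produces (~0.30).
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Length-2 integer range `(min, max)` of notes
#'   per patient.
#' @param lines_per_note Range of content lines per note.
#' @param tokens_per_line Range of tokens per content line.
#' @param copy_fraction Fraction in `[0, 1]` of a note's lines copied
#'   verbatim from the patient's previous note (the redundancy dial;
#'   first note of a patient copies nothing).
#' @param vocab_size Vocabulary size (must exceed `10 * n_topics`).
#' @param zipf_exponent Zipf shape of word weights (default 1.1).
#' @param n_topics Latent topics; each topic owns an interleaved block of
#'   the non-common vocabulary with Zipfian weights inside the block.
#' @param common_word_frac Probability that a token is drawn from the
#'   shared common-word pool (the top-ranked words, available to every
#'   topic) instead of the patient's topic mixture. This is what creates
#'   the small cross-patient alignment floor.
#' @param name_tokens_per_patient Patient-unique name tokens written as
#'   one adjacent run on a dedicated line of every note (default 2, like
#'   a signature); 0 disables.
#' @param burstiness Probability in `[0, 1)` that a freshly generated
#'   token repeats a word already used earlier in the same note (Polya-urn
#'   word burstiness, default 0.4). Real prose is bursty — a note that
#'   mentions a term tends to mention it again — and burstiness is what
#'   gives each note idiosyncratic content; without it, duplicated notes
#'   are statistically exchangeable with fresh ones and whole-document
#'   duplication would be a harmless reweighting.
#' @param topic_concentration Dirichlet concentration of patient topic
#'   mixtures (default 0.3; smaller = more skewed patients).
#' @param seed Integer seed; identical config and seed reproduce the
#'   corpus byte for byte.
#' @return An object of class `synth_ehr_config`.
#' @export
synth_ehr_config <- function(n_patients = 50,
                             notes_per_patient = c(4L, 10L),
                             lines_per_note = c(6L, 12L),
                             tokens_per_line = c(5L, 10L),
                             copy_fraction = 0.55,
                             vocab_size = 2000,
                             zipf_exponent = 1.1,
                             n_topics = 10,
                             common_word_frac = 0.4,
                             name_tokens_per_patient = 2,
                             burstiness = 0.4,
                             topic_concentration = 0.3,
                             seed = 1) {
  rng <- function(r) length(r) == 2L && r[1L] >= 1 && r[1L] <= r[2L]
  stopifnot(n_patients >= 1, rng(notes_per_patient), rng(lines_per_note),
            rng(tokens_per_line), copy_fraction >= 0, copy_fraction <= 1,
            vocab_size > 10 * n_topics, zipf_exponent > 0, n_topics >= 1,
            common_word_frac >= 0, common_word_frac < 1,
            name_tokens_per_patient >= 0, burstiness >= 0, burstiness < 1,
            topic_concentration > 0)
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 lines_per_note = as.integer(lines_per_note),
                 tokens_per_line = as.integer(tokens_per_line),
                 copy_fraction = copy_fraction,
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 n_topics = as.integer(n_topics),
                 common_word_frac = common_word_frac,
                 name_tokens_per_patient = as.integer(name_tokens_per_patient),
                 burstiness = burstiness,
                 topic_concentration = topic_concentration,
                 seed = as.integer(seed)),
            class = "synth_ehr_config")
}

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

#' Generate a synthetic EHR-like corpus
#'
#' Simulates patient-grouped notes with Zipfian vocabulary, latent topic
#' structure, patient-specific name tokens and chain copy-paste: each note
#' copies `round(copy_fraction * L)` lines verbatim from the patient's
#' immediately preceding note (so copied content compounds along the
#' chain, as clinical copy-paste does) and generates its remaining lines
#' from the patient's topic mixture. Notes carry sequential dates (one
#' week apart) and rotating informative note types.
#'
#' @param config A [synth_ehr_config()].
#' @return An `ehr_corpus`. The attribute `synth_truth` records the
#'   generating structure (vocabulary, common-word pool, per-topic word
#'   index blocks, per-patient topic mixtures) for parameter-recovery
#'   studies.
#' @export
generate_ehr_corpus <- function(config = synth_ehr_config()) {
  stopifnot(inherits(config, "synth_ehr_config"))
  with_seed(config$seed, {
    V <- config$vocab_size
    vocab <- sprintf("w%05d", seq_len(V))
    w_global <- 1 / seq_len(V)^config$zipf_exponent

    n_common <- max(10L, min(50L, V %/% 20L))
    common <- seq_len(n_common)
    topic_words <- lapply(seq_len(config$n_topics), function(t)
      seq.int(n_common + t, V, by = config$n_topics))
    topic_w <- lapply(topic_words, function(ix) {
      w <- w_global[ix]; w / sum(w)
    })
    common_w <- w_global[common] / sum(w_global[common])

    note_types <- c("primary-provider", "clinical-note", "follow-up-note")
    docs <- list()
    thetas <- matrix(0, config$n_patients, config$n_topics)
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("p%03d", p)
      theta <- stats::rgamma(config$n_topics, config$topic_concentration)
      theta <- theta / sum(theta)
      thetas[p, ] <- theta
      names_p <- if (config$name_tokens_per_patient > 0)
        sprintf("zz%sname%d", pid, seq_len(config$name_tokens_per_patient))
      else character()
      n_notes <- sample_range(config$notes_per_patient)
      prev_lines <- character()
      for (j in seq_len(n_notes)) {
        L <- sample_range(config$lines_per_note)
        n_copy <- min(round(config$copy_fraction * L), length(prev_lines))
        copied <- if (n_copy > 0)
          prev_lines[sort(sample.int(length(prev_lines), n_copy))]
        else character()
        bag <- character()  # words already used in this note (burstiness urn)
        fresh <- vapply(seq_len(L - n_copy), function(.) {
          nt <- sample_range(config$tokens_per_line)
          tok <- character(nt)
          for (q in seq_len(nt)) {
            if (length(bag) && stats::runif(1) < config$burstiness) {
              tok[q] <- bag[sample.int(length(bag), 1L)]
            } else if (stats::runif(1) < config$common_word_frac) {
              tok[q] <- vocab[sample(common, 1L, prob = common_w)]
            } else {
              t <- sample.int(config$n_topics, 1L, prob = theta)
              tok[q] <- vocab[sample(topic_words[[t]], 1L, prob = topic_w[[t]])]
            }
            bag <<- c(bag, tok[q])
          }
          paste(tok, collapse = " ")
        }, "")
        lines <- c(copied, fresh)
        if (length(names_p)) lines <- c(lines, paste(names_p, collapse = " "))
        docs[[length(docs) + 1L]] <- ehr_document(
          doc_id = sprintf("%s-n%02d", pid, j),
          raw_lines = lines, patient_id = pid,
          date = as.character(as.Date("2020-01-01") + 7L * (j - 1L)),
          note_type = note_types[(j - 1L) %% 3L + 1L])
        prev_lines <- lines[seq_len(L)]  # name line is not part of the copy pool
      }
    }
    out <- ehr_corpus(docs)
    attr(out, "synth_truth") <- list(vocab = vocab, common = common,
                                     topic_words = topic_words,
                                     patient_theta = thetas)
    out
  })
}

#' Uniform corpus duplication (xK scheme)
#'
#' Every document appears exactly `K` times, copies grouped per base
#' document in base order, with derived ids `<doc_id>#<copy>`. Token
#' counts scale exactly by `K`; association scores and spectrum shape
#' invariances of the other modules are exercised against this output.
#'
#' @param base An `ehr_corpus`.
#' @param K Number of copies (>= 1).
#' @return An `ehr_corpus` of `K * length(base)` documents.
#' @export
duplicate_corpus <- function(base, K) {
  stopifnot(inherits(base, "ehr_corpus"))
  if (K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  docs <- list()
  for (d in base$documents) {
    for (k in seq_len(K)) {
      dk <- d
      dk$doc_id <- sprintf("%s#%d", d$doc_id, k)
      docs[[length(docs) + 1L]] <- dk
    }
  }
  ehr_corpus(docs, layer = base$layer)
}

#' Non-uniform corpus sampling (sK scheme)
#'
#' Each document's multiplicity is drawn independently and uniformly from
#' `{1, ..., max_copies}` (so with `max_copies = 5` each count has
#' probability 0.2 and the expected size is `3 * length(base)`). Unlike
#' uniform duplication, this changes relative frequencies and thereby
#' perturbs association scores and spectrum shape.
#'
#' @param base An `ehr_corpus`.
#' @param max_copies Maximum multiplicity (>= 1).
#' @param seed Integer seed.
#' @return An `ehr_corpus` with derived ids `<doc_id>#<copy>`.
#' @export
sample_corpus <- function(base, max_copies, seed = 1) {
  stopifnot(inherits(base, "ehr_corpus"), max_copies >= 1)
  mult <- with_seed(seed,
    sample.int(as.integer(max_copies), length(base), replace = TRUE))
  docs <- list()
  for (i in seq_along(base$documents)) {
    d <- base$documents[[i]]
    for (k in seq_len(mult[i])) {
      dk <- d
      dk$doc_id <- sprintf("%s#%d", d$doc_id, k)
      docs[[length(docs) + 1L]] <- dk
    }
  }
  ehr_corpus(docs, layer = base$layer)
}
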