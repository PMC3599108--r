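#' LDA configuration
#'
#' Settings for the collapsed Gibbs sampler. Priors are fixed and
#' symmetric: `alpha = 50 / T` on document-topic mixtures and
#' `beta = 0.01` on topic-word distributions.
#'
#' @param T Number of topics (>= 1).
#' @param alpha Symmetric document-topic prior (default `50 / T`).
#' @param beta Symmetric topic-word prior (default 0.01).
#' @param iterations Gibbs sweeps over the corpus (default 1000).
#' @param seed Integer seed for the sampler's private RNG stream.
#' @return An object of class `lda_config`.
#' @export
lda_config <- function(T, alpha = 50 / T, beta = 0.01, iterations = 1000,
                       seed = 1) {
  stopifnot(T >= 1, alpha > 0, beta > 0, iterations >= 1)
  structure(list(T = as.integer(T), alpha = alpha, beta = beta,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "lda_config")
}

# Internal: map a corpus onto an integer document-term representation for
# a given vocabulary (words in corpus order of first appearance).
corpus_to_ids <- function(corpus, vocabulary) {
  lapply(corpus$documents, function(d) {
    ids <- match(doc_tokens(d, corpus$layer), vocabulary)
    as.integer(ids[!is.na(ids)]) - 1L
  })
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Builds the training vocabulary (words occurring at least `min_count`
#' times, default 2), initializes topic assignments at random from a
#' seeded private RNG stream and runs `config$iterations` sweeps of the
#' collapsed Gibbs sampler. The same corpus, configuration and seed give
#' bit-identical count matrices.
#'
#' @param corpus An `ehr_corpus`.
#' @param config An [lda_config()].
#' @param min_count Minimum training frequency for a word to enter the
#'   vocabulary.
#' @param vocab Optional explicit vocabulary (character vector), overriding
#'   the frequency filter. Use a shared vocabulary when comparing held-out
#'   fit across corpora of different sizes: otherwise the larger corpus
#'   admits extra rare words and its per-token likelihood is not
#'   comparable.
#' @return An object of class `topic_model`: `topic_word_counts` (`T x V`),
#'   `doc_topic_counts` (`D x T`), `vocabulary`, `config`.
#' @export
fit_lda <- function(corpus, config, min_count = 2, vocab = NULL) {
  stopifnot(inherits(corpus, "ehr_corpus"), inherits(config, "lda_config"))
  if (is.null(vocab)) {
    toks <- unlist(lapply(corpus$documents, doc_tokens, layer = corpus$layer),
                   use.names = FALSE)
    counts <- table(toks)
    vocabulary <- names(counts)[counts >= min_count]
  } else vocabulary <- unique(as.character(vocab))
  if (!length(vocabulary)) stop("empty vocabulary after frequency filtering")
  docs <- corpus_to_ids(corpus, vocabulary)
  fit <- lda_gibbs_cpp(docs, length(vocabulary), config$T, config$alpha,
                       config$beta, config$iterations, config$seed)
  colnames(fit$topic_word_counts) <- vocabulary
  structure(list(topic_word_counts = fit$topic_word_counts,
                 doc_topic_counts = fit$doc_topic_counts,
                 vocabulary = vocabulary, config = config),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model: T=%d, V=%d, %d documents, %d tokens>\n",
              x$config$T, length(x$vocabulary), nrow(x$doc_topic_counts),
              sum(x$topic_word_counts)))
  invisible(x)
}

# Topic-word probabilities phi (T x V) under the model's beta smoothing.
model_phi <- function(model) {
  beta <- model$config$beta
  tw <- model$topic_word_counts + beta
  tw / rowSums(tw)
}

#' Top words per topic
#'
#' @param model A [fit_lda()] result.
#' @param k Number of words per topic.
#' @return Character matrix, one row per topic, words ranked by
#'   topic-word count.
#' @export
top_words <- function(model, k = 10) {
  stopifnot(inherits(model, "topic_model"))
  t(apply(model$topic_word_counts, 1L, function(row) {
    model$vocabulary[order(-row)][seq_len(k)]
  }))
}

#' Held-out log-likelihood (left-to-right estimator)
#'
#' Estimates the log probability of held-out documents under a fitted
#' model with the left-to-right sequential estimator: words of each
#' document are scored in order, each word's predictive probability
#' averaged over `particles` sampled topic-assignment states of the
#' preceding words. Out-of-vocabulary tokens are dropped and counted.
#'
#' @param model A [fit_lda()] result (or any `topic_model`).
#' @param heldout An `ehr_corpus` of unseen documents.
#' @param particles Number of particles (default 10).
#' @param seed Integer seed for the estimator's private RNG stream.
#' @return An object of class `heldout_estimate`: `total_loglik` (natural
#'   log, <= 0), `n_tokens` (in-vocabulary tokens scored), `per_token`,
#'   `n_oov` (dropped tokens), `particles`.
#' @export
heldout_loglik <- function(model, heldout, particles = 10, seed = 1) {
  stopifnot(inherits(model, "topic_model"), inherits(heldout, "ehr_corpus"),
            particles >= 1)
  docs <- corpus_to_ids(heldout, model$vocabulary)
  n_total <- sum(vapply(heldout$documents, function(d)
    length(doc_tokens(d, heldout$layer)), 0L))
  n_in <- sum(lengths(docs))
  if (n_in == 0L)
    return(structure(list(total_loglik = 0, n_tokens = 0L, per_token = NaN,
                          n_oov = n_total, particles = particles),
                     class = "heldout_estimate"))
  est <- left_to_right_cpp(docs, model_phi(model), model$config$alpha,
                           as.integer(particles), as.integer(seed))
  structure(list(total_loglik = est$total_loglik,
                 n_tokens = as.integer(est$n_tokens),
                 per_token = est$total_loglik / est$n_tokens,
                 n_oov = n_total - n_in, particles = particles),
            class = "heldout_estimate")
}

#' @export
print.heldout_estimate <- function(x, ...) {
  cat(sprintf("<heldout_estimate: %.1f nats over %d tokens (%.3f per token, %d OOV dropped)>\n",
              x$total_loglik, x$n_tokens, x$per_token, x$n_oov))
  invisible(x)
}

#' Held-out fit as a function of the number of topics
#'
#' Fits one model per entry of `T_grid` and evaluates each on the held-out
#' corpus, producing the model-fit curve used to compare corpora of
#' different sizes and redundancy levels. Train and held-out corpora must
#' be disjoint: shared document ids — or, when patient ids exist, shared
#' patients — are an error, mirroring the removal of same-patient notes
#' from training data to prevent contamination.
#'
#' @param train,heldout `ehr_corpus` objects.
#' @param T_grid Integer vector of topic counts.
#' @param iterations Gibbs sweeps per fit.
#' @param particles Particles for the left-to-right estimator.
#' @param seed Base seed; per-T seeds are derived deterministically.
#' @param min_count Vocabulary frequency floor (default 2).
#' @param vocab Optional shared vocabulary passed to [fit_lda()].
#' @return Data frame with columns `T`, `total_loglik`, `n_tokens`,
#'   `per_token`.
#' @export
topic_curve <- function(train, heldout, T_grid, iterations = 1000,
                        particles = 10, seed = 1, min_count = 2,
                        vocab = NULL) {
  overlap <- intersect(corpus_ids(train), corpus_ids(heldout))
  if (length(overlap))
    stop("held-out corpus shares documents with training corpus: ",
         overlap[1L])
  tp <- stats::na.omit(corpus_patients(train))
  hp <- stats::na.omit(corpus_patients(heldout))
  shared_pat <- intersect(tp, hp)
  if (length(shared_pat))
    stop("held-out corpus shares patients with training corpus: ",
         shared_pat[1L])
  rows <- lapply(T_grid, function(T) {
    s <- (seed + 7919L * as.integer(T)) %% .Machine$integer.max
    model <- fit_lda(train, lda_config(T, iterations = iterations, seed = s),
                     min_count = min_count, vocab = vocab)
    est <- heldout_loglik(model, heldout, particles = particles, seed = s + 1L)
    data.frame(T = T, total_loglik = est$total_loglik,
               n_tokens = est$n_tokens, per_token = est$per_token)
  })
  do.call(rbind, rows)
}
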