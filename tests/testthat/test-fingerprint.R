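test_that("full and selective line fingerprints follow the window counts", {
  expect_length(line_fingerprints("abcdefgh", 3, "full"), 6L)  # m - n + 1
  expect_equal(line_fingerprints("abcdefgh", 3, "selective"), c("abc", "def"))
  expect_equal(line_fingerprints("ab", 3, "full"), character(0))
  expect_equal(line_fingerprints("ab", 3, "selective"), character(0))
  expect_equal(line_fingerprints("abcdef", 3, "selective"), c("abc", "def"))
  expect_equal(line_fingerprints("abcde", 2, "full"),
               c("ab", "bc", "cd", "de"))
})

test_that("document profiles use set semantics and respect line boundaries", {
  cfg4 <- reduction_config(0.5, n = 4, hash = FALSE)
  one <- ehr_document("a", "abcdefgh")
  two <- ehr_document("b", "abcdefgh\nabcdefgh")
  expect_setequal(document_fingerprints(one, cfg4)$fingerprints,
                  c("abcd", "efgh"))
  expect_setequal(document_fingerprints(two, cfg4)$fingerprints,
                  document_fingerprints(one, cfg4)$fingerprints)
  # no fingerprint spans the line break
  split2 <- ehr_document("c", "abcd\nefgh")
  expect_setequal(document_fingerprints(split2, reduction_config(0.5, n = 8,
                                                                 hash = FALSE))$fingerprints,
                  character(0))
})

test_that("random documents match the substring-set oracle, hashed and not", {
  set.seed(31)
  for (scheme in c("selective", "full")) {
    for (i in 1:10) {
      lines <- vapply(seq_len(sample(1:6, 1)), function(.)
        paste(sample(letters, sample(3:60, 1), replace = TRUE), collapse = ""), "")
      doc <- ehr_document(paste0("d", i), paste(lines, collapse = "\n"))
      cfg <- reduction_config(0.5, n = 7, scheme = scheme, hash = FALSE)
      expect_setequal(document_fingerprints(doc, cfg)$fingerprints,
                      fingerprint_set_oracle(lines, 7, scheme))
      cfg_h <- reduction_config(0.5, n = 7, scheme = scheme, hash = TRUE)
      expect_setequal(document_fingerprints(doc, cfg_h)$fingerprints,
                      unique(noteredund:::fnv1a64_cpp(
                        fingerprint_set_oracle(lines, 7, scheme))))
    }
  }
})

test_that("fingerprint similarity is the shared count over A's profile size", {
  cfg <- reduction_config(0.5, n = 4, hash = FALSE)
  a <- document_fingerprints(ehr_document("a", "aaaabbbbccccdddd"), cfg)  # 4 fps
  b <- document_fingerprints(ehr_document("b", "aaaabbbbxxxxyyyy"), cfg)  # shares 2
  expect_equal(fingerprint_similarity(b, a), 0.5)
  expect_equal(fingerprint_similarity(a, a), 1.0)
  disj <- document_fingerprints(ehr_document("c", "zzzzwwwwqqqqrrrr"), cfg)
  expect_equal(fingerprint_similarity(disj, a), 0.0)
  empty <- document_fingerprints(ehr_document("d", "ab"), cfg)
  expect_equal(fingerprint_similarity(b, empty), 0)
  cfg5 <- reduction_config(0.5, n = 5, hash = FALSE)
  a5 <- document_fingerprints(ehr_document("a", "aaaabbbbccccdddd"), cfg5)
  expect_error(fingerprint_similarity(a5, a), "granularity|scheme")
})

test_that("greedy reduction handles identity and disjoint extremes", {
  five <- ehr_corpus(lapply(1:5, function(i)
    ehr_document(paste0("d", i), "this note body is exactly the same every time")))
  red <- reduce_corpus(five, reduction_config(0.5, n = 10))
  expect_equal(red$report$retained_ids, "d1")
  expect_equal(nrow(red$report$rejected), 4L)
  expect_true(all(red$report$rejected$similarity == 1.0))
  expect_equal(red$report$rejected$blocking_doc_id, rep("d1", 4))

  disjoint <- ehr_corpus(lapply(1:6, function(i)
    ehr_document(paste0("d", i), strrep(letters[i], 40))))
  red0 <- reduce_corpus(disjoint, reduction_config(0.0, n = 8))
  expect_length(red0$report$retained_ids, 6L)

  # cutoff 1.0 rejects nothing: similarity can never exceed 1
  red1 <- reduce_corpus(five, reduction_config(1.0, n = 10))
  expect_length(red1$report$retained_ids, 5L)
})

test_that("the inverted-index reduction equals the quadratic oracle", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 12, copy_fraction = 0.6,
                                             seed = 23))
  for (cutoff in c(0.2, 0.33)) {
    cfg <- reduction_config(cutoff)
    got <- reduce_corpus(co, cfg)
    expect_identical(got$report$retained_ids, reduce_oracle(co, cfg))
    expect_true(all(got$report$rejected$similarity > cutoff))
    # retained + rejected partition the input
    expect_setequal(c(got$report$retained_ids, got$report$rejected$doc_id),
                    corpus_ids(co))
  }
})

test_that("every retained pair stays at or below the cutoff in both directions", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 10, copy_fraction = 0.7,
                                             seed = 29))
  cfg <- reduction_config(0.25)
  red <- reduce_corpus(co, cfg)
  profs <- lapply(red$corpus$documents, document_fingerprints, config = cfg)
  for (i in seq_along(profs)) for (j in seq_along(profs)) {
    if (i == j) next
    expect_lte(fingerprint_similarity(profs[[i]], profs[[j]]), cfg$cutoff)
  }
})

test_that("visit order changes which duplicates survive but not the guarantee", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 6, copy_fraction = 0.8,
                                             seed = 41))
  by_date <- reduce_corpus(co, reduction_config(0.25, order = "date"))
  by_rand <- reduce_corpus(co, reduction_config(0.25, order = "random", seed = 2))
  by_rand2 <- reduce_corpus(co, reduction_config(0.25, order = "random", seed = 2))
  expect_identical(by_rand$report$retained_ids, by_rand2$report$retained_ids)
  expect_true(length(by_date$report$retained_ids) < length(co))
})

test_that("the last-note baseline keeps one latest note per patient", {
  mk <- function(id, pid, date) ehr_document(id, paste("note", id),
                                             patient_id = pid, date = date)
  co <- corpus_of(mk("a1", "p1", "2020-01-01"), mk("a2", "p1", "2020-03-01"),
                  mk("b1", "p2", "2020-02-01"), mk("b2", "p2", "2020-02-01"),
                  mk("b3", "p2", "2020-01-15"), mk("c1", "p3", "2020-05-05"))
  base <- last_note_baseline(co)
  expect_setequal(corpus_ids(base), c("a2", "b2", "c1"))  # b2 wins the date tie
  no_date <- corpus_of(mk("a1", "p1", "2020-01-01"),
                       ehr_document("a2", "x", patient_id = "p1"))
  expect_error(last_note_baseline(no_date), "a2")
})

test_that("fingerprint similarity predicts alignment redundancy", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 20, copy_fraction = 0.5,
                                             seed = 17))
  prof <- redundancy_profile(co, "same_patient", pair_sample = 120, seed = 5)
  cfg <- reduction_config(0.25)
  fps <- lapply(co$documents, document_fingerprints, config = cfg)
  fsim <- mapply(function(a, b) {
    (fingerprint_similarity(fps[[b]], fps[[a]]) +
     fingerprint_similarity(fps[[a]], fps[[b]])) / 2
  }, prof$pair_records$doc_a, prof$pair_records$doc_b)
  rho <- cor(fsim, prof$pair_records$redundancy_sym, method = "spearman")
  expect_gt(rho, 0.7)
})
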