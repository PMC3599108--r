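test_that("identical and disjoint sequences give the extreme matched counts", {
  a <- c("pt", "seen", "today", "for", "routine", "follow", "up")
  expect_equal(align_local(a, a)$matched_tokens, 7L)
  expect_equal(align_local(a, c("x1", "x2", "x3"))$matched_tokens, 0L)
  expect_equal(align_local(character(0), a)$matched_tokens, 0L)
})

test_that("the reordered-sentence pair aligns as the DP oracle says", {
  a <- tokenize("Pt developed abd pain and acute cholecystitis")
  b <- tokenize("Pt developed acute abd pain and cholecystitis")
  expect_equal(shared_word_identity(a, b), 1.0)
  single <- align_local(a, b, alignment_scoring(repeated = FALSE))
  ora <- sw_oracle(a, b)
  expect_equal(single$score, ora$score)
  expect_equal(single$matched_tokens, ora$matched_tokens)
  # moving "acute" costs one aligned token in each direction: 6 of 7 match
  expect_equal(align_local(a, b)$matched_tokens, 6L)
})

test_that("single-alignment mode reproduces the naive Smith-Waterman oracle", {
  set.seed(421)
  alphabet <- sprintf("t%02d", 1:12)
  for (i in 1:60) {
    a <- random_token_seq(sample(1:40, 1), alphabet)
    b <- random_token_seq(sample(1:40, 1), alphabet)
    got <- align_local(a, b, alignment_scoring(repeated = FALSE))
    ora <- sw_oracle(a, b)
    expect_equal(got$score, ora$score)
    expect_equal(got$matched_tokens, ora$matched_tokens)
  }
})

test_that("matched tokens are bounded and monotone under novel-token padding", {
  set.seed(77)
  alphabet <- sprintf("t%02d", 1:8)
  for (i in 1:25) {
    a <- random_token_seq(sample(5:30, 1), alphabet)
    b <- random_token_seq(sample(5:30, 1), alphabet)
    m <- align_local(a, b)$matched_tokens
    expect_lte(m, min(length(a), length(b)))
    b_pad <- c(b, sprintf("novel%02d", 1:10))
    expect_gte(align_local(a, b_pad)$matched_tokens, m)
  }
})

test_that("repeated extraction finds multiple shared segments a single pass misses", {
  shared1 <- c("assess", "and", "plan", "reviewed")
  shared2 <- c("renal", "function", "stable", "today")
  a <- c(shared1, "x1", "x2", "x3", shared2)
  b <- c(shared2, "y1", "y2", "y3", shared1)
  expect_equal(align_local(a, b, alignment_scoring(repeated = FALSE))$matched_tokens, 4L)
  rep_res <- align_local(a, b)
  expect_equal(rep_res$matched_tokens, 8L)
  expect_equal(nrow(rep_res$segments), 2L)
})

test_that("segments never overlap within a sequence", {
  set.seed(99)
  alphabet <- sprintf("t%02d", 1:6)
  for (i in 1:20) {
    a <- random_token_seq(40, alphabet)
    b <- random_token_seq(40, alphabet)
    segs <- align_local(a, b)$segments
    if (nrow(segs) < 2) next
    for (cols in list(c("start_a", "end_a"), c("start_b", "end_b"))) {
      iv <- segs[, cols, drop = FALSE]
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      expect_true(all(iv[-nrow(iv), 2] <= iv[-1, 1]))
    }
  }
})

test_that("pair redundancy normalizes per direction and symmetrizes", {
  d <- doc_from_tokens("d1", list(c("a", "b", "c", "d"), c("e", "f", "g", "h")))
  expect_equal(unname(pair_redundancy(d, d)), c(1, 1, 1))

  contained <- doc_from_tokens("d2", list(
    c("a", "b", "c", "d"), c("e", "f", "g", "h"),
    c("n1", "n2", "n3", "n4"), c("n5", "n6", "n7", "n8")))
  r <- pair_redundancy(d, contained)
  expect_equal(unname(r["redundancy_a"]), 1.0)
  expect_equal(unname(r["redundancy_b"]), 0.5)
  expect_equal(unname(r["redundancy_sym"]), 0.75)

  empty <- ehr_document("d3", "")
  expect_equal(unname(pair_redundancy(empty, d)), c(0, 0, 0))
})

test_that("redundancy is symmetric in its arguments", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 4, seed = 15))
  docs <- co$documents
  for (k in 1:8) {
    ij <- sample(length(docs), 2)
    r1 <- pair_redundancy(docs[[ij[1]]], docs[[ij[2]]])
    r2 <- pair_redundancy(docs[[ij[2]]], docs[[ij[1]]])
    expect_equal(unname(r1["redundancy_sym"]), unname(r2["redundancy_sym"]))
  }
})

test_that("redundancy profiles sample eligible pairs and bin deciles", {
  one_pat <- ehr_corpus(lapply(1:3, function(i)
    ehr_document(paste0("n", i), paste("text of note", i), patient_id = "p1")))
  prof <- redundancy_profile(one_pat, "same_patient", pair_sample = 10, seed = 1)
  expect_equal(nrow(prof$pair_records), 3L)  # only 3 unordered pairs exist
  expect_equal(sum(prof$histogram), 3L)
  expect_error(redundancy_profile(one_pat, "cross_patient", 10, 1), "cross_patient")

  dup <- ehr_corpus(lapply(1:4, function(i)
    ehr_document(paste0("c", i), "identical note body here for everyone",
                 patient_id = paste0("p", i))))
  prof2 <- redundancy_profile(dup, "cross_patient", pair_sample = 6, seed = 2)
  expect_equal(prof2$mean_sym, 1.0)
  expect_equal(prof2$histogram[10], 6L)

  # seeded sampling is reproducible and respects pair_sample
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 8, seed = 4))
  p1 <- redundancy_profile(co, "same_patient", pair_sample = 20, seed = 9)
  p2 <- redundancy_profile(co, "same_patient", pair_sample = 20, seed = 9)
  expect_identical(p1$pair_records, p2$pair_records)
  expect_equal(nrow(p1$pair_records), 20L)
  expect_true(all(p1$pair_records$redundancy_sym >= 0 &
                  p1$pair_records$redundancy_sym <= 1))
})

test_that("copy-paste synthesis separates same-patient from cross-patient redundancy", {
  co <- generate_ehr_corpus(synth_ehr_config(n_patients = 15, copy_fraction = 0.5,
                                             seed = 8))
  same <- redundancy_profile(co, "same_patient", pair_sample = 200, seed = 1)
  cross <- redundancy_profile(co, "cross_patient", pair_sample = 200, seed = 1)
  expect_gt(same$mean_sym, cross$mean_sym + 0.1)
  tt <- t.test(same$pair_records$redundancy_sym, cross$pair_records$redundancy_sym)
  expect_lt(tt$p.value, 1e-6)
})
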