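toy_fm <- function() {
  build_frequency_matrix(tokens_corpus(toy_tokens(), toy_ref_pos),
                         no_stop_cfg())
}

test_that("word scores on the toy corpus match the hand-computed values", {
  fm <- toy_fm()
  wst <- compute_word_scores(fm, reference_assignment(toy_ref_pos))
  expect_equal(wst$scores[["a"]], 0, tolerance = 1e-15)
  expect_equal(wst$scores[["b"]], 0.5, tolerance = 1e-15)  # F_b equal in both refs
  expect_equal(wst$scores[["c"]], 1, tolerance = 1e-15)
  expect_identical(unname(wst$n_refs_containing[c("a", "b", "c")]),
                   c(1L, 2L, 1L))
})

test_that("degenerate reference assignments are rejected", {
  fm <- toy_fm()
  expect_error(reference_assignment(c(R1 = 0.3, R2 = 0.3)), "distinct")
  expect_error(reference_assignment(c(R1 = 0)), "two reference")
  expect_error(reference_assignment(c(0, 1)), "named")
  expect_error(
    compute_word_scores(fm, reference_assignment(c(R1 = 0, ZZ = 1))),
    "ZZ"
  )
})

test_that("virgin scoring matches hand oracles, including the centering pull", {
  fm <- toy_fm()
  wst <- compute_word_scores(fm, reference_assignment(toy_ref_pos))
  expect_equal(score_document(fm, wst, "V1")$omega_raw, 0.5,
               tolerance = 1e-15)
  # re-scoring a reference as virgin is pulled towards the middle
  expect_equal(score_document(fm, wst, "R1")$omega_raw, 1 / 6,
               tolerance = 1e-15)
  expect_equal(score_document(fm, wst, "R2")$omega_raw, 5 / 6,
               tolerance = 1e-15)

  ds <- score_document(fm, wst, "V1")
  expect_identical(ds$n_scored_tokens, 3L)
  expect_identical(ds$n_unique_scored, 3L)
})

test_that("a document with no scored tokens is an error naming it", {
  docs <- list(R1 = c("a", "a"), R2 = c("b", "b"), V1 = c("z", "z"))
  fm <- build_frequency_matrix(tokens_corpus(docs, toy_ref_pos), no_stop_cfg())
  wst <- compute_word_scores(fm, reference_assignment(toy_ref_pos))
  expect_error(score_document(fm, wst, "V1"), "V1")
})

test_that("virgin-only words are excluded from scoring and counts", {
  docs <- list(R1 = c("a", "a", "b"), R2 = c("b", "c", "c"),
               V1 = c("a", "b", "c", "zz", "zz", "zz"))
  fm <- build_frequency_matrix(tokens_corpus(docs, toy_ref_pos), no_stop_cfg())
  wst <- compute_word_scores(fm, reference_assignment(toy_ref_pos))
  expect_false("zz" %in% names(wst$scores))
  ds <- score_document(fm, wst, "V1")
  expect_equal(ds$omega_raw, 0.5, tolerance = 1e-15)  # zz ignored entirely
  expect_identical(ds$n_scored_tokens, 3L)
})

test_that("score uncertainty matches the closed form on the toy corpus", {
  fm <- toy_fm()
  wst <- compute_word_scores(fm, reference_assignment(toy_ref_pos))
  un <- score_uncertainty(fm, wst, "V1")
  expect_equal(un$se, sqrt((1 / 6) / 3), tolerance = 1e-15)
  expect_equal(un$ci_low, 0.5 - 1.96 * un$se, tolerance = 1e-15)
  expect_equal(un$ci_high, 0.5 + 1.96 * un$se, tolerance = 1e-15)

  # all scored roots sharing one score -> zero variance
  docs <- list(R1 = c("a", "b"), R2 = c("c", "d"), V1 = c("a", "b", "a"))
  fm2 <- build_frequency_matrix(tokens_corpus(docs, toy_ref_pos), no_stop_cfg())
  wst2 <- compute_word_scores(fm2, reference_assignment(toy_ref_pos))
  expect_equal(score_uncertainty(fm2, wst2, "V1")$se, 0, tolerance = 1e-15)
})

test_that("duplicating a document's text shrinks its SE by exactly 1/sqrt(2)", {
  tk <- toy_tokens()
  tk2 <- tk
  tk2$V1 <- c(tk$V1, tk$V1)
  fm1 <- build_frequency_matrix(tokens_corpus(tk, toy_ref_pos), no_stop_cfg())
  fm2 <- build_frequency_matrix(tokens_corpus(tk2, toy_ref_pos), no_stop_cfg())
  ra <- reference_assignment(toy_ref_pos)
  s1 <- score_corpus(fm1, ra, "V1")
  s2 <- score_corpus(fm2, ra, "V1")
  expect_equal(s2$omega_raw, s1$omega_raw, tolerance = 1e-15)
  expect_identical(s2$n_scored, 2L * s1$n_scored)
  expect_equal(s2$se, s1$se / sqrt(2), tolerance = 1e-12)
})

test_that("score_corpus batches consistently and handles empty input", {
  fm <- toy_fm()
  ra <- reference_assignment(toy_ref_pos)
  empty <- score_corpus(fm, ra, character())
  expect_identical(nrow(empty), 0L)

  batch <- score_corpus(fm, ra, c("R1", "R2", "V1"))
  wst <- compute_word_scores(fm, ra)
  for (i in seq_len(nrow(batch))) {
    solo <- score_document(fm, wst, batch$doc_id[i])
    expect_equal(batch$omega_raw[i], solo$omega_raw, tolerance = 1e-15)
  }
  expect_error(score_corpus(fm, ra, "ghost"), "ghost")
})

test_that("implementation matches the brute-force oracle on small random corpora", {
  set.seed(101)
  roots <- c("aa", "bb", "cc", "dd", "ee", "ff")
  for (rep in 1:25) {
    n_docs <- sample(2:3, 1)
    docs <- lapply(seq_len(n_docs), function(i) {
      sample(roots[1:sample(3:6, 1)], sample(4:12, 1), replace = TRUE)
    })
    names(docs) <- paste0("D", seq_len(n_docs))
    ref_pos <- c(D1 = 0, D2 = 1)
    # ensure a shared scoring universe exists for every doc
    docs <- lapply(docs, function(tk) c(tk, "aa"))
    fm <- build_frequency_matrix(tokens_corpus(docs, ref_pos), no_stop_cfg())
    wst <- compute_word_scores(fm, reference_assignment(ref_pos))
    S_oracle <- oracle_word_scores(docs, ref_pos)
    expect_equal(sort(names(wst$scores)), sort(names(S_oracle)))
    expect_equal(wst$scores[names(S_oracle)], S_oracle, tolerance = 1e-12)
    for (d in names(docs)) {
      o <- oracle_score_document(docs, ref_pos, d)
      ds <- score_document(fm, wst, d)
      un <- score_uncertainty(fm, wst, d, omega = ds$omega_raw)
      expect_equal(ds$omega_raw, o$omega, tolerance = 1e-12)
      expect_equal(un$se, o$se, tolerance = 1e-12)
      expect_identical(ds$n_scored_tokens, as.integer(o$n_scored))
    }
  }
})

test_that("all word and document scores are bounded by the reference positions", {
  set.seed(202)
  roots <- paste0("r", letters[1:8])
  for (rep in 1:20) {
    ref_pos <- c(A = runif(1, 0, 0.3), B = runif(1, 0.7, 1))
    docs <- list(
      A = sample(roots, 20, replace = TRUE),
      B = sample(roots, 20, replace = TRUE),
      V = sample(roots, 15, replace = TRUE)
    )
    fm <- build_frequency_matrix(tokens_corpus(docs, ref_pos), no_stop_cfg())
    wst <- compute_word_scores(fm, reference_assignment(ref_pos))
    expect_true(all(wst$scores >= min(ref_pos) - 1e-12))
    expect_true(all(wst$scores <= max(ref_pos) + 1e-12))
    om <- score_corpus(fm, reference_assignment(ref_pos), names(docs))$omega_raw
    expect_true(all(om >= min(ref_pos) - 1e-12 & om <= max(ref_pos) + 1e-12))
  }
})

test_that("disjoint reference vocabularies recover assigned positions exactly", {
  docs <- list(R1 = c("xx", "yy", "xx"), R2 = c("uu", "vv"),
               V1 = c("xx", "uu"))
  ra <- reference_assignment(c(R1 = 0.2, R2 = 0.9))
  fm <- build_frequency_matrix(tokens_corpus(docs, c(R1 = 0.2, R2 = 0.9)),
                               no_stop_cfg())
  sc <- score_corpus(fm, ra, c("R1", "R2"))
  expect_equal(sc$omega_raw, c(0.2, 0.9), tolerance = 1e-15)
  # a root appearing only in R2 scores exactly at R2's position
  wst <- compute_word_scores(fm, ra)
  expect_equal(wst$scores[["uu"]], 0.9, tolerance = 1e-15)
})

test_that("swapping reference labels maps every score to 1 minus itself", {
  tk <- toy_tokens()
  fm <- toy_fm()
  ra <- reference_assignment(c(R1 = 0, R2 = 1))
  ra_swap <- reference_assignment(c(R1 = 1, R2 = 0))
  s <- score_corpus(fm, ra, names(tk))
  s_swap <- score_corpus(fm, ra_swap, names(tk))
  expect_equal(s_swap$omega_raw, 1 - s$omega_raw, tolerance = 1e-12)
  w <- compute_word_scores(fm, ra)$scores
  w_swap <- compute_word_scores(fm, ra_swap)$scores
  expect_equal(w_swap[names(w)], 1 - w, tolerance = 1e-12)
})

test_that("continuous (non-binary) reference positions are supported", {
  docs <- list(R1 = c("aa", "bb"), R2 = c("bb", "cc"), R3 = c("cc", "dd"),
               V = c("aa", "bb", "cc", "dd"))
  ra <- reference_assignment(c(R1 = 0.1, R2 = 0.5, R3 = 0.8))
  fm <- build_frequency_matrix(
    tokens_corpus(docs, c(R1 = 0.1, R2 = 0.5, R3 = 0.8)), no_stop_cfg()
  )
  wst <- compute_word_scores(fm, ra)
  S_oracle <- oracle_word_scores(docs, c(R1 = 0.1, R2 = 0.5, R3 = 0.8))
  expect_equal(wst$scores[names(S_oracle)], S_oracle, tolerance = 1e-12)
  expect_equal(wst$scores[["bb"]], 0.3, tolerance = 1e-15)  # equal F in R1, R2
})
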