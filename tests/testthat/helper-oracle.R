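# Independent brute-force implementation of the scoring equations, written
# as explicit loops over tokens/words/references.  Used as the oracle the
# matrix implementation must match; deliberately shares no code with R/.

oracle_word_scores <- function(docs_tokens, ref_pos) {
  vocab <- sort(unique(unlist(docs_tokens, use.names = FALSE)))
  relf <- function(d, w) {
    tk <- docs_tokens[[d]]
    sum(tk == w) / length(tk)
  }
  S <- numeric(0)
  for (w in vocab) {
    denom <- 0
    for (r in names(ref_pos)) denom <- denom + relf(r, w)
    if (denom > 0) {
      sw <- 0
      for (r in names(ref_pos)) {
        sw <- sw + (relf(r, w) / denom) * ref_pos[[r]]
      }
      S[w] <- sw
    }
  }
  S
}

oracle_score_document <- function(docs_tokens, ref_pos, doc_id) {
  S <- oracle_word_scores(docs_tokens, ref_pos)
  tk <- docs_tokens[[doc_id]]
  scored <- unique(tk)[unique(tk) %in% names(S)]
  counts <- vapply(scored, function(w) sum(tk == w), numeric(1))
  N <- sum(counts)
  fstar <- counts / N
  omega <- sum(fstar * S[scored])
  V <- sum(fstar * (S[scored] - omega)^2)
  list(omega = omega, se = sqrt(V / N), n_scored = N,
       n_unique = length(scored))
}

# corpus whose tokens survive preprocessing untouched (no stopwords config)
tokens_corpus <- function(docs_tokens, ref_pos = NULL) {
  ids <- names(docs_tokens)
  role <- if (is.null(ref_pos)) {
    rep("virgin", length(ids))
  } else {
    ifelse(ids %in% names(ref_pos), "reference", "virgin")
  }
  pos <- rep(NA_real_, length(ids))
  if (!is.null(ref_pos)) pos[match(names(ref_pos), ids)] <- ref_pos
  ws_corpus(ids,
            vapply(docs_tokens, paste, character(1), collapse = " "),
            group = "synthetic", role = role, position = pos)
}

no_stop_cfg <- function() cleaning_config(stopwords = "none")

# the classic 3-document toy: two references with one shared word
toy_tokens <- function() {
  list(
    R1 = c("a", "a", "b"),
    R2 = c("b", "c", "c"),
    V1 = c("a", "b", "c")
  )
}

toy_ref_pos <- c(R1 = 0, R2 = 1)
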