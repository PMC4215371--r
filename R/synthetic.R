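# Synthetic corpora with known ground-truth positions.  Documents are bags
# of tokens drawn from a two-pole mixture: a document at position theta
# draws each token from theta * p_health + (1 - theta) * p_tobacco.

#' Specification of a synthetic two-pole corpus
#'
#' Defines the generative design: a vocabulary split into shared
#' (non-discriminating) words, used at equal rates by both poles, and
#' discriminating words, each favoured by its own pole by an odds factor
#' `pole_skew`; reference document counts at the two poles; and virgin
#' documents at known intermediate positions.  The defaults mirror a
#' realistic lobbying-study design: 8 tobacco-pole and 5 health-pole
#' references, 30% discriminating vocabulary with a 3:1 usage skew, and
#' documents of 2000 scored tokens (mid-range for position papers of a
#' few thousand words).
#'
#' @param vocab_size Total vocabulary size (>= 4).
#' @param discriminating_fraction Fraction of the vocabulary that
#'   discriminates between poles, in `[0, 1]`; the discriminating words
#'   are split evenly between the poles (an odd count is an error, since
#'   the poles could not then share the non-discriminating rate exactly).
#' @param pole_skew Probability ratio (> 1) by which a discriminating
#'   word favours its own pole.
#' @param doc_length Tokens per document (>= 1).
#' @param ref_counts Integer vector `c(tobacco, health)`: number of
#'   reference documents at poles 0 and 1.
#' @param virgin_positions True positions `theta` in `[0, 1]`, one virgin
#'   document each.
#' @param seed Integer seed consumed by [generate_corpus()]; `NULL` uses
#'   the current RNG state.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(vocab_size = 2000L,
                           discriminating_fraction = 0.3,
                           pole_skew = 3,
                           doc_length = 2000L,
                           ref_counts = c(tobacco = 8L, health = 5L),
                           virgin_positions = seq(0, 1, length.out = 10L),
                           seed = NULL) {
  vocab_size <- as.integer(vocab_size)
  doc_length <- as.integer(doc_length)
  if (is.na(vocab_size) || vocab_size < 4L) {
    stop("`vocab_size` must be >= 4", call. = FALSE)
  }
  if (discriminating_fraction < 0 || discriminating_fraction > 1) {
    stop("`discriminating_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(pole_skew) || pole_skew <= 1) {
    stop("`pole_skew` must be finite and > 1", call. = FALSE)
  }
  if (is.na(doc_length) || doc_length < 1L) {
    stop("`doc_length` must be >= 1", call. = FALSE)
  }
  ref_counts <- as.integer(ref_counts)
  if (length(ref_counts) != 2L || anyNA(ref_counts) || any(ref_counts < 0L)) {
    stop("`ref_counts` must be two non-negative integers (tobacco, health)",
         call. = FALSE)
  }
  virgin_positions <- as.numeric(virgin_positions)
  if (length(virgin_positions) &&
      (min(virgin_positions) < 0 || max(virgin_positions) > 1)) {
    stop("`virgin_positions` must lie in [0, 1]", call. = FALSE)
  }
  n_disc <- round(discriminating_fraction * vocab_size)
  if (n_disc %% 2L != 0L) {
    stop("`discriminating_fraction` * `vocab_size` must be even ",
         "(the discriminating words are split evenly between the poles)",
         call. = FALSE)
  }
  structure(
    list(
      vocab_size = vocab_size,
      discriminating_fraction = discriminating_fraction,
      n_discriminating = as.integer(n_disc),
      pole_skew = pole_skew,
      doc_length = doc_length,
      ref_counts = stats::setNames(ref_counts, c("tobacco", "health")),
      virgin_positions = virgin_positions,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Vocabulary words are all-consonant strings ("w" + base-15 code over
# consonants), which are Porter2 fixed points, never stopwords and never
# merged by stemming, so preprocessing is exercised without distorting the
# designed frequencies.
.synthetic_vocab <- function(n) {
  alphabet <- c("b", "c", "f", "g", "h", "k", "m", "p",
                "q", "r", "t", "v", "w", "x", "z")
  base <- length(alphabet)
  width <- max(3L, ceiling(log(max(n, 2L)) / log(base)))
  idx <- seq_len(n) - 1L
  code <- character(n)
  for (k in seq_len(width)) {
    code <- paste0(alphabet[(idx %% base) + 1L], code)
    idx <- idx %/% base
  }
  paste0("w", code)
}

#' Token distributions of the two poles
#'
#' Builds the per-pole token probability vectors implied by a
#' [synthetic_spec()]: shared words have identical probability under both
#' poles, and each discriminating word is `pole_skew` times more probable
#' under its own pole than under the other.  Both vectors sum to 1.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `vocab` (character), `p_tobacco` and `p_health`
#'   (numeric probability vectors over `vocab`), and the index vectors
#'   `tobacco_words`, `health_words`, `shared_words`.
#' @export
build_pole_distributions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  v <- spec$vocab_size
  n_disc <- spec$n_discriminating
  n_half <- n_disc %/% 2L
  vocab <- .synthetic_vocab(v)
  idx_t <- seq_len(n_half)
  idx_h <- if (n_half > 0L) n_half + seq_len(n_half) else integer()
  idx_s <- setdiff(seq_len(v), c(idx_t, idx_h))
  s <- spec$pole_skew
  w_t <- rep(1, v)
  w_h <- rep(1, v)
  w_t[idx_t] <- s; w_h[idx_t] <- 1
  w_t[idx_h] <- 1; w_h[idx_h] <- s
  # equal pole halves => equal normalising constants, so shared words have
  # identical probability under both poles and skewed ratios are exact
  list(
    vocab = vocab,
    p_tobacco = w_t / sum(w_t),
    p_health = w_h / sum(w_h),
    tobacco_words = idx_t,
    health_words = idx_h,
    shared_words = idx_s
  )
}

#' Sample one synthetic document
#'
#' Draws `spec$doc_length` independent tokens from the mixture
#' `theta * p_health + (1 - theta) * p_tobacco` and concatenates them into
#' a document text.  Uses the current RNG state; seed beforehand (or via
#' [generate_corpus()]) for reproducibility.
#'
#' @param theta True position in `[0, 1]` (0 = tobacco pole, 1 = health
#'   pole).
#' @param spec A `synthetic_spec`.
#' @param doc_id,group,role Metadata for the generated document.
#' @param poles Optional precomputed [build_pole_distributions()] result.
#' @return A one-row [ws_corpus].
#' @export
sample_document <- function(theta, spec, doc_id = "synth1",
                            group = "synthetic", role = "virgin",
                            poles = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.na(theta) || theta < 0 || theta > 1) {
    stop("`theta` must be in [0, 1]", call. = FALSE)
  }
  if (is.null(poles)) poles <- build_pole_distributions(spec)
  p <- theta * poles$p_health + (1 - theta) * poles$p_tobacco
  tokens <- sample(poles$vocab, spec$doc_length, replace = TRUE, prob = p)
  ws_corpus(doc_id, paste(tokens, collapse = " "), group = group,
            role = role,
            position = if (role == "reference") theta else NA_real_)
}

#' Generate a synthetic corpus with known true positions
#'
#' Produces `ref_counts["tobacco"]` reference documents at `theta = 0`,
#' `ref_counts["health"]` references at `theta = 1`, and one virgin
#' document per entry of `virgin_positions`.  The result is a valid input
#' for [build_frequency_matrix()] / [run_primary_analysis()] and can be
#' round-tripped through [write_corpus()] / [load_corpus()].  The truth
#' map `doc_id -> theta` is attached as attribute `"truth"`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [ws_corpus] with attributes `"truth"` (named numeric) and
#'   `"spec"`.
#' @examples
#' spec <- synthetic_spec(vocab_size = 40, doc_length = 200,
#'                        ref_counts = c(2, 2),
#'                        virgin_positions = c(0.25, 0.75), seed = 1)
#' corp <- generate_corpus(spec)
#' attr(corp, "truth")
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  poles <- build_pole_distributions(spec)
  n_t <- spec$ref_counts[["tobacco"]]
  n_h <- spec$ref_counts[["health"]]
  docs <- list()
  truth <- numeric()
  if (n_t > 0L) {
    for (i in seq_len(n_t)) {
      id <- sprintf("T%02d", i)
      docs[[id]] <- sample_document(0, spec, doc_id = id, group = "tobacco",
                                    role = "reference", poles = poles)
      truth[id] <- 0
    }
  }
  if (n_h > 0L) {
    for (i in seq_len(n_h)) {
      id <- sprintf("H%02d", i)
      docs[[id]] <- sample_document(1, spec, doc_id = id, group = "health",
                                    role = "reference", poles = poles)
      truth[id] <- 1
    }
  }
  for (i in seq_along(spec$virgin_positions)) {
    id <- sprintf("V%02d", i)
    docs[[id]] <- sample_document(spec$virgin_positions[i], spec,
                                  doc_id = id, group = "synthetic",
                                  role = "virgin", poles = poles)
    truth[id] <- spec$virgin_positions[i]
  }
  out <- do.call(rbind, docs)
  rownames(out) <- NULL
  class(out) <- c("ws_corpus", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}
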