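#' Build the document-term frequency matrix
#'
#' Runs every document through cleaning ([clean_text()]) and
#' tokenisation/stemming ([tokenize_and_stem()]) and tabulates word-root
#' counts.  The vocabulary is the union of all roots in deterministic
#' lexicographic order.  Relative frequencies are per-document:
#' `rel_freq[d, w] = counts[d, w] / total_tokens(d)`, so every row sums
#' to 1.
#'
#' @param corpus A [ws_corpus].
#' @param cfg A [cleaning_config()].
#' @return An object of class `freq_matrix`: a list with `doc_ids`,
#'   `word_roots`, integer matrix `counts` (documents x roots), numeric
#'   matrix `rel_freq`, per-document `total_tokens`, and the document
#'   metadata (`group`, `role`, `position`).
#' @examples
#' corp <- ws_corpus(c("D1", "D2"), c("tobacco tax rises", "tobacco ads"),
#'                   role = "virgin")
#' fm <- build_frequency_matrix(corp, cleaning_config(stopwords = "none"))
#' fm$counts
#' @export
build_frequency_matrix <- function(corpus, cfg = cleaning_config()) {
  stopifnot(inherits(corpus, "ws_corpus"))
  if (nrow(corpus) < 1L) stop("corpus is empty", call. = FALSE)
  cleaned <- clean_text(corpus, cfg)
  surface <- .tokenize_surface(cleaned$text, cfg)
  # stem the corpus-wide unique token set once
  usurf <- unique(unlist(surface, use.names = FALSE))
  ustem <- stem_words(usurf)
  toks <- lapply(surface, function(tk) ustem[match(tk, usurf)])
  empty <- lengths(toks) == 0L
  if (any(empty)) {
    stop("no surviving tokens in document(s): ",
         paste(corpus$doc_id[empty], collapse = ", "), call. = FALSE)
  }
  vocab <- sort(unique(unlist(toks, use.names = FALSE)), method = "radix")
  counts <- matrix(0L, nrow = nrow(corpus), ncol = length(vocab),
                   dimnames = list(corpus$doc_id, vocab))
  for (i in seq_along(toks)) {
    counts[i, ] <- tabulate(
      factor(toks[[i]], levels = vocab),
      nbins = length(vocab)
    )
  }
  total <- rowSums(counts)
  structure(
    list(
      doc_ids = corpus$doc_id,
      word_roots = vocab,
      counts = counts,
      rel_freq = counts / total,
      total_tokens = stats::setNames(as.integer(total), corpus$doc_id),
      group = stats::setNames(corpus$group, corpus$doc_id),
      role = stats::setNames(corpus$role, corpus$doc_id),
      position = stats::setNames(corpus$position, corpus$doc_id)
    ),
    class = "freq_matrix"
  )
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix: %d documents x %d word roots, %d tokens>\n",
              length(x$doc_ids), length(x$word_roots),
              sum(x$total_tokens)))
  invisible(x)
}

#' Group-average percentage frequency of a word root
#'
#' Unweighted mean over the given documents of the per-document percentage
#' frequency (100 x relative frequency) of one word root, reported rounded
#' to 2 decimals.  A root absent from the vocabulary counts as 0 in every
#' document.
#'
#' The data-frame method averages already-computed percentage columns
#' (documents in rows, word roots in columns), as used for published
#' frequency tables such as [tpd_frequency_table()].
#'
#' @param x A `freq_matrix`, or a data frame of percentage frequencies
#'   with document ids as row names.
#' @param doc_ids Documents to average over (non-empty).
#' @param word_root The word root.
#' @return A single numeric percentage, rounded to 2 decimals.
#' @export
group_average_frequency <- function(x, doc_ids, word_root) {
  UseMethod("group_average_frequency")
}

# published frequency tables round half-way cases away from zero (the
# convention of the usual stats packages), not half-to-even like round();
# the 1e-9 guard absorbs binary representation error in e.g. 0.825
.round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

.check_group_ids <- function(doc_ids, have) {
  if (length(doc_ids) == 0L) stop("`doc_ids` must be non-empty", call. = FALSE)
  bad <- setdiff(doc_ids, have)
  if (length(bad)) {
    stop("unknown doc_id: ", paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' @export
group_average_frequency.freq_matrix <- function(x, doc_ids, word_root) {
  .check_group_ids(doc_ids, x$doc_ids)
  pct <- if (word_root %in% x$word_roots) {
    100 * x$rel_freq[doc_ids, word_root]
  } else {
    rep(0, length(doc_ids))
  }
  .round_half_up(mean(pct))
}

#' @export
group_average_frequency.data.frame <- function(x, doc_ids, word_root) {
  .check_group_ids(doc_ids, rownames(x))
  pct <- if (word_root %in% colnames(x)) {
    as.numeric(x[doc_ids, word_root])
  } else {
    rep(0, length(doc_ids))
  }
  .round_half_up(mean(pct))
}

#' Most frequent word roots in a corpus
#'
#' The `k` roots with the highest total count pooled over all documents,
#' in descending count order; ties are broken lexicographically.
#'
#' @param fm A `freq_matrix`.
#' @param k Number of roots to return (`0 < k <=` vocabulary size).
#' @return Character vector of `k` word roots.
#' @export
top_k_words <- function(fm, k) {
  stopifnot(inherits(fm, "freq_matrix"))
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("`k` must be a positive integer", call. = FALSE)
  if (k > length(fm$word_roots)) {
    stop("`k` exceeds the vocabulary size (", length(fm$word_roots), ")",
         call. = FALSE)
  }
  pooled <- colSums(fm$counts)
  ord <- order(-pooled, fm$word_roots, method = "radix")
  fm$word_roots[ord][seq_len(k)]
}

#' Write a frequency matrix to TSV files
#'
#' Serialises counts and percentage frequencies as two TSV files
#' (`<basename>_counts.tsv`, `<basename>_percent.tsv`), documents in rows
#' and word roots in lexicographic column order.  Percentages are written
#' at full precision.
#'
#' @param fm A `freq_matrix`.
#' @param dir Output directory (created if needed).
#' @param basename File basename, default `"freq_matrix"`.
#' @return Invisibly, the two file paths.
#' @export
write_frequency_matrix <- function(fm, dir, basename = "freq_matrix") {
  stopifnot(inherits(fm, "freq_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(basename, c("_counts.tsv", "_percent.tsv")))
  cnt <- data.frame(doc_id = fm$doc_ids, fm$counts, check.names = FALSE)
  utils::write.table(cnt, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pct <- data.frame(doc_id = fm$doc_ids, 100 * fm$rel_freq,
                    check.names = FALSE)
  utils::write.table(pct, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Published word-frequency percentages for the EU tobacco-directive corpus
#'
#' Per-document percentage frequencies of the 15 most common word roots in
#' a published analysis of stakeholder submissions on the EU Tobacco
#' Products Directive revision: 3 EU legislative drafts, 5 health-NGO
#' documents, 8 tobacco-industry documents and 7 other-stakeholder
#' documents.  Shipped as a plain-text TSV; useful as a worked example for
#' [group_average_frequency()].
#'
#' @return A list with `percent` (23 x 15 data frame, document ids as row
#'   names) and `groups` (named character vector: `"eu"`, `"health"`,
#'   `"tobacco"` or `"other"` per document).
#' @examples
#' tab <- tpd_frequency_table()
#' health_ids <- names(tab$groups)[tab$groups == "health"]
#' group_average_frequency(tab$percent, health_ids, "health")
#' @export
tpd_frequency_table <- function() {
  path <- system.file("extdata", "tpd_word_freq.tsv", package = "wordscaling",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  groups <- stats::setNames(raw$group, raw$doc_id)
  pct <- raw[, setdiff(names(raw), c("doc_id", "group")), drop = FALSE]
  rownames(pct) <- raw$doc_id
  list(percent = pct, groups = groups)
}
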