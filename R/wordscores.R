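#' Reference position assignment
#'
#' Maps reference document ids to their analyst-assigned positions on the
#' scaling metric (conventionally 0 for one pole, 1 for the other, but any
#' real values are allowed, including the continuous positions used by the
#' two-stage robustness procedure).  At least two documents with at least
#' two distinct positions are required, otherwise the scale is degenerate.
#'
#' @param positions Named numeric vector, `doc_id -> position`.
#' @return A named numeric vector of class `reference_assignment`.
#' @examples
#' reference_assignment(c(PMI1 = 0, PMI2 = 0, EPHA1 = 1, EPHA2 = 1))
#' @export
reference_assignment <- function(positions) {
  if (!is.numeric(positions) || is.null(names(positions)) ||
      any(!nzchar(names(positions)))) {
    stop("`positions` must be a named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(positions))) {
    stop("duplicate reference doc_id", call. = FALSE)
  }
  if (anyNA(positions)) stop("reference positions must not be NA", call. = FALSE)
  if (length(positions) < 2L) {
    stop("at least two reference documents are required", call. = FALSE)
  }
  if (length(unique(positions)) < 2L) {
    stop("reference positions must take at least two distinct values",
         call. = FALSE)
  }
  structure(positions, class = "reference_assignment")
}

#' Estimate word scores from reference texts
#'
#' For each word root `w` present in at least one reference text, computes
#' the conditional probability of reading reference `r` given word `w`,
#' `P(r | w) = F_wr / sum_r' F_wr'` (with `F_wr` the relative frequency of
#' `w` in `r`), and the word score as the weighted average of the assigned
#' reference positions, `S_w = sum_r P(r | w) * A_r`.  Roots absent from
#' all references receive no score.  Because `P(r | w)` is built from
#' relative frequencies, references are weighted equally regardless of
#' length; no smoothing is applied, so zero frequencies are genuine zeros.
#'
#' @param fm A [build_frequency_matrix()] result containing all reference
#'   documents.
#' @param ra A [reference_assignment()].
#' @return An object of class `word_scores`: list with `scores` (named
#'   numeric, `word_root -> S_w`), `n_refs_containing` (named integer) and
#'   `positions` (the assignment used).
#' @export
compute_word_scores <- function(fm, ra) {
  stopifnot(inherits(fm, "freq_matrix"))
  ra <- reference_assignment(unclass(ra))
  missing <- setdiff(names(ra), fm$doc_ids)
  if (length(missing)) {
    stop("reference document(s) not in frequency matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  f <- fm$rel_freq[names(ra), , drop = FALSE]
  colsum <- colSums(f)
  present <- colsum > 0
  f <- f[, present, drop = FALSE]
  p_r_given_w <- sweep(f, 2L, colsum[present], "/")
  scores <- as.numeric(crossprod(p_r_given_w, as.numeric(ra)))
  names(scores) <- colnames(f)
  structure(
    list(
      scores = scores,
      n_refs_containing = stats::setNames(
        as.integer(colSums(f > 0)), colnames(f)
      ),
      positions = ra
    ),
    class = "word_scores"
  )
}

#' @export
print.word_scores <- function(x, ...) {
  cat(sprintf("<word_scores: %d scored word roots from %d references, range [%.4g, %.4g]>\n",
              length(x$scores), length(x$positions),
              min(x$scores), max(x$scores)))
  invisible(x)
}

.scored_profile <- function(fm, wst, doc_id) {
  if (!doc_id %in% fm$doc_ids) {
    stop("unknown doc_id: ", doc_id, call. = FALSE)
  }
  scored_roots <- names(wst$scores)[
    names(wst$scores) %in% fm$word_roots[fm$counts[doc_id, ] > 0L]
  ]
  if (length(scored_roots) == 0L) {
    stop("document has no scored tokens: ", doc_id, call. = FALSE)
  }
  f <- fm$rel_freq[doc_id, scored_roots]
  list(
    roots = scored_roots,
    fstar = f / sum(f),  # renormalised over scored roots only
    s = wst$scores[scored_roots],
    n_scored = sum(fm$counts[doc_id, scored_roots]),
    n_unique = length(scored_roots)
  )
}

#' Raw Wordscores position of one document
#'
#' Scores a document as the weighted average of its scored word roots,
#' `omega = sum_w F*_wv * S_w`, where `F*_wv` is the document's relative
#' frequency renormalised over scored roots only.  Tokens whose root is
#' absent from every reference are excluded from both numerator and
#' denominator and do not count towards `n_scored_tokens`.
#'
#' @param fm A `freq_matrix` containing the document.
#' @param wst A [compute_word_scores()] result.
#' @param doc_id The document to score.
#' @return A list of class `doc_score` with `doc_id`, `omega_raw`,
#'   `n_scored_tokens` (token occurrences with a scored root) and
#'   `n_unique_scored` (distinct scored roots).
#' @export
score_document <- function(fm, wst, doc_id) {
  stopifnot(inherits(fm, "freq_matrix"), inherits(wst, "word_scores"))
  pr <- .scored_profile(fm, wst, doc_id)
  structure(
    list(
      doc_id = doc_id,
      omega_raw = as.numeric(sum(pr$fstar * pr$s)),
      n_scored_tokens = as.integer(pr$n_scored),
      n_unique_scored = as.integer(pr$n_unique)
    ),
    class = "doc_score"
  )
}

#' Standard error and confidence interval of a document score
#'
#' The score variance over scored tokens is
#' `V = sum_w F*_wv (S_w - omega)^2`; with `N` scored token occurrences
#' the standard error is `sqrt(V / N)` and the confidence interval the
#' normal-approximation `omega +/- z * se`.
#'
#' @param fm A `freq_matrix`.
#' @param wst A `word_scores` table.
#' @param doc_id Document id.
#' @param omega The document's raw score (from [score_document()]); if
#'   `NULL`, recomputed.
#' @param z Normal quantile for the interval; 1.96 gives a 95% CI.
#' @return Named list with `se`, `ci_low`, `ci_high`.
#' @export
score_uncertainty <- function(fm, wst, doc_id, omega = NULL, z = 1.96) {
  stopifnot(inherits(fm, "freq_matrix"), inherits(wst, "word_scores"))
  pr <- .scored_profile(fm, wst, doc_id)
  if (is.null(omega)) omega <- as.numeric(sum(pr$fstar * pr$s))
  v <- sum(pr$fstar * (pr$s - omega)^2)
  se <- sqrt(v / pr$n_scored)
  list(se = se, ci_low = omega - z * se, ci_high = omega + z * se)
}

#' Score a set of documents against reference texts
#'
#' Batch driver: estimates word scores from the reference assignment, then
#' scores each requested document (which may include the references
#' themselves, re-scored "as virgin" — required for fitting rescaling
#' anchors) with standard errors and confidence intervals.
#'
#' @param fm A `freq_matrix` containing references and virgins.
#' @param ra A [reference_assignment()].
#' @param virgin_ids Documents to score, in output order.  May be empty.
#' @param z Normal quantile for the confidence intervals.
#' @return A data frame of class `doc_scores` with columns `doc_id`,
#'   `n_unique`, `n_scored`, `omega_raw`, `se`, `ci_low`, `ci_high`, and
#'   the `word_scores` object as attribute `"word_scores"`.
#' @export
score_corpus <- function(fm, ra, virgin_ids, z = 1.96) {
  stopifnot(inherits(fm, "freq_matrix"))
  bad <- setdiff(virgin_ids, fm$doc_ids)
  if (length(bad)) {
    stop("virgin_ids not in frequency matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  wst <- compute_word_scores(fm, ra)
  rows <- lapply(virgin_ids, function(id) {
    ds <- score_document(fm, wst, id)
    un <- score_uncertainty(fm, wst, id, omega = ds$omega_raw, z = z)
    data.frame(
      doc_id = id,
      n_unique = ds$n_unique_scored,
      n_scored = ds$n_scored_tokens,
      omega_raw = ds$omega_raw,
      se = un$se,
      ci_low = un$ci_low,
      ci_high = un$ci_high,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      doc_id = character(), n_unique = integer(), n_scored = integer(),
      omega_raw = numeric(), se = numeric(), ci_low = numeric(),
      ci_high = numeric(), stringsAsFactors = FALSE
    )
  }
  attr(out, "word_scores") <- wst
  class(out) <- c("doc_scores", "data.frame")
  out
}

#' Write a document score table as TSV
#'
#' Columns mirror the standard published layout: `doc_id`, `n_unique`,
#' `n_scored`, `omega_raw`, `se`, `ci_low`, `ci_high`, plus any rescaled
#' columns present.  Full precision is retained.
#'
#' @param scores A `doc_scores` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
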