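#' Study configuration for a full scaling analysis
#'
#' Collects everything [run_primary_analysis()] needs: the corpus (or a
#' manifest path plus text directory), the cleaning configuration, how
#' reference groups map to pole positions, which documents to score, the
#' rescaling method and anchor policy, and the CI quantile.
#'
#' @param corpus A [ws_corpus], or `NULL` if `manifest` is given.
#' @param manifest,text_dir Paths handed to [load_corpus()] when `corpus`
#'   is `NULL`.
#' @param cleaning A [cleaning_config()], or a path readable by
#'   [read_cleaning_config()].
#' @param reference_coding Named numeric vector mapping group labels of
#'   reference-role documents to pole positions; the default codes
#'   tobacco-industry texts 0 and health-NGO texts 1.  A document's
#'   explicit manifest `position` takes precedence when present.
#' @param virgin_ids Documents to score; default all `role == "virgin"`
#'   documents, in corpus order.
#' @param rescale_method `"MV"` (Martin-Vanberg) or `"LBG"` (mean/spread).
#' @param anchor_policy Anchor pool for MV; see [fit_anchors()].
#' @param z Normal quantile for confidence intervals (1.96 = 95%).
#' @param outdir Optional report output directory for [build_report()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(corpus = NULL, manifest = NULL, text_dir = NULL,
                         cleaning = cleaning_config(),
                         reference_coding = c(health = 1, tobacco = 0),
                         virgin_ids = NULL,
                         rescale_method = c("MV", "LBG"),
                         anchor_policy = c("rescored_refs", "all_scored"),
                         z = 1.96, outdir = NULL) {
  if (is.null(corpus) && is.null(manifest)) {
    stop("supply `corpus`, or `manifest` + `text_dir`", call. = FALSE)
  }
  if (is.character(cleaning)) cleaning <- read_cleaning_config(cleaning)
  stopifnot(inherits(cleaning, "cleaning_config"))
  if (length(unique(reference_coding)) < 2L) {
    stop("`reference_coding` must contain at least two distinct positions",
         call. = FALSE)
  }
  structure(
    list(
      corpus = corpus, manifest = manifest, text_dir = text_dir,
      cleaning = cleaning, reference_coding = reference_coding,
      virgin_ids = virgin_ids,
      rescale_method = match.arg(rescale_method),
      anchor_policy = match.arg(anchor_policy),
      z = z, outdir = outdir
    ),
    class = "study_config"
  )
}

.cfg_corpus <- function(cfg) {
  if (!is.null(cfg$corpus)) return(cfg$corpus)
  load_corpus(cfg$manifest, cfg$text_dir)
}

# assigned position of each reference-role document: explicit manifest
# position when present, otherwise the group coding
.reference_positions <- function(corpus, reference_coding) {
  refs <- corpus[corpus$role == "reference", , drop = FALSE]
  if (nrow(refs) == 0L) stop("corpus has no reference documents", call. = FALSE)
  pos <- refs$position
  needs <- is.na(pos)
  if (any(needs)) {
    coded <- reference_coding[refs$group[needs]]
    if (anyNA(coded)) {
      stop("no position or group coding for reference document(s): ",
           paste(refs$doc_id[needs][is.na(coded)], collapse = ", "),
           call. = FALSE)
    }
    pos[needs] <- coded
  }
  reference_assignment(stats::setNames(pos, refs$doc_id))
}

.rescale_scores <- function(scores, ra, cfg, fm) {
  if (cfg$rescale_method == "MV") {
    spec <- fit_anchors(scores, ref_ids = names(ra),
                        policy = cfg$anchor_policy)
    mv_transform(scores, spec)
  } else {
    virgin <- setdiff(scores$doc_id, names(ra))
    rescaled <- lbg_transform(
      scores[scores$doc_id %in% virgin, , drop = FALSE], ra
    )
    merged <- merge(as.data.frame(scores),
                    rescaled[, c("doc_id", "omega_lbg", "ci_low_lbg",
                                 "ci_high_lbg", "method")],
                    by = "doc_id", all.x = TRUE, sort = FALSE)
    merged <- merged[match(scores$doc_id, merged$doc_id), , drop = FALSE]
    class(merged) <- class(scores)
    merged
  }
}

#' Run the primary position-estimation analysis
#'
#' Executes the full chain: corpus loading, cleaning/tokenisation,
#' frequency matrix construction, word-score estimation from the
#' references, scoring of every reference (re-scored as virgin, for the
#' rescaling anchors) and every virgin document with standard errors, and
#' rescaling.  The returned object logs the anchors, vocabulary size and
#' configuration for reproducibility.
#'
#' @param cfg A [study_config()].
#' @return A list of class `ws_analysis`: `fm` (the `freq_matrix`),
#'   `word_scores`, `ra` (the reference assignment used), `scores` (a
#'   `doc_scores` data frame covering references then virgins, with
#'   rescaled columns), and `log` (anchors, vocabulary size, scored-doc
#'   counts).
#' @export
run_primary_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  corpus <- .cfg_corpus(cfg)
  fm <- build_frequency_matrix(corpus, cfg$cleaning)
  ra <- .reference_positions(corpus, cfg$reference_coding)
  virgin_ids <- cfg$virgin_ids %||% corpus$doc_id[corpus$role == "virgin"]
  scores <- score_corpus(fm, ra, c(names(ra), virgin_ids), z = cfg$z)
  scores <- .rescale_scores(scores, ra, cfg, fm)
  structure(
    list(
      fm = fm, word_scores = attr(scores, "word_scores"), ra = ra,
      scores = scores,
      log = list(
        vocab_size = length(fm$word_roots),
        n_references = length(ra),
        n_virgins = length(virgin_ids),
        rescale_method = cfg$rescale_method,
        anchor_policy = cfg$anchor_policy,
        anchors = attr(scores, "transform_spec")
      )
    ),
    class = "ws_analysis"
  )
}

#' @export
print.ws_analysis <- function(x, ...) {
  cat(sprintf(
    "<ws_analysis: %d refs, %d virgins, vocabulary %d, rescale %s>\n",
    x$log$n_references, x$log$n_virgins, x$log$vocab_size,
    x$log$rescale_method
  ))
  print.data.frame(
    within(as.data.frame(x$scores), {
      omega_raw <- round(omega_raw, 4L)
      se <- signif(se, 3L)
    })[, c("doc_id", "n_unique", "n_scored", "omega_raw", "se")],
    row.names = FALSE
  )
  invisible(x)
}

#' Two-stage robustness re-estimation
#'
#' Stage 1 uses only `stage1_ref_ids` (at their assigned pole positions)
#' as references and estimates raw positions for the remaining
#' reference-role documents as virgins.  Stage 2 re-runs Wordscores with
#' ALL reference-role documents as references — the stage-1 references at
#' their assigned positions and the stage-1 virgins at their estimated
#' raw positions (a continuous reference assignment) — and then scores the
#' usual virgin set.  When the stage-1 virgins are estimated exactly at
#' the pole values (disjoint vocabularies) this collapses to the primary
#' analysis.
#'
#' @param cfg A [study_config()].
#' @param stage1_ref_ids Ids of the stage-1 reference documents (a subset
#'   of the corpus's reference-role documents).
#' @return A `ws_analysis` list as in [run_primary_analysis()], with an
#'   extra `stage1` element (the stage-1 `doc_scores`).
#' @export
run_two_stage_robustness <- function(cfg, stage1_ref_ids) {
  stopifnot(inherits(cfg, "study_config"))
  corpus <- .cfg_corpus(cfg)
  missing <- setdiff(stage1_ref_ids, corpus$doc_id)
  if (length(missing)) {
    stop("stage 1: stage1_ref_ids not in corpus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fm <- build_frequency_matrix(corpus, cfg$cleaning)
  ra_full <- .reference_positions(corpus, cfg$reference_coding)
  if (!all(stage1_ref_ids %in% names(ra_full))) {
    stop("stage 1: stage1_ref_ids must be reference-role documents",
         call. = FALSE)
  }
  stage1_virgins <- setdiff(names(ra_full), stage1_ref_ids)
  ra1 <- reference_assignment(ra_full[stage1_ref_ids])
  stage1 <- score_corpus(fm, ra1, stage1_virgins, z = cfg$z)

  # stage-2 references: assigned positions for stage-1 refs, estimated raw
  # positions (continuous) for stage-1 virgins
  ra2 <- reference_assignment(c(
    ra_full[stage1_ref_ids],
    stats::setNames(stage1$omega_raw, stage1$doc_id)
  ))
  virgin_ids <- cfg$virgin_ids %||% corpus$doc_id[corpus$role == "virgin"]
  scores <- score_corpus(fm, ra2, c(names(ra2), virgin_ids), z = cfg$z)
  scores <- .rescale_scores(scores, ra2, cfg, fm)
  structure(
    list(
      fm = fm, word_scores = attr(scores, "word_scores"), ra = ra2,
      scores = scores, stage1 = stage1,
      log = list(
        vocab_size = length(fm$word_roots),
        n_references = length(ra2),
        n_virgins = length(virgin_ids),
        rescale_method = cfg$rescale_method,
        anchor_policy = cfg$anchor_policy,
        anchors = attr(scores, "transform_spec"),
        stage1_ref_ids = stage1_ref_ids
      )
    ),
    class = "ws_analysis"
  )
}

#' Compare positions along an ordered document sequence
#'
#' For a sequence of scored documents (e.g. successive legislative
#' drafts), flags each adjacent pair — and the endpoint pair — as
#' significantly different when their confidence intervals do not overlap
#' (intervals touching at a single point count as overlapping).  The
#' overall direction is taken from the sign of the endpoint difference:
#' towards pole 0, towards pole 1, or mixed when the endpoints tie.
#'
#' @param scores A `doc_scores` data frame with rescaled columns
#'   (`omega_mv`, `ci_low_mv`, `ci_high_mv`; raw columns are used if no
#'   rescaled ones are present).
#' @param ordered_ids At least two document ids, in sequence order.
#' @return A list of class `trend_result`: `doc_ids`, `omega`, `ci_low`,
#'   `ci_high`, `pairs` (data frame `from`, `to`, `significant`),
#'   `direction`.
#' @export
compare_trend <- function(scores, ordered_ids) {
  if (length(ordered_ids) < 2L) {
    stop("at least two document ids are required", call. = FALSE)
  }
  missing <- setdiff(ordered_ids, scores$doc_id)
  if (length(missing)) {
    stop("documents not scored: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- if ("omega_mv" %in% names(scores)) {
    c("omega_mv", "ci_low_mv", "ci_high_mv")
  } else if ("omega_lbg" %in% names(scores)) {
    c("omega_lbg", "ci_low_lbg", "ci_high_lbg")
  } else {
    c("omega_raw", "ci_low", "ci_high")
  }
  idx <- match(ordered_ids, scores$doc_id)
  omega <- scores[[cols[1L]]][idx]
  lo <- scores[[cols[2L]]][idx]
  hi <- scores[[cols[3L]]][idx]
  n <- length(ordered_ids)
  pair_idx <- cbind(seq_len(n - 1L), 2:n)
  if (n > 2L) pair_idx <- rbind(pair_idx, c(1L, n))
  pairs <- data.frame(
    from = ordered_ids[pair_idx[, 1L]],
    to = ordered_ids[pair_idx[, 2L]],
    significant = hi[pair_idx[, 1L]] < lo[pair_idx[, 2L]] |
      hi[pair_idx[, 2L]] < lo[pair_idx[, 1L]],
    stringsAsFactors = FALSE
  )
  delta <- omega[n] - omega[1L]
  direction <- if (delta < 0) "toward_0" else if (delta > 0) "toward_1" else "mixed"
  structure(
    list(doc_ids = ordered_ids, omega = omega, ci_low = lo, ci_high = hi,
         pairs = pairs, direction = direction, scale = cols[1L]),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result (%s): %s, direction %s>\n", x$scale,
              paste(sprintf("%s=%.3f", x$doc_ids, x$omega), collapse = " -> "),
              x$direction))
  print.data.frame(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Write the standard study report files
#'
#' Emits three deterministic TSV files: (a) `frequency_top.tsv`, the
#' percentage frequencies of the `k` most common word roots with a
#' per-group `Average` row appended under each group (2-decimal
#' rounding, matching [group_average_frequency()]); (b) `scores.tsv`, the
#' score table ordered from lowest to highest raw word score; and (c)
#' `trend.tsv`, the trend sequence with pairwise significance flags
#' (when a trend is supplied).
#'
#' @param fm A `freq_matrix`.
#' @param scores A `doc_scores` data frame.
#' @param trend Optional `trend_result`.
#' @param dir Output directory (created if needed).
#' @param k Number of top word roots in the frequency report.
#' @return Invisibly, a character vector of the files written.
#' @export
build_report <- function(fm, scores, trend = NULL, dir, k = 15L) {
  stopifnot(inherits(fm, "freq_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- min(as.integer(k), length(fm$word_roots))
  top <- top_k_words(fm, k)
  pct <- round(100 * fm$rel_freq[, top, drop = FALSE], 2L)
  rows <- list()
  for (g in unique(unname(fm$group))) {
    ids <- fm$doc_ids[fm$group[fm$doc_ids] == g]
    block <- data.frame(doc_id = ids, group = g, pct[ids, , drop = FALSE],
                        check.names = FALSE, stringsAsFactors = FALSE)
    avg <- vapply(top, function(w) group_average_frequency(fm, ids, w),
                  numeric(1L))
    block <- rbind(block, data.frame(doc_id = "Average", group = g,
                                     as.list(avg), check.names = FALSE))
    rows[[g]] <- block
  }
  freq_path <- file.path(dir, "frequency_top.tsv")
  utils::write.table(do.call(rbind, rows), freq_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  score_path <- file.path(dir, "scores.tsv")
  ordered <- as.data.frame(scores)[order(scores$omega_raw), , drop = FALSE]
  utils::write.table(ordered, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  written <- c(freq_path, score_path)
  if (!is.null(trend)) {
    trend_path <- file.path(dir, "trend.tsv")
    tr <- data.frame(doc_id = trend$doc_ids, omega = trend$omega,
                     ci_low = trend$ci_low, ci_high = trend$ci_high,
                     stringsAsFactors = FALSE)
    utils::write.table(tr, trend_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(trend$pairs, file.path(dir, "trend_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, trend_path, file.path(dir, "trend_pairs.tsv"))
  }
  invisible(written)
}
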