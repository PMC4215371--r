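#' Fit Martin-Vanberg rescaling anchors
#'
#' The Martin-Vanberg transformation maps raw virgin scores back onto the
#' reference metric using the most extreme raw scores observed in an
#' anchor pool.  Under the canonical policy (`"rescored_refs"`) the pool
#' is the reference documents re-scored as virgins; under `"all_scored"`
#' it is every scored document.
#'
#' @param scores A `doc_scores` data frame from [score_corpus()].
#' @param ref_ids Reference document ids (used by the `"rescored_refs"`
#'   policy; they must be present in `scores`).
#' @param policy Anchor pool: `"rescored_refs"` (default) or
#'   `"all_scored"`.
#' @return A `transform_spec` list: `method = "MV"`, `omega1` (pool
#'   minimum), `omega2` (pool maximum), `anchor_policy`.
#' @export
fit_anchors <- function(scores, ref_ids = NULL,
                        policy = c("rescored_refs", "all_scored")) {
  policy <- match.arg(policy)
  pool <- if (policy == "rescored_refs") {
    if (is.null(ref_ids) || length(ref_ids) == 0L) {
      stop('policy "rescored_refs" needs `ref_ids`', call. = FALSE)
    }
    missing <- setdiff(ref_ids, scores$doc_id)
    if (length(missing)) {
      stop("anchor documents not scored: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    scores$omega_raw[scores$doc_id %in% ref_ids]
  } else {
    scores$omega_raw
  }
  omega1 <- min(pool)
  omega2 <- max(pool)
  if (!(omega1 < omega2)) {
    stop("degenerate anchor pool: all raw scores equal", call. = FALSE)
  }
  structure(
    list(method = "MV", omega1 = omega1, omega2 = omega2,
         anchor_policy = policy),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec: %s, anchors (%.6g, %.6g), policy %s>\n",
              x$method, x$omega1, x$omega2, x$anchor_policy))
  invisible(x)
}

#' Martin-Vanberg transformation of raw document scores
#'
#' Applies the affine map `omega_mv = (omega_raw - omega1) / (omega2 -
#' omega1)`, pinning the anchor documents to exactly 0 and 1.  Confidence
#' interval endpoints are transformed by the same map, so interval widths
#' scale by `1 / (omega2 - omega1)`.  Scores outside `[0, 1]` (documents
#' more extreme than the anchors) are reported as-is, never clipped.
#'
#' @param scores A `doc_scores` data frame (or a single `doc_score`-like
#'   list with `omega_raw`, `ci_low`, `ci_high`).
#' @param spec A `transform_spec` from [fit_anchors()].
#' @return `scores` with added columns `omega_mv`, `ci_low_mv`,
#'   `ci_high_mv`, `method`; the spec is attached as attribute
#'   `"transform_spec"`.
#' @export
mv_transform <- function(scores, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  tr <- function(x) (x - spec$omega1) / (spec$omega2 - spec$omega1)
  if (is.data.frame(scores)) {
    scores$omega_mv <- tr(scores$omega_raw)
    scores$ci_low_mv <- tr(scores$ci_low)
    scores$ci_high_mv <- tr(scores$ci_high)
    scores$method <- spec$method
    attr(scores, "transform_spec") <- spec
    scores
  } else {
    list(
      doc_id = scores$doc_id,
      omega_mv = tr(scores$omega_raw),
      ci_low_mv = tr(scores$ci_low %||% NA_real_),
      ci_high_mv = tr(scores$ci_high %||% NA_real_),
      spec = spec
    )
  }
}

#' Classic mean/spread rescaling of virgin scores
#'
#' The alternative transformation used for robustness checks: each virgin
#' raw score is shifted and stretched so the virgin set's spread matches
#' the reference metric,
#' `omega* = (omega_v - mean_v) * (sd_ref / sd_v) + mean_v`,
#' with `mean_v`, `sd_v` over the virgin raw scores and `sd_ref` over the
#' assigned reference positions.  Confidence intervals scale by the same
#' factor.
#'
#' @param scores A `doc_scores` data frame of at least two virgin scores.
#' @param ref_positions Assigned reference positions (a
#'   [reference_assignment()] or plain numeric vector).
#' @return `scores` with added columns `omega_lbg`, `ci_low_lbg`,
#'   `ci_high_lbg`, `method`.
#' @export
lbg_transform <- function(scores, ref_positions) {
  if (nrow(scores) < 2L) {
    stop("at least two virgin scores are required", call. = FALSE)
  }
  mean_v <- mean(scores$omega_raw)
  sd_v <- stats::sd(scores$omega_raw)
  if (sd_v == 0) {
    stop("virgin raw scores have zero spread; cannot rescale", call. = FALSE)
  }
  sd_ref <- stats::sd(as.numeric(ref_positions))
  k <- sd_ref / sd_v
  scores$omega_lbg <- (scores$omega_raw - mean_v) * k + mean_v
  scores$ci_low_lbg <- (scores$ci_low - mean_v) * k + mean_v
  scores$ci_high_lbg <- (scores$ci_high - mean_v) * k + mean_v
  scores$method <- "LBG"
  scores
}
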