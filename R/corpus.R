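#' Construct a corpus from documents in memory
#'
#' A corpus is a data frame with one row per document and columns
#' `doc_id`, `group`, `role`, `position` and `text`.  Reference documents
#' carry an analyst-assigned position (conventionally 0 for one pole and 1
#' for the other); virgin documents have `NA` position and are the ones to
#' be scored.
#'
#' @param doc_id Character vector of unique short document identifiers.
#' @param text Character vector of document texts (UTF-8).
#' @param group Group label per document: one of `"health"`, `"tobacco"`,
#'   `"other"`, `"eu"`, `"synthetic"`.
#' @param role `"reference"` or `"virgin"` per document.
#' @param position Numeric assigned position per document (`NA` for
#'   virgins).
#' @return A data frame of class `ws_corpus`.
#' @export
ws_corpus <- function(doc_id, text, group = "other", role = "virgin",
                      position = NA_real_) {
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  groups <- c("health", "tobacco", "other", "eu", "synthetic")
  group <- rep_len(as.character(group), length(doc_id))
  if (!all(group %in% groups)) {
    stop("`group` must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  role <- rep_len(as.character(role), length(doc_id))
  if (!all(role %in% c("reference", "virgin"))) {
    stop('`role` must be "reference" or "virgin"', call. = FALSE)
  }
  out <- data.frame(
    doc_id = doc_id,
    group = group,
    role = role,
    position = rep_len(as.numeric(position), length(doc_id)),
    text = as.character(text),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ws_corpus", "data.frame")
  out
}

.read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(manifest_path))
  man <- if (ext == "csv") {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  }
  needed <- c("doc_id", "group", "role", "filename")
  missing <- setdiff(needed, names(man))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(man$position)) man$position <- NA_real_
  man$position <- suppressWarnings(as.numeric(man$position))
  man
}

#' Load a corpus from a manifest and a directory of text files
#'
#' The manifest (TSV or CSV) lists one document per row with columns
#' `doc_id`, `group`, `role`, `position` (may be empty for virgins) and
#' `filename`.  Each file is read as UTF-8 plain text.  Row order is
#' preserved.
#'
#' @param manifest_path Path to the manifest file.
#' @param text_dir Directory containing the text files named in the
#'   manifest.
#' @return A [ws_corpus] data frame in manifest order.
#' @seealso [write_corpus()] for the inverse, used by the synthetic
#'   generator.
#' @export
load_corpus <- function(manifest_path, text_dir) {
  man <- .read_manifest(manifest_path)
  if (anyDuplicated(man$doc_id)) {
    stop("duplicate doc_id in manifest: ",
         paste(unique(man$doc_id[duplicated(man$doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  paths <- file.path(text_dir, man$filename)
  absent <- !file.exists(paths)
  if (any(absent)) {
    stop("text file missing for doc_id: ",
         paste(man$doc_id[absent], collapse = ", "), call. = FALSE)
  }
  texts <- vapply(paths, function(p) {
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1L), USE.NAMES = FALSE)
  ws_corpus(man$doc_id, texts, group = man$group, role = man$role,
            position = man$position)
}

#' Write a corpus as manifest + text files
#'
#' Emits the same layout [load_corpus()] consumes: one UTF-8 `.txt` file
#' per document plus a TSV manifest (`doc_id`, `group`, `role`, `position`,
#' `filename`).  If the corpus carries a ground-truth attribute (as
#' corpora from [generate_corpus()] do), a `truth.tsv` with columns
#' `doc_id`, `theta` is written alongside.
#'
#' @param corpus A [ws_corpus].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "ws_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- paste0(corpus$doc_id, ".txt")
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$text[i], file.path(dir, fn[i]), useBytes = TRUE)
  }
  man <- data.frame(
    doc_id = corpus$doc_id, group = corpus$group, role = corpus$role,
    position = corpus$position, filename = fn, stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- attr(corpus, "truth")
  if (!is.null(truth)) {
    utils::write.table(
      data.frame(doc_id = names(truth), theta = unname(truth)),
      file.path(dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(manifest_path)
}

#' @export
print.ws_corpus <- function(x, ...) {
  cat(sprintf("<ws_corpus: %d documents (%d reference, %d virgin)>\n",
              nrow(x), sum(x$role == "reference"), sum(x$role == "virgin")))
  show <- x[, c("doc_id", "group", "role", "position")]
  show$tokens_approx <- lengths(strsplit(x$text, "[[:space:]]+"))
  print.data.frame(utils::head(show, 20L), row.names = FALSE)
  if (nrow(x) > 20L) cat("... and", nrow(x) - 20L, "more\n")
  invisible(x)
}
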