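#' Cleaning and tokenisation configuration
#'
#' Bundles the text-preprocessing choices applied to every document before
#' frequency counting: literal stop-phrases to delete (organisation names,
#' headers, contact details), marker pairs delimiting passages to drop
#' wholesale (e.g. sections on a topic excluded from the analysis), the
#' stopword list, and the minimum token length.
#'
#' @param stop_phrases Character vector of literal phrases deleted wherever
#'   they occur.  Deletion is exact (fixed-string), so it never clips
#'   characters outside the phrase span.
#' @param excluded_topics List of length-2 character vectors
#'   `c(start_marker, end_marker)`.  Every passage from a start marker up to
#'   and including the next end marker is removed before any other cleaning.
#' @param stopwords Either a character vector of stopwords, or one of the
#'   named list identifiers `"english"` (the shipped Snowball list) or
#'   `"none"`.
#' @param min_token_length Minimum length (in characters) a token must have
#'   to be kept; at least 1.
#' @return An object of class `cleaning_config`.
#' @seealso [clean_text()], [tokenize_and_stem()], [build_frequency_matrix()]
#' @examples
#' cfg <- cleaning_config(stop_phrases = "Philip Morris International")
#' @export
cleaning_config <- function(stop_phrases = character(),
                            excluded_topics = list(),
                            stopwords = "english",
                            min_token_length = 1L) {
  if (is.character(stopwords) && length(stopwords) == 1L &&
      stopwords %in% c("english", "none")) {
    stopword_list_id <- stopwords
    stopwords <- if (stopwords == "english") english_stopwords() else character()
  } else {
    if (!is.character(stopwords)) {
      stop("`stopwords` must be a character vector or a list identifier",
           call. = FALSE)
    }
    stopword_list_id <- "custom"
  }
  if (length(excluded_topics) && !is.list(excluded_topics)) {
    excluded_topics <- list(excluded_topics)
  }
  for (et in excluded_topics) {
    if (!is.character(et) || length(et) != 2L) {
      stop("each `excluded_topics` entry must be c(start_marker, end_marker)",
           call. = FALSE)
    }
  }
  min_token_length <- as.integer(min_token_length)
  if (is.na(min_token_length) || min_token_length < 1L) {
    stop("`min_token_length` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      stop_phrases = as.character(stop_phrases),
      excluded_topics = excluded_topics,
      stopword_list_id = stopword_list_id,
      stopwords = stopwords,
      min_token_length = min_token_length
    ),
    class = "cleaning_config"
  )
}

#' Read a cleaning configuration from a YAML or JSON file
#'
#' The file may define any of the fields of [cleaning_config()];
#' `excluded_topics` entries are two-element arrays.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cleaning_config` object.
#' @export
read_cleaning_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  excl <- raw$excluded_topics %||% list()
  if (is.matrix(excl)) excl <- asplit(excl, 1L)
  if (is.character(excl)) excl <- list(excl)
  cleaning_config(
    stop_phrases = raw$stop_phrases %||% character(),
    excluded_topics = lapply(excl, as.character),
    stopwords = raw$stopwords %||% "english",
    min_token_length = raw$min_token_length %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.remove_topic_passages <- function(text, markers) {
  start <- markers[[1L]]; end <- markers[[2L]]
  repeat {
    i <- regexpr(start, text, fixed = TRUE)
    if (i < 0L) break
    rest <- substr(text, i + nchar(start), nchar(text))
    j <- regexpr(end, rest, fixed = TRUE)
    if (j < 0L) {
      stop("unmatched excluded-topic start marker: ", dQuote(start),
           call. = FALSE)
    }
    text <- paste0(
      substr(text, 1L, i - 1L),
      substr(rest, j + nchar(end), nchar(rest))
    )
  }
  text
}

#' Remove stop-phrases and excluded passages from document text
#'
#' Applies the manual-cleaning stage: passages between excluded-topic
#' markers are dropped, then every occurrence of each literal stop-phrase
#' is deleted.  All other text is left untouched.  A document whose text
#' becomes empty (no non-whitespace characters) is an error, since it can
#' no longer be scored.
#'
#' @param x A character vector of document texts (optionally named by
#'   document id), or a corpus data frame as returned by [load_corpus()].
#' @param cfg A [cleaning_config()].
#' @return Same shape as `x`, with cleaned text.
#' @examples
#' cfg <- cleaning_config(stop_phrases = "ACME Corp")
#' clean_text("ACME Corp supports the measure.", cfg)
#' @export
clean_text <- function(x, cfg) {
  UseMethod("clean_text")
}

#' @export
clean_text.character <- function(x, cfg) {
  stopifnot(inherits(cfg, "cleaning_config"))
  out <- x
  for (markers in cfg$excluded_topics) {
    out <- vapply(out, .remove_topic_passages, character(1L),
                  markers = markers, USE.NAMES = FALSE)
  }
  for (phrase in cfg$stop_phrases) {
    if (nzchar(phrase)) out <- gsub(phrase, "", out, fixed = TRUE)
  }
  empty <- !grepl("[^[:space:]]", out)
  if (any(empty)) {
    ids <- if (!is.null(names(x))) names(x)[empty] else which(empty)
    stop("cleaning emptied document(s): ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  names(out) <- names(x)
  out
}

#' @export
clean_text.ws_corpus <- function(x, cfg) {
  txt <- x$text
  names(txt) <- x$doc_id
  x$text <- unname(clean_text(txt, cfg))
  x
}

#' Tokenise a document and reduce tokens to word roots
#'
#' Lowercases the text, extracts maximal runs of alphabetic characters
#' (so numbers and symbols never yield tokens and hyphenated words split
#' at the hyphen), drops tokens shorter than the configured minimum length,
#' removes stopwords on their surface forms, and finally stems the
#' survivors with the built-in Porter2 stemmer.  Stopword removal happens
#' before stemming, so a non-stopword whose stem equals a stopword is kept.
#'
#' @param x A single document text (character scalar), or a character
#'   vector of texts (a list of token vectors is then returned).
#' @param cfg A [cleaning_config()].
#' @return Character vector of word-root tokens in text order (or a list of
#'   such vectors).  May be empty.
#' @examples
#' tokenize_and_stem("Tobacco products, 2010!", cleaning_config())
#' @export
tokenize_and_stem <- function(x, cfg = cleaning_config()) {
  stopifnot(is.character(x), inherits(cfg, "cleaning_config"))
  toks <- lapply(.tokenize_surface(x, cfg), function(tk) {
    if (length(tk) == 0L) character() else stem_words(tk)
  })
  if (length(x) == 1L) toks[[1L]] else toks
}

# surface-form tokenisation (everything tokenize_and_stem does except the
# final stemming); build_frequency_matrix uses it so the corpus-wide token
# set can be stemmed in one memoised pass
.tokenize_surface <- function(x, cfg) {
  lapply(x, function(text) {
    text <- tolower(text)
    m <- gregexpr("\\p{L}+", text, perl = TRUE)[[1L]]
    if (m[1L] < 0L) return(character())
    tk <- regmatches(text, list(m))[[1L]]
    if (cfg$min_token_length > 1L) {
      tk <- tk[nchar(tk) >= cfg$min_token_length]
    }
    tk[!(tk %in% cfg$stopwords)]
  })
}
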