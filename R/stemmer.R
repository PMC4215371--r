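# English (Porter2 / Snowball) stemmer, implemented from the published
# algorithm description.  Operates on single lowercase words; the vectorised
# entry point is stem_words().

.p2_vowel_set <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

# words handled outside the rules
.p2_exceptions <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)
.p2_exceptions_1a <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

.p2_ends <- function(w, s) {
  n <- nchar(w); m <- nchar(s)
  n >= m && substr(w, n - m + 1L, n) == s
}

.p2_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

.p2_is_vowel <- function(ch) ch %in% .p2_vowel_set  # "Y" is a consonant

# R1 = region after the first non-vowel following a vowel (with the standard
# gener-/commun-/arsen- prefix exceptions); R2 = same rule applied inside R1.
# Returned as start positions; position > nchar(w) means the region is empty.
.p2_regions <- function(chars, w) {
  n <- length(chars)
  vow <- chars %in% .p2_vowel_set
  r1 <- n + 1L
  for (pfx in c("gener", "commun", "arsen")) {
    if (startsWith(w, pfx)) { r1 <- nchar(pfx) + 1L; break }
  }
  if (r1 == n + 1L && n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (vow[i] && !vow[i + 1L]) { r1 <- i + 2L; break }
    }
  }
  r2 <- n + 1L
  if (r1 <= n - 1L) {
    for (i in r1:(n - 1L)) {
      if (vow[i] && !vow[i + 1L]) { r2 <- i + 2L; break }
    }
  }
  c(r1 = r1, r2 = r2)
}

# TRUE when w ends in a short syllable: either non-vowel + vowel + non-vowel
# (last not w/x/Y), or a word-initial vowel + non-vowel pair.
.p2_short_syllable_end <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  vow <- ch %in% .p2_vowel_set
  if (n == 2L) return(vow[1L] && !vow[2L])
  !vow[n - 2L] && vow[n - 1L] && !vow[n] && !(ch[n] %in% c("w", "x", "Y"))
}

.p2_contains_vowel <- function(w, from, to) {
  if (to < from) return(FALSE)
  ch <- strsplit(substr(w, from, to), "", fixed = TRUE)[[1L]]
  any(ch %in% .p2_vowel_set)
}

.p2_in_r <- function(w, suffix, rstart) {
  nchar(w) - nchar(suffix) + 1L >= rstart
}

.p2_stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # strip apostrophe forms
  if (startsWith(w, "'")) w <- substr(w, 2L, nchar(w))
  for (s in c("'s'", "'s", "'")) {
    if (.p2_ends(w, s)) { w <- .p2_chop(w, nchar(s)); break }
  }
  if (nchar(w) <= 2L) return(w)

  ex <- .p2_exceptions[w]
  if (!is.na(ex)) return(unname(ex))

  # mark consonant y as "Y": word-initial y, or y after a vowel
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (ch[1L] == "y") ch[1L] <- "Y"
  if (n >= 2L) {
    for (i in 2:n) {
      if (ch[i] == "y" && .p2_is_vowel(ch[i - 1L])) ch[i] <- "Y"
    }
  }
  w <- paste(ch, collapse = "")
  reg <- .p2_regions(ch, w)
  r1 <- reg[["r1"]]

  # Step 1a
  if (.p2_ends(w, "sses")) {
    w <- paste0(.p2_chop(w, 4L), "ss")
  } else if (.p2_ends(w, "ied") || .p2_ends(w, "ies")) {
    w <- .p2_chop(w, 3L)
    w <- paste0(w, if (nchar(w) > 1L) "i" else "ie")
  } else if (.p2_ends(w, "us") || .p2_ends(w, "ss")) {
    # leave alone
  } else if (.p2_ends(w, "s")) {
    if (.p2_contains_vowel(w, 1L, nchar(w) - 2L)) w <- .p2_chop(w, 1L)
  }

  if (w %in% .p2_exceptions_1a) return(w)

  # Step 1b
  s1b <- NULL
  for (s in c("eedly", "ingly", "edly", "eed", "ing", "ed")) {
    if (.p2_ends(w, s)) { s1b <- s; break }
  }
  if (!is.null(s1b)) {
    if (s1b %in% c("eed", "eedly")) {
      if (.p2_in_r(w, s1b, r1)) w <- paste0(.p2_chop(w, nchar(s1b)), "ee")
    } else if (.p2_contains_vowel(w, 1L, nchar(w) - nchar(s1b))) {
      w <- .p2_chop(w, nchar(s1b))
      if (.p2_ends(w, "at") || .p2_ends(w, "bl") || .p2_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (nchar(w) >= 2L &&
                 substr(w, nchar(w) - 1L, nchar(w)) %in% .p2_doubles) {
        w <- .p2_chop(w, 1L)
      } else if (r1 > nchar(w) && .p2_short_syllable_end(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # Step 1c: y -> i after a non-vowel that is not the first letter
  n <- nchar(w)
  if (n >= 3L && substr(w, n, n) %in% c("y", "Y")) {
    prev <- substr(w, n - 1L, n - 1L)
    if (!.p2_is_vowel(prev)) w <- paste0(.p2_chop(w, 1L), "i")
  }

  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  reg <- .p2_regions(ch, w)
  r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 2 (longest suffix; replacement only when the suffix lies in R1)
  step2 <- list(
    c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
    c("ousness", "ous"), c("iveness", "ive"),
    c("tional", "tion"), c("biliti", "ble"), c("lessli", "less"),
    c("entli", "ent"), c("ation", "ate"), c("alism", "al"),
    c("aliti", "al"), c("ousli", "ous"), c("iviti", "ive"),
    c("fulli", "ful"),
    c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
    c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
    c("bli", "ble"), c("ogi", "og"), c("li", "")
  )
  for (pair in step2) {
    s <- pair[[1L]]
    if (.p2_ends(w, s)) {
      if (.p2_in_r(w, s, r1)) {
        stem <- .p2_chop(w, nchar(s))
        if (s == "ogi") {
          if (.p2_ends(stem, "l")) w <- paste0(stem, "og")
        } else if (s == "li") {
          if (nchar(stem) >= 1L &&
              substr(stem, nchar(stem), nchar(stem)) %in% .p2_li_valid) {
            w <- stem
          }
        } else {
          w <- paste0(stem, pair[[2L]])
        }
      }
      break
    }
  }

  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  reg <- .p2_regions(ch, w)
  r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 3 (in R1; "ative" additionally requires R2)
  step3 <- list(
    c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
    c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (pair in step3) {
    s <- pair[[1L]]
    if (.p2_ends(w, s)) {
      if (.p2_in_r(w, s, r1)) {
        if (s == "ative") {
          if (.p2_in_r(w, s, r2)) w <- .p2_chop(w, nchar(s))
        } else {
          w <- paste0(.p2_chop(w, nchar(s)), pair[[2L]])
        }
      }
      break
    }
  }

  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  reg <- .p2_regions(ch, w)
  r2 <- reg[["r2"]]

  # Step 4 (deletion in R2; "ion" only after s/t)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment",
             "ant", "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
             "al", "er", "ic")
  for (s in step4) {
    if (.p2_ends(w, s)) {
      if (.p2_in_r(w, s, r2)) {
        stem <- .p2_chop(w, nchar(s))
        if (s == "ion") {
          if (.p2_ends(stem, "s") || .p2_ends(stem, "t")) w <- stem
        } else {
          w <- stem
        }
      }
      break
    }
  }

  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  reg <- .p2_regions(ch, w)
  r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 5
  n <- nchar(w)
  if (substr(w, n, n) == "e") {
    if (n >= r2 ||
        (n >= r1 && !.p2_short_syllable_end(.p2_chop(w, 1L)))) {
      w <- .p2_chop(w, 1L)
    }
  } else if (substr(w, n, n) == "l") {
    if (n >= r2 && .p2_ends(.p2_chop(w, 1L), "l")) w <- .p2_chop(w, 1L)
  }

  chartr("Y", "y", w)
}

#' Stem English words with the built-in Porter2 stemmer
#'
#' Reduces each word to its root with the Porter2 (Snowball English)
#' stemming algorithm, so that inflectional variants such as "warn",
#' "warned" and "warning" collapse onto a single word root.  Input is
#' expected to be lowercase; words of two characters or fewer are returned
#' unchanged.
#'
#' @param x Character vector of (lowercase) words.
#' @return Character vector of stems, same length as `x`.
#' @examples
#' stem_words(c("warnings", "warned", "products", "tobacco"))
#' @export
stem_words <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector", call. = FALSE)
  if (length(x) == 0L) return(character())
  # stem each distinct word once
  ux <- unique(x)
  stems <- vapply(ux, .p2_stem1, character(1L), USE.NAMES = FALSE)
  stems[match(x, ux)]
}
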