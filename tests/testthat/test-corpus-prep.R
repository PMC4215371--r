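make_disk_corpus <- function(dir, docs, groups = NULL, roles = NULL,
                             positions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(docs)
  man <- data.frame(
    doc_id = ids,
    group = groups %||% rep("other", length(ids)),
    role = roles %||% rep("virgin", length(ids)),
    position = positions %||% rep(NA_real_, length(ids)),
    filename = paste0(ids, ".txt")
  )
  for (id in ids) writeLines(docs[[id]], file.path(dir, paste0(id, ".txt")))
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_corpus reads manifest rows in order and checks files", {
  dir <- withr::local_tempdir()
  man <- make_disk_corpus(dir, c(B = "beta text", A = "alpha text",
                                 C = "gamma text"))
  corp <- load_corpus(man, dir)
  expect_s3_class(corp, "ws_corpus")
  expect_identical(corp$doc_id, c("B", "A", "C"))
  expect_identical(corp$text[2], "alpha text")

  # absent file: error names the doc_id
  unlink(file.path(dir, "C.txt"))
  expect_error(load_corpus(man, dir), "C")
})

test_that("load_corpus rejects duplicated doc_ids", {
  dir <- withr::local_tempdir()
  man <- make_disk_corpus(dir, c(PMI1 = "one", X = "two"))
  tab <- read.delim(man)
  tab$doc_id <- c("PMI1", "PMI1")
  write.table(tab, man, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("dup", file.path(dir, "X.txt"))
  expect_error(load_corpus(man, dir), "PMI1")
})

test_that("clean_text deletes literal stop-phrases and nothing else", {
  cfg <- cleaning_config(stop_phrases = "Philip Morris International")
  expect_identical(
    clean_text("Philip Morris International welcomes the proposal.", cfg),
    " welcomes the proposal."
  )
  # empty stop-phrase list: identity
  expect_identical(
    clean_text("Some text.", cleaning_config()),
    "Some text."
  )
  # phrase spans are exact: surrounding words never clipped
  cfg2 <- cleaning_config(stop_phrases = "ACME")
  expect_identical(clean_text("xACMEy ACME z", cfg2), "xy  z")
  # a document that is only a stop-phrase becomes empty -> error
  expect_error(
    clean_text(c(D1 = "Philip Morris International"), cfg),
    "D1"
  )
})

test_that("excluded-topic markers drop whole passages", {
  cfg <- cleaning_config(
    excluded_topics = list(c("<ecig>", "</ecig>"))
  )
  expect_identical(
    clean_text("Plain packs. <ecig>vaping stance</ecig> Health warnings.", cfg),
    "Plain packs.  Health warnings."
  )
  expect_error(
    clean_text("start <ecig>never closed", cfg),
    "unmatched"
  )
})

test_that("tokenize_and_stem lowercases, drops numbers/symbols/stopwords, stems", {
  expect_identical(
    tokenize_and_stem("Tobacco products, 2010!", cleaning_config()),
    c("tobacco", "product")
  )
  expect_identical(tokenize_and_stem("the and of", cleaning_config()),
                   character())
  stems <- tokenize_and_stem("warn warned warning", cleaning_config())
  expect_length(stems, 3L)
  expect_length(unique(stems), 1L)
  # hyphenated words split at the hyphen
  expect_identical(
    tokenize_and_stem("tar-free", cleaning_config(stopwords = "none")),
    c("tar", "free")
  )
  # min token length
  expect_identical(
    tokenize_and_stem("an ox ran far", cleaning_config(stopwords = "none",
                                                       min_token_length = 3)),
    c("ran", "far")
  )
})

test_that("stopword removal happens on surface forms, before stemming", {
  # "abouts" is not a stopword but its stem "about" is; it must survive
  out <- tokenize_and_stem("whereabouts abouts about", cleaning_config())
  expect_true("about" %in% out)       # from "abouts"
  expect_false(any(out == ""))
  expect_length(out, 2L)              # "about" itself was removed as stopword
})

test_that("frequency matrix matches hand counts and is row-stochastic", {
  corp <- tokens_corpus(list(D1 = c("a", "a", "b"), D2 = c("b", "c", "c")))
  fm <- build_frequency_matrix(corp, no_stop_cfg())
  expect_identical(fm$word_roots, c("a", "b", "c"))
  expect_equal(unname(fm$rel_freq["D1", ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(fm$rel_freq["D2", ]), c(0, 1 / 3, 2 / 3))
  expect_identical(unname(fm$total_tokens), c(3L, 3L))
  expect_equal(unname(rowSums(fm$rel_freq)), c(1, 1), tolerance = 1e-12)

  single <- tokens_corpus(list(S = rep("x", 4)))
  fm1 <- build_frequency_matrix(single, no_stop_cfg())
  expect_equal(unname(fm1$rel_freq[1, "x"]), 1)
  expect_identical(unname(fm1$total_tokens), 4L)
})

test_that("relative frequencies are invariant to duplicating a document", {
  txt <- "tobacco products need health warnings on packaging"
  corp1 <- ws_corpus("D", txt)
  corp2 <- ws_corpus("D", paste(txt, txt))
  cfg <- cleaning_config()
  fm1 <- build_frequency_matrix(corp1, cfg)
  fm2 <- build_frequency_matrix(corp2, cfg)
  expect_identical(fm1$word_roots, fm2$word_roots)
  expect_equal(fm1$rel_freq, fm2$rel_freq, tolerance = 1e-12)
  expect_identical(unname(fm2$total_tokens), 2L * unname(fm1$total_tokens))
})

test_that("frequency matrix construction is deterministic and errors on empty docs", {
  corp <- ws_corpus(c("D1", "D2"), c("smoking kills", "the and of"))
  expect_error(build_frequency_matrix(corp, cleaning_config()), "D2")

  corp_ok <- ws_corpus(c("D1", "D2"), c("b a c b", "c a a"))
  f1 <- build_frequency_matrix(corp_ok, no_stop_cfg())
  f2 <- build_frequency_matrix(corp_ok, no_stop_cfg())
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$word_roots, sort(f1$word_roots))
})

test_that("group_average_frequency averages per-document percentages", {
  corp <- tokens_corpus(list(D1 = c("a", "a", "b", "b"), D2 = c("a", "b", "b", "b")))
  fm <- build_frequency_matrix(corp, no_stop_cfg())
  # D1: 50%, D2: 25% -> mean 37.5
  expect_equal(group_average_frequency(fm, c("D1", "D2"), "a"), 37.5)
  # single-document group: its own percentage
  expect_equal(group_average_frequency(fm, "D1", "a"), 50)
  # absent root counts as zero everywhere
  expect_equal(group_average_frequency(fm, c("D1", "D2"), "zz"), 0)
  expect_error(group_average_frequency(fm, character(), "a"), "non-empty")
  expect_error(group_average_frequency(fm, "nope", "a"), "nope")
})

test_that("top_k_words ranks by pooled count with lexicographic ties", {
  corp <- tokens_corpus(list(
    D1 = c("b", "b", "a", "c"),
    D2 = c("b", "a", "d")
  ))
  fm <- build_frequency_matrix(corp, no_stop_cfg())
  # pooled: b=3, a=2, c=1, d=1 (c/d tie -> c first)
  expect_identical(top_k_words(fm, 2), c("b", "a"))
  expect_identical(top_k_words(fm, 4), c("b", "a", "c", "d"))
  expect_setequal(top_k_words(fm, length(fm$word_roots)), fm$word_roots)
  expect_error(top_k_words(fm, 0), "positive")
  expect_error(top_k_words(fm, 99), "vocabulary")
})

test_that("published frequency table fixture loads with groups", {
  tab <- tpd_frequency_table()
  expect_identical(dim(tab$percent), c(23L, 15L))
  expect_identical(sum(tab$groups == "health"), 5L)
  expect_identical(sum(tab$groups == "tobacco"), 8L)
  expect_equal(tab$percent["ESTA", "tobacco"], 6.67)
})
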