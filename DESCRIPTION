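Package: wordscaling
Title: Supervised Text Scaling of Policy Positions with Wordscores
Version: 1.0.0
Authors@R: person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the policy positions of documents on a bounded
    reference scale using the Wordscores supervised scaling algorithm.
    Reference texts with analyst-assigned positions calibrate per-word
    scores; unknown ("virgin") texts are scored as frequency-weighted
    averages of those word scores, with analytic standard errors and
    confidence intervals.  Includes the Martin-Vanberg affine rescaling
    that corrects the centering bias of raw virgin scores, the classic
    mean/spread rescaling alternative, a two-stage robustness procedure
    that re-estimates reference positions from a document subset, trend
    comparison across ordered document sequences, a preprocessing
    pipeline (cleaning, tokenisation, stopword removal, built-in Porter2
    stemming, document-term frequency matrices), and a synthetic corpus
    generator with known ground-truth positions for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
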