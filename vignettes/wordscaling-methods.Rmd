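---
title: "Methods: supervised text scaling with wordscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised text scaling with wordscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordscaling)
```

## The model and its assumptions

Wordscores is a supervised scaling estimator. Its single substantive
assumption is that an author's position on the dimension of interest is
expressed through systematic differences in word choice: documents near one
pole over-use one part of the vocabulary, documents near the other pole
over-use another part, and the rest of the vocabulary is shared. Under that
assumption the relative frequency $F_{wr}$ of word root $w$ in reference
text $r$ identifies

$$P(r \mid w) = \frac{F_{wr}}{\sum_{r'} F_{wr'}}, \qquad
S_w = \sum_r P(r \mid w)\, A_r,$$

where $A_r$ is the assigned position of reference $r$, and a virgin text
$v$ is scored as

$$\omega_v = \sum_w F^{*}_{wv}\, S_w,$$

with $F^{*}_{wv}$ the virgin's relative frequencies renormalised over
*scored* roots only. Three consequences of this construction matter in
practice:

* **Boundedness.** Every $S_w$ and every $\omega_v$ is a convex
  combination of reference positions, hence lies in
  $[\min A_r, \max A_r]$.
* **Equal reference weighting.** Because $P(r \mid w)$ is built from
  relative (not raw) frequencies, a long reference does not dominate a
  short one.
* **Centering bias.** Shared vocabulary has $S_w$ near the middle of the
  scale, so virgin scores — and references re-scored as virgins — are
  pulled towards the centre. This motivates rescaling (below).

Words that occur in no reference carry no information under the model and
are excluded from the numerator, the denominator and the scored-token
count $N_v$. We count $N_v$ over token *occurrences*, not unique roots:
this is what makes the standard error shrink with document length, which
is the behaviour published score tables display.

## Uncertainty

The score is a weighted mean of per-token word scores, so we use the
weighted-variance estimator
$V_v = \sum_w F^{*}_{wv} (S_w - \omega_v)^2$,
$\mathrm{se}(\omega_v) = \sqrt{V_v / N_v}$, and normal-approximation
intervals $\omega_v \pm z\,\mathrm{se}$ with $z = 1.96$ by default. Two
closed-form checks are enforced in the tests: a document whose scored
roots share a single score has $\mathrm{se} = 0$, and concatenating a
document with itself leaves $\omega_v$ and $F^{*}$ unchanged while
doubling $N_v$, so the SE shrinks by exactly $1/\sqrt{2}$.

Published tables built on this machinery are ambiguous about whether the
parenthesised column is an SD or an SE; we implement the SE reading
because the printed values decrease with document length, which only the
SE does.

## Rescaling

**Martin–Vanberg (default).** References are re-scored as if they were
virgins; the extremes of those re-scored values, $\omega_1 < \omega_2$,
become anchors and every score is mapped by the affine transform
$(\omega_v - \omega_1)/(\omega_2 - \omega_1)$. Anchor documents land at
exactly 0 and 1; CI endpoints are transformed by the same map, which is
equivalent to rescaling the SE by $1/(\omega_2 - \omega_1)$. Virgins more
extreme than the anchors legitimately map outside $[0,1]$ and are
**not clipped** — clipping would hide estimation behaviour.

The anchor pool is a genuinely open design choice: the verbal descriptions
in the literature ("estimated positions for the reference texts along with
the virgin texts") can be read either as anchoring on the re-scored
references or on all scored documents. We default to
`anchor_policy = "rescored_refs"`, the canonical construction, and expose
`"all_scored"` as an alternative; the chosen policy and the fitted anchors
are logged in every analysis object so a report can never silently mix
them.

**Mean/spread (LBG) alternative.** For robustness checks,
$\omega^{*}_v = (\omega_v - \bar\omega_v)\,(\mathrm{sd}_{ref}/\mathrm{sd}_v)
+ \bar\omega_v$ matches the virgin set's spread to the spread of the
assigned reference positions. We use the sample SD on both sides; the
ratio is what matters and both tests' closed-form cases are insensitive to
the convention. Both transforms are strictly increasing, so document
rankings are invariant to the choice.

**Two-stage robustness.** Stage 1 scores the non-subset references as
virgins from a small reference subset; stage 2 re-runs the scaling with
*all* of them as references — the subset at assigned positions, the rest
at their stage-1 **raw** estimates. Raw (not rescaled) estimates are used
because the scoring equation consumes positions on the reference metric
and rescaling anchors are undefined mid-procedure. When stage-1 virgins
are recovered exactly at the poles (disjoint pole vocabularies) the
procedure collapses to the primary analysis; the tests assert this
identity at 1e-12.

**Trend comparison.** Movement along an ordered document sequence is
declared significant for a pair when the two confidence intervals do not
overlap — conservative relative to a z-test on the difference — and
intervals touching at a single point count as overlapping. The reported
direction follows the sign of the endpoint difference.

## Preprocessing

Cleaning runs before tokenisation, in this order: excluded-topic passages
(marker-delimited, e.g. sections on a topic deliberately left out of an
analysis) are dropped; literal stop-phrases (organisation names, headers,
contact details) are deleted with fixed-string matching, which can never
clip characters outside the phrase span. A document emptied by cleaning is
a fatal error, as is a document with no tokens left after tokenisation.

Tokens are maximal runs of alphabetic characters after lowercasing, so
numbers and symbols never yield tokens and hyphenated words split at the
hyphen. Stopwords (the shipped Snowball English list, overridable) are
removed on **surface forms before stemming** — so "only" is removed but a
non-stopword like "abouts", whose stem is a stopword, survives; the test
suite asserts this ordering. Stemming uses a Porter2 (Snowball English)
implementation written for this package and validated against a curated
list of classic and domain inflection families plus fixed-point property
tests.

Percentage frequency tables round to 2 decimals with half-away-from-zero
rounding, the convention of the major statistics packages whose output
published tables reproduce (R's own `round()` is half-to-even); internal
arithmetic is always full precision. Vocabulary order is lexicographic
everywhere, and count ties in top-$k$ rankings break lexicographically,
so all outputs are byte-deterministic given identical inputs.

## The synthetic corpus generator

The generator emulates the statistical structure the estimator assumes:
two opposed reference groups with partially disjoint discriminating
vocabularies plus shared non-discriminating vocabulary, and virgin
documents at known intermediate positions. A spec defines a vocabulary of
which a fraction discriminates (split evenly between poles, each
discriminating word favoured by its pole by an odds factor `pole_skew`);
shared words have identical probability under both poles, and a document
at position $\theta$ draws i.i.d. tokens from
$\theta\,p_{health} + (1-\theta)\,p_{tobacco}$.

Defaults mirror a realistic lobbying-study design: 8 + 5 references,
documents of 2000 scored tokens (position papers of a few thousand words
fall in roughly the 1000–12000 scored-token range), vocabulary 2000, 30%
discriminating vocabulary at 3:1 skew — a moderate signal: individual
discriminating words are only three times likelier at their own pole,
recovery is driven by aggregation.

Vocabulary words are all-consonant strings (`"wbcc"`, …). They are
Porter2 fixed points and never stopwords, so generated corpora exercise
the full preprocessing pipeline without distorting the designed
frequencies. (Digit-bearing labels would be destroyed by the alphabetic
tokeniser, and vowel-bearing ones could be stemmed or stopword-matched.)
Real inflected words are injected by separate test fixtures instead.

What the generator does **not** model: topical/rhetorical structure, word
burstiness (tokens are i.i.d., so real SEs will be anti-conservative in
comparison), document-length heterogeneity, and vocabulary growth with
length. Passing recovery tests therefore demonstrates correctness of the
estimator under its own assumptions, not performance on real submissions.

## Validation design and problem sizes

The test suite validates at three levels:

1. **Exact oracles.** Toy corpora of at most 3 documents and 6 roots are
   checked to 1e-12 against an independent brute-force implementation of
   the scoring equations (explicit loops, no shared code), alongside
   hand-derived identities: anchor pinning, recovery of assigned positions
   under disjoint reference vocabularies, label-swap antisymmetry
   ($\omega \mapsto 1-\omega$), and the $1/\sqrt2$ SE law.
2. **Published arithmetic.** The shipped per-document frequency table
   reproduces all 45 printed group-average cells exactly at 2-decimal
   rounding.
3. **Recovery studies.** 100 seeded replicates of the study-scale design
   (above) require Spearman correlation between true and estimated virgin
   positions of at least 0.9 in at least 95 replicates; a smaller design
   (vocabulary 300, 4 + 4 references, 5 virgins, 6 seeds per condition)
   checks that the mean absolute MV-score bias falls as documents grow
   from 500 to 5000 tokens; and the two-stage procedure must preserve the
   ranking of draft-analogue virgins. These sizes keep the full suite
   under a minute on one CPU while leaving the multinomial noise well
   below the tested margins.

## Interfaces

All functionality is exposed as plain R functions returning data frames
and lightweight S3 objects, which is how an analyst consumes a scaling
package interactively; `build_report()` and the `write_*` helpers emit
deterministic TSV artefacts for downstream tooling, and
`scripts/acceptance.R` demonstrates a fully scripted, seeded end-to-end
run.

## Known limitations

* Exact reproduction of any particular published study requires its exact
  documents and its preprocessing tool's exact stemming/stopword
  behaviour; neither is generally available, and stemmers differ at the
  margin. The package's claims are therefore structural (oracle
  equivalence, identities, recovery) plus the published-table arithmetic.
* The SE treats tokens as independent draws; topical clustering in real
  text inflates true sampling variance.
* CI non-overlap is conservative for pairwise comparisons.
* The MV transform is exactly identified only with at least two distinct
  re-scored anchor values; degenerate pools raise errors rather than
  guessing.
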