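---
title: "Scoring verbal creativity by semantic distance: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring verbal creativity by semantic distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdis)
```

## The measurement problem

Divergent-thinking tasks such as the Alternate Uses Task (AUT) ask a
participant to produce creative uses for a common object ("box", "rope",
"brick"). Scoring the originality of thousands of free-text responses with
human raters is slow, expensive, and rater-dependent. Distributional
semantics offers an automated proxy: a response that is *semantically
distant* from its cue tends to be judged more original. `semdis` implements
this scoring engine end to end — embedding lookup, text cleaning, vector
composition, cosine-based distance, and aggregation across several
embedding models into a mean score and a latent-factor score.

## The score

Every registered *semantic space* maps words to real vectors (GloVe or
word2vec plain-text formats; typically 300–400 dimensions in published
spaces). For a cue vector $u$ and a composed response vector $v$, the score
for that space is

$$ \mathrm{dist}(u, v) \;=\; 1 - \cos(u, v) \;=\; 1 - \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}. $$

Since $\cos \in [-1, 1]$, distances lie in $[0, 2]$. (Some descriptions of
this family of scores state a range of $-1$ to $1$; that is inconsistent
with the $1-\cos$ definition and we treat it as an erratum — the package
implements the formula, and property tests pin the $[0, 2]$ range.)

Multi-word responses must first be composed into a single vector:

* **additive** — the componentwise sum of the token vectors;
* **multiplicative** — the componentwise (elementwise) product, the model
  that best matches human relatedness judgments and the package default.

Composition is accumulated in input token order. For the multiplicative
model the accumulator is renormalized to unit length after every pairwise
product: with components typically far below 1, a raw product over tens of
tokens underflows to zero, while cosine depends only on direction, so
positive per-step rescaling changes no distance (a test checks the
direction against an exact log-space product). A composition that collapses
to the exact zero vector — cancellation under addition, disjoint support
under multiplication — is *degenerate* and scores as missing rather than as
a fabricated extreme value.

### Why composition choice matters: elaboration bias

Longer responses (higher *elaboration*) are rated as more creative by
humans, yet under additive composition extra words tend to pull the summed
vector toward common ground with the cue, so distance *falls* with word
count. Elementwise multiplication acts more like feature intersection —
repeated related content sharpens the product onto the response's
distinctive components — and the correlation between word count and
distance flips sign. `elaboration_diagnostic()` reports the Pearson
correlation between word count and any chosen score so users can see the
bias in their own data, and the bundled fixture (below) reproduces the sign
contrast, which the test suite and acceptance script compute.

## Cleaning

`cleaning_config()` exposes three levels:

* `none` — lowercase, split on whitespace;
* `basic` — every non-alphabetic character becomes a separator, numerals
  are deleted (`"door-stop"` → `door`, `stop`; `"don't"` → `don`, `t`);
* `stop` — `basic` plus removal of the bundled, frozen 174-entry English
  stop-word list (`inst/extdata/stopwords_english.txt`). The list is
  shipped verbatim rather than taken from whatever text-mining library is
  installed, because silent list drift changes scores. Entries containing
  apostrophes can never match basic-cleaned tokens; they are retained for
  fidelity to the published list.

Two further options mirror manual practice: cue-word removal
(`remove_cue`, default off) deletes the cue and naive `+s`/`+es` plurals
(`default_cue_forms("box")` → `box`, `boxs`, `boxes`; spurious forms delete
nothing, and an explicit list can override), and the missing-data policy
drops out-of-vocabulary tokens *word-wise* — a misspelled word is lost, not
the whole response — with every dropped token listed in the OOV report. No
spell-checking is attempted; the OOV report is the hook for correcting
unambiguous misspellings upstream.

Cue texts themselves are always cleaned at the `basic` level: cues are
content words and must never be deleted by the stop list or by cue removal.

## Aggregation

With $k$ registered spaces, each response gets $k$ distances. Two
aggregates are offered:

* `semdis_mean` — the arithmetic mean of the non-missing per-space
  distances (emitted when at least `min_spaces_for_mean` spaces
  contributed, default 1);
* `semdis_factor` — the regression score from a one-factor
  maximum-likelihood model fitted to the per-space distances at the
  response (trial) level.

The factor model is $\Sigma(\lambda, \psi) = \lambda\lambda^\top +
\operatorname{diag}(\psi)$ with factor variance fixed at 1 and all
loadings free, estimated by minimizing the ML discrepancy

$$ F_{ML} = \log\lvert\Sigma\rvert + \operatorname{tr}(S\Sigma^{-1}) -
\log\lvert S\rvert - p $$

against the sample covariance $S$ of the raw distances. Identification
details: sign fixed by a non-negative first loading; deterministic
initialization from a principal-axis solution with squared-multiple-
correlation communalities, so repeated fits are bit-stable; uniquenesses
optimized on the log scale (hence strictly positive), with solutions pinned
at the boundary flagged as Heywood cases and treated as non-converged.
Requirements: at least 3 indicators (one factor is under-identified below
that) and more complete rows than indicators; rows missing any space are
deleted listwise for the fit and receive no factor score (they still get a
mean). Scores are the regression (Thurstone) kind,
$\hat f = \lambda^\top \Sigma^{-1} (x - \bar x)$, which average to zero
over the fitted rows; Bartlett scores are a possible alternative we did not
implement.

Three choices here were genuinely open and are our documented defaults
rather than prescribed behavior: the fit is on the covariance of raw
distances (not standardized indicators — ML factor analysis is
scale-equivariant, and a test cross-checks our loadings against
`stats::factanal` after rescaling); person-level indicators, when wanted,
are the per-participant-per-item *mean* of response-level scores
(`person_level()`); and vocabulary lookup is lowercased by default
(configurable off), which makes out-of-vocabulary behavior predictable.

## Synthetic fixtures: what they emulate and what they do not

No published multi-gigabyte embedding space ships with the package; the
generators in the fixtures module make every path testable offline.

* `make_toy_space()` builds a small vocabulary around cluster centroids.
  The noise scale starts at the analytic value $\sigma = \sqrt{1/c - 1}$
  for a target within-cluster cosine $c$ (for unit centroids with isotropic
  unit-expected-norm noise, $E[\cos] \approx 1/(1+\sigma^2)$) and is
  refined by bisection against the realized similarity on a fixed noise
  draw, so generation is deterministic given the seed and lands within
  about 0.1 of the target. Reserved cue tokens (`box`, `rope`, `brick`,
  ...) sit at their centroids and a handful of real stop words near the
  global centroid, so cleaning paths are exercised end to end.
* `make_heterogeneous_spaces()` re-perturbs one base space $k$ times,
  emulating embedding models trained on different corpora: broadly
  agreeing, imperfectly correlated — exactly the situation in which a
  latent factor over per-space distances is meaningful.
* `make_elaboration_table()` builds responses as a core token from a
  non-cue cluster padded with near-synonyms of the core and cue-cluster
  filler, balanced over lengths 1..`max_words`. On a *nonnegative* toy
  space this reproduces the elaboration-bias sign contrast by
  construction: cue-near filler pulls additive sums toward the cue, while
  elementwise products sharpen onto the core cluster's distinctive
  components. Nonnegative components make the multiplicative mechanism
  (shared-feature intersection) clean at toy scale; real embeddings are
  mixed-sign and far higher-dimensional.
* `simulate_factor_data()` draws exact one-factor data
  ($x_{ij} = \lambda_j f_i + \varepsilon_{ij}$, unit total variances) and
  returns the true factor for recovery tests.

Passing tests on these fixtures shows the *engine* is correct — formulas,
missing-data routing, determinism, recovery of known structure. It does not
show that toy distances predict human creativity ratings: that property
belongs to the full-scale published spaces and real response sets, which
are deliberately out of scope here.

## Numerical and policy choices

* Cosines are clamped to $[-1, 1]$ against rounding before the
  subtraction.
* Degenerate compositions and empty/all-OOV responses are missing (`NA`;
  empty cells in CSV output), never sentinel numbers.
* Float accumulation order is fixed to token order; scoring a table twice
  is bit-identical, and the CLI golden test pins byte-identical output.
* The optimizer's "false convergence" report at machine-precision minima
  of a near-zero discrepancy is accepted as convergence when
  $F_{ML} < 10^{-8}$.
* Duplicate words in an embedding file are an error, not last-wins.
* Problem sizes used throughout the tests and the acceptance script —
  toy spaces of roughly 60 words in 50 dimensions, response tables of
  30–120 rows, factor recovery at $n = 1000$ over 50 replications — were
  chosen as the smallest scales at which the statistical properties under
  test are stable.

## Known limitations

* No spell-checking, stemming, lemmatization, or multi-language support;
  the separator-based tokenization of hyphens/apostrophes is a documented
  choice, not the only defensible one.
* Whole-response missing on any OOV token is available as a policy in
  spirit but the shipped default is word-level drop; users needing
  stricter behavior should filter on the OOV report.
* Binary embedding formats and memory-mapped loading of multi-GB spaces
  are not implemented; correctness at moderate scale is the contract.
* The factor machinery is deliberately minimal: one factor, plain ML, no
  robust standard errors — the package exports scores, not inference.
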