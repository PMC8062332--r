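Package: semdis
Title: Automated Semantic-Distance Scoring of Verbal Creativity Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores free-text responses to verbal creativity tasks (e.g., the
    Alternate Uses Task) by semantic distance to the task cue. Loads word
    embeddings in the GloVe and word2vec plain-text formats, cleans responses
    with configurable stop-word and cue-word removal, composes multi-word
    responses with additive or elementwise-multiplicative vector composition,
    and computes 1 minus the cosine similarity between cue and response in
    each registered semantic space. Per-space distances are aggregated into a
    mean score and a latent-factor score from a one-factor maximum-likelihood
    model with regression (Thurstone) factor scores. Includes generators for
    synthetic semantic spaces and response tables, an elaboration-bias
    diagnostic, and a command-line interface for batch scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    readr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
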