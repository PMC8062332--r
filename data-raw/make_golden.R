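# Regenerates the committed golden output for the end-to-end CLI test.
# Run from the repository root after any deliberate change to the pipeline:
#   Rscript data-raw/make_golden.R
library(semdis)
dir <- tempfile("golden")
fx <- cmd_make_fixtures(file.path(dir, "fx"), k_spaces = 5L,
                        n_responses = 30L, seed = 42L)
out <- file.path(dir, "scores.csv")
cmd_score(fx$responses, fx$manifest, out, cleaning = "stop",
          composition = "mult", emit = c("per_space", "mean", "factor"),
          quiet = TRUE)
file.copy(out, "tests/testthat/golden_scores.csv", overwrite = TRUE)
cat("wrote tests/testthat/golden_scores.csv\n")
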