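# Independent brute-force oracles. These recompute scores straight from a
# vector matrix with the textbook formulas and deliberately share no code
# with the package's composition/scoring path.

oracle_cosine <- function(u, v) {
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

# direct 1 - cos(cue, composed response): additive = column sums of rows,
# multiplicative = columnwise product (safe at toy scale, no renorm)
oracle_distance <- function(M, cue_tokens, response_tokens, method) {
  compose <- function(toks) {
    rows <- M[toks, , drop = FALSE]
    if (method == "additive") colSums(rows)
    else apply(rows, 2, prod)
  }
  u <- compose(cue_tokens)
  v <- compose(response_tokens)
  if (all(u == 0) || all(v == 0)) return(NA_real_)
  1 - oracle_cosine(u, v)
}

# direction of an elementwise product of many vectors, computed in
# log-magnitude space so it cannot underflow
oracle_product_direction <- function(vectors) {
  sgn <- Reduce(`*`, lapply(vectors, sign))
  logm <- Reduce(`+`, lapply(vectors, function(v) log(abs(v))))
  mag <- exp(logm - max(logm))
  d <- sgn * mag
  d / sqrt(sum(d^2))
}

# small deterministic toy space as a plain matrix + semantic_space
toy_matrix <- function(words, dim, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(M) <- words
  M
}

random_word <- function(n_chars = 4) {
  paste(sample(letters, n_chars, replace = TRUE), collapse = "")
}

# random printable string with letters, digits, punctuation, whitespace
random_messy_string <- function(max_len = 60) {
  pool <- c(letters, LETTERS, 0:9, " ", " ", " ", "-", "'", ",", ".", "!",
            "?", "(", ")", "/", ";", ":")
  n <- sample.int(max_len, 1)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
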