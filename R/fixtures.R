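# run code under a temporary RNG state so generators are pure functions of
# their spec + seed and never disturb the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# pronounceable synthetic word labels: deterministic consonant-vowel
# syllable triples ("bakori", "lusena", ...), unique by construction
synthetic_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  idx <- seq_len(n) - 1L
  k <- length(syll)
  paste0(syll[idx %% k + 1L],
         syll[(idx %/% k) %% k + 1L],
         syll[(idx %/% (k * k)) %% k + 1L])
}

#' Specification for a synthetic toy semantic space
#'
#' Toy spaces stand in for full-scale published embeddings in tests and
#' demos: a small vocabulary with controlled cluster structure, so that
#' within-cluster cosine similarity hits a chosen target and between-
#' cluster similarity stays lower.
#'
#' @param n_words number of regular vocabulary words (cue tokens and,
#'   optionally, stop-word tokens are added on top).
#' @param dimension vector dimension (>= 2).
#' @param n_clusters number of semantic clusters (1 <= n_clusters <=
#'   n_words). The first clusters reserve the cue tokens `box`, `rope`,
#'   `brick`, then `cue4`, `cue5`, ...
#' @param within_cluster_cos target mean pairwise cosine within a cluster,
#'   in (0, 1).
#' @param seed integer RNG seed.
#' @param nonnegative if `TRUE`, all vector components are non-negative
#'   (useful for fixtures where elementwise products must retain shared-
#'   feature structure).
#' @param include_stopwords if `TRUE` (default), a handful of real English
#'   stop words are added to the vocabulary so preprocessing paths can be
#'   exercised end to end.
#' @return An object of class `toy_space_spec`.
#' @export
toy_space_spec <- function(n_words = 60L, dimension = 50L, n_clusters = 3L,
                           within_cluster_cos = 0.6, seed = 1L,
                           nonnegative = FALSE, include_stopwords = TRUE) {
  if (n_clusters < 1L || n_words < n_clusters)
    stop("need n_words >= n_clusters >= 1", call. = FALSE)
  if (dimension < 2L) stop("dimension must be >= 2", call. = FALSE)
  if (within_cluster_cos <= 0 || within_cluster_cos >= 1)
    stop("within_cluster_cos must lie in (0, 1)", call. = FALSE)
  structure(
    list(n_words = as.integer(n_words), dimension = as.integer(dimension),
         n_clusters = as.integer(n_clusters),
         within_cluster_cos = within_cluster_cos, seed = as.integer(seed),
         nonnegative = isTRUE(nonnegative),
         include_stopwords = isTRUE(include_stopwords)),
    class = "toy_space_spec"
  )
}

cue_names <- function(k) {
  base <- c("box", "rope", "brick")
  if (k <= 3L) base[seq_len(k)]
  else c(base, paste0("cue", seq(4L, k)))
}

# realized mean pairwise within-cluster cosine for word vectors built as
# centroid + sigma * noise (clamped when nonnegative)
realized_within_cos <- function(centroids, Z, cluster, sigma, nonnegative) {
  W <- centroids[cluster, , drop = FALSE] + sigma * Z
  if (nonnegative) W <- pmax(W, 0.01)
  W <- W / sqrt(rowSums(W^2))
  vals <- c()
  for (k in unique(cluster)) {
    idx <- which(cluster == k)
    if (length(idx) < 2L) next
    G <- tcrossprod(W[idx, , drop = FALSE])
    vals <- c(vals, G[upper.tri(G)])
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Generate a synthetic toy semantic space
#'
#' Draws one unit centroid per cluster, then places each word at its
#' cluster centroid plus isotropic noise. The noise scale starts at the
#' analytic value `sqrt(1/c - 1)` for target cosine `c` and is refined by
#' bisection against the realized mean within-cluster cosine (computed on
#' a fixed noise draw, so the whole construction is deterministic given
#' the seed). Each cluster's reserved cue token sits at its centroid;
#' stop-word tokens, when included, sit near the global centroid.
#'
#' @param spec a [toy_space_spec()].
#' @return A [semantic_space()] whose realized within-cluster cosine is
#'   within about 0.1 of the target.
#' @export
make_toy_space <- function(spec) {
  stopifnot(inherits(spec, "toy_space_spec"))
  with_seed(spec$seed, {
    d <- spec$dimension
    k <- spec$n_clusters
    n <- spec$n_words
    centroids <- matrix(stats::rnorm(k * d), k, d)
    if (spec$nonnegative) centroids <- abs(centroids)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    cluster <- rep(seq_len(k), length.out = n)
    Z <- matrix(stats::rnorm(n * d), n, d) / sqrt(d)  # E||row||^2 = 1

    target <- spec$within_cluster_cos
    sigma <- sqrt(1 / target - 1)
    if (any(table(cluster) >= 2L)) {
      lo <- sigma / 8; hi <- sigma * 8
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        r <- realized_within_cos(centroids, Z, cluster, mid,
                                 spec$nonnegative)
        if (r > target) lo <- mid else hi <- mid
      }
      sigma <- (lo + hi) / 2
    }

    W <- centroids[cluster, , drop = FALSE] + sigma * Z
    if (spec$nonnegative) W <- pmax(W, 0.01)
    rownames(W) <- synthetic_words(n)

    cues <- centroids
    rownames(cues) <- cue_names(k)
    mat <- rbind(W, cues)

    if (spec$include_stopwords) {
      sw <- c("the", "a", "of", "and", "it", "as")
      g <- colMeans(centroids)
      if (sqrt(sum(g^2)) < 1e-8) g <- centroids[1, ]
      g <- g / sqrt(sum(g^2))
      SW <- matrix(rep(g, each = length(sw)), length(sw), d) +
        0.2 * matrix(stats::rnorm(length(sw) * d), length(sw), d) / sqrt(d)
      if (spec$nonnegative) SW <- pmax(SW, 0.01)
      rownames(SW) <- sw
      mat <- rbind(mat, SW)
    }
    sp <- semantic_space(mat, name = paste0("toy", spec$seed))
    attr(sp, "cluster") <- stats::setNames(cluster, rownames(W))
    attr(sp, "cues") <- cue_names(k)
    sp
  })
}

#' Generate k correlated-but-distinct toy spaces
#'
#' Real embedding models trained on different corpora agree broadly but
#' differ in detail, which is what makes a latent factor over per-space
#' distances meaningful. This generator emulates that: all k spaces share
#' one vocabulary and cluster structure (from `base_spec`), but each adds
#' its own independent perturbation, so distances computed from any two
#' spaces on the same responses correlate positively yet imperfectly.
#'
#' @param k number of spaces (>= 3, so a one-factor model is identified).
#' @param base_spec a [toy_space_spec()] for the shared structure.
#' @param seed integer seed for the per-space perturbations.
#' @param perturbation perturbation scale; 0 makes all spaces identical.
#' @return Named list of k [semantic_space()] objects
#'   (`space1`..`spacek`).
#' @export
make_heterogeneous_spaces <- function(k = 5L, base_spec = toy_space_spec(),
                                      seed = 1L, perturbation = 0.35) {
  if (k < 3L)
    stop("need k >= 3 spaces: a one-factor model over per-space ",
         "distances requires at least 3 indicators", call. = FALSE)
  base <- make_toy_space(base_spec)
  M <- base$vectors
  with_seed(seed, {
    spaces <- vector("list", k)
    for (j in seq_len(k)) {
      E <- matrix(stats::rnorm(length(M)), nrow(M), ncol(M)) /
        sqrt(ncol(M))
      Mj <- M + perturbation * E
      if (base_spec$nonnegative) Mj <- pmax(Mj, 0.01)
      rownames(Mj) <- rownames(M)
      spj <- semantic_space(Mj, name = paste0("space", j))
      attr(spj, "cluster") <- attr(base, "cluster")
      attr(spj, "cues") <- attr(base, "cues")
      spaces[[j]] <- spj
    }
    names(spaces) <- paste0("space", seq_len(k))
    spaces
  })
}

#' Specification for the elaboration-bias fixture
#'
#' Describes a response table engineered so that additive composition
#' penalizes longer responses while multiplicative composition rewards
#' them -- the qualitative elaboration-bias contrast.
#'
#' @param n_responses number of responses.
#' @param cue cue token; must be in the scoring space's vocabulary.
#' @param max_words maximum response length in tokens (>= 2); lengths
#'   1..max_words are balanced across the table.
#' @param synonym_cos minimum cosine (to the response's core token) for a
#'   word to count as a near-synonym elaboration token.
#' @param seed integer RNG seed.
#' @return An object of class `elaboration_fixture_spec`.
#' @export
elaboration_fixture_spec <- function(n_responses = 120L, cue = "box",
                                     max_words = 6L, synonym_cos = 0.5,
                                     seed = 101L) {
  if (max_words < 2L) stop("max_words must be >= 2", call. = FALSE)
  structure(
    list(n_responses = as.integer(n_responses), cue = tolower(cue),
         max_words = as.integer(max_words), synonym_cos = synonym_cos,
         seed = as.integer(seed)),
    class = "elaboration_fixture_spec"
  )
}

#' Generate the elaboration-bias response table
#'
#' Each response is a core token drawn from a cluster other than the
#' cue's, padded (for longer responses) with a mix of near-synonyms of the
#' core token and generic filler tokens from the cue's own cluster. Under
#' additive composition the cue-near filler pulls the summed vector toward
#' the cue, so distance falls as responses lengthen; under elementwise
#' multiplication repeated near-synonyms sharpen the product onto the core
#' cluster's distinctive components, pushing distance up. Word counts are
#' balanced across lengths 1..max_words and the table is deterministic
#' given the seed.
#'
#' @param spec an [elaboration_fixture_spec()].
#' @param space a [semantic_space()] from [make_toy_space()] (cluster
#'   attribute required; a nonnegative space gives the cleanest contrast).
#' @return Tibble of response records (`id`, `item`, `response`,
#'   `serial_position`).
#' @export
make_elaboration_table <- function(spec, space) {
  stopifnot(inherits(spec, "elaboration_fixture_spec"),
            inherits(space, "semantic_space"))
  cue_vec <- lookup(space, spec$cue)
  if (is.null(cue_vec))
    stop("cue '", spec$cue, "' is not in the space vocabulary",
         call. = FALSE)
  if (spec$n_responses == 0L)
    return(tibble::tibble(id = character(), item = character(),
                          response = character(),
                          serial_position = integer()))
  cluster <- attr(space, "cluster")
  if (is.null(cluster))
    stop("space lacks cluster structure; build it with make_toy_space()",
         call. = FALSE)
  cues <- attr(space, "cues")
  cue_cluster <- which(cues == spec$cue)
  if (!length(cue_cluster))
    stop("cue '", spec$cue, "' is not one of the space's reserved cues",
         call. = FALSE)

  words <- names(cluster)
  M <- space$vectors[words, , drop = FALSE]
  U <- M / sqrt(rowSums(M^2))
  cos_cue <- as.numeric(U %*% (cue_vec / sqrt(sum(cue_vec^2))))
  names(cos_cue) <- words
  core_pool <- words[cluster != cue_cluster]
  filler_pool <- words[cluster == cue_cluster]
  core_pool <- core_pool[order(cos_cue[core_pool])]
  core_pool <- core_pool[seq_len(max(3L, length(core_pool) %/% 2L))]
  G <- tcrossprod(U)  # pairwise cosines among regular words
  dimnames(G) <- list(words, words)

  with_seed(spec$seed, {
    lens <- rep(seq_len(spec$max_words), length.out = spec$n_responses)
    rows <- vector("list", spec$n_responses)
    for (i in seq_len(spec$n_responses)) {
      core <- sample(core_pool, 1L)
      toks <- core
      if (lens[i] > 1L) {
        syn_pool <- setdiff(words[G[core, ] >= spec$synonym_cos], core)
        for (j in seq_len(lens[i] - 1L)) {
          if (j %% 2L == 1L && length(filler_pool)) {
            toks <- c(toks, sample(filler_pool, 1L))
          } else if (length(syn_pool)) {
            toks <- c(toks, sample(syn_pool, 1L))
          } else {
            toks <- c(toks, sample(filler_pool, 1L))
          }
        }
      }
      rows[[i]] <- tibble::tibble(
        id = sprintf("p%03d", i), item = spec$cue,
        response = paste(toks, collapse = " "),
        serial_position = i)
    }
    do.call(rbind, rows)
  })
}

#' Simulate factor-structured indicator data
#'
#' Draws `x_ij = lambda_j f_i + e_ij` with `f ~ N(0, 1)` and
#' `e_ij ~ N(0, 1 - lambda_j^2)`, so the population covariance is exactly
#' `lambda lambda' + diag(1 - lambda^2)` with unit variances. Used as the
#' ground-truth oracle for factor-recovery tests.
#'
#' @param n rows (>= 50).
#' @param loadings numeric vector of loadings, all `|lambda| < 1`.
#' @param seed integer RNG seed.
#' @return List with `X` (n x p matrix, columns `ind1..indp`) and `factor`
#'   (the true latent values).
#' @export
simulate_factor_data <- function(n, loadings, seed) {
  if (n < 50L) stop("n must be >= 50", call. = FALSE)
  if (any(!is.finite(loadings)) || any(abs(loadings) >= 1))
    stop("all loadings must satisfy |lambda| < 1", call. = FALSE)
  p <- length(loadings)
  with_seed(seed, {
    f <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * p), n, p) %*%
      diag(sqrt(1 - loadings^2), p)
    X <- tcrossprod(f, loadings) + E
    colnames(X) <- paste0("ind", seq_len(p))
    list(X = X, factor = f)
  })
}

#' Write a response table to CSV
#'
#' Inverse of [read_responses()]; missing values become empty cells.
#'
#' @param records tibble/data frame of response records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}
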