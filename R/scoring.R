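#' Additive vector composition
#'
#' Combines token vectors by componentwise summation, the classic additive
#' compositional model. An empty token list yields a missing composition; a
#' sum that cancels exactly to the zero vector is flagged degenerate and
#' also treated as missing (a zero vector has no direction, so no cosine).
#'
#' @param vectors list of numeric vectors sharing one dimension.
#' @return An object of class `composed_vector`: list with `vector`
#'   (numeric or `NULL`), `method`, `n_tokens_used`, `degenerate`.
#' @export
compose_additive <- function(vectors) {
  check_dims(vectors)
  n <- length(vectors)
  if (n == 0L) return(composed(NULL, "additive", 0L, FALSE))
  acc <- vectors[[1]]
  if (n > 1L) for (i in 2:n) acc <- acc + vectors[[i]]
  if (all(acc == 0)) return(composed(NULL, "additive", n, TRUE))
  composed(acc, "additive", n, FALSE)
}

#' Multiplicative (elementwise) vector composition
#'
#' Combines token vectors by elementwise multiplication, the composition
#' model that performs best against human relatedness judgments. The
#' product is accumulated pairwise in input order, renormalizing the
#' accumulator to unit length after each pairwise product: with typical
#' embedding components well below 1 in magnitude, a raw product over tens
#' of tokens underflows to zero, while cosine similarity depends only on
#' direction, so per-step positive rescaling changes no downstream distance.
#' A product with empty support (exact zero accumulator) is degenerate and
#' scored missing.
#'
#' @inheritParams compose_additive
#' @return A `composed_vector`; when non-missing, the vector is unit length.
#' @export
compose_multiplicative <- function(vectors) {
  check_dims(vectors)
  n <- length(vectors)
  if (n == 0L) return(composed(NULL, "multiplicative", 0L, FALSE))
  acc <- vectors[[1]]
  nrm <- sqrt(sum(acc^2))
  if (nrm == 0) return(composed(NULL, "multiplicative", n, TRUE))
  acc <- acc / nrm
  if (n > 1L) for (i in 2:n) {
    acc <- acc * vectors[[i]]
    nrm <- sqrt(sum(acc^2))
    if (nrm == 0) return(composed(NULL, "multiplicative", n, TRUE))
    acc <- acc / nrm
  }
  composed(acc, "multiplicative", n, FALSE)
}

composed <- function(vector, method, n_tokens_used, degenerate) {
  structure(
    list(vector = vector, method = method,
         n_tokens_used = as.integer(n_tokens_used),
         degenerate = isTRUE(degenerate)),
    class = "composed_vector"
  )
}

check_dims <- function(vectors) {
  if (!is.list(vectors))
    stop("`vectors` must be a list of numeric vectors", call. = FALSE)
  if (length(vectors) > 1L) {
    d <- lengths(vectors)
    if (any(d != d[1]))
      stop("dimension mismatch in composition: lengths ",
           paste(unique(d), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

is_missing_composition <- function(cv) {
  is.null(cv$vector) || cv$degenerate
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against floating-point
#' rounding. Zero-norm inputs are an error: callers must route degenerate
#' compositions to missing before reaching the cosine.
#'
#' @param u,v numeric vectors of equal length, both non-zero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("cosine: vectors differ in dimension", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine undefined for a zero-norm vector", call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Semantic distance between a cue and a response in one space
#'
#' The core score: tokens are resolved against the space's vocabulary
#' (out-of-vocabulary tokens dropped word-wise), cue and response are each
#' composed under the chosen model, and the distance is 1 minus the cosine
#' similarity of the two composed vectors. Values therefore lie in
#' `[0, 2]`; larger means more semantically distant, the automated proxy
#' for originality. If either side has no usable tokens or composes to a
#' degenerate zero vector the distance is missing (`NA`), never fabricated.
#'
#' Multi-word cues are composed with the same method as responses.
#'
#' @param space a [semantic_space()].
#' @param cue_tokens,response_tokens character vectors of *cleaned* tokens
#'   (see [clean_text()]).
#' @param method `"multiplicative"` (default, the better-performing model)
#'   or `"additive"`.
#' @return A single numeric distance, or `NA_real_` when missing.
#' @export
semantic_distance <- function(space, cue_tokens, response_tokens,
                              method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  stopifnot(inherits(space, "semantic_space"))
  compose <- if (method == "additive") compose_additive
              else compose_multiplicative
  cue_iv <- resolve_missing(cue_tokens, space)$in_vocab
  res_iv <- resolve_missing(response_tokens, space)$in_vocab
  cue_cv <- compose(lapply(cue_iv, function(w) lookup(space, w)))
  res_cv <- compose(lapply(res_iv, function(w) lookup(space, w)))
  if (is_missing_composition(cue_cv) || is_missing_composition(res_cv))
    return(NA_real_)
  1 - cosine_similarity(cue_cv$vector, res_cv$vector)
}

#' Score a response table against registered semantic spaces
#'
#' The batch driver: cleans each cue/response pair once, then computes the
#' per-space semantic distance for every registered space. One output row
#' per input record; `word_count` is the number of cleaned tokens before
#' the out-of-vocabulary drop (the elaboration measure). Missing scores are
#' `NA`. Deterministic given inputs: scoring the same table twice is
#' bit-identical.
#'
#' @param records data frame with columns `id`, `item`, `response`
#'   (see [read_responses()]).
#' @param spaces named list of [semantic_space()] objects (>= 1).
#' @param method composition model, `"multiplicative"` or `"additive"`.
#' @param config a [cleaning_config()]. When `config$remove_cue` is `TRUE`
#'   and `config$cue_forms` is empty, cue forms default to
#'   [default_cue_forms()] of each row's own item.
#' @return A tibble: `id`, `item`, `response`, `word_count`, then one
#'   `<space>_dis` column per space. Attribute `"oov"` carries a tibble of
#'   dropped out-of-vocabulary tokens (`id`, `item`, `space`, `token`).
#' @export
score_table <- function(records, spaces,
                        method = c("multiplicative", "additive"),
                        config = cleaning_config()) {
  method <- match.arg(method)
  if (!is.list(spaces) || !length(spaces))
    stop("at least one semantic space must be registered", call. = FALSE)
  if (inherits(spaces, "semantic_space")) spaces <- list(spaces)
  if (is.null(names(spaces)) || any(!nzchar(names(spaces))))
    names(spaces) <- vapply(spaces, `[[`, character(1), "name")
  required <- c("id", "item", "response")
  miss <- setdiff(required, names(records))
  if (length(miss))
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(is.na(records$item) | !nzchar(trimws(records$item)))
  if (length(bad))
    stop("malformed record at row ", bad[1], ": empty `item`",
         call. = FALSE)

  n <- nrow(records)
  word_count <- integer(n)
  cue_tok <- vector("list", n)
  res_tok <- vector("list", n)
  cue_cfg <- cleaning_config("basic")  # cues are content words: never
                                       # stop-filtered, never cue-removed
  for (i in seq_len(n)) {
    cfg <- config
    if (cfg$remove_cue && !length(cfg$cue_forms))
      cfg$cue_forms <- default_cue_forms(records$item[i])
    cue_tok[[i]] <- clean_text(records$item[i], cue_cfg)$tokens
    cr <- clean_text(records$response[i], cfg)
    res_tok[[i]] <- cr$tokens
    word_count[i] <- length(cr$tokens)
  }

  out <- tibble::tibble(
    id = as.character(records$id),
    item = records$item,
    response = records$response,
    word_count = word_count
  )
  oov_rows <- list()
  for (sname in names(spaces)) {
    sp <- spaces[[sname]]
    d <- vapply(seq_len(n), function(i)
      semantic_distance(sp, cue_tok[[i]], res_tok[[i]], method = method),
      numeric(1))
    out[[paste0(sname, "_dis")]] <- d
    for (i in seq_len(n)) {
      oov <- resolve_missing(res_tok[[i]], sp)$oov
      if (length(oov))
        oov_rows[[length(oov_rows) + 1L]] <- tibble::tibble(
          id = out$id[i], item = out$item[i], space = sname, token = oov)
    }
  }
  attr(out, "oov") <- if (length(oov_rows)) do.call(rbind, oov_rows)
    else tibble::tibble(id = character(), item = character(),
                        space = character(), token = character())
  attr(out, "method") <- method
  out
}

#' Names of the per-space distance columns in a score table
#' @param scores a tibble from [score_table()].
#' @return Character vector of `<space>_dis` column names.
#' @export
distance_columns <- function(scores) {
  grep("_dis$", names(scores), value = TRUE)
}
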