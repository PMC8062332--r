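#' Cleaning configuration for free-text responses
#'
#' Three cleaning levels are offered. `"none"` lowercases and splits on
#' whitespace only. `"basic"` strips special characters and numbers: every
#' non-alphabetic character becomes a token separator, so hyphenated and
#' contracted words split (`"door-stop"` -> `door`, `stop`; `"don't"` ->
#' `don`, `t`) and numerals are deleted outright, not spelled out. `"stop"`
#' additionally removes stop words using the bundled frozen English list
#' (174 entries, one per line in `extdata/stopwords_english.txt`); the list
#' is frozen because stop-list drift silently changes scores.
#'
#' @param level `"none"`, `"basic"` (default) or `"stop"`.
#' @param remove_cue if `TRUE`, tokens in `cue_forms` are deleted from the
#'   response. Off by default: cue removal is an optional step.
#' @param cue_forms explicit character set of tokens to delete when
#'   `remove_cue` is `TRUE`; build one with [default_cue_forms()]. Entries
#'   are cleaned (lowercase alphabetic) before use.
#' @param stopwords optional character vector overriding the bundled stop
#'   list.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(level = c("basic", "none", "stop"),
                            remove_cue = FALSE, cue_forms = character(),
                            stopwords = NULL) {
  level <- match.arg(level)
  if (is.null(stopwords)) stopwords <- semdis_stopwords()
  stopwords <- unique(tolower(stopwords))
  if (level == "stop" && !length(stopwords))
    stop("level = 'stop' requires a non-empty stop-word list", call. = FALSE)
  cue_forms <- unique(unlist(lapply(as.character(cue_forms), base_tokens)))
  structure(
    list(level = level, remove_cue = isTRUE(remove_cue),
         cue_forms = cue_forms, stopwords = stopwords),
    class = "cleaning_config"
  )
}

#' The bundled English stop-word list
#'
#' A frozen snapshot of the standard 174-entry English stop-word list used
#' by text-mining tools. Shipped as a plain-text file so the exact list a
#' run used is inspectable and stable across versions.
#'
#' @return Character vector of 174 stop words.
#' @export
semdis_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "semdis",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

# lowercase, map every non-alphabetic character to a separator, split,
# drop empty fragments
base_tokens <- function(text) {
  if (length(text) == 0L || is.na(text)) return(character())
  x <- tolower(text)
  x <- gsub("[^a-z]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Clean a free-text response into a token list
#'
#' Deterministically lowercases, tokenizes, and filters a response according
#' to a [cleaning_config()]. Surviving tokens keep their original relative
#' order. Removal counters are populated so that for inputs with no empty
#' fragments `n_raw_tokens = length(tokens) + n_removed_stop +
#' n_removed_cue`.
#'
#' @param text a single free-text string (may be empty or `NA`; both clean
#'   to zero tokens).
#' @param config a [cleaning_config()].
#' @return An object of class `cleaned_response`: a list with `tokens`
#'   (character), `n_raw_tokens`, `n_removed_stop`, `n_removed_cue`.
#' @export
#' @examples
#' clean_text("Use it as a door-stop!!", cleaning_config("basic"))
#' clean_text("Use it as a door-stop!!", cleaning_config("stop"))
clean_text <- function(text, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  toks <- if (config$level == "none") {
    if (length(text) == 0L || is.na(text)) character()
    else {
      t0 <- strsplit(trimws(tolower(text)), "[ \t\r\n]+")[[1]]
      t0[nzchar(t0)]
    }
  } else {
    base_tokens(text)
  }
  n_raw <- length(toks)
  n_stop <- 0L
  if (config$level == "stop") {
    is_stop <- toks %in% config$stopwords
    n_stop <- sum(is_stop)
    toks <- toks[!is_stop]
  }
  n_cue <- 0L
  if (config$remove_cue && length(config$cue_forms)) {
    is_cue <- toks %in% config$cue_forms
    n_cue <- sum(is_cue)
    toks <- toks[!is_cue]
  }
  structure(
    list(tokens = toks, n_raw_tokens = n_raw,
         n_removed_stop = as.integer(n_stop),
         n_removed_cue = as.integer(n_cue)),
    class = "cleaned_response"
  )
}

#' Default cue forms for cue-word removal
#'
#' Cue words and their plurals can bias semantic distance when echoed inside
#' a response ("put things in boxes" for the cue "box"), so an optional
#' cleaning step deletes them. Pluralization here is deliberately naive and
#' transparent: the cleaned cue token plus `+"s"` and `+"es"`. Spurious
#' forms (e.g. `boxs`) are harmless -- they delete nothing. Supply an
#' explicit set via [cleaning_config()] for irregular plurals.
#'
#' @param item the cue text (usually a single word, e.g. `"box"`).
#' @return Character set of tokens to delete, deduplicated.
#' @export
#' @examples
#' default_cue_forms("box")    # box boxs boxes
#' default_cue_forms("Brick!") # brick bricks brickes
default_cue_forms <- function(item) {
  toks <- base_tokens(item)
  if (!length(toks))
    stop("cue item cleans to zero tokens: ", item, call. = FALSE)
  unique(c(toks, paste0(toks, "s"), paste0(toks, "es")))
}

#' Partition cleaned tokens by vocabulary membership
#'
#' Tokens the semantic space does not recognize (misspellings, rare words)
#' are set to missing data at the word level: they are dropped from the
#' composition and their identities logged, while recognized tokens score
#' normally. No spell-checking is attempted.
#'
#' @param tokens character vector of cleaned tokens, or a
#'   [clean_text()] result.
#' @param space a [semantic_space()].
#' @return List with `in_vocab` and `oov` character vectors (order
#'   preserved within each).
#' @export
resolve_missing <- function(tokens, space) {
  if (inherits(tokens, "cleaned_response")) tokens <- tokens$tokens
  if (!length(tokens)) return(list(in_vocab = character(),
                                   oov = character()))
  hit <- in_vocabulary(space, tokens)
  list(in_vocab = tokens[hit], oov = tokens[!hit])
}

#' Read a response table from CSV
#'
#' Required columns: `id`, `item` (the cue text), `response` (free text).
#' Optional: `serial_position`, `timestamp`. One response per row.
#'
#' @param path CSV file path (UTF-8).
#' @return A tibble with the response records; malformed input (missing
#'   required columns, empty cue) raises an error naming the problem.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required <- c("id", "item", "response")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("response CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("serial_position" %in% names(df))
    df$serial_position <- as.integer(df$serial_position)
  if ("timestamp" %in% names(df))
    df$timestamp <- as.numeric(df$timestamp)
  bad <- which(is.na(df$item) | !nzchar(trimws(df$item)))
  if (length(bad))
    stop("empty cue (`item`) in response CSV at data row ", bad[1],
         call. = FALSE)
  df$response[is.na(df$response)] <- ""
  df
}
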