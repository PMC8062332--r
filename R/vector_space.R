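#' Construct a semantic space
#'
#' A semantic space is a named vocabulary-to-vector map of fixed dimension:
#' the in-memory form of a trained word-embedding model (LSA, GloVe, CBOW,
#' or a synthetic toy space). Words are stored lowercased under the default
#' case policy so lookups are case-insensitive.
#'
#' @param vectors numeric matrix, one row per word, with unique rownames
#'   giving the vocabulary.
#' @param name label for the space (e.g. `"glove"`, `"tasa"`, `"cbow_ukwac"`,
#'   or a toy name).
#' @param source_format either `"glove_text"` or `"word2vec_text"`; recorded
#'   for provenance only.
#' @param lowercase if `TRUE` (default), vocabulary and query tokens are
#'   lowercased before matching.
#'
#' @return An object of class `semantic_space` with elements `name`,
#'   `dimension`, `vectors` (the matrix), `source_format`, and `lowercase`.
#' @export
semantic_space <- function(vectors, name, source_format = "glove_text",
                           lowercase = TRUE) {
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop("`vectors` must be a numeric matrix", call. = FALSE)
  if (nrow(vectors) == 0L)
    stop("semantic space must have a non-empty vocabulary", call. = FALSE)
  words <- rownames(vectors)
  if (is.null(words) || any(!nzchar(words)))
    stop("`vectors` must have non-empty rownames (the vocabulary)",
         call. = FALSE)
  if (isTRUE(lowercase)) {
    words <- tolower(words)
    rownames(vectors) <- words
  }
  dup <- words[duplicated(words)]
  if (length(dup))
    stop("duplicate word(s) in vocabulary: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("all vector components must be finite (no NA/NaN/Inf)",
         call. = FALSE)
  source_format <- match.arg(source_format, c("glove_text", "word2vec_text"))
  structure(
    list(name = as.character(name)[1],
         dimension = ncol(vectors),
         vectors = vectors,
         source_format = source_format,
         lowercase = isTRUE(lowercase)),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space '%s': %d words x %d dims, %s%s>\n",
              x$name, nrow(x$vectors), x$dimension, x$source_format,
              if (x$lowercase) ", lowercased" else ""))
  invisible(x)
}

#' Load a word-vector space from a plain-text embedding file
#'
#' Reads the two standard plain-text embedding dialects. `glove_text` files
#' have one entry per line: the word followed by its vector components,
#' whitespace-separated, no header. `word2vec_text` files start with a header
#' line `vocab_count dimension` followed by glove-style rows.
#'
#' Malformed files fail loudly: a row whose component count disagrees with
#' the inferred dimension names the offending line, and duplicate words are
#' an error rather than a silent overwrite (last-wins would corrupt scores
#' irreproducibly).
#'
#' @param path path to the embedding file (UTF-8).
#' @param format `"glove_text"` or `"word2vec_text"`. Default `"auto"`
#'   treats a first line consisting of exactly two integers as a word2vec
#'   header.
#' @param name label for the space; defaults to the file name without
#'   extension.
#' @inheritParams semantic_space
#' @return A [semantic_space()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("box 1 0", "rope 0 1", "brick 1 1"), tf)
#' sp <- load_space(tf, format = "glove_text", name = "toy")
#' lookup(sp, "box")
load_space <- function(path, format = c("auto", "glove_text", "word2vec_text"),
                       name = NULL, lowercase = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("embedding file not found: ", path, call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty embedding file: ", path, call. = FALSE)

  first <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
  looks_w2v <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first))) &&
    all(grepl("^[0-9]+$", first))
  if (format == "auto")
    format <- if (looks_w2v) "word2vec_text" else "glove_text"

  header_offset <- 0L
  declared_count <- NA_integer_
  dim <- NA_integer_
  if (format == "word2vec_text") {
    if (!looks_w2v)
      stop("word2vec_text file must begin with a header line 'count dim': ",
           path, call. = FALSE)
    declared_count <- as.integer(first[1])
    dim <- as.integer(first[2])
    header_offset <- 1L
    lines <- lines[-1L]
    if (length(lines) == 0L)
      stop("word2vec_text file has a header but no vectors: ", path,
           call. = FALSE)
  }

  toks <- strsplit(trimws(lines), "[ \t]+")
  if (is.na(dim)) {
    dim <- length(toks[[1]]) - 1L
    if (dim < 1L)
      stop(sprintf("format error at line 1 of %s: no vector components",
                   path), call. = FALSE)
  }
  lens <- lengths(toks)
  bad <- which(lens != dim + 1L)
  if (length(bad))
    stop(sprintf(
      "format error at line %d of %s: expected %d components, found %d",
      bad[1] + header_offset, path, dim, lens[bad[1]] - 1L), call. = FALSE)

  words <- vapply(toks, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(toks, `[`, -1L), use.names = FALSE)))
  if (anyNA(vals)) {
    row_of <- function(i) ceiling(i / dim)
    stop(sprintf("format error at line %d of %s: non-numeric component",
                 row_of(which(is.na(vals))[1]) + header_offset, path),
         call. = FALSE)
  }
  mat <- matrix(vals, nrow = length(words), ncol = dim, byrow = TRUE)
  rownames(mat) <- words
  if (!is.na(declared_count) && declared_count != nrow(mat))
    warning(sprintf("word2vec header declares %d words but file has %d",
                    declared_count, nrow(mat)), call. = FALSE)
  semantic_space(mat, name = name, source_format = format,
                 lowercase = lowercase)
}

#' Write a semantic space to a plain-text embedding file
#'
#' Components are written at full precision (17 significant digits) so that
#' a write/reload round trip reproduces every vector bit-identically.
#'
#' @param space a [semantic_space()].
#' @param path output file path.
#' @param format `"glove_text"` (no header) or `"word2vec_text"`
#'   (`count dim` header line).
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path,
                        format = c("glove_text", "word2vec_text")) {
  stopifnot(inherits(space, "semantic_space"))
  format <- match.arg(format)
  m <- space$vectors
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1))
  if (format == "word2vec_text")
    rows <- c(paste(nrow(m), ncol(m)), rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Look up a word's vector in a semantic space
#'
#' Exact (case-normalized) match only; out-of-vocabulary tokens return
#' `NULL`, which downstream code treats as missing data. There is no fuzzy
#' or subword matching.
#'
#' @param space a [semantic_space()].
#' @param word a single non-empty token.
#' @return The stored numeric vector, or `NULL` if the word is not in the
#'   vocabulary.
#' @export
lookup <- function(space, word) {
  stopifnot(inherits(space, "semantic_space"))
  if (length(word) != 1L || is.na(word) || !nzchar(word))
    stop("`word` must be a single non-empty token", call. = FALSE)
  if (space$lowercase) word <- tolower(word)
  i <- match(word, rownames(space$vectors))
  if (is.na(i)) return(NULL)
  space$vectors[i, ]
}

#' Test vocabulary membership for a vector of tokens
#'
#' @param space a [semantic_space()].
#' @param words character vector of tokens.
#' @return Logical vector: `TRUE` where the token is in vocabulary.
#' @export
in_vocabulary <- function(space, words) {
  stopifnot(inherits(space, "semantic_space"))
  if (space$lowercase) words <- tolower(words)
  words %in% rownames(space$vectors)
}

#' Read a space manifest and load the listed spaces
#'
#' The manifest is a plain-text key/value file registering 1..k semantic
#' spaces, one per line: `slot_name = path/to/embeddings.txt`. Blank lines
#' and lines starting with `#` are ignored. Relative paths resolve against
#' the manifest's directory. File format (glove vs word2vec text) is
#' auto-detected per file.
#'
#' @param path manifest file path.
#' @param lowercase passed through to [load_space()].
#' @return Named list of [semantic_space()] objects, in manifest order.
#' @export
load_space_manifest <- function(path, lowercase = TRUE) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("manifest registers no spaces: ", path, call. = FALSE)
  parts <- regmatches(lines, regexec("^([^=]+)=(.+)$", lines))
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed manifest line (expected 'name = path'): ",
         lines[bad[1]], call. = FALSE)
  nms <- trimws(vapply(parts, `[[`, character(1), 2L))
  paths <- trimws(vapply(parts, `[[`, character(1), 3L))
  if (anyDuplicated(nms))
    stop("duplicate space name in manifest: ",
         nms[duplicated(nms)][1], call. = FALSE)
  base <- dirname(normalizePath(path))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                  file.path(base, paths))
  spaces <- lapply(seq_along(nms), function(i)
    load_space(paths[i], name = nms[i], lowercase = lowercase))
  names(spaces) <- nms
  spaces
}
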