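# BIO corpus container and CoNLL-style reader/writer.
#
# A corpus is a tibble with one row per token and columns:
#   sentence  integer sentence index (1-based, consecutive)
#   token     character surface form (non-empty, no whitespace)
#   tag       character, "O" or "<B|I>-<type>"
# carrying class "bio_corpus". Tags are case-sensitive throughout.

TAG_PATTERN <- "^(O|[BI]-\\S+)$"

#' Construct a BIO corpus from token-level vectors
#'
#' A `bio_corpus` is a tibble with one row per token and columns `sentence`
#' (integer sentence index), `token` (surface form) and `tag` (`"O"` or a
#' `B-`/`I-`-prefixed entity tag). It is the container all scoring and
#' macrofactor computations consume.
#'
#' @param sentence Integer vector of sentence indices (non-decreasing values
#'   are renumbered to consecutive 1-based indices).
#' @param token Character vector of token surface forms. Tokens must be
#'   non-empty and contain no whitespace.
#' @param tag Character vector of BIO tags, `"O"` or `"B-<type>"`/`"I-<type>"`.
#' @return A `bio_corpus` tibble.
#' @examples
#' bio_corpus(c(1, 1, 1), c("IL-2", "gene", "expression"), c("B-DNA", "I-DNA", "O"))
#' @export
bio_corpus <- function(sentence = integer(), token = character(), tag = character()) {
  stopifnot(length(sentence) == length(token), length(token) == length(tag))
  sentence <- as.integer(sentence)
  validate_tokens(token)
  validate_tags(tag)
  if (length(sentence) > 0L) {
    if (any(diff(sentence) < 0L)) {
      stop("sentence indices must be non-decreasing", call. = FALSE)
    }
    sentence <- cumsum(c(1L, diff(sentence) != 0L))
  }
  out <- tibble::tibble(sentence = sentence, token = token, tag = tag)
  class(out) <- c("bio_corpus", class(out))
  out
}

validate_tokens <- function(token, line = NULL) {
  bad <- which(is.na(token) | nchar(token) == 0L | grepl("\\s", token))
  if (length(bad) > 0L) {
    where <- if (is.null(line)) paste("token", bad[1L]) else paste("line", line[bad[1L]])
    stop("empty or whitespace-containing token at ", where, call. = FALSE)
  }
  invisible(token)
}

validate_tags <- function(tag, line = NULL) {
  bad <- which(is.na(tag) | !grepl(TAG_PATTERN, tag))
  if (length(bad) > 0L) {
    where <- if (is.null(line)) paste("position", bad[1L]) else paste("line", line[bad[1L]])
    stop(
      "malformed tag ", encodeString(tag[bad[1L]], quote = '"'), " at ", where,
      ': expected "O" or "B-<type>"/"I-<type>"',
      call. = FALSE
    )
  }
  invisible(tag)
}

#' @export
print.bio_corpus <- function(x, ...) {
  cat(
    "<bio_corpus> ", n_sentences(x), " sentence(s), ", nrow(x), " token(s), ",
    length(corpus_tagset(x)), " distinct entity tag(s)\n",
    sep = ""
  )
  NextMethod()
}

#' Number of sentences in a corpus
#' @param corpus A `bio_corpus`.
#' @return Integer sentence count.
#' @export
n_sentences <- function(corpus) {
  if (nrow(corpus) == 0L) 0L else max(corpus$sentence)
}

#' Distinct non-O tags observed in a corpus
#' @param corpus A `bio_corpus`.
#' @return Sorted character vector of entity tags (the `O` tag is excluded).
#' @export
corpus_tagset <- function(corpus) {
  sort(setdiff(unique(corpus$tag), "O"))
}

#' Read a CoNLL-style BIO-annotated corpus
#'
#' Parses a token-per-line file: whitespace-delimited columns, blank lines
#' separating sentences, lines starting with `#` skipped as comments. Files
#' are read as UTF-8. The column layout is configurable because CoNLL
#' dialects differ; by default the first column is the token and the last
#' column the tag.
#'
#' @param source Path to a file, or a character vector of lines (useful for
#'   tests and inline examples).
#' @param token_column 1-based index of the token column.
#' @param tag_column 1-based index of the tag column, or `NULL` for the last
#'   column.
#' @return A [bio_corpus()].
#' @examples
#' read_conll(c("immunoglobulin B-DNA", "( I-DNA", "Ig I-DNA", ") I-DNA", ""))
#' @export
read_conll <- function(source, token_column = 1L, tag_column = NULL) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(source)
  }
  lineno <- seq_along(lines)
  keep <- !startsWith(trimws(lines, "left"), "#")
  lines <- lines[keep]
  lineno <- lineno[keep]

  blank <- trimws(lines) == ""
  # sentence id = running count of preceding blank separators
  sent_of_line <- cumsum(blank) + 1L
  data_idx <- which(!blank)
  if (length(data_idx) == 0L) {
    return(bio_corpus())
  }
  fields <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(
      "ragged columns at line ", lineno[data_idx[bad]],
      ": expected ", nf[1L], " field(s), found ", nf[bad],
      call. = FALSE
    )
  }
  tag_column <- if (is.null(tag_column)) nf[1L] else as.integer(tag_column)
  if (token_column > nf[1L] || tag_column > nf[1L]) {
    stop("requested column exceeds the ", nf[1L], " field(s) present", call. = FALSE)
  }
  mat <- matrix(unlist(fields), ncol = nf[1L], byrow = TRUE)
  token <- mat[, token_column]
  tag <- mat[, tag_column]
  validate_tokens(token, line = lineno[data_idx])
  validate_tags(tag, line = lineno[data_idx])
  bio_corpus(sentence = sent_of_line[data_idx], token = token, tag = tag)
}

#' Write a corpus in CoNLL-style BIO format
#'
#' One `token<TAB>tag` line per token, one blank line after every sentence.
#' `read_conll()` on the output reproduces the corpus exactly.
#'
#' @param corpus A `bio_corpus`.
#' @param path Output file path, or `NULL` to return the lines invisibly
#'   without writing.
#' @return Invisibly, the character vector of lines written.
#' @export
write_conll <- function(corpus, path = NULL) {
  lines <- character(0)
  if (nrow(corpus) > 0L) {
    per_sent <- split(paste0(corpus$token, "\t", corpus$tag), corpus$sentence)
    lines <- unlist(lapply(per_sent, function(x) c(x, "")), use.names = FALSE)
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(lines)
}

# Run-length phrase decomposition of one sentence's tag vector.
# Returns integer start positions (1-based), ends (inclusive) and types.
# Orphan I- tags (no preceding B/I of the same type) start a new phrase, so
# every non-O token belongs to exactly one phrase; an I-Y directly after an
# X phrase closes X and opens Y.
phrase_spans <- function(tags) {
  n <- length(tags)
  starts <- integer(0)
  ends <- integer(0)
  types <- character(0)
  cur_type <- NA_character_
  cur_start <- NA_integer_
  flush <- function(i) {
    if (!is.na(cur_start)) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- i
      types[[length(types) + 1L]] <<- cur_type
    }
  }
  for (i in seq_len(n)) {
    t <- tags[i]
    if (t == "O") {
      flush(i - 1L)
      cur_type <- NA_character_
      cur_start <- NA_integer_
    } else {
      prefix <- substr(t, 1L, 1L)
      type <- substring(t, 3L)
      if (prefix == "B" || is.na(cur_type) || type != cur_type) {
        flush(i - 1L)
        cur_type <- type
        cur_start <- i
      }
    }
  }
  flush(n)
  list(start = starts, end = ends, type = types)
}

#' Extract entity phrases from a corpus
#'
#' An entity phrase is a maximal contiguous run of tokens annotated with one
#' entity type: one `B-X` token followed by zero or more `I-X` tokens. Orphan
#' `I-X` tags (not preceded by a tag of type X) start a new phrase, so every
#' non-O token — including symbols such as parentheses tagged inside a phrase
#' — belongs to exactly one phrase.
#'
#' @param corpus A `bio_corpus`.
#' @return A tibble with one row per phrase: `sentence`, `start` and `end`
#'   (1-based inclusive token offsets within the sentence), `entity_type`,
#'   `n_tokens` (the phrase's entity word count), and `surface` (member
#'   tokens joined by single spaces), ordered by sentence then start.
#' @examples
#' co <- read_conll(c("immunoglobulin B-DNA", "( I-DNA", "Ig I-DNA", ") I-DNA", ""))
#' extract_phrases(co)
#' @export
extract_phrases <- function(corpus) {
  empty <- tibble::tibble(
    sentence = integer(), start = integer(), end = integer(),
    entity_type = character(), n_tokens = integer(), surface = character()
  )
  if (nrow(corpus) == 0L) {
    return(empty)
  }
  out <- lapply(split(corpus, corpus$sentence), function(s) {
    sp <- phrase_spans(s$tag)
    if (length(sp$start) == 0L) {
      return(NULL)
    }
    tibble::tibble(
      sentence = s$sentence[1L],
      start = sp$start,
      end = sp$end,
      entity_type = sp$type,
      n_tokens = sp$end - sp$start + 1L,
      surface = vapply(
        seq_along(sp$start),
        function(i) paste(s$token[sp$start[i]:sp$end[i]], collapse = " "),
        character(1)
      )
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) empty else out
}
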