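# The six macrofactor metrics.
#
# Per entity word: sLen (character length of the containing sentence),
# eLen (character length of the containing entity phrase), eNum (entity
# words in the phrase, counting the B- token and its I- continuations as
# one run), eDen = eLen / sLen, elCon (label-consistency weight omega =
# 1 / number of distinct tags the term carries anywhere in the corpus).
# Per entity type or tag: tEWC, the total entity word count.
#
# String lengths count characters of the single-space token join, including
# the internal spaces; the corpora are tokenized, so original spacing is
# unrecoverable and the join is the documented convention.

#' Canonical macrofactor names
#'
#' The six macrofactors in canonical order. This order is also the
#' tie-breaking order inside the elimination layers of [run_mfe()].
#' @return `c("sLen", "eLen", "eNum", "eDen", "tEWC", "elCon")`
#' @export
mf_factor_names <- function() {
  c("sLen", "eLen", "eNum", "eDen", "tEWC", "elCon")
}

#' Sentence string length (sLen)
#'
#' Character length of the sentence rendered as its tokens joined by single
#' spaces: the sum of token lengths plus one per gap. Quantifies the
#' contextual space in which entities appear.
#'
#' @param tokens Character vector of the sentence's token surfaces.
#' @return Integer character count.
#' @examples
#' sentence_length(c("IL-2", "binds", "receptor")) # 19
#' @export
sentence_length <- function(tokens) {
  if (length(tokens) == 0L) {
    stop("cannot compute the length of an empty sentence", call. = FALSE)
  }
  sum(nchar(tokens)) + (length(tokens) - 1L)
}

#' Catalog corpus terms with their entity tags and consistency weight
#'
#' Every distinct non-O token surface is cataloged with the set of tags it
#' carries anywhere in the corpus. The entity-label-consistency weight is
#' omega = 1/k where k is the number of distinct tags: a term used under a
#' single tag weighs 1, a term seen under two tags (e.g. both `B-cell_type`
#' and `I-cell_type`) weighs 0.5, and so on. Low omega flags terms whose
#' labeling is inconsistent across contexts, which tend to be harder to
#' predict.
#'
#' Distinct tags are counted at full-tag granularity (B-X and I-X are two
#' tags). Term identity is the exact token surface; set `case_fold = TRUE`
#' to catalog case-insensitively.
#'
#' @param corpus A `bio_corpus`.
#' @param case_fold Lower-case token surfaces before cataloging?
#' @return A tibble with `term`, `tags` (list column of distinct tags),
#'   `n_tags`, and `omega = 1/n_tags`.
#' @export
build_term_catalog <- function(corpus, case_fold = FALSE) {
  ent <- corpus[corpus$tag != "O", , drop = FALSE]
  if (nrow(ent) == 0L) {
    return(tibble::tibble(
      term = character(), tags = list(), n_tags = integer(), omega = numeric()
    ))
  }
  term <- if (case_fold) tolower(ent$token) else ent$token
  tag_sets <- lapply(split(ent$tag, term), function(x) sort(unique(x)))
  k <- unname(lengths(tag_sets))
  tibble::tibble(
    term = names(tag_sets),
    tags = unname(tag_sets),
    n_tags = k,
    omega = 1 / k
  )
}

#' Per-entity-word macrofactor rows
#'
#' Emits one row per non-O token (entity word). Each row inherits the
#' sentence's sLen, its phrase's eLen/eNum/eDen, and its own term's omega as
#' elCon. Symbols such as parentheses tagged inside a phrase are entity
#' words like any other.
#'
#' @param corpus A `bio_corpus`.
#' @param catalog Optional term catalog from [build_term_catalog()]; built
#'   from `corpus` when `NULL`.
#' @param case_fold Passed to [build_term_catalog()] when the catalog is
#'   built here; must match the catalog's setting otherwise.
#' @return A tibble with one row per entity word: `sentence`, `position`
#'   (token offset within the sentence), `token`, `tag`, `entity_type`,
#'   `sLen`, `eLen`, `eNum`, `eDen`, `elCon`.
#' @export
entity_word_rows <- function(corpus, catalog = NULL, case_fold = FALSE) {
  if (is.null(catalog)) {
    catalog <- build_term_catalog(corpus, case_fold = case_fold)
  }
  empty <- tibble::tibble(
    sentence = integer(), position = integer(), token = character(),
    tag = character(), entity_type = character(),
    sLen = integer(), eLen = integer(), eNum = integer(),
    eDen = numeric(), elCon = numeric()
  )
  phrases <- extract_phrases(corpus)
  if (nrow(phrases) == 0L) {
    return(empty)
  }
  slen <- vapply(split(corpus$token, corpus$sentence), sentence_length, numeric(1))
  omega <- stats::setNames(catalog$omega, catalog$term)

  pos_in_sentence <- stats::ave(
    seq_len(nrow(corpus)), corpus$sentence,
    FUN = seq_along
  )
  rows <- lapply(seq_len(nrow(phrases)), function(i) {
    ph <- phrases[i, ]
    idx <- which(corpus$sentence == ph$sentence)[ph$start:ph$end]
    e_len <- nchar(ph$surface)
    s_len <- slen[[as.character(ph$sentence)]]
    term <- if (isTRUE(case_fold)) tolower(corpus$token[idx]) else corpus$token[idx]
    tibble::tibble(
      sentence = ph$sentence,
      position = pos_in_sentence[idx],
      token = corpus$token[idx],
      tag = corpus$tag[idx],
      entity_type = ph$entity_type,
      sLen = as.integer(s_len),
      eLen = as.integer(e_len),
      eNum = ph$n_tokens,
      eDen = e_len / s_len,
      elCon = unname(omega[term])
    )
  })
  dplyr::bind_rows(rows)
}

#' Parse a trim-policy string
#'
#' `"tukey"` drops values outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; `"pct:<p>"` drops the lowest and highest
#' p percent (default `pct:5`); `"none"` keeps everything. The published
#' aggregate macrofactor means exclude extreme values without pinning the
#' rule down, so the rule is a documented, configurable convention.
#'
#' @param policy Policy string.
#' @return A list with `kind` and, for percentile trimming, `p`.
#' @export
trim_policy <- function(policy = "tukey") {
  if (is.list(policy)) {
    return(policy)
  }
  if (identical(policy, "tukey")) {
    return(list(kind = "tukey"))
  }
  if (identical(policy, "none")) {
    return(list(kind = "none"))
  }
  if (grepl("^pct(:[0-9.]+)?$", policy)) {
    p <- if (grepl(":", policy)) as.numeric(sub("^pct:", "", policy)) else 5
    if (is.na(p) || p < 0 || p >= 50) {
      stop("percentile trim fraction must be in [0, 50)", call. = FALSE)
    }
    return(list(kind = "pct", p = p))
  }
  stop("unknown trim policy: ", policy, call. = FALSE)
}

# Keep the values that survive trimming; fall back to all values (with a
# warning) should the rule trim everything.
trim_values <- function(x, policy) {
  policy <- trim_policy(policy)
  keep <- switch(policy$kind,
    none = rep(TRUE, length(x)),
    tukey = {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
    },
    pct = {
      q <- stats::quantile(x, c(policy$p / 100, 1 - policy$p / 100), names = FALSE, type = 7)
      x >= q[1] & x <= q[2]
    }
  )
  if (!any(keep)) {
    warning("trim policy removed every value in a group; using untrimmed mean", call. = FALSE)
    keep <- rep(TRUE, length(x))
  }
  x[keep]
}

#' Aggregate macrofactors per entity tag or type
#'
#' Trimmed means of sLen, eLen, eNum, eDen and elCon per group, plus the
#' group's total entity word count (tEWC). Trimming guards the means against
#' extreme values; tEWC is always the untrimmed group size, since it is a
#' count, not a mean.
#'
#' @param rows Entity-word rows from [entity_word_rows()].
#' @param level `"tag"` groups by full tag (B-X and I-X separately, matching
#'   per-tag F1 reporting); `"type"` groups by entity type for trend
#'   summaries.
#' @param trim A trim policy string or [trim_policy()] object.
#' @return A tibble with one row per group: the grouping column (`tag` or
#'   `entity_type`), `mean_sLen`, `mean_eLen`, `mean_eNum`, `mean_eDen`,
#'   `mean_elCon`, and `tEWC`.
#' @export
aggregate_by_type <- function(rows, level = c("tag", "type"), trim = "tukey") {
  level <- match.arg(level)
  key <- if (level == "tag") "tag" else "entity_type"
  policy <- trim_policy(trim)
  groups <- split(rows, rows[[key]])
  out <- lapply(names(groups), function(g) {
    gr <- groups[[g]]
    tmean <- function(x) mean(trim_values(x, policy))
    tibble::tibble(
      group = g,
      mean_sLen = tmean(gr$sLen),
      mean_eLen = tmean(gr$eLen),
      mean_eNum = tmean(gr$eNum),
      mean_eDen = tmean(gr$eDen),
      mean_elCon = tmean(gr$elCon),
      tEWC = nrow(gr)
    )
  })
  out <- dplyr::bind_rows(out)
  names(out)[names(out) == "group"] <- key
  out
}
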