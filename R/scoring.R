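# Token-level per-tag scoring with leveraged micro/macro averages.
#
# Scoring is deliberately token-level per full tag (B-X and I-X are separate
# classes) rather than phrase-level exact-span matching: per-tag F1 is what
# the macrofactor dataset uses as its label, and B-/I- tags are reported
# separately throughout.

#' Score predicted BIO tags against gold annotations
#'
#' Computes a per-tag confusion summary over aligned token streams. A token
#' counts as a true positive for tag `t` when gold = pred = `t`, a false
#' positive for `t` when pred = `t` but gold differs, and a false negative
#' for `t` when gold = `t` but pred differs. The `O` tag is never scored as
#' a class of its own and is excluded from both averages.
#'
#' Precision and recall follow the 0/0 = 0 convention, so a tag present in
#' gold but never predicted scores F1 = 0 rather than dropping out of the
#' macro average.
#'
#' @param gold Gold-standard `bio_corpus`.
#' @param pred Predicted `bio_corpus`, token-aligned with `gold` (same
#'   sentence structure and token surfaces).
#' @return An object of class `ner_score`: a list with `rows` (tibble of
#'   `tag`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, one row per non-O
#'   tag occurring in gold or pred), `avg_micro` (F1 of pooled counts) and
#'   `avg_macro` (unweighted mean of per-tag F1). When neither corpus
#'   contains an entity tag both averages are 0 by convention.
#' @examples
#' gold <- bio_corpus(rep(1, 4), c("a", "b", "c", "d"), c("B-X", "B-X", "O", "B-Y"))
#' pred <- bio_corpus(rep(1, 4), c("a", "b", "c", "d"), c("B-X", "B-Y", "O", "B-Y"))
#' score_tags(gold, pred)
#' @export
score_tags <- function(gold, pred) {
  check_aligned(gold, pred)
  g <- gold$tag
  p <- pred$tag
  tags <- sort(union(setdiff(unique(g), "O"), setdiff(unique(p), "O")))
  tp <- fp <- fn <- integer(length(tags))
  for (i in seq_along(tags)) {
    t <- tags[i]
    tp[i] <- sum(g == t & p == t)
    fp[i] <- sum(p == t & g != t)
    fn[i] <- sum(g == t & p != t)
  }
  rows <- tibble::tibble(
    tag = tags, tp = tp, fp = fp, fn = fn,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = f1_from_counts(tp, fp, fn)
  )
  structure(
    list(
      rows = rows,
      # all-O degenerate pair: both averages 0 by documented convention
      avg_micro = if (nrow(rows) == 0L) 0 else micro_average(rows),
      avg_macro = if (nrow(rows) == 0L) 0 else macro_average(rows)
    ),
    class = "ner_score"
  )
}

check_aligned <- function(gold, pred) {
  if (nrow(gold) != nrow(pred)) {
    stop(
      "gold and pred are not aligned: ", nrow(gold), " vs ", nrow(pred),
      " tokens",
      call. = FALSE
    )
  }
  div <- which(gold$sentence != pred$sentence | gold$token != pred$token)
  if (length(div) > 0L) {
    i <- div[1L]
    stop(
      "gold and pred diverge at token ", i, " (sentence ", gold$sentence[i],
      "): ", encodeString(gold$token[i], quote = '"'), " vs ",
      encodeString(pred$token[i], quote = '"'),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

f1_from_counts <- function(tp, fp, fn) {
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Micro-averaged F1 over per-tag count rows
#'
#' Pools true positives, false positives and false negatives across all tags
#' and computes a single F1 from the summed counts. This is the leveraged
#' AVG_MICRO summary: it weights every entity token equally, so abundant
#' tags dominate.
#'
#' @param rows A tibble with `tp`, `fp`, `fn` columns (as in
#'   `score_tags()$rows`).
#' @return Pooled F1 in `[0, 1]`; 0 with a warning for an empty row set.
#' @export
micro_average <- function(rows) {
  if (nrow(rows) == 0L) {
    warning("no entity tags to average; returning 0", call. = FALSE)
    return(0)
  }
  f1_from_counts(sum(rows$tp), sum(rows$fp), sum(rows$fn))
}

#' Macro-averaged F1 over per-tag rows
#'
#' The unweighted mean of per-tag F1 values — the leveraged AVG_MACRO
#' summary. Every tag counts equally regardless of frequency, so rare entity
#' types are not swamped by abundant ones.
#'
#' @param rows A tibble with an `f1` column (as in `score_tags()$rows`).
#' @return Mean F1 in `[0, 1]`; 0 with a warning for an empty row set.
#' @export
macro_average <- function(rows) {
  if (nrow(rows) == 0L) {
    warning("no entity tags to average; returning 0", call. = FALSE)
    return(0)
  }
  mean(rows$f1)
}

#' @export
print.ner_score <- function(x, ...) {
  cat("<ner_score> ", nrow(x$rows), " tag(s)\n", sep = "")
  print(x$rows, n = Inf)
  cat(sprintf("AVG_MICRO %.4f  AVG_MACRO %.4f\n", x$avg_micro, x$avg_macro))
  invisible(x)
}

#' Write a score table to a delimited file
#'
#' @param score A `ner_score` object.
#' @param path Output path.
#' @param format `"tsv"` for a tab-separated table with `#AVG_MICRO` /
#'   `#AVG_MACRO` footer comments, or `"json"` for a structured object.
#' @return Invisibly, `score`.
#' @export
write_score_table <- function(score, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(
        rows = score$rows,
        avg_micro = score$avg_micro,
        avg_macro = score$avg_macro
      ),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    body <- c(
      paste(c("tag", "tp", "fp", "fn", "precision", "recall", "f1"), collapse = "\t"),
      sprintf(
        "%s\t%d\t%d\t%d\t%s\t%s\t%s",
        score$rows$tag, score$rows$tp, score$rows$fp, score$rows$fn,
        format_num(score$rows$precision), format_num(score$rows$recall),
        format_num(score$rows$f1)
      ),
      paste0("#AVG_MICRO\t", format_num(score$avg_micro)),
      paste0("#AVG_MACRO\t", format_num(score$avg_macro))
    )
    writeLines(body, path, useBytes = TRUE)
  }
  invisible(score)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE), character(1))
}

#' Read a per-tag F1 table
#'
#' Accepts the scorer's TSV output directly (comment footer lines are
#' skipped), or any tab-delimited table with `tag` and `f1` columns.
#'
#' @param path Path to a delimited table.
#' @return Named numeric vector of F1 values keyed by tag.
#' @export
read_f1_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("tag", "f1") %in% names(df))) {
    stop("F1 table must have 'tag' and 'f1' columns", call. = FALSE)
  }
  stats::setNames(as.numeric(df$f1), df$tag)
}
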