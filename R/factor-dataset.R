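# Supervised macrofactor dataset: one row per entity word, the six
# macrofactors as features, and the per-tag F1 of a chosen model as label.

#' Assemble a macrofactor dataset from a corpus and a per-tag F1 table
#'
#' Emits one row per entity word with the raw (untrimmed) per-word values of
#' sLen, eLen, eNum, eDen and elCon, the tag's total entity word count
#' (tEWC, constant within a tag but carried per row because the elimination
#' algorithm consumes it as an ordinary feature), and the tag's F1 as the
#' supervised label. Trimming applies only to reported aggregates, never to
#' these rows.
#'
#' @param corpus A `bio_corpus`.
#' @param f1_table Named numeric vector of per-tag F1 values (e.g. from
#'   [read_f1_table()] or `score_tags()$rows` via
#'   `setNames(rows$f1, rows$tag)`).
#' @param on_missing What to do when a corpus tag has no F1 entry:
#'   `"error"` (default) or `"drop"` (drop the rows, with a message).
#' @param case_fold Passed to [build_term_catalog()].
#' @param provenance Optional character note recorded on the dataset.
#' @return A `macrofactor_dataset`: a tibble with columns `sLen`, `eLen`,
#'   `eNum`, `eDen`, `tEWC`, `elCon`, `tag`, `label`, in corpus order, with
#'   attributes `factor_names` and `provenance`.
#' @export
build_factor_dataset <- function(corpus, f1_table,
                                 on_missing = c("error", "drop"),
                                 case_fold = FALSE,
                                 provenance = NULL) {
  on_missing <- match.arg(on_missing)
  rows <- entity_word_rows(corpus, case_fold = case_fold)
  missing <- setdiff(unique(rows$tag), names(f1_table))
  if (length(missing) > 0L) {
    if (on_missing == "error") {
      stop(
        "no F1 entry for tag(s): ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    message(
      "dropping ", sum(rows$tag %in% missing), " row(s) for unlabeled tag(s): ",
      paste(missing, collapse = ", ")
    )
    rows <- rows[!rows$tag %in% missing, , drop = FALSE]
  }
  tewc <- table(rows$tag)
  out <- tibble::tibble(
    sLen = as.numeric(rows$sLen),
    eLen = as.numeric(rows$eLen),
    eNum = as.numeric(rows$eNum),
    eDen = rows$eDen,
    tEWC = as.numeric(tewc[rows$tag]),
    elCon = rows$elCon,
    tag = rows$tag,
    label = unname(f1_table[rows$tag])
  )
  new_macrofactor_dataset(out, provenance = provenance)
}

new_macrofactor_dataset <- function(df, provenance = NULL) {
  needed <- c(mf_factor_names(), "tag", "label")
  stopifnot(all(needed %in% names(df)))
  structure(
    df,
    factor_names = mf_factor_names(),
    provenance = provenance,
    class = c("macrofactor_dataset", class(tibble::tibble()))
  )
}

#' @export
print.macrofactor_dataset <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(
    "<macrofactor_dataset> ", nrow(x), " entity word(s), ",
    length(unique(x$tag)), " tag(s)",
    if (!is.null(prov)) paste0(" [", prov, "]"), "\n",
    sep = ""
  )
  NextMethod()
}

#' Pick the best-scoring model from a set of score tables
#'
#' Selects the model with the highest micro-averaged F1; ties break by
#' macro-averaged F1, then by name order. Used to choose, per model
#' category, whose per-tag F1 values label the macrofactor dataset.
#'
#' @param score_tables Named list of `ner_score` objects, one per model.
#' @return The name of the winning model.
#' @export
pick_best_model <- function(score_tables) {
  if (length(score_tables) == 0L || is.null(names(score_tables))) {
    stop("score_tables must be a non-empty named list", call. = FALSE)
  }
  micro <- vapply(score_tables, function(s) s$avg_micro, numeric(1))
  macro <- vapply(score_tables, function(s) s$avg_macro, numeric(1))
  ord <- order(-micro, -macro, names(score_tables))
  names(score_tables)[ord[1L]]
}

#' Write a macrofactor dataset as a delimited table
#'
#' Tab-separated with a header of the six factors, `tag` and `label`.
#' Rebuilding and rewriting from the same inputs is byte-identical.
#'
#' @param dataset A `macrofactor_dataset`.
#' @param path Output path.
#' @return Invisibly, `dataset`.
#' @export
write_factor_dataset <- function(dataset, path) {
  cols <- c(mf_factor_names(), "tag", "label")
  df <- as.data.frame(dataset)[, cols]
  lines <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(lapply(df, function(x) {
      if (is.numeric(x)) format_num(x) else x
    }), sep = "\t"))
  )
  if (nrow(df) == 0L) lines <- lines[1L]
  writeLines(lines, path, useBytes = TRUE)
  invisible(dataset)
}

#' Read a macrofactor dataset written by [write_factor_dataset()]
#'
#' @param path Path to the table.
#' @return A `macrofactor_dataset`.
#' @export
read_factor_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_macrofactor_dataset(tibble::as_tibble(df), provenance = path)
}
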