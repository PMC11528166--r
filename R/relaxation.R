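# Categorical relaxation: merge fine-grained entity types into broader
# categories (e.g. DNA/RNA/protein -> Macromolecule) and re-score.
# B/I prefixes are preserved through merging; predictions are re-mapped
# post hoc, not re-trained.

#' Read a label-merge mapping file
#'
#' Two whitespace-delimited columns — source entity type, merged entity
#' type — with `#` comment lines skipped. Types not listed pass through
#' unchanged.
#'
#' @param path Path to the mapping file.
#' @return A named character vector: `mapping[source] = merged`.
#' @export
read_merge_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(trimws(lines, "left"), "#") & trimws(lines) != ""]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop("mapping line ", bad[1L], " does not have exactly two columns", call. = FALSE)
  }
  mapping <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L),
    vapply(fields, `[[`, character(1), 1L)
  )
  validate_merge_map(mapping)
}

validate_merge_map <- function(mapping) {
  if (length(mapping) == 0L) {
    return(mapping)
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("merge mapping must be a named character vector", call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    stop("duplicate source type in merge mapping", call. = FALSE)
  }
  if ("O" %in% names(mapping) || "O" %in% mapping) {
    stop('the "O" tag cannot take part in a merge mapping', call. = FALSE)
  }
  # single-step mapping: a merged target may not itself be remapped further,
  # except as the identity (Disease -> Disease is fine)
  chained <- setdiff(intersect(unname(mapping), names(mapping)),
                     names(mapping)[mapping == names(mapping)])
  if (length(chained) > 0L) {
    stop(
      "merged type ", encodeString(chained[1L], quote = '"'),
      " is itself a source key; mappings must be single-step",
      call. = FALSE
    )
  }
  mapping
}

#' Built-in merge mappings for the three evaluation corpora
#'
#' Ships the categorical-relaxation tables used for the Revised JNLPBA
#' (DNA/RNA/protein to Macromolecule, cell line/cell type to Cell), BC5CDR
#' (identity — its two types are already broad), and AnatEM (12 types down
#' to 4 broad anatomical categories) corpora.
#'
#' @param corpus One of `"jnlpba"`, `"bc5cdr"`, `"anatem"`.
#' @return A named character mapping as from [read_merge_map()].
#' @export
builtin_merge_map <- function(corpus = c("jnlpba", "bc5cdr", "anatem")) {
  corpus <- match.arg(corpus)
  path <- system.file(
    "extdata", paste0("merge_map_", corpus, ".tsv"),
    package = "nermacro", mustWork = TRUE
  )
  read_merge_map(path)
}

#' Apply categorical relaxation to a corpus
#'
#' Rewrites each tag `P-T` as `P-mapping[T]` for mapped types, preserving
#' the B/I prefix; `O` tags and token surfaces are untouched. Phrase
#' boundaries are a function of the tag sequence, so adjacent phrases of
#' newly identical type merge only where the rewritten tags form one run
#' (a following `B-` still opens a new phrase).
#'
#' @param corpus A `bio_corpus`.
#' @param mapping Named character vector (source type to merged type), e.g.
#'   from [read_merge_map()] or [builtin_merge_map()].
#' @return The relaxed `bio_corpus`.
#' @export
apply_merge <- function(corpus, mapping) {
  mapping <- validate_merge_map(mapping)
  tag <- corpus$tag
  ent <- tag != "O"
  type <- substring(tag[ent], 3L)
  hit <- type %in% names(mapping)
  type[hit] <- unname(mapping[type[hit]])
  tag[ent] <- paste0(substr(tag[ent], 1L, 2L), type)
  out <- corpus
  out$tag <- tag
  out
}

#' Score predictions after categorical relaxation
#'
#' Equivalent to `score_tags(apply_merge(gold, mapping),
#' apply_merge(pred, mapping))`: confusions between types that merge into
#' the same category become correct, so token-level micro-F1 over entity
#' tags can only rise relative to the unmerged score.
#'
#' @inheritParams score_tags
#' @param mapping A merge mapping.
#' @return A `ner_score` object on the merged tagset.
#' @export
merged_score <- function(gold, pred, mapping) {
  score_tags(apply_merge(gold, mapping), apply_merge(pred, mapping))
}
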