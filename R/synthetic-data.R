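# Synthetic BIO corpora, noisy predictions, and planted-signal macrofactor
# datasets. Everything is a deterministic function of its integer seed, so
# every downstream module is testable without external corpora.

# Pronounceable pseudo-words: 2-4 consonant+vowel syllables.
make_words <- function(n, min_syl = 2L, max_syl = 4L) {
  consonants <- c(
    "b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z",
    "th", "pl", "tr", "st", "gl"
  )
  vowels <- c("a", "e", "i", "o", "u", "ae", "io")
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    syl <- sample(min_syl:max_syl, need, replace = TRUE)
    batch <- vapply(syl, function(k) {
      paste0(sample(consonants, k, replace = TRUE),
             sample(vowels, k, replace = TRUE),
             collapse = "")
    }, character(1))
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

#' Generate a synthetic BIO corpus
#'
#' Builds a corpus of pseudo-word sentences with controllable sentence
#' lengths, entity phrase lengths, entity density, and deliberate label
#' ambiguity. Each entity tag draws from its own vocabulary, so by default
#' every term carries exactly one tag (label-consistency weight omega = 1);
#' a fraction `ambiguous_fraction` of entity word slots instead draws from
#' an ambiguous vocabulary whose terms are used under both the B- and I-
#' tag of their type (omega = 0.5 once both are observed). A fraction
#' `symbol_fraction` of phrases embeds a parenthesized abbreviation —
#' `term ( ab )` — whose bracket tokens are tagged inside the phrase,
#' mimicking symbol entity words in real biomedical corpora.
#'
#' @param n_sentences Number of sentences.
#' @param sentence_tokens Length-2 integer range of tokens per sentence.
#' @param types Character vector of entity type names.
#' @param phrase_tokens Length-2 integer range of entity words per phrase.
#' @param density Probability of opening an entity phrase at an available
#'   token position, in (0, 1).
#' @param ambiguous_fraction Probability that an entity word slot draws an
#'   ambiguous (two-tag) term, in `[0, 1]`.
#' @param symbol_fraction Probability that a phrase carries a parenthesized
#'   abbreviation, in `[0, 1]`.
#' @param vocab_size Terms per entity-tag vocabulary.
#' @param seed Integer seed; the corpus is a pure function of the
#'   arguments and this seed.
#' @return A `bio_corpus`.
#' @examples
#' co <- gen_corpus(n_sentences = 5, seed = 1)
#' extract_phrases(co)
#' @export
gen_corpus <- function(n_sentences = 100L,
                       sentence_tokens = c(15L, 35L),
                       types = c("Disease", "Chemical"),
                       phrase_tokens = c(1L, 4L),
                       density = 0.15,
                       ambiguous_fraction = 0.1,
                       symbol_fraction = 0.05,
                       vocab_size = 40L,
                       seed = 1L) {
  stopifnot(
    n_sentences >= 1L, length(sentence_tokens) == 2L,
    sentence_tokens[1L] >= 1L, sentence_tokens[1L] <= sentence_tokens[2L],
    length(phrase_tokens) == 2L, phrase_tokens[1L] >= 1L,
    phrase_tokens[1L] <= phrase_tokens[2L],
    density > 0, density < 1,
    ambiguous_fraction >= 0, ambiguous_fraction <= 1,
    symbol_fraction >= 0, symbol_fraction <= 1,
    length(types) >= 1L
  )
  if (phrase_tokens[1L] > sentence_tokens[2L]) {
    stop("minimum phrase length exceeds the maximum sentence length", call. = FALSE)
  }
  withr::local_seed(seed)

  n_types <- length(types)
  # disjoint vocabularies: one per tag plus a shared-per-type ambiguous pool
  # and a background pool for O tokens
  all_words <- make_words((2L * n_types + 1L) * vocab_size + n_types * max(4L, vocab_size %/% 4L))
  cut <- 0L
  take <- function(k) {
    w <- all_words[(cut + 1L):(cut + k)]
    cut <<- cut + k
    w
  }
  vocab_b <- stats::setNames(lapply(types, function(t) take(vocab_size)), types)
  vocab_i <- stats::setNames(lapply(types, function(t) take(vocab_size)), types)
  vocab_amb <- stats::setNames(
    lapply(types, function(t) take(max(4L, vocab_size %/% 4L))), types
  )
  vocab_bg <- take(vocab_size)

  draw_word <- function(type, prefix) {
    if (stats::runif(1) < ambiguous_fraction) {
      sample(vocab_amb[[type]], 1L)
    } else if (prefix == "B") {
      sample(vocab_b[[type]], 1L)
    } else {
      sample(vocab_i[[type]], 1L)
    }
  }

  sent <- integer(0)
  token <- character(0)
  tag <- character(0)
  for (s in seq_len(n_sentences)) {
    len <- sample(sentence_tokens[1L]:sentence_tokens[2L], 1L)
    toks <- character(0)
    tags <- character(0)
    i <- 1L
    while (i <= len) {
      remaining <- len - i + 1L
      if (remaining >= phrase_tokens[1L] && stats::runif(1) < density) {
        type <- sample(types, 1L)
        l <- sample(phrase_tokens[1L]:min(phrase_tokens[2L], remaining), 1L)
        words <- vapply(seq_len(l), function(j) {
          draw_word(type, if (j == 1L) "B" else "I")
        }, character(1))
        ptags <- c(paste0("B-", type), rep(paste0("I-", type), l - 1L))
        if (stats::runif(1) < symbol_fraction) {
          ab <- toupper(substr(sample(vocab_amb[[type]], 1L), 1L, 2L))
          words <- c(words, "(", ab, ")")
          ptags <- c(ptags, rep(paste0("I-", type), 3L))
          l <- l + 3L
        }
        toks <- c(toks, words)
        tags <- c(tags, ptags)
        i <- i + l
      } else {
        toks <- c(toks, sample(vocab_bg, 1L))
        tags <- c(tags, "O")
        i <- i + 1L
      }
    }
    sent <- c(sent, rep(s, length(toks)))
    token <- c(token, toks)
    tag <- c(tag, tags)
  }
  bio_corpus(sentence = sent, token = token, tag = tag)
}

#' Generate noisy predictions for a gold corpus
#'
#' Produces a prediction corpus token-aligned with the gold corpus by
#' perturbing gold tags: each entity token's tag is, independently, deleted
#' (set to `O`) with its deletion probability or substituted by a different
#' entity tag with its substitution probability; each `O` token is given a
#' random entity tag with probability `insertion`. Rates may be single
#' numbers or named per tag. Expected per-tag recall is
#' `1 - substitution - deletion`.
#'
#' @param gold A `bio_corpus`.
#' @param substitution Substitution probability, scalar or named by tag.
#' @param deletion Deletion probability, scalar or named by tag.
#' @param insertion False-positive probability on `O` tokens.
#' @param seed Integer seed.
#' @return A `bio_corpus` with identical token structure to `gold`.
#' @export
gen_predictions <- function(gold, substitution = 0, deletion = 0,
                            insertion = 0, seed = 1L) {
  withr::local_seed(seed)
  tagset <- corpus_tagset(gold)
  rate_for <- function(rate, tags) {
    if (is.null(names(rate))) {
      rep_len(as.numeric(rate), length(tags))
    } else {
      out <- rep(0, length(tags))
      hit <- tags %in% names(rate)
      out[hit] <- as.numeric(rate[tags[hit]])
      out
    }
  }
  tag <- gold$tag
  ent <- which(tag != "O")
  if (length(ent) > 0L && length(tagset) > 0L) {
    sub_p <- rate_for(substitution, tag[ent])
    del_p <- rate_for(deletion, tag[ent])
    if (any(sub_p + del_p > 1)) {
      stop("substitution + deletion probability exceeds 1 for some tag", call. = FALSE)
    }
    u <- stats::runif(length(ent))
    for (k in seq_along(ent)) {
      i <- ent[k]
      if (u[k] < del_p[k]) {
        tag[i] <- "O"
      } else if (u[k] < del_p[k] + sub_p[k]) {
        others <- setdiff(tagset, tag[i])
        if (length(others) == 0L) others <- "O"
        tag[i] <- sample(others, 1L)
      }
    }
  }
  if (insertion > 0 && length(tagset) > 0L) {
    o_idx <- which(gold$tag == "O")
    flip <- o_idx[stats::runif(length(o_idx)) < insertion]
    if (length(flip) > 0L) {
      tag[flip] <- sample(tagset, length(flip), replace = TRUE)
    }
  }
  bio_corpus(sentence = gold$sentence, token = gold$token, tag = tag)
}

#' Generate a macrofactor dataset with a planted signal
#'
#' Draws the six macrofactors independently from ranges matching realistic
#' biomedical corpus magnitudes and builds the label as
#' `label = effect * z(F) + noise_sd * eps`, where `z(F)` is the planted
#' factor standardized to unit variance and `eps` is standard Gaussian
#' noise. With `target = NULL` the label is pure noise, independent of all
#' factors (the null configuration). The analytic correlation between the
#' planted factor and the label is
#' `effect / sqrt(effect^2 + noise_sd^2)`.
#'
#' @param n Number of rows.
#' @param target Planted factor name among the six, or `NULL` for a null
#'   dataset.
#' @param effect Effect size in label units per standard deviation of the
#'   planted factor.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param ranges Named list of sampling ranges per factor; entries override
#'   the defaults (sLen 100-250, eLen 3-25, eNum 1-5, eDen 0.01-0.1,
#'   tEWC 100-5000, elCon in {1, 1/2, 1/3}).
#' @param seed Integer seed.
#' @return A `macrofactor_dataset` with `tag = "synthetic"` and the planted
#'   label in `label`.
#' @examples
#' d <- gen_factor_dataset(n = 100, target = "eLen", effect = 3, seed = 1)
#' factor_correlation(d$eLen, d$label)
#' @export
gen_factor_dataset <- function(n = 500L, target = NULL, effect = 3,
                               noise_sd = 1, ranges = list(), seed = 1L) {
  stopifnot(n >= 1L)
  if (!is.null(target) && !target %in% mf_factor_names()) {
    stop("target must be one of: ", paste(mf_factor_names(), collapse = ", "), call. = FALSE)
  }
  withr::local_seed(seed)
  rg <- utils::modifyList(
    list(
      sLen = c(100, 250), eLen = c(3, 25), eNum = c(1, 5),
      eDen = c(0.01, 0.1), tEWC = c(100, 5000), elCon = c(1, 1 / 2, 1 / 3)
    ),
    ranges
  )
  df <- tibble::tibble(
    sLen = round(stats::runif(n, rg$sLen[1], rg$sLen[2])),
    eLen = round(stats::runif(n, rg$eLen[1], rg$eLen[2])),
    eNum = as.numeric(sample(rg$eNum[1]:rg$eNum[2], n, replace = TRUE)),
    eDen = stats::runif(n, rg$eDen[1], rg$eDen[2]),
    tEWC = round(stats::runif(n, rg$tEWC[1], rg$tEWC[2])),
    elCon = sample(rg$elCon, n, replace = TRUE),
    tag = "synthetic"
  )
  eps <- stats::rnorm(n)
  df$label <- if (is.null(target)) {
    noise_sd * eps
  } else {
    z <- as.numeric(scale(df[[target]]))
    effect * z + noise_sd * eps
  }
  new_macrofactor_dataset(
    df,
    provenance = paste0(
      "synthetic(n=", n, ", target=", target %||% "none",
      ", effect=", effect, ", noise_sd=", noise_sd, ", seed=", seed, ")"
    )
  )
}
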