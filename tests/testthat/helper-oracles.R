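# Independent oracles used to cross-check package computations.
# These deliberately share no code with the implementation: scoring is
# counted token by token in an explicit loop, trimming by sort-and-slice.

# Token-level per-tag confusion counting, one token at a time.
oracle_score <- function(gold_tags, pred_tags) {
  tags <- sort(unique(c(gold_tags, pred_tags)))
  tags <- tags[tags != "O"]
  tp <- fp <- fn <- stats::setNames(rep(0L, length(tags)), tags)
  for (i in seq_along(gold_tags)) {
    g <- gold_tags[i]
    p <- pred_tags[i]
    if (g == p) {
      if (g != "O") tp[g] <- tp[g] + 1L
    } else {
      if (p != "O") fp[p] <- fp[p] + 1L
      if (g != "O") fn[g] <- fn[g] + 1L
    }
  }
  prf <- function(tp1, fp1, fn1) {
    prec <- if (tp1 + fp1 > 0) tp1 / (tp1 + fp1) else 0
    rec <- if (tp1 + fn1 > 0) tp1 / (tp1 + fn1) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  per_tag <- t(vapply(tags, function(t) prf(tp[t], fp[t], fn[t]), numeric(3)))
  pooled <- prf(sum(tp), sum(fp), sum(fn))
  list(
    tags = tags, tp = tp, fp = fp, fn = fn,
    precision = per_tag[, 1], recall = per_tag[, 2], f1 = per_tag[, 3],
    micro = if (length(tags) > 0) pooled[3] else 0,
    macro = if (length(tags) > 0) sum(per_tag[, 3]) / length(tags) else 0
  )
}

# Tukey-fence trimmed mean by explicit sort-and-slice.
oracle_tukey_mean <- function(x) {
  s <- sort(x)
  q1 <- stats::quantile(s, 0.25, names = FALSE)
  q3 <- stats::quantile(s, 0.75, names = FALSE)
  lo <- q1 - 1.5 * (q3 - q1)
  hi <- q3 + 1.5 * (q3 - q1)
  kept <- s[s >= lo & s <= hi]
  mean(kept)
}

# Percentile trimmed mean by explicit sort-and-slice.
oracle_pct_mean <- function(x, p) {
  s <- sort(x)
  lo <- stats::quantile(s, p / 100, names = FALSE)
  hi <- stats::quantile(s, 1 - p / 100, names = FALSE)
  kept <- s[s >= lo & s <= hi]
  mean(kept)
}

# A small aligned gold/prediction pair built from the synthetic generator.
random_pair <- function(seed, n_sentences = 15) {
  gold <- gen_corpus(
    n_sentences = n_sentences, sentence_tokens = c(5L, 15L),
    density = 0.25, ambiguous_fraction = 0.2, seed = seed
  )
  pred <- gen_predictions(
    gold,
    substitution = 0.2, deletion = 0.1, insertion = 0.02, seed = seed + 1000L
  )
  list(gold = gold, pred = pred)
}
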