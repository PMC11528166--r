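# The six macrofactor metrics and their aggregation.

symbol_phrase_corpus <- function() {
  bio_corpus(
    rep(1L, 4L), c("immunoglobulin", "(", "Ig", ")"),
    c("B-DNA", "I-DNA", "I-DNA", "I-DNA")
  )
}

test_that("sentence length counts the single-space join", {
  expect_equal(sentence_length("Ig"), 2L)
  expect_equal(sentence_length(c("IL-2", "binds", "receptor")), 19L)
  toks <- c("a", "bb", "ccc")
  expect_equal(sentence_length(toks), sum(nchar(toks)) + length(toks) - 1L)
  expect_error(sentence_length(character(0)), "empty")
})

test_that("phrase metrics follow the character and token counts", {
  rows <- entity_word_rows(symbol_phrase_corpus())
  expect_equal(nrow(rows), 4L)
  expect_true(all(rows$eLen == 21L))
  expect_true(all(rows$eNum == 4L))
  expect_true(all(rows$sLen == 21L))
  expect_true(all(rows$eDen == 1)) # phrase spans the whole sentence
})

test_that("entity density is the length ratio", {
  co <- bio_corpus(
    rep(1L, 3L), c("interleukin", "stimulates", "proliferation"),
    c("B-protein", "O", "O")
  )
  rows <- entity_word_rows(co)
  expect_equal(rows$eLen, 11L)
  expect_equal(rows$sLen, 36L)
  expect_equal(rows$eDen, 11 / 36)
})

test_that("term weights are the inverse of the distinct tag count", {
  co <- bio_corpus(
    c(1L, 1L, 2L, 2L),
    c("lymphocyte", "count", "blood", "lymphocyte"),
    c("B-cell_type", "O", "B-cell_type", "I-cell_type")
  )
  cat <- build_term_catalog(co)
  expect_equal(cat$omega[cat$term == "lymphocyte"], 0.5)
  expect_equal(cat$omega[cat$term == "blood"], 1)
  expect_false("count" %in% cat$term) # O tokens are not cataloged

  # a term observed under 4 distinct tags
  co4 <- bio_corpus(
    1:4, rep("p53", 4),
    c("B-DNA", "I-DNA", "B-protein", "I-protein")
  )
  expect_equal(build_term_catalog(co4)$omega, 0.25)
})

test_that("case folding is optional and off by default", {
  co <- bio_corpus(1:2, c("Interleukin", "interleukin"), c("B-protein", "I-protein"))
  expect_equal(nrow(build_term_catalog(co)), 2L)
  folded <- build_term_catalog(co, case_fold = TRUE)
  expect_equal(nrow(folded), 1L)
  expect_equal(folded$omega, 0.5)
})

test_that("catalog weight never increases as more tags are observed", {
  co1 <- bio_corpus(1L, "tnf", "B-protein")
  co2 <- bio_corpus(1:2, c("tnf", "tnf"), c("B-protein", "B-DNA"))
  co3 <- bio_corpus(1:3, c("tnf", "tnf", "tnf"), c("B-protein", "B-DNA", "I-DNA"))
  omegas <- vapply(list(co1, co2, co3), function(co) build_term_catalog(co)$omega, numeric(1))
  expect_equal(omegas, c(1, 0.5, 1 / 3))
  expect_true(all(diff(omegas) < 0))
})

test_that("entity word rows cover every non-O token exactly once", {
  expect_equal(nrow(entity_word_rows(bio_corpus(1L, "x", "O"))), 0L)
  for (seed in 1:5) {
    co <- gen_corpus(n_sentences = 30, ambiguous_fraction = 0.3, seed = seed)
    rows <- entity_word_rows(co)
    expect_equal(nrow(rows), sum(co$tag != "O"))
    expect_true(all(rows$eDen > 0 & rows$eDen <= 1))
    expect_true(all(rows$eLen <= rows$sLen))
    expect_true(all(rows$eNum >= 1))
    # elCon is always a unit fraction 1/k
    expect_true(all(abs(1 / rows$elCon - round(1 / rows$elCon)) < 1e-9))
  }
})

test_that("tokens of one phrase share their phrase metrics", {
  co <- bio_corpus(
    rep(1L, 3L), c("tumor", "necrosis", "factor"),
    c("B-protein", "I-protein", "O")
  )
  rows <- entity_word_rows(co)
  expect_equal(nrow(rows), 2L)
  expect_equal(length(unique(rows$eLen)), 1L)
  expect_equal(length(unique(rows$eNum)), 1L)
  expect_equal(rows$eLen[1], nchar("tumor necrosis"))
})

test_that("tag-level entity word counts sum to the non-O token count", {
  co <- gen_corpus(n_sentences = 40, seed = 9)
  agg <- aggregate_by_type(entity_word_rows(co), level = "tag", trim = "none")
  expect_equal(sum(agg$tEWC), sum(co$tag != "O"))
  agg_type <- aggregate_by_type(entity_word_rows(co), level = "type")
  expect_equal(sum(agg_type$tEWC), sum(co$tag != "O"))
})

test_that("aggregation handles single rows and outlier-free groups", {
  co <- bio_corpus(1L, "insulin", "B-protein")
  rows <- entity_word_rows(co)
  agg <- aggregate_by_type(rows, level = "tag")
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$mean_sLen, rows$sLen)
  expect_equal(agg$mean_eLen, rows$eLen)
  expect_equal(agg$tEWC, 1L)

  # no outliers under the fence rule: trimmed mean equals the plain mean
  rows5 <- do.call(rbind, replicate(5, rows, simplify = FALSE))
  rows5$sLen <- c(10, 11, 12, 13, 14)
  tuk <- aggregate_by_type(rows5, level = "tag", trim = "tukey")
  none <- aggregate_by_type(rows5, level = "tag", trim = "none")
  expect_equal(tuk$mean_sLen, none$mean_sLen)
})

test_that("trimmed means match the sort-and-slice oracle", {
  set.seed(31)
  for (rep in 1:5) {
    x <- c(stats::rlnorm(50, 3, 0.4), 1000) # heavy outlier
    rows <- tibble::tibble(
      sentence = 1L, position = seq_along(x), token = "t", tag = "B-X",
      entity_type = "X", sLen = x, eLen = x / 2, eNum = 1L,
      eDen = 0.5, elCon = 1
    )
    tuk <- aggregate_by_type(rows, level = "tag", trim = "tukey")
    expect_equal(tuk$mean_sLen, oracle_tukey_mean(x))
    pct <- aggregate_by_type(rows, level = "tag", trim = "pct:10")
    expect_equal(pct$mean_sLen, oracle_pct_mean(x, 10))
  }
})

test_that("degenerate trimming falls back to the untrimmed mean", {
  rows <- tibble::tibble(
    sentence = 1L, position = 1:2, token = "t", tag = "B-X",
    entity_type = "X", sLen = c(0, 100), eLen = c(0, 50), eNum = 1L,
    eDen = 0.5, elCon = 1
  )
  w <- testthat::capture_warnings(
    agg <- aggregate_by_type(rows, level = "tag", trim = "pct:49")
  )
  expect_true(any(grepl("untrimmed", w)))
  expect_equal(agg$mean_sLen, 50)
})

test_that("trim policies parse and reject nonsense", {
  expect_equal(trim_policy("tukey")$kind, "tukey")
  expect_equal(trim_policy("pct")$p, 5)
  expect_equal(trim_policy("pct:2.5")$p, 2.5)
  expect_error(trim_policy("pct:60"), "\\[0, 50\\)")
  expect_error(trim_policy("median"), "unknown trim policy")
})

test_that("aggregation is invariant to row order", {
  co <- gen_corpus(n_sentences = 30, seed = 13)
  rows <- entity_word_rows(co)
  set.seed(1)
  shuffled <- rows[sample(nrow(rows)), ]
  a <- aggregate_by_type(rows, level = "tag")
  b <- aggregate_by_type(shuffled, level = "tag")
  expect_equal(a, b)
})
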