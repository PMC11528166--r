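# Multilevel factor elimination: correlation screen, forest elimination,
# regression elimination, and the composed pipeline.

# factors with a prescribed population correlation against a shared label
ladder_dataset <- function(r_values, n = 500, seed = 1) {
  withr::with_seed(seed, {
    y <- stats::rnorm(n)
    cols <- lapply(r_values, function(r) {
      r * y + sqrt(1 - r^2) * stats::rnorm(n)
    })
    names(cols) <- mf_factor_names()[seq_along(r_values)]
    df <- tibble::as_tibble(cols)
    df$tag <- "synthetic"
    df$label <- y
    nermacro:::new_macrofactor_dataset(df)
  })
}

test_that("the correlation coefficient matches its longhand evaluation", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 5, 9)
  # longhand: sum of cross-deviations 11; sums of squares 5 and 26
  expect_equal(factor_correlation(x, y), 11 / sqrt(130))
  expect_equal(factor_correlation(x, x), 1)
  expect_equal(factor_correlation(x, -x), -1)
})

test_that("degenerate and malformed correlation inputs are handled", {
  expect_warning(r <- factor_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(r, 0)
  expect_error(factor_correlation(1:3, 1:4), "equal length")
  expect_error(factor_correlation(1:2, 1:2), "at least 3")
})

test_that("correlation is affine-invariant and antisymmetric", {
  set.seed(8)
  for (i in 1:10) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
    r <- factor_correlation(x, y)
    expect_equal(factor_correlation(2.5 * x + 7, y), r, tolerance = 1e-12)
    expect_equal(factor_correlation(x, 0.1 * y - 3), r, tolerance = 1e-12)
    expect_equal(factor_correlation(-x, y), -r, tolerance = 1e-12)
    expect_equal(r, stats::cor(x, y), tolerance = 1e-12)
  }
})

test_that("layer 1 ranks a planted correlation ladder correctly", {
  ds <- ladder_dataset(c(0.9, 0.7, 0.5, 0.3, 0.1, 0.0), n = 500, seed = 42)
  l1 <- layer1_rank(ds, keep = 4)
  expect_equal(l1$selected, mf_factor_names()[1:4])
  expect_equal(l1$ranking$factor[1:4], l1$selected)
  expect_equal(nrow(l1$ranking), 6L)
  # keep >= available retains everything
  expect_length(layer1_rank(ds, keep = 6)$selected, 6L)
})

test_that("layer 1 keeps strong negative correlates under absolute ranking", {
  ds <- ladder_dataset(c(-0.9, 0.3, 0.1, 0.05, 0.02, 0.0), n = 500, seed = 7)
  expect_equal(layer1_rank(ds, keep = 4)$selected[1], "sLen")
  expect_false(layer1_rank(ds, keep = 1, use_abs = FALSE)$selected[1] == "sLen")
})

test_that("a perfect correlate ranks first among noise", {
  ds <- gen_factor_dataset(n = 200, target = "eDen", effect = 1, noise_sd = 0, seed = 3)
  expect_equal(layer1_rank(ds)$selected[1], "eDen")
})

test_that("layer 2 with stop_count equal to the input is a no-op", {
  ds <- gen_factor_dataset(n = 200, target = "eNum", seed = 5)
  l2 <- layer2_forest_eliminate(ds, c("sLen", "eNum"), stop_count = 2, seed = 5)
  expect_equal(l2$selected, c("sLen", "eNum"))
  expect_equal(unique(l2$trace$round), 1L)
  expect_true(all(c("importance", "cv_r2") %in% names(l2$trace)))
  expect_error(
    layer2_forest_eliminate(ds, c("sLen", "eNum"), stop_count = 3, seed = 1),
    "stop_count"
  )
})

test_that("layer 2 keeps a planted signal in the surviving pair", {
  hits <- 0L
  for (seed in 1:10) {
    ds <- gen_factor_dataset(n = 500, target = "eNum", effect = 3, noise_sd = 1, seed = seed)
    l2 <- layer2_forest_eliminate(
      ds, c("sLen", "eLen", "eNum", "eDen"),
      stop_count = 2, seed = seed
    )
    hits <- hits + ("eNum" %in% l2$selected)
  }
  expect_gte(hits, 9L)
})

test_that("layer 3 reduces to the planted factor and respects a single input", {
  ds <- gen_factor_dataset(n = 500, target = "eLen", effect = 3, seed = 2)
  expect_equal(layer3_regression_eliminate(ds, "eLen", seed = 2)$selected, "eLen")
  expect_error(layer3_regression_eliminate(ds, character(0), seed = 1), "at least one")

  hits <- 0L
  for (seed in 1:10) {
    ds <- gen_factor_dataset(n = 500, target = "eLen", effect = 3, seed = seed)
    l3 <- layer3_regression_eliminate(ds, c("eLen", "tEWC"), seed = seed)
    hits <- hits + identical(l3$selected, "eLen")
  }
  expect_gte(hits, 9L)
})

test_that("layer 3 retains two factors that both carry signal", {
  withr::with_seed(17, {
    n <- 500
    ds <- gen_factor_dataset(n = n, target = NULL, noise_sd = 0, seed = 17)
    z <- function(x) as.numeric(scale(x))
    ds$label <- 3 * z(ds$eLen) + 3 * z(ds$eDen) + 0.5 * stats::rnorm(n)
  })
  l3 <- layer3_regression_eliminate(ds, c("eLen", "eDen"), seed = 17)
  expect_setequal(l3$selected, c("eLen", "eDen"))
})

test_that("the composed pipeline nests its layers and recovers a plant", {
  ds <- gen_factor_dataset(n = 500, target = "eNum", effect = 3, seed = 23)
  rep <- run_mfe(ds, seed = 23)
  expect_true(all(rep$layer3 %in% rep$layer2))
  expect_true(all(rep$layer2 %in% rep$layer1))
  expect_true(all(rep$layer1 %in% rep$input_factors))
  expect_length(rep$layer1, 4L)
  expect_length(rep$layer2, 2L)
  expect_equal(rep$layer3, "eNum")
  expect_s3_class(rep$diagnostics$correlation, "tbl_df")
})

test_that("the pipeline can terminate on eLen when eLen drives the label", {
  ds <- gen_factor_dataset(n = 500, target = "eLen", effect = 3, seed = 29)
  rep <- run_mfe(ds, seed = 29)
  expect_equal(rep$layer3, "eLen")
})

test_that("identical seeds give identical reports", {
  ds <- gen_factor_dataset(n = 300, target = "eDen", effect = 2, seed = 31)
  r1 <- run_mfe(ds, seed = 99)
  r2 <- run_mfe(ds, seed = 99)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_mfe_report(r1, p1)
  write_mfe_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("constant factors are dropped before layer 1 with a warning", {
  ds <- gen_factor_dataset(
    n = 300, target = "eNum", effect = 3, seed = 37,
    ranges = list(tEWC = c(500, 500))
  )
  expect_warning(rep <- run_mfe(ds, seed = 37), "tEWC")
  expect_false("tEWC" %in% rep$layer1)
  expect_equal(rep$diagnostics$dropped_constant, "tEWC")
})
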