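# Multilevel factor elimination (MFE).
#
# Three nested screening layers over the macrofactor dataset:
#   layer 1 — rank factors by the product-moment correlation of each factor
#             with the label; keep the top 4 by |r|.
#   layer 2 — iteratively fit a random-forest regressor on the surviving
#             factors, evaluate it, and drop the factor with the lowest
#             impurity importance until 2 remain.
#   layer 3 — fit a linear regression on z-standardized factors, drop the
#             factor with the smallest |beta|, refit; stop when a removal
#             would lower the cross-validated R^2, or one factor remains.
# Ties in rank, importance or |beta| break toward keeping the factor that
# comes first in canonical order (sLen, eLen, eNum, eDen, tEWC, elCon).

#' Product-moment correlation between a factor and the label
#'
#' The classical correlation coefficient
#' \deqn{r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}{
#'   \sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}}
#' quantifying the strength and direction of the linear relationship
#' between a macrofactor and model performance. A constant argument makes
#' the denominator zero; r is then defined as 0 with a warning, so
#' degenerate factors rank last rather than poisoning the screen.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`.
#' @export
factor_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    warning("constant input; correlation defined as 0", call. = FALSE)
    return(0)
  }
  sum(dx * dy) / den
}

canonical_order <- function(factors) {
  factors[order(match(factors, mf_factor_names()))]
}

# Drop the latest-in-canonical-order member of `cands` (tie-break rule).
tie_break_drop <- function(cands) {
  cands[which.max(match(cands, mf_factor_names()))]
}

#' Layer 1: correlation ranking of macrofactors
#'
#' Computes the correlation of every factor with the label and ranks
#' factors by correlation strength. Ranking uses `|r|` by default so that a
#' strongly negative correlate (label consistency typically anti-correlates
#' with accuracy) is retained rather than discarded; set `use_abs = FALSE`
#' for signed ranking.
#'
#' @param dataset A `macrofactor_dataset` (or tibble with factor columns and
#'   a `label` column).
#' @param factors Factors to rank; defaults to all six.
#' @param keep Number of top-ranked factors to retain (default 4). When
#'   fewer factors are available, all are returned.
#' @param use_abs Rank by `|r|` (default) or signed r?
#' @return A list with `selected` (character vector of retained factors in
#'   rank order) and `ranking` (tibble of `factor`, `r`, `abs_r` for every
#'   input factor, best first).
#' @export
layer1_rank <- function(dataset, factors = NULL, keep = 4L, use_abs = TRUE) {
  factors <- factors %||% intersect(mf_factor_names(), names(dataset))
  if (length(factors) == 0L) {
    stop("no factors to rank", call. = FALSE)
  }
  r <- vapply(factors, function(f) factor_correlation(dataset[[f]], dataset$label), numeric(1))
  key <- if (use_abs) abs(r) else r
  ord <- order(-key, match(factors, mf_factor_names()))
  ranking <- tibble::tibble(factor = factors[ord], r = r[ord], abs_r = abs(r[ord]))
  if (keep < length(factors)) {
    selected <- ranking$factor[seq_len(keep)]
  } else {
    selected <- ranking$factor
  }
  list(selected = selected, ranking = ranking)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Out-of-fold R^2 of a fitting routine under seeded k-fold splits.
# fit_predict(train_df, test_df) must return test predictions.
cv_r2 <- function(df, folds, fit_predict) {
  n <- nrow(df)
  fold_id <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    pred[hold] <- fit_predict(df[!hold, , drop = FALSE], df[hold, , drop = FALSE])
  }
  1 - sum((df$label - pred)^2) / sum((df$label - mean(df$label))^2)
}

#' Layer 2: iterative random-forest importance elimination
#'
#' Repeatedly fits a random-forest regressor of the label on the current
#' factor set, records its fit quality, and drops the factor with the
#' lowest feature importance, until `stop_count` factors remain.
#' Importance is out-of-bag permutation importance by default: impurity
#' importance systematically inflates continuous, high-cardinality
#' features relative to discrete ones (entity word counts and consistency
#' weights take few values), which would bias elimination even when no
#' factor carries signal; permutation importance is neutral under that
#' null. Evaluation uses the forest's out-of-bag R^2 by default — the
#' internal cross-validation of a bagged ensemble, where every tree is
#' scored on the samples it never saw — or explicit k-fold
#' cross-validation with `cv = "kfold"`.
#'
#' @param dataset A `macrofactor_dataset`.
#' @param factors Factors entering the layer (normally layer 1's survivors).
#' @param stop_count Number of survivors (default 2).
#' @param num_trees Trees per forest (default 500).
#' @param importance `"permutation"` (default) or `"impurity"`.
#' @param cv `"oob"` (default) or `"kfold"`.
#' @param folds Folds for `cv = "kfold"`.
#' @param seed Integer seed controlling forest fitting and fold assignment.
#' @return A list with `selected` (survivors, canonical order) and `trace`
#'   (tibble of `round`, `factor`, `importance`, `cv_r2`, `dropped`).
#' @export
layer2_forest_eliminate <- function(dataset, factors, stop_count = 2L,
                                    num_trees = 500L,
                                    importance = c("permutation", "impurity"),
                                    cv = c("oob", "kfold"),
                                    folds = 5L, seed = 1L) {
  cv <- match.arg(cv)
  importance <- match.arg(importance)
  if (stop_count > length(factors)) {
    stop("stop_count exceeds the number of factors", call. = FALSE)
  }
  current <- canonical_order(factors)
  trace <- list()
  round <- 0L
  withr::local_seed(seed)
  repeat {
    round <- round + 1L
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    df <- as.data.frame(dataset)[, c(current, "label")]
    fit <- ranger::ranger(
      dependent.variable.name = "label", data = df,
      num.trees = num_trees, importance = importance,
      seed = sub_seed, num.threads = 1L
    )
    score <- if (cv == "oob") {
      1 - fit$prediction.error / stats::var(df$label)
    } else {
      cv_r2(df, folds, function(train, test) {
        m <- ranger::ranger(
          dependent.variable.name = "label", data = train,
          num.trees = num_trees, seed = sub_seed, num.threads = 1L
        )
        stats::predict(m, data = test)$predictions
      })
    }
    imp <- fit$variable.importance[current]
    done <- length(current) <= stop_count
    drop <- if (done) NA_character_ else tie_break_drop(current[imp == min(imp)])
    trace[[round]] <- tibble::tibble(
      round = round, factor = current, importance = unname(imp),
      cv_r2 = score, dropped = !is.na(drop) & current == drop
    )
    if (done) break
    current <- setdiff(current, drop)
  }
  list(selected = current, trace = dplyr::bind_rows(trace))
}

#' Layer 3: regression-coefficient elimination
#'
#' Fits an ordinary least-squares regression of the label on z-standardized
#' factors, so coefficient magnitudes are comparable across factors, and
#' uses `|beta|` as the influence of each factor. The factor with the
#' smallest influence is removed and the model refit; elimination stops
#' when a removal would meaningfully lower the cross-validated R^2 — no
#' further improvement — or when a single factor remains. "Meaningfully"
#' is governed by `tol`: removing a pure-noise regressor perturbs the
#' out-of-fold R^2 by only O(1/n) with arbitrary sign, so a strict
#' any-decrease rule would stop on sampling noise about half the time;
#' the default tolerance of 0.01 R^2 units ignores such jitter while any
#' informative factor's removal (which costs R^2 on the scale of its
#' explained variance) still halts elimination.
#'
#' @param dataset A `macrofactor_dataset`.
#' @param factors Factors entering the layer (normally layer 2's survivors).
#' @param folds Cross-validation folds (default 5).
#' @param tol Largest cross-validated R^2 decrease still treated as "no
#'   further improvement" (default 0.01).
#' @param seed Integer seed controlling fold assignment.
#' @return A list with `selected` (survivors, canonical order) and `trace`
#'   (tibble of `step`, `factor`, `beta`, `cv_r2`, `dropped`).
#' @export
layer3_regression_eliminate <- function(dataset, factors, folds = 5L,
                                        tol = 0.01, seed = 1L) {
  if (length(factors) == 0L) {
    stop("layer 3 requires at least one factor", call. = FALSE)
  }
  current <- canonical_order(factors)
  df <- as.data.frame(dataset)[, c(current, "label")]
  df[current] <- lapply(df[current], function(x) as.numeric(scale(x)))
  withr::local_seed(seed)
  # one fold assignment per run so successive models see identical splits
  fold_id <- sample(rep_len(seq_len(folds), nrow(df)))
  score_of <- function(fac) {
    if (length(fac) == 0L) {
      return(-Inf)
    }
    pred <- numeric(nrow(df))
    fml <- stats::as.formula(paste("label ~", paste(fac, collapse = " + ")))
    for (k in seq_len(folds)) {
      hold <- fold_id == k
      m <- stats::lm(fml, data = df[!hold, , drop = FALSE])
      pred[hold] <- stats::predict(m, newdata = df[hold, , drop = FALSE])
    }
    1 - sum((df$label - pred)^2) / sum((df$label - mean(df$label))^2)
  }
  betas_of <- function(fac) {
    fml <- stats::as.formula(paste("label ~", paste(fac, collapse = " + ")))
    stats::coef(stats::lm(fml, data = df))[fac]
  }
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    beta <- betas_of(current)
    score <- score_of(current)
    if (length(current) == 1L) {
      trace[[step]] <- tibble::tibble(
        step = step, factor = current, beta = unname(beta),
        cv_r2 = score, dropped = FALSE
      )
      break
    }
    cand <- tie_break_drop(current[abs(beta) == min(abs(beta))])
    reduced <- setdiff(current, cand)
    reduced_score <- score_of(reduced)
    stop_here <- reduced_score < score - tol
    trace[[step]] <- tibble::tibble(
      step = step, factor = current, beta = unname(beta),
      cv_r2 = score, dropped = !stop_here & current == cand
    )
    if (stop_here) break
    current <- reduced
  }
  list(selected = current, trace = dplyr::bind_rows(trace))
}

#' Run the full multilevel factor elimination algorithm
#'
#' Composes the three screening layers — correlation ranking (keep the top
#' `keep`), iterative random-forest importance elimination (down to
#' `stop_count`), and regression-coefficient elimination (until performance
#' stops improving) — and returns a report of every intermediate selection.
#' Factors that are constant over the dataset are removed before layer 1
#' with a warning, since their correlation with the label is undefined.
#'
#' @param dataset A `macrofactor_dataset`.
#' @param keep Layer-1 survivors (default 4).
#' @param stop_count Layer-2 survivors (default 2).
#' @param folds Cross-validation folds (default 5).
#' @param num_trees Trees per random forest (default 500).
#' @param importance Layer-2 importance measure, `"permutation"` (default)
#'   or `"impurity"`.
#' @param cv Layer-2 evaluation, `"oob"` (default) or `"kfold"`.
#' @param tol Layer-3 stopping tolerance (see
#'   [layer3_regression_eliminate()]).
#' @param use_abs Rank layer 1 by `|r|` (default) or signed r.
#' @param seed Integer seed; fixes the entire run, making reports
#'   byte-identical across repeats.
#' @return An `mfe_report`: list with `input_factors`, `layer1`, `layer2`,
#'   `layer3` (character vectors, nested), `diagnostics` (the per-layer
#'   ranking and traces), `config` and `seed`.
#' @examples
#' d <- gen_factor_dataset(n = 200, target = "eNum", effect = 3, seed = 7)
#' run_mfe(d, seed = 7)
#' @export
run_mfe <- function(dataset, keep = 4L, stop_count = 2L, folds = 5L,
                    num_trees = 500L,
                    importance = c("permutation", "impurity"),
                    cv = c("oob", "kfold"),
                    tol = 0.01, use_abs = TRUE, seed = 1L) {
  cv <- match.arg(cv)
  importance <- match.arg(importance)
  input <- intersect(mf_factor_names(), names(dataset))
  constant <- input[vapply(input, function(f) {
    length(unique(dataset[[f]])) < 2L
  }, logical(1))]
  if (length(constant) > 0L) {
    warning(
      "dropping constant factor(s) before layer 1: ",
      paste(constant, collapse = ", "),
      call. = FALSE
    )
  }
  usable <- setdiff(input, constant)
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  l1 <- layer1_rank(dataset, factors = usable, keep = keep, use_abs = use_abs)
  l2 <- layer2_forest_eliminate(
    dataset, l1$selected,
    stop_count = min(stop_count, length(l1$selected)),
    num_trees = num_trees, importance = importance, cv = cv, folds = folds,
    seed = seeds[1L]
  )
  l3 <- layer3_regression_eliminate(
    dataset, l2$selected,
    folds = folds, tol = tol, seed = seeds[2L]
  )
  structure(
    list(
      input_factors = input,
      layer1 = l1$selected,
      layer2 = l2$selected,
      layer3 = l3$selected,
      diagnostics = list(
        dropped_constant = constant,
        correlation = l1$ranking,
        forest_trace = l2$trace,
        regression_trace = l3$trace
      ),
      config = list(
        keep = keep, stop_count = stop_count, folds = folds,
        num_trees = num_trees, importance = importance, cv = cv, tol = tol,
        use_abs = use_abs
      ),
      seed = seed
    ),
    class = "mfe_report"
  )
}

#' @export
print.mfe_report <- function(x, ...) {
  cat("Multilevel factor elimination\n")
  cat("  Input   ", paste(x$input_factors, collapse = ", "), "\n")
  cat("  Layer 1 ", paste(x$layer1, collapse = ", "), "\n")
  cat("  Layer 2 ", paste(x$layer2, collapse = ", "), "\n")
  cat("  Layer 3 ", paste(x$layer3, collapse = ", "), "\n")
  cat("  (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write an MFE report to a JSON file
#'
#' @param report An `mfe_report`.
#' @param path Output path.
#' @return Invisibly, `report`.
#' @export
write_mfe_report <- function(report, path) {
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}
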