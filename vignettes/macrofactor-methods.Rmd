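---
title: "Macrofactor methods: metrics, scoring conventions, and the MFE algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrofactor methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nermacro)
```

This vignette records the scientific conventions behind `nermacro`: what
each quantity means, the choices we made where the underlying definitions
are open, and what the synthetic validation does and does not establish
about real corpora.

## The data model

A corpus is a flat token table (`sentence`, `token`, `tag`) under the BIO
scheme: `B-X` opens an entity phrase of type X, `I-X` continues it, `O`
is background. Two parsing conventions matter and are fixed here:

* **Orphan `I-` tags start a phrase.** An `I-X` with no live phrase of
  type X opens one. Real corpora contain such tokens (and tagged symbols
  such as the parentheses in an abbreviation like "immunoglobulin (
  Ig )"), and every non-`O` token must land in exactly one phrase for the
  per-entity-word accounting below to be a partition.
* **An `I-Y` after an X phrase closes X and opens Y**; a `B-` tag always
  opens a new phrase, even inside a same-type run.

Tags are case-sensitive, input is UTF-8, and the CoNLL column layout is
configurable (default: first column token, last column tag) because
dialects differ.

## Scoring conventions

Scoring is **token-level per full tag**. `B-X` and `I-X` are separate
classes because the downstream analysis consumes per-tag F1 as its label;
exact-span phrase matching is deliberately out of scope. Conventions:

* precision = recall = 0 when their denominator is 0, so a tag present in
  gold but never predicted contributes F1 = 0 to the macro average
  instead of silently vanishing — unpredicted rare tags should hurt;
* `O` is excluded from both averages: it dominates any corpus and would
  swamp the entity-tag signal the averages exist to summarize;
* `AVG_MICRO` is the F1 of pooled tp/fp/fn; `AVG_MACRO` the unweighted
  mean of per-tag F1; an all-`O` pair scores 0 on both by convention.

Categorical relaxation rewrites `P-T` to `P-m(T)` for a single-step type
mapping m, preserving the B/I prefix (relaxed tags are still scored
separately per prefix). Only predictions and gold are re-mapped; nothing
is re-trained, and the package makes no claim about what re-training on
merged labels would give. Token-level micro-F1 is monotone under merging
— confusions inside a merged category become correct, never the reverse —
and the test suite verifies this exhaustively on 4-token sentences over
two types.

## Macrofactor definitions and their free choices

For entity word w in phrase p in sentence s:

* `sLen(s)` — characters of the sentence's single-space token join. The
  corpora are tokenized; original spacing is unrecoverable, so the join
  (token lengths plus one per gap) is the documented convention.
* `eLen(p)` — characters of the phrase's single-space join.
* `eNum(p)` — tokens in the phrase (the `B-` token and its `I-`
  continuations counted as one run).
* `eDen` — `eLen / sLen`, in (0, 1].
* `elCon(w)` — ω = 1/k with k the number of distinct tags carried by w's
  surface form anywhere in the corpus. Distinctness is at full-tag
  granularity (`B-cell_type` and `I-cell_type` are two tags: a term seen
  under both weighs 0.5). Term identity is the exact surface by default;
  case folding is a switch, not the default, because the evaluation
  corpora are machine-consistent in case.
* `tEWC` — entity words per tag (or per type at type-level aggregation),
  an untrimmed count over whatever corpus files the user supplies; no
  train/test split is hard-coded.

Reported *aggregate* means exclude extreme values. No published rule pins
down "extreme", so the trim policy is explicit and configurable:
Tukey fences (default; drop outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`) or
symmetric percentile trimming `pct:p` (default p = 5), or `none`. Two
consequences worth knowing: on a heavily skewed discrete metric such as ω
(mostly 1, a minority at 0.5) the Tukey fences can collapse to a point
and trim the whole minority — the occurrence-level mean of ω is better
read untrimmed; and if a policy trims an entire group the aggregate falls
back to the untrimmed mean with a warning. elCon aggregates average ω
over *occurrences* (entity words), not distinct terms, matching the
per-entity-word framing of every other factor; a per-term average can be
had by averaging the catalog directly.

The supervised macrofactor dataset takes the **raw per-word values**
(trimming applies only to reported summaries): one row per entity word,
`tEWC` repeated per row (constant within tag, but the elimination
algorithm treats it as an ordinary feature), and the tag's F1 joined as
the label. Which model's F1 to use is the caller's choice;
`pick_best_model()` implements the argmax by AVG_MICRO, tie-broken by
AVG_MACRO then name.

## The MFE algorithm: defaults and why

`run_mfe()` composes three screens; every decision point below is a
configurable argument, and the defaults are:

* **Layer 1 — correlation filter, keep 4.** The explicit product-moment
  formula (`factor_correlation()`), ranked by |r|. Absolute ranking is
  the default because label consistency genuinely anti-correlates with
  accuracy in corpus data; a signed rank would discard exactly the
  interesting negative correlate. Constant factors (e.g. `tEWC` in a
  single-tag dataset) are dropped beforehand with a warning — their
  correlation is undefined.
* **Layer 2 — random-forest elimination, stop at 2.** 500 trees, default
  split parameters, one factor dropped per round. Importance is
  out-of-bag **permutation** importance: impurity importance
  systematically inflates continuous, many-valued features over discrete
  ones (`eNum` takes ~5 values, `elCon` 3), and under a label independent
  of all factors that bias alone decided which factors survived; with
  permutation importance the null selection is close to uniform. Each
  round's model quality is recorded as the forest's out-of-bag R² — the
  internal cross-validation of a bagged ensemble — with explicit k-fold
  CV available (`cv = "kfold"`) at ~6× the cost.
* **Layer 3 — regression elimination, floor of 1.** OLS on z-standardized
  factors so |β| values are comparable across scales (raw-coefficient
  comparison would be unit-dependent), drop the smallest |β|, refit,
  evaluate by 5-fold out-of-fold R² on one fixed fold assignment per run.
  Elimination stops when a removal lowers that R² by more than
  `tol = 0.01`: the R² change from removing a pure-noise regressor is
  O(1/n) with arbitrary sign, so a strict any-decrease rule would stop on
  sampling jitter roughly half the time, while removing a factor that
  carries signal costs R² on the scale of its explained variance — orders
  of magnitude above the tolerance at any realistic effect size.
* **Ties** in rank, importance or |β| break by keeping the factor earlier
  in canonical order (`sLen`, `eLen`, `eNum`, `eDen`, `tEWC`, `elCon`).
* **Determinism.** One integer seed drives sub-seeds for the forests and
  fold assignments (single-threaded forests); the same seed and dataset
  give a byte-identical report.

## What the synthetic generator emulates — and what it does not

`gen_corpus()` produces pseudo-word sentences with controllable sentence
length (default 15–35 tokens, giving sentence string lengths around
100–250 characters), phrase length (1–4 entity words), entity density,
deliberately ambiguous vocabulary (terms pre-assigned to appear under
both the `B-` and `I-` tag of their type, so ω = 0.5 once both are
observed), and parenthesized abbreviations whose bracket tokens are
tagged inside the phrase. `gen_predictions()` perturbs gold
tags with per-tag substitution/deletion probabilities plus an optional
false-positive rate on `O` tokens, so expected per-tag recall is
`1 − substitution − deletion`. `gen_factor_dataset()` draws the six
factors independently from ranges matching the magnitudes seen in real
biomedical corpora (sLen 100–250, eLen 3–25, eNum 1–5, eDen 0.01–0.1,
tEWC 100–5000, ω ∈ {1, ½, ⅓}) and builds the label as
`effect · z(F) + noise_sd · ε`; the planted correlation is
`effect / sqrt(effect² + noise_sd²)` (0.949 at the default 3:1
signal-to-noise), or pure noise under the null.

These generators validate the *machinery*: parsing round-trips, score
identities, selection calibration (a planted factor is recovered at
layer 3 in ≥ 90% of seeded replicates at n = 500; under a null label no
factor dominates). They do not reproduce real corpora's correlated
factor structure — in real text `eDen` is literally `eLen/sLen`, whereas
the planted datasets draw the factors independently precisely so that
"recovered the planted factor" is well defined. Validation sizes
(n = 500 rows, 50 replicates per configuration, ~10,000-token corpora
for distributional checks) were chosen so each simulated check resolves
its stated threshold comfortably. Passing them shows the algorithm does
what it claims under its own assumptions, not that any particular factor
drives any particular real model — on real data MFE's output is a
screening result to be interpreted, with collinear factors (eLen/eDen)
capable of standing in for one another at layer 3.

## Degenerate inputs and numerical notes

Empty corpora read and write as empty; an all-`O` pair scores 0/0 rows by
convention; misaligned gold/prediction streams fail fast naming the first
divergent token; mappings touching `O` or chaining two steps are
rejected; `0/0` ratios never produce NaN anywhere in the scoring path.
Correlations are exact sums (no incremental updates); standardization in
layer 3 uses the full-dataset mean and standard deviation once per run.

## Known limitations

* Phrase-level (exact-span) evaluation is intentionally absent.
* Relaxation re-maps post hoc; conclusions about re-trained merged-label
  models are out of reach by design.
* `elCon` uses surface identity — no lemmatization, so "receptor" and
  "receptors" are distinct terms.
* The trim policy is a convention; aggregate means quoted from different
  extreme-value rules are not directly comparable.
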