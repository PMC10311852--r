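#' Assemble a dataset under a positive-negative sampling regime
#'
#' Literature-graph interaction benchmarks are heavily imbalanced (the
#' closed-world negatives outnumber positives by roughly 54 to 1 on real
#' graphs), so three sampling regimes are supported:
#'
#' * `balanced` -- keep all positives and draw an equal number of negatives
#'   uniformly at random (1:1);
#' * `ratio_1_10` -- keep all positives and 10x as many negatives; test
#'   folds preserve the 1:10 imbalance, while each training fold is further
#'   subsampled to the ratio chosen by inner cross-validation;
#' * `ratio_1_54` -- as above at 1:54, the native imbalance.
#'
#' @param pairs a labeled pair table (`drug_id`, `gene_id`, `label`).
#' @param regime one of `"balanced"`, `"ratio_1_10"`, `"ratio_1_54"`.
#' @param seed integer seed for the negative draw.
#' @param candidate_ratios negative:positive ratios offered to the inner
#'   cross-validation in the ratio regimes.
#' @return A list of class `blgpa_dataset` with the sampled `pairs`, the
#'   `regime`, the `candidate_ratios` and the `seed`.
#' @export
sample_dataset <- function(pairs, regime = c("balanced", "ratio_1_10",
                                             "ratio_1_54"),
                           seed = 1L,
                           candidate_ratios = c(1, 2, 5, 10, 20, 54)) {
  regime <- match.arg(regime)
  pairs <- check_pairs(pairs)
  pos <- which(pairs$label == 1L)
  neg <- which(pairs$label == 0L)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present", call. = FALSE)
  mult <- switch(regime, balanced = 1, ratio_1_10 = 10, ratio_1_54 = 54)
  need <- mult * length(pos)
  if (length(neg) < need)
    stop(sprintf("regime %s needs %d negatives but only %d are available",
                 regime, need, length(neg)), call. = FALSE)
  set.seed(seed)
  keep <- sort(c(pos, sample(neg, need)))
  structure(list(pairs = pairs[keep, , drop = FALSE], regime = regime,
                 candidate_ratios = candidate_ratios, seed = seed),
            class = "blgpa_dataset")
}

#' @export
print.blgpa_dataset <- function(x, ...) {
  cat("blgpa dataset (", x$regime, "): ", sum(x$pairs$label == 1),
      " positive / ", sum(x$pairs$label == 0), " negative pairs\n", sep = "")
  invisible(x)
}

## Stratified fold assignment: within each class, indices are shuffled and
## dealt round-robin, so every fold holds positives.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the link predictor
#'
#' Stratified k-fold (default 10) outer cross-validation with strictly
#' leakage-free feature mining: within each fold, relational chains are mined
#' only from that fold's training pairs, and (in the ratio regimes) the
#' training negative:positive ratio is chosen by an inner 5-fold
#' cross-validation on the training pool only, maximizing inner positive-class
#' F1. The untouched test fold is scored once. Reported metrics are the
#' positive-class precision, recall and F1 per fold and their macro averages
#' (arithmetic means across folds).
#'
#' All randomness -- negative sampling, fold assignment, inner subsampling
#' and the forests -- flows from the single `seed`, so two runs with equal
#' arguments produce identical reports.
#'
#' @param pairs a labeled pair table, or a [sample_dataset()] result.
#' @param graph a [knowledge_graph()] object.
#' @param regime sampling regime, see [sample_dataset()]; ignored when
#'   `pairs` is already a `blgpa_dataset`.
#' @param folds number of outer folds (default 10).
#' @param inner_folds folds of the inner ratio-selection loop (default 5).
#' @param candidate_ratios ratios offered to the inner loop.
#' @param seed master seed.
#' @param ... model parameters forwarded to [blgpa()] (`max_len`,
#'   `top_chains`, `ntree`, `vocab`, ...).
#' @return An object of class `blgpa_cv`: `folds` (per-fold metrics and
#'   chosen inner ratio), `macro` (averaged metrics), `config`, and
#'   `fold_pairs` (the per-fold train/test/mining pair ids, kept so the
#'   leakage audit can be re-run, see [leakage_audit()]).
#' @export
blgpa_cv <- function(pairs, graph, regime = "balanced", folds = 10,
                     inner_folds = 5, candidate_ratios = c(1, 2, 5, 10, 20, 54),
                     seed = 1L, ...) {
  blgpa_cv_impl(pairs, graph, regime = regime, folds = folds,
                inner_folds = inner_folds,
                candidate_ratios = candidate_ratios, seed = seed, ...)
}

## Implementation with an optional feature cache (.pf): a
## pair_path_features() result for exactly the dataset's pairs, in row
## order. Labels play no part in .pf, so repeated evaluations of the same
## pairs under shuffled labels (permutation nulls) can share one cache.
blgpa_cv_impl <- function(pairs, graph, regime = "balanced", folds = 10,
                          inner_folds = 5,
                          candidate_ratios = c(1, 2, 5, 10, 20, 54),
                          seed = 1L, .pf = NULL, ...) {
  if (inherits(pairs, "blgpa_dataset")) {
    ds <- pairs
  } else {
    ds <- sample_dataset(pairs, regime = regime, seed = seed,
                         candidate_ratios = candidate_ratios)
  }
  pairs <- ds$pairs
  n_pos <- sum(pairs$label == 1L)
  if (n_pos < folds)
    stop("need at least one positive per fold: ", n_pos, " positives for ",
         folds, " folds", call. = FALSE)

  dots <- list(...)
  vocab <- dots$vocab %||% default_vocabulary()
  config <- list(max_len = dots$max_len %||% 3,
                 top_chains = dots$top_chains %||% 100,
                 ntree = dots$ntree %||% 100,
                 use_pr = dots$use_pr %||% TRUE,
                 binary_se = dots$binary_se %||% FALSE,
                 degree_cap = dots$degree_cap,
                 path_cap = dots$path_cap %||% 100000L,
                 substring_match = dots$substring_match %||% FALSE,
                 classwt = dots$classwt,
                 threshold = dots$threshold %||% 0.5,
                 seed = seed, regime = ds$regime, folds = folds,
                 inner_folds = inner_folds,
                 candidate_ratios = candidate_ratios)

  layout <- se_layout(config$max_len, vocab)
  pf <- .pf %||% pair_path_features(graph, pairs, layout,
                                    degree_cap = config$degree_cap,
                                    path_cap = config$path_cap,
                                    binary_se = config$binary_se)
  if (length(pf$path_sets) != nrow(pairs))
    stop("feature cache does not match the dataset", call. = FALSE)

  set.seed(seed + 1L)
  fold_of <- stratified_folds(pairs$label, folds)
  ids <- pair_id(pairs)

  fold_rows <- vector("list", folds)
  fold_pairs <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    pool_idx <- which(fold_of != f)

    inner_ratio <- NA_real_
    ratio_sel_ids <- character(0)
    train_idx <- pool_idx
    if (ds$regime != "balanced") {
      inner_ratio <- select_inner_ratio(pairs, pf, layout, config, pool_idx,
                                        inner_folds, candidate_ratios,
                                        seed + 1000L * f)
      ratio_sel_ids <- ids[pool_idx]
      set.seed(seed + 1000L * f + 999L)
      train_idx <- subsample_ratio(pairs$label, pool_idx, inner_ratio)
    }

    fold_cfg <- config
    fold_cfg$seed <- seed + 100L + f
    model <- fit_blgpa_cached(pairs, pf, layout, fold_cfg,
                              train_idx = train_idx)
    Xte <- feature_matrix(pf, model$chains, pairs, fold_cfg, idx = test_idx)
    pred <- predict_features(model, Xte, type = "class")
    m <- positive_metrics(pairs$label[test_idx], pred)

    fold_rows[[f]] <- data.frame(fold = f, n_train = length(train_idx),
                                 n_test = length(test_idx),
                                 precision = m["precision"],
                                 recall = m["recall"], f1 = m["f1"],
                                 inner_ratio = inner_ratio,
                                 row.names = NULL)
    fold_pairs[[f]] <- list(train = ids[train_idx], test = ids[test_idx],
                            mined = ids[train_idx],
                            ratio_selection = ratio_sel_ids)
  }
  fold_df <- do.call(rbind, fold_rows)
  macro <- list(precision = mean(fold_df$precision),
                recall = mean(fold_df$recall),
                f1 = mean(fold_df$f1))
  structure(list(folds = fold_df, macro = macro, config = config,
                 fold_pairs = fold_pairs),
            class = "blgpa_cv")
}

## Subsample the negatives of a training pool to `ratio` negatives per
## positive (all positives kept); returns sorted pair indices.
subsample_ratio <- function(labels, pool_idx, ratio) {
  pos <- pool_idx[labels[pool_idx] == 1L]
  neg <- pool_idx[labels[pool_idx] == 0L]
  take <- min(length(neg), round(ratio * length(pos)))
  sort(c(pos, sample(neg, take)))
}

## Inner cross-validated choice of the training negative:positive ratio,
## maximizing mean positive-class F1 (ties favour the smaller ratio).
select_inner_ratio <- function(pairs, pf, layout, config, pool_idx,
                               inner_folds, candidate_ratios, seed) {
  set.seed(seed)
  inner_fold <- stratified_folds(pairs$label[pool_idx], inner_folds)
  mean_f1 <- numeric(length(candidate_ratios))
  for (r in seq_along(candidate_ratios)) {
    f1s <- numeric(inner_folds)
    for (g in seq_len(inner_folds)) {
      tr <- pool_idx[inner_fold != g]
      te <- pool_idx[inner_fold == g]
      set.seed(seed + 10L * r + g)
      tr_sub <- subsample_ratio(pairs$label, tr, candidate_ratios[r])
      if (length(unique(pairs$label[tr_sub])) < 2) { f1s[g] <- 0; next }
      cfg <- config
      cfg$seed <- seed + 10L * r + g
      model <- fit_blgpa_cached(pairs, pf, layout, cfg, train_idx = tr_sub)
      Xte <- feature_matrix(pf, model$chains, pairs, cfg, idx = te)
      pred <- predict_features(model, Xte, type = "class")
      f1s[g] <- positive_metrics(pairs$label[te], pred)["f1"]
    }
    mean_f1[r] <- mean(f1s)
  }
  candidate_ratios[which.max(mean_f1)]
}

#' @export
print.blgpa_cv <- function(x, ...) {
  cat("blgpa ", x$config$folds, "-fold cross-validation (",
      x$config$regime, " regime)\n", sep = "")
  print.data.frame(transform(x$folds,
                             precision = round(precision, 3),
                             recall = round(recall, 3),
                             f1 = round(f1, 3)), row.names = FALSE)
  cat(sprintf("macro: precision %.3f  recall %.3f  F1 %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  invisible(x)
}

#' Audit a cross-validation report for train/test leakage
#'
#' Verifies, from the pair ids recorded in the report, that no test-fold
#' pair entered chain mining, ratio selection or forest training of its own
#' fold.
#'
#' @param cv a [blgpa_cv()] report.
#' @return `TRUE` if the audit passes; otherwise `FALSE` with a `violations`
#'   attribute listing the offending folds.
#' @export
leakage_audit <- function(cv) {
  stopifnot(inherits(cv, "blgpa_cv"))
  bad <- integer(0)
  for (f in seq_along(cv$fold_pairs)) {
    fp <- cv$fold_pairs[[f]]
    used <- unique(c(fp$train, fp$mined, fp$ratio_selection))
    if (length(intersect(fp$test, used)) > 0) bad <- c(bad, f)
  }
  ok <- length(bad) == 0
  if (!ok) attr(ok, "violations") <- bad
  ok
}
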