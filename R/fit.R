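#' Fit a drug-gene interaction link predictor on a knowledge graph
#'
#' `blgpa()` is the package's central fitting function. Given a labeled table
#' of drug-gene pairs and a literature knowledge graph, it
#'
#' 1. enumerates all simple paths of length up to `max_len` between each pair
#'    (orientation-agnostic, see [enumerate_paths()]);
#' 2. mines relational chains from the training pairs and keeps the
#'    `top_chains` most important ones ([mine_chains()],
#'    [select_top_chains()]);
#' 3. represents each pair as the concatenation of its aggregated
#'    semantic-encoding block ([encode_path()], [aggregate_se()]) and its
#'    path-ranking block ([pr_vector()]) -- with the default vocabularies and
#'    parameters, a vector of `3 * 162 + 100 = 586` features;
#' 4. fits a random forest (100 trees by default) on these features.
#'
#' Labels follow the closed-world assumption of literature-graph link
#' prediction: a pair absent from the interaction benchmark is a negative.
#'
#' @param pairs a data.frame with columns `drug_id`, `gene_id`, `label`
#'   (0/1); both classes must be present.
#' @param graph a [knowledge_graph()] object containing all pair nodes.
#' @param max_len maximum path length l (default 3; longer paths are
#'   uninformative on dense literature graphs because hub concepts connect
#'   everything within a few hops).
#' @param top_chains number of top-ranked relational chains M kept as
#'   path-ranking features (default 100).
#' @param ntree number of trees in the random forest.
#' @param vocab a [vocabulary()] driving the semantic-encoding layout.
#' @param use_pr if `FALSE`, drop the path-ranking block entirely (the
#'   SE-only ablation); the feature vector shrinks by `top_chains`.
#' @param binary_se clip per-path SE counts to presence/absence.
#' @param degree_cap,path_cap hub safeguards, see [enumerate_paths()].
#' @param substring_match chain matching mode, see [pr_vector()].
#' @param classwt optional class weights passed to the forest (by default
#'   unweighted, the forest's standard settings).
#' @param threshold probability threshold for the positive class (default
#'   0.5).
#' @param seed integer seed; every random draw in fitting flows from it, so
#'   equal inputs and seed give an identical model.
#' @return An object of class `blgpa` with components `forest` (the fitted
#'   [randomForest::randomForest]), `chains` (the ranked chain list),
#'   `layout`, `config`, and `training` (feature matrix, labels and pair
#'   table, retained for surrogate fitting and feature selection).
#' @seealso [predict.blgpa()], [blgpa_cv()], [fit_surrogate()],
#'   [feature_importance()]
#' @examples
#' sim <- generate_kg(synthetic_config(n_drugs = 6, n_genes = 6,
#'                                     n_concepts = 12, n_articles = 10,
#'                                     seed = 7))
#' fit <- blgpa(sim$pairs, sim$graph, top_chains = 10, ntree = 25, seed = 7)
#' fit
#' @export
blgpa <- function(pairs, graph, max_len = 3, top_chains = 100, ntree = 100,
                  vocab = default_vocabulary(), use_pr = TRUE,
                  binary_se = FALSE, degree_cap = NULL, path_cap = 100000L,
                  substring_match = FALSE, classwt = NULL, threshold = 0.5,
                  seed = NULL) {
  pairs <- check_pairs(pairs)
  layout <- se_layout(max_len, vocab)
  pf <- pair_path_features(graph, pairs, layout, degree_cap = degree_cap,
                           path_cap = path_cap, binary_se = binary_se)
  config <- list(max_len = max_len, top_chains = top_chains, ntree = ntree,
                 use_pr = use_pr, binary_se = binary_se,
                 degree_cap = degree_cap, path_cap = path_cap,
                 substring_match = substring_match, classwt = classwt,
                 threshold = threshold, seed = seed)
  fit_blgpa_cached(pairs, pf, layout, config)
}

## Fit from cached per-pair features; shared by blgpa() and blgpa_cv().
## train_idx selects the pairs used for chain mining and forest training.
fit_blgpa_cached <- function(pairs, pf, layout, config,
                             train_idx = seq_len(nrow(pairs))) {
  y <- pairs$label[train_idx]
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)

  chains <- NULL
  if (config$use_pr) {
    scores <- mine_chains(pf$path_sets[train_idx], y)
    if (nrow(scores) == 0)
      stop("no relational chains observed in the training pairs", call. = FALSE)
    chains <- select_top_chains(scores, M = config$top_chains)
  }
  X <- feature_matrix(pf, chains, pairs, config, idx = train_idx)

  if (!is.null(config$seed)) set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)),
    ntree = config$ntree, classwt = config$classwt)

  structure(
    list(forest = forest, chains = chains, layout = layout, config = config,
         feature_names = colnames(X),
         training = list(x = X, y = y, pairs = pairs[train_idx, , drop = FALSE])),
    class = "blgpa")
}

feature_matrix <- function(pf, chains, pairs, config, idx) {
  se <- pf$se[idx, , drop = FALSE]
  if (!config$use_pr) return(se)
  if (isTRUE(config$substring_match)) {
    pr <- t(vapply(pf$path_sets[idx], pr_vector, chains = chains,
                   substring_match = TRUE,
                   FUN.VALUE = integer(nrow(chains))))
    colnames(pr) <- chains$rank_name
  } else {
    pr <- pr_matrix(pf$chain_counts[idx], chains)
  }
  cbind(se, pr)
}

check_pairs <- function(pairs) {
  need <- c("drug_id", "gene_id", "label")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns drug_id, gene_id, label", call. = FALSE)
  pairs <- as.data.frame(pairs)[need]
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$gene_id <- as.character(pairs$gene_id)
  pairs$label <- as.integer(pairs$label)
  if (!all(pairs$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  rownames(pairs) <- NULL
  pairs
}

pair_id <- function(pairs) paste(pairs$drug_id, pairs$gene_id, sep = "|")

#' Predict interactions for new drug-gene pairs
#'
#' Featurizes the pairs with the fitted model's chain list and layout and
#' applies the forest.
#'
#' @param object a fitted [blgpa()] model.
#' @param pairs a data.frame with columns `drug_id`, `gene_id` (a `label`
#'   column, if present, is ignored).
#' @param graph the [knowledge_graph()] to featurize against.
#' @param type `"prob"` for the positive-class probability, `"class"` for
#'   the thresholded 0/1 label.
#' @param ... unused.
#' @return A numeric (prob) or integer (class) vector, one entry per pair.
#' @export
predict.blgpa <- function(object, pairs, graph, type = c("prob", "class"),
                          ...) {
  type <- match.arg(type)
  pairs$label <- 0L  # placeholder; labels are not used for prediction
  pairs <- check_pairs(pairs)
  cfg <- object$config
  pf <- pair_path_features(graph, pairs, object$layout,
                           degree_cap = cfg$degree_cap,
                           path_cap = cfg$path_cap,
                           binary_se = cfg$binary_se)
  X <- feature_matrix(pf, object$chains, pairs, cfg, idx = seq_len(nrow(pairs)))
  predict_features(object, X, type)
}

## Predict from an already-built feature matrix.
predict_features <- function(object, X, type = c("prob", "class")) {
  type <- match.arg(type)
  p <- stats::predict(object$forest, newdata = X, type = "prob")[, "1"]
  if (type == "prob") p else as.integer(p > object$config$threshold)
}

#' @export
print.blgpa <- function(x, ...) {
  cat("blgpa link predictor\n")
  cat("  features: ", length(x$feature_names), " (SE ", x$layout$total_len,
      if (x$config$use_pr) paste0(" + PR ", nrow(x$chains)) else " , no PR",
      ")\n", sep = "")
  cat("  forest:   ", x$config$ntree, "trees;  training pairs:",
      nrow(x$training$pairs),
      sprintf("(%d positive)", sum(x$training$y == 1)), "\n")
  if (x$config$use_pr) {
    cat("  top chain (PATH0):", x$chains$chain[1], "\n")
  }
  invisible(x)
}

#' Summarize a fitted link predictor
#'
#' Reports the feature layout, out-of-bag error, and the most important
#' features and chains.
#'
#' @param object a fitted [blgpa()] model.
#' @param n_top how many top features to list.
#' @param ... unused.
#' @return A list of class `summary.blgpa`.
#' @export
summary.blgpa <- function(object, n_top = 10, ...) {
  imp <- feature_importance(object)
  out <- list(
    n_features = length(object$feature_names),
    se_len = object$layout$total_len,
    pr_len = if (object$config$use_pr) nrow(object$chains) else 0L,
    n_pairs = nrow(object$training$pairs),
    n_pos = sum(object$training$y == 1),
    oob_error = object$forest$err.rate[object$config$ntree, "OOB"],
    top_features = utils::head(imp, n_top),
    top_chains = if (object$config$use_pr)
      utils::head(as.data.frame(object$chains), 5) else NULL
  )
  class(out) <- "summary.blgpa"
  out
}

#' @export
print.summary.blgpa <- function(x, ...) {
  cat("blgpa link predictor:", x$n_pairs, "training pairs (", x$n_pos,
      "positive ),", x$n_features, "features\n")
  cat("  OOB error:", format(x$oob_error, digits = 3), "\n")
  cat("  top features:\n")
  print.data.frame(x$top_features, row.names = FALSE)
  if (!is.null(x$top_chains)) {
    cat("  top chains:\n")
    print.data.frame(x$top_chains, row.names = FALSE)
  }
  invisible(x)
}

#' Plot feature importances of a fitted link predictor
#'
#' Horizontal bar chart of the top forest feature importances (impurity
#' based, normalized to sum to one), mirroring the usual "top-40 features"
#' display for this model family.
#'
#' @param x a fitted [blgpa()] model.
#' @param n_top number of features to show.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return Invisibly, the plotted importance table.
#' @export
plot.blgpa <- function(x, n_top = 20, ...) {
  imp <- utils::head(feature_importance(x), n_top)
  graphics::barplot(rev(imp$importance), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "importance",
                    main = "blgpa feature importance", ...)
  invisible(imp)
}

#' Positive-class precision, recall and F1
#'
#' Metrics for the interaction (positive) class. Empty denominators yield 0.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return A named numeric vector `precision`, `recall`, `f1`.
#' @export
positive_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Importance-based feature selection with refit
#'
#' Masks the feature set by forest importance -- either the `top_k` most
#' important features or all features with normalized importance strictly
#' above `threshold` -- refits the forest on the masked features, and reports
#' out-of-bag positive-class metrics for both the baseline and the refit.
#'
#' @param object a fitted [blgpa()] model.
#' @param top_k keep this many features (mutually exclusive with
#'   `threshold`).
#' @param threshold keep features with normalized importance above this
#'   value.
#' @return A list of class `blgpa_fs`: `mask` (named logical), `baseline`
#'   and `selected` metric vectors, and `model` (the refitted `blgpa`
#'   object).
#' @export
select_features <- function(object, top_k = NULL, threshold = NULL) {
  stopifnot(inherits(object, "blgpa"))
  if (is.null(top_k) == is.null(threshold))
    stop("supply exactly one of top_k or threshold", call. = FALSE)
  imp <- feature_importance(object)
  keep <- if (!is.null(top_k)) utils::head(imp$feature, top_k)
          else imp$feature[imp$importance > threshold]
  mask <- object$feature_names %in% keep
  names(mask) <- object$feature_names
  if (!any(mask)) stop("feature mask is empty", call. = FALSE)

  oob_metrics <- function(forest, y)
    positive_metrics(y, as.integer(as.character(forest$predicted)))

  X <- object$training$x[, mask, drop = FALSE]
  if (!is.null(object$config$seed)) set.seed(object$config$seed)
  refit_forest <- randomForest::randomForest(
    x = X, y = factor(object$training$y, levels = c(0, 1)),
    ntree = object$config$ntree, classwt = object$config$classwt)

  refit <- object
  refit$forest <- refit_forest
  refit$feature_names <- colnames(X)
  refit$training$x <- X

  structure(list(mask = mask,
                 baseline = oob_metrics(object$forest, object$training$y),
                 selected = oob_metrics(refit_forest, object$training$y),
                 model = refit),
            class = "blgpa_fs")
}

#' @export
print.blgpa_fs <- function(x, ...) {
  cat("blgpa feature selection:", sum(x$mask), "of", length(x$mask),
      "features kept\n")
  m <- rbind(baseline = x$baseline, selected = x$selected)
  print(round(m, 4))
  invisible(x)
}
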