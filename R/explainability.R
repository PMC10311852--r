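#' Ranked feature importances of the fitted forest
#'
#' Impurity-based (mean decrease in Gini) importances of every feature,
#' normalized to sum to one and sorted in non-increasing order, with the
#' human-readable feature names of the SE/PR layout (`nod1_phsu`,
#' `rel1_TREATS`, `PATH0`, ...). Constant features get importance 0.
#'
#' @param object a fitted [blgpa()] model.
#' @return A data.frame with columns `feature` and `importance`.
#' @export
feature_importance <- function(object) {
  if (!inherits(object, "blgpa") || is.null(object$forest))
    stop("feature_importance needs a fitted blgpa model", call. = FALSE)
  imp <- object$forest$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

## ---- surrogate decision tree -------------------------------------------
## Internal tree representation: a recursive list. A leaf is
##   list(leaf = TRUE, class = 0L|1L, counts = c(`0` = n0, `1` = n1))
## and an internal node adds feature, threshold, left, right, where the
## right branch is taken when x[feature] > threshold.

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (node$leaf) return(1L)
  tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

predict_tree <- function(node, x) {
  out <- integer(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    right <- x[idx, node$feature] > node$threshold
    rec(node$right, idx[right])
    rec(node$left, idx[!right])
  }
  rec(node, seq_len(nrow(x)))
  out
}

tree_fidelity <- function(node, x, target) {
  pred <- predict_tree(node, x)
  c(accuracy = mean(pred == target),
    f1 = positive_metrics(target, pred)[["f1"]])
}

majority_class <- function(counts) {
  if (counts[["1"]] > counts[["0"]]) 1L else 0L
}

## Convert a fitted rpart object (method = "class", maxcompete = 0,
## maxsurrogate = 0) into the internal tree representation. rpart sends
## x < threshold left for continuous splits (ncat = -1); ncat = +1 flips the
## children. Thresholds are midpoints of observed values, so the internal
## "right iff x > threshold" convention agrees with rpart on any data point.
rpart_to_tree <- function(fit) {
  frame <- fit$frame
  nn <- as.integer(rownames(frame))
  ylev <- attr(fit, "ylevels")
  yval2 <- frame$yval2
  is_int <- frame$var != "<leaf>"
  split_row <- integer(nrow(frame))
  split_row[is_int] <- seq_len(sum(is_int))

  build <- function(num) {
    i <- match(num, nn)
    counts <- as.numeric(yval2[i, 1L + seq_along(ylev)])
    names(counts) <- ylev
    counts <- counts[c("0", "1")]
    cls <- as.integer(ylev[yval2[i, 1]])
    if (!is_int[i])
      return(list(leaf = TRUE, class = cls, counts = counts))
    sr <- split_row[i]
    thr <- fit$splits[sr, "index"]
    lft <- build(2L * num)
    rgt <- build(2L * num + 1L)
    if (fit$splits[sr, "ncat"] > 0) { tmp <- lft; lft <- rgt; rgt <- tmp }
    list(leaf = FALSE, feature = as.character(frame$var[i]), threshold = thr,
         class = cls, counts = counts, left = lft, right = rgt)
  }
  build(1L)
}

new_surrogate <- function(tree, feature_names, x, target, params = list(),
                          cv_fidelity = NULL, floor_unmet = FALSE) {
  fid <- tree_fidelity(tree, x, target)
  structure(
    list(tree = tree, feature_names = feature_names,
         fidelity = list(accuracy = fid[["accuracy"]], f1 = fid[["f1"]],
                         cv = cv_fidelity),
         depth = tree_depth(tree), n_leaves = tree_n_leaves(tree),
         params = params, floor_unmet = floor_unmet,
         training = list(x = x, target = target)),
    class = "blgpa_surrogate")
}

#' Distill the forest into a decision-tree surrogate
#'
#' Trains a single decision tree to imitate the forest: the tree's targets
#' are the forest's *predicted* labels on the training pairs, not the ground
#' truth, so the tree approximates the model rather than the data. Tree
#' hyperparameters (maximum depth and minimum leaf size) are chosen from a
#' grid by cross-validated fidelity -- the agreement between tree and forest
#' on held-out samples -- and the chosen tree is refit on all samples.
#' Fidelity is reported as accuracy and positive-class F1 against the forest
#' predictions, both on the training pool and as the cross-validation
#' estimate.
#'
#' @param object a fitted [blgpa()] model.
#' @param x feature matrix to distill on; defaults to the model's training
#'   features.
#' @param grid named list with numeric vectors `maxdepth` and `minbucket`
#'   (and optionally `cp`) defining the tuning grid. A single-combination
#'   grid with `cv_folds = 0` fits an unrestricted/untuned tree directly.
#' @param cv_folds folds of the fidelity cross-validation (default 5; 0 or 1
#'   skips tuning and uses the first grid combination).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `blgpa_surrogate` holding the tree, its depth
#'   and leaf count, the fidelity estimates, and the distillation data (kept
#'   so [post_prune()] can re-evaluate fidelity).
#' @seealso [post_prune()], [trace_decision()]
#' @export
fit_surrogate <- function(object, x = NULL,
                          grid = list(maxdepth = c(2, 3, 4, 5, 6, 8),
                                      minbucket = c(1, 5, 10)),
                          cv_folds = 5, seed = 1L) {
  stopifnot(inherits(object, "blgpa"))
  if (is.null(x)) x <- object$training$x
  target <- predict_features(object, x, type = "class")
  if (length(unique(target)) < 2)
    stop("forest predicts a single class everywhere; surrogate target is degenerate",
         call. = FALSE)

  grid$cp <- grid$cp %||% 0
  combos <- expand.grid(maxdepth = grid$maxdepth, minbucket = grid$minbucket,
                        cp = grid$cp)
  df <- as.data.frame(x)
  df$.target <- factor(target, levels = c(0, 1))

  fit_one <- function(rows, combo) {
    rpart::rpart(.target ~ ., data = df[rows, , drop = FALSE],
                 method = "class",
                 control = rpart::rpart.control(
                   maxdepth = combo$maxdepth, minbucket = combo$minbucket,
                   minsplit = max(2L, 2L * combo$minbucket), cp = combo$cp,
                   maxcompete = 0, maxsurrogate = 0, usesurrogate = 0,
                   xval = 0))
  }

  cv_fid <- NULL
  if (cv_folds >= 2 && nrow(combos) > 1) {
    set.seed(seed)
    fold <- stratified_folds(target, cv_folds)
    acc <- f1 <- matrix(0, nrow(combos), cv_folds)
    for (ci in seq_len(nrow(combos))) {
      for (g in seq_len(cv_folds)) {
        tr <- which(fold != g); te <- which(fold == g)
        fit <- fit_one(tr, combos[ci, ])
        tree <- rpart_to_tree(fit)
        fid <- tree_fidelity(tree, x[te, , drop = FALSE], target[te])
        acc[ci, g] <- fid[["accuracy"]]; f1[ci, g] <- fid[["f1"]]
      }
    }
    score <- rowMeans(acc)
    ## ties favour the shallower, then the coarser-leaved tree
    best <- order(-score, combos$maxdepth, -combos$minbucket)[1]
    cv_fid <- list(accuracy = score[best], f1 = rowMeans(f1)[best])
  } else {
    best <- 1L
  }
  combo <- combos[best, ]
  fit <- fit_one(seq_len(nrow(df)), combo)
  if (fit$frame$var[1] == "<leaf>" && nrow(fit$frame) == 1 &&
      length(unique(target)) > 1 && combo$cp == 0)
    warning("surrogate degenerated to a single leaf", call. = FALSE)
  new_surrogate(rpart_to_tree(fit), colnames(x), x, target,
                params = as.list(combo), cv_fidelity = cv_fid)
}

#' @export
print.blgpa_surrogate <- function(x, ...) {
  cat("blgpa surrogate decision tree: depth", x$depth, ",", x$n_leaves,
      "leaves\n")
  cat(sprintf("  fidelity vs forest (training pool): accuracy %.3f, F1 %.3f\n",
              x$fidelity$accuracy, x$fidelity$f1))
  if (!is.null(x$fidelity$cv))
    cat(sprintf("  fidelity (cross-validated): accuracy %.3f, F1 %.3f\n",
                x$fidelity$cv$accuracy, x$fidelity$cv$f1))
  if (isTRUE(x$floor_unmet))
    cat("  NOTE: requested fidelity floor was unattainable; tree is unpruned\n")
  invisible(x)
}

## Collapse the subtree at `address` (character vector of "l"/"r") into a
## leaf labeled with the majority class of its stored training counts.
collapse_at <- function(node, address) {
  if (length(address) == 0)
    return(list(leaf = TRUE, class = majority_class(node$counts),
                counts = node$counts))
  side <- if (address[1] == "l") "left" else "right"
  node[[side]] <- collapse_at(node[[side]], address[-1])
  node
}

internal_addresses <- function(node, prefix = character(0)) {
  if (node$leaf) return(list())
  c(list(prefix),
    internal_addresses(node$left, c(prefix, "l")),
    internal_addresses(node$right, c(prefix, "r")))
}

#' Iteratively post-prune a surrogate tree
#'
#' Greedy depth reduction under a fidelity constraint: at each iteration,
#' every internal node is tentatively collapsed into a majority-class leaf,
#' and the collapse that loses the least fidelity (accuracy against the
#' forest predictions) is committed, provided fidelity stays at or above
#' `fidelity_floor`. Iteration stops when no further collapse respects the
#' floor. On the distillation data itself fidelity is non-increasing and
#' depth non-increasing across iterations. If even the unpruned tree is
#' below the floor, it is returned unchanged with the `floor_unmet` flag
#' set.
#'
#' @param surrogate a [fit_surrogate()] result.
#' @param fidelity_floor minimum acceptable fidelity accuracy (default
#'   0.95).
#' @param x,target optional evaluation data (feature matrix and forest
#'   labels); default to the distillation data stored in the surrogate.
#' @return A pruned `blgpa_surrogate`.
#' @export
post_prune <- function(surrogate, fidelity_floor = 0.95, x = NULL,
                       target = NULL) {
  stopifnot(inherits(surrogate, "blgpa_surrogate"))
  if (is.null(x)) x <- surrogate$training$x
  if (is.null(target)) target <- surrogate$training$target
  tree <- surrogate$tree

  if (tree_fidelity(tree, x, target)[["accuracy"]] < fidelity_floor) {
    out <- new_surrogate(tree, surrogate$feature_names, x, target,
                         params = surrogate$params,
                         cv_fidelity = surrogate$fidelity$cv,
                         floor_unmet = TRUE)
    return(out)
  }

  repeat {
    addrs <- internal_addresses(tree)
    if (length(addrs) == 0) break
    accs <- depths <- numeric(length(addrs))
    for (i in seq_along(addrs)) {
      cand <- collapse_at(tree, addrs[[i]])
      accs[i] <- tree_fidelity(cand, x, target)[["accuracy"]]
      depths[i] <- tree_depth(cand)
    }
    ok <- accs >= fidelity_floor
    if (!any(ok)) break
    ## least fidelity loss; ties resolved toward the shallower result,
    ## then the first node in preorder
    pick <- which(ok)[order(-accs[ok], depths[ok])[1]]
    tree <- collapse_at(tree, addrs[[pick]])
  }

  new_surrogate(tree, surrogate$feature_names, x, target,
                params = c(surrogate$params,
                           list(fidelity_floor = fidelity_floor)),
                cv_fidelity = surrogate$fidelity$cv)
}

#' Trace the decision rule applied to one pair
#'
#' Walks the surrogate tree with a pair's feature vector and returns the
#' root-to-leaf rule: the ordered list of threshold conditions, the
#' predicted class, and the leaf purity (majority count over leaf total).
#'
#' @param surrogate a [fit_surrogate()] (optionally [post_prune()]d) result.
#' @param x a named numeric feature vector matching the surrogate's layout.
#' @return An object of class `blgpa_rule`; its print method renders e.g.
#'   `IF rel1_TREATS > 49.5 AND PATH2 > 8.5 THEN Interaction (800/841)`.
#' @export
trace_decision <- function(surrogate, x) {
  stopifnot(inherits(surrogate, "blgpa_surrogate"))
  if (is.null(names(x)) || !all(surrogate$feature_names %in% names(x)))
    stop("feature vector does not match the surrogate's layout", call. = FALSE)
  node <- surrogate$tree
  conds <- list()
  while (!node$leaf) {
    if (x[[node$feature]] > node$threshold) {
      conds[[length(conds) + 1L]] <-
        data.frame(feature = node$feature, comparator = ">",
                   threshold = node$threshold, stringsAsFactors = FALSE)
      node <- node$right
    } else {
      conds[[length(conds) + 1L]] <-
        data.frame(feature = node$feature, comparator = "\u2264",
                   threshold = node$threshold, stringsAsFactors = FALSE)
      node <- node$left
    }
  }
  conditions <- if (length(conds) > 0) do.call(rbind, conds)
    else data.frame(feature = character(0), comparator = character(0),
                    threshold = numeric(0), stringsAsFactors = FALSE)
  structure(
    list(conditions = conditions, class = node$class,
         majority = unname(node$counts[[as.character(node$class)]]),
         total = unname(sum(node$counts))),
    class = "blgpa_rule")
}

#' @export
format.blgpa_rule <- function(x, ...) {
  label <- if (x$class == 1L) "Interaction" else "No interaction"
  cond <- if (nrow(x$conditions) == 0) "TRUE" else
    paste(sprintf("%s %s %s", x$conditions$feature, x$conditions$comparator,
                  format(x$conditions$threshold, trim = TRUE)),
          collapse = " AND ")
  sprintf("IF %s THEN %s (%d/%d)", cond, label,
          as.integer(x$majority), as.integer(x$total))
}

#' @export
print.blgpa_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
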