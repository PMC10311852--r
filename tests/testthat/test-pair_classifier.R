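test_that("featurized pairs have the documented concatenated length", {
  fx <- fig3_fixture()
  lay <- se_layout(3)
  chains100 <- chain_list(c(fx$chains$chain,
                            sprintf("TREATS|USES|PATH_FILLER_%02d", 1:94)))
  v <- featurize_pair(fx$graph, "C1122962", "C0812265", chains100, lay)
  expect_length(v, 586)  # 3 x 162 + 100

  ## nonzeros sit exactly at the worked example's SE slots plus PATH0/PATH5
  expect_setequal(names(v)[v != 0],
                  c(names(fx$manifest$se), names(fx$manifest$pr)))

  ## a disconnected pair featurizes to the zero vector
  g2 <- mk_kg(pred_row("d9", "TREATS", "c9"), pred_row("g9", "AFFECTS", "c8",
                                                       st = "gngm", ot = "dsyn"))
  v0 <- featurize_pair(g2, "d9", "g9", chains100, lay)
  expect_length(v0, 586)
  expect_true(all(v0 == 0))
})

test_that("sampling regimes draw the stated class ratios, reproducibly", {
  pairs <- data.frame(
    drug_id = sprintf("d%03d", 1:430),
    gene_id = "g1",
    label = c(rep(1L, 30), rep(0L, 400)))
  bal <- sample_dataset(pairs, "balanced", seed = 4)
  expect_equal(as.vector(table(bal$pairs$label)), c(30, 30))
  r10 <- sample_dataset(pairs, "ratio_1_10", seed = 4)
  expect_equal(sum(r10$pairs$label == 0), 300)
  expect_equal(sum(r10$pairs$label == 1), 30)
  ## deterministic given the seed
  expect_identical(sample_dataset(pairs, "balanced", seed = 4)$pairs,
                   bal$pairs)
  expect_false(identical(sample_dataset(pairs, "balanced", seed = 5)$pairs,
                         bal$pairs))
  ## 1:54 would need 1620 negatives
  expect_error(sample_dataset(pairs, "ratio_1_54", seed = 4), "negatives")
})

## small, fully separable benchmark shared by the model tests
sep_sim <- generate_kg(synthetic_config(
  n_drugs = 6, n_genes = 6, n_concepts = 10, n_articles = 12,
  planted_chains = list(list(chain = c("INTERACTS_WITH", "TREATS", "AFFECTS"),
                             p_pos = 1, p_neg = 0)),
  background_edge_rate = 0, mention_rate = 0.5, seed = 21))

test_that("the forest separates a fully planted benchmark on its training set", {
  fit <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 20, ntree = 50,
               seed = 2)
  expect_s3_class(fit, "blgpa")
  expect_length(fit$feature_names, 486 + nrow(fit$chains))
  pred <- predict_features(fit, fit$training$x, type = "class")
  expect_equal(positive_metrics(fit$training$y, pred)[["f1"]], 1.0)
  ## the planted chain is rank 0
  expect_equal(fit$chains$chain[1], "INTERACTS_WITH|TREATS|AFFECTS")
})

test_that("fits and predictions are reproducible from the seed", {
  fit1 <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 10, ntree = 30,
                seed = 7)
  fit2 <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 10, ntree = 30,
                seed = 7)
  p1 <- predict(fit1, sep_sim$pairs, sep_sim$graph, type = "prob")
  p2 <- predict(fit2, sep_sim$pairs, sep_sim$graph, type = "prob")
  expect_identical(p1, p2)
})

test_that("single-class training data is rejected", {
  pos_only <- sep_sim$pairs[sep_sim$pairs$label == 1, ]
  expect_error(blgpa(pos_only, sep_sim$graph, top_chains = 5, ntree = 10,
                     seed = 1), "both classes")
})

test_that("dropping the PR block shrinks the feature vector by M exactly", {
  fit_pr <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 10, ntree = 20,
                  seed = 3)
  fit_se <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 10, ntree = 20,
                  seed = 3, use_pr = FALSE)
  expect_equal(length(fit_pr$feature_names) - length(fit_se$feature_names),
               nrow(fit_pr$chains))
  expect_length(fit_se$feature_names, 486)
})

test_that("cross-validation partitions pairs and audits clean", {
  cv <- blgpa_cv(sep_sim$pairs, sep_sim$graph, regime = "balanced",
                 folds = 5, top_chains = 10, ntree = 30, seed = 5)
  ids <- unlist(lapply(cv$fold_pairs, `[[`, "test"))
  expect_equal(sort(ids), sort(pair_id <- unique(ids)))  # no duplicates
  expect_equal(length(ids),
               sum(cv$folds$n_test))
  for (fp in cv$fold_pairs) {
    expect_length(intersect(fp$train, fp$test), 0)
    expect_length(intersect(fp$mined, fp$test), 0)
  }
  expect_true(leakage_audit(cv))
  ## fully separable signal: near-perfect macro F1
  expect_gte(cv$macro$f1, 0.9)
  ## metrics bounded
  expect_true(all(cv$folds$f1 >= 0 & cv$folds$f1 <= 1))
})

test_that("ratio regime selects an inner ratio and keeps test imbalance", {
  sim <- generate_kg(synthetic_config(
    n_drugs = 4, n_genes = 22, n_concepts = 10, n_articles = 12,
    planted_chains = list(list(chain = c("INTERACTS_WITH", "TREATS", "AFFECTS"),
                               p_pos = 1, p_neg = 0)),
    background_edge_rate = 0.5, mention_rate = 0.5,
    pos_fraction = 1 / 11, seed = 31))
  cv <- blgpa_cv(sim$pairs, sim$graph, regime = "ratio_1_10", folds = 2,
                 inner_folds = 2, candidate_ratios = c(1, 10),
                 top_chains = 5, ntree = 20, seed = 6)
  expect_true(all(cv$folds$inner_ratio %in% c(1, 10)))
  expect_true(leakage_audit(cv))
  ## test folds keep roughly the 1:10 imbalance of the sampled dataset
  expect_gt(sum(cv$folds$n_test), 60)
})

test_that("feature selection masks by importance and refits", {
  fit <- blgpa(sep_sim$pairs, sep_sim$graph, top_chains = 10, ntree = 30,
               seed = 9)
  ## keeping every feature reproduces the baseline exactly (same seed)
  fs_all <- select_features(fit, top_k = length(fit$feature_names))
  expect_true(all(fs_all$mask))
  expect_equal(fs_all$baseline, fs_all$selected)

  ## a zero threshold drops exactly the zero-importance features
  fs_thr <- select_features(fit, threshold = 0)
  zero_cols <- colSums(fit$training$x) == 0
  expect_true(all(!fs_thr$mask[zero_cols]))

  ## the decisive planted features survive a top-40 mask
  fs40 <- select_features(fit, top_k = 40)
  expect_true(fs_thr$mask[["PATH0"]])
  expect_true(fs40$mask[["PATH0"]])
  expect_error(select_features(fit, top_k = 10, threshold = 0.1),
               "exactly one")
})
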