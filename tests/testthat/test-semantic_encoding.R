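test_that("default layout has 162-wide blocks and 486 total features", {
  lay <- se_layout(3)
  expect_equal(lay$block_width, 162)
  expect_equal(lay$total_len, 486)
  expect_equal(lay$feature_names[1], "nod1_aapp")
  expect_equal(lay$feature_names[128], "rel1_ADMINISTERED_TO")
  expect_equal(lay$feature_names[163], "nod2_aapp")
  ## layout adapts to the supplied vocabulary
  small <- se_layout(2, vocabulary(c("phsu", "gngm"), c("TREATS", "AFFECTS")))
  expect_equal(small$total_len, 8)
})

test_that("worked-example paths encode unit values at the documented slots", {
  fx <- fig3_fixture()
  lay <- se_layout(3)
  ps <- enumerate_paths(fx$graph, "C1122962", "C0812265", 3)
  vs <- lapply(ps$paths, encode_path, graph = fx$graph, layout = lay)
  agg <- aggregate_se(vs)
  expect_equal(unclass(agg)[names(fx$manifest$se)],
               fx$manifest$se[names(fx$manifest$se)],
               ignore_attr = TRUE)
  expect_equal(unname(agg["rel1_INTERACTS_WITH"]), 2)
  nz <- names(agg)[unclass(agg) != 0]
  expect_setequal(nz, names(fx$manifest$se))
  ## per-path vectors are 0/1 under unit support
  for (v in vs) expect_true(all(unclass(v) %in% 0:1))
})

test_that("blocks beyond the path length stay zero", {
  g <- mk_kg(pred_row("d", "TREATS", "c", ot = "dsyn"))
  lay <- se_layout(3)
  v <- encode_path(g, list(nodes = c("d", "c"), relations = "TREATS"), lay)
  expect_true(all(unclass(v)[163:486] == 0))
  expect_equal(unname(v["rel1_TREATS"]), 1)
  expect_equal(unname(v["nod1_phsu"]), 1)
})

test_that("article multiplicity drives the counts; binary mode clips them", {
  g <- mk_kg(pred_row("d", "TREATS", "c", st = "phsu", ot = "dsyn", art = "p1"),
             pred_row("d", "TREATS", "c", st = "phsu", ot = "dsyn", art = "p2"),
             pred_row("d", "TREATS", "c", st = "phsu", ot = "dsyn", art = "p3"))
  lay <- se_layout(2)
  path <- list(nodes = c("d", "c"), relations = "TREATS")
  v <- encode_path(g, path, lay)
  expect_equal(unname(v["nod1_phsu"]), 3)
  expect_equal(unname(v["rel1_TREATS"]), 3)
  expect_equal(unname(encode_path(g, path, lay, binary = TRUE)["rel1_TREATS"]),
               1)
})

test_that("one article attributing two types credits both type features", {
  g <- mk_kg(pred_row("d", "TREATS", "c", st = "phsu", art = "p1"),
             pred_row("d", "TREATS", "c", st = "orch", art = "p1"))
  v <- encode_path(g, list(nodes = c("d", "c"), relations = "TREATS"),
                   se_layout(1))
  expect_equal(unname(v["nod1_phsu"]), 1)
  expect_equal(unname(v["nod1_orch"]), 1)
  expect_equal(unname(v["rel1_TREATS"]), 1)  # one distinct article
})

test_that("unscored relations are skipped with a warning, types still counted", {
  g <- mk_kg(pred_row("d", "is_a", "c", st = "phsu", ot = "phsu", art = ""))
  expect_warning(
    v <- encode_path(g, list(nodes = c("d", "c"), relations = "is_a"),
                     se_layout(1)),
    "is_a")
  expect_equal(unname(v["nod1_phsu"]), 1)
  expect_equal(sum(unclass(v)), 1)
})

test_that("aggregation is linear, order-invariant, and layout-checked", {
  set.seed(3)
  g <- random_kg(n_nodes = 8, n_edges = 20, n_rels = 3, seed = 3)
  lay <- se_layout(3)
  ps <- enumerate_paths(g, "n01", "n02", 3)
  vs <- lapply(ps$paths, encode_path, graph = g, layout = lay)
  expect_gt(length(vs), 2)
  total <- aggregate_se(vs)

  ## any partition sums to the same aggregate
  cut <- sample(length(vs) - 1, 1)
  part <- aggregate_se(list(aggregate_se(vs[1:cut]),
                            aggregate_se(vs[(cut + 1):length(vs)])))
  expect_equal(unclass(part), unclass(total))
  ## permutation invariance
  expect_equal(unclass(aggregate_se(vs[sample(length(vs))])), unclass(total))
  ## identity and empty cases
  expect_equal(unclass(aggregate_se(vs[1])), unclass(vs[[1]]))
  expect_equal(sum(aggregate_se(list(), layout = lay)), 0)

  v2 <- encode_path(g, ps$paths[[1]], se_layout(2))
  expect_error(aggregate_se(list(vs[[1]], v2)), "layout")
})

test_that("under unit support, relation-block sums count paths reaching it", {
  fx <- fig3_fixture()
  lay <- se_layout(3)
  ps <- enumerate_paths(fx$graph, "C1122962", "C0812265", 3)
  agg <- aggregate_se(lapply(ps$paths, encode_path, graph = fx$graph,
                             layout = lay))
  n_types <- length(lay$vocab$semantic_types)
  for (j in 1:3) {
    block <- unclass(agg)[((j - 1) * 162 + n_types + 1):(j * 162)]
    reach <- sum(vapply(ps$paths, function(p) length(p$relations) >= j,
                        logical(1)))
    expect_equal(sum(block), reach)
  }
})

test_that("paths absent from the graph are rejected", {
  g <- mk_kg(pred_row("d", "TREATS", "c"))
  expect_error(encode_path(g, list(nodes = c("d", "c"), relations = "AFFECTS"),
                           se_layout(1)), "not in the graph")
  expect_error(encode_path(g, list(nodes = c("d", "c"),
                                   relations = c("TREATS", "TREATS")),
                           se_layout(3)), "one more node")
})
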