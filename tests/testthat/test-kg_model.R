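test_that("default vocabulary ships the expected code sets", {
  v <- default_vocabulary()
  expect_length(v$semantic_types, 127)
  expect_length(v$relations, 35)
  expect_false(anyDuplicated(v$semantic_types) > 0)
  expect_false(anyDuplicated(v$relations) > 0)
  expect_true(all(c("MENTIONED_IN", "HAS_MESH", "INTERACTS_WITH", "TREATS",
                    "AFFECTS", "LITERATURE_DTI") %in% v$relations))
  expect_identical(v$auxiliary_relations, "is_a")
  expect_error(vocabulary(c("phsu", "phsu"), "TREATS"), "unique")
})

test_that("predication TSV loading counts rows, nodes and deduplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- rbind(pred_row("d1", "TREATS", "c1"),
                pred_row("c1", "AFFECTS", "g1", st = "dsyn", art = "a2"),
                pred_row("d1", "INTERACTS_WITH", "g1"))
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_predications(f)
  expect_equal(nrow(g$predications), 3)
  expect_equal(nrow(g$nodes), 3)

  ## identical row twice collapses to one predication
  writeLines(c("subject_id\tsubject_type\trelation\tobject_id\tobject_type\tarticle_id",
               "d1\tphsu\tTREATS\tc1\tdsyn\ta1",
               "d1\tphsu\tTREATS\tc1\tdsyn\ta1"), f)
  expect_equal(nrow(load_predications(f)$predications), 1)
})

test_that("loader enforces the relation vocabulary and column structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tsubject_type\trelation\tobject_id\tobject_type\tarticle_id",
               "d1\tphsu\tFOO\tc1\tdsyn\ta1"), f)
  expect_error(load_predications(f), "FOO")
  g <- load_predications(f, allow_unknown_relations = TRUE)
  expect_equal(g$predications$relation, "FOO")

  writeLines(c("subject_id\tsubject_type\trelation\tobject_id\tobject_type\tarticle_id",
               "d1\tphsu\tTREATS\tc1\tdsyn\ta1\textra\tcols"), f)
  expect_error(load_predications(f), "line 2")
})

test_that("node kinds are inferred and kind conflicts rejected", {
  g <- mk_kg(pred_row("c1", "MENTIONED_IN", "a9", ot = "", art = "a9"),
             pred_row("a9", "HAS_MESH", "c2", st = "", ot = "dsyn", art = "a9"))
  expect_equal(g$nodes$kind[g$nodes$id == "a9"], "article")
  expect_setequal(g$nodes$id[g$nodes$kind == "concept"], c("c1", "c2"))

  ## a9 as a MENTIONED_IN object and a semantic-relation subject: conflict
  expect_error(
    mk_kg(pred_row("c1", "MENTIONED_IN", "a9", ot = "", art = "a9"),
          pred_row("a9", "TREATS", "c2")),
    "article")
})

test_that("triple_support counts distinct articles in either orientation", {
  g <- mk_kg(pred_row("d1", "TREATS", "c1", art = "p1"),
             pred_row("d1", "TREATS", "c1", art = "p2"),
             pred_row("d1", "TREATS", "c1", art = "p3"),
             ## same article, two attributed subject types: one article
             pred_row("d1", "AFFECTS", "c2", st = "phsu", art = "p1"),
             pred_row("d1", "AFFECTS", "c2", st = "orch", art = "p1"),
             pred_row("c3", "is_a", "c1", st = "dsyn", ot = "dsyn", art = ""))
  expect_equal(triple_support(g, "d1", "TREATS", "c1"), 3)
  expect_equal(triple_support(g, "c1", "TREATS", "d1"), 3)  # reverse lookup
  expect_equal(triple_support(g, "d1", "AFFECTS", "c2"), 1)
  expect_equal(triple_support(g, "d1", "INTERACTS_WITH", "c1"), 0)
  expect_equal(triple_support(g, "c3", "is_a", "c1"), 1)  # ontology support
  expect_error(triple_support(g, "nope", "TREATS", "c1"), "unknown node")
})

test_that("kg_neighbors lists sorted distinct incidences, collapsing provenance", {
  g <- mk_kg(pred_row("a", "TREATS", "b", art = "p1"),
             pred_row("a", "TREATS", "b", art = "p2"),
             pred_row("c", "AFFECTS", "a", st = "dsyn", ot = "phsu"))
  nb <- kg_neighbors(g, "a")
  expect_equal(nb$relation, c("AFFECTS", "TREATS"))
  expect_equal(nb$neighbor, c("c", "b"))
  expect_equal(nb$orientation, c("reverse", "forward"))
  ## provenance collapsed: a-TREATS-b appears once despite two articles
  expect_equal(sum(nb$neighbor == "b"), 1)
  expect_error(kg_neighbors(g, "zz"), "unknown node")
})

test_that("write/load round-trips up to row order; adjacency matches edges", {
  sim <- generate_kg(synthetic_config(n_drugs = 4, n_genes = 4,
                                      n_concepts = 8, n_articles = 8,
                                      seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predications(sim$graph, f)
  g2 <- load_predications(f)
  key <- function(p) do.call(paste, c(p, sep = "\x1f"))
  expect_setequal(key(g2$predications), key(sim$graph$predications))

  ## sum of forward-orientation adjacency entries = distinct triples
  fwd <- sum(vapply(sim$graph$nodes$id, function(id)
    sum(kg_neighbors(sim$graph, id)$orientation == "forward"), integer(1)))
  expect_equal(fwd, nrow(sim$graph$edges))
})
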