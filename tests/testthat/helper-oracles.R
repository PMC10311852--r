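## Test helpers: independent oracles and small graph builders.

## One predication row.
pred_row <- function(s, r, o, st = "phsu", ot = "gngm", art = "a1") {
  data.frame(subject_id = s, subject_type = st, relation = r,
             object_id = o, object_type = ot, article_id = art,
             stringsAsFactors = FALSE)
}

mk_kg <- function(..., vocab = default_vocabulary()) {
  knowledge_graph(do.call(rbind, list(...)), vocab = vocab)
}

## Brute-force path oracle, independent of the package's DFS: enumerate all
## simple node sequences from the edge table, then expand every combination
## of relation labels available on each step (either stored orientation).
oracle_paths <- function(graph, source, target, max_len) {
  edges <- graph$edges
  rels_between <- function(a, b)
    sort(unique(c(edges$relation[edges$subject_id == a & edges$object_id == b],
                  edges$relation[edges$subject_id == b & edges$object_id == a])))
  nodes <- graph$nodes$id
  out <- list()
  extend <- function(seq_nodes) {
    last <- seq_nodes[length(seq_nodes)]
    if (length(seq_nodes) > 1 && last == target) {
      rel_opts <- lapply(seq_len(length(seq_nodes) - 1), function(j)
        rels_between(seq_nodes[j], seq_nodes[j + 1]))
      combos <- expand.grid(rel_opts, stringsAsFactors = FALSE)
      for (k in seq_len(nrow(combos)))
        out[[length(out) + 1L]] <<- list(
          nodes = seq_nodes, relations = as.character(unlist(combos[k, ])))
      return()
    }
    if (length(seq_nodes) - 1L >= max_len) return()
    for (nb in nodes) {
      if (nb %in% seq_nodes) next
      if (length(rels_between(last, nb)) == 0) next
      extend(c(seq_nodes, nb))
    }
  }
  extend(source)
  path_sort(out)
}

path_sort <- function(paths) {
  if (length(paths) <= 1) return(paths)
  keys <- vapply(paths, path_key, character(1))
  paths[order(keys)]
}

path_key <- function(p)
  paste(paste(p$nodes, collapse = "\x1f"),
        paste(p$relations, collapse = "\x1f"), sep = "\x1e")

## Random typed multigraph over <= n_nodes nodes, semantic relations only.
random_kg <- function(n_nodes = 8, n_edges = 14, n_rels = 3, seed = 1) {
  set.seed(seed)
  vocab <- default_vocabulary()
  rels <- setdiff(vocab$relations, c("MENTIONED_IN", "HAS_MESH"))
  rels <- rels[seq_len(n_rels)]
  ids <- sprintf("n%02d", seq_len(n_nodes))
  s <- sample(ids, n_edges, replace = TRUE)
  o <- sample(ids, n_edges, replace = TRUE)
  ok <- s != o
  p <- data.frame(subject_id = s[ok], subject_type = "dsyn",
                  relation = sample(rels, sum(ok), replace = TRUE),
                  object_id = o[ok], object_type = "gngm",
                  article_id = sample(c("", sprintf("a%d", 1:4)), sum(ok),
                                      replace = TRUE),
                  stringsAsFactors = FALSE)
  ## anchor the two query endpoints so they always exist
  p <- rbind(p, data.frame(subject_id = ids[1], subject_type = "dsyn",
                           relation = rels[1], object_id = ids[2],
                           object_type = "gngm", article_id = "a1",
                           stringsAsFactors = FALSE))
  knowledge_graph(p, vocab)
}

## A path-set shell around hand-written paths (enough structure for
## pr_vector / mine_chains, which read only $paths).
mk_paths <- function(paths, source = "d", target = "g") {
  structure(list(source = source, target = target, paths = paths,
                 truncated = FALSE), class = "blgpa_paths")
}

mk_path <- function(relations, nodes = NULL) {
  if (is.null(nodes))
    nodes <- c("d", sprintf("v%d", seq_len(length(relations) - 1)), "g")
  list(nodes = nodes, relations = relations)
}

## A minimal object that quacks like a fitted blgpa model, for surrogate and
## importance tests that need a forest but not the graph pipeline.
mk_forest_model <- function(X, y, ntree = 50, seed = 42) {
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                       ntree = ntree)
  structure(list(forest = forest,
                 config = list(threshold = 0.5, ntree = ntree, seed = seed),
                 feature_names = colnames(X),
                 training = list(x = X, y = y)),
            class = "blgpa")
}
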