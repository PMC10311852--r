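#' Construct a literature knowledge graph from predications
#'
#' The graph is a provenance-aware multigraph: each predication is a typed
#' subject--relation--object triple extracted from one article (the
#' `article_id`), so the same triple asserted in several articles is kept as
#' several predications. Two auxiliary edge families tie the literature in:
#' `MENTIONED_IN` (concept occurs in an article) and `HAS_MESH` (article is
#' indexed under a MeSH concept). Node kinds are inferred, never declared: an
#' id that appears as a `MENTIONED_IN` object or a `HAS_MESH` subject is an
#' article node, everything else is a concept node, and an id playing both
#' roles is an error.
#'
#' @param predications a data.frame with character columns `subject_id`,
#'   `subject_type`, `relation`, `object_id`, `object_type`, `article_id`.
#'   Empty strings mark missing types (article nodes) and missing provenance
#'   (ontology-derived `is_a` edges). Duplicate rows are collapsed.
#' @param vocab a [vocabulary()]; every relation label must be a member of
#'   its scored or auxiliary set unless `allow_unknown_relations` is `TRUE`.
#' @param allow_unknown_relations if `TRUE`, relations outside the vocabulary
#'   are admitted in the graph (they are never scored as features).
#' @return An object of class `blgpa_kg` with elements `predications` (the
#'   deduplicated predication table), `nodes` (data.frame of `id`, `kind`),
#'   `edges` (distinct subject--relation--object triples) and `vocab`.
#' @seealso [load_predications()], [triple_support()], [kg_neighbors()]
#' @export
knowledge_graph <- function(predications, vocab = default_vocabulary(),
                            allow_unknown_relations = FALSE) {
  cols <- c("subject_id", "subject_type", "relation",
            "object_id", "object_type", "article_id")
  if (!all(cols %in% names(predications)))
    stop("predications must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  p <- predications[cols]
  for (cc in cols) {
    p[[cc]] <- as.character(p[[cc]])
    p[[cc]][is.na(p[[cc]])] <- ""
  }
  if (any(p$subject_id == "") || any(p$object_id == ""))
    stop("subject_id and object_id must be non-empty", call. = FALSE)

  known <- all_relations(vocab)
  unknown <- setdiff(unique(p$relation), known)
  if (length(unknown) > 0 && !allow_unknown_relations)
    stop("unknown relation label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  p <- unique(p)
  rownames(p) <- NULL

  ## node-kind inference from the literature-link edges
  art <- unique(c(p$object_id[p$relation == "MENTIONED_IN"],
                  p$subject_id[p$relation == "HAS_MESH"]))
  con <- unique(c(p$subject_id[p$relation == "MENTIONED_IN"],
                  p$object_id[p$relation == "HAS_MESH"],
                  p$subject_id[!p$relation %in% c("MENTIONED_IN", "HAS_MESH")],
                  p$object_id[!p$relation %in% c("MENTIONED_IN", "HAS_MESH")]))
  clash <- intersect(art, con)
  if (length(clash) > 0)
    stop("node(s) used both as article and as concept: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  ids <- sort(unique(c(art, con)))
  nodes <- data.frame(id = ids,
                      kind = ifelse(ids %in% art, "article", "concept"),
                      stringsAsFactors = FALSE)

  edges <- unique(p[c("subject_id", "relation", "object_id")])
  rownames(edges) <- NULL

  g <- structure(
    list(predications = p, nodes = nodes, edges = edges, vocab = vocab),
    class = "blgpa_kg"
  )
  g$index <- build_kg_index(g)
  g
}

## Hash indexes used by traversal and support counting:
##   adj:  node id -> data.frame(relation, neighbor, orientation), sorted
##   trip: "s\x1fr\x1fo" -> predication row numbers (forward orientation only)
build_kg_index <- function(g) {
  p <- g$predications
  e <- g$edges
  key <- function(s, r, o) paste(s, r, o, sep = "\x1f")

  trip <- new.env(parent = emptyenv(), size = max(16L, nrow(e)))
  byk <- split(seq_len(nrow(p)), key(p$subject_id, p$relation, p$object_id))
  for (k in names(byk)) assign(k, byk[[k]], envir = trip)

  fwd <- data.frame(node = e$subject_id, relation = e$relation,
                    neighbor = e$object_id, orientation = "forward",
                    stringsAsFactors = FALSE)
  rev <- data.frame(node = e$object_id, relation = e$relation,
                    neighbor = e$subject_id, orientation = "reverse",
                    stringsAsFactors = FALSE)
  inc <- rbind(fwd, rev)
  inc <- inc[order(inc$node, inc$relation, inc$neighbor, inc$orientation), ]
  adj <- new.env(parent = emptyenv(), size = max(16L, nrow(g$nodes)))
  parts <- split(inc[c("relation", "neighbor", "orientation")], inc$node)
  for (nm in names(parts)) {
    df <- parts[[nm]]
    rownames(df) <- NULL
    assign(nm, df, envir = adj)
  }
  list(adj = adj, trip = trip, key = key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a predication TSV file into a knowledge graph
#'
#' The file must be UTF-8 tab-separated with the header
#' `subject_id subject_type relation object_id object_type article_id`;
#' empty strings mark missing semantic types and missing article provenance.
#' Rows are deduplicated on load.
#'
#' @param path path to the TSV file.
#' @inheritParams knowledge_graph
#' @return A [knowledge_graph()] object.
#' @export
load_predications <- function(path, vocab = default_vocabulary(),
                              allow_unknown_relations = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty predication file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ## trailing empty fields are dropped by strsplit; pad back to 6
  nf <- lengths(fields)
  bad <- which(nf > 6L | nf < 3L)
  if (length(bad) > 0)
    stop(sprintf("malformed row at line %d of %s: expected 6 tab-separated columns, found %d",
                 bad[1], path, nf[bad[1]]), call. = FALSE)
  fields <- lapply(fields, function(f) c(f, rep("", 6L - length(f))))
  m <- do.call(rbind, fields)
  header <- c("subject_id", "subject_type", "relation",
              "object_id", "object_type", "article_id")
  if (!identical(as.vector(m[1, ]), header))
    stop("predication file must start with the header: ",
         paste(header, collapse = "\t"), call. = FALSE)
  p <- as.data.frame(m[-1, , drop = FALSE], stringsAsFactors = FALSE)
  names(p) <- header
  knowledge_graph(p, vocab = vocab,
                  allow_unknown_relations = allow_unknown_relations)
}

#' Write a knowledge graph back to a predication TSV file
#'
#' Inverse of [load_predications()] up to row order and deduplication.
#'
#' @param graph a [knowledge_graph()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predications <- function(graph, path) {
  stopifnot(inherits(graph, "blgpa_kg"))
  utils::write.table(graph$predications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

check_node <- function(graph, id) {
  if (!id %in% graph$nodes$id)
    stop("unknown node id: ", id, call. = FALSE)
  invisible(TRUE)
}

#' Article support of a triple
#'
#' Counts the number of distinct articles asserting the triple
#' (`subject_id`, `relation`, `object_id`), looking the triple up in both
#' stored orientations. Ontology-derived edges with no article provenance
#' (empty `article_id`) contribute a support of 1.
#'
#' @param graph a [knowledge_graph()] object.
#' @param subject_id,relation,object_id the triple to look up.
#' @return A non-negative integer count; 0 if the triple is absent.
#' @export
triple_support <- function(graph, subject_id, relation, object_id) {
  stopifnot(inherits(graph, "blgpa_kg"))
  check_node(graph, subject_id)
  check_node(graph, object_id)
  rows <- edge_predication_rows(graph, subject_id, relation, object_id)
  if (length(rows) == 0) return(0L)
  ## empty article_id (ontology edges) counts as one pseudo-article
  length(unique(graph$predications$article_id[rows]))
}

## Predication rows supporting an edge between a and b under `relation`,
## in either stored orientation. Attribute "side_type" carries, per row, the
## semantic type attributed to node `a` in that predication instance.
edge_predication_rows <- function(graph, a, relation, b) {
  ix <- graph$index
  fwd <- get0(ix$key(a, relation, b), envir = ix$trip,
              ifnotfound = integer(0))
  bwd <- get0(ix$key(b, relation, a), envir = ix$trip,
              ifnotfound = integer(0))
  rows <- c(fwd, bwd)
  side <- c(graph$predications$subject_type[fwd],
            graph$predications$object_type[bwd])
  attr(rows, "side_type") <- side
  rows
}

#' Incident edges of a node
#'
#' Lists the distinct `(relation, neighbor, orientation)` entries incident to
#' a node, collapsing parallel provenance (the same triple from several
#' articles appears once). Orientation records how the underlying predication
#' is stored: `forward` if the node is the subject, `reverse` if it is the
#' object. Entries are sorted, so the order is deterministic.
#'
#' @param graph a [knowledge_graph()] object.
#' @param node_id a node identifier present in the graph.
#' @return A data.frame with columns `relation`, `neighbor`, `orientation`.
#' @export
kg_neighbors <- function(graph, node_id) {
  stopifnot(inherits(graph, "blgpa_kg"))
  check_node(graph, node_id)
  get0(node_id, envir = graph$index$adj,
       ifnotfound = data.frame(relation = character(0),
                               neighbor = character(0),
                               orientation = character(0),
                               stringsAsFactors = FALSE))
}

#' @export
print.blgpa_kg <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = c("concept", "article")))
  arts <- unique(x$predications$article_id)
  arts <- arts[arts != ""]
  cat("blgpa knowledge graph\n")
  cat("  nodes:       ", nrow(x$nodes), " (", kinds[["concept"]], " concepts, ",
      kinds[["article"]], " articles)\n", sep = "")
  cat("  predications:", nrow(x$predications), "\n")
  cat("  edges:       ", nrow(x$edges), "distinct triples\n")
  cat("  provenance:  ", length(arts), "distinct source articles\n")
  invisible(x)
}

#' Summary counts for a knowledge graph
#'
#' @param object a [knowledge_graph()] object.
#' @param ... unused.
#' @return A named list of counts (nodes, concepts, articles, predications,
#'   distinct edges, distinct provenance articles, relations in use).
#' @export
summary.blgpa_kg <- function(object, ...) {
  arts <- unique(object$predications$article_id)
  arts <- arts[arts != ""]
  out <- list(
    nodes = nrow(object$nodes),
    concepts = sum(object$nodes$kind == "concept"),
    articles = sum(object$nodes$kind == "article"),
    predications = nrow(object$predications),
    edges = nrow(object$edges),
    source_articles = length(arts),
    relations = sort(unique(object$predications$relation))
  )
  class(out) <- "summary.blgpa_kg"
  out
}

#' @export
print.summary.blgpa_kg <- function(x, ...) {
  cat("nodes:", x$nodes, "(", x$concepts, "concepts,", x$articles, "articles )\n")
  cat("predications:", x$predications, " distinct edges:", x$edges,
      " source articles:", x$source_articles, "\n")
  cat("relations in use:", paste(x$relations, collapse = ", "), "\n")
  invisible(x)
}
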