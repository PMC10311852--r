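#' Semantic-encoding feature layout
#'
#' The semantic-encoding (SE) representation of a path assigns one block of
#' features to each position `j = 1 ... l` along the path. A block holds one
#' count per semantic-type code (`nodj_<type>`) followed by one count per
#' scored relation label (`relj_<relation>`), so the block width is
#' `T + R` (162 with the default vocabularies: 127 types + 35 relations) and
#' the full vector length is `l * (T + R)` (486 at `l = 3`). The type of the
#' path's final node is never encoded: on drug--gene paths it is always the
#' gene type, so it carries no information.
#'
#' @param max_len maximum path length `l` the layout covers.
#' @param vocab a [vocabulary()] supplying the ordered type and relation lists.
#' @return An object of class `blgpa_se_layout` with elements `max_len`,
#'   `vocab`, `block_width`, `total_len` and `feature_names` (the full
#'   `nodj_*` / `relj_*` name vector, position-major).
#' @examples
#' lay <- se_layout(3)
#' lay$block_width   # 162 with the default vocabulary
#' lay$total_len     # 486
#' @export
se_layout <- function(max_len = 3, vocab = default_vocabulary()) {
  stopifnot(max_len >= 1)
  T_ <- length(vocab$semantic_types)
  R_ <- length(vocab$relations)
  nm <- unlist(lapply(seq_len(max_len), function(j)
    c(paste0("nod", j, "_", vocab$semantic_types),
      paste0("rel", j, "_", vocab$relations))))
  structure(
    list(max_len = as.integer(max_len), vocab = vocab,
         block_width = T_ + R_, total_len = as.integer(max_len * (T_ + R_)),
         feature_names = nm),
    class = "blgpa_se_layout"
  )
}

#' @export
print.blgpa_se_layout <- function(x, ...) {
  cat("blgpa SE layout: l =", x$max_len, ", block width =", x$block_width,
      "(", length(x$vocab$semantic_types), "types +",
      length(x$vocab$relations), "relations ), total length =",
      x$total_len, "\n")
  invisible(x)
}

#' Encode one path as a positional semantic-encoding vector
#'
#' For each transition `j` of the path, the features `nodj_<type>` and
#' `relj_<relation>` count supporting literature: every predication instance
#' backing that edge contributes its distinct articles, crediting the
#' semantic type that the instance attributes to the node at the start of the
#' transition. One article attributing two different types to the same node
#' (via two predication rows) credits both type features. Edges with no
#' article provenance (ontology `is_a` facts) count as support 1. Blocks
#' beyond the path's length stay zero, and an edge whose start node carries
#' no semantic type (an article node) or whose relation is outside the scored
#' set contributes only the features that exist.
#'
#' With `binary = TRUE` the per-path vector is reduced to presence/absence
#' (0/1), discarding article multiplicity.
#'
#' @param graph a [knowledge_graph()] object.
#' @param path one path from [enumerate_paths()] (a list with `nodes` and
#'   `relations`).
#' @param layout an [se_layout()]; the path must not be longer than
#'   `layout$max_len`.
#' @param binary if `TRUE`, clip per-path counts to 0/1.
#' @return An integer vector of length `layout$total_len`, named with the
#'   layout's feature names, of class `blgpa_se`.
#' @export
encode_path <- function(graph, path, layout, binary = FALSE) {
  stopifnot(inherits(graph, "blgpa_kg"), inherits(layout, "blgpa_se_layout"))
  n <- length(path$relations)
  if (n > layout$max_len)
    stop("path length ", n, " exceeds layout max_len ", layout$max_len,
         call. = FALSE)
  if (length(path$nodes) != n + 1L)
    stop("malformed path: need one more node than relations", call. = FALSE)

  v <- integer(layout$total_len)
  names(v) <- layout$feature_names
  vocab <- layout$vocab
  skipped <- character(0)

  for (j in seq_len(n)) {
    a <- path$nodes[j]; b <- path$nodes[j + 1L]; r <- path$relations[j]
    rows <- edge_predication_rows(graph, a, r, b)
    if (length(rows) == 0)
      stop(sprintf("path edge %s -[%s]- %s is not in the graph", a, r, b),
           call. = FALSE)
    side_type <- attr(rows, "side_type")
    articles <- graph$predications$article_id[rows]
    base <- (j - 1L) * layout$block_width

    n_articles <- length(unique(articles))  # "" = one pseudo-article
    if (r %in% vocab$relations) {
      v[base + length(vocab$semantic_types) + match(r, vocab$relations)] <-
        v[base + length(vocab$semantic_types) + match(r, vocab$relations)] +
        n_articles
    } else {
      skipped <- union(skipped, r)
    }

    typed <- side_type != ""
    if (any(typed)) {
      per_type <- tapply(articles[typed], side_type[typed],
                         function(x) length(unique(x)))
      for (tp in names(per_type)) {
        k <- match(tp, vocab$semantic_types)
        if (is.na(k)) next  # type outside the layout vocabulary
        v[base + k] <- v[base + k] + as.integer(per_type[[tp]])
      }
    }
  }
  if (length(skipped) > 0)
    warning("relation(s) outside the scored vocabulary skipped in SE encoding: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (binary) v <- as.integer(v > 0L)
  names(v) <- layout$feature_names
  structure(v, layout = layout, class = "blgpa_se")
}

#' Aggregate per-path semantic-encoding vectors for a pair
#'
#' Element-wise summation of the per-path SE vectors of all paths connecting
#' a drug--gene pair. An empty list yields the all-zero vector (a
#' disconnected pair).
#'
#' @param vectors a list of [encode_path()] outputs sharing one layout.
#' @param layout the layout, required only when `vectors` is empty.
#' @return A named integer vector of class `blgpa_se`.
#' @export
aggregate_se <- function(vectors, layout = NULL) {
  if (length(vectors) == 0) {
    if (is.null(layout))
      stop("layout is required to aggregate an empty path set", call. = FALSE)
    v <- integer(layout$total_len)
    names(v) <- layout$feature_names
    return(structure(v, layout = layout, class = "blgpa_se"))
  }
  layouts <- lapply(vectors, attr, "layout")
  first <- layouts[[1]]
  same <- vapply(layouts, function(l)
    identical(l$feature_names, first$feature_names), logical(1))
  if (!all(same))
    stop("cannot aggregate SE vectors with different layouts", call. = FALSE)
  v <- Reduce(`+`, lapply(vectors, unclass))
  structure(v, layout = first, class = "blgpa_se")
}

#' @export
print.blgpa_se <- function(x, ...) {
  nz <- which(unclass(x) != 0)
  cat("blgpa SE vector: length", length(x), "-", length(nz), "nonzero\n")
  if (length(nz) > 0) {
    show <- utils::head(nz, 20)
    cat(paste0("  ", names(x)[show], " = ", unclass(x)[show]), sep = "\n")
    if (length(nz) > 20) cat("  ...\n")
  }
  invisible(x)
}
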