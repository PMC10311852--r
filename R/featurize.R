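#' Featurize one drug-gene pair
#'
#' Runs the full feature-extraction pipeline for a single pair: enumerate all
#' simple paths up to the layout's maximum length, encode and aggregate the
#' semantic-encoding block, compute the path-ranking block against a ranked
#' chain list, and concatenate the two. A disconnected pair yields the
#' all-zero vector.
#'
#' @param graph a [knowledge_graph()] object.
#' @param drug_id,gene_id node ids of the pair.
#' @param chains a [select_top_chains()] or [chain_list()] object (the PR
#'   block layout).
#' @param layout an [se_layout()].
#' @param degree_cap,path_cap passed to [enumerate_paths()].
#' @param binary_se clip per-path SE counts to presence/absence.
#' @param substring_match passed to [pr_vector()].
#' @return A named numeric vector of length
#'   `layout$total_len + nrow(chains)` (586 with all defaults:
#'   3 x 162 + 100).
#' @examples
#' fx <- fig3_fixture()
#' v <- featurize_pair(fx$graph, fx$pair$drug_id, fx$pair$gene_id,
#'                     fx$chains, se_layout(3))
#' v[v != 0]
#' @export
featurize_pair <- function(graph, drug_id, gene_id, chains, layout,
                           degree_cap = NULL, path_cap = 100000L,
                           binary_se = FALSE, substring_match = FALSE) {
  ps <- enumerate_paths(graph, drug_id, gene_id, max_len = layout$max_len,
                        degree_cap = degree_cap, path_cap = path_cap)
  se <- aggregate_se(lapply(ps$paths, encode_path, graph = graph,
                            layout = layout, binary = binary_se),
                     layout = layout)
  pr <- pr_vector(ps, chains, substring_match = substring_match)
  c(unclass(se), pr)
}

## Batch path/feature extraction, computed once per pair and reused across
## cross-validation folds (only the PR block depends on the fold's mined
## chain list; SE and the per-pair chain counts do not).
pair_path_features <- function(graph, pairs, layout, degree_cap = NULL,
                               path_cap = 100000L, binary_se = FALSE) {
  n <- nrow(pairs)
  se <- matrix(0L, nrow = n, ncol = layout$total_len,
               dimnames = list(NULL, layout$feature_names))
  chain_counts <- vector("list", n)
  path_sets <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- enumerate_paths(graph, pairs$drug_id[i], pairs$gene_id[i],
                          max_len = layout$max_len, degree_cap = degree_cap,
                          path_cap = path_cap)
    path_sets[[i]] <- ps
    if (length(ps$paths) > 0) {
      se[i, ] <- aggregate_se(lapply(ps$paths, encode_path, graph = graph,
                                     layout = layout, binary = binary_se),
                              layout = layout)
      keys <- vapply(ps$paths, function(p) chain_key(p$relations), character(1))
      chain_counts[[i]] <- table(keys)
    } else {
      chain_counts[[i]] <- table(character(0))
    }
  }
  list(se = se, chain_counts = chain_counts, path_sets = path_sets)
}

## PR feature matrix from cached per-pair chain-count tables.
pr_matrix <- function(chain_counts, chains) {
  m <- matrix(0L, nrow = length(chain_counts), ncol = nrow(chains),
              dimnames = list(NULL, chains$rank_name))
  for (i in seq_along(chain_counts)) {
    tab <- chain_counts[[i]]
    hit <- match(chains$chain, names(tab))
    ok <- !is.na(hit)
    if (any(ok)) m[i, ok] <- as.integer(tab[hit[ok]])
  }
  m
}
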