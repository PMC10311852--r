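#' Relational chain of a path
#'
#' The relational chain is the ordered sequence of relation labels along a
#' path, ignoring the nodes entirely -- a metapath over relations. Two
#' node-disjoint paths with the same relation sequence have equal chains.
#'
#' @param path one path from [enumerate_paths()].
#' @return A character vector of relation labels.
#' @export
chain_of <- function(path) as.character(path$relations)

chain_key <- function(relations) paste(relations, collapse = "|")

#' Mine relational chains from labeled training pairs
#'
#' Computes, for every relational chain observed in any pair's path set, its
#' support in the positive and in the negative class: the fraction of pairs
#' of that class whose path set contains at least one path with that exact
#' chain. The importance of a chain is its support in positives minus its
#' support in negatives, so chains that preferentially connect interacting
#' pairs score high. Chains of every length from 1 up to the enumeration
#' bound are eligible.
#'
#' Support is pair-level containment, not a path count: duplicating paths
#' within one pair's set changes nothing.
#'
#' @param path_sets a list of [enumerate_paths()] results, one per pair.
#' @param labels an integer/logical vector of the same length; 1 (or `TRUE`)
#'   marks an interacting pair. Both classes must be represented.
#' @return A data.frame of class `blgpa_chain_scores` with columns `chain`
#'   (relations joined by `|`), `freq_pos`, `freq_neg` and `importance`,
#'   sorted by decreasing importance with lexicographic tie-breaking on the
#'   chain string.
#' @export
mine_chains <- function(path_sets, labels) {
  labels <- as.integer(labels)
  if (length(path_sets) != length(labels))
    stop("path_sets and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("both a positive and a negative pair are required to mine chains",
         call. = FALSE)

  per_pair <- lapply(path_sets, function(ps)
    unique(vapply(ps$paths, function(p) chain_key(p$relations), character(1))))

  pos_tab <- table(unlist(per_pair[labels == 1L]))
  neg_tab <- table(unlist(per_pair[labels == 0L]))
  chains <- sort(unique(c(names(pos_tab), names(neg_tab))))
  if (length(chains) == 0)
    return(structure(data.frame(chain = character(0), freq_pos = numeric(0),
                                freq_neg = numeric(0), importance = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("blgpa_chain_scores", "data.frame")))

  fp <- as.numeric(pos_tab[chains]) / n_pos
  fn <- as.numeric(neg_tab[chains]) / n_neg
  fp[is.na(fp)] <- 0
  fn[is.na(fn)] <- 0
  out <- data.frame(chain = chains, freq_pos = fp, freq_neg = fn,
                    importance = fp - fn, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$chain), ]
  rownames(out) <- NULL
  class(out) <- c("blgpa_chain_scores", "data.frame")
  out
}

#' Select the top-M relational chains
#'
#' Keeps the `M` highest-importance chains (all of them, if fewer were
#' mined) and assigns the rank names `PATH0 ... PATH{M-1}` that label the
#' path-ranking feature block. Ties at the cut are already resolved
#' deterministically by [mine_chains()]'s lexicographic ordering.
#'
#' @param scores the output of [mine_chains()].
#' @param M number of chains to keep (default 100).
#' @return An object of class `blgpa_chains`: the truncated score table with
#'   a `rank_name` column (`PATH0` is the most important chain).
#' @export
select_top_chains <- function(scores, M = 100) {
  stopifnot(M >= 1)
  if (nrow(scores) < M)
    message("only ", nrow(scores), " chains available; PR block will have ",
            nrow(scores), " features instead of ", M)
  out <- utils::head(as.data.frame(scores), M)
  out$rank_name <- paste0("PATH", seq_len(nrow(out)) - 1L)
  rownames(out) <- NULL
  class(out) <- c("blgpa_chains", "data.frame")
  out
}

#' Build a chain list directly from relation sequences
#'
#' Constructs a `blgpa_chains` object with the given chains at the given
#' ranks, for use when the ranked chain list is known rather than mined
#' (e.g. a published list of top-ranked chains). Support columns are `NA`.
#'
#' @param chains a list of character vectors (relation sequences) or a
#'   character vector of `|`-joined chains, in rank order (`PATH0` first).
#' @return A `blgpa_chains` object.
#' @export
chain_list <- function(chains) {
  if (is.list(chains))
    chains <- vapply(chains, chain_key, character(1))
  if (anyDuplicated(chains))
    stop("duplicate chains in chain list", call. = FALSE)
  out <- data.frame(chain = as.character(chains), freq_pos = NA_real_,
                    freq_neg = NA_real_, importance = NA_real_,
                    rank_name = paste0("PATH", seq_along(chains) - 1L),
                    stringsAsFactors = FALSE)
  class(out) <- c("blgpa_chains", "data.frame")
  out
}

#' @export
print.blgpa_chains <- function(x, max = 10, ...) {
  cat("blgpa chain list:", nrow(x), "ranked relational chains\n")
  print.data.frame(utils::head(as.data.frame(x), max))
  if (nrow(x) > max) cat("... and", nrow(x) - max, "more\n")
  invisible(x)
}

#' Path-ranking feature vector of a pair
#'
#' Entry `k` counts the paths in the pair's path set whose relational chain
#' matches the chain at rank `k` of the chain list (the indicator summed over
#' paths). By default a match is exact whole-sequence equality; with
#' `substring_match = TRUE` a chain also matches any path that contains it as
#' a contiguous relation subsequence.
#'
#' @param path_set an [enumerate_paths()] result.
#' @param chains a [select_top_chains()] or [chain_list()] object.
#' @param substring_match match chains as contiguous subsequences instead of
#'   whole sequences.
#' @return A named integer vector (names `PATH0`, `PATH1`, ...) of length
#'   `nrow(chains)`.
#' @export
pr_vector <- function(path_set, chains, substring_match = FALSE) {
  stopifnot(inherits(chains, "blgpa_chains"))
  keys <- vapply(path_set$paths, function(p) chain_key(p$relations),
                 character(1))
  if (!substring_match) {
    counts <- vapply(chains$chain, function(ch) sum(keys == ch), integer(1))
  } else {
    counts <- vapply(chains$chain, function(ch) {
      pat <- strsplit(ch, "|", fixed = TRUE)[[1]]
      sum(vapply(path_set$paths, function(p)
        has_contiguous(p$relations, pat), logical(1)))
    }, integer(1))
  }
  names(counts) <- chains$rank_name
  counts
}

has_contiguous <- function(seq, pat) {
  n <- length(seq); m <- length(pat)
  if (m > n) return(FALSE)
  for (s in seq_len(n - m + 1L))
    if (all(seq[s:(s + m - 1L)] == pat)) return(TRUE)
  FALSE
}
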