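#' Configuration of the synthetic literature knowledge-graph generator
#'
#' The generator emulates the statistical structure the link predictor
#' relies on: a sparse multigraph of drug, gene, concept and article nodes in
#' which interacting (positive) drug-gene pairs are preferentially connected
#' by short planted relational chains, against a background of random
#' semantic edges and concept-article mentions. Labels are assigned first;
#' wiring follows the labels.
#'
#' @param n_drugs,n_genes,n_concepts,n_articles sizes of the four node pools.
#'   All drug-gene combinations become labeled pairs.
#' @param planted_chains a list of `list(chain, p_pos, p_neg)` entries: for
#'   each pair and each entry, a path realizing `chain` (a character vector
#'   of relation labels) is wired with probability `p_pos` for positive and
#'   `p_neg` for negative pairs. At least one entry should separate the
#'   classes (`p_pos > p_neg`), otherwise the benchmark is uninformative and
#'   generation warns.
#' @param background_edge_rate expected number of random semantic noise edges
#'   per concept-kind node.
#' @param mention_rate expected number of `MENTIONED_IN` noise edges per
#'   concept-kind node.
#' @param article_support_mean mean of the geometric distribution of
#'   distinct articles supporting each planted/noise triple (default 2).
#' @param pos_fraction fraction of pairs labeled positive.
#' @param reuse_prob probability that an intermediate node of a planted path
#'   reuses an intermediate created for an earlier planted path instead of a
#'   fresh node; mild hubness without path explosion (default 0.3).
#' @param concept_types small semantic-type sub-vocabulary for synthetic
#'   concepts, so SE blocks are exercised without the full 127-type set.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A list of class `blgpa_sim_config`.
#' @export
synthetic_config <- function(n_drugs = 20, n_genes = 20, n_concepts = 60,
                             n_articles = 80,
                             planted_chains = list(list(
                               chain = c("INTERACTS_WITH", "TREATS", "AFFECTS"),
                               p_pos = 0.9, p_neg = 0.1)),
                             background_edge_rate = 2, mention_rate = 1,
                             article_support_mean = 2, pos_fraction = 0.5,
                             reuse_prob = 0.3,
                             concept_types = c("phsu", "gngm", "dsyn", "aapp",
                                               "neop", "orch", "celf", "patf"),
                             seed = 1L) {
  stopifnot(n_drugs >= 1, n_genes >= 1, n_concepts >= 0, n_articles >= 0,
            article_support_mean >= 1, pos_fraction >= 0, pos_fraction <= 1,
            reuse_prob >= 0, reuse_prob <= 1)
  for (pc in planted_chains) {
    if (is.null(pc$chain) || length(pc$chain) < 1)
      stop("each planted chain needs a non-empty relation sequence",
           call. = FALSE)
    if (any(c(pc$p_pos, pc$p_neg) < 0) || any(c(pc$p_pos, pc$p_neg) > 1))
      stop("planted chain probabilities must be in [0, 1]", call. = FALSE)
  }
  if (!any(vapply(planted_chains, function(pc) pc$p_pos > pc$p_neg,
                  logical(1))))
    warning("no planted chain separates the classes (p_pos > p_neg); ",
            "the benchmark will be uninformative", call. = FALSE)
  if (mention_rate > 0 && n_articles == 0)
    stop("mention_rate > 0 requires at least one article", call. = FALSE)
  structure(list(n_drugs = n_drugs, n_genes = n_genes,
                 n_concepts = n_concepts, n_articles = n_articles,
                 planted_chains = planted_chains,
                 background_edge_rate = background_edge_rate,
                 mention_rate = mention_rate,
                 article_support_mean = article_support_mean,
                 pos_fraction = pos_fraction, reuse_prob = reuse_prob,
                 concept_types = concept_types, seed = as.integer(seed)),
            class = "blgpa_sim_config")
}

## Infer the node kinds (concept/article) along a planted chain by constraint
## propagation: endpoints are concepts; semantic relations join two concepts;
## MENTIONED_IN and HAS_MESH join one concept and one article.
chain_node_kinds <- function(chain) {
  lit <- c("MENTIONED_IN", "HAS_MESH")
  n <- length(chain)
  kind <- rep(NA_character_, n + 1L)
  kind[1] <- kind[n + 1L] <- "concept"
  for (j in seq_len(n)) {
    if (!chain[j] %in% lit) kind[c(j, j + 1L)] <- "concept"
  }
  repeat {
    changed <- FALSE
    for (j in which(chain %in% lit)) {
      a <- kind[j]; b <- kind[j + 1L]
      if (!is.na(a) && !is.na(b)) {
        if (a == b) stop("chain (", paste(chain, collapse = ","),
                         ") cannot be realized: a literature edge needs one ",
                         "concept and one article endpoint", call. = FALSE)
      } else if (!is.na(a)) {
        kind[j + 1L] <- if (a == "concept") "article" else "concept"
        changed <- TRUE
      } else if (!is.na(b)) {
        kind[j] <- if (b == "concept") "article" else "concept"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## remaining ambiguity (chained literature edges): make the later node the
  ## article, deterministically
  for (j in seq_len(n + 1L)) if (is.na(kind[j])) {
    kind[j] <- if (j > 1 && !is.na(kind[j - 1L]) && kind[j - 1L] == "concept")
      "article" else "concept"
  }
  kind
}

#' Generate a synthetic knowledge graph with planted relational chains
#'
#' Builds the graph described by a [synthetic_config()]: every drug-gene
#' combination is labeled (positives drawn at the configured fraction), each
#' pair receives a fresh realizing path for each planted chain with the
#' class-appropriate probability (intermediate nodes fresh or reused), and
#' random semantic edges and concept mentions are layered on top as noise.
#' The returned manifest records exactly which planted paths were wired for
#' which pair. The same configuration and seed reproduce the graph
#' byte-identically.
#'
#' @param config a [synthetic_config()].
#' @return A list with `graph` (a [knowledge_graph()]), `pairs` (data.frame
#'   `drug_id`, `gene_id`, `label`), `manifest` (data.frame with one row per
#'   pair and planted chain: `drug_id`, `gene_id`, `label`, `chain`,
#'   `planted`, `nodes` -- the realized node sequence, `""` if not planted)
#'   and `config`.
#' @examples
#' sim <- generate_kg(synthetic_config(n_drugs = 4, n_genes = 4,
#'                                     n_concepts = 10, n_articles = 10,
#'                                     seed = 42))
#' sim$graph
#' head(sim$manifest)
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "blgpa_sim_config"))
  set.seed(config$seed)

  drugs <- sprintf("D%03d", seq_len(config$n_drugs))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  concepts <- if (config$n_concepts > 0)
    sprintf("C%04d", seq_len(config$n_concepts)) else character(0)
  articles <- if (config$n_articles > 0)
    sprintf("A%05d", seq_len(config$n_articles)) else character(0)

  node_type <- new.env(parent = emptyenv())
  for (d in drugs) assign(d, "phsu", envir = node_type)
  for (g in genes) assign(g, "gngm", envir = node_type)
  for (cc in concepts)
    assign(cc, sample(config$concept_types, 1), envir = node_type)
  type_of <- function(id) get0(id, envir = node_type, ifnotfound = "")

  pairs <- expand.grid(drug_id = drugs, gene_id = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$drug_id, pairs$gene_id), ]
  rownames(pairs) <- NULL
  n_pos <- round(config$pos_fraction * nrow(pairs))
  pairs$label <- 0L
  pairs$label[sample(nrow(pairs), n_pos)] <- 1L

  ## predication accumulator
  preds <- list()
  emit <- function(s, r, o, n_support) {
    arts <- sample(articles, min(n_support, length(articles)))
    if (length(arts) == 0) arts <- ""
    preds[[length(preds) + 1L]] <<- data.frame(
      subject_id = s, subject_type = type_of(s), relation = r,
      object_id = o, object_type = type_of(o), article_id = arts,
      stringsAsFactors = FALSE)
  }
  support <- function()
    1L + stats::rgeom(1, prob = 1 / config$article_support_mean)

  ## Planted chains: intermediates are fresh nodes, or (at reuse_prob) reuse
  ## an intermediate of an earlier planted path drawn from a keyed pool:
  ## drug-side positions share only among paths of the same drug, gene-side
  ## positions only among paths of the same gene. This creates hub nodes
  ## while guaranteeing that recombined fragments can never assemble a
  ## realizing path for a pair that was not itself planted.
  reuse_pool <- new.env(parent = emptyenv())
  made_nodes <- character(0)
  fresh_id <- 0L
  manifest_rows <- list()

  for (pc in config$planted_chains) {
    kinds <- chain_node_kinds(pc$chain)
    ckey <- chain_key(pc$chain)
    for (i in seq_len(nrow(pairs))) {
      p <- if (pairs$label[i] == 1L) pc$p_pos else pc$p_neg
      hit <- stats::runif(1) < p
      nodes_str <- ""
      if (hit) {
        n <- length(pc$chain)
        nodes <- character(n + 1L)
        nodes[1] <- pairs$drug_id[i]
        nodes[n + 1L] <- pairs$gene_id[i]
        for (j in seq(2, n)) {
          anchor <- if (j <= ceiling((n + 1) / 2)) pairs$drug_id[i]
                    else pairs$gene_id[i]
          pool_key <- paste(ckey, j, anchor, sep = "\x1f")
          pool <- setdiff(get0(pool_key, envir = reuse_pool,
                               ifnotfound = character(0)), nodes)
          if (length(pool) > 0 && stats::runif(1) < config$reuse_prob) {
            nodes[j] <- if (length(pool) == 1) pool else sample(pool, 1)
          } else {
            fresh_id <- fresh_id + 1L
            if (kinds[j] == "concept") {
              nodes[j] <- sprintf("X%05d", fresh_id)
              assign(nodes[j], sample(config$concept_types, 1),
                     envir = node_type)
            } else {
              nodes[j] <- sprintf("P%05d", fresh_id)
            }
            made_nodes <- c(made_nodes, nodes[j])
            assign(pool_key,
                   c(get0(pool_key, envir = reuse_pool,
                          ifnotfound = character(0)), nodes[j]),
                   envir = reuse_pool)
          }
        }
        for (j in seq_len(n)) {
          a <- nodes[j]; b <- nodes[j + 1L]; r <- pc$chain[j]
          if (r == "MENTIONED_IN") {
            if (kinds[j] == "article") { tmp <- a; a <- b; b <- tmp }
            preds[[length(preds) + 1L]] <- data.frame(
              subject_id = a, subject_type = type_of(a), relation = r,
              object_id = b, object_type = "", article_id = b,
              stringsAsFactors = FALSE)
          } else if (r == "HAS_MESH") {
            if (kinds[j] == "concept") { tmp <- a; a <- b; b <- tmp }
            preds[[length(preds) + 1L]] <- data.frame(
              subject_id = a, subject_type = "", relation = r,
              object_id = b, object_type = type_of(b), article_id = a,
              stringsAsFactors = FALSE)
          } else {
            emit(a, r, b, support())
          }
        }
        nodes_str <- paste(nodes, collapse = "|")
      }
      manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
        drug_id = pairs$drug_id[i], gene_id = pairs$gene_id[i],
        label = pairs$label[i], chain = ckey, planted = hit,
        nodes = nodes_str, stringsAsFactors = FALSE)
    }
  }

  ## background semantic noise among concept-kind nodes
  vocab <- default_vocabulary()
  noise_rel <- setdiff(vocab$relations, c("MENTIONED_IN", "HAS_MESH"))
  cnodes <- c(drugs, genes, concepts, made_nodes[startsWith(made_nodes, "X")])
  n_noise <- stats::rpois(1, config$background_edge_rate * length(cnodes))
  for (k in seq_len(n_noise)) {
    ab <- sample(cnodes, 2)
    emit(ab[1], sample(noise_rel, 1), ab[2], support())
  }

  ## mention noise: concept -> article occurrences
  all_articles <- c(articles, made_nodes[startsWith(made_nodes, "P")])
  if (config$mention_rate > 0 && length(all_articles) > 0) {
    for (cc in cnodes) {
      m <- stats::rpois(1, config$mention_rate)
      for (a in utils::head(sample(all_articles,
                                   min(m, length(all_articles))), m)) {
        preds[[length(preds) + 1L]] <- data.frame(
          subject_id = cc, subject_type = type_of(cc),
          relation = "MENTIONED_IN", object_id = a, object_type = "",
          article_id = a, stringsAsFactors = FALSE)
      }
    }
  }

  pred_df <- do.call(rbind, preds)

  ## every pair endpoint must exist in the graph: anchor isolated drugs,
  ## genes and base concepts with one mention (or a self-descriptive is_a
  ## when there are no articles)
  present <- unique(c(pred_df$subject_id, pred_df$object_id))
  missing <- setdiff(c(drugs, genes, concepts), present)
  for (id in missing) {
    if (length(all_articles) > 0) {
      a <- sample(all_articles, 1)
      pred_df <- rbind(pred_df, data.frame(
        subject_id = id, subject_type = type_of(id),
        relation = "MENTIONED_IN", object_id = a, object_type = "",
        article_id = a, stringsAsFactors = FALSE))
    } else {
      anchor <- sample(setdiff(c(drugs, genes, concepts), id), 1)
      pred_df <- rbind(pred_df, data.frame(
        subject_id = id, subject_type = type_of(id), relation = "is_a",
        object_id = anchor, object_type = type_of(anchor), article_id = "",
        stringsAsFactors = FALSE))
    }
  }

  graph <- knowledge_graph(pred_df, vocab = vocab)
  manifest <- do.call(rbind, manifest_rows)
  rownames(manifest) <- NULL
  list(graph = graph, pairs = pairs, manifest = manifest, config = config)
}

#' Deterministic worked-example fixture: one drug-gene pair, two paths
#'
#' Builds the small graph of the feature-extraction worked example: the drug
#' Gefitinib (C1122962) and the gene ERBB3 (C0812265) connected by exactly
#' two length-3 paths, one carrying the relation chain
#' `(INTERACTS_WITH, TREATS, AFFECTS)` and one carrying
#' `(INTERACTS_WITH, MENTIONED_IN, MENTIONED_IN)` -- the latter traversing
#' its final mention edge in reverse (gene mentioned in the shared article).
#' Every triple is supported by exactly one article (unit support). The
#' accompanying chain list places those chains at ranks 0 and 5, and the
#' manifest lists the expected nonzero feature values: each PR entry is 1 at
#' `PATH0` and `PATH5`, and the aggregated SE entry `rel1_INTERACTS_WITH` is
#' 2 because both paths start with `INTERACTS_WITH`.
#'
#' @return A list with `graph`, `pair` (data.frame `drug_id`, `gene_id`,
#'   `label = 1`), `chains` (a [chain_list()] with the two chains at ranks 0
#'   and 5) and `manifest` (`se` and `pr`: named vectors of the expected
#'   nonzero entries).
#' @export
fig3_fixture <- function() {
  drug <- "C1122962"  # Gefitinib, phsu
  gene <- "C0812265"  # ERBB3, gngm
  p <- data.frame(
    subject_id   = c(drug,   "C_T1", "C_D1", drug,   "C_D2", gene),
    subject_type = c("phsu", "phsu", "dsyn", "phsu", "dsyn", "gngm"),
    relation     = c("INTERACTS_WITH", "TREATS", "AFFECTS",
                     "INTERACTS_WITH", "MENTIONED_IN", "MENTIONED_IN"),
    object_id    = c("C_T1", "C_D1", gene,   "C_D2", "A0001", "A0001"),
    object_type  = c("phsu", "dsyn", "gngm", "dsyn", "",      ""),
    article_id   = c("PM001", "PM002", "PM003", "PM004", "A0001", "A0001"),
    stringsAsFactors = FALSE)
  graph <- knowledge_graph(p)

  chains <- chain_list(c(
    "INTERACTS_WITH|TREATS|AFFECTS",                  # PATH0
    "INTERACTS_WITH|INTERACTS_WITH|INTERACTS_WITH",
    "TREATS|MENTIONED_IN|MENTIONED_IN",
    "TREATS",
    "AFFECTS",
    "INTERACTS_WITH|MENTIONED_IN|MENTIONED_IN"))      # PATH5

  se <- c(nod1_phsu = 2, rel1_INTERACTS_WITH = 2,
          nod2_phsu = 1, nod2_dsyn = 1, rel2_TREATS = 1,
          rel2_MENTIONED_IN = 1,
          nod3_dsyn = 1, rel3_AFFECTS = 1, rel3_MENTIONED_IN = 1)
  pr <- c(PATH0 = 1, PATH5 = 1)

  list(graph = graph,
       pair = data.frame(drug_id = drug, gene_id = gene, label = 1L,
                         stringsAsFactors = FALSE),
       chains = chains,
       manifest = list(se = se, pr = pr))
}
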