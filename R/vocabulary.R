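#' Vocabularies for semantic types and relations
#'
#' A `blgpa_vocabulary` holds the two ordered code lists that drive the
#' semantic-encoding feature layout: the UMLS/MetaMap semantic-type codes
#' (127 in the default resource) and the scored relation labels (35 in the
#' default resource, including the literature-link labels `MENTIONED_IN` and
#' `HAS_MESH`). Auxiliary relation labels (by default only `is_a`) are
#' admitted in a graph but never scored as features.
#'
#' The order of both lists is fixed and meaningful: it defines the column
#' order of every semantic-encoding block, so two graphs featurized under the
#' same vocabulary are directly comparable.
#'
#' @param semantic_types character vector of unique semantic-type codes.
#' @param relations character vector of unique scored relation labels.
#' @param auxiliary_relations character vector of additional labels admitted
#'   in predication files but excluded from feature scoring.
#' @return An object of class `blgpa_vocabulary`.
#' @examples
#' v <- vocabulary(c("phsu", "gngm"), c("INTERACTS_WITH", "TREATS"))
#' v$relations
#' @export
vocabulary <- function(semantic_types, relations, auxiliary_relations = "is_a") {
  semantic_types <- as.character(semantic_types)
  relations <- as.character(relations)
  auxiliary_relations <- as.character(auxiliary_relations)
  if (anyDuplicated(semantic_types))
    stop("semantic type codes must be unique", call. = FALSE)
  if (anyDuplicated(c(relations, auxiliary_relations)))
    stop("relation labels must be unique across scored and auxiliary sets",
         call. = FALSE)
  structure(
    list(semantic_types = semantic_types,
         relations = relations,
         auxiliary_relations = auxiliary_relations),
    class = "blgpa_vocabulary"
  )
}

#' Load a vocabulary from a JSON resource file
#'
#' The JSON file must contain the keys `semantic_types` and `relations`
#' (ordered arrays of strings) and may contain `auxiliary_relations`.
#'
#' @param path path to a JSON vocabulary file.
#' @return A [vocabulary()] object.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$semantic_types) || is.null(x$relations))
    stop("vocabulary file must define 'semantic_types' and 'relations'",
         call. = FALSE)
  vocabulary(x$semantic_types, x$relations,
             auxiliary_relations = if (is.null(x$auxiliary_relations)) character(0)
                                   else x$auxiliary_relations)
}

#' Default vocabulary shipped with the package
#'
#' 127 MetaMap semantic-type codes and 35 scored relation labels (SemRep-style
#' predicates plus `MENTIONED_IN`, `HAS_MESH` and `LITERATURE_DTI`), with
#' `is_a` as the only auxiliary label. The relation membership is a
#' configurable stand-in for the scored set used on real literature graphs;
#' any vocabulary file with the same JSON layout can replace it.
#'
#' @return A [vocabulary()] object.
#' @export
default_vocabulary <- function() {
  load_vocabulary(system.file("extdata", "default_vocabulary.json",
                              package = "blgpa", mustWork = TRUE))
}

#' @export
print.blgpa_vocabulary <- function(x, ...) {
  cat("blgpa vocabulary:", length(x$semantic_types), "semantic types,",
      length(x$relations), "scored relations,",
      length(x$auxiliary_relations), "auxiliary\n")
  invisible(x)
}

all_relations <- function(vocab) c(vocab$relations, vocab$auxiliary_relations)
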