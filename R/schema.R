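#' Entity categories of the trait-gene knowledge graph
#'
#' The closed vocabulary of 13 node categories. Traits, genes and proteins are
#' the central entities; the remainder are functional annotations attached to
#' genes or proteins (GO terms, pathways, localizations, families, domains,
#' enzymes, gene symbols).
#'
#' @return Character vector of the 13 category names.
#' @export
#' @examples
#' kg_entity_categories()
kg_entity_categories <- function() {
  c(
    "trait", "gene", "protein", "gene_symbol", "signal_pathway",
    "subcellular_localization", "protein_domain", "protein_family",
    "cellular_component", "molecular_function", "biological_process",
    "metabolic_pathway", "enzyme"
  )
}

#' Relation types and their legal endpoint categories
#'
#' The closed vocabulary of 14 edge types, each tied to the pair of entity
#' categories it may connect. Edges are stored with the direction given in the
#' input, but schema validation treats the category pair as unordered and all
#' neighborhood queries are undirected.
#'
#' @return A tibble with columns `relation`, `head_category`, `tail_category`.
#' @export
#' @examples
#' kg_relation_types()
kg_relation_types <- function() {
  tibble::tribble(
    ~relation,                          ~head_category, ~tail_category,
    "associates_with",                  "protein",      "trait",
    "homologous_to",                    "protein",      "protein",
    "interacts_with",                   "protein",      "protein",
    "corresponding_to",                 "protein",      "gene",
    "identify_with",                    "protein",      "gene_symbol",
    "involves_in_signal_pathway",       "protein",      "signal_pathway",
    "located_in_subcellular_localization", "protein",   "subcellular_localization",
    "has_protein_domain",               "protein",      "protein_domain",
    "belongs_to_protein_family",        "protein",      "protein_family",
    "located_in_cellular_component",    "gene",         "cellular_component",
    "performs",                         "gene",         "molecular_function",
    "involves_in_biological_process",   "gene",         "biological_process",
    "involves_in_metabolic_pathway",    "gene",         "metabolic_pathway",
    "encodes_enzyme_type",              "gene",         "enzyme"
  )
}

# TRUE where (head_cat, tail_cat) matches the relation's legal category pair
# in either orientation (direction is provenance, not schema).
relation_pair_ok <- function(relation, head_cat, tail_cat) {
  schema <- kg_relation_types()
  idx <- match(relation, schema$relation)
  legal_h <- schema$head_category[idx]
  legal_t <- schema$tail_category[idx]
  !is.na(idx) & (
    (head_cat == legal_h & tail_cat == legal_t) |
      (head_cat == legal_t & tail_cat == legal_h)
  )
}

kg_species_labels <- function() {
  c("arabidopsis", "rice", "maize", "wheat", "none")
}
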