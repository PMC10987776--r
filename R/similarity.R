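# Gene-pair similarity S(g1, g2) = C(k) * D(k) * Sp(p1, p2):
#   k  = intersection of the two genes' scoring neighborhoods,
#   C  = number of entities in k,
#   D  = number of distinct entity categories in k,
#   Sp = similarity of the proteins the genes encode.
# C and D are topological attributes of the gene nodes; Sp is a data
# attribute capturing conserved function.

#' Scoring configuration for the gene-pair similarity
#'
#' @param excluded_categories Entity categories removed from scoring
#'   neighborhoods. Trait nodes are excluded by default: including the very
#'   trait being predicted would leak the label into the score.
#' @param include_protein_hop If `TRUE` (default) a gene's scoring
#'   neighborhood also contains the 1-hop neighbors of each protein linked to
#'   it by `corresponding_to`, so annotations attached at the protein level
#'   (pathways, localizations, families, domains) count as shared evidence.
#' @param protein_pair_policy How to pick the protein pair when a gene maps to
#'   several proteins: `"max"` (pair with the highest provider score, default)
#'   or `"first"` (first pair in id order).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(excluded_categories = "trait",
                           include_protein_hop = TRUE,
                           protein_pair_policy = c("max", "first")) {
  bad <- setdiff(excluded_categories, kg_entity_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown excluded categories: ", paste(bad, collapse = ", ")),
          class = "kgtrait_bad_input")
  }
  structure(
    list(excluded_categories = excluded_categories,
         include_protein_hop = isTRUE(include_protein_hop),
         protein_pair_policy = match.arg(protein_pair_policy)),
    class = "scoring_config"
  )
}

kg_check_gene <- function(kg, gene_id) {
  kg_check_entity(kg, gene_id)
  cat <- kg$entities$category[kg$entities$id == gene_id]
  if (cat != "gene") {
    abort(paste0(gene_id, " has category '", cat, "', not 'gene'"),
          class = "kgtrait_bad_input")
  }
}

# protein entities linked to a gene by corresponding_to (either direction)
gene_proteins <- function(kg, gene_id) {
  tr <- kg$triples
  hit <- tr$relation == "corresponding_to" & (tr$head == gene_id | tr$tail == gene_id)
  ids <- unique(c(tr$head[hit], tr$tail[hit]))
  ids <- setdiff(ids, gene_id)
  sort(ids[ids %in% kg$entities$id[kg$entities$category == "protein"]])
}

#' Scoring neighborhood of a gene
#'
#' The union of the gene's 1-hop neighbors and (with
#' `include_protein_hop = TRUE`) the 1-hop neighbors of each of its
#' corresponding proteins, minus excluded categories and the gene itself.
#'
#' @param kg A `kg` object.
#' @param gene_id A gene entity id.
#' @param config A [scoring_config()].
#' @return Tibble of entities (`id`, `category`, `species`).
#' @export
kg_scoring_neighborhood <- function(kg, gene_id, config = scoring_config()) {
  kg_check_gene(kg, gene_id)
  nb <- kg_neighbors(kg, gene_id)
  if (config$include_protein_hop) {
    for (p in gene_proteins(kg, gene_id)) {
      nb <- bind_rows(nb, kg_neighbors(kg, p))
    }
  }
  nb |>
    distinct() |>
    filter(!.data$category %in% config$excluded_categories,
           .data$id != gene_id) |>
    arrange(.data$id)
}

#' Coincident entities of a gene pair
#'
#' The set k: the intersection of the two genes' scoring neighborhoods.
#'
#' @inheritParams kg_scoring_neighborhood
#' @param g1,g2 Gene entity ids.
#' @return Tibble of shared entities (`id`, `category`, `species`).
#' @export
kg_coincident_set <- function(kg, g1, g2, config = scoring_config()) {
  n1 <- kg_scoring_neighborhood(kg, g1, config)
  n2 <- kg_scoring_neighborhood(kg, g2, config)
  semi_join(n1, n2, by = "id")
}

#' Gene-pair similarity score
#'
#' Computes `S = C * D * Sp` for one pair of genes: `C` coincident entities,
#' `D` distinct categories among them, `Sp` protein similarity from the
#' provider. The result is symmetric in the two genes.
#'
#' @inheritParams kg_coincident_set
#' @param provider A `sim_provider` (see [table_provider()]).
#' @return One-row tibble: `g1`, `g2`, `C`, `D`, `Sp`, `S`, `p1`, `p2`.
#'   A pair the provider cannot score raises `kgtrait_unknown_pair` (it is
#'   unscorable, not zero).
#' @export
#' @examples
#' # the worked rice example: 12 shared entities over 4 categories,
#' # protein similarity 79.191 => S = 12 * 4 * 79.191 = 3801.17
gene_similarity <- function(kg, g1, g2, provider, config = scoring_config()) {
  if (identical(g1, g2)) {
    abort("self-pair: g1 and g2 must differ", class = "kgtrait_bad_input")
  }
  k <- kg_coincident_set(kg, g1, g2, config)
  pr1 <- gene_proteins(kg, g1)
  pr2 <- gene_proteins(kg, g2)
  if (length(pr1) == 0 || length(pr2) == 0) {
    abort(paste0("no corresponding protein for gene ",
                 if (length(pr1) == 0) g1 else g2),
          class = "kgtrait_no_protein")
  }
  combos <- tidyr::expand_grid(p1 = pr1, p2 = pr2)
  scored <- combos |>
    mutate(sp = map_dbl(seq_len(nrow(combos)), function(i) {
      tryCatch(protein_similarity(provider, combos$p1[i], combos$p2[i]),
               kgtrait_unknown_pair = function(e) NA_real_)
    })) |>
    filter(!is.na(.data$sp))
  if (nrow(scored) == 0) {
    abort(paste0("no scorable protein pair for genes (", g1, ", ", g2, ")"),
          class = "kgtrait_unknown_pair")
  }
  pick <- switch(config$protein_pair_policy,
    max = slice(arrange(scored, desc(.data$sp), .data$p1, .data$p2), 1),
    first = slice(arrange(scored, .data$p1, .data$p2), 1)
  )
  C <- nrow(k)
  D <- n_distinct(k$category)
  Sp <- pick$sp
  tibble(g1 = g1, g2 = g2, C = C, D = D, Sp = Sp, S = C * D * Sp,
         p1 = pick$p1, p2 = pick$p2)
}

#' Similarity of one gene to all known trait-regulating genes
#'
#' Scores `gene` against every distinct gene in the association records,
#' skipping the self-pair and pairs the provider cannot score. Each row is
#' tagged with the known gene's trait(s).
#'
#' @inheritParams gene_similarity
#' @param gene The query (unknown) gene id.
#' @param associations Tibble from [kg_load_associations()] (columns
#'   `gene_id`, `trait`, ...).
#' @return Tibble with one row per scorable known gene, ordered by known gene
#'   id: `g1` (query), `g2` (known), `C`, `D`, `Sp`, `S`, `p1`, `p2`,
#'   `traits` (list column of the known gene's trait labels). Skipped pairs
#'   are tallied in the `skipped` attribute.
#' @export
similarity_to_known <- function(kg, gene, associations, provider,
                                config = scoring_config()) {
  kg_check_gene(kg, gene)
  assoc <- tibble::as_tibble(associations)
  missing_genes <- setdiff(unique(assoc$gene_id), kg$entities$id)
  if (length(missing_genes) > 0) {
    abort(paste0("known gene(s) absent from graph: ",
                 paste(head(missing_genes, 3), collapse = ", ")),
          class = "kgtrait_unknown_entity")
  }
  known <- assoc |>
    group_by(.data$gene_id) |>
    summarise(traits = list(sort(unique(.data$trait))), .groups = "drop") |>
    filter(.data$gene_id != gene) |>
    arrange(.data$gene_id)
  skipped <- character(0)
  rows <- purrr::map(known$gene_id, function(g2) {
    tryCatch(gene_similarity(kg, gene, g2, provider, config),
             kgtrait_unknown_pair = function(e) { skipped <<- c(skipped, g2); NULL },
             kgtrait_no_protein = function(e) { skipped <<- c(skipped, g2); NULL })
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(g1 = character(), g2 = character(), C = integer(),
                  D = integer(), Sp = double(), S = double(),
                  p1 = character(), p2 = character())
  }
  out <- left_join(out, rename(known, g2 = "gene_id"), by = "g2")
  attr(out, "skipped") <- skipped
  out
}
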