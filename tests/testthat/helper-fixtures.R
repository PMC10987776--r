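# In-code fixtures shared across test files.

triple_row <- function(head, hc, rel, tail, tc, src = "test") {
  tibble::tibble(head = head, head_category = hc, relation = rel,
                 tail = tail, tail_category = tc, source = src)
}

# the 3-line toy graph: g1 -corresponding_to- p1, p1 in pathway s1,
# g1 performs mf m1
toy_triples <- function() {
  dplyr::bind_rows(
    triple_row("g1", "gene", "corresponding_to", "p1", "protein"),
    triple_row("p1", "protein", "involves_in_signal_pathway", "s1", "signal_pathway"),
    triple_row("g1", "gene", "performs", "m1", "molecular_function")
  )
}

write_triples_file <- function(triples, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(triples, path, col_names = FALSE, progress = FALSE)
  path
}

# two genes sharing `n_shared` annotations spread over `categories`, each
# with its own protein; optionally extra private annotations
shared_annotation_graph <- function(n_shared, categories = c(
    "molecular_function", "biological_process",
    "signal_pathway", "subcellular_localization")) {
  rel_of <- c(molecular_function = "performs",
              biological_process = "involves_in_biological_process",
              signal_pathway = "involves_in_signal_pathway",
              subcellular_localization = "located_in_subcellular_localization",
              metabolic_pathway = "involves_in_metabolic_pathway",
              enzyme = "encodes_enzyme_type",
              cellular_component = "located_in_cellular_component")
  gene_level <- c("molecular_function", "biological_process",
                  "metabolic_pathway", "enzyme", "cellular_component")
  rows <- dplyr::bind_rows(
    triple_row("pA", "protein", "corresponding_to", "gA", "gene"),
    triple_row("pB", "protein", "corresponding_to", "gB", "gene")
  )
  for (i in seq_len(n_shared)) {
    cat <- categories[((i - 1) %% length(categories)) + 1]
    ann <- sprintf("ann_%02d", i)
    for (g in c("A", "B")) {
      if (cat %in% gene_level) {
        rows <- dplyr::bind_rows(rows, triple_row(
          paste0("g", g), "gene", rel_of[[cat]], ann, cat))
      } else {
        rows <- dplyr::bind_rows(rows, triple_row(
          paste0("p", g), "protein", rel_of[[cat]], ann, cat))
      }
    }
  }
  kgtrait::kg_build(rows)
}

# random schema-conformant graph for property tests: n_genes genes, each with
# a protein, attached to annotations drawn from a small pool
random_small_graph <- function(n_genes = 4, n_annotations = 8, p_edge = 0.4) {
  cats <- c("molecular_function", "biological_process", "signal_pathway",
            "subcellular_localization")
  rel_of <- c(molecular_function = "performs",
              biological_process = "involves_in_biological_process",
              signal_pathway = "involves_in_signal_pathway",
              subcellular_localization = "located_in_subcellular_localization")
  ann_cat <- sample(cats, n_annotations, replace = TRUE)
  rows <- NULL
  for (i in seq_len(n_genes)) {
    g <- sprintf("g%02d", i); p <- sprintf("p%02d", i)
    rows <- dplyr::bind_rows(rows, triple_row(p, "protein", "corresponding_to", g, "gene"))
    for (a in seq_len(n_annotations)) {
      if (stats::runif(1) < p_edge) {
        cat <- ann_cat[a]; ann <- sprintf("ann%02d", a)
        if (cat %in% c("molecular_function", "biological_process")) {
          rows <- dplyr::bind_rows(rows, triple_row(g, "gene", rel_of[[cat]], ann, cat))
        } else {
          rows <- dplyr::bind_rows(rows, triple_row(p, "protein", rel_of[[cat]], ann, cat))
        }
      }
    }
  }
  kgtrait::kg_build(rows)
}

# uniform provider: every pair of the given proteins scores `value`
uniform_provider <- function(proteins, value = 50) {
  pairs <- t(utils::combn(sort(proteins), 2))
  kgtrait::table_provider(tibble::tibble(
    protein_a = c(pairs[, 1], sort(proteins)),
    protein_b = c(pairs[, 2], sort(proteins)),
    score = value
  ))
}
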