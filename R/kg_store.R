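# Knowledge-graph container: a light S3 object over two tibbles.
# `entities`: id, category, species. `triples`: head, relation, tail, source.
# Duplicate triples (same head/relation/tail) collapse to one row; the
# similarity score counts entities, never parallel edges.

new_kg <- function(entities, triples) {
  structure(
    list(entities = entities, triples = triples),
    class = "kg"
  )
}

#' Construct a knowledge graph from tibbles of entities and triples
#'
#' @param triples Data frame with columns `head`, `head_category`, `relation`,
#'   `tail`, `tail_category` and optionally `source`.
#' @param species Optional data frame with columns `id`, `species` annotating
#'   entities; unannotated entities get species `"none"`.
#' @param strict If `TRUE` (default) any schema violation (unknown category or
#'   relation, illegal category pair, self-loop, empty id) is an error; if
#'   `FALSE` violating rows are dropped and tallied in the `load_report`
#'   attribute.
#'
#' @return A `kg` object: a list with tibbles `entities` (id, category,
#'   species) and `triples` (head, relation, tail, source), plus a
#'   `load_report` attribute counting rows dropped per reason.
#' @export
#' @examples
#' tr <- tibble::tribble(
#'   ~head, ~head_category, ~relation, ~tail, ~tail_category, ~source,
#'   "p1", "protein", "corresponding_to", "g1", "gene", "toy",
#'   "g1", "gene", "performs", "mf1", "molecular_function", "toy"
#' )
#' kg <- kg_build(tr)
#' kg_neighbors(kg, "g1")
kg_build <- function(triples, species = NULL, strict = TRUE) {
  tr <- tibble::as_tibble(triples)
  needed <- c("head", "head_category", "relation", "tail", "tail_category")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols) > 0) {
    abort(paste0("triples is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "kgtrait_bad_input")
  }
  if (!"source" %in% names(tr)) tr$source <- NA_character_
  tr <- mutate(tr, across(all_of(c(needed, "source")), as.character))

  report <- c(empty_id = 0L, unknown_category = 0L, unknown_relation = 0L,
              illegal_pair = 0L, self_loop = 0L)
  drop <- function(bad, reason, msg) {
    n_bad <- sum(bad)
    if (n_bad > 0) {
      if (strict) abort(paste0(msg, " (", n_bad, " row(s))"), class = "kgtrait_schema")
      report[[reason]] <<- report[[reason]] + n_bad
      tr <<- tr[!bad, , drop = FALSE]
    }
  }

  drop(is.na(tr$head) | tr$head == "" | is.na(tr$tail) | tr$tail == "",
       "empty_id", "empty entity id")
  drop(!(tr$head_category %in% kg_entity_categories()) |
         !(tr$tail_category %in% kg_entity_categories()),
       "unknown_category", "unknown entity category")
  drop(!(tr$relation %in% kg_relation_types()$relation),
       "unknown_relation", "unknown relation type")
  drop(!relation_pair_ok(tr$relation, tr$head_category, tr$tail_category),
       "illegal_pair", "head/tail categories illegal for relation")
  # no relation is reflexive; a self-homologous protein is dropped with a warning
  if (any(tr$head == tr$tail)) {
    if (strict) {
      abort("self-loop triple (head == tail)", class = "kgtrait_schema")
    }
    warn(paste0(sum(tr$head == tr$tail), " self-loop triple(s) dropped"))
    report[["self_loop"]] <- sum(tr$head == tr$tail)
    tr <- filter(tr, .data$head != .data$tail)
  }

  triples_out <- distinct(tr, .data$head, .data$relation, .data$tail, .keep_all = TRUE)
  entities <- distinct(
    bind_rows(
      select(triples_out, id = "head", category = "head_category"),
      select(triples_out, id = "tail", category = "tail_category")
    )
  )
  dup <- entities$id[duplicated(entities$id)]
  if (length(dup) > 0) {
    abort(paste0("entity id used with more than one category: ",
                 paste(unique(dup), collapse = ", ")),
          class = "kgtrait_schema")
  }
  entities$species <- "none"
  if (!is.null(species)) {
    sp <- tibble::as_tibble(species)
    entities <- entities |>
      left_join(rename(sp, sp = "species"), by = "id") |>
      mutate(species = dplyr::coalesce(.data$sp, .data$species)) |>
      select(-"sp")
  }
  out <- new_kg(
    arrange(entities, .data$id),
    arrange(select(triples_out, "head", "relation", "tail", "source"),
            .data$head, .data$relation, .data$tail)
  )
  attr(out, "load_report") <- report
  out
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg> %d entities (%d categories), %d triples (%d relation types)\n",
              nrow(x$entities), dplyr::n_distinct(x$entities$category),
              nrow(x$triples), dplyr::n_distinct(x$triples$relation)))
  invisible(x)
}

#' Load a knowledge graph from a typed-triple TSV file
#'
#' The file is UTF-8, tab-separated with 6 columns (`head_id`, `head_category`,
#' `relation`, `tail_id`, `tail_category`, `source`), no quoting, `#` comment
#' lines allowed. Duplicate triples collapse to one. Loading is idempotent.
#'
#' @param path Path to the triple file.
#' @param strict Abort on any schema violation (default) or skip and count
#'   offending lines.
#' @return A `kg` object (see [kg_build()]).
#' @export
kg_load_triples <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("triple file not found: ", path), class = "kgtrait_io")
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("head", "head_category", "relation", "tail", "tail_category", "source"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", quote = "", progress = FALSE
  )
  probs <- readr::problems(raw)
  if (ncol(raw) < 6 || nrow(probs) > 0) {
    abort("malformed triple line(s): expected 6 tab-separated columns",
          class = "kgtrait_io")
  }
  kg_build(raw, strict = strict)
}

#' Load gene-trait association records
#'
#' Reads a CSV with header `gene_id,trait,year,evidence`; the publication year
#' drives time-sliced train/validation splits.
#'
#' @param path CSV path.
#' @return Tibble with columns `gene_id`, `trait`, `year` (integer),
#'   `evidence`, in file order.
#' @export
kg_load_associations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("association file not found: ", path), class = "kgtrait_io")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  needed <- c("gene_id", "trait", "year", "evidence")
  if (!all(needed %in% names(df))) {
    abort(paste0("association file must have header ", paste(needed, collapse = ",")),
          class = "kgtrait_io")
  }
  yr <- suppressWarnings(as.integer(df$year))
  bad <- is.na(yr) & !is.na(df$year)
  if (any(bad)) {
    abort(paste0("unparsable year: '", df$year[which(bad)[1]], "'"),
          class = "kgtrait_io")
  }
  if (any(!is.na(yr) & (yr < 1900 | yr > 2100))) {
    abort("year outside [1900, 2100]", class = "kgtrait_bad_input")
  }
  mutate(select(df, all_of(needed)), year = yr)
}

kg_check_entity <- function(kg, id) {
  if (!id %in% kg$entities$id) {
    abort(paste0("unknown entity id: ", id), class = "kgtrait_unknown_entity")
  }
}

#' Neighbors of an entity
#'
#' All entities connected to `id` by at least one triple in either direction;
#' adjacency is undirected and never includes the entity itself.
#'
#' @param kg A `kg` object.
#' @param id Entity id.
#' @return Tibble of neighbor entities (`id`, `category`, `species`).
#' @export
kg_neighbors <- function(kg, id) {
  kg_check_entity(kg, id)
  nb <- unique(c(
    kg$triples$tail[kg$triples$head == id],
    kg$triples$head[kg$triples$tail == id]
  ))
  filter(kg$entities, .data$id %in% nb)
}

#' Summarise a knowledge graph by (head category, relation, tail category)
#'
#' One row per observed (head category, relation, tail category) combination
#' with distinct head count, triple count and distinct tail count; totals are
#' available via [glance.kg()].
#'
#' @param kg A `kg` object.
#' @return Tibble with columns `head_category`, `relation`, `tail_category`,
#'   `n_head`, `n_triples`, `n_tail`.
#' @export
kg_summary <- function(kg) {
  cat_of <- setNames(kg$entities$category, kg$entities$id)
  kg$triples |>
    mutate(head_category = unname(cat_of[.data$head]),
           tail_category = unname(cat_of[.data$tail])) |>
    group_by(.data$head_category, .data$relation, .data$tail_category) |>
    summarise(n_head = n_distinct(.data$head),
              n_triples = n(),
              n_tail = n_distinct(.data$tail), .groups = "drop") |>
    arrange(.data$head_category, .data$relation, .data$tail_category)
}

#' @describeIn kg_summary Graph-level totals (nodes, triples, categories,
#'   relation types) as a one-row tibble.
#' @param x A `kg` object.
#' @param ... Unused.
#' @method glance kg
#' @export
glance.kg <- function(x, ...) {
  tibble(
    n_entities = nrow(x$entities),
    n_triples = nrow(x$triples),
    n_categories = n_distinct(x$entities$category),
    n_relation_types = n_distinct(x$triples$relation)
  )
}

#' @method tidy kg
#' @export
tidy.kg <- function(x, ...) kg_summary(x)

#' Export a knowledge graph as bulk-import CSV files
#'
#' Writes one node file per entity category (`nodes_<category>.csv` with
#' columns `id:ID`, `category:LABEL`, `species`) and one relationship file per
#' relation type (`rels_<relation>.csv` with columns `:START_ID`, `:END_ID`,
#' `:TYPE`, `source`), following the bulk CSV import convention of property
#' graph databases. [kg_import_bulk_csv()] round-trips the export.
#'
#' @param kg A `kg` object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
kg_export_bulk_csv <- function(kg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create directory: ", out_dir), class = "kgtrait_io")
  }
  paths <- character(0)
  for (cat in sort(unique(kg$entities$category))) {
    nodes <- filter(kg$entities, .data$category == cat)
    df <- tibble(`id:ID` = nodes$id, `category:LABEL` = nodes$category,
                 species = nodes$species)
    p <- file.path(out_dir, paste0("nodes_", cat, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths <- c(paths, p)
  }
  for (rel in sort(unique(kg$triples$relation))) {
    tr <- filter(kg$triples, .data$relation == rel)
    df <- tibble(`:START_ID` = tr$head, `:END_ID` = tr$tail,
                 `:TYPE` = tr$relation, source = tr$source)
    p <- file.path(out_dir, paste0("rels_", rel, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @describeIn kg_export_bulk_csv Rebuild a `kg` from a bulk-CSV export
#'   directory.
#' @param dir Directory written by [kg_export_bulk_csv()].
#' @export
kg_import_bulk_csv <- function(dir) {
  node_files <- list.files(dir, pattern = "^nodes_.*\\.csv$", full.names = TRUE)
  rel_files <- list.files(dir, pattern = "^rels_.*\\.csv$", full.names = TRUE)
  if (length(node_files) == 0) {
    abort(paste0("no node files under ", dir), class = "kgtrait_io")
  }
  nodes <- purrr::map(node_files, function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }) |> list_rbind()
  nodes <- tibble(id = nodes$`id:ID`, category = nodes$`category:LABEL`,
                  species = nodes$species)
  rels <- purrr::map(rel_files, function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }) |> list_rbind()
  cat_of <- setNames(nodes$category, nodes$id)
  triples <- tibble(
    head = rels$`:START_ID`,
    head_category = unname(cat_of[rels$`:START_ID`]),
    relation = rels$`:TYPE`,
    tail = rels$`:END_ID`,
    tail_category = unname(cat_of[rels$`:END_ID`]),
    source = rels$source
  )
  kg_build(triples, species = select(nodes, "id", "species"))
}

#' Write a knowledge graph back to the 6-column triple TSV format
#'
#' @param kg A `kg` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
kg_write_triples <- function(kg, path) {
  cat_of <- setNames(kg$entities$category, kg$entities$id)
  df <- tibble(
    head = kg$triples$head,
    head_category = unname(cat_of[kg$triples$head]),
    relation = kg$triples$relation,
    tail = kg$triples$tail,
    tail_category = unname(cat_of[kg$triples$tail]),
    source = dplyr::coalesce(kg$triples$source, "unknown")
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
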