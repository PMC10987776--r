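# Synthetic knowledge-graph fixtures with planted ground truth.
#
# The generator emulates the statistical structure the similarity score
# exploits: genes regulating a common trait share a core of annotation
# entities spread over several categories (so both C and D carry signal,
# mirroring the worked example's C = 12, D = 4) and encode similar proteins,
# while decoy genes share little and encode dissimilar proteins. Everything
# is driven by one integer seed and is byte-reproducible.

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a small cohort with a strong planted signal: trait-mate
#' genes share 12 annotation entities across 4 categories (molecular
#' function, biological process, signal pathway, subcellular localization)
#' and proteins of mean similarity 80, while decoys share at most a single
#' noise annotation and proteins of mean similarity 10.
#'
#' @param n_traits Number of traits.
#' @param known_genes_per_trait Literature-known genes planted per trait.
#' @param n_unknown_true Unannotated genes planted to carry trait signal;
#'   each carries `n_traits_per_unknown` traits (polyphenotype by
#'   construction when >= 2).
#' @param n_traits_per_unknown Traits per planted unknown gene.
#' @param n_decoys Unrelated decoy genes.
#' @param shared_annotations_signal Size of the annotation core shared by a
#'   trait's genes.
#' @param shared_annotations_noise Annotations a decoy draws from the trait
#'   cores.
#' @param protein_sim_signal,protein_sim_noise Mean protein similarity for
#'   trait-sharing vs unrelated gene pairs (0-100 scale).
#' @param protein_sim_sd Spread of similarity scores.
#' @param year_range Publication-year window; years are placed so that 80% of
#'   known associations fall at or before the cutoff year (an 8:2 time slice
#'   exists by construction) and planted unknowns post-date it.
#' @param max_labeled_pairs Upper bound on the number of gene-gene pairs
#'   scored into the labeled-pair table; larger pair sets are subsampled
#'   (seeded) to keep generation fast.
#' @param seed Integer seed fixing all randomness.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_traits = 2, known_genes_per_trait = 3,
                           n_unknown_true = 4, n_traits_per_unknown = 2,
                           n_decoys = 10,
                           shared_annotations_signal = 12,
                           shared_annotations_noise = 1,
                           protein_sim_signal = 80, protein_sim_noise = 10,
                           protein_sim_sd = 3,
                           year_range = c(1990, 2023),
                           max_labeled_pairs = 500, seed = 1L) {
  stopifnot(n_traits >= 1, known_genes_per_trait >= 1, n_unknown_true >= 0,
            n_decoys >= 0, shared_annotations_signal >= 1,
            shared_annotations_noise >= 0,
            year_range[1] < year_range[2])
  n_traits_per_unknown <- min(n_traits_per_unknown, n_traits)
  structure(as.list(environment()), class = "fixture_config")
}

signal_categories <- function() {
  # gene-level and protein-level attachment points, 4 categories in all
  tibble::tribble(
    ~category,                  ~relation,                         ~level,
    "molecular_function",       "performs",                        "gene",
    "biological_process",       "involves_in_biological_process",  "gene",
    "signal_pathway",           "involves_in_signal_pathway",      "protein",
    "subcellular_localization", "located_in_subcellular_localization", "protein"
  )
}

# an annotation's category is fixed by the trailing index in its id, so the
# same entity always re-attaches under the same category
annotation_triples <- function(gene, protein, annot_ids) {
  cats <- signal_categories()
  k <- as.integer(sub(".*_(\\d+)$", "\\1", annot_ids))
  idx <- ((k - 1) %% nrow(cats)) + 1
  tibble(
    head = ifelse(cats$level[idx] == "gene", gene, protein),
    head_category = ifelse(cats$level[idx] == "gene", "gene", "protein"),
    relation = cats$relation[idx],
    tail = annot_ids,
    tail_category = cats$category[idx],
    source = "synthetic"
  )
}

#' Generate a synthetic fixture bundle with planted ground truth
#'
#' Builds a schema-conformant knowledge graph, a gene-trait association
#' table, a pairwise protein-similarity table, and labeled gene-gene pairs
#' scored with [gene_similarity()] against the generated graph. The manifest
#' records exactly which genes carry which traits. With the same config the
#' output is byte-identical across runs.
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory; when given, the bundle is written as
#'   `triples.tsv`, `associations.csv`, `protein_sim.tsv`,
#'   `labeled_pairs.tsv` and `manifest.json`.
#' @return List with `kg`, `associations`, `sim_table`, `labeled_pairs`,
#'   `manifest` and (when `dir` is given) `paths`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, generate_fixture_impl(config, dir))
}

generate_fixture_impl <- function(cfg, dir) {
  fmt <- function(prefix, i) sprintf("%s%02d", prefix, i)
  traits <- fmt("trait_", seq_len(cfg$n_traits))

  # annotation pool check: each trait needs its own core
  cats <- signal_categories()
  # gene roster ------------------------------------------------------------
  known <- purrr::imap(traits, function(tr, j) {
    tibble(gene = sprintf("G_%s_K%02d", toupper(tr), seq_len(cfg$known_genes_per_trait)),
           role = "known", trait = tr)
  }) |> list_rbind()
  planted <- if (cfg$n_unknown_true > 0) {
    purrr::map(seq_len(cfg$n_unknown_true), function(i) {
      trs <- traits[(((i - 1) + seq_len(cfg$n_traits_per_unknown) - 1) %% cfg$n_traits) + 1]
      tibble(gene = sprintf("G_UNK%02d", i), role = "planted", trait = unique(trs))
    }) |> list_rbind()
  } else tibble(gene = character(), role = character(), trait = character())
  decoys <- if (cfg$n_decoys > 0) {
    tibble(gene = sprintf("G_DEC%02d", seq_len(cfg$n_decoys)),
           role = "decoy", trait = NA_character_)
  } else tibble(gene = character(), role = character(), trait = character())
  roster <- bind_rows(known, planted, decoys)
  genes <- unique(roster$gene)
  protein_of <- setNames(sub("^G_", "P_", genes), genes)

  # triples ----------------------------------------------------------------
  triples <- list()
  triples$corr <- tibble(
    head = unname(protein_of[genes]), head_category = "protein",
    relation = "corresponding_to", tail = genes, tail_category = "gene",
    source = "synthetic"
  )
  # known proteins associate with their trait (excluded from scoring by default)
  triples$assoc <- known |>
    mutate(head = unname(protein_of[.data$gene]), head_category = "protein",
           relation = "associates_with", tail = .data$trait,
           tail_category = "trait", source = "synthetic") |>
    select("head", "head_category", "relation", "tail", "tail_category", "source")
  # trait cores: every signal gene of a trait attaches to the full core
  cores <- setNames(purrr::map(seq_along(traits), function(j) {
    sprintf("A_%s_%02d", toupper(traits[j]), seq_len(cfg$shared_annotations_signal))
  }), traits)
  signal_roster <- filter(roster, .data$role %in% c("known", "planted"))
  triples$signal <- purrr::map(seq_len(nrow(signal_roster)), function(i) {
    g <- signal_roster$gene[i]
    annotation_triples(g, protein_of[[g]], cores[[signal_roster$trait[i]]])
  }) |> list_rbind()
  # decoys: a few private annotations plus a small draw from the trait cores
  if (cfg$n_decoys > 0) {
    all_core <- unlist(cores, use.names = FALSE)
    triples$decoy <- purrr::map(seq_len(cfg$n_decoys), function(i) {
      g <- decoys$gene[i]
      priv <- sprintf("A_PRIV_%02d_%02d", i, 1:3)
      noise <- if (cfg$shared_annotations_noise > 0) {
        sample(all_core, min(cfg$shared_annotations_noise, length(all_core)))
      } else character(0)
      annotation_triples(g, protein_of[[g]], c(priv, noise))
    }) |> list_rbind()
  }
  kg <- kg_build(distinct(list_rbind(triples)))

  # associations (known genes only) with an 8:2 time slice by construction --
  ymin <- cfg$year_range[1]; ymax <- cfg$year_range[2]
  cutoff_year <- floor(ymin + 0.8 * (ymax - ymin))
  n_known <- nrow(known)
  n_train <- max(1L, ceiling(0.8 * n_known))
  early <- sample(seq_len(n_known)) <= n_train
  assoc_years <- integer(n_known)
  assoc_years[early] <- sample(seq(ymin, cutoff_year), sum(early), replace = TRUE)
  if (any(!early)) {
    assoc_years[!early] <- sample(seq(cutoff_year + 1, ymax), sum(!early),
                                  replace = TRUE)
  }
  associations <- tibble(
    gene_id = known$gene, trait = known$trait, year = assoc_years,
    evidence = sprintf("SYNTH:%s", known$gene)
  )
  # planted unknowns are "discovered" after the cutoff
  planted_years <- if (nrow(planted) > 0) {
    setNames(sample(seq(cutoff_year + 1, ymax), length(unique(planted$gene)),
                    replace = TRUE), unique(planted$gene))
  } else integer(0)

  # protein similarity table ------------------------------------------------
  truth_traits <- roster |>
    filter(!is.na(.data$trait)) |>
    group_by(.data$gene) |>
    summarise(traits = list(unique(.data$trait)), .groups = "drop")
  traits_of <- setNames(truth_traits$traits, truth_traits$gene)
  share_trait <- function(a, b) {
    length(intersect(traits_of[[a]] %||% character(0),
                     traits_of[[b]] %||% character(0))) > 0
  }
  pairs <- t(combn(sort(genes), 2))
  sim_table <- tibble(
    protein_a = unname(protein_of[pairs[, 1]]),
    protein_b = unname(protein_of[pairs[, 2]]),
    score = map_dbl(seq_len(nrow(pairs)), function(i) {
      mu <- if (share_trait(pairs[i, 1], pairs[i, 2])) cfg$protein_sim_signal
            else cfg$protein_sim_noise
      round(min(100, max(0, rnorm(1, mu, cfg$protein_sim_sd))), 3)
    })
  )
  provider <- table_provider(sim_table)

  # labeled gene-gene pairs scored against the generated graph --------------
  signal_genes <- unique(signal_roster$gene)
  year_of <- c(setNames(assoc_years, known$gene), planted_years)
  lp <- t(combn(sort(signal_genes), 2))
  # add signal-decoy pairs as extra negatives
  if (cfg$n_decoys > 0) {
    extra <- cbind(rep(sort(signal_genes), each = 1),
                   rep(sort(decoys$gene), length.out = length(signal_genes)))
    lp <- rbind(lp, extra)
    year_of <- c(year_of, setNames(sample(seq(ymin, ymax), cfg$n_decoys,
                                          replace = TRUE), decoys$gene))
  }
  if (nrow(lp) > cfg$max_labeled_pairs) {
    lp <- lp[sort(sample(nrow(lp), cfg$max_labeled_pairs)), , drop = FALSE]
  }
  labeled_pairs <- purrr::map(seq_len(nrow(lp)), function(i) {
    g1 <- lp[i, 1]; g2 <- lp[i, 2]
    s <- gene_similarity(kg, g1, g2, provider)$S
    tibble(g1 = g1, g2 = g2, score = s,
           label = if (share_trait(g1, g2)) "positive" else "negative",
           year = max(year_of[[g1]], year_of[[g2]]))
  }) |> list_rbind()

  manifest <- list(
    config = unclass(cfg),
    cutoff_year = cutoff_year,
    roster = roster,
    planted_links = select(filter(roster, .data$role == "planted"),
                           "gene", "trait"),
    planted_years = as.list(planted_years)
  )

  bundle <- list(kg = kg, associations = associations, sim_table = sim_table,
                 labeled_pairs = labeled_pairs, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      triples = file.path(dir, "triples.tsv"),
      associations = file.path(dir, "associations.csv"),
      protein_sim = file.path(dir, "protein_sim.tsv"),
      labeled_pairs = file.path(dir, "labeled_pairs.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    kg_write_triples(kg, paths[["triples"]])
    readr::write_csv(associations, paths[["associations"]], progress = FALSE)
    readr::write_tsv(sim_table, paths[["protein_sim"]], progress = FALSE)
    readr::write_tsv(labeled_pairs, paths[["labeled_pairs"]], progress = FALSE)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    bundle$paths <- paths
  }
  bundle
}

#' Generate DEG tables matched to planted trait genes
#'
#' For each trait, genes truly carrying the trait appear as differentially
#' expressed (|log2 fold change| >= 1) with probability `overlap_fraction`;
#' otherwise they fall below the cutoff. Decoy genes are mostly below the
#' cutoff.
#'
#' @param bundle A [generate_fixture()] bundle.
#' @param dir Directory for the per-trait TSV files (`deg_<trait>.tsv`).
#' @param overlap_fraction Probability that a true trait gene passes the DEG
#'   filter (default 0.66).
#' @param seed Integer seed.
#' @return Named character vector of file paths, one per trait.
#' @export
generate_deg_tables <- function(bundle, dir, overlap_fraction = 0.66,
                                seed = 1L) {
  roster <- bundle$manifest$roster
  traits <- sort(unique(roster$trait[!is.na(roster$trait)]))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    paths <- setNames(character(length(traits)), traits)
    for (tr in traits) {
      true_genes <- sort(unique(roster$gene[!is.na(roster$trait) & roster$trait == tr]))
      others <- sort(setdiff(unique(roster$gene), true_genes))
      hit <- runif(length(true_genes)) < overlap_fraction
      lfc_true <- ifelse(hit, sample(c(-1, 1), length(true_genes), TRUE) * runif(length(true_genes), 1, 4),
                         sample(c(-1, 1), length(true_genes), TRUE) * runif(length(true_genes), 0, 0.9))
      lfc_other <- sample(c(-1, 1), length(others), TRUE) * runif(length(others), 0, 0.9)
      df <- tibble(gene_id = c(true_genes, others),
                   log_fc = round(c(lfc_true, lfc_other), 3))
      p <- file.path(dir, paste0("deg_", tr, ".tsv"))
      readr::write_tsv(df, p, progress = FALSE)
      paths[[tr]] <- p
    }
    paths
  })
}
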