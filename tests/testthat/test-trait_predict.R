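# graph with one query gene and four known genes at controlled similarity:
# build each known gene to share a chosen number of annotations with the
# query, and set protein similarities so best scores are exact
multi_known_graph <- function() {
  # query gQ shares 4 annotations over 4 categories with each known gene,
  # via a common annotation core per known gene
  rel_of <- c(molecular_function = "performs",
              biological_process = "involves_in_biological_process",
              signal_pathway = "involves_in_signal_pathway",
              subcellular_localization = "located_in_subcellular_localization")
  gene_level <- c("molecular_function", "biological_process")
  known <- c("gSalt", "gDrought", "gDisease", "gPHGW")
  rows <- triple_row("pQ", "protein", "corresponding_to", "gQ", "gene")
  for (g in known) {
    p <- sub("^g", "p", g)
    rows <- dplyr::bind_rows(rows, triple_row(p, "protein", "corresponding_to", g, "gene"))
    for (i in 1:4) {
      cat <- names(rel_of)[i]
      ann <- paste0("ann_", g, "_", i)
      for (who in c(g, "gQ")) {
        pw <- sub("^g", "p", who)
        if (cat %in% gene_level) {
          rows <- dplyr::bind_rows(rows, triple_row(who, "gene", rel_of[[cat]], ann, cat))
        } else {
          rows <- dplyr::bind_rows(rows, triple_row(pw, "protein", rel_of[[cat]], ann, cat))
        }
      }
    }
  }
  kg_build(rows)
}

multi_known_provider <- function(sims) {
  table_provider(tibble::tibble(
    protein_a = "pQ", protein_b = sub("^g", "p", names(sims)),
    score = unname(sims)))
}

multi_known_assoc <- tibble::tibble(
  gene_id = c("gSalt", "gDrought", "gDisease", "gPHGW", "gPHGW"),
  trait = c("salt_resistance", "drought_resistance", "disease_resistance",
            "plant_height", "grain_weight"),
  year = c(2001L, 2005L, 2010L, 2012L, 2013L), evidence = "lit")

test_that("a gene above threshold for one trait's known gene gets that trait", {
  kg <- shared_annotation_graph(12)
  pr <- table_provider(tibble::tibble(protein_a = "pA", protein_b = "pB",
                                      score = 79.191))
  assoc <- tibble::tibble(gene_id = "gB", trait = "drought_resistance",
                          year = 2014L, evidence = "PMID")
  pred <- predict_traits(kg, "gA", assoc, pr, threshold = 502.36)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$trait, "drought_resistance")
  expect_equal(round(pred$best_score, 2), 3801.17)
  expect_true(pred$passed)
  expect_equal(pred$supporting_gene, "gB")
})

test_that("a known gene carrying two traits supports both, yielding five predicted traits", {
  kg <- multi_known_graph()
  # each pair shares C = 4, D = 4; choose Sp so best scores land where wanted
  pr <- multi_known_provider(c(gSalt = 1156.86, gDrought = 671.88,
                               gDisease = 653.84, gPHGW = 645.00) / 16)
  pred <- predict_traits(kg, "gQ", multi_known_assoc, pr, threshold = 502.36)
  expect_equal(nrow(pred), 5)
  expect_true(all(pred$passed))
  expect_setequal(pred$trait, c("salt_resistance", "drought_resistance",
                                "disease_resistance", "plant_height", "grain_weight"))
  # the dual-trait supporter backs both of its traits with the same score
  ph <- pred[pred$trait %in% c("plant_height", "grain_weight"), ]
  expect_equal(unique(ph$supporting_gene), "gPHGW")
  expect_equal(round(ph$best_score, 2), c(645, 645))
  # ordering is by descending best score
  expect_equal(pred$trait[1], "salt_resistance")
})

test_that("raising the threshold never adds a predicted trait", {
  kg <- multi_known_graph()
  pr <- multi_known_provider(c(gSalt = 70, gDrought = 40, gDisease = 30, gPHGW = 20))
  prev <- NULL
  for (th in c(0, 300, 500, 700, 2000)) {
    pred <- predict_traits(kg, "gQ", multi_known_assoc, pr, threshold = th)
    passed <- sort(pred$trait[pred$passed])
    if (!is.null(prev)) expect_true(all(passed %in% prev))
    prev <- passed
  }
  # and all scores below threshold means nothing passes
  none <- predict_traits(kg, "gQ", multi_known_assoc, pr, threshold = 1e6)
  expect_false(any(none$passed))
})

test_that("per-trait best score equals a brute-force max over known genes", {
  b <- generate_fixture(fixture_config(seed = 29))
  pr <- table_provider(b$sim_table)
  g <- b$manifest$planted_links$gene[1]
  pred <- predict_traits(b$kg, g, b$associations, pr, threshold = 0)
  for (i in seq_len(nrow(pred))) {
    knowns <- unique(b$associations$gene_id[b$associations$trait == pred$trait[i]])
    knowns <- setdiff(knowns, g)
    best <- max(vapply(knowns, function(kgene) {
      gene_similarity(b$kg, g, kgene, pr)$S
    }, numeric(1)))
    expect_equal(pred$best_score[i], best)
  }
})

test_that("batch prediction aggregates per-gene failures without aborting", {
  b <- generate_fixture(fixture_config(seed = 29))
  pr <- table_provider(b$sim_table)
  genes <- c(b$manifest$planted_links$gene[1], "not_a_gene")
  pred <- predict_all(b$kg, genes, b$associations, pr, threshold = 0)
  expect_true(nrow(pred) > 0)
  skipped <- attr(pred, "skipped")
  expect_equal(skipped$gene, "not_a_gene")

  empty <- predict_all(b$kg, character(0), b$associations, pr, threshold = 0)
  expect_equal(nrow(empty), 0)
})

test_that("batch predictions at the swept threshold recover the planted truth exactly", {
  b <- generate_fixture(fixture_config(seed = 37))
  pr <- table_provider(b$sim_table)
  sw <- sweep_threshold(time_slice_split(b$labeled_pairs, b$manifest$cutoff_year)$train)
  unknowns <- unique(b$manifest$planted_links$gene)
  decoys <- b$manifest$roster$gene[b$manifest$roster$role == "decoy"]
  pred <- predict_all(b$kg, c(unknowns, decoys), b$associations, pr,
                      threshold = sw$threshold)
  got <- dplyr::arrange(pred[pred$passed, c("gene", "trait")], gene, trait)
  want <- dplyr::arrange(b$manifest$planted_links, gene, trait)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})
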