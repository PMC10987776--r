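test_that("the scoring neighborhood unions gene and protein hops and filters categories", {
  rows <- dplyr::bind_rows(
    triple_row("p", "protein", "corresponding_to", "g", "gene"),
    triple_row("g", "gene", "involves_in_biological_process", "bp1", "biological_process"),
    triple_row("g", "gene", "performs", "mf1", "molecular_function"),
    triple_row("p", "protein", "involves_in_signal_pathway", "s1", "signal_pathway"),
    triple_row("p", "protein", "associates_with", "t1", "trait")
  )
  kg <- kg_build(rows)
  expect_setequal(kg_scoring_neighborhood(kg, "g")$id, c("p", "bp1", "mf1", "s1"))
  # without the protein hop the pathway is out of reach
  cfg <- scoring_config(include_protein_hop = FALSE)
  expect_setequal(kg_scoring_neighborhood(kg, "g", cfg)$id, c("p", "bp1", "mf1"))
  # trait nodes are excluded by default (label leakage), included on request
  cfg2 <- scoring_config(excluded_categories = character(0))
  expect_true("t1" %in% kg_scoring_neighborhood(kg, "g", cfg2)$id)
  expect_false("t1" %in% kg_scoring_neighborhood(kg, "g")$id)

  expect_error(kg_scoring_neighborhood(kg, "p"), class = "kgtrait_bad_input")
  expect_error(scoring_config(excluded_categories = "widget"),
               class = "kgtrait_bad_input")
})

test_that("coincident sets are exact intersections", {
  kg <- shared_annotation_graph(3, c("molecular_function", "biological_process",
                                     "signal_pathway"))
  k <- kg_coincident_set(kg, "gA", "gB")
  expect_setequal(k$id, c("ann_01", "ann_02", "ann_03"))
  # disjoint neighborhoods
  rows <- dplyr::bind_rows(
    triple_row("pA", "protein", "corresponding_to", "gA", "gene"),
    triple_row("pB", "protein", "corresponding_to", "gB", "gene"),
    triple_row("gA", "gene", "performs", "m1", "molecular_function"),
    triple_row("gB", "gene", "performs", "m2", "molecular_function")
  )
  expect_equal(nrow(kg_coincident_set(kg_build(rows), "gA", "gB")), 0)
})

test_that("the worked example arithmetic holds: 12 shared entities x 4 categories x 79.191", {
  kg <- shared_annotation_graph(12)
  pr <- table_provider(tibble::tibble(protein_a = "pA", protein_b = "pB",
                                      score = 79.191))
  res <- gene_similarity(kg, "gA", "gB", pr)
  expect_equal(res$C, 12)
  expect_equal(res$D, 4)
  expect_equal(res$Sp, 79.191)
  expect_equal(round(res$S, 2), 3801.17)
  expect_equal(res$S, 12 * 4 * 79.191)
})

test_that("gene similarity is symmetric, annihilates at C = 0, and flags unscorable pairs", {
  kg <- shared_annotation_graph(3, c("molecular_function", "biological_process",
                                     "signal_pathway"))
  pr <- table_provider(tibble::tibble(protein_a = "pA", protein_b = "pB", score = 50))
  ab <- gene_similarity(kg, "gA", "gB", pr)
  ba <- gene_similarity(kg, "gB", "gA", pr)
  expect_equal(ab[c("C", "D", "Sp", "S")], ba[c("C", "D", "Sp", "S")])
  expect_equal(ab$S, 3 * 3 * 50)

  # C = 0 forces S = 0 whatever the protein similarity
  rows <- dplyr::bind_rows(
    triple_row("pA", "protein", "corresponding_to", "gA", "gene"),
    triple_row("pB", "protein", "corresponding_to", "gB", "gene"),
    triple_row("gA", "gene", "performs", "m1", "molecular_function")
  )
  res0 <- gene_similarity(kg_build(rows), "gA", "gB", pr)
  expect_equal(res0$C, 0)
  expect_equal(res0$S, 0)

  expect_error(gene_similarity(kg, "gA", "gA", pr), class = "kgtrait_bad_input")
  empty_pr <- table_provider(tibble::tibble(protein_a = character(),
                                            protein_b = character(),
                                            score = double()))
  expect_error(gene_similarity(kg, "gA", "gB", empty_pr),
               class = "kgtrait_unknown_pair")
  # a gene with no corresponding protein is unscorable, not zero
  nop <- kg_build(dplyr::bind_rows(
    triple_row("pA", "protein", "corresponding_to", "gA", "gene"),
    triple_row("gB", "gene", "performs", "m1", "molecular_function"),
    triple_row("gA", "gene", "performs", "m1", "molecular_function")
  ))
  expect_error(gene_similarity(nop, "gA", "gB", pr), class = "kgtrait_no_protein")
})

test_that("C and D match a brute-force intersection oracle on random graphs", {
  withr::with_seed(101, {
    for (rep in 1:12) {
      kg <- random_small_graph(n_genes = sample(2:4, 1),
                               n_annotations = sample(4:8, 1))
      genes <- kg$entities$id[kg$entities$category == "gene"]
      proteins <- kg$entities$id[kg$entities$category == "protein"]
      pr <- uniform_provider(proteins, 50)
      pairs <- t(utils::combn(genes, 2))
      for (i in seq_len(nrow(pairs))) {
        got <- gene_similarity(kg, pairs[i, 1], pairs[i, 2], pr)
        want <- oracle_CD(kg, pairs[i, 1], pairs[i, 2])
        expect_equal(got$C, want$C, info = paste(pairs[i, ], collapse = "/"))
        expect_equal(got$D, want$D, info = paste(pairs[i, ], collapse = "/"))
        expect_lte(got$D, min(got$C, 13))
      }
    }
  })
})

test_that("adding a shared annotation never decreases C, D or S", {
  pr <- table_provider(tibble::tibble(protein_a = "pA", protein_b = "pB", score = 60))
  prev <- c(C = -1, D = -1, S = -1)
  for (n in 1:8) {
    kg <- shared_annotation_graph(n)
    res <- gene_similarity(kg, "gA", "gB", pr)
    expect_gte(res$C, prev[["C"]])
    expect_gte(res$D, prev[["D"]])
    expect_gte(res$S, prev[["S"]])
    prev <- c(C = res$C, D = res$D, S = res$S)
  }
})

test_that("multi-protein genes follow the configured pair policy", {
  rows <- dplyr::bind_rows(
    triple_row("pA1", "protein", "corresponding_to", "gA", "gene"),
    triple_row("pA2", "protein", "corresponding_to", "gA", "gene"),
    triple_row("pB", "protein", "corresponding_to", "gB", "gene"),
    triple_row("gA", "gene", "performs", "m1", "molecular_function"),
    triple_row("gB", "gene", "performs", "m1", "molecular_function")
  )
  kg <- kg_build(rows)
  pr <- table_provider(tibble::tibble(
    protein_a = c("pA1", "pA2"), protein_b = c("pB", "pB"), score = c(30, 90)))
  res_max <- gene_similarity(kg, "gA", "gB", pr)
  expect_equal(res_max$Sp, 90)
  expect_equal(res_max$p1, "pA2")
  res_first <- gene_similarity(kg, "gA", "gB", pr,
                               scoring_config(protein_pair_policy = "first"))
  expect_equal(res_first$Sp, 30)
})

test_that("similarity to known genes skips self-pairs and tags traits", {
  kg <- shared_annotation_graph(4)
  pr <- table_provider(tibble::tibble(protein_a = "pA", protein_b = "pB", score = 70))
  assoc <- tibble::tibble(
    gene_id = c("gB", "gB", "gA"),
    trait = c("drought_resistance", "salt_resistance", "plant_height"),
    year = c(2014L, 2016L, 2010L), evidence = "x")
  res <- similarity_to_known(kg, "gA", assoc, pr)
  expect_equal(nrow(res), 1)  # the self-pair gA is skipped
  expect_equal(res$g2, "gB")
  expect_setequal(res$traits[[1]], c("drought_resistance", "salt_resistance"))

  expect_equal(nrow(similarity_to_known(kg, "gA", assoc[0, ], pr)), 0)
  expect_error(similarity_to_known(kg, "gA", tibble::tibble(
    gene_id = "ghost", trait = "t", year = 2000L, evidence = "e"), pr),
    class = "kgtrait_unknown_entity")
})
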