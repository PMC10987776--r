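pred_row <- function(gene, trait, score, passed = TRUE) {
  tibble::tibble(gene = gene, trait = trait, best_score = score,
                 supporting_gene = "k", threshold = 500, passed = passed)
}

test_that("polyphenotype mining keeps only genes passing two or more traits", {
  pred <- dplyr::bind_rows(
    pred_row("g1", "salt_resistance", 900),
    pred_row("g1", "drought_resistance", 800),
    pred_row("g2", "salt_resistance", 700),
    pred_row("g3", "salt_resistance", 950),
    pred_row("g3", "drought_resistance", 600, passed = FALSE)
  )
  poly <- mine_polyphenotype(pred)
  expect_equal(poly$gene, "g1")
  expect_equal(poly$traits[[1]], c("drought_resistance", "salt_resistance"))
  expect_equal(poly$n_traits, 2L)
  # below-threshold traits never count: g3 passes only one trait

  # status annotation from the association file
  assoc <- tibble::tibble(gene_id = "g1", trait = "salt_resistance",
                          year = 2000L, evidence = "x")
  expect_equal(mine_polyphenotype(pred, assoc)$status, "known")
  expect_equal(mine_polyphenotype(pred)$status, "unknown")
})

test_that("a planted multi-trait gene is mined with exactly its planted traits", {
  cfg <- fixture_config(n_traits = 3, n_traits_per_unknown = 3, seed = 41)
  b <- generate_fixture(cfg)
  pr <- table_provider(b$sim_table)
  sw <- sweep_threshold(b$labeled_pairs)
  g <- b$manifest$planted_links$gene[1]
  pred <- predict_all(b$kg, g, b$associations, pr, threshold = sw$threshold)
  poly <- mine_polyphenotype(pred)
  expect_equal(poly$gene, g)
  expect_equal(poly$traits[[1]],
               sort(b$manifest$planted_links$trait[b$manifest$planted_links$gene == g]))
})

test_that("combination counts group by full trait set and conserve genes", {
  pred <- dplyr::bind_rows(
    pred_row("g1", "salt", 1), pred_row("g1", "drought", 1),
    pred_row("g2", "salt", 1), pred_row("g2", "drought", 1),
    pred_row("g3", "salt", 1), pred_row("g3", "drought", 1),
    pred_row("g3", "disease", 1)
  )
  poly <- mine_polyphenotype(pred)
  tab <- combination_counts(poly)
  expect_equal(tab$traits, c("drought, salt", "disease, drought, salt"))
  expect_equal(tab$n_genes, c(2L, 1L))
  expect_equal(sum(tab$n_genes), nrow(poly))

  expect_equal(nrow(combination_counts(poly[0, ])), 0)

  # conservation on a generated cohort
  b <- generate_fixture(fixture_config(n_unknown_true = 6, seed = 43))
  pr <- table_provider(b$sim_table)
  pred_all <- predict_all(b$kg, unique(b$manifest$planted_links$gene),
                          b$associations, pr, threshold = 100)
  poly_all <- mine_polyphenotype(pred_all)
  expect_equal(sum(combination_counts(poly_all)$n_genes), nrow(poly_all))
})

test_that("per-trait ranking implements dense and ordinal tie policies", {
  scores <- c(a = 900, b = 700, c = 700, d = 500)
  dense <- per_trait_rank(scores)
  expect_equal(stats::setNames(dense$rank, dense$gene),
               c(a = 1L, b = 2L, c = 2L, d = 3L))
  ordinal <- per_trait_rank(scores, "ordinal")
  expect_equal(stats::setNames(ordinal$rank, ordinal$gene),
               c(a = 1L, b = 2L, c = 3L, d = 4L))
  expect_equal(per_trait_rank(c(z = 5))$rank, 1L)

  # dense ranks cover 1..#distinct scores and match the sort-and-scan oracle
  withr::with_seed(47, {
    for (i in 1:5) {
      sc <- stats::setNames(sample(1:6, 10, TRUE) * 10, paste0("g", 1:10))
      got <- per_trait_rank(sc)
      expect_equal(sort(unique(got$rank)), seq_len(length(unique(sc))))
      expect_equal(stats::setNames(got$rank, got$gene)[names(oracle_rank(sc))],
                   oracle_rank(sc))
    }
  })
})

test_that("comprehensive ranking reproduces the printed mean ranks", {
  mk <- function(gene, ranks, traits) {
    tibble::tibble(gene = gene, trait = traits, rank = ranks)
  }
  t3 <- paste0("tr", 1:3)
  t5 <- paste0("tr", 1:5)
  ranks <- dplyr::bind_rows(
    mk("Zm00001d031451", c(8, 5, 4), t3),
    mk("LOC_Os02g47280", c(2, 1, 29), t3),
    mk("LOC_Os08g39890", c(1, 1, 1), t3)
  )
  rt <- comprehensive_rank(ranks, t3)
  ssum <- stats::setNames(rt$ssum, rt$gene)
  expect_equal(round(ssum[["Zm00001d031451"]], 1), 5.7)
  expect_equal(ssum[["Zm00001d031451"]], 17 / 3)  # full precision retained
  expect_equal(round(ssum[["LOC_Os02g47280"]], 1), 10.7)
  expect_equal(rt$r_comp[rt$gene == "LOC_Os08g39890"], 1L)

  ranks5 <- dplyr::bind_rows(
    mk("AT5G53950", c(4, 7, 5, 6, 8), t5),
    mk("TraesCS5A02G275900", c(10, 4, 4, 9, 10), t5)
  )
  rt5 <- comprehensive_rank(ranks5, t5)
  expect_equal(rt5$ssum[rt5$gene == "AT5G53950"], 6.0)
  expect_equal(rt5$ssum[rt5$gene == "TraesCS5A02G275900"], 7.4)

  expect_error(comprehensive_rank(ranks[-1, ], t3), class = "kgtrait_bad_input")
})

test_that("ssum is permutation-invariant and bounded by the per-trait ranks", {
  withr::with_seed(53, {
    for (i in 1:5) {
      traits <- paste0("t", 1:4)
      genes <- paste0("g", 1:6)
      ranks <- tidyr::expand_grid(gene = genes, trait = traits)
      ranks$rank <- sample(1:6, nrow(ranks), TRUE)
      rt <- comprehensive_rank(ranks, traits)
      rt_perm <- comprehensive_rank(ranks, rev(traits))
      expect_equal(stats::setNames(rt$ssum, rt$gene),
                   stats::setNames(rt_perm$ssum, rt_perm$gene))
      for (g in genes) {
        r <- ranks$rank[ranks$gene == g]
        expect_gte(rt$ssum[rt$gene == g], min(r))
        expect_lte(rt$ssum[rt$gene == g], max(r))
        expect_equal(rt$ssum[rt$gene == g], mean(r))
      }
    }
  })
})

test_that("tied mean ranks share a dense comprehensive rank and top-k may exceed k", {
  # the published top-10 pattern: ties at 18.3 share rank 9, ties at 18.7
  # share rank 10, so ten ranks hold twelve genes
  ssums <- c(1, 5.7, 7, 9, 10.7, 12, 13.7, 18, 18.3, 18.3, 18.7, 18.7)
  genes <- sprintf("g%02d", seq_along(ssums))
  ranks <- tibble::tibble(gene = rep(genes, each = 3), trait = rep(paste0("t", 1:3), 12),
                          rank = as.vector(vapply(ssums, function(s) {
                            c(s, s, s)
                          }, numeric(3))))
  rt <- comprehensive_rank(ranks, paste0("t", 1:3))
  expect_equal(rt$r_comp[rt$ssum == 18.3], c(9L, 9L))
  expect_equal(rt$r_comp[rt$ssum == 18.7], c(10L, 10L))
  expect_equal(nrow(top_k(rt, 10)), 12)

  # ordinal policy gives distinct ranks to ties (the 6.0/6.0 -> 1, 2 pattern)
  rt_ord <- comprehensive_rank(ranks, paste0("t", 1:3), tie_policy = "ordinal")
  expect_equal(rt_ord$r_comp, 1:12)
  expect_equal(nrow(top_k(rt_ord, 10)), 10)

  expect_equal(nrow(top_k(rt, 99)), 12)
  expect_error(top_k(rt, 0), class = "kgtrait_bad_input")
})

test_that("rank_candidates restricts to genes predicted for all target traits", {
  pred <- dplyr::bind_rows(
    pred_row("g1", "salt", 900), pred_row("g1", "drought", 700),
    pred_row("g2", "salt", 800), pred_row("g2", "drought", 900),
    pred_row("g3", "salt", 950)  # missing drought: excluded
  )
  rt <- rank_candidates(pred, c("salt", "drought"))
  expect_setequal(rt$gene, c("g1", "g2"))
  expect_equal(rt$ssum[rt$gene == "g1"], mean(c(1, 2)))
  expect_equal(rt$ssum[rt$gene == "g2"], mean(c(2, 1)))
  expect_error(rank_candidates(pred, c("salt", "height")),
               class = "kgtrait_bad_input")
})
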