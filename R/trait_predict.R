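# Link prediction: an unknown gene is predicted to regulate a trait when its
# best similarity score against that trait's known genes reaches the
# calibrated threshold.

#' Predict traits for one gene
#'
#' Scores the gene against every known trait-regulating gene and aggregates
#' per trait by the maximum score (one sufficiently similar known gene
#' suffices). A gene may itself be known for some trait; its own association
#' with a trait never supports a prediction for that trait.
#'
#' @param kg A `kg` object.
#' @param gene Query gene id.
#' @param associations Known gene-trait association tibble
#'   (see [kg_load_associations()]).
#' @param provider A `sim_provider`.
#' @param config A [scoring_config()].
#' @param threshold Non-negative decision threshold; `passed` is
#'   `best_score >= threshold`.
#' @return Tibble sorted by descending `best_score`: `gene`, `trait`,
#'   `best_score`, `supporting_gene`, `threshold`, `passed` — one row per
#'   trait with at least one scorable known gene.
#' @export
predict_traits <- function(kg, gene, associations, provider,
                           config = scoring_config(), threshold) {
  if (threshold < 0) abort("threshold must be >= 0", class = "kgtrait_bad_input")
  sims <- similarity_to_known(kg, gene, associations, provider, config)
  empty <- tibble(gene = character(), trait = character(), best_score = double(),
                  supporting_gene = character(), threshold = double(),
                  passed = logical())
  if (nrow(sims) == 0) {
    warn(paste0("no scorable known genes for ", gene))
    return(empty)
  }
  # the query's own association records never support a prediction: sims
  # already excludes the self-pair, so every supporting gene is another gene
  long <- tidyr::unnest(sims, "traits") |> rename(trait = "traits")
  long <- filter(long, .data$g2 != gene)
  if (nrow(long) == 0) return(empty)
  long |>
    group_by(.data$trait) |>
    arrange(desc(.data$S), .data$g2, .by_group = TRUE) |>
    summarise(best_score = first(.data$S), supporting_gene = first(.data$g2),
              .groups = "drop") |>
    mutate(gene = gene, threshold = threshold,
           passed = .data$best_score >= threshold) |>
    select("gene", "trait", "best_score", "supporting_gene", "threshold", "passed") |>
    arrange(desc(.data$best_score), .data$trait)
}

#' Predict traits for a batch of genes
#'
#' Applies [predict_traits()] to each gene; per-gene failures (gene absent,
#' no protein, nothing scorable) are collected into a skip report instead of
#' aborting the batch.
#'
#' @inheritParams predict_traits
#' @param genes Character vector of query gene ids.
#' @return Tibble of concatenated predictions ordered by gene id then
#'   descending score, with a `skipped` attribute tibble (`gene`, `reason`).
#' @export
predict_all <- function(kg, genes, associations, provider,
                        config = scoring_config(), threshold) {
  skipped <- tibble(gene = character(), reason = character())
  rows <- purrr::map(sort(unique(genes)), function(g) {
    tryCatch(
      suppressWarnings(predict_traits(kg, g, associations, provider, config, threshold)),
      error = function(e) {
        skipped <<- bind_rows(skipped, tibble(gene = g, reason = conditionMessage(e)))
        NULL
      }
    )
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) > 0) out <- arrange(out, .data$gene, desc(.data$best_score))
  attr(out, "skipped") <- skipped
  out
}
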