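# Polyphenotype mining and prioritization. A polyphenotype gene is one
# predicted to regulate two or more traits. Candidates are ordered by the
# comprehensive rank: per-trait similarity-score ranks are averaged into
# Ssum = sum_i R(g_i) / n, and genes are sorted by ascending Ssum.

#' Mine polyphenotype genes from a prediction table
#'
#' Keeps genes whose predictions pass the threshold for at least two traits.
#'
#' @param predictions Tibble from [predict_all()] (columns `gene`, `trait`,
#'   `best_score`, `passed`).
#' @param associations Optional association tibble used to annotate status:
#'   a gene with any literature-verified trait is `"known"`, otherwise
#'   `"unknown"`.
#' @return Tibble with one row per polyphenotype gene: `gene`, `traits`
#'   (list column, sorted), `n_traits`, `scores` (list column parallel to
#'   `traits`), `status`.
#' @export
mine_polyphenotype <- function(predictions, associations = NULL) {
  pred <- filter(tibble::as_tibble(predictions), .data$passed)
  known_genes <- if (is.null(associations)) character(0) else
    unique(associations$gene_id)
  pred |>
    group_by(.data$gene) |>
    arrange(.data$trait, .by_group = TRUE) |>
    summarise(traits = list(.data$trait), n_traits = n(),
              scores = list(setNames(.data$best_score, .data$trait)),
              .groups = "drop") |>
    filter(.data$n_traits >= 2) |>
    mutate(status = ifelse(.data$gene %in% known_genes, "known", "unknown")) |>
    arrange(.data$gene)
}

#' Tabulate trait combinations of polyphenotype genes
#'
#' Each gene is counted once, under its full trait set. Rows are ordered by
#' combination size then lexicographically.
#'
#' @param records Tibble from [mine_polyphenotype()].
#' @return Tibble with columns `traits` (comma-joined, canonically sorted),
#'   `n_traits`, `n_genes`. Counts sum to `nrow(records)`.
#' @export
combination_counts <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(traits = character(), n_traits = integer(), n_genes = integer()))
  }
  records |>
    mutate(traits = map_chr(.data$traits, function(t) paste(sort(t), collapse = ", ")),
           n_traits = map_int(strsplit(.data$traits, ", ", fixed = TRUE), length)) |>
    count(.data$traits, .data$n_traits, name = "n_genes") |>
    arrange(.data$n_traits, .data$traits)
}

#' Rank genes by similarity score within one trait
#'
#' Rank 1 is the highest score. With `tie_policy = "dense"` equal scores
#' share a rank and the next distinct score takes the next integer; with
#' `"ordinal"` ties break by gene id.
#'
#' @param scores Named numeric vector (names = gene ids) or tibble with
#'   columns `gene`, `score`.
#' @param tie_policy `"dense"` (default) or `"ordinal"`.
#' @return Tibble `gene`, `score`, `rank`, ordered by rank then gene id.
#' @export
per_trait_rank <- function(scores, tie_policy = c("dense", "ordinal")) {
  tie_policy <- match.arg(tie_policy)
  if (is.numeric(scores)) {
    scores <- tibble(gene = names(scores), score = unname(scores))
  }
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) abort("no scores to rank", class = "kgtrait_bad_input")
  out <- arrange(scores, desc(.data$score), .data$gene)
  out$rank <- switch(tie_policy,
    dense = dense_rank(desc(out$score)),
    ordinal = seq_len(nrow(out))
  )
  out
}

#' Comprehensive ranking of candidate polyphenotype genes
#'
#' Averages each gene's per-trait ranks into the mean rank
#' `Ssum = sum_i R(g_i) / n` over the `n` target traits, orders genes by
#' ascending Ssum, and assigns the comprehensive rank `r_comp`. Ssum is kept
#' at full precision; round only for display (e.g. 17/3 prints as 5.7).
#'
#' @param ranks Long tibble with columns `gene`, `trait`, `rank` — every gene
#'   must carry a rank for every target trait.
#' @param traits Target trait labels; defaults to all traits present.
#' @param tie_policy `"dense"` (equal Ssum shares an `r_comp`, default) or
#'   `"ordinal"` (ties broken by gene id).
#' @param status Optional named character vector (gene -> "known"/"unknown")
#'   carried into the table.
#' @return A `rank_table` tibble: `gene`, one `rank_<trait>` column per
#'   trait, `ssum`, `r_comp`, and `status` when supplied.
#' @export
#' @examples
#' ranks <- tibble::tribble(
#'   ~gene, ~trait, ~rank,
#'   "gA", "plant_height", 8, "gA", "grain_weight", 5, "gA", "disease", 4,
#'   "gB", "plant_height", 1, "gB", "grain_weight", 1, "gB", "disease", 1
#' )
#' comprehensive_rank(ranks)  # gB ssum 1, gA ssum 17/3
comprehensive_rank <- function(ranks, traits = NULL,
                               tie_policy = c("dense", "ordinal"),
                               status = NULL) {
  tie_policy <- match.arg(tie_policy)
  ranks <- tibble::as_tibble(ranks)
  traits <- traits %||% sort(unique(ranks$trait))
  ranks <- filter(ranks, .data$trait %in% traits)
  cover <- ranks |> group_by(.data$gene) |>
    summarise(n = n_distinct(.data$trait), .groups = "drop")
  incomplete <- cover$gene[cover$n < length(traits)]
  if (length(incomplete) > 0) {
    abort(paste0("gene(s) missing a rank for some target trait: ",
                 paste(head(incomplete, 3), collapse = ", ")),
          class = "kgtrait_bad_input")
  }
  wide <- ranks |>
    mutate(trait = factor(.data$trait, levels = traits)) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "trait",
                       values_from = "rank", names_prefix = "rank_")
  ssum <- ranks |>
    group_by(.data$gene) |>
    summarise(ssum = sum(.data$rank) / length(traits), .groups = "drop")
  out <- left_join(wide, ssum, by = "gene") |>
    arrange(.data$ssum, .data$gene)
  out$r_comp <- switch(tie_policy,
    dense = dense_rank(out$ssum),
    ordinal = seq_len(nrow(out))
  )
  if (!is.null(status)) out$status <- unname(status[out$gene])
  structure(out, class = c("rank_table", class(out)),
            traits = traits, tie_policy = tie_policy)
}

#' @method tidy rank_table
#' @export
tidy.rank_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::starts_with("rank_"),
                      names_to = "trait", values_to = "rank",
                      names_prefix = "rank_")
}

#' @method glance rank_table
#' @export
glance.rank_table <- function(x, ...) {
  tibble(n_genes = nrow(x), n_traits = length(attr(x, "traits")),
         tie_policy = attr(x, "tie_policy"))
}

#' Top-k genes of a comprehensive ranking
#'
#' With the dense tie policy every gene sharing the k-th comprehensive rank
#' is included, so the list may hold more than `k` genes; with the ordinal
#' policy exactly `min(k, n)` genes return.
#'
#' @param rank_table A [comprehensive_rank()] result.
#' @param k Number of comprehensive ranks to keep (>= 1).
#' @return The qualifying rows of the rank table, in rank order.
#' @export
top_k <- function(rank_table, k) {
  if (k < 1) abort("k must be >= 1", class = "kgtrait_bad_input")
  filter(rank_table, .data$r_comp <= k)
}

#' Rank candidate genes across a set of target traits
#'
#' Convenience driver: restricts a prediction table to genes predicted
#' (passed) for all target traits, ranks per trait by best score, and
#' aggregates with [comprehensive_rank()].
#'
#' @param predictions Tibble from [predict_all()].
#' @param traits Character vector of target trait labels (n >= 2).
#' @param tie_policy Passed to [per_trait_rank()] and [comprehensive_rank()].
#' @param associations Optional association tibble for known/unknown status.
#' @return A `rank_table` (see [comprehensive_rank()]).
#' @export
rank_candidates <- function(predictions, traits,
                            tie_policy = c("dense", "ordinal"),
                            associations = NULL) {
  tie_policy <- match.arg(tie_policy)
  pred <- filter(tibble::as_tibble(predictions), .data$passed,
                 .data$trait %in% traits)
  cover <- pred |> group_by(.data$gene) |>
    summarise(n = n_distinct(.data$trait), .groups = "drop")
  candidates <- cover$gene[cover$n == length(traits)]
  if (length(candidates) == 0) {
    abort("no gene is predicted for every target trait", class = "kgtrait_bad_input")
  }
  pred <- filter(pred, .data$gene %in% candidates)
  long <- purrr::map(traits, function(tr) {
    sc <- filter(pred, .data$trait == tr)
    per_trait_rank(setNames(sc$best_score, sc$gene), tie_policy) |>
      mutate(trait = tr)
  }) |> list_rbind()
  status <- NULL
  if (!is.null(associations)) {
    known <- unique(associations$gene_id)
    status <- setNames(ifelse(candidates %in% known, "known", "unknown"), candidates)
  }
  comprehensive_rank(select(long, "gene", "trait", "rank"), traits,
                     tie_policy, status)
}
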