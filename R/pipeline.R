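# End-to-end driver: build graph -> score labeled pairs -> sweep threshold ->
# predict traits -> mine polyphenotype genes -> rank -> DEG overlap. Stages
# communicate through files so each is independently usable; a stage failure
# aborts with the stage named, keeping earlier artifacts.

#' Pipeline configuration
#'
#' @param triples Path to the triple TSV (see [kg_load_triples()]).
#' @param associations Path to the gene-trait association CSV.
#' @param sim_table Path to a protein-similarity TSV (table provider), or
#'   `NULL` with `fasta` set.
#' @param fasta Optional FASTA of protein sequences (alignment provider).
#' @param deg_tables Optional named character vector of DEG TSV paths
#'   (names = phenotype labels).
#' @param cutoff_year Training/validation cutoff year (inclusive on train).
#' @param threshold Optional fixed decision threshold; when `NULL` (default)
#'   the threshold is swept on the training slice.
#' @param genes Optional character vector of query genes; defaults to every
#'   gene in the graph without a literature association.
#' @param target_traits Optional traits for the comprehensive ranking stage.
#' @param tie_policy Rank tie policy, `"dense"` or `"ordinal"`.
#' @param top Number of comprehensive ranks to report (default 10).
#' @param negative_ratio Negatives per positive when labeling pairs.
#' @param out_dir Optional output directory for stage artifacts.
#' @param seed Integer seed (negative-pair sampling).
#' @param config A [scoring_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(triples, associations, sim_table = NULL,
                            fasta = NULL, deg_tables = NULL,
                            cutoff_year, threshold = NULL, genes = NULL,
                            target_traits = NULL,
                            tie_policy = c("dense", "ordinal"), top = 10,
                            negative_ratio = 1, out_dir = NULL, seed = 1L,
                            config = scoring_config()) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(sim_table) && is.null(fasta)) {
    abort("need sim_table or fasta for the similarity provider",
          class = "kgtrait_bad_input")
  }
  if (!is.null(threshold) && threshold < 0) {
    abort("threshold override must be >= 0", class = "kgtrait_bad_input")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments (`deg_tables` as a name: path map).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$deg_tables)) y$deg_tables <- unlist(y$deg_tables)
  if (!is.null(y$config)) y$config <- do.call(scoring_config, y$config)
  do.call(pipeline_config, y)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "kgtrait_pipeline", parent = e)
  })
}

#' Run the full prediction and mining pipeline
#'
#' Stages, in order: load graph and associations; build the similarity
#' provider; score and label gene-gene pairs; time-slice at `cutoff_year`;
#' sweep the F1-maximizing threshold on the training slice (unless a fixed
#' `threshold` is supplied, in which case the sweep is skipped and the
#' override recorded); evaluate on the validation slice; predict traits for
#' the query genes; mine polyphenotype genes and tabulate trait
#' combinations; comprehensively rank candidates for the target traits; and
#' compute the DEG-overlap report when DEG tables are given. Identical
#' config and seed give identical output.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_report` list: `threshold`, `threshold_source`,
#'   `sweep`, `validation_metrics`, `predictions`, `polyphenotype`,
#'   `combinations`, `rank_table`, `top`, `overlap`, and `artifacts` (paths
#'   written, when `out_dir` is set).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  art <- character(0)
  save_tsv <- function(df, name) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(cfg$out_dir, name)
      readr::write_tsv(df, p, progress = FALSE)
      art[[name]] <<- p
    }
  }

  kg <- pipeline_stage("load_graph", kg_load_triples(cfg$triples))
  assoc <- pipeline_stage("load_associations", kg_load_associations(cfg$associations))
  provider <- pipeline_stage("provider", {
    if (!is.null(cfg$sim_table)) table_provider(cfg$sim_table)
    else alignment_provider(read_fasta(cfg$fasta))
  })

  pairs <- pipeline_stage("label_pairs", labeled_pairs_from_associations(
    kg, assoc, provider, cfg$config, cfg$negative_ratio, cfg$seed))
  save_tsv(pairs, "labeled_pairs.tsv")
  split <- pipeline_stage("time_slice", time_slice_split(pairs, cfg$cutoff_year))

  sweep <- NULL
  if (is.null(cfg$threshold)) {
    sweep <- pipeline_stage("sweep", sweep_threshold(split$train))
    threshold <- sweep$threshold
    threshold_source <- "swept"
    save_tsv(sweep$curve, "sweep_curve.tsv")
  } else {
    threshold <- cfg$threshold
    threshold_source <- "override"
    inform(sprintf("threshold override %.4g: sweep skipped", threshold))
  }

  validation_metrics <- NULL
  if (nrow(split$validation) > 0) {
    validation_metrics <- pipeline_stage("evaluate",
      eval_metrics(classify_pairs(split$validation, threshold)))
  }

  genes <- cfg$genes %||% sort(setdiff(
    kg$entities$id[kg$entities$category == "gene"], unique(assoc$gene_id)))
  predictions <- pipeline_stage("predict", predict_all(
    kg, genes, assoc, provider, cfg$config, threshold))
  save_tsv(predictions, "predictions.tsv")

  poly <- pipeline_stage("mine", mine_polyphenotype(predictions, assoc))
  combos <- pipeline_stage("combinations", combination_counts(poly))
  save_tsv(combos, "trait_combinations.tsv")

  rank_table <- NULL
  top_table <- NULL
  if (!is.null(cfg$target_traits)) {
    rank_table <- pipeline_stage("rank", rank_candidates(
      predictions, cfg$target_traits, cfg$tie_policy, assoc))
    top_table <- top_k(rank_table, cfg$top)
    save_tsv(as_tibble(top_table), "top_genes.tsv")
  }

  overlap <- NULL
  if (!is.null(cfg$deg_tables)) {
    if (nrow(poly) == 0) {
      inform("no polyphenotype genes: DEG overlap stage skipped")
    } else {
      overlap <- pipeline_stage("venn", {
        sets <- purrr::imap(as.list(cfg$deg_tables), function(p, nm) {
          load_deg_table(p, phenotype = nm)
        })
        overlap_report(poly$gene, sets)
      })
    }
  } else {
    inform("no DEG tables given: DEG overlap stage skipped")
  }

  report <- structure(
    list(threshold = threshold, threshold_source = threshold_source,
         sweep = sweep, validation_metrics = validation_metrics,
         predictions = predictions, polyphenotype = poly,
         combinations = combos, rank_table = rank_table, top = top_table,
         overlap = overlap, artifacts = art),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) {
    p <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(pipeline_report_json(report), p, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    report$artifacts[["report.json"]] <- p
  }
  report
}

pipeline_report_json <- function(r) {
  list(
    threshold = r$threshold,
    threshold_source = r$threshold_source,
    best_f1 = if (!is.null(r$sweep)) r$sweep$best_f1 else NULL,
    validation_metrics = if (!is.null(r$validation_metrics))
      as.list(r$validation_metrics) else NULL,
    n_predictions = nrow(r$predictions),
    n_polyphenotype = nrow(r$polyphenotype),
    n_trait_combinations = nrow(r$combinations),
    verified_fraction = if (!is.null(r$overlap)) r$overlap$verified_fraction else NULL
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> threshold %.4g (%s)\n", x$threshold,
              x$threshold_source))
  if (!is.null(x$validation_metrics)) {
    m <- x$validation_metrics
    cat(sprintf("  validation: accuracy %.2f  precision %.2f  recall %.2f  F1 %.2f\n",
                m$accuracy, m$precision, m$recall, m$f1))
  }
  cat(sprintf("  %d predictions, %d polyphenotype genes, %d trait combinations\n",
              nrow(x$predictions), nrow(x$polyphenotype), nrow(x$combinations)))
  if (!is.null(x$overlap)) {
    cat(sprintf("  DEG-verified: %.0f%%\n", 100 * x$overlap$verified_fraction))
  }
  invisible(x)
}

#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    threshold = x$threshold, threshold_source = x$threshold_source,
    best_f1 = if (!is.null(x$sweep)) x$sweep$best_f1 else NA_real_,
    validation_f1 = if (!is.null(x$validation_metrics)) x$validation_metrics$f1 else NA_real_,
    n_polyphenotype = nrow(x$polyphenotype),
    verified_fraction = if (!is.null(x$overlap)) x$overlap$verified_fraction else NA_real_
  )
}
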