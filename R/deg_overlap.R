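# Validation of mined polyphenotype genes against transcriptome DEG sets:
# each gene falls in exactly one Venn region (the subset of DEG sets that
# contain it, or none), and the verification fraction is the share of genes
# found in at least one DEG set.

#' Load a differentially-expressed-gene set from a TSV table
#'
#' Keeps genes with `|log_fc| >= lfc_threshold` (inclusive; the conventional
#' log2 fold-change filter at 1). Duplicate gene ids collapse.
#'
#' @param path TSV with columns `gene_id` and `log_fc` (extra columns are
#'   ignored).
#' @param phenotype Label for the set (defaults to the file name).
#' @param lfc_threshold Absolute log fold-change cutoff, default 1.
#' @param species Optional species label.
#' @return A `deg_set`: list with `phenotype`, `species`, `genes` (character
#'   vector) and `provenance`.
#' @export
load_deg_table <- function(path, phenotype = NULL, lfc_threshold = 1,
                           species = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("DEG table not found: ", path), class = "kgtrait_io")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE)
  if (!all(c("gene_id", "log_fc") %in% names(df))) {
    abort("DEG table needs columns gene_id, log_fc", class = "kgtrait_io")
  }
  lfc <- suppressWarnings(as.numeric(df$log_fc))
  if (any(is.na(lfc) & !is.na(df$log_fc))) {
    abort("non-numeric log_fc value", class = "kgtrait_io")
  }
  deg_set(unique(df$gene_id[!is.na(lfc) & abs(lfc) >= lfc_threshold]),
          phenotype = phenotype %||% basename(path), species = species,
          provenance = path)
}

#' @rdname load_deg_table
#' @param genes Character vector of gene ids.
#' @param provenance Free-text provenance.
#' @export
deg_set <- function(genes, phenotype, species = NA_character_,
                    provenance = NA_character_) {
  genes <- unique(as.character(genes))
  if (any(!nzchar(genes))) abort("empty gene id", class = "kgtrait_bad_input")
  structure(list(phenotype = phenotype, species = species, genes = genes,
                 provenance = provenance),
            class = "deg_set")
}

#' Venn-region accounting of polyphenotype genes against DEG sets
#'
#' Assigns each polyphenotype gene to the exact subset of DEG sets containing
#' it. The verification fraction is `(total - in_none) / total`: the share of
#' mined genes independently observed as differentially expressed under at
#' least one matched stress.
#'
#' @param poly_genes Character vector of polyphenotype gene ids (or a tibble
#'   from [mine_polyphenotype()], whose `gene` column is used).
#' @param deg_sets List of [deg_set()] objects (or named list of character
#'   vectors).
#' @return An `overlap_report`: list with `total_poly`, `regions` (tibble
#'   `region`, `sets`, `count`), `in_none`, `verified_fraction`. Region
#'   counts plus `in_none` always sum to `total_poly`.
#' @export
overlap_report <- function(poly_genes, deg_sets) {
  if (is.data.frame(poly_genes)) poly_genes <- poly_genes$gene
  poly_genes <- unique(as.character(poly_genes))
  if (length(poly_genes) == 0) {
    abort("no polyphenotype genes: fraction undefined", class = "kgtrait_bad_input")
  }
  if (length(deg_sets) == 0) abort("need at least one DEG set", class = "kgtrait_bad_input")
  sets <- purrr::imap(deg_sets, function(s, nm) {
    if (inherits(s, "deg_set")) s
    else deg_set(s, phenotype = if (is.character(nm) && nzchar(nm)) nm else paste0("set", nm))
  })
  labels <- map_chr(sets, "phenotype")
  if (anyDuplicated(labels)) {
    abort("duplicate DEG set phenotype labels", class = "kgtrait_bad_input")
  }
  membership <- vapply(sets, function(s) poly_genes %in% s$genes,
                       logical(length(poly_genes)))
  membership <- matrix(membership, nrow = length(poly_genes),
                       dimnames = list(poly_genes, labels))
  region_of <- unname(apply(membership, 1, function(row) {
    paste(sort(labels[row]), collapse = " & ")
  }))
  in_none <- sum(region_of == "")
  reg <- tibble(region = region_of[region_of != ""]) |>
    count(.data$region, name = "count") |>
    mutate(n_sets = map_int(strsplit(.data$region, " & ", fixed = TRUE), length)) |>
    arrange(.data$n_sets, .data$region) |>
    select("region", "n_sets", "count")
  structure(
    list(total_poly = length(poly_genes), regions = reg, in_none = in_none,
         verified_fraction = (length(poly_genes) - in_none) / length(poly_genes),
         set_labels = labels, membership = membership),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d polyphenotype genes vs %d DEG set(s)\n",
              x$total_poly, length(x$set_labels)))
  if (nrow(x$regions) > 0) {
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("  %-40s %d\n", x$regions$region[i], x$regions$count[i]))
    }
  }
  cat(sprintf("  %-40s %d\n", "(in no DEG set)", x$in_none))
  cat(sprintf("  verified: %d/%d = %.0f%%\n", x$total_poly - x$in_none,
              x$total_poly, 100 * x$verified_fraction))
  invisible(x)
}

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  bind_rows(x$regions,
            tibble(region = "(none)", n_sets = 0L, count = x$in_none))
}

#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(total_poly = x$total_poly, verified = x$total_poly - x$in_none,
         in_none = x$in_none, verified_fraction = x$verified_fraction,
         verified_percent = round(100 * x$verified_fraction))
}

#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$region, .data$n_sets),
                                   y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.3, size = 3) +
    ggplot2::labs(x = "DEG-set region", y = "polyphenotype genes",
                  title = sprintf("%.0f%% of %d polyphenotype genes verified by DEGs",
                                  100 * object$verified_fraction, object$total_poly)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
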