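# Time-sliced calibration of the decision threshold on the similarity score,
# and the four standard evaluation metrics. A pair is predicted positive when
# its score is greater than or equal to the threshold.

normalize_labels <- function(label) {
  if (is.logical(label)) return(label)
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) {
      abort("numeric labels must be 0/1", class = "kgtrait_bad_input")
    }
    return(label == 1)
  }
  lab <- tolower(as.character(label))
  if (!all(lab %in% c("positive", "negative", "pos", "neg", "1", "0"))) {
    abort("labels must be positive/negative (or 1/0)", class = "kgtrait_bad_input")
  }
  lab %in% c("positive", "pos", "1")
}

#' Split labeled gene pairs by discovery year
#'
#' Pairs with `year <= cutoff_year` form the training set, later pairs the
#' validation set, so validation associations strictly post-date all training
#' associations (time slicing).
#'
#' @param pairs Tibble with at least columns `score`, `label`, `year`.
#' @param cutoff_year Integer year, inclusive on the training side.
#' @return List with tibbles `train` and `validation`.
#' @export
time_slice_split <- function(pairs, cutoff_year) {
  pairs <- tibble::as_tibble(pairs)
  if (!"year" %in% names(pairs) || any(is.na(pairs$year))) {
    abort("every pair needs a non-missing year", class = "kgtrait_bad_input")
  }
  list(
    train = filter(pairs, .data$year <= cutoff_year),
    validation = filter(pairs, .data$year > cutoff_year)
  )
}

#' Classify labeled pairs at a threshold
#'
#' Predicted positive iff `score >= threshold` (a score exactly equal to the
#' threshold is positive).
#'
#' @param pairs Tibble with columns `score` and `label` (positive/negative,
#'   1/0, or logical).
#' @param threshold Non-negative decision threshold.
#' @return One-row tibble of confusion counts: `tp`, `tn`, `fp`, `fn`.
#' @export
classify_pairs <- function(pairs, threshold) {
  if (threshold < 0) abort("threshold must be >= 0", class = "kgtrait_bad_input")
  pairs <- tibble::as_tibble(pairs)
  truth <- normalize_labels(pairs$label)
  pred <- pairs$score >= threshold
  tibble(
    tp = sum(pred & truth), tn = sum(!pred & !truth),
    fp = sum(pred & !truth), fn = sum(!pred & truth)
  )
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2 P R / (P + R). A metric whose denominator is
#' zero is reported as 0 and flagged in the `undefined` attribute. F1 is
#' always computed from unrounded counts.
#'
#' @param counts One-row tibble (or list) with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble `accuracy`, `precision`, `recall`, `f1`.
#' @export
eval_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("empty confusion counts", class = "kgtrait_bad_input")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  out <- tibble(accuracy = (tp + tn) / total, precision = precision,
                recall = recall, f1 = f1)
  attr(out, "undefined") <- undefined
  out
}

#' F1-maximizing threshold sweep
#'
#' Evaluates F1 at every distinct observed score (F1 is piecewise constant
#' between observed scores, so this grid is exact) and returns the score with
#' maximal F1; ties break toward the smallest threshold, which maximizes
#' recall at equal F1.
#'
#' @param train_pairs Tibble with columns `score` and `label`; must contain at
#'   least one positive pair.
#' @return A `threshold_sweep` object: list with `threshold`, `best_f1`, and
#'   the full `curve` tibble (`threshold`, `f1`) for plotting.
#' @export
sweep_threshold <- function(train_pairs) {
  pairs <- tibble::as_tibble(train_pairs)
  truth <- normalize_labels(pairs$label)
  if (!any(truth)) {
    abort("no positive pairs: F1 undefined everywhere", class = "kgtrait_bad_input")
  }
  cand <- sort(unique(pairs$score))
  f1 <- map_dbl(cand, function(th) eval_metrics(classify_pairs(pairs, th))$f1)
  best <- which.max(f1)  # which.max takes the first (smallest) maximizer
  structure(
    list(threshold = cand[best], best_f1 = f1[best],
         curve = tibble(threshold = cand, f1 = f1)),
    class = "threshold_sweep"
  )
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> threshold = %.4g (F1 = %.4f) over %d candidates\n",
              x$threshold, x$best_f1, nrow(x$curve)))
  invisible(x)
}

#' @method tidy threshold_sweep
#' @export
tidy.threshold_sweep <- function(x, ...) x$curve

#' @method glance threshold_sweep
#' @export
glance.threshold_sweep <- function(x, ...) {
  tibble(threshold = x$threshold, best_f1 = x$best_f1,
         n_candidates = nrow(x$curve))
}

#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$threshold, y = .data$f1)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "similarity score threshold", y = "F1",
                  title = sprintf("F1-maximizing threshold = %.4g", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Build labeled gene-gene pairs from association records
#'
#' Positive pairs are pairs of known genes documented to regulate a common
#' trait; negatives are sampled uniformly (with a fixed seed) from gene pairs
#' sharing no trait. The pair's year is the later of the two genes' first
#' publication years (the pair is only knowable once both genes are), and
#' each pair is scored with [gene_similarity()].
#'
#' @param kg A `kg` object.
#' @param associations Tibble from [kg_load_associations()].
#' @param provider A `sim_provider`.
#' @param config A [scoring_config()].
#' @param negative_ratio Negatives sampled per positive (default 1).
#' @param seed Integer seed for negative sampling.
#' @return Tibble `g1`, `g2`, `score`, `label`, `year`; unscorable pairs are
#'   dropped and tallied in the `skipped` attribute.
#' @export
labeled_pairs_from_associations <- function(kg, associations, provider,
                                            config = scoring_config(),
                                            negative_ratio = 1, seed = 1L) {
  assoc <- tibble::as_tibble(associations)
  per_gene <- assoc |>
    group_by(.data$gene_id) |>
    summarise(traits = list(sort(unique(.data$trait))),
              year = min(.data$year), .groups = "drop") |>
    arrange(.data$gene_id)
  if (nrow(per_gene) < 2) {
    abort("need at least two associated genes", class = "kgtrait_bad_input")
  }
  pairs <- t(combn(per_gene$gene_id, 2))
  traits_of <- setNames(per_gene$traits, per_gene$gene_id)
  year_of <- setNames(per_gene$year, per_gene$gene_id)
  shared <- map_int(seq_len(nrow(pairs)), function(i) {
    length(intersect(traits_of[[pairs[i, 1]]], traits_of[[pairs[i, 2]]]))
  })
  pos_idx <- which(shared > 0)
  neg_pool <- which(shared == 0)
  n_neg <- min(length(neg_pool), ceiling(negative_ratio * length(pos_idx)))
  neg_idx <- withr::with_seed(seed, sort(sample(neg_pool, n_neg)))
  take <- c(pos_idx, neg_idx)
  skipped <- character(0)
  rows <- purrr::map(take, function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    s <- tryCatch(gene_similarity(kg, g1, g2, provider, config)$S,
                  kgtrait_unknown_pair = function(e) NA_real_,
                  kgtrait_no_protein = function(e) NA_real_)
    if (is.na(s)) { skipped <<- c(skipped, paste(g1, g2)); return(NULL) }
    tibble(g1 = g1, g2 = g2, score = s,
           label = if (i %in% pos_idx) "positive" else "negative",
           year = max(year_of[[g1]], year_of[[g2]]))
  })
  out <- list_rbind(purrr::compact(rows))
  attr(out, "skipped") <- skipped
  out
}
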