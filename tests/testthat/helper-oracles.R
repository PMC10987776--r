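# Independent oracles, written against the definitions rather than the
# package internals: plain loops and matrices, no dplyr, no Biostrings.

# Optimal global alignment score with affine gaps (Gotoh three-matrix DP).
# A gap of length L costs gap_open + gap_extend * L, matching the package's
# alignment parameter convention.
oracle_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  o <- gap_open + gap_extend  # cost of the first gap position
  e <- gap_extend
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a residue vs gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(o + (i - 2) * e)
  for (j in 2:(m + 1)) Y[1, j] <- -(o + (j - 2) * e)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - o, X[i - 1, j] - e, Y[i - 1, j] - o)
      Y[i, j] <- max(M[i, j - 1] - o, Y[i, j - 1] - e, X[i, j - 1] - o)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force coincident-entity count C and category count D for a gene pair:
# explicit row scans over the triple table, base R only.
oracle_CD <- function(kg, g1, g2, excluded = "trait", protein_hop = TRUE) {
  tr <- as.data.frame(kg$triples)
  ent <- as.data.frame(kg$entities)
  adj <- function(id) {
    out <- character(0)
    for (r in seq_len(nrow(tr))) {
      if (tr$head[r] == id) out <- c(out, tr$tail[r])
      if (tr$tail[r] == id) out <- c(out, tr$head[r])
    }
    unique(out)
  }
  hood <- function(g) {
    nb <- adj(g)
    if (protein_hop) {
      for (x in nb) {
        cat_x <- ent$category[ent$id == x]
        linked <- FALSE
        for (r in seq_len(nrow(tr))) {
          if (tr$relation[r] == "corresponding_to" &&
              ((tr$head[r] == g && tr$tail[r] == x) ||
               (tr$head[r] == x && tr$tail[r] == g))) linked <- TRUE
        }
        if (cat_x == "protein" && linked) nb <- c(nb, adj(x))
      }
    }
    nb <- unique(nb)
    nb <- nb[nb != g]
    keep <- logical(length(nb))
    for (i in seq_along(nb)) {
      keep[i] <- !(ent$category[ent$id == nb[i]] %in% excluded)
    }
    nb[keep]
  }
  k <- intersect(hood(g1), hood(g2))
  cats <- unique(vapply(k, function(x) ent$category[ent$id == x], character(1)))
  list(C = length(k), D = length(cats), k = sort(k))
}

# Brute-force F1 evaluated at a threshold with explicit loops.
oracle_f1_at <- function(scores, positive, threshold) {
  tp <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && positive[i]) tp <- tp + 1
    if (pred && !positive[i]) fp <- fp + 1
    if (!pred && positive[i]) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

oracle_best_threshold <- function(scores, positive) {
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(th) oracle_f1_at(scores, positive, th), numeric(1))
  list(threshold = cand[which.max(f1)], best_f1 = max(f1),
       curve = data.frame(threshold = cand, f1 = f1))
}

# Dense and ordinal ranking by independent sort-and-scan.
oracle_rank <- function(scores) {
  ord <- order(-scores, names(scores))
  sorted <- scores[ord]
  rk <- integer(length(sorted))
  rk[1] <- 1
  if (length(sorted) > 1) {
    for (i in 2:length(sorted)) {
      rk[i] <- if (sorted[i] == sorted[i - 1]) rk[i - 1] else rk[i - 1] + 1
    }
  }
  stats::setNames(rk, names(sorted))
}
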