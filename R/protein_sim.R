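# Protein-protein similarity term Sp of the gene-pair score.
# Two interchangeable providers: global-alignment percent identity computed
# from sequences, or a user-supplied pairwise score table (0-100 scale) so
# externally computed homology scores can be injected verbatim.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_EXTENDED <- c(AA_STANDARD, "X", "B", "Z", "U")

#' Read protein sequences from a FASTA file
#'
#' Record ids are the token before the first whitespace in each header.
#' Residues are uppercased on load. In strict mode any residue outside the 20
#' standard amino acids plus X/B/Z/U is an error.
#'
#' @param path FASTA file path.
#' @param strict Reject non-standard residues (default `TRUE`).
#' @return Tibble with columns `id`, `residues`, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "kgtrait_io")
  }
  # Biostrings drops residues outside its amino-acid alphabet with a warning;
  # in strict mode that is a hard error, otherwise a silent normalization
  aas <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        if (strict) {
          abort("illegal residue code in FASTA input", class = "kgtrait_io")
        }
        invokeRestart("muffleWarning")
      }
    }
  )
  if (length(aas) == 0) {
    abort("empty FASTA file", class = "kgtrait_io")
  }
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]),
          class = "kgtrait_io")
  }
  res <- toupper(as.character(aas))
  if (strict) {
    ok <- vapply(strsplit(res, ""), function(ch) all(ch %in% AA_EXTENDED), logical(1))
    if (!all(ok)) {
      abort(paste0("illegal residue in sequence: ", ids[!ok][1]),
            class = "kgtrait_io")
    }
  }
  if (any(nchar(res) == 0)) {
    abort("empty sequence record", class = "kgtrait_io")
  }
  tibble(id = ids, residues = unname(res))
}

#' Percent identity of a global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with an affine gap penalty (gap of length
#' L costs `gap_open + gap_extend * L`), scored under a standard substitution
#' matrix. Identity is the number of identical aligned residue pairs divided
#' by the denominator, times 100.
#'
#' @param a,b Amino-acid strings (one-letter codes), both non-empty.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10 and 0.5).
#' @param denominator `"alignment"` (full alignment length including gap
#'   columns, the default) or `"shortest"` (length of the shorter sequence).
#' @return Percent identity in \\[0, 100\\].
#' @export
#' @examples
#' align_percent_identity("MKV", "MKV")  # 100
align_percent_identity <- function(a, b, matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 0.5,
                                   denominator = c("alignment", "shortest")) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", class = "kgtrait_bad_input")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_ident <- sum(pa == pb & pa != "-")
  denom <- switch(denominator,
    alignment = length(pa),
    shortest = min(nchar(a), nchar(b))
  )
  100 * n_ident / denom
}

#' Similarity providers
#'
#' A provider maps an unordered protein-id pair to a non-negative similarity
#' score. `table_provider()` wraps a precomputed score table (TSV columns
#' `protein_a`, `protein_b`, `score`, 0-100 scale); `alignment_provider()`
#' aligns sequences on demand via [align_percent_identity()]. Both are
#' symmetric: `protein_similarity(pr, a, b) == protein_similarity(pr, b, a)`.
#'
#' @param table A data frame with columns `protein_a`, `protein_b`, `score`,
#'   or a path to such a TSV file.
#' @return A `sim_provider` object.
#' @export
table_provider <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- readr::read_tsv(table, col_types = readr::cols(
      protein_a = readr::col_character(), protein_b = readr::col_character(),
      score = readr::col_double()
    ), progress = FALSE)
  }
  tb <- tibble::as_tibble(table)
  if (!all(c("protein_a", "protein_b", "score") %in% names(tb))) {
    abort("similarity table needs columns protein_a, protein_b, score",
          class = "kgtrait_bad_input")
  }
  if (any(tb$score < 0)) {
    abort("similarity scores must be non-negative", class = "kgtrait_bad_input")
  }
  keys <- pair_key(tb$protein_a, tb$protein_b)
  scores <- setNames(tb$score, keys)
  structure(list(kind = "table", scores = scores), class = "sim_provider")
}

#' @rdname table_provider
#' @param sequences Tibble from [read_fasta()] (columns `id`, `residues`).
#' @inheritParams align_percent_identity
#' @export
alignment_provider <- function(sequences, matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 0.5,
                               denominator = "alignment") {
  seqs <- tibble::as_tibble(sequences)
  if (!all(c("id", "residues") %in% names(seqs))) {
    abort("sequences need columns id, residues", class = "kgtrait_bad_input")
  }
  structure(
    list(kind = "alignment", residues = setNames(seqs$residues, seqs$id),
         matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         denominator = denominator),
    class = "sim_provider"
  )
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Query a similarity provider for one protein pair
#'
#' @param provider A `sim_provider`.
#' @param p1,p2 Protein ids.
#' @return The similarity score. A pair the provider cannot score raises an
#'   error of class `kgtrait_unknown_pair`, so callers can skip the gene pair
#'   rather than treat it as zero.
#' @export
protein_similarity <- function(provider, p1, p2) {
  stopifnot(inherits(provider, "sim_provider"))
  if (provider$kind == "table") {
    key <- pair_key(p1, p2)
    if (!key %in% names(provider$scores)) {
      abort(paste0("no similarity entry for pair (", p1, ", ", p2, ")"),
            class = "kgtrait_unknown_pair")
    }
    unname(provider$scores[[key]])
  } else {
    res <- provider$residues
    if (!p1 %in% names(res) || !p2 %in% names(res)) {
      missing_id <- if (p1 %in% names(res)) p2 else p1
      abort(paste0("no sequence for protein ", missing_id),
            class = "kgtrait_unknown_pair")
    }
    # align in canonical id order so the score is exactly symmetric
    ord <- order(c(p1, p2))
    pair <- c(p1, p2)[ord]
    align_percent_identity(res[[pair[1]]], res[[pair[2]]],
                           matrix = provider$matrix,
                           gap_open = provider$gap_open,
                           gap_extend = provider$gap_extend,
                           denominator = provider$denominator)
  }
}

#' Compute an all-against-all similarity table from sequences
#'
#' @inheritParams alignment_provider
#' @return Tibble `protein_a`, `protein_b`, `score` for every unordered pair.
#' @export
pairwise_similarity_table <- function(sequences, matrix = "BLOSUM62",
                                      gap_open = 10, gap_extend = 0.5,
                                      denominator = "alignment") {
  pr <- alignment_provider(sequences, matrix, gap_open, gap_extend, denominator)
  ids <- sort(sequences$id)
  if (length(ids) < 2) return(tibble(protein_a = character(), protein_b = character(),
                                     score = double()))
  pairs <- t(combn(ids, 2))
  tibble(
    protein_a = pairs[, 1], protein_b = pairs[, 2],
    score = map_dbl(seq_len(nrow(pairs)),
                    function(i) protein_similarity(pr, pairs[i, 1], pairs[i, 2]))
  )
}
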