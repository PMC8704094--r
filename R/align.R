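#' Alignment parameters
#'
#' Scoring scheme for global pairwise alignment. A gap of length k costs
#' `gap_open + k * gap_extend`. Near-identical barcode pairs — the regime the
#' analyses live in — are insensitive to these values; they are nevertheless
#' echoed in every report for reproducibility.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -2,
                             gap_extend = -0.5) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global pairwise alignment of two sequence records
#'
#' Needleman-Wunsch global alignment with affine gaps (via Biostrings), used
#' when distances are computed in pairwise mode. `N` scores 0 against
#' everything. Traceback is deterministic, so identical inputs always give
#' the identical alignment.
#'
#' @param a,b Sequence records: one-row sequence tibbles, or plain strings.
#' @param params An [alignment_params()] scheme.
#' @return An `aligned_pair`: list with `idA`, `idB`, `rowA`, `rowB`
#'   (equal-length gapped strings), `score` and `params`.
#' @export
align_pair <- function(a, b, params = alignment_params()) {
  a <- as_seq_record(a, "seqA")
  b <- as_seq_record(b, "seqB")
  if (nchar(a$residues) == 0L || nchar(b$residues) == 0L) {
    abort("cannot align an empty sequence")
  }
  mat <- substitution_matrix(params)
  pa <- Biostrings::pairwiseAlignment(a$residues, b$residues, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = abs(params$gap_open),
                                      gapExtension = abs(params$gap_extend))
  structure(list(idA = a$id, idB = b$id,
                 rowA = as.character(Biostrings::alignedPattern(pa)),
                 rowB = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa), params = params),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair>", x$idA, "vs", x$idB,
      sprintf("(length %d, score %.2f)\n", nchar(x$rowA), x$score))
  invisible(x)
}

substitution_matrix <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(params$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- params$match
  mat["N", ] <- 0
  mat[, "N"] <- 0
  mat
}

as_seq_record <- function(x, default_id) {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = default_id, residues = toupper(chartr("U", "T", x))))
  }
  if (is.data.frame(x) && nrow(x) == 1L && all(c("id", "residues") %in% names(x))) {
    return(list(id = x$id, residues = x$residues))
  }
  abort("expected a single sequence string or a one-row sequence tibble")
}

as_aligned_rows <- function(pair, rowB) {
  if (inherits(pair, "aligned_pair")) {
    rows <- list(rowA = pair$rowA, rowB = pair$rowB)
  } else if (is.character(pair) && !is.null(rowB)) {
    rows <- list(rowA = pair, rowB = rowB)
  } else {
    abort("expected an aligned_pair or two aligned strings")
  }
  if (nchar(rows$rowA) != nchar(rows$rowB)) {
    abort("aligned rows must have equal length")
  }
  rows
}

#' Count substitutions between two aligned rows
#'
#' Tallies the K2P ingredients over an aligned pair: `L` compared sites (both
#' residues in A/C/G/T; columns with a gap or `N` on either row are excluded —
#' pairwise deletion), `s` transitions (A<->G, C<->T), `v` transversions, and
#' the proportions `P = s/L`, `Q = v/L`.
#'
#' @param pair An [align_pair()] result, or the first aligned row as a string.
#' @param rowB Second aligned row when `pair` is a string.
#' @return A one-row tibble with columns `L`, `s`, `v`, `P`, `Q`.
#' @export
substitution_counts <- function(pair, rowB = NULL) {
  rows <- as_aligned_rows(pair, rowB)
  a <- strsplit(rows$rowA, "", fixed = TRUE)[[1]]
  b <- strsplit(rows$rowB, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  L <- sum(use)
  diff <- use & a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                  (a == "C" & b == "T") | (a == "T" & b == "C"))
  s <- sum(ts)
  v <- sum(diff) - s
  tibble(L = L, s = s, v = v,
         P = if (L > 0) s / L else NA_real_,
         Q = if (L > 0) v / L else NA_real_)
}

#' Percent identity of an aligned pair
#'
#' @param pair An [align_pair()] result, or the first aligned row as a string.
#' @param rowB Second aligned row when `pair` is a string.
#' @param mode Denominator: `"compared_sites"` (default; columns with both
#'   residues in A/C/G/T) or `"shorter_seq"` (ungapped length of the shorter
#'   sequence).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(pair, rowB = NULL,
                             mode = c("compared_sites", "shorter_seq")) {
  mode <- match.arg(mode)
  rows <- as_aligned_rows(pair, rowB)
  a <- strsplit(rows$rowA, "", fixed = TRUE)[[1]]
  b <- strsplit(rows$rowB, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  matches <- sum(use & a == b)
  denom <- switch(mode,
                  compared_sites = sum(use),
                  shorter_seq = min(sum(a != "-"), sum(b != "-")))
  if (denom == 0L) abort("zero denominator: no comparable sites")
  100 * matches / denom
}
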