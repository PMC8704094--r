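#' All-vs-all pairwise distances for a sequence set
#'
#' Computes every off-diagonal pairwise distance in a sequence tibble. In
#' `"pairwise"` mode each pair is globally aligned on its own ([align_pair()]);
#' in `"msa"` mode the residues are taken as rows of a shared multiple
#' alignment (equal lengths required) and no alignment is performed. Gap and
#' `N` columns are dropped per pair (pairwise deletion) or, with
#' `deletion = "complete"` in MSA mode, once across the whole set.
#'
#' @param seqs Sequence tibble (`id`, `residues`, optionally `species`).
#' @param method Distance: `"k2p"` (default), `"p"`, or `"identity"`
#'   (1 - fraction identical).
#' @param mode `"pairwise"` or `"msa"`.
#' @param deletion `"pairwise"` (default) or `"complete"` (MSA mode only).
#' @param params [alignment_params()] for pairwise mode.
#' @return A long tibble with one row per unordered pair: `idA`, `idB`, `L`,
#'   `s`, `v`, `distance` (fraction; `NA` when undefined). Undefined entries
#'   are kept, never dropped.
#' @seealso [distance_matrix()] for the square form.
#' @export
pairwise_distances <- function(seqs, method = c("k2p", "p", "identity"),
                               mode = c("pairwise", "msa"),
                               deletion = c("pairwise", "complete"),
                               params = alignment_params()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  deletion <- match.arg(deletion)
  check_seq_tbl(seqs)
  n <- nrow(seqs)
  if (n < 2L) abort("need at least two sequences")
  residues <- seqs$residues
  if (mode == "msa") {
    if (length(unique(nchar(residues))) != 1L) {
      abort("msa mode requires equal-length aligned rows")
    }
    if (deletion == "complete") {
      m <- do.call(rbind, strsplit(residues, "", fixed = TRUE))
      keep <- colSums(m == "-" | m == "N") == 0L
      residues <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    }
  } else if (deletion == "complete") {
    abort("complete deletion is only defined for msa mode")
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- purrr::map(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (mode == "msa") {
      cnt <- substitution_counts(residues[i], residues[j])
    } else {
      pa <- align_pair(seqs[i, ], seqs[j, ], params = params)
      cnt <- substitution_counts(pa)
    }
    d <- switch(method,
                k2p = k2p_distance(cnt),
                p = p_distance(cnt),
                identity = if (cnt$L > 0) 1 - (cnt$L - cnt$s - cnt$v) / cnt$L else NA_real_)
    tibble(idA = seqs$id[i], idB = seqs$id[j],
           L = cnt$L, s = cnt$s, v = cnt$v, distance = d)
  })
  out <- bind_rows(rows)
  attr(out, "method") <- method
  attr(out, "mode") <- mode
  attr(out, "deletion") <- deletion
  out
}

#' Square distance matrix
#'
#' Symmetric matrix form of [pairwise_distances()]: zero diagonal, `NA` for
#' undefined (saturated) entries.
#'
#' @inheritParams pairwise_distances
#' @return A symmetric numeric matrix with id dimnames and attribute
#'   `method`.
#' @export
distance_matrix <- function(seqs, method = c("k2p", "p", "identity"),
                            mode = c("pairwise", "msa"),
                            deletion = c("pairwise", "complete"),
                            params = alignment_params()) {
  tbl <- pairwise_distances(seqs, method = method, mode = mode,
                            deletion = deletion, params = params)
  dist_to_matrix(tbl, ids = seqs$id)
}

#' Convert a long distance tibble to a square matrix
#'
#' @param tbl Long tibble with `idA`, `idB`, `distance`.
#' @param ids Optional id order for the matrix (default: order of appearance).
#' @return A symmetric matrix with zero diagonal.
#' @export
dist_to_matrix <- function(tbl, ids = NULL) {
  ids <- ids %||% unique(c(tbl$idA, tbl$idB))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(tbl$idA, ids)
  j <- match(tbl$idB, ids)
  m[cbind(i, j)] <- tbl$distance
  m[cbind(j, i)] <- tbl$distance
  attr(m, "method") <- attr(tbl, "method")
  m
}

#' Write a distance matrix as square and long TSV
#'
#' Square TSV with an id header row/column, masked (undefined) entries as
#' `NA`; the long form has columns `idA`, `idB`, `method`, `distance`
#' (fraction) and `percent` (half-even rounded to one decimal).
#'
#' @param tbl Long tibble from [pairwise_distances()].
#' @param square_path,long_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the input tibble.
#' @export
write_distance_tsv <- function(tbl, square_path = NULL, long_path = NULL) {
  method <- attr(tbl, "method") %||% "k2p"
  if (!is.null(square_path)) {
    m <- dist_to_matrix(tbl)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, square_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(long_path)) {
    long <- tbl %>%
      mutate(method = method,
             percent = round_half_even(100 * .data$distance, 1)) %>%
      select("idA", "idB", "method", "distance", "percent")
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tbl)
}
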