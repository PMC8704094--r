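#' Default anchor motifs for ITS spacer delimitation
#'
#' Conserved motifs flanking the two internal transcribed spacers of the
#' fungal rRNA cistron: the 3' region of the 18S (SSU), both ends of the 5.8S
#' gene, and the 5' region of the 28S (LSU). The defaults are the widely
#' conserved primer-region motifs of fungal ribosomal genes (ITS1/5.8S-Fun/
#' ITS3/ITS4 neighbourhoods), written with IUPAC degeneracy where fungi vary.
#' Spacers are delimited as the residues strictly between matched anchors, so
#' ITS1 and ITS2 exclude the 5.8S.
#'
#' @param ssu_end,s58_start,s58_end,lsu_start Degenerate DNA motifs.
#' @param max_mismatch Mismatch tolerance per motif (default 1).
#' @return An `anchor_config` list consumed by [extract_spacers()].
#' @export
default_anchors <- function(ssu_end = "TCCGTAGGTGAACCTGCGG",
                            s58_start = "AACTTTYAACAAYGGATCTCTT",
                            s58_end = "GAATCATCGAATCTTTGAACGCA",
                            lsu_start = "GCATATCAATAAGCGGAGGA",
                            max_mismatch = 1L) {
  structure(list(ssu_end = ssu_end, s58_start = s58_start,
                 s58_end = s58_end, lsu_start = lsu_start,
                 max_mismatch = as.integer(max_mismatch)),
            class = "anchor_config")
}

#' Extract ITS1 and ITS2 spacers from full ITS sequences
#'
#' Delimits the two spacers of each full-length ITS record by locating the
#' flanking conserved anchors ([default_anchors()]): ITS1 lies between the 18S
#' anchor and the 5.8S start, ITS2 between the 5.8S end and the 28S anchor.
#' When only one anchor of a spacer is found the spacer is returned
#' best-effort with the missing side open (status `open_5p` / `open_3p`);
#' when neither anchor is found the spacer is marked `undelimited` and its
#' residues are `NA`, never silently returned.
#'
#' @param seqs Sequence tibble with `locus == "ITS"`.
#' @param anchors An [default_anchors()] configuration.
#' @return A tibble with one row per record per spacer: `id`, `species`,
#'   `spacer` (`"ITS1"`/`"ITS2"`), `residues`, `start`, `end` (1-based closed
#'   coordinates on the input sequence) and `status` in
#'   `{complete, open_5p, open_3p, undelimited}`.
#' @export
extract_spacers <- function(seqs, anchors = default_anchors()) {
  check_seq_tbl(seqs)
  if ("locus" %in% names(seqs) && any(seqs$locus != "ITS")) {
    abort("extract_spacers expects full ITS records (locus == \"ITS\")")
  }
  rows <- purrr::map(seq_len(nrow(seqs)), function(i) {
    extract_spacers_one(seqs$id[i],
                        if ("species" %in% names(seqs)) seqs$species[i] else NA_character_,
                        seqs$residues[i], anchors)
  })
  bind_rows(rows)
}

extract_spacers_one <- function(id, species, residues, anchors) {
  subject <- Biostrings::DNAString(residues)
  hit <- function(motif) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                  max.mismatch = anchors$max_mismatch,
                                  fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    c(start = Biostrings::start(m)[1L], end = Biostrings::end(m)[1L])
  }
  ssu <- hit(anchors$ssu_end)
  s58a <- hit(anchors$s58_start)
  s58b <- hit(anchors$s58_end)
  lsu <- hit(anchors$lsu_start)
  len <- nchar(residues)

  spacer_row <- function(spacer, left, right) {
    # left/right are the flanking anchor hits; spacer is strictly between them
    if (is.null(left) && is.null(right)) {
      return(tibble(id = id, species = species, spacer = spacer,
                    residues = NA_character_, start = NA_integer_,
                    end = NA_integer_, status = "undelimited"))
    }
    start <- if (is.null(left)) 1L else unname(left["end"]) + 1L
    end <- if (is.null(right)) len else unname(right["start"]) - 1L
    status <- if (is.null(left)) "open_5p" else if (is.null(right)) "open_3p" else "complete"
    if (start > end) {
      return(tibble(id = id, species = species, spacer = spacer,
                    residues = NA_character_, start = NA_integer_,
                    end = NA_integer_, status = "undelimited"))
    }
    tibble(id = id, species = species, spacer = spacer,
           residues = substr(residues, start, end),
           start = as.integer(start), end = as.integer(end), status = status)
  }

  bind_rows(spacer_row("ITS1", ssu, s58a), spacer_row("ITS2", s58b, lsu))
}
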