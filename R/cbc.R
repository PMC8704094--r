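#' Structural category of an RNA base pair
#'
#' Categories follow the CBC species-concept vocabulary: canonical
#' (Watson-Crick) pairs `G=C`, `C=G`, `A-U`, `U-A`; near-isosteric wobble
#' pairs `G/U`, `U/G` and the protonated `A+/C`, `C/A+`; everything else over
#' A/C/G/U is noncanonical; any gap, `N` or non-ACGU character makes the
#' state `gapped`. Whether both orientations of A/C count as wobble is
#' configurable (`ac_wobble`), since published treatments differ.
#'
#' @param base5,base3 Characters at the 5' and 3' partner positions
#'   (vectorised; DNA `T` is read as `U`).
#' @param ac_wobble Treat A/C (both orientations) as wobble (default `TRUE`).
#' @return Character vector over
#'   `{canonical, wobble, noncanonical, gapped}`.
#' @export
pair_category <- function(base5, base3, ac_wobble = TRUE) {
  b5 <- chartr("T", "U", toupper(base5))
  b3 <- chartr("T", "U", toupper(base3))
  pair <- paste0(b5, b3)
  canonical <- c("GC", "CG", "AU", "UA")
  wobble <- c("GU", "UG", if (ac_wobble) c("AC", "CA"))
  ok <- b5 %in% c("A", "C", "G", "U") & b3 %in% c("A", "C", "G", "U")
  out <- rep("noncanonical", length(pair))
  out[pair %in% canonical] <- "canonical"
  out[pair %in% wobble] <- "wobble"
  out[!ok] <- "gapped"
  out
}

#' Classify the change between two states of a structural base pair
#'
#' Implements the three substitution types of the CBC species concept for a
#' helix base pair observed in two species:
#' * `CBC` — compensatory base change: both nucleotides differ and both
#'   states are canonical pairs (e.g. `G=C` to `C=G`, `A-U` or `U-A`),
#'   leaving the helix unperturbed.
#' * `hCBC` — hemi-compensatory: exactly one nucleotide differs, converting
#'   a canonical pair into a near-isosteric wobble pair (`G/U`, `A+/C`) or
#'   back.
#' * `nonCBC` — either state is a noncanonical pair: the substitution
#'   replaces a canonical or wobble pair with a non-canonical one.
#' * `combined` — both nucleotides differ between paired (canonical/wobble)
#'   states without being canonical-to-canonical (e.g. `G=C` to `U/G`); such
#'   doubles decompose into an hCBC plus another event and are reported as
#'   their own class.
#' * `identical` when nothing changed; `indeterminate` when either state is
#'   gapped.
#'
#' Classification is total and deterministic, and symmetric for
#' `{identical, CBC, nonCBC, combined}`; hCBC direction (canonical to wobble
#' or back) is noted by callers where it matters.
#'
#' @param pairA,pairB Two-character pair states (5' then 3' base), vectorised;
#'   e.g. `"GC"`, `"GU"`. DNA `T` is read as `U`.
#' @param ac_wobble Passed to [pair_category()].
#' @return Character vector over
#'   `{identical, CBC, hCBC, nonCBC, combined, indeterminate}`.
#' @examples
#' classify_pair_change("GC", "CG")  # CBC
#' classify_pair_change("GC", "GU")  # hCBC
#' classify_pair_change("AU", "AA")  # nonCBC
#' @export
classify_pair_change <- function(pairA, pairB, ac_wobble = TRUE) {
  pa <- chartr("T", "U", toupper(pairA))
  pb <- chartr("T", "U", toupper(pairB))
  if (any(nchar(pa) != 2L) || any(nchar(pb) != 2L)) {
    abort("pair states must be two-character strings")
  }
  a5 <- substr(pa, 1L, 1L); a3 <- substr(pa, 2L, 2L)
  b5 <- substr(pb, 1L, 1L); b3 <- substr(pb, 2L, 2L)
  catA <- pair_category(a5, a3, ac_wobble)
  catB <- pair_category(b5, b3, ac_wobble)
  n_diff <- (a5 != b5) + (a3 != b3)
  out <- rep("combined", length(pa))
  out[n_diff == 1L] <- "hCBC"
  out[n_diff == 2L & catA == "canonical" & catB == "canonical"] <- "CBC"
  out[catA == "noncanonical" | catB == "noncanonical"] <- "nonCBC"
  out[n_diff == 0L] <- "identical"
  out[catA == "gapped" | catB == "gapped"] <- "indeterminate"
  out
}

#' Enumerate substitution events over an ITS2 alignment and structure
#'
#' For each species pair (or each species against a reference species) and
#' each structural base pair, the two pair states are compared with
#' [classify_pair_change()] and tallied per helix. Species with several
#' distinct sequences are first collapsed to a majority-rule consensus
#' (ties become `N`, flagged), since the comparison is species-level.
#' Differences at unpaired alignment columns — single mutations in hairpin
#' loops and junction areas — are tallied separately and attached as the
#' `loop_mutations` attribute.
#'
#' @param aln Aligned ITS2 sequence tibble (`id`, `species`, `residues`);
#'   rows must all have the structure's length.
#' @param struct A [parse_dotbracket()] structure on alignment coordinates
#'   (use [project_structure()] if it is on ungapped reference coordinates).
#' @param reference_species Optional species name: compare every other
#'   species against this one instead of all pairs.
#' @param include_identical Keep `identical`/`indeterminate` rows (default
#'   `FALSE`: only actual events are returned).
#' @param ac_wobble Passed to [pair_category()].
#' @return A tibble of class `event_table`: `speciesA`, `speciesB`, `helix`,
#'   `pos5`, `pos3`, `pairA`, `pairB`, `class`. Attributes: `loop_mutations`
#'   (tibble `speciesA`, `speciesB`, `n_diff`), `n_structural_pairs`,
#'   `n_species_pairs`, `consensus_ambiguous` (species whose consensus had
#'   ties), `mode`.
#' @export
enumerate_events <- function(aln, struct, reference_species = NULL,
                             include_identical = FALSE, ac_wobble = TRUE) {
  check_seq_tbl(aln, require_species = TRUE)
  if (length(unique(nchar(aln$residues))) != 1L ||
      nchar(aln$residues[1L]) != struct$length) {
    abort("alignment rows must all match the structure length")
  }
  cons <- species_consensus(aln)
  species <- names(cons$sequences)
  if (!is.null(reference_species)) {
    if (!reference_species %in% species) {
      abort(paste0("reference species not in alignment: ", reference_species))
    }
    pairs <- tibble(speciesA = reference_species,
                    speciesB = setdiff(species, reference_species))
    mode <- "vs_reference"
  } else {
    if (length(species) < 2L) abort("need at least two species")
    cmb <- utils::combn(sort(species), 2L)
    pairs <- tibble(speciesA = cmb[1L, ], speciesB = cmb[2L, ])
    mode <- "all_pairs"
  }
  mats <- lapply(cons$sequences, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  pr <- struct$pairs
  unp <- struct$unpaired
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    a <- mats[[pairs$speciesA[k]]]
    b <- mats[[pairs$speciesB[k]]]
    pairA <- paste0(a[pr$pos5], a[pr$pos3])
    pairB <- paste0(b[pr$pos5], b[pr$pos3])
    tibble(speciesA = pairs$speciesA[k], speciesB = pairs$speciesB[k],
           helix = pr$helix, pos5 = pr$pos5, pos3 = pr$pos3,
           pairA = chartr("T", "U", pairA), pairB = chartr("T", "U", pairB),
           class = classify_pair_change(pairA, pairB, ac_wobble))
  })
  events <- bind_rows(rows)
  loop <- purrr::map(seq_len(nrow(pairs)), function(k) {
    a <- mats[[pairs$speciesA[k]]]
    b <- mats[[pairs$speciesB[k]]]
    au <- a[unp]; bu <- b[unp]
    ok <- au %in% c("A", "C", "G", "T") & bu %in% c("A", "C", "G", "T")
    tibble(speciesA = pairs$speciesA[k], speciesB = pairs$speciesB[k],
           n_diff = sum(ok & au != bu))
  })
  if (!include_identical) {
    events <- filter(events, !.data$class %in% c("identical", "indeterminate"))
  }
  class(events) <- c("event_table", class(events))
  attr(events, "loop_mutations") <- bind_rows(loop)
  attr(events, "n_structural_pairs") <- nrow(pr)
  attr(events, "n_species_pairs") <- nrow(pairs)
  attr(events, "consensus_ambiguous") <- cons$ambiguous
  attr(events, "mode") <- mode
  events
}

# majority-rule consensus per species; ties -> N (flagged)
species_consensus <- function(aln) {
  split_rows <- split(aln$residues, aln$species)
  ambiguous <- character(0)
  sequences <- lapply(split_rows, function(rows) {
    if (length(rows) == 1L) return(rows)
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    cons <- apply(m, 2L, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      if (length(tab) > 1L && tab[1L] == tab[2L]) "N" else names(tab)[1L]
    })
    paste(cons, collapse = "")
  })
  for (sp in names(split_rows)) {
    if (length(split_rows[[sp]]) > 1L &&
        length(unique(split_rows[[sp]])) > 1L) {
      ambiguous <- c(ambiguous, sp)
    }
  }
  list(sequences = sequences, ambiguous = ambiguous)
}

#' Per-class event totals
#'
#' @param x An [enumerate_events()] table.
#' @param ... Unused.
#' @return A one-row tibble with counts per event class plus
#'   `n_loop_mutations`.
#' @method glance event_table
#' @export
glance.event_table <- function(x, ...) {
  classes <- c("CBC", "hCBC", "nonCBC", "combined")
  counts <- vapply(classes, function(cl) sum(x$class == cl), 0L)
  loops <- attr(x, "loop_mutations")
  tibble(!!!as.list(counts),
         n_loop_mutations = if (is.null(loops)) 0L else sum(loops$n_diff))
}

#' Loop and junction single-mutation tally
#'
#' @param events An [enumerate_events()] table.
#' @return Tibble `speciesA`, `speciesB`, `n_diff` over unpaired columns.
#' @export
loop_mutations <- function(events) {
  attr(events, "loop_mutations") %||%
    abort("no loop_mutations attribute; run enumerate_events() first")
}

#' Species supported by the CBC species concept
#'
#' Under the CBC criterion a species is corroborated when it shows at least
#' one compensatory base change against every other congener in the table.
#'
#' @param events An [enumerate_events()] table over one genus.
#' @return Sorted character vector of supported species (possibly empty).
#' @export
cbc_species_support <- function(events) {
  species <- sort(unique(c(events$speciesA, events$speciesB)))
  if (length(species) < 2L) return(character(0))
  cbc <- filter(as_tibble(events), .data$class == "CBC")
  supported <- vapply(species, function(sp) {
    others <- setdiff(species, sp)
    all(vapply(others, function(o) {
      any((cbc$speciesA == sp & cbc$speciesB == o) |
            (cbc$speciesA == o & cbc$speciesB == sp))
    }, TRUE))
  }, TRUE)
  species[supported]
}

#' Write an event table as long TSV
#'
#' @param events An [enumerate_events()] table.
#' @param path Output path.
#' @param genus Optional genus label for the first column.
#' @return Invisibly, `path`.
#' @export
write_event_tsv <- function(events, path, genus = NA_character_) {
  df <- as_tibble(events) %>%
    mutate(genus = genus) %>%
    select("genus", "speciesA", "speciesB", "helix",
           column5 = "pos5", column3 = "pos3",
           baseA = "pairA", baseB = "pairB", "class")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
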