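#' Read barcode sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a sequence tibble, the container every
#' analysis function in the package consumes. Residues are uppercased and
#' normalised to the DNA alphabet (`U` becomes `T`); species labels come from
#' `species_map` when supplied, otherwise from a `"id|species"` header
#' convention.
#'
#' @param path Path to a FASTA file.
#' @param locus Locus tag shared by all records; one of `"ITS"`, `"ITS1"`,
#'   `"ITS2"`, `"28S"`, `"tef1a"`.
#' @param species_map Optional id-to-species table: a two-column data frame
#'   (`id`, `species`) or a named character vector. Takes precedence over any
#'   species embedded in the FASTA headers.
#' @param header_sep Separator splitting the FASTA header into id and species
#'   (default `"|"`). Text after the first separator is the species label.
#' @param ambiguity `"strict"` rejects IUPAC ambiguity codes other than `N`
#'   with the offending position; `"lenient"` maps them to `N`. Downstream
#'   exact matching needs defined semantics, hence the strict default.
#'
#' @return A tibble with columns `id`, `species`, `locus`, `residues` — one
#'   row per FASTA record, ids unique.
#' @seealso [write_fasta()], [read_species_map()]
#' @export
read_fasta <- function(path, locus, species_map = NULL, header_sep = "|",
                       ambiguity = c("strict", "lenient")) {
  ambiguity <- match.arg(ambiguity)
  locus <- match_locus(locus)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  ids <- vapply(strsplit(headers, header_sep, fixed = TRUE), `[`, "", 1L)
  ids <- trimws(ids)
  embedded <- vapply(strsplit(headers, header_sep, fixed = TRUE), function(x) {
    if (length(x) >= 2L) trimws(paste(x[-1L], collapse = header_sep)) else NA_character_
  }, "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  residues <- vapply(seq_along(set), function(i) {
    normalize_residues(as.character(set[[i]]), id = ids[[i]], ambiguity = ambiguity)
  }, "")
  species <- embedded
  if (!is.null(species_map)) {
    map <- as_species_map(species_map)
    mapped <- unname(map[ids])
    species <- if_else(is.na(mapped), species, mapped)
  }
  tibble(id = ids, species = species, locus = locus, residues = residues)
}

#' Write a sequence tibble to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id` or `id|species` when a species
#' label is present, so a written file is self-describing and round-trips.
#'
#' @param seqs Sequence tibble (`id`, `species`, `residues`).
#' @param path Output path.
#' @param header_sep Separator between id and species in headers.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, header_sep = "|") {
  check_seq_tbl(seqs)
  headers <- ifelse(is.na(seqs$species) | seqs$species == "",
                    seqs$id, paste(seqs$id, seqs$species, sep = header_sep))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an id-to-species map from a two-column TSV
#'
#' @param path TSV with columns `id` and `species` (header optional; the first
#'   two columns are used).
#' @return A tibble with columns `id` and `species`.
#' @export
read_species_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\\t", first)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  df <- df[, 1:2]
  names(df) <- c("id", "species")
  as_tibble(df)
}

# normalize one residue string: uppercase, U->T, validate alphabet
normalize_residues <- function(x, id = "<seq>", ambiguity = "strict") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) abort(paste0("record ", id, " has empty residues"))
  legal <- chars %in% c("A", "C", "G", "T", "N", "-")
  if (!all(legal)) {
    iupac <- chars %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    bad <- which(!legal & !iupac)
    if (length(bad) > 0L) {
      abort(sprintf("record %s: illegal residue '%s' at position %d",
                    id, chars[bad[1L]], bad[1L]))
    }
    if (ambiguity == "strict") {
      pos <- which(!legal)[1L]
      abort(sprintf(paste0("record %s: ambiguity code '%s' at position %d ",
                           "(use ambiguity = \"lenient\" to map to N)"),
                    id, chars[pos], pos))
    }
    chars[!legal] <- "N"
    x <- paste(chars, collapse = "")
  }
  x
}

match_locus <- function(locus) {
  loci <- c("ITS", "ITS1", "ITS2", "28S", "tef1a")
  m <- match(locus, loci)
  if (is.na(m)) abort(paste0("unknown locus '", locus, "'; expected one of ",
                             paste(loci, collapse = ", ")))
  loci[m]
}

as_species_map <- function(species_map) {
  if (is.data.frame(species_map)) {
    setNames(as.character(species_map[[2L]]), as.character(species_map[[1L]]))
  } else if (is.character(species_map) && !is.null(names(species_map))) {
    species_map
  } else {
    abort("species_map must be a two-column data frame or a named character vector")
  }
}

check_seq_tbl <- function(seqs, require_species = FALSE) {
  if (!is.data.frame(seqs) || !all(c("id", "residues") %in% names(seqs))) {
    abort("expected a sequence tibble with columns id, residues")
  }
  if (!"species" %in% names(seqs)) seqs$species <- NA_character_
  if (anyDuplicated(seqs$id)) abort("sequence ids must be unique")
  if (require_species && anyNA(seqs$species)) {
    abort(paste0("unlabeled ids: ",
                 paste(seqs$id[is.na(seqs$species)], collapse = ", ")))
  }
  invisible(seqs)
}
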