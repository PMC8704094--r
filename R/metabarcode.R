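#' Build a per-species spacer haplotype table
#'
#' Collapses identical spacer sequences within each (species, spacer) cell
#' into haplotypes, the reference against which environmental reads are
#' matched. Haplotypes identical across species are allowed and recorded —
#' the distinctiveness screen reports them.
#'
#' @param spacers Spacer tibble (`id`, `species`, `spacer`, `residues`),
#'   e.g. from [extract_spacers()]; `spacer` must be `"ITS1"` or `"ITS2"`.
#' @return A tibble of class `haplotype_table`: `species`, `spacer`,
#'   `haplotype` (uppercase ACGTN string), `n_records`, `record_ids`
#'   (list-column of source ids).
#' @export
build_reference <- function(spacers) {
  if (!is.data.frame(spacers) ||
      !all(c("id", "species", "spacer", "residues") %in% names(spacers))) {
    abort("expected columns id, species, spacer, residues")
  }
  spacers <- filter(spacers, !is.na(.data$residues))
  if (nrow(spacers) == 0L) abort("no delimited spacer sequences to collapse")
  if (!all(spacers$spacer %in% c("ITS1", "ITS2"))) {
    abort("spacer must be ITS1 or ITS2")
  }
  if (anyNA(spacers$species)) abort("every record needs a species label")
  out <- spacers %>%
    mutate(haplotype = toupper(chartr("U", "T", .data$residues))) %>%
    group_by(.data$species, .data$spacer, .data$haplotype) %>%
    summarise(n_records = n(), record_ids = list(.data$id), .groups = "drop") %>%
    arrange(.data$species, .data$spacer, .data$haplotype)
  bad <- grepl("[^ACGTN]", out$haplotype)
  if (any(bad)) abort("haplotypes must be over A, C, G, T, N")
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Per-spacer species distinctiveness
#'
#' For each spacer and each species pair, the minimum number of differing
#' positions over all cross-species haplotype pairs, computed on an
#' end-gap-free alignment (terminal overhangs are not penalised as gaps).
#' When a haplotype is a terminal extension of the other with no internal
#' difference, the terminal length difference is reported instead, so
#' `min_diff == 0` exactly when the two species share an identical
#' haplotype. A pair is `separable` on a spacer when `min_diff >= 1`;
#' species pairs separable on only one spacer are the reason per-spacer
#' screening exists.
#'
#' @param haplos A [build_reference()] table (>= 2 species).
#' @return A tibble: `spacer`, `speciesA`, `speciesB`, `min_diff`,
#'   `separable`, symmetric entries stored once with `speciesA < speciesB`.
#' @export
distinctiveness <- function(haplos) {
  species <- sort(unique(haplos$species))
  if (length(species) < 2L) abort("need at least two species")
  rows <- list()
  for (sp in unique(haplos$spacer)) {
    cells <- split(haplos$haplotype[haplos$spacer == sp],
                   haplos$species[haplos$spacer == sp])
    present <- names(cells)
    if (length(present) < 2L) next
    cmb <- utils::combn(present, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cells[[cmb[1L, k]]]
      b <- cells[[cmb[2L, k]]]
      dd <- min(vapply(a, function(x) {
        min(vapply(b, function(y) haplotype_diff(x, y), 0L))
      }, 0L))
      rows[[length(rows) + 1L]] <- tibble(
        spacer = sp, speciesA = cmb[1L, k], speciesB = cmb[2L, k],
        min_diff = dd, separable = dd >= 1L)
    }
  }
  bind_rows(rows)
}

# end-gap-free difference count between two haplotypes; nested-haplotype rule
haplotype_diff <- function(x, y) {
  if (x == y) return(0L)
  if (nchar(x) == nchar(y)) {
    a <- strsplit(x, "", fixed = TRUE)[[1]]
    b <- strsplit(y, "", fixed = TRUE)[[1]]
    return(sum(a != b))
  }
  pa <- Biostrings::pairwiseAlignment(x, y, type = "overlap",
                                      substitutionMatrix = substitution_matrix(alignment_params()),
                                      gapOpening = 2, gapExtension = 0.5)
  ra <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  rb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  d <- sum(ra != rb)
  if (d == 0L) d <- abs(nchar(x) - nchar(y))  # nested haplotypes still differ
  as.integer(d)
}

trim_tolerance <- function(spacer, trim_tol = NULL) {
  if (!is.null(trim_tol)) {
    if (length(trim_tol) == 1L && is.null(names(trim_tol))) return(as.integer(trim_tol))
    if (spacer %in% names(trim_tol)) return(as.integer(trim_tol[[spacer]]))
  }
  if (spacer == "ITS2") 2L else 0L
}

# dictionary of (possibly 5'-trimmed) haplotypes -> species/haplotype/trim
trim_dictionary <- function(haplos, spacer, trim_tol) {
  cell <- filter(as_tibble(haplos), .data$spacer == !!spacer)
  entries <- purrr::map(seq_len(nrow(cell)), function(i) {
    h <- cell$haplotype[i]
    ks <- 0:min(trim_tol, nchar(h) - 1L)
    tibble(key = substring(h, ks + 1L), species = cell$species[i],
           haplotype = h, trim = as.integer(ks))
  })
  dict <- bind_rows(entries)
  # N is a mismatch everywhere, so keyed variants containing N can never match
  dict[!grepl("N", dict$key, fixed = TRUE), ]
}

#' Match one environmental read against the haplotype table
#'
#' GlobalFungi-style assignment: 100% similarity with full-length coverage.
#' A query matches a haplotype only if it is identical to it over the full
#' compared length, allowing the reference to exceed the query by at most
#' `trim_tol` bases at the 5' end (environmental ITS2 spacers usually lack
#' 1-2 bp there); no 3' slack, no mismatches, and `N` mismatches everything.
#'
#' @param query Query spacer sequence (ACGTN string).
#' @param haplos A [build_reference()] table.
#' @param spacer `"ITS1"` or `"ITS2"`.
#' @param trim_tol 5' trim tolerance in bp; default 2 for ITS2, 0 for ITS1.
#' @return One-row tibble: `status` (`"unique"`, `"ambiguous"`, `"none"`),
#'   `species` (list-column of matched species), `haplotype`, `trim`.
#' @export
match_query <- function(query, haplos, spacer, trim_tol = NULL) {
  tol <- trim_tolerance(spacer, trim_tol)
  dict <- trim_dictionary(haplos, spacer, tol)
  match_one(toupper(chartr("U", "T", query)), dict)
}

match_one <- function(query, dict) {
  hit <- dict[dict$key == query, ]
  if (nrow(hit) == 0L || grepl("N", query, fixed = TRUE)) {
    return(tibble(status = "none", species = list(character(0)),
                  haplotype = NA_character_, trim = NA_integer_))
  }
  best <- min(hit$trim)
  species <- sort(unique(hit$species))
  tibble(status = if (length(species) == 1L) "unique" else "ambiguous",
         species = list(species),
         haplotype = hit$haplotype[hit$trim == best][1L],
         trim = as.integer(best))
}

#' Assign an environmental dataset and join its metadata
#'
#' Runs [match_query()] over a whole query table and joins per-sample
#' metadata by id. Ambiguous assignments are retained and flagged (they are
#' excluded from species summaries by default); queries without metadata and
#' metadata without queries are flagged as orphans.
#'
#' @param queries Query tibble: `id`, `spacer`, `residues`.
#' @param metadata Metadata tibble keyed by `id` (columns such as
#'   `substrate`, `biome`, `climate_zone`, `MAT`, `MAP`).
#' @param haplos A [build_reference()] table.
#' @param trim_tol Named vector of per-spacer 5' trim tolerances, e.g.
#'   `c(ITS1 = 0, ITS2 = 2)` (the default).
#' @return A tibble of class `assignment_table`: query columns, `status`,
#'   `species` (matched set, comma-joined in `species_label`), `haplotype`,
#'   `trim`, `orphan` flag, and the metadata columns. Attribute
#'   `orphan_metadata` holds metadata rows with no query.
#' @export
assign_dataset <- function(queries, metadata = NULL, haplos, trim_tol = NULL) {
  if (!is.data.frame(queries) ||
      !all(c("id", "spacer", "residues") %in% names(queries))) {
    abort("queries need columns id, spacer, residues")
  }
  if (nrow(queries) == 0L) {
    out <- tibble(id = character(), spacer = character(), residues = character(),
                  status = character(), species = list(),
                  species_label = character(), haplotype = character(),
                  trim = integer(), orphan = logical())
    class(out) <- c("assignment_table", class(out))
    attr(out, "orphan_metadata") <- metadata
    return(out)
  }
  dicts <- lapply(setNames(nm = unique(queries$spacer)), function(sp) {
    trim_dictionary(haplos, sp, trim_tolerance(sp, trim_tol))
  })
  res <- bind_rows(purrr::map(seq_len(nrow(queries)), function(i) {
    match_one(toupper(chartr("U", "T", queries$residues[i])),
              dicts[[queries$spacer[i]]])
  }))
  out <- bind_cols(as_tibble(queries), res) %>%
    mutate(species_label = vapply(.data$species, paste, "", collapse = ","))
  orphan_meta <- NULL
  if (!is.null(metadata)) {
    out <- left_join(out, as_tibble(metadata), by = "id")
    out$orphan <- !out$id %in% metadata$id
    orphan_meta <- anti_join(as_tibble(metadata), out, by = "id")
    if (any(out$orphan)) {
      warn(sprintf("%d queries have no metadata row", sum(out$orphan)))
    }
  } else {
    out$orphan <- TRUE
  }
  class(out) <- c("assignment_table", class(out))
  attr(out, "orphan_metadata") <- orphan_meta
  out
}

koppen_group <- function(zone) {
  first <- toupper(substr(zone, 1L, 1L))
  dplyr::case_match(first,
                    "A" ~ "tropical", "B" ~ "arid", "C" ~ "temperate",
                    "D" ~ "continental", "E" ~ "polar",
                    .default = NA_character_)
}

#' Per-species biogeographic summaries
#'
#' Summarises uniquely assigned samples per species: sample count, substrate
#' and biome proportions, mean annual temperature (MAT, degrees C) and mean
#' annual precipitation (MAP, mm) over samples with defined values,
#' Koppen-Geiger climate-zone tallies, and a distribution type. The
#' distribution rule (thresholds configurable and echoed in the output):
#' `tropical` when at least `tropical_prop` of samples lie in tropical zones
#' (Koppen group A), `temperate/continental` when at least `temperate_prop`
#' lie in temperate plus continental zones (C or D), otherwise `global`.
#'
#' @param assignments An [assign_dataset()] table with metadata columns.
#' @param include_ambiguous Also count ambiguous assignments, attributing
#'   the sample to every matched species (default `FALSE`).
#' @param tropical_prop,temperate_prop Rule thresholds (default 0.8).
#' @return A tibble, one row per species: `species`, `n_samples`,
#'   `substrate` and `biome` (list-columns of named proportion vectors),
#'   `mean_mat`, `mean_map`, `climate_zones` (list-column of named tallies),
#'   `distribution_type`. Attribute `rule` records the thresholds.
#' @export
summarize_species <- function(assignments, include_ambiguous = FALSE,
                              tropical_prop = 0.8, temperate_prop = 0.8) {
  keep <- assignments$status == "unique" |
    (include_ambiguous & assignments$status == "ambiguous")
  df <- as_tibble(assignments)[keep, ]
  df <- tidyr::unnest(df, "species")
  all_species <- sort(unique(unlist(assignments$species)))
  prop_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(numeric(0))
    sort(table(x) / length(x), decreasing = TRUE)
  }
  rows <- purrr::map(all_species, function(sp) {
    d <- df[df$species == sp, ]
    zones <- if ("climate_zone" %in% names(d)) d$climate_zone else character(0)
    groups <- koppen_group(zones[!is.na(zones)])
    p_trop <- if (length(groups)) mean(groups == "tropical") else NA_real_
    p_temp <- if (length(groups)) mean(groups %in% c("temperate", "continental")) else NA_real_
    dist_type <- dplyr::case_when(
      is.na(p_trop) ~ NA_character_,
      p_trop >= tropical_prop ~ "tropical",
      p_temp >= temperate_prop ~ "temperate/continental",
      .default = "global")
    tibble(species = sp, n_samples = nrow(d),
           substrate = list(prop_of(d[["substrate"]])),
           biome = list(prop_of(d[["biome"]])),
           mean_mat = mean(d[["MAT"]], na.rm = TRUE),
           mean_map = mean(d[["MAP"]], na.rm = TRUE),
           climate_zones = list(table(zones[!is.na(zones)])),
           distribution_type = dist_type)
  })
  out <- bind_rows(rows)
  attr(out, "rule") <- list(tropical_prop = tropical_prop,
                            temperate_prop = temperate_prop,
                            include_ambiguous = include_ambiguous)
  out
}
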