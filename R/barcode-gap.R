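#' Partition pairwise distances into intra- and interspecific sets
#'
#' Splits a long distance tibble by species labels: every off-diagonal pair
#' lands in exactly one of the two sets. Singleton species contribute no
#' intraspecific entries. Undefined (masked) distances are excluded and
#' counted in the `n_excluded` attribute, never dropped silently.
#'
#' @param dist_tbl Long distance tibble from [pairwise_distances()].
#' @param species_map Id-to-species table (two-column data frame or named
#'   character vector). Every id must be labeled.
#' @return A tibble of class `distance_partition` with columns `idA`, `idB`,
#'   `speciesA`, `speciesB`, `type` (`"intra"`/`"inter"`), `distance`.
#' @export
partition_distances <- function(dist_tbl, species_map) {
  map <- as_species_map(species_map)
  ids <- unique(c(dist_tbl$idA, dist_tbl$idB))
  missing <- ids[!ids %in% names(map)]
  if (length(missing) > 0L) {
    abort(paste0("unlabeled ids: ", paste(missing, collapse = ", ")))
  }
  out <- dist_tbl %>%
    mutate(speciesA = unname(map[.data$idA]),
           speciesB = unname(map[.data$idB]),
           type = if_else(.data$speciesA == .data$speciesB, "intra", "inter")) %>%
    select("idA", "idB", "speciesA", "speciesB", "type", "distance")
  n_excluded <- sum(is.na(out$distance))
  out <- filter(out, !is.na(.data$distance))
  class(out) <- c("distance_partition", class(out))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Barcoding-gap report
#'
#' The barcoding gap is the open interval between the largest intraspecific
#' and the smallest interspecific distance, `(max_intra, min_inter)`. The gap
#' is overlapping (absent) when `max_intra >= min_inter`. An empty intra or
#' inter set yields an undefined bound and is flagged rather than an error.
#'
#' @param partition A [partition_distances()] result.
#' @return A `gap_report` object; see [glance.gap_report()] for the one-row
#'   summary and [tidy.gap_report()] for per-species-pair extremes.
#' @export
gap_report <- function(partition) {
  intra <- partition$distance[partition$type == "intra"]
  inter <- partition$distance[partition$type == "inter"]
  max_intra <- if (length(intra) > 0) max(intra) else NA_real_
  min_inter <- if (length(inter) > 0) min(inter) else NA_real_
  width <- min_inter - max_intra
  structure(list(max_intra = max_intra, min_inter = min_inter,
                 gap_low = max_intra, gap_high = min_inter,
                 overlap = isTRUE(width <= 0),
                 undefined = is.na(max_intra) || is.na(min_inter),
                 width = width,
                 n_intra = length(intra), n_inter = length(inter),
                 n_excluded = attr(partition, "n_excluded") %||% 0L,
                 partition = partition),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n")
  fmtp <- function(v) if (is.na(v)) "undefined" else sprintf("%.4g%%", 100 * v)
  cat("  max intraspecific:", fmtp(x$max_intra),
      sprintf("(n = %d)\n", x$n_intra))
  cat("  min interspecific:", fmtp(x$min_inter),
      sprintf("(n = %d)\n", x$n_inter))
  if (x$undefined) {
    cat("  gap: undefined (empty intra or inter set)\n")
  } else if (x$overlap) {
    cat("  gap: OVERLAP (no barcoding gap)\n")
  } else {
    cat(sprintf("  gap: (%s, %s), width %s\n",
                fmtp(x$gap_low), fmtp(x$gap_high), fmtp(x$width)))
  }
  if (x$n_excluded > 0) cat("  excluded undefined distances:", x$n_excluded, "\n")
  invisible(x)
}

#' One-row summary of a gap report
#'
#' @param x A [gap_report()] object.
#' @param ... Unused.
#' @return A one-row tibble: `max_intra`, `min_inter`, `gap_low`, `gap_high`,
#'   `width`, `overlap`, `n_intra`, `n_inter`, `n_excluded`, plus the percent
#'   scale `max_intra_pct`, `min_inter_pct`.
#' @method glance gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble(max_intra = x$max_intra, min_inter = x$min_inter,
         gap_low = x$gap_low, gap_high = x$gap_high, width = x$width,
         overlap = x$overlap, n_intra = x$n_intra, n_inter = x$n_inter,
         n_excluded = x$n_excluded,
         max_intra_pct = round_half_even(100 * x$max_intra, 1),
         min_inter_pct = round_half_even(100 * x$min_inter, 1))
}

#' Per-species-pair distance extremes of a gap report
#'
#' @param x A [gap_report()] object.
#' @param ... Unused.
#' @return A tibble with one row per species pair (intra pairs have
#'   `speciesA == speciesB`): `type`, `n`, `min`, `max`.
#' @method tidy gap_report
#' @export
tidy.gap_report <- function(x, ...) {
  x$partition %>%
    as_tibble() %>%
    group_by(.data$speciesA, .data$speciesB, .data$type) %>%
    summarise(n = n(), min = min(.data$distance), max = max(.data$distance),
              .groups = "drop") %>%
    arrange(.data$type, .data$speciesA, .data$speciesB)
}

#' Barcoding-gap histogram
#'
#' Counts intra- and interspecific distances on common uniform bins starting
#' at 0. Bins are right-closed, left-open, except the first bin which is
#' closed at 0, so a value exactly on an edge belongs to the bin it ends.
#' Bin widths of 0.001 (and 0.0005 for low-divergence genera) suit K2P
#' barcode distances.
#'
#' @param partition A [partition_distances()] result.
#' @param bin_width Positive bin width (fraction scale; default 0.001).
#' @return A tibble of class `gap_histogram`: `bin_low`, `bin_high`, `type`,
#'   `count`.
#' @export
gap_histogram <- function(partition, bin_width = 0.001) {
  if (!is.numeric(bin_width) || bin_width <= 0) abort("bin_width must be > 0")
  d <- partition$distance
  n_bins <- max(1L, ceiling(max(d, 0) / bin_width + 1e-9))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  grid <- tidyr::expand_grid(bin = seq_len(n_bins), type = c("intra", "inter"))
  binned <- tibble(type = partition$type,
                   bin = pmax(1L, ceiling(d / bin_width - 1e-9)))
  out <- grid %>%
    left_join(count(binned, .data$bin, .data$type), by = c("bin", "type")) %>%
    mutate(count = dplyr::coalesce(.data$n, 0L),
           bin_low = edges[.data$bin], bin_high = edges[.data$bin + 1L]) %>%
    select("bin_low", "bin_high", "type", "count")
  class(out) <- c("gap_histogram", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Extreme interspecific species pairs
#'
#' For every species pair the minimum and maximum over its strain pairs is
#' taken; the report returns the globally closest species pair (minimum of
#' the minima) and the most divergent one (maximum of the maxima), the
#' numbers barcode studies print as the lowest and highest interspecific
#' divergence.
#'
#' @param partition A [partition_distances()] result (needs >= 2 species).
#' @return A two-row tibble: `extreme` (`"min"`/`"max"`), `speciesA`,
#'   `speciesB`, `idA`, `idB`, `distance`, `percent`.
#' @export
extreme_pairs <- function(partition) {
  inter <- filter(as_tibble(partition), .data$type == "inter")
  if (nrow(inter) == 0L) abort("need at least two species with defined distances")
  lo <- inter[which.min(inter$distance), ]
  hi <- inter[which.max(inter$distance), ]
  bind_rows(mutate(lo, extreme = "min"), mutate(hi, extreme = "max")) %>%
    mutate(percent = round_half_even(100 * .data$distance, 1)) %>%
    select("extreme", "speciesA", "speciesB", "idA", "idB", "distance", "percent")
}
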