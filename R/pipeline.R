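#' Read and validate a run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with the
#' input paths and analysis settings of the end-to-end stages. Referenced
#' paths are checked at validation time, and the configuration is serialised
#' verbatim into every report bundle so a run is reproducible from its
#' outputs.
#'
#' Recognised fields (stage-dependent): `fasta`, `species_map`, `locus`,
#' `alignment` (FASTA of aligned ITS2 rows), `structure` (structure file),
#' `reference_fasta`/`reference_spacers`, `queries`, `metadata`, `out_dir`,
#' `bin_widths`, `mode`, `deletion`, `method`, `trim_tol`, `seed`,
#' `alignment_params` (list with match/mismatch/gap_open/gap_extend).
#'
#' @param config A named list or path to a YAML file.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a named list or a YAML path")
  for (field in c("fasta", "species_map", "alignment", "structure",
                  "reference_spacers", "queries", "metadata")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config field '%s' points to a missing file: %s", field, p))
    }
  }
  config$out_dir <- config$out_dir %||% "barcodegap-run"
  structure(config, class = c("run_config", "list"))
}

run_params <- function(cfg) {
  ap <- cfg$alignment_params %||% list()
  do.call(alignment_params, ap)
}

report_header <- function(cfg) {
  hashed <- unclass(cfg)
  hashed$out_dir <- NULL  # the hash identifies the analysis, not its location
  list(tool = "barcodegap",
       version = as.character(utils::packageVersion("barcodegap")),
       config = unclass(cfg),
       config_hash = rlang::hash(hashed),
       alignment_params = unclass(run_params(cfg)),
       deletion = cfg$deletion %||% "pairwise",
       rounding = "percent values half-even to one decimal")
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the barcoding-gap analysis stage
#'
#' Reads labeled barcode sequences, computes the distance matrix, partitions
#' it by species, and writes the gap report, histograms at the configured
#' bin widths, and the extreme-pair table into the run directory
#' (`matrices/`, `reports/`, `tables/`).
#'
#' @param config A [read_run_config()] input (list or YAML path) with at
#'   least `fasta` and `species_map` (unless species are embedded in
#'   headers).
#' @return Invisibly, a list with `distances`, `partition`, `report`,
#'   `histograms`, `extremes` and the output directory.
#' @export
run_barcode_analysis <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$fasta)) abort("config needs a 'fasta' field")
  map <- if (!is.null(cfg$species_map)) read_species_map(cfg$species_map)
  seqs <- read_fasta(cfg$fasta, cfg$locus %||% "ITS", species_map = map)
  check_seq_tbl(seqs, require_species = TRUE)
  dists <- pairwise_distances(seqs, method = cfg$method %||% "k2p",
                              mode = cfg$mode %||% "pairwise",
                              deletion = cfg$deletion %||% "pairwise",
                              params = run_params(cfg))
  part <- partition_distances(dists, setNames(seqs$species, seqs$id))
  rep <- gap_report(part)
  bins <- cfg$bin_widths %||% c(0.001)
  hists <- lapply(bins, function(bw) gap_histogram(part, bw))
  names(hists) <- paste0("bin_", bins)
  ext <- if (rep$n_inter > 0) extreme_pairs(part) else NULL

  out <- file.path(cfg$out_dir)
  for (d in c("matrices", "reports", "tables")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_distance_tsv(dists,
                     square_path = file.path(out, "matrices", "distances_square.tsv"),
                     long_path = file.path(out, "matrices", "distances_long.tsv"))
  g <- glance(rep)
  write_report_json(c(report_header(cfg),
                      list(gap = as.list(g),
                           undefined = rep$undefined,
                           extreme_pairs = if (!is.null(ext)) {
                             lapply(seq_len(nrow(ext)), function(i) as.list(ext[i, ]))
                           })),
                    file.path(out, "reports", "gap_report.json"))
  for (nm in names(hists)) {
    write.table(hists[[nm]], file.path(out, "tables", paste0("histogram_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ext)) {
    write.table(ext, file.path(out, "tables", "extreme_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(distances = dists, partition = part, report = rep,
                 histograms = hists, extremes = ext, out_dir = out))
}

#' Run the ITS2 structural substitution stage
#'
#' Consumes an aligned ITS2 FASTA plus a structure file (sequence,
#' dot-bracket, helix spans; projected onto the alignment through the
#' matching row when needed) and writes the event table, per-helix summary
#' and CBC-supported species list.
#'
#' @param config A [read_run_config()] input with `alignment`, `structure`,
#'   and optionally `species_map`, `reference_species`.
#' @return Invisibly, a list with `events`, `summary`, `cbc_species`,
#'   `out_dir`.
#' @export
run_structure_analysis <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$alignment) || is.null(cfg$structure)) {
    abort("config needs 'alignment' and 'structure' fields")
  }
  map <- if (!is.null(cfg$species_map)) read_species_map(cfg$species_map)
  aln <- read_fasta(cfg$alignment, "ITS2", species_map = map)
  sf <- read_structure_file(cfg$structure)
  struct <- sf$structure
  if (struct$length != nchar(aln$residues[1L])) {
    ref_row <- aln$residues[gsub("-", "", aln$residues) ==
                              gsub("-", "", sf$sequence)][1]
    if (is.na(ref_row)) {
      abort("structure length differs from the alignment and no alignment row matches the structure's sequence")
    }
    struct <- project_structure(struct, ref_row)
  }
  events <- enumerate_events(aln, struct,
                             reference_species = cfg$reference_species)
  helix_summary <- as_tibble(events) %>%
    count(.data$helix, .data$class, name = "count") %>%
    arrange(.data$helix, .data$class)
  cbc <- cbc_species_support(events)

  out <- file.path(cfg$out_dir)
  dir.create(file.path(out, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)
  write_event_tsv(events, file.path(out, "tables", "its2_events.tsv"),
                  genus = cfg$genus %||% NA_character_)
  write.table(loop_mutations(events),
              file.path(out, "tables", "loop_mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_report_json(c(report_header(cfg),
                      list(mode = attr(events, "mode"),
                           consensus_ambiguous = attr(events, "consensus_ambiguous"),
                           totals = as.list(glance(events)),
                           per_helix = lapply(seq_len(nrow(helix_summary)),
                                              function(i) as.list(helix_summary[i, ])),
                           cbc_supported_species = cbc)),
                    file.path(out, "reports", "structure_report.json"))
  invisible(list(events = events, summary = helix_summary,
                 cbc_species = cbc, out_dir = out))
}

#' Run the environmental exact-match assignment stage
#'
#' Builds the reference haplotype table from spacer sequences, screens
#' per-spacer distinctiveness, assigns the environmental queries under the
#' 100%-identity full-length-coverage rule, and writes assignments and
#' per-species biogeographic summaries.
#'
#' @param config A [read_run_config()] input with `reference_spacers` (TSV:
#'   id, species, spacer, residues), `queries` (TSV: id, spacer, residues),
#'   and optionally `metadata` (TSV keyed by id), `trim_tol`.
#' @return Invisibly, a list with `reference`, `distinctiveness`,
#'   `assignments`, `summaries`, `out_dir`.
#' @export
run_metabarcode <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$reference_spacers) || is.null(cfg$queries)) {
    abort("config needs 'reference_spacers' and 'queries' fields")
  }
  read_tsv_base <- function(p) {
    as_tibble(read.table(p, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = ""))
  }
  refs <- build_reference(read_tsv_base(cfg$reference_spacers))
  queries <- read_tsv_base(cfg$queries)
  metadata <- if (!is.null(cfg$metadata)) read_tsv_base(cfg$metadata)
  trim_tol <- unlist(cfg$trim_tol) %||% c(ITS1 = 0, ITS2 = 2)
  dmat <- distinctiveness(refs)
  assign <- assign_dataset(queries, metadata, refs, trim_tol = trim_tol)
  summaries <- if (!is.null(metadata)) summarize_species(assign)

  out <- file.path(cfg$out_dir)
  dir.create(file.path(out, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "tables"), recursive = TRUE, showWarnings = FALSE)
  write.table(dmat, file.path(out, "tables", "distinctiveness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  flat <- as_tibble(assign) %>%
    select(-dplyr::any_of("species")) %>%
    rename(species = "species_label")
  write.table(flat, file.path(out, "tables", "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_report_json(c(report_header(cfg),
                      list(n_queries = nrow(assign),
                           status_counts = as.list(table(assign$status)),
                           summaries = if (!is.null(summaries)) {
                             lapply(seq_len(nrow(summaries)), function(i) {
                               s <- summaries[i, ]
                               list(species = s$species, n_samples = s$n_samples,
                                    substrate = as.list(s$substrate[[1]]),
                                    biome = as.list(s$biome[[1]]),
                                    mean_mat = s$mean_mat, mean_map = s$mean_map,
                                    climate_zones = as.list(s$climate_zones[[1]]),
                                    distribution_type = s$distribution_type)
                             })
                           })),
                    file.path(out, "reports", "metabarcode_report.json"))
  invisible(list(reference = refs, distinctiveness = dmat,
                 assignments = assign, summaries = summaries, out_dir = out))
}
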