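#' Random DNA sequence
#'
#' @param length Sequence length.
#' @param seed Optional integer seed (local, does not disturb the session RNG).
#' @param gc GC content (default 0.5).
#' @return A DNA string.
#' @export
random_sequence <- function(length, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) withr::local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs), collapse = "")
}

#' Evolve a sequence under the K2P substitution process
#'
#' Per-site substitution under the Kimura two-parameter model with
#' transition/transversion rate ratio `kappa`, with the branch length scaled
#' so that the expected K2P-estimated distance between input and output
#' equals `d`. With rates `alpha` (transition) and `beta` (each
#' transversion), `d = (alpha + 2 beta) t` and the site-change probabilities
#' follow the K2P transition-probability matrix; plugging their expectations
#' into the K2P estimator returns exactly `d`, which is what makes "target
#' distance" well-defined. Deterministic under `seed`.
#'
#' @param seq DNA string over A/C/G/T.
#' @param d Target K2P distance (fraction, >= 0).
#' @param kappa Transition/transversion rate ratio alpha/beta (default 2).
#' @param seed Optional integer seed.
#' @return The mutated sequence (same length).
#' @export
evolve_k2p <- function(seq, d, kappa = 2, seed = NULL) {
  if (d < 0) abort("d must be >= 0")
  if (grepl("[^ACGT]", seq)) abort("seq must be over A, C, G, T")
  probs <- k2p_site_probs(d, kappa)
  if (probs$w1 < 1e-12) {
    abort("d is too large: the K2P log argument saturates in expectation")
  }
  if (d == 0) return(seq)
  if (!is.null(seed)) withr::local_seed(seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- runif(n)
  take_ts <- u < probs$p_ts
  take_tv1 <- !take_ts & u < probs$p_ts + probs$p_tv_each
  take_tv2 <- !take_ts & !take_tv1 & u < probs$p_ts + 2 * probs$p_tv_each
  chars[take_ts] <- ts_map[chars[take_ts]]
  chars[take_tv1] <- tv1[chars[take_tv1]]
  chars[take_tv2] <- tv2[chars[take_tv2]]
  paste(chars, collapse = "")
}

# K2P transition-probability ingredients at target distance d
k2p_site_probs <- function(d, kappa) {
  at <- kappa * d / (kappa + 2)  # alpha * t
  bt <- d / (kappa + 2)          # beta * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv_each <- 0.25 - 0.25 * exp(-4 * bt)
  list(p_ts = p_ts, p_tv_each = p_tv_each,
       w1 = exp(-2 * (at + bt)))
}

#' Simulate a genus with planted intra- and interspecific divergence
#'
#' Star-within-star design: species ancestors evolve independently from a
#' genus root at distance `inter_d` each, and strains evolve from their
#' species ancestor at `intra_d / 2` each. Intraspecific pairwise distances
#' therefore concentrate around `intra_d`, and interspecific ones around
#' `2 * inter_d + intra_d`, keeping the minimum interspecific distance above
#' the `inter_d` floor — the regime a clean barcoding gap requires.
#'
#' @param n_species Number of species (default 4).
#' @param strains_per_species Strains per species (default 3).
#' @param length Sequence length (default 600, ITS-like).
#' @param intra_d Target intraspecific pairwise distance (default 0.002).
#' @param inter_d Target root-to-ancestor distance (default 0.02); must
#'   exceed `intra_d`.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Optional integer seed.
#' @return A list with `sequences` (tibble `id`, `species`, `locus`,
#'   `residues`), `species_map` (named vector) and `truth` (root, ancestors,
#'   branch lengths, config).
#' @export
simulate_genus <- function(n_species = 4, strains_per_species = 3,
                           length = 600, intra_d = 0.002, inter_d = 0.02,
                           kappa = 2, seed = NULL) {
  if (intra_d < 0 || intra_d >= inter_d) abort("need 0 <= intra_d < inter_d")
  if (length <= 0) abort("length must be > 0")
  if (!is.null(seed)) withr::local_seed(seed)
  species <- sprintf("Species_%02d", seq_len(n_species))
  root <- random_sequence(length)
  ancestors <- setNames(vapply(species, function(sp) {
    evolve_k2p(root, inter_d, kappa)
  }, ""), species)
  rows <- purrr::map(species, function(sp) {
    tibble(id = sprintf("%s_s%d", sp, seq_len(strains_per_species)),
           species = sp, locus = "ITS",
           residues = vapply(seq_len(strains_per_species), function(i) {
             evolve_k2p(ancestors[[sp]], intra_d / 2, kappa)
           }, ""))
  })
  sequences <- bind_rows(rows)
  truth <- list(root = root, ancestors = ancestors,
                ancestor_branch = inter_d, strain_branch = intra_d / 2,
                config = list(n_species = n_species,
                              strains_per_species = strains_per_species,
                              length = length, intra_d = intra_d,
                              inter_d = inter_d, kappa = kappa, seed = seed))
  list(sequences = sequences,
       species_map = setNames(sequences$species, sequences$id),
       truth = truth)
}

canonical_pairs <- c("GC", "CG", "AU", "UA")
wobble_neighbors <- list(GC = c("GU", "AC"), CG = c("UG", "CA"),
                         AU = c("GU", "AC"), UA = c("UG", "CA"),
                         GU = c("GC", "AU"), UG = c("CG", "UA"),
                         AC = c("GC", "AU"), CA = c("CG", "UA"))

#' Plant structural substitution events into an ITS2-like sequence
#'
#' Builds a variant of a template sequence that differs by exactly the
#' requested CBC, hCBC and non-CBC events at structural base pairs of the
#' given helices — and by nothing else — so downstream event enumeration has
#' exact planted truth. CBCs swap a canonical pair for a different canonical
#' pair (both bases change); hCBCs change one partner between canonical and
#' wobble; non-CBCs change one base of a canonical or wobble pair into a
#' noncanonical pair. Each event uses its own base pair.
#'
#' @param template Template sequence (DNA or RNA; the variant keeps the
#'   template's alphabet).
#' @param struct A [parse_dotbracket()] structure on template coordinates.
#' @param events Data frame with columns `class`
#'   (`"CBC"`/`"hCBC"`/`"nonCBC"`), `helix`, `count`; or a list of
#'   `c(class, helix, count)` triples.
#' @param seed Optional integer seed.
#' @return A list with `variant` (sequence), `truth` (tibble `class`,
#'   `helix`, `pos5`, `pos3`, `from`, `to`).
#' @export
plant_structure_events <- function(template, struct, events, seed = NULL) {
  if (!is.data.frame(events)) {
    events <- do.call(rbind, lapply(events, function(e) {
      data.frame(class = e[[1L]], helix = e[[2L]], count = as.integer(e[[3L]]))
    }))
  }
  events <- as_tibble(events)
  if (nchar(template) != struct$length) {
    abort("template length does not match the structure")
  }
  was_dna <- grepl("T", toupper(template)) || !grepl("U", toupper(template))
  chars <- strsplit(chartr("T", "U", toupper(template)), "", fixed = TRUE)[[1]]
  if (!is.null(seed)) withr::local_seed(seed)
  pr <- struct$pairs
  pr$state <- paste0(chars[pr$pos5], chars[pr$pos3])
  pr$category <- pair_category(substr(pr$state, 1, 1), substr(pr$state, 2, 2))
  used <- rep(FALSE, nrow(pr))
  truth <- list()
  for (r in seq_len(nrow(events))) {
    cls <- events$class[r]
    hx <- events$helix[r]
    for (k in seq_len(events$count[r])) {
      eligible <- which(!used & pr$helix == hx &
                          pr$category %in% eligible_categories(cls))
      if (length(eligible) == 0L) {
        abort(sprintf("not enough eligible base pairs in %s for a %s event",
                      hx, cls))
      }
      i <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      used[i] <- TRUE
      from <- pr$state[i]
      to <- plant_target(cls, from)
      truth[[length(truth) + 1L]] <- tibble(
        class = cls, helix = hx, pos5 = pr$pos5[i], pos3 = pr$pos3[i],
        from = from, to = to)
      chars[pr$pos5[i]] <- substr(to, 1L, 1L)
      chars[pr$pos3[i]] <- substr(to, 2L, 2L)
    }
  }
  variant <- paste(chars, collapse = "")
  if (was_dna) variant <- chartr("U", "T", variant)
  list(variant = variant,
       truth = if (length(truth)) bind_rows(truth) else
         tibble(class = character(), helix = character(), pos5 = integer(),
                pos3 = integer(), from = character(), to = character()))
}

eligible_categories <- function(class) {
  switch(class,
         CBC = "canonical",
         hCBC = c("canonical", "wobble"),
         nonCBC = c("canonical", "wobble"),
         abort(paste0("unknown event class: ", class)))
}

plant_target <- function(class, from) {
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  if (class == "CBC") {
    return(pick(setdiff(canonical_pairs, from)))
  }
  if (class == "hCBC") {
    return(pick(wobble_neighbors[[from]]))
  }
  # nonCBC: single-base change producing a noncanonical pair
  b5 <- substr(from, 1L, 1L); b3 <- substr(from, 2L, 2L)
  alts <- c(paste0(setdiff(c("A", "C", "G", "U"), b5), b3),
            paste0(b5, setdiff(c("A", "C", "G", "U"), b3)))
  noncanon <- alts[pair_category(substr(alts, 1, 1), substr(alts, 2, 2)) ==
                     "noncanonical"]
  pick(noncanon)
}

#' Simulate environmental spacer reads with metadata
#'
#' Generates planted environmental queries from a reference haplotype table
#' (each read is a haplotype with a sampled 5' truncation, emulating the
#' 1-2 bp usually missing at the 5' end of database ITS2 spacers), plus
#' decoy reads guaranteed to differ from every reference haplotype and every
#' allowed trim of it, and per-sample metadata drawn from per-species
#' categorical (substrate, biome, climate zone) and normal (MAT, MAP)
#' models.
#'
#' @param haplos A [build_reference()] table.
#' @param n_per_species Planted reads per species (default 10).
#' @param spacer Spacer to read from (default `"ITS2"`).
#' @param trim_probs Probabilities of 0, 1, 2 bp 5' truncation (default
#'   `c(0.4, 0.3, 0.3)`).
#' @param n_decoys Number of decoy reads (default 5).
#' @param metadata_model Optional per-species list of models
#'   (`substrate`/`biome`/`climate_zone` as named probability vectors,
#'   `MAT`/`MAP` as `c(mean, sd)`); by default species alternate between a
#'   tropical profile (zones Af/Am/Aw, MAT ~ N(24, 2) degC, MAP ~ N(2600,
#'   300) mm) and a temperate/continental one (Cfb/Dfb, MAT ~ N(10, 3),
#'   MAP ~ N(900, 200)), matching the two dominant distribution types of
#'   the studied genera.
#' @param seed Optional integer seed.
#' @return A list with `queries` (tibble `id`, `spacer`, `residues`),
#'   `metadata` (tibble `id`, `substrate`, `biome`, `climate_zone`, `MAT`,
#'   `MAP`) and `truth` (origin species, trims, decoy ids, metadata model).
#' @export
simulate_env_reads <- function(haplos, n_per_species = 10, spacer = "ITS2",
                               trim_probs = c(`0` = 0.4, `1` = 0.3, `2` = 0.3),
                               n_decoys = 5, metadata_model = NULL,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  cell <- filter(as_tibble(haplos), .data$spacer == !!spacer)
  if (nrow(cell) == 0L) abort(paste0("no ", spacer, " haplotypes in the table"))
  species <- sort(unique(cell$species))
  model <- metadata_model %||% default_metadata_model(species)
  trims <- as.integer(names(trim_probs))
  qrows <- list(); origin <- list()
  for (sp in species) {
    hps <- cell$haplotype[cell$species == sp]
    for (k in seq_len(n_per_species)) {
      h <- if (length(hps) == 1L) hps else sample(hps, 1L)
      tr <- sample(trims, 1L, prob = trim_probs)
      tr <- min(tr, nchar(h) - 1L)
      id <- sprintf("q_%s_%03d", gsub("[^A-Za-z0-9]", "", sp), k)
      qrows[[id]] <- tibble(id = id, spacer = spacer,
                            residues = substring(h, tr + 1L))
      origin[[id]] <- tibble(id = id, species = sp, haplotype = h, trim = tr,
                             decoy = FALSE)
    }
  }
  # decoys: mutate a haplotype, rejection-sample against all allowed trims
  all_keys <- unlist(lapply(cell$haplotype, function(h) {
    substring(h, seq(1L, 1L + max(trims)))
  }))
  for (k in seq_len(n_decoys)) {
    repeat {
      h <- cell$haplotype[sample(nrow(cell), 1L)]
      chars <- strsplit(h, "", fixed = TRUE)[[1]]
      pos <- sample(length(chars), 1L)
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
      decoy <- paste(chars, collapse = "")
      if (!decoy %in% all_keys) break
    }
    id <- sprintf("decoy_%03d", k)
    qrows[[id]] <- tibble(id = id, spacer = spacer, residues = decoy)
    origin[[id]] <- tibble(id = id, species = NA_character_,
                           haplotype = NA_character_, trim = NA_integer_,
                           decoy = TRUE)
  }
  queries <- bind_rows(qrows)
  origin <- bind_rows(origin)
  metadata <- bind_rows(purrr::map(seq_len(nrow(origin)), function(i) {
    sp <- origin$species[i]
    m <- if (is.na(sp)) model[[sample(length(model), 1L)]] else model[[sp]]
    tibble(id = origin$id[i],
           substrate = sample(names(m$substrate), 1L, prob = m$substrate),
           biome = sample(names(m$biome), 1L, prob = m$biome),
           climate_zone = sample(names(m$climate_zone), 1L, prob = m$climate_zone),
           MAT = rnorm(1L, m$MAT[1L], m$MAT[2L]),
           MAP = rnorm(1L, m$MAP[1L], m$MAP[2L]))
  }))
  list(queries = queries, metadata = metadata,
       truth = list(origin = origin, metadata_model = model,
                    trim_probs = trim_probs, spacer = spacer))
}

default_metadata_model <- function(species) {
  tropical <- list(
    substrate = c(soil = 0.65, root = 0.2, litter = 0.15),
    biome = c(forest = 0.85, grassland = 0.15),
    climate_zone = c(Af = 0.5, Am = 0.3, Aw = 0.2),
    MAT = c(24, 2), MAP = c(2600, 300))
  temperate <- list(
    substrate = c(soil = 0.6, root = 0.25, deadwood = 0.15),
    biome = c(forest = 0.7, grassland = 0.2, cropland = 0.1),
    climate_zone = c(Cfb = 0.6, Dfb = 0.4),
    MAT = c(10, 3), MAP = c(900, 200))
  out <- lapply(seq_along(species), function(i) {
    if (i %% 2L == 1L) tropical else temperate
  })
  setNames(out, species)
}
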