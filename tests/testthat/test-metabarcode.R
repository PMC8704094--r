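toy_reference <- function() {
  # two Codinaeella-like species sharing their ITS1 but distinct in ITS2 by
  # two positions, plus a third species distinct everywhere
  shared_its1 <- "ACGTACGTACGTACGTACGT"
  its2_a <- "GGGGCCCCAAAATTTTGGCC"
  its2_b <- "GGGGCCCCAAAATTTTGGAA"  # 2 differences vs its2_a
  its2_c <- "TTTTGGGGCCCCAAAATTTT"
  spacers <- tibble::tibble(
    id = c("a1", "a2", "b1", "c1", "a1", "b1", "c1"),
    species = c("Sp minuta", "Sp minuta", "Sp filamentosa", "Sp lutea",
                "Sp minuta", "Sp filamentosa", "Sp lutea"),
    spacer = c("ITS1", "ITS1", "ITS1", "ITS1", "ITS2", "ITS2", "ITS2"),
    residues = c(shared_its1, shared_its1, shared_its1, "ACGTACGTACGTACGTAGGT",
                 its2_a, its2_b, its2_c))
  build_reference(spacers)
}

test_that("haplotype collapsing keeps one row per distinct sequence", {
  refs <- toy_reference()
  minuta_its1 <- refs[refs$species == "Sp minuta" & refs$spacer == "ITS1", ]
  expect_equal(nrow(minuta_its1), 1L)  # two identical records collapse
  expect_equal(minuta_its1$n_records, 2L)
  expect_setequal(minuta_its1$record_ids[[1]], c("a1", "a2"))

  # cross-species identical haplotypes are allowed and kept in both cells
  shared <- refs$haplotype[refs$spacer == "ITS1" &
                             refs$species %in% c("Sp minuta", "Sp filamentosa")]
  expect_equal(shared[1], shared[2])

  expect_error(build_reference(tibble::tibble(id = character(),
                                              species = character(),
                                              spacer = character(),
                                              residues = character())),
               "no delimited")
})

test_that("distinctiveness finds the per-spacer minimum difference", {
  refs <- toy_reference()
  dd <- distinctiveness(refs)
  shared <- dd[dd$spacer == "ITS1" & dd$speciesA == "Sp filamentosa" &
                 dd$speciesB == "Sp minuta", ]
  expect_equal(shared$min_diff, 0L)
  expect_false(shared$separable)

  its2 <- dd[dd$spacer == "ITS2" & dd$speciesA == "Sp filamentosa" &
               dd$speciesB == "Sp minuta", ]
  expect_equal(its2$min_diff, 2L)
  expect_true(its2$separable)
})

test_that("nested haplotypes still count as different", {
  refs <- build_reference(tibble::tibble(
    id = c("x1", "y1"), species = c("X", "Y"), spacer = "ITS2",
    residues = c("ACGTACGTACGT", "ACGTACGTACGTAA")))
  dd <- distinctiveness(refs)
  expect_equal(dd$min_diff, 2L)  # terminal extension, no internal difference
  expect_true(dd$separable)
})

test_that("exact matching honours the 100% rule and 5' trim tolerance", {
  refs <- toy_reference()
  h <- refs$haplotype[refs$species == "Sp lutea" & refs$spacer == "ITS2"]

  hit <- match_query(h, refs, "ITS2")
  expect_equal(hit$status, "unique")
  expect_equal(hit$species[[1]], "Sp lutea")
  expect_equal(hit$trim, 0L)

  # query equal to a haplotype minus its first 2 bases: trim offset 2
  hit2 <- match_query(substring(h, 3), refs, "ITS2")
  expect_equal(hit2$status, "unique")
  expect_equal(hit2$trim, 2L)

  # one internal mismatch means no assignment
  mm <- h
  substr(mm, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(h, 9, 9))[1]
  expect_equal(match_query(mm, refs, "ITS2")$status, "none")

  # trims beyond tolerance do not match
  expect_equal(match_query(substring(h, 4), refs, "ITS2")$status, "none")
  expect_equal(match_query(substring(h, 2), refs, "ITS2", trim_tol = 0)$status,
               "none")

  # N is a mismatch even against itself
  expect_equal(match_query(paste0("N", substring(h, 2)), refs, "ITS2")$status,
               "none")

  # a haplotype shared by k species yields ambiguous with k species
  shared <- refs$haplotype[refs$species == "Sp minuta" & refs$spacer == "ITS1"]
  amb <- match_query(shared, refs, "ITS1")
  expect_equal(amb$status, "ambiguous")
  expect_equal(length(amb$species[[1]]), 2L)
})

test_that("matching agrees with a brute-force scan on random cases", {
  withr::local_seed(17)
  refs <- toy_reference()
  hps <- refs[refs$spacer == "ITS2", ]
  for (i in 1:1000) {
    kind <- sample(c("exact", "trimmed", "mutated", "random"), 1)
    h <- hps$haplotype[sample(nrow(hps), 1)]
    q <- switch(kind,
                exact = h,
                trimmed = substring(h, sample(1:4, 1)),
                mutated = {
                  p <- sample(nchar(h), 1)
                  paste0(substr(h, 1, p - 1),
                         sample(c("A", "C", "G", "T", "N"), 1),
                         substring(h, p + 1))
                },
                random = random_dna(nchar(h)))
    got <- match_query(q, refs, "ITS2", trim_tol = 2)
    exp <- oracle_match(q, refs, "ITS2", trim_tol = 2)
    expect_equal(got$status, exp$status)
    expect_equal(got$species[[1]], exp$species)
    if (!is.na(got$trim)) expect_equal(got$trim, exp$trim)
  }
})

test_that("dataset assignment joins metadata and flags orphans", {
  refs <- toy_reference()
  sim <- simulate_env_reads(refs, n_per_species = 10, n_decoys = 5, seed = 23)
  asg <- assign_dataset(sim$queries, sim$metadata, refs)
  truth <- sim$truth$origin

  planted <- asg[!truth$decoy[match(asg$id, truth$id)], ]
  expect_true(all(planted$status == "unique"))
  expect_equal(vapply(planted$species, `[`, "", 1),
               truth$species[match(planted$id, truth$id)])

  decoys <- asg[truth$decoy[match(asg$id, truth$id)], ]
  expect_true(all(decoys$status == "none"))

  # empty query set yields an empty, well-formed table
  empty <- assign_dataset(sim$queries[0, ], sim$metadata, refs)
  expect_equal(nrow(empty), 0L)

  # missing metadata rows are flagged
  expect_warning(asg2 <- assign_dataset(sim$queries, sim$metadata[-1, ], refs),
                 "no metadata")
  expect_true(asg2$orphan[asg2$id == sim$metadata$id[1]])
})

test_that("species summaries recover the generating metadata model", {
  refs <- toy_reference()
  sim <- simulate_env_reads(refs, n_per_species = 120, n_decoys = 0, seed = 29)
  asg <- assign_dataset(sim$queries, sim$metadata, refs)
  sums <- summarize_species(asg)

  # ITS2 reads of the shared-ITS1 pair are species-resolved, so all three
  # species appear with their planted sample counts
  expect_setequal(sums$species, unique(refs$species))
  expect_true(all(sums$n_samples == 120L))

  for (i in seq_len(nrow(sums))) {
    model <- sim$truth$metadata_model[[sums$species[i]]]
    se <- model$MAT[2] / sqrt(sums$n_samples[i])
    expect_lt(abs(sums$mean_mat[i] - model$MAT[1]), 3 * se)
    se_map <- model$MAP[2] / sqrt(sums$n_samples[i])
    expect_lt(abs(sums$mean_map[i] - model$MAP[1]), 3 * se_map)
    expect_equal(sum(sums$substrate[[i]]), 1, tolerance = 1e-9)
  }
})

test_that("distribution types follow the configured climate-zone rule", {
  asg <- tibble::tibble(
    id = sprintf("q%02d", 1:30),
    spacer = "ITS2", residues = "ACGT",
    status = "unique",
    species = c(rep(list("Trop"), 10), rep(list("Temp"), 10),
                rep(list("Glob"), 10)),
    haplotype = "ACGT", trim = 0L, orphan = FALSE,
    substrate = "soil", biome = "forest",
    climate_zone = c(rep("Af", 9), "Cfb",            # 90% tropical
                     rep("Dfb", 5), rep("Cfb", 4), "Af",  # 90% temp+cont
                     rep("Af", 5), rep("Cfb", 3), rep("BWh", 2)),  # mixed
    MAT = 15, MAP = 1000)
  class(asg) <- c("assignment_table", class(asg))
  sums <- summarize_species(asg)
  expect_equal(sums$distribution_type[sums$species == "Trop"], "tropical")
  expect_equal(sums$distribution_type[sums$species == "Temp"],
               "temperate/continental")
  expect_equal(sums$distribution_type[sums$species == "Glob"], "global")

  # all samples one substrate: proportion 1
  expect_equal(unname(sums$substrate[[1]]["soil"]), 1)

  # stricter threshold flips the 90% tropical species to global
  strict <- summarize_species(asg, tropical_prop = 0.95)
  expect_equal(strict$distribution_type[strict$species == "Trop"], "global")
})
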