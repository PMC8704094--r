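two_species_partition <- function() {
  # 2 species x 2 strains, hand-set distances
  tbl <- tibble::tribble(
    ~idA, ~idB, ~distance,
    "a1", "a2", 0.002,
    "a1", "b1", 0.015,
    "a1", "b2", 0.020,
    "a2", "b1", 0.013,
    "a2", "b2", 0.018,
    "b1", "b2", 0.001)
  partition_distances(tbl, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
}

test_that("partitioning is exhaustive and respects species labels", {
  part <- two_species_partition()
  expect_equal(sum(part$type == "intra"), 2L)
  expect_equal(sum(part$type == "inter"), 4L)
  expect_true(all(part$speciesA[part$type == "intra"] ==
                    part$speciesB[part$type == "intra"]))

  # all strains one species: inter empty
  tbl <- tibble::tibble(idA = "x1", idB = "x2", distance = 0.01)
  p1 <- partition_distances(tbl, c(x1 = "X", x2 = "X"))
  expect_equal(sum(p1$type == "inter"), 0L)

  expect_error(partition_distances(tbl, c(x1 = "X")), "unlabeled")
})

test_that("partition bookkeeping matches n(n-1)/2 on a simulated genus", {
  sim <- simulate_genus(n_species = 4, strains_per_species = 3, length = 300,
                        seed = 21)
  tbl <- pairwise_distances(sim$sequences, mode = "msa")
  part <- partition_distances(tbl, sim$species_map)
  expect_equal(sum(part$type == "intra"), 12L)  # 4 * choose(3, 2)
  expect_equal(sum(part$type == "inter"), 54L)  # rest of choose(12, 2)
  n <- nrow(sim$sequences)
  expect_equal(nrow(part) + attr(part, "n_excluded"), n * (n - 1) / 2)
})

test_that("gap report computes bounds, overlap and undefined flags", {
  part <- two_species_partition()
  rep <- gap_report(part)
  expect_equal(rep$gap_low, 0.002)
  expect_equal(rep$gap_high, 0.013)
  expect_false(rep$overlap)
  expect_equal(rep$width, 0.011)
  g <- glance(rep)
  expect_equal(g$max_intra_pct, 0.2)

  # overlap when max intra exceeds min inter
  tbl <- tibble::tibble(idA = c("a1", "a1", "a2"), idB = c("a2", "b1", "b1"),
                        distance = c(0.02, 0.013, 0.014))
  p2 <- partition_distances(tbl, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_true(gap_report(p2)$overlap)

  # single species: inter side undefined, flagged not fatal
  p3 <- partition_distances(tibble::tibble(idA = "x1", idB = "x2",
                                           distance = 0.01),
                            c(x1 = "X", x2 = "X"))
  r3 <- gap_report(p3)
  expect_true(r3$undefined)
  expect_true(is.na(r3$min_inter))
})

test_that("masked distances are excluded with a count, not dropped silently", {
  tbl <- tibble::tibble(idA = c("a1", "a1", "a2"), idB = c("a2", "b1", "b1"),
                        distance = c(0.002, NA, 0.015))
  part <- partition_distances(tbl, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(attr(part, "n_excluded"), 1L)
  expect_equal(gap_report(part)$n_excluded, 1L)
})

test_that("histogram bins are right-closed with the first bin closed at zero", {
  part <- two_species_partition()
  h <- gap_histogram(part, 0.001)
  first_intra <- h$count[h$bin_low == 0 & h$type == "intra"]
  expect_equal(first_intra, 1L)  # 0.001 lands in (0, 0.001]

  # a value of exactly 0.0004 falls in the first bin
  tbl <- tibble::tibble(idA = "a1", idB = "a2", distance = 0.0004)
  p <- partition_distances(tbl, c(a1 = "A", a2 = "A"))
  h2 <- gap_histogram(p, 0.001)
  expect_equal(h2$count[h2$bin_low == 0 & h2$type == "intra"], 1L)

  # a value exactly on an interior edge joins the bin that ends there
  tbl3 <- tibble::tibble(idA = "a1", idB = "a2", distance = 0.002)
  p3 <- partition_distances(tbl3, c(a1 = "A", a2 = "A"))
  h3 <- gap_histogram(p3, 0.001)
  expect_equal(h3$count[abs(h3$bin_high - 0.002) < 1e-12 & h3$type == "intra"], 1L)

  expect_error(gap_histogram(part, 0), "bin_width")
})

test_that("histogram counts equal an independent counting oracle", {
  sim <- simulate_genus(n_species = 3, strains_per_species = 3, length = 400,
                        seed = 33)
  part <- partition_distances(pairwise_distances(sim$sequences, mode = "msa"),
                              sim$species_map)
  for (bw in c(0.001, 0.0005)) {
    h <- gap_histogram(part, bw)
    expect_equal(sum(h$count), nrow(part))
    for (type in c("intra", "inter")) {
      vals <- part$distance[part$type == type]
      sub <- h[h$type == type, ]
      for (r in seq_len(nrow(sub))) {
        bin_index <- as.integer(round(sub$bin_high[r] / bw))
        expect_equal(sub$count[r], oracle_hist_count(vals, bw, bin_index))
      }
    }
  }
})

test_that("no histogram bin strictly inside a clean gap holds counts", {
  part <- two_species_partition()
  rep <- gap_report(part)
  h <- gap_histogram(part, 0.001)
  inside <- h$bin_low >= rep$gap_low - 1e-12 & h$bin_high < rep$gap_high - 1e-12
  expect_true(all(h$count[inside] == 0L))
})

test_that("adding a smaller interspecific distance can only shrink the gap", {
  part <- two_species_partition()
  w0 <- gap_report(part)$width
  extra <- tibble::tibble(idA = "a1", idB = "c1", speciesA = "A",
                          speciesB = "C", type = "inter", distance = 0.005)
  part2 <- dplyr::bind_rows(tibble::as_tibble(part), extra)
  class(part2) <- class(part)
  attr(part2, "n_excluded") <- 0L
  expect_lt(gap_report(part2)$width, w0)
})

test_that("extreme pairs report the species-pair-level extrema", {
  part <- two_species_partition()
  ext <- extreme_pairs(part)
  expect_equal(ext$distance[ext$extreme == "min"], 0.013)
  expect_equal(ext$distance[ext$extreme == "max"], 0.020)
  expect_equal(ext$percent[ext$extreme == "min"], 1.3)

  # planted closest species pair in a simulated genus is recovered
  sim <- simulate_genus(n_species = 4, strains_per_species = 2, length = 2000,
                        intra_d = 0.002, inter_d = 0.02, seed = 55)
  seqs <- sim$sequences
  # plant a much closer pair: make Species_04 a near-copy of Species_03
  donor <- seqs$residues[seqs$species == "Species_03"][1]
  seqs$residues[seqs$species == "Species_04"] <-
    vapply(1:2, function(i) evolve_k2p(donor, 0.004, seed = 100 + i), "")
  part2 <- partition_distances(pairwise_distances(seqs, mode = "msa"),
                               sim$species_map)
  ext2 <- extreme_pairs(part2)
  expect_setequal(unlist(ext2[ext2$extreme == "min", c("speciesA", "speciesB")]),
                  c("Species_03", "Species_04"))

  p1 <- partition_distances(tibble::tibble(idA = "x1", idB = "x2",
                                           distance = 0.01),
                            c(x1 = "X", x2 = "X"))
  expect_error(extreme_pairs(p1), "two species")
})
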