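test_that("pair categories follow the canonical/wobble vocabulary", {
  expect_equal(pair_category("G", "C"), "canonical")
  expect_equal(pair_category("A", "U"), "canonical")
  expect_equal(pair_category("G", "U"), "wobble")
  expect_equal(pair_category("A", "C"), "wobble")
  expect_equal(pair_category("A", "C", ac_wobble = FALSE), "noncanonical")
  expect_equal(pair_category("A", "A"), "noncanonical")
  expect_equal(pair_category("G", "-"), "gapped")
  expect_equal(pair_category("N", "C"), "gapped")
  expect_equal(pair_category("G", "T"), "wobble")  # DNA input read as RNA
})

test_that("classification reproduces the definitional examples", {
  expect_equal(classify_pair_change("GC", "CG"), "CBC")
  expect_equal(classify_pair_change("GC", "AU"), "CBC")
  expect_equal(classify_pair_change("GC", "GU"), "hCBC")
  expect_equal(classify_pair_change("AU", "AC"), "hCBC")
  expect_equal(classify_pair_change("GU", "GC"), "hCBC")
  expect_equal(classify_pair_change("AU", "AA"), "nonCBC")
  expect_equal(classify_pair_change("GC", "GC"), "identical")
  expect_equal(classify_pair_change("GC", "UG"), "combined")
  expect_equal(classify_pair_change("GC", "-C"), "indeterminate")
})

test_that("classification matches the exhaustive enumerated fixture", {
  fix <- read.table(test_path("fixtures", "pair-change-classes.tsv"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(fix), 256L)
  got <- classify_pair_change(fix$pairA, fix$pairB)
  expect_equal(got, fix$class)
})

test_that("classification is total, deterministic, and symmetric where defined", {
  states <- apply(expand.grid(c("A", "C", "G", "U", "N", "-"),
                              c("A", "C", "G", "U", "N", "-")),
                  1, paste, collapse = "")
  grid <- expand.grid(a = states, b = states, stringsAsFactors = FALSE)
  cls_ab <- classify_pair_change(grid$a, grid$b)
  cls_ba <- classify_pair_change(grid$b, grid$a)
  expect_true(all(cls_ab %in% c("identical", "CBC", "hCBC", "nonCBC",
                                "combined", "indeterminate")))
  sym <- cls_ab %in% c("identical", "CBC", "nonCBC", "combined", "indeterminate")
  expect_equal(cls_ab[sym], cls_ba[sym])
  # hCBC is symmetric too (direction flips but the class does not)
  expect_equal(cls_ab[cls_ab == "hCBC"], cls_ba[cls_ab == "hCBC"])
})

its2_toy <- function() {
  # two helices: H2 = 4 pairs, H3 = 5 pairs, with loops between
  db <- "((((....))))..(((((.....)))))"
  spans <- data.frame(label = c("H2", "H3"), start = c(1, 15), end = c(12, 29))
  # build a template whose bracketed positions all hold canonical pairs
  struct <- parse_dotbracket(db, spans)
  chars <- rep("A", struct$length)
  canon <- c("GC", "CG", "AU", "UA")
  withr::with_seed(1, {
    for (k in seq_len(nrow(struct$pairs))) {
      p <- sample(canon, 1)
      chars[struct$pairs$pos5[k]] <- substr(p, 1, 1)
      chars[struct$pairs$pos3[k]] <- substr(p, 2, 2)
    }
  })
  list(template = chartr("U", "T", paste(chars, collapse = "")),
       struct = struct)
}

test_that("identical alignment rows yield no events anywhere", {
  toy <- its2_toy()
  aln <- seq_tbl(c("a", "b"), rep(toy$template, 2),
                 species = c("SpA", "SpB"), locus = "ITS2")
  ev <- enumerate_events(aln, toy$struct)
  expect_equal(nrow(ev), 0L)
  expect_equal(sum(loop_mutations(ev)$n_diff), 0L)
})

test_that("planted events are recovered exactly per helix and class", {
  toy <- its2_toy()
  plant <- plant_structure_events(
    toy$template, toy$struct,
    data.frame(class = c("CBC", "hCBC"), helix = c("H2", "H3"),
               count = c(2L, 3L)),
    seed = 9)
  aln <- seq_tbl(c("a", "b"), c(toy$template, plant$variant),
                 species = c("SpA", "SpB"), locus = "ITS2")
  ev <- enumerate_events(aln, toy$struct)
  expect_equal(sum(ev$class == "CBC" & ev$helix == "H2"), 2L)
  expect_equal(sum(ev$class == "hCBC" & ev$helix == "H3"), 3L)
  expect_equal(nrow(ev), 5L)
  # positions agree with the planted truth
  expect_setequal(ev$pos5, plant$truth$pos5)
})

test_that("event totals account for every structural pair", {
  toy <- its2_toy()
  plant <- plant_structure_events(toy$template, toy$struct,
                                  list(c("nonCBC", "H3", 1)), seed = 4)
  aln <- seq_tbl(c("a", "b"), c(toy$template, plant$variant),
                 species = c("SpA", "SpB"), locus = "ITS2")
  ev <- enumerate_events(aln, toy$struct, include_identical = TRUE)
  expect_equal(nrow(ev), attr(ev, "n_structural_pairs") *
                 attr(ev, "n_species_pairs"))
  expect_equal(sum(ev$class == "nonCBC"), 1L)
})

test_that("events are invariant under gap-column reindexing", {
  toy <- its2_toy()
  plant <- plant_structure_events(toy$template, toy$struct,
                                  list(c("CBC", "H2", 1), c("hCBC", "H3", 2)),
                                  seed = 13)
  aln <- seq_tbl(c("a", "b"), c(toy$template, plant$variant),
                 species = c("SpA", "SpB"), locus = "ITS2")
  ev0 <- glance(enumerate_events(aln, toy$struct))

  # insert a shared gap column mid-sequence: same pair map, shifted columns
  at <- 14L
  gapped <- vapply(aln$residues, function(s) {
    paste0(substr(s, 1, at - 1), "-", substr(s, at, nchar(s)))
  }, "")
  ungapped_struct <- toy$struct
  proj <- project_structure(ungapped_struct, gapped[1])
  aln2 <- seq_tbl(aln$id, unname(gapped), species = aln$species, locus = "ITS2")
  ev1 <- glance(enumerate_events(aln2, proj))
  expect_equal(ev1, ev0)
})

test_that("multi-haplotype species are collapsed by majority rule and flagged", {
  toy <- its2_toy()
  plant <- plant_structure_events(toy$template, toy$struct,
                                  list(c("CBC", "H2", 1)), seed = 2)
  # SpA has 3 strains, one diverging at an unpaired site only
  divergent <- toy$template
  loop_pos <- toy$struct$unpaired[5]
  substr(divergent, loop_pos, loop_pos) <- "T"
  aln <- seq_tbl(c("a1", "a2", "a3", "b1"),
                 c(toy$template, toy$template, divergent, plant$variant),
                 species = c("SpA", "SpA", "SpA", "SpB"), locus = "ITS2")
  ev <- enumerate_events(aln, toy$struct)
  expect_equal(attr(ev, "consensus_ambiguous"), "SpA")
  expect_equal(sum(ev$class == "CBC"), 1L)  # majority masks the minority strain
})

test_that("CBC species support requires a CBC against every congener", {
  ev <- tibble::tibble(
    speciesA = c("X", "X", "X", "Y"),
    speciesB = c("Y", "Z", "W", "Z"),
    helix = "H2", pos5 = 1L, pos3 = 10L, pairA = "GC", pairB = "CG",
    class = c("CBC", "CBC", "CBC", "hCBC"))
  class(ev) <- c("event_table", class(ev))
  expect_equal(cbc_species_support(ev), "X")

  ev$class <- "hCBC"
  expect_equal(cbc_species_support(ev), character(0))
})

test_that("reference-species mode compares every species to the reference", {
  toy <- its2_toy()
  plant <- plant_structure_events(toy$template, toy$struct,
                                  list(c("CBC", "H3", 1)), seed = 3)
  aln <- seq_tbl(c("a", "b", "c"),
                 c(toy$template, plant$variant, toy$template),
                 species = c("Ref", "SpB", "SpC"), locus = "ITS2")
  ev <- enumerate_events(aln, toy$struct, reference_species = "Ref")
  expect_equal(attr(ev, "mode"), "vs_reference")
  expect_equal(attr(ev, "n_species_pairs"), 2L)
  expect_true(all(ev$speciesA == "Ref"))
})
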