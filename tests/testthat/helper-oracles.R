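# Independent oracles used across tests. These deliberately take the
# slow/obvious route (per-site loops, regex reduction, exhaustive scans) so
# they share no code path with the package implementation.

seq_tbl <- function(ids, residues, species = NA_character_, locus = "ITS") {
  tibble::tibble(id = ids, species = species, locus = locus, residues = residues)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# loop-based substitution counting (pairwise deletion), independent of
# substitution_counts()
oracle_counts <- function(rowA, rowB) {
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  L <- 0L; s <- 0L; v <- 0L
  transitions <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T")) {
      L <- L + 1L
      if (a[i] != b[i]) {
        is_ts <- any(vapply(transitions, function(p) {
          a[i] == p[1] && b[i] == p[2]
        }, TRUE))
        if (is_ts) s <- s + 1L else v <- v + 1L
      }
    }
  }
  list(L = L, s = s, v = v)
}

oracle_k2p <- function(L, s, v) {
  if (L == 0) return(NA_real_)
  P <- s / L; Q <- v / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

# dot-bracket matcher by iterative innermost reduction (regex-style), not a
# stack
oracle_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pairs <- NULL
  repeat {
    found <- FALSE
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "(") {
        j <- i + 1L
        while (j <= length(chars) && chars[j] == ".") j <- j + 1L
        if (j <= length(chars) && chars[j] == ")") {
          pairs <- rbind(pairs, c(i, j))
          chars[c(i, j)] <- "."
          found <- TRUE
        }
      }
      i <- i + 1L
    }
    if (!found) break
  }
  if (is.null(pairs)) {
    matrix(integer(0), ncol = 2)
  } else {
    pairs[order(pairs[, 1]), , drop = FALSE]
  }
}

random_balanced_dotbracket <- function(n_pairs, n_dots) {
  # random push/pop walk that never goes negative, dots sprinkled in
  symbols <- character(0)
  open <- 0L; remaining <- n_pairs
  while (remaining > 0L || open > 0L) {
    can_open <- remaining > 0L
    can_close <- open > 0L
    choice <- sample(c(if (can_open) "(", if (can_close) ")", "."), 1L)
    if (choice == "(") { open <- open + 1L; remaining <- remaining - 1L }
    if (choice == ")") open <- open - 1L
    symbols <- c(symbols, choice)
  }
  extra <- sample(0:n_dots, 1L)
  out <- paste(c(symbols, rep(".", extra)), collapse = "")
  if (nchar(out) == 0L) "." else out
}

# brute-force matcher: scan every haplotype and every allowed 5' trim
oracle_match <- function(query, haplos, spacer, trim_tol) {
  cell <- haplos[haplos$spacer == spacer, ]
  hits <- NULL
  for (i in seq_len(nrow(cell))) {
    h <- cell$haplotype[i]
    for (k in 0:trim_tol) {
      if (k >= nchar(h)) next
      trimmed <- substring(h, k + 1)
      if (grepl("N", trimmed) || grepl("N", query)) next
      if (identical(query, trimmed)) {
        hits <- rbind(hits, data.frame(species = cell$species[i], trim = k))
      }
    }
  }
  if (is.null(hits)) {
    return(list(status = "none", species = character(0), trim = NA_integer_))
  }
  species <- sort(unique(hits$species))
  list(status = if (length(species) == 1) "unique" else "ambiguous",
       species = species, trim = min(hits$trim))
}

# counting oracle for histograms: first bin [0, w], then (kw, (k+1)w]
oracle_hist_count <- function(values, bin_width, bin_index) {
  lo <- (bin_index - 1) * bin_width
  hi <- bin_index * bin_width
  if (bin_index == 1) sum(values >= 0 & values <= hi + 1e-12)
  else sum(values > lo + 1e-12 & values <= hi + 1e-12)
}

# tiny planted-alignment builder for event tests
with_fixed_seed <- function(seed, code) withr::with_seed(seed, code)
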