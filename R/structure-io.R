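#' Parse a dot-bracket secondary structure with helix annotations
#'
#' Builds a base-pair map from dot-bracket notation by stack matching and
#' assigns each pair to the helix whose span contains its 5' position. The
#' ITS2 ring model used throughout the package has three main helices H1-H3
#' (helix H4 is absent in the target genera); pairs outside every span get the
#' label `"other"`.
#'
#' Coordinates are 1-based, closed intervals.
#'
#' @param structure_text Dot-bracket string over `(`, `)` and `.`.
#' @param helix_spans Helix spans: a data frame with columns `label`, `start`,
#'   `end`, or a list of `c(label, start, end)` triples. Spans may not overlap.
#' @return A `secondary_structure` object: list with `length`, `pairs` (tibble
#'   `pos5`, `pos3`, `helix`) and `unpaired` (integer positions).
#' @examples
#' parse_dotbracket("((..))", data.frame(label = "H1", start = 1, end = 6))
#' @export
parse_dotbracket <- function(structure_text, helix_spans = NULL) {
  chars <- strsplit(structure_text, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) abort("empty structure string")
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    abort(sprintf("illegal structure character '%s' at position %d",
                  chars[bad[1L]], bad[1L]))
  }
  stack <- integer(0)
  p5 <- integer(0)
  p3 <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        abort(sprintf("unbalanced brackets: unmatched ')' at position %d", i))
      }
      p5 <- c(p5, stack[length(stack)])
      p3 <- c(p3, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    abort(sprintf("unbalanced brackets: unmatched '(' at position %d",
                  stack[length(stack)]))
  }
  spans <- as_helix_spans(helix_spans, length(chars))
  helix <- assign_helix(p5, spans)
  ord <- order(p5)
  pairs <- tibble(pos5 = p5[ord], pos3 = p3[ord], helix = helix[ord])
  unpaired <- setdiff(seq_along(chars), c(p5, p3))
  new_secondary_structure(length(chars), pairs, unpaired)
}

new_secondary_structure <- function(length, pairs, unpaired) {
  structure(list(length = as.integer(length), pairs = pairs,
                 unpaired = as.integer(sort(unpaired))),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> length", x$length, "nt,",
      nrow(x$pairs), "base pairs,", length(x$unpaired), "unpaired\n")
  if (nrow(x$pairs) > 0) {
    tally <- table(x$pairs$helix)
    cat("  helices:", paste(names(tally), tally, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

as_helix_spans <- function(helix_spans, len) {
  if (is.null(helix_spans)) {
    return(tibble(label = character(), start = integer(), end = integer()))
  }
  if (!is.data.frame(helix_spans)) {
    helix_spans <- do.call(rbind, lapply(helix_spans, function(s) {
      data.frame(label = as.character(s[[1L]]), start = as.integer(s[[2L]]),
                 end = as.integer(s[[3L]]))
    }))
  }
  spans <- as_tibble(helix_spans[, c("label", "start", "end")])
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  if (any(spans$start > spans$end)) abort("helix span with start > end")
  if (any(spans$start < 1L) || any(spans$end > len)) {
    abort("helix span outside the structure length")
  }
  if (nrow(spans) > 1L) {
    ord <- order(spans$start)
    s <- spans[ord, ]
    if (any(s$start[-1L] <= s$end[-nrow(s)])) abort("overlapping helix spans")
  }
  spans
}

assign_helix <- function(pos5, spans) {
  if (length(pos5) == 0L) return(character(0))
  out <- rep("other", length(pos5))
  for (k in seq_len(nrow(spans))) {
    hit <- pos5 >= spans$start[k] & pos5 <= spans$end[k]
    out[hit] <- spans$label[k]
  }
  out
}

#' Read a structure file (sequence, dot-bracket, helix spans)
#'
#' File format: line 1 the sequence, line 2 the dot-bracket string, lines 3+
#' helix spans as `label<TAB>start<TAB>end`.
#'
#' @param path Path to the structure file.
#' @return A list with `sequence` (character) and `structure`
#'   (a [parse_dotbracket()] result).
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 2L) abort("structure file needs a sequence and a structure line")
  seq <- toupper(trimws(lines[1L]))
  db <- trimws(lines[2L])
  if (nchar(seq) != nchar(db)) {
    abort("sequence and structure lines differ in length")
  }
  spans <- NULL
  if (length(lines) > 2L) {
    parts <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
    spans <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) != 3L) abort("helix span lines must be label<TAB>start<TAB>end")
      data.frame(label = p[1L], start = as.integer(p[2L]), end = as.integer(p[3L]))
    }))
  }
  list(sequence = seq, structure = parse_dotbracket(db, spans))
}

#' Write a structure file
#'
#' @param sequence Sequence string matching the structure length.
#' @param structure A `secondary_structure` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(sequence, structure, path) {
  stopifnot(inherits(structure, "secondary_structure"))
  if (nchar(sequence) != structure$length) {
    abort("sequence length does not match the structure")
  }
  db <- rep(".", structure$length)
  db[structure$pairs$pos5] <- "("
  db[structure$pairs$pos3] <- ")"
  spans <- helix_spans_of(structure)
  lines <- c(sequence, paste(db, collapse = ""),
             sprintf("%s\t%d\t%d", spans$label, spans$start, spans$end))
  writeLines(lines, path)
  invisible(path)
}

# recover contiguous helix spans (over pos5) from pair labels
helix_spans_of <- function(structure) {
  pr <- structure$pairs
  pr <- pr[pr$helix != "other", ]
  if (nrow(pr) == 0L) {
    return(tibble(label = character(), start = integer(), end = integer()))
  }
  pr %>%
    group_by(.data$helix) %>%
    summarise(start = min(.data$pos5), end = max(.data$pos5), .groups = "drop") %>%
    rename(label = "helix")
}

#' Project an ungapped structure onto alignment coordinates
#'
#' Maps a structure given on the ungapped coordinates of one reference
#' sequence onto the columns of an alignment, using the gapped reference row.
#' Alignment columns that are gaps in the reference become unpaired.
#'
#' @param structure A `secondary_structure` on ungapped reference coordinates.
#' @param reference_row The aligned (gapped) reference sequence.
#' @return A `secondary_structure` on alignment coordinates.
#' @export
project_structure <- function(structure, reference_row) {
  chars <- strsplit(reference_row, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-")
  if (length(residue_cols) != structure$length) {
    abort(sprintf(paste0("reference row has %d residues but the structure ",
                         "covers %d positions"),
                  length(residue_cols), structure$length))
  }
  pairs <- structure$pairs
  pairs$pos5 <- residue_cols[pairs$pos5]
  pairs$pos3 <- residue_cols[pairs$pos3]
  unpaired <- setdiff(seq_along(chars), c(pairs$pos5, pairs$pos3))
  new_secondary_structure(length(chars), pairs, unpaired)
}
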