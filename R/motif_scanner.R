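#' Construct a mature protein sequence record
#'
#' A light container for one mature (signal-peptide-removed) protein
#' sequence. `numbering_offset` gives the residue label of the first residue,
#' so printed precursor-frame positions (e.g. Cys33 of a protein whose mature
#' region starts at residue 18) can be reproduced without renumbering.
#'
#' @param id character identifier.
#' @param residues amino-acid string; lowercase input is uppercased.
#' @param numbering_offset integer >= 1, residue label of the first residue.
#' @param phylum optional label: `"Ascomycota"`, `"Basidiomycota"` or
#'   `"unknown"`.
#' @param class_annotation optional label: `"I"`, `"II"`, `"none"` or
#'   `"unknown"`.
#' @return An object of class `mature_sequence`.
#' @examples
#' mature_sequence("toy", "GCAACCTTGGCAACCAATTCCGGCATT")
#' @export
mature_sequence <- function(id, residues, numbering_offset = 1L,
                            phylum = "unknown", class_annotation = "unknown") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L,
            nchar(residues) > 0L)
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L)
    stop("numbering_offset must be an integer >= 1")
  phylum <- match.arg(phylum, c("unknown", "Ascomycota", "Basidiomycota"))
  class_annotation <- match.arg(class_annotation,
                                c("unknown", "I", "II", "none"))
  structure(list(id = id, residues = toupper(residues),
                 numbering_offset = numbering_offset,
                 phylum = phylum, class_annotation = class_annotation),
            class = "mature_sequence")
}

#' @export
print.mature_sequence <- function(x, ...) {
  cat(sprintf("<mature_sequence> %s (%d aa, first residue %d, %s/%s)\n",
              x$id, nchar(x$residues), x$numbering_offset,
              x$phylum, x$class_annotation))
  invisible(x)
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# residue labels (sequence numbering frame) of all cysteines
cys_positions <- function(seq) {
  res <- strsplit(seq$residues, "")[[1]]
  which(res == "C") + seq$numbering_offset - 1L
}

# does an ascending 8-vector of residue positions form C, CC, C, C, CC, C?
# doublets are C2C3 and C6C7; all other neighbours must be non-adjacent.
is_canonical_arrangement <- function(pos) {
  d <- diff(pos)
  d[2] == 1L && d[6] == 1L && all(d[c(1, 3, 4, 5, 7)] >= 2L)
}

new_cys_pattern <- function(positions) {
  positions <- as.integer(positions)
  structure(list(positions = positions,
                 doublets = list(c(2L, 3L), c(6L, 7L)),
                 segment_lengths = diff(positions) - 1L),
            class = "cys_pattern")
}

#' Scan a sequence for the canonical eight-cysteine hydrophobin arrangement
#'
#' The hydrophobin family is defined by eight conserved cysteines arranged as
#' C, CC, C, C, CC, C (C1..C8, with adjacent doublets C2C3 and C6C7). In
#' `"strict"` mode a sequence is canonical iff it contains exactly eight
#' cysteines in that arrangement. In `"tolerant"` mode sequences with more
#' than eight cysteines are accepted when at least one 8-subset of their
#' cysteines forms the arrangement (all matching subsets are reported),
#' which supports mining noisier sequence sets.
#'
#' @param seq a [mature_sequence()].
#' @param mode `"strict"` (default) or `"tolerant"`.
#' @return A list of class `scan_result` with elements `canonical` (logical),
#'   `pattern` (a `cys_pattern` with positions `C1..C8` in the sequence's
#'   numbering frame, or `NULL`), `reason` (string, `""` when canonical) and,
#'   in tolerant mode, `all_patterns` (list of every matching subset).
#' @examples
#' s <- mature_sequence("toy", "AACAACCAAACAAACAAACCAAACAA")
#' scan_canonical(s)$canonical
#' @export
scan_canonical <- function(seq, mode = c("strict", "tolerant")) {
  mode <- match.arg(mode)
  res <- strsplit(seq$residues, "")[[1]]
  bad <- setdiff(unique(res), c(AA_ALPHABET20, "X"))
  if (length(bad) > 0L)
    return(scan_result(FALSE, reason = paste0(
      "invalid_letters:", paste(sort(bad), collapse = ""))))
  pos <- cys_positions(seq)
  nc <- length(pos)
  if (mode == "strict") {
    if (nc != 8L)
      return(scan_result(FALSE, reason = "cys_count!=8"))
    if (!is_canonical_arrangement(pos))
      return(scan_result(FALSE, reason = "doublet_arrangement_mismatch"))
    return(scan_result(TRUE, pattern = new_cys_pattern(pos)))
  }
  # tolerant: every 8-subset forming the arrangement
  if (nc < 8L)
    return(scan_result(FALSE, reason = "cys_count!=8"))
  hits <- tolerant_matches(pos)
  if (length(hits) == 0L)
    return(scan_result(FALSE, reason = "doublet_arrangement_mismatch"))
  out <- scan_result(TRUE, pattern = new_cys_pattern(hits[[1L]]))
  out$all_patterns <- lapply(hits, new_cys_pattern)
  out
}

scan_result <- function(canonical, pattern = NULL, reason = "") {
  structure(list(canonical = canonical, pattern = pattern, reason = reason),
            class = "scan_result")
}

# enumerate 8-subsets matching the arrangement without full combn blowup:
# choose the two adjacent doublets first, then singlets in the gaps.
tolerant_matches <- function(pos) {
  n <- length(pos)
  adj <- which(diff(pos) == 1L)          # i where (pos[i], pos[i+1]) adjacent
  hits <- list()
  for (d1 in adj) for (d2 in adj) {
    if (d2 <= d1 + 1L) next              # doublets ordered, non-overlapping
    left  <- pos[pos < pos[d1] - 1L]                         # C1 candidates
    mid   <- pos[pos > pos[d1 + 1L] + 1L & pos < pos[d2] - 1L]  # C4, C5
    right <- pos[pos > pos[d2 + 1L] + 1L]                    # C8 candidates
    if (length(mid) < 2L) next
    midpairs <- utils::combn(mid, 2L, simplify = FALSE)
    midpairs <- Filter(function(p) p[2] - p[1] >= 2L, midpairs)
    for (c1 in left) for (mp in midpairs) for (c8 in right) {
      hits[[length(hits) + 1L]] <-
        c(c1, pos[d1], pos[d1 + 1L], mp, pos[d2], pos[d2 + 1L], c8)
    }
  }
  unique(hits)
}

#' Inter-cysteine spacing features of a canonical pattern
#'
#' Returns the seven inter-cysteine segment lengths (residue counts strictly
#' between consecutive cysteines, in C1 to C8 order) plus the N- and
#' C-terminal tail lengths. Classically, hydrophobins were divided into Class
#' I and II on the basis of exactly these spacings.
#'
#' @param pattern a `cys_pattern` from [scan_canonical()].
#' @param seq the [mature_sequence()] the pattern came from (needed for the
#'   tail lengths); omit for segment lengths only.
#' @return Named integer vector `L1..L7` plus, when `seq` is given, `n_tail`
#'   and `c_tail`.
#' @export
spacing_features <- function(pattern, seq = NULL) {
  stopifnot(inherits(pattern, "cys_pattern"))
  segs <- pattern$segment_lengths
  names(segs) <- paste0("L", 1:7)
  if (is.null(seq)) return(segs)
  first <- seq$numbering_offset
  last <- seq$numbering_offset + nchar(seq$residues) - 1L
  c(segs,
    n_tail = pattern$positions[1L] - first,
    c_tail = last - pattern$positions[8L])
}

#' Canonical hydrophobin disulfide connectivity
#'
#' Applies the family's conserved disulfide-bonding rule C1-C6, C2-C5,
#' C3-C4, C7-C8 to the eight cysteine positions of a canonical pattern,
#' yielding four unordered residue-number pairs. For the *S. commune*
#' hydrophobin SC16 (cysteines at 33, 40, 41, 76, 89, 95, 96, 109) this
#' reproduces the experimentally observed pairs (33,95), (40,89), (41,76)
#' and (96,109).
#'
#' @param pattern a `cys_pattern` from [scan_canonical()].
#' @return A 4x2 integer matrix, one row per disulfide, each row sorted
#'   ascending, rows ordered by first position.
#' @export
canonical_connectivity <- function(pattern) {
  stopifnot(inherits(pattern, "cys_pattern"))
  p <- pattern$positions
  pairs <- rbind(c(p[1], p[6]), c(p[2], p[5]), c(p[3], p[4]), c(p[7], p[8]))
  pairs <- t(apply(pairs, 1L, sort))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("cys_a", "cys_b"))
  pairs
}

#' Scan a batch of sequences and tabulate results
#'
#' @param seqs list of [mature_sequence()] objects.
#' @param mode passed to [scan_canonical()].
#' @return A data.frame with one row per sequence: `id`, `canonical`,
#'   `C1..C8`, `L1..L7`, `n_tail`, `c_tail`, `reason`.
#' @export
scan_batch <- function(seqs, mode = "strict") {
  rows <- lapply(seqs, function(s) {
    r <- scan_canonical(s, mode = mode)
    if (r$canonical) {
      sf <- spacing_features(r$pattern, s)
      pos <- as.list(r$pattern$positions)
      names(pos) <- paste0("C", 1:8)
      c(list(id = s$id, canonical = TRUE), pos, as.list(sf),
        list(reason = ""))
    } else {
      nas <- as.list(rep(NA_integer_, 17L))
      names(nas) <- c(paste0("C", 1:8), paste0("L", 1:7), "n_tail", "c_tail")
      c(list(id = s$id, canonical = FALSE), nas, list(reason = r$reason))
    }
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
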