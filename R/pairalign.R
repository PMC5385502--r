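#' Retrieve a substitution matrix by name
#'
#' Looks up the scoring matrices shipped with Biostrings (BLOSUM45/50/62/80/
#' 100, PAM30/40/70/120/250). A user-supplied square numeric matrix with
#' matching dimnames is passed through unchanged.
#'
#' @param matrix matrix name (e.g. `"BLOSUM62"`) or a numeric matrix.
#' @return A square numeric substitution matrix with residue dimnames.
#' @export
substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) {
    if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
      stop("substitution matrix must be square with identical row/col names")
    return(matrix)
  }
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!matrix %in% known)
    stop("unknown substitution matrix: ", matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

seq_string <- function(x) {
  if (inherits(x, "mature_sequence")) x$residues else toupper(as.character(x))
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under an affine gap model: a gap run of
#' length k costs `gap_open + (k - 1) * gap_extend`. The traceback is
#' deterministic, preferring diagonal over up (gap in `b`) over left (gap in
#' `a`) on ties.
#'
#' @param a,b sequences (strings or [mature_sequence()] objects), non-empty.
#' @param matrix substitution matrix name or matrix (see
#'   [substitution_matrix()]).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return A list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `matrix_name`, `gap_open`,
#'   `gap_extend`.
#' @examples
#' global_align("ACDE", "ACDE")$score
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  sa <- seq_string(a); sb <- seq_string(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("both sequences must be non-empty")
  S <- substitution_matrix(matrix)
  ra <- strsplit(sa, "")[[1]]; rb <- strsplit(sb, "")[[1]]
  miss <- setdiff(unique(c(ra, rb)), rownames(S))
  if (length(miss) > 0L)
    stop("residues absent from substitution matrix: ",
         paste(miss, collapse = ", "))
  scores <- S[ra, rb, drop = FALSE]
  storage.mode(scores) <- "double"
  dp <- affine_dp(scores, gap_open, gap_extend)
  ga <- ifelse(dp$a_index == 0L, "-", ra[pmax(dp$a_index, 1L)])
  gb <- ifelse(dp$b_index == 0L, "-", rb[pmax(dp$b_index, 1L)])
  structure(list(aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = dp$score,
                 matrix_name = if (is.matrix(matrix)) "custom" else matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 a_index = dp$a_index, b_index = dp$b_index),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f (%s, open %g extend %g)\n",
              x$score, x$matrix_name, x$gap_open, x$gap_extend))
  cat(x$aligned_a, "\n"); cat(x$aligned_b, "\n")
  invisible(x)
}

# resolve a span request into alignment-column indices.
# span is interpreted on the ungapped coordinates of sequence `a`:
#   "all", "first_to_last_cys", "core" (first Cys to C-terminus),
#   or an integer c(start, end) in a's 1-based ungapped coordinates.
span_columns <- function(aln, span) {
  na <- max(aln$a_index)
  if (is.character(span)) {
    span <- match.arg(span, c("all", "first_to_last_cys", "core"))
    if (span == "all") return(seq_along(aln$a_index))
    resa <- strsplit(gsub("-", "", aln$aligned_a), "")[[1]]
    cys <- which(resa == "C")
    if (length(cys) == 0L)
      stop("span '", span, "' needs at least one cysteine in sequence a")
    rng <- if (span == "first_to_last_cys") c(cys[1L], cys[length(cys)])
           else c(cys[1L], na)
  } else {
    rng <- as.integer(span)
    if (length(rng) != 2L || any(is.na(rng)) || rng[1L] < 1L ||
        rng[2L] > na || rng[1L] > rng[2L])
      stop("span out of range for sequence a")
  }
  ca <- which(aln$a_index == rng[1L])
  cb <- which(aln$a_index == rng[2L])
  ca:cb
}

aln_chars <- function(aln) {
  list(a = strsplit(aln$aligned_a, "")[[1]],
       b = strsplit(aln$aligned_b, "")[[1]])
}

#' Percent identity of an alignment over a span
#'
#' Identity = identical residue columns / total alignment columns within the
#' span (gapped columns count in the denominator by default; set
#' `ungapped_only = TRUE` to restrict the denominator to columns with a
#' residue in both rows). Spans are resolved on sequence `a`:
#' `"first_to_last_cys"` covers its first to last cysteine (the convention
#' behind hydrophobin identity figures such as SC16 vs SC3), `"core"` its
#' first cysteine to the C-terminus.
#'
#' @param aln a `pairwise_alignment`.
#' @param span `"all"`, `"first_to_last_cys"`, `"core"`, or `c(start, end)`
#'   in `a`'s ungapped 1-based coordinates.
#' @param ungapped_only logical, see above.
#' @return Percentage in `[0, 100]`, rounded to 0.1.
#' @export
percent_identity <- function(aln, span = "all", ungapped_only = FALSE) {
  cols <- span_columns(aln, span)
  ch <- aln_chars(aln)
  a <- ch$a[cols]; b <- ch$b[cols]
  both <- a != "-" & b != "-"
  denom <- if (ungapped_only) sum(both) else length(cols)
  if (denom == 0L) return(0)
  round(100 * sum(both & a == b) / denom, 1L)
}

#' Percent similarity of an alignment over a span
#'
#' As [percent_identity()], but a column counts when its substitution-matrix
#' score is strictly positive (gap columns never count).
#'
#' @inheritParams percent_identity
#' @param matrix substitution matrix used to judge similarity; defaults to
#'   the one the alignment was built with.
#' @return Percentage in `[0, 100]`, rounded to 0.1.
#' @export
percent_similarity <- function(aln, span = "all", matrix = NULL,
                               ungapped_only = FALSE) {
  S <- substitution_matrix(if (is.null(matrix)) aln$matrix_name else matrix)
  cols <- span_columns(aln, span)
  ch <- aln_chars(aln)
  a <- ch$a[cols]; b <- ch$b[cols]
  both <- a != "-" & b != "-"
  sim <- both
  sim[both] <- S[cbind(a[both], b[both])] > 0
  denom <- if (ungapped_only) sum(both) else length(cols)
  if (denom == 0L) return(0)
  round(100 * sum(sim) / denom, 1L)
}

# ---- multiple alignment ----------------------------------------------------

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) == 1L)
  structure(list(ids = ids, rows = rows, n_columns = nchar(rows[[1L]])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

# encode an MSA row set as an integer matrix (codes into symbol table)
msa_codes <- function(msa, symbols) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  matrix(match(m, symbols), nrow = nrow(m))
}

# augmented substitution matrix: gap row/column scoring 0 against everything
augment_gap <- function(S) {
  S2 <- rbind(cbind(S, 0), 0)
  rownames(S2) <- colnames(S2) <- c(rownames(S), "-")
  S2
}

# profile = list(freq = L x nsym frequency matrix, rows = gapped strings)
profile_of <- function(rows, symbols) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  f <- matrix(0, nrow = L, ncol = length(symbols),
              dimnames = list(NULL, symbols))
  for (s in seq_along(symbols))
    f[, s] <- colSums(m == symbols[s]) / nrow(m)
  list(freq = f, rows = rows)
}

align_profiles <- function(p1, p2, S2, gap_open, gap_extend) {
  # expected substitution score between columns; gap symbol scores 0
  scores <- p1$freq %*% S2 %*% t(p2$freq)
  dp <- affine_dp(scores, gap_open, gap_extend)
  gap1 <- paste(rep("-", length(dp$a_index)), collapse = "")
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  list(rows1 = expand(p1$rows, dp$a_index),
       rows2 = expand(p2$rows, dp$b_index))
}

#' Progressive multiple sequence alignment
#'
#' A desk-scale progressive aligner: pairwise global alignments give a
#' distance matrix (1 - fractional identity), a neighbour-joining guide tree
#' is built with \pkg{ape}, and profiles are merged leaf-to-root with the
#' same affine-gap scoring used pairwise (gap symbols score zero in the
#' expected column score). Intended for simulated or small curated sets;
#' import an external alignment (e.g. MAFFT output) via [read_fasta_msa()]
#' or [read_clustal()] for production-scale sets.
#'
#' @param seqs list of sequences ([mature_sequence()] or strings); length
#'   >= 2 (a single sequence is returned as a 1-row MSA with a warning).
#' @inheritParams global_align
#' @return An `msa` object: `ids`, `rows` (equal-length gapped strings, one
#'   per input, same order), `n_columns`.
#' @export
progressive_msa <- function(seqs, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  ids <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(s, "mature_sequence")) s$id
    else if (!is.null(names(seqs)[i]) && nzchar(names(seqs)[i])) names(seqs)[i]
    else paste0("seq", i)
  }, character(1L))
  strs <- vapply(seqs, seq_string, character(1L))
  n <- length(strs)
  if (n == 1L) {
    warning("single sequence: returning it as a 1-row MSA")
    return(new_msa(ids, strs))
  }
  S <- substitution_matrix(matrix)
  S2 <- augment_gap(S)
  symbols <- rownames(S2)

  if (n == 2L) {
    aln <- global_align(strs[1L], strs[2L], matrix, gap_open, gap_extend)
    return(new_msa(ids, c(aln$aligned_a, aln$aligned_b)))
  }

  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- global_align(strs[i], strs[j], S, gap_open, gap_extend)
    D[i, j] <- D[j, i] <- 1 - percent_identity(aln, "all") / 100
  }
  dimnames(D) <- list(ids, ids)
  merges <- guide_tree_merges(D)

  profiles <- lapply(strs, function(s) profile_of(s, symbols))
  members <- as.list(seq_len(n))
  for (mg in merges) {
    i <- mg[1L]; j <- mg[2L]
    al <- align_profiles(profiles[[i]], profiles[[j]], S2,
                         gap_open, gap_extend)
    rows <- c(al$rows1, al$rows2)
    profiles[[i]] <- profile_of(rows, symbols)
    members[[i]] <- c(members[[i]], members[[j]])
    profiles[j] <- list(NULL)   # keep slot positions stable
    members[[j]] <- integer(0)
  }
  root <- which(vapply(members, length, integer(1L)) == n)
  ord <- order(members[[root]])
  new_msa(ids, profiles[[root]]$rows[ord])
}

# post-order merge schedule (pairs of cluster slot indices) from an NJ tree
guide_tree_merges <- function(D) {
  n <- nrow(D)
  tr <- ape::nj(stats::as.dist(D))
  tr <- ape::reorder.phylo(tr, "postorder")
  # slot of each node: tips start in their own slot, internals fill in
  slot <- integer(max(tr$edge))
  slot[seq_len(n)] <- seq_len(n)
  merges <- list()
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  for (node in unique(tr$edge[, 1L])) {   # postorder parents
    kids <- children[[as.character(node)]]
    s <- slot[kids[1L]]
    for (k in kids[-1L]) {
      merges[[length(merges) + 1L]] <- c(s, slot[k])
    }
    slot[node] <- s
  }
  merges
}

#' Degap an MSA row back to its source sequence
#' @param msa an `msa` object.
#' @param i row index.
#' @return Ungapped string.
#' @export
msa_degap <- function(msa, i) gsub("-", "", msa$rows[[i]])
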