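#' Pairwise substitution-score similarity matrix of an alignment
#'
#' For every pair of rows of an MSA, sums the substitution-matrix score over
#' aligned columns; columns where either row carries a gap contribute zero.
#' The resulting symmetric matrix is the "sequence alignment matrix" whose
#' principal components organise hydrophobin sequence space.
#'
#' @param msa an `msa` object.
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @return An `n x n` symmetric numeric matrix with sequence ids as dimnames.
#' @export
pairwise_score_matrix <- function(msa, matrix = "BLOSUM62") {
  if (!inherits(msa, "msa") || length(msa$ids) == 0L)
    stop("non-empty msa required")
  S2 <- augment_gap(substitution_matrix(matrix))
  S2["-", ] <- 0; S2[, "-"] <- 0
  symbols <- rownames(S2)
  codes <- msa_codes(msa, symbols)
  if (anyNA(codes))
    stop("alignment contains symbols absent from the substitution matrix")
  n <- nrow(codes)
  out <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (cc in seq_len(ncol(codes))) {
    v <- codes[, cc]
    out <- out + S2[v, v, drop = FALSE]
  }
  out
}

#' Principal components of a similarity matrix
#'
#' Double-centers a symmetric similarity matrix (subtract row means and
#' column means, add the grand mean), eigendecomposes it, and scales each
#' eigenvector by the square root of its (non-negative part of the)
#' eigenvalue to give per-sequence coordinates. Components are ordered by
#' descending eigenvalue; each component's sign is fixed so that its
#' largest-magnitude loading is positive. Eigenvalues below `1e-9` times the
#' largest are reported as zero.
#'
#' @param S symmetric numeric matrix (e.g. from [pairwise_score_matrix()]).
#' @param k number of components to keep, `1 <= k <= nrow(S)`.
#' @return A list of class `projection`: `eigenvalues` (all `n`,
#'   non-increasing), `coordinates` (`n x k` matrix, columns `PC1..PCk`),
#'   `component_count`.
#' @export
eigen_project <- function(S, k = 2L) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("S must be a square matrix")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  n <- nrow(S)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and nrow(S)")
  rm_ <- rowMeans(S); cm_ <- colMeans(S); gm <- mean(S)
  B <- S - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  vals[abs(vals) < 1e-9 * max(abs(vals), .Machine$double.eps)] <- 0
  coords <- sapply(seq_len(k), function(m) {
    v <- e$vectors[, m]
    if (v[which.max(abs(v))] < 0) v <- -v
    v * sqrt(max(vals[m], 0))
  })
  coords <- matrix(coords, nrow = n,
                   dimnames = list(rownames(S), paste0("PC", seq_len(k))))
  structure(list(eigenvalues = vals, coordinates = coords,
                 component_count = k),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %d sequences, %d components; top eigenvalues: %s\n",
              nrow(x$coordinates), x$component_count,
              paste(signif(utils::head(x$eigenvalues, 3L), 4), collapse = ", ")))
  invisible(x)
}
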