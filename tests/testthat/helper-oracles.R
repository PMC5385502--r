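# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations they check.

# exhaustive 8-subset scan oracle: TRUE iff some 8-subset of the cysteine
# positions has the C, CC, C, C, CC, C shape (doublet gaps 0, others >= 1)
oracle_has_canonical_subset <- function(residues) {
  pos <- which(strsplit(residues, "")[[1]] == "C")
  if (length(pos) < 8L) return(FALSE)
  subsets <- utils::combn(pos, 8L, simplify = FALSE)
  any(vapply(subsets, function(p) {
    d <- diff(p)
    d[2] == 1 && d[6] == 1 && all(d[c(1, 3, 4, 5, 7)] >= 2)
  }, logical(1L)))
}

oracle_strict_canonical <- function(residues) {
  pos <- which(strsplit(residues, "")[[1]] == "C")
  length(pos) == 8L && oracle_has_canonical_subset(residues)
}

random_test_sequence <- function(max_len = 60L, max_cys = 10L) {
  n <- sample(8:max_len, 1L)
  ncys <- sample(0:max_cys, 1L)
  res <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C"),
                n, replace = TRUE)
  if (ncys > 0L) res[sample(n, min(ncys, n))] <- "C"
  paste(res, collapse = "")
}

# brute-force global affine alignment score by enumerating every alignment.
# state: positions i, j; last move (0 none, 1 diag, 2 up, 3 left).
# gap run of length k costs open + (k - 1) * extend.
oracle_align_score <- function(a, b, S, open, extend) {
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  na <- length(ra); nb <- length(rb)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > na && j > nb) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, 1L, acc + S[ra[i], rb[j]])
    if (i <= na)
      rec(i + 1L, j, 2L, acc - if (last == 2L) extend else open)
    if (j <= nb)
      rec(i, j + 1L, 3L, acc - if (last == 3L) extend else open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# cyclic Jacobi eigenvalue iteration for symmetric matrices
oracle_jacobi_eigenvalues <- function(A, sweeps = 50L, tol = 1e-12) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (s in seq_len(sweeps)) {
    off <- sum(A[upper.tri(A)]^2)
    if (off < tol) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) < 1e-300) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t_ <- 1
      cs <- 1 / sqrt(t_^2 + 1); sn <- t_ * cs
      J <- diag(n); J[p, p] <- cs; J[q, q] <- cs
      J[p, q] <- sn; J[q, p] <- -sn
      A <- t(J) %*% A %*% J
    }
  }
  sort(diag(A), decreasing = TRUE)
}

# analytic SASA of two equal spheres of accessible radius R at distance d:
# each loses a cap of height h = R - d/2 (area 2*pi*R*h)
oracle_two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# quaternion (Horn) method optimal-superposition RMSD
oracle_quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, R, t_) {
  sweep(xyz %*% t(R), 2, t_, `+`)
}

# the printed SC16 facts used by desk-scale checks
sc16_cys_positions <- c(33L, 40L, 41L, 76L, 89L, 95L, 96L, 109L)
sc16_printed_pairs <- rbind(c(33L, 95L), c(40L, 89L), c(41L, 76L), c(96L, 109L))
sc16_strand_spans <- list(b1 = c(38L, 46L), b2 = c(71L, 79L),
                          b3 = c(92L, 100L), b4 = c(105L, 111L))
sc16_helix_span <- c(52L, 60L)

# synthetic SC16-like mature sequence (printed Cys positions, offset 18)
sc16_synthetic <- function() {
  p <- system.file("extdata", "sc16_synthetic.fasta", package = "hydrin")
  read_fasta(p, numbering_offset = 18L)[[1L]]
}
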