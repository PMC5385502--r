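#' Van der Waals radii used for surface calculations (Angstrom)
#' @format Named numeric vector, element symbol to radius.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

new_structure_model <- function(atoms, model = 1L, radii = VDW_RADII) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "resno", "resname", "chain",
                  "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  structure(list(model = model, atoms = atoms, radii = radii),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> model %d: %d atoms, residues %d-%d\n",
              x$model, nrow(x$atoms), min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

# element from PDB atom name when the element field is blank: strip digits
# and primes, take the first letter; two-letter elements must come through
# the element column (NMR/X-ray protein deposits are H/C/N/O/S/P).
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  toupper(substr(nm, 1L, 1L))
}

#' Read a PDB file into one structure model per MODEL record
#'
#' Parsing is delegated to [bio3d::read.pdb()]; files without MODEL records
#' yield a single model. Element symbols missing from the deposit are
#' inferred from the atom name (digits and primes stripped, first letter).
#'
#' @param path PDB-format file.
#' @return List of `structure_model` objects.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  elem[blank] <- infer_element(at$elety[blank])
  nmodels <- nrow(pdb$xyz)
  lapply(seq_len(nmodels), function(mi) {
    xyz <- matrix(pdb$xyz[mi, ], ncol = 3L, byrow = TRUE)
    new_structure_model(data.frame(
      name = at$elety, element = elem, resno = at$resno,
      resname = at$resid, chain = at$chain,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE), model = mi)
  })
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 0.5) * 2
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_xyz <- function(m, subset = NULL) {
  a <- m$atoms
  if (!is.null(subset)) a <- a[subset, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

atom_radii <- function(m, subset = NULL) {
  a <- m$atoms
  if (!is.null(subset)) a <- a[subset, , drop = FALSE]
  r <- m$radii[a$element]
  if (anyNA(r))
    stop("no radius for element(s): ",
         paste(unique(a$element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic test-point SASA: each atom's solvent-accessible sphere (van der
#' Waals radius + probe) is sampled with a deterministic quasi-uniform
#' point set; points buried inside any neighbour's accessible sphere are
#' occluded, and the exposed fraction scales the sphere area.
#'
#' @param m a `structure_model` (or a subset via `subset`, a logical/integer
#'   index into its atom table).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points test points per sphere (default 960).
#' @param subset optional atom subset; SASA is computed for the subset in
#'   isolation.
#' @return A list of class `sasa_result`: `area` (per-atom SASA, Angstrom^2),
#'   `total`, `probe`, `n_points`, `atoms` (the atom table used).
#' @export
shrake_rupley_sasa <- function(m, probe = 1.4, n_points = 960L,
                               subset = NULL) {
  xyz <- atom_xyz(m, subset)
  rad <- atom_radii(m, subset) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists via squared-distance threshold
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- sweep(pts * rad[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(p[free, , drop = FALSE], 2L, xyz[j, ])^2)
      free[free] <- dj2 > rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  a <- m$atoms
  if (!is.null(subset)) a <- a[subset, , drop = FALSE]
  structure(list(area = area, total = sum(area), probe = probe,
                 n_points = n_points, atoms = a),
            class = "sasa_result")
}

#' Hydrophobic fraction of solvent accessible surface area
#'
#' The apolar share of the surface: SASA summed over carbon and sulfur
#' atoms within a residue span, divided by SASA over all atoms in the span.
#'
#' @param sasa a `sasa_result`.
#' @param span residue-number range `c(lo, hi)` (inclusive); `NULL` for all.
#' @return Percentage in `[0, 100]`.
#' @export
hydrophobic_fraction <- function(sasa, span = NULL) {
  a <- sasa$atoms
  keep <- if (is.null(span)) rep(TRUE, nrow(a))
          else a$resno >= span[1L] & a$resno <= span[2L]
  if (!any(keep)) stop("empty residue span")
  tot <- sum(sasa$area[keep])
  if (tot == 0) return(0)
  apolar <- keep & a$element %in% c("C", "S")
  100 * sum(sasa$area[apolar]) / tot
}

#' Detect disulfide bonds from cysteine sulfur geometry
#'
#' Pairs cysteine Sg (SG) atoms whose distance is at most `max_ss`, greedily
#' by ascending distance so each sulfur joins at most one bridge.
#'
#' @param m a `structure_model`.
#' @param max_ss maximum S-S distance in Angstrom (default 2.5).
#' @return Integer matrix with columns `cys_a`, `cys_b` (residue numbers,
#'   each row sorted), possibly 0 rows.
#' @export
detect_disulfides <- function(m, max_ss = 2.5) {
  a <- m$atoms
  sg <- which(a$resname == "CYS" & trimws(a$name) == "SG")
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("cys_a", "cys_b")))
  if (length(sg) < 2L) return(out)
  xyz <- atom_xyz(m, sg)
  cand <- which(upper.tri(matrix(0, length(sg), length(sg))), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[cand[, 1L], , drop = FALSE] -
                     xyz[cand[, 2L], , drop = FALSE])^2))
  ok <- d <= max_ss
  cand <- cand[ok, , drop = FALSE]; d <- d[ok]
  used <- logical(length(sg))
  for (k in order(d)) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, sort(c(a$resno[sg[i]], a$resno[sg[j]])))
  }
  out[order(out[, 1L]), , drop = FALSE]
}

#' Optimal rigid superposition RMSD (Kabsch)
#'
#' Least-squares rigid-body superposition (rotation + translation, no
#' reflection) of paired coordinate sets, returning the RMSD over the pairs.
#'
#' @param A,B numeric `n x 3` coordinate matrices.
#' @param pairing 2-column integer matrix of index correspondences (row of A,
#'   row of B); defaults to row-by-row pairing.
#' @return RMSD in the units of the coordinates.
#' @export
kabsch_rmsd <- function(A, B, pairing = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (is.null(pairing)) {
    if (nrow(A) != nrow(B)) stop("A and B differ in size; give a pairing")
    pairing <- cbind(seq_len(nrow(A)), seq_len(nrow(A)))
  }
  P <- A[pairing[, 1L], , drop = FALSE]
  Q <- B[pairing[, 2L], , drop = FALSE]
  if (nrow(P) < 3L) stop("need at least 3 paired atoms")
  P <- sweep(P, 2L, colMeans(P)); Q <- sweep(Q, 2L, colMeans(Q))
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], .Machine$double.eps))
    stop("degenerate (collinear) coordinate set")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P %*% t(R)
  sqrt(mean(rowSums((Pr - Q)^2)))
}

# average residue masses (Da) and the mass of water
RESIDUE_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Molecular weight of a protein sequence
#'
#' Average isotopic residue masses plus one water; cysteines are counted
#' reduced (no disulfide mass correction).
#'
#' @param seq sequence string or [mature_sequence()]; standard residues only.
#' @param unit `"kDa"` (default, rounded to 0.1) or `"Da"`.
#' @return Molecular weight.
#' @export
molecular_weight <- function(seq, unit = c("kDa", "Da")) {
  unit <- match.arg(unit)
  s <- seq_string(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  res <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(res), names(RESIDUE_MASS))
  if (length(bad) > 0L)
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  da <- sum(RESIDUE_MASS[res]) + WATER_MASS
  if (unit == "Da") da else round(da / 1000, 1L)
}

#' Principal-axis bounding dimensions of a structure
#'
#' Rotates the coordinates onto their principal axes and reports the extents
#' along the three axes, ascending -- a "bounding box" statement of molecular
#' size such as 17 x 17 x 35 Angstrom.
#'
#' @param m a `structure_model`.
#' @param subset optional atom subset.
#' @return Numeric length-3 vector, ascending, in Angstrom.
#' @export
bounding_dimensions <- function(m, subset = NULL) {
  xyz <- atom_xyz(m, subset)
  if (nrow(xyz) < 2L) stop("need at least 2 atoms")
  ctr <- sweep(xyz, 2L, colMeans(xyz))
  rot <- ctr %*% eigen(crossprod(ctr), symmetric = TRUE)$vectors
  sort(apply(rot, 2L, function(v) diff(range(v))))
}

#' Hydrophobic surface area buried between two parts of a structure
#'
#' The apolar (carbon + sulfur) SASA of each part computed in isolation,
#' minus the apolar SASA of the complex, halved: the per-side hydrophobic
#' area hidden at the interface (e.g. between an amphipathic helix and the
#' beta-barrel it packs against).
#'
#' @param m a `structure_model`.
#' @param span_a,span_b disjoint residue-number ranges `c(lo, hi)`.
#' @param probe,n_points passed to [shrake_rupley_sasa()].
#' @return Buried hydrophobic area per side, Angstrom^2.
#' @export
buried_hydrophobic_area <- function(m, span_a, span_b,
                                    probe = 1.4, n_points = 960L) {
  if (max(span_a[1L], span_b[1L]) <= min(span_a[2L], span_b[2L]))
    stop("spans overlap")
  a <- m$atoms
  in_a <- a$resno >= span_a[1L] & a$resno <= span_a[2L]
  in_b <- a$resno >= span_b[1L] & a$resno <= span_b[2L]
  if (!any(in_a) || !any(in_b)) stop("empty span")
  apolar_area <- function(subset) {
    s <- shrake_rupley_sasa(m, probe, n_points, subset = which(subset))
    sum(s$area[s$atoms$element %in% c("C", "S")])
  }
  (apolar_area(in_a) + apolar_area(in_b) - apolar_area(in_a | in_b)) / 2
}

#' Count disulfides linking two sets of residue spans
#'
#' Utility for topology statements such as "two disulfide bonds lie within
#' the beta-barrel": counts pairs with both partners inside spans drawn from
#' `spans` (a list of `c(lo, hi)` ranges).
#'
#' @param pairs 2-column matrix of residue-number pairs.
#' @param spans list of inclusive residue ranges.
#' @return Number of pairs with both members inside (any of) the spans.
#' @export
count_pairs_within_spans <- function(pairs, spans) {
  inside <- function(r) any(vapply(spans,
    function(s) r >= s[1L] && r <= s[2L], logical(1L)))
  sum(apply(pairs, 1L, function(p) inside(p[1L]) && inside(p[2L])))
}
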