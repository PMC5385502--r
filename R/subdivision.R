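#' Partition the PC1/PC2 plane into an equal-sized rectangular grid
#'
#' Covers the occupied extent of the first two components (padded by 1% of
#' each range, split evenly between the two sides; a degenerate zero range is
#' padded by 0.5 absolute) with `nx * ny` equal-sized, axis-aligned,
#' non-overlapping cells. Membership uses half-open intervals `[lo, hi)`
#' except the last cell along each axis, which is closed, so every point in
#' bounds falls in exactly one cell.
#'
#' @param proj a `projection` with at least 2 components.
#' @param nx,ny cell counts along PC1 and PC2 (>= 1).
#' @return A list of class `region_grid`: `bounds` (named vector x0,x1,y0,y1),
#'   `nx`, `ny`, `membership` (integer cell index 1..nx*ny per sequence,
#'   named by id), `cells` (data.frame of cell rectangles, index = (iy-1)*nx+ix).
#' @export
partition <- function(proj, nx = 7L, ny = 2L) {
  if (!inherits(proj, "projection") || proj$component_count < 2L)
    stop("projection with >= 2 components required")
  if (nrow(proj$coordinates) == 0L) stop("empty projection")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  x <- proj$coordinates[, 1L]; y <- proj$coordinates[, 2L]
  pad <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w2 <- 0.5 else w2 <- 0.005 * w
    c(r[1L] - w2, r[2L] + w2)
  }
  bx <- pad(x); by <- pad(y)
  cell_of <- function(v, lo, hi, ncell) {
    idx <- floor((v - lo) / (hi - lo) * ncell) + 1L
    pmin.int(pmax.int(as.integer(idx), 1L), ncell)
  }
  ix <- cell_of(x, bx[1L], bx[2L], nx)
  iy <- cell_of(y, by[1L], by[2L], ny)
  membership <- (iy - 1L) * nx + ix
  names(membership) <- rownames(proj$coordinates)
  xs <- seq(bx[1L], bx[2L], length.out = nx + 1L)
  ys <- seq(by[1L], by[2L], length.out = ny + 1L)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cells$index <- (cells$iy - 1L) * nx + cells$ix
  cells$x0 <- xs[cells$ix]; cells$x1 <- xs[cells$ix + 1L]
  cells$y0 <- ys[cells$iy]; cells$y1 <- ys[cells$iy + 1L]
  structure(list(bounds = c(x0 = bx[1L], x1 = bx[2L],
                            y0 = by[1L], y1 = by[2L]),
                 nx = nx, ny = ny, membership = membership,
                 cells = cells[order(cells$index), ]),
            class = "region_grid")
}

#' Majority consensus sequence of an alignment subset
#'
#' Per column of the alignment, restricted to the member rows: the most
#' frequent symbol wins, with the gap symbol eligible only when it is the
#' strict majority (> 0.5) of the column. The winner is emitted when its
#' fraction reaches `threshold`, otherwise the column is written as `"x"`.
#' Per-column support (the winner's fraction) is recorded.
#'
#' @param msa an `msa`.
#' @param members character ids (must all be in the MSA) or integer row
#'   indices; non-empty.
#' @param threshold minimum winning fraction in `(0, 1]`; default 0.5.
#' @return A list of class `consensus_sequence`: `letters` (string over the
#'   residue alphabet plus `x` and `-`), `support` (numeric per column).
#' @export
region_consensus <- function(msa, members, threshold = 0.5) {
  idx <- resolve_members(msa, members)
  if (length(idx) == 0L) stop("empty member set")
  m <- do.call(rbind, strsplit(msa$rows[idx], ""))
  cons <- character(ncol(m)); supp <- numeric(ncol(m))
  for (cc in seq_len(ncol(m))) {
    tab <- table(m[, cc])
    frac <- as.numeric(tab) / nrow(m)
    names(frac) <- names(tab)
    gap_frac <- if ("-" %in% names(frac)) frac[["-"]] else 0
    if (gap_frac > 0.5) {
      winner <- "-"; wfrac <- gap_frac
    } else {
      res <- frac[names(frac) != "-"]
      winner <- names(res)[which.max(res)]
      wfrac <- max(res)
    }
    supp[cc] <- wfrac
    cons[cc] <- if (wfrac >= threshold) winner else "x"
  }
  structure(list(letters = paste(cons, collapse = ""), support = supp),
            class = "consensus_sequence")
}

resolve_members <- function(msa, members) {
  if (is.character(members)) {
    idx <- match(members, msa$ids)
    if (anyNA(idx)) stop("members not in MSA: ",
                         paste(members[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(members)
}

#' Composition summary and label for one grid cell
#'
#' Tabulates phylum and class-annotation fractions over the cell's members
#' and assigns a label: `II` when at least `frac` of annotated members are
#' Class II; `IA` (`IB`) when at least `frac` are Class I and at least `frac`
#' are Ascomycota (Basidiomycota); `sparse` when fewer than `min_n` members;
#' otherwise `mixed`.
#'
#' @param grid a `region_grid`.
#' @param cell cell index.
#' @param annotations data.frame with columns `id`, `phylum`,
#'   `class_annotation` (labels as in [mature_sequence()]).
#' @param frac purity threshold (default 0.8).
#' @param min_n occupancy below which an unlabelled cell is called `sparse`
#'   rather than `mixed` (default 3).
#' @return A list of class `region_summary`: `cell`, `n_sequences`,
#'   `phylum_fractions`, `class_fractions`, `label`.
#' @export
summarize_region <- function(grid, cell, annotations, frac = 0.8, min_n = 3L) {
  ids <- names(grid$membership)[grid$membership == cell]
  n <- length(ids)
  ann <- annotations[match(ids, annotations$id), , drop = FALSE]
  ann <- ann[!is.na(ann$id), , drop = FALSE]
  pf <- prop.table(table(factor(ann$phylum,
                                c("Ascomycota", "Basidiomycota", "unknown"))))
  cf <- prop.table(table(factor(ann$class_annotation,
                                c("I", "II", "none", "unknown"))))
  label <- if (nrow(ann) > 0L && cf[["II"]] >= frac) "II"
    else if (nrow(ann) > 0L && cf[["I"]] >= frac && pf[["Ascomycota"]] >= frac) "IA"
    else if (nrow(ann) > 0L && cf[["I"]] >= frac && pf[["Basidiomycota"]] >= frac) "IB"
    else if (n < min_n) "sparse"
    else "mixed"
  structure(list(cell = cell, n_sequences = n,
                 phylum_fractions = pf, class_fractions = cf,
                 label = label),
            class = "region_summary")
}

#' Pairwise percent-identity table over MSA rows
#'
#' Column identity between already-aligned rows (no realignment): identical
#' residue columns over columns where at least one of the two rows has a
#' residue (both-gap columns are skipped).
#'
#' @param msa an `msa`.
#' @param members >= 2 ids or row indices.
#' @return A list: `matrix` (symmetric percent identities, 100 on the
#'   diagonal) and `mean` (mean of the off-diagonal upper triangle).
#' @export
identity_table <- function(msa, members) {
  idx <- resolve_members(msa, members)
  if (length(idx) < 2L) stop("need >= 2 members")
  m <- do.call(rbind, strsplit(msa$rows[idx], ""))
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(msa$ids[idx], msa$ids[idx]))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    keep <- !(a == "-" & b == "-")
    pid <- if (!any(keep)) 0 else
      round(100 * sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep), 1L)
    out[i, j] <- out[j, i] <- pid
  }
  list(matrix = out, mean = mean(out[upper.tri(out)]))
}
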