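#' Built-in class specifications for synthetic hydrophobin-like sequences
#'
#' Returns a `sequence_class_spec`: a class label, mean/sd/min for the seven
#' inter-cysteine segment lengths and the two tails, a concrete residue
#' template drawn once (deterministically from `template_seed`), and
#' substitution/indel rates. The three stylized defaults mirror the
#' field's description of the classes rather than any measured profile:
#' Class II short, low-variance segments (high conservation); Class IA long
#' loop segments; Class IB segment lengths matching the SC16 spacing
#' (6, 0, 34, 12, 5, 0, 12). Spacing alone separates the three.
#'
#' @param class_label `"IA"`, `"IB"` or `"II"`.
#' @param substitution_rate per-site substitution probability (non-cysteine
#'   sites), default 0.02.
#' @param indel_rate per-segment probability of a 1-residue length change,
#'   default 0.05.
#' @param template_seed seed for the deterministic template draw.
#' @return A list of class `sequence_class_spec`.
#' @export
class_spec <- function(class_label = c("IA", "IB", "II"),
                       substitution_rate = 0.02, indel_rate = 0.05,
                       template_seed = 20170410L) {
  class_label <- match.arg(class_label)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  seg_mean <- switch(class_label,
    II = c(7, 0, 11, 16, 8, 0, 6),
    IA = c(10, 0, 26, 5, 18, 0, 18),
    IB = c(6, 0, 34, 12, 5, 0, 12))
  tails <- switch(class_label,
    II = c(10, 3), IA = c(12, 4), IB = c(15, 7))
  template <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(template_seed + match(class_label, c("IA", "IB", "II")))
    build_canonical(seg_mean, tails)
  })
  structure(list(class_label = class_label, seg_mean = seg_mean,
                 seg_sd = rep(1, 7), seg_min = pmax(seg_mean - 3, 0),
                 tails = tails, template = template,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate),
            class = "sequence_class_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

NONCYS <- setdiff(AA_ALPHABET20, "C")

random_residues <- function(n) {
  if (n <= 0L) return("")
  paste(sample(NONCYS, n, replace = TRUE), collapse = "")
}

# assemble a canonical sequence from segment lengths (doublets length 0)
build_canonical <- function(seg_len, tails) {
  seg_len <- as.integer(round(seg_len))
  stopifnot(length(seg_len) == 7L, seg_len[2L] == 0L, seg_len[6L] == 0L,
            all(seg_len[c(1, 3, 4, 5, 7)] >= 1L))
  paste0(random_residues(tails[1L]),
         "C", random_residues(seg_len[1L]),
         "CC", random_residues(seg_len[3L]),
         "C", random_residues(seg_len[4L]),
         "C", random_residues(seg_len[5L]),
         "CC", random_residues(seg_len[7L]),
         "C", random_residues(tails[2L]))
}

mutate_canonical <- function(template, spec) {
  ch <- strsplit(template, "")[[1]]
  noncys <- which(ch != "C")
  hit <- noncys[stats::runif(length(noncys)) < spec$substitution_rate]
  if (length(hit) > 0L)
    ch[hit] <- sample(NONCYS, length(hit), replace = TRUE)
  s <- paste(ch, collapse = "")
  if (spec$indel_rate > 0 && stats::runif(1) < spec$indel_rate) {
    # 1-residue indel, never touching a Cys and never fusing two Cys
    ch2 <- strsplit(s, "")[[1]]
    n2 <- length(ch2)
    left <- c("^", ch2[-n2]); right <- c(ch2[-1L], "$")
    del_ok <- which(ch2 != "C" & !(left == "C" & right == "C"))
    if (stats::runif(1) < 0.5 && length(del_ok) > 0L && n2 > 20L) {
      p <- sample(del_ok, 1L)
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, n2))
    } else {
      p <- sample(which(ch2 != "C"), 1L)
      s <- paste0(substr(s, 1L, p), sample(NONCYS, 1L),
                  substr(s, p + 1L, n2))
    }
  }
  s
}

#' Generate class-structured canonical hydrophobin-like sequences
#'
#' Every record carries exactly eight cysteines in the canonical C, CC, C,
#' C, CC, C arrangement; substitutions and 1-residue indels perturb the
#' class template at the spec's rates. Output is bit-reproducible for a
#' fixed seed.
#'
#' @param spec a [class_spec()] (or list of them, one block per spec).
#' @param n sequences per spec (>= 1).
#' @param seed integer seed.
#' @return A list: `sequences` (list of [mature_sequence()]), `truth`
#'   (data.frame id, class_label, phylum, template).
#' @export
gen_sequences <- function(spec, n, seed = 1L) {
  if (inherits(spec, "sequence_class_spec")) spec <- list(spec)
  stopifnot(n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seqs <- list(); truth <- list()
  for (sp in spec) {
    phylum <- switch(sp$class_label, IB = "Basidiomycota", "Ascomycota")
    klass <- if (sp$class_label == "II") "II" else "I"
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", sp$class_label, i)
      s <- mutate_canonical(sp$template, sp)
      seqs[[id]] <- mature_sequence(id, s, phylum = phylum,
                                    class_annotation = klass)
      truth[[id]] <- data.frame(id = id, class_label = sp$class_label,
                                phylum = phylum, template = sp$template,
                                stringsAsFactors = FALSE)
    }
  }
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Generate sequences violating the canonical arrangement
#'
#' Negative controls for the scanner: each record breaks the canonical
#' pattern in one recorded way -- 7 cysteines, 9 cysteines, or 8 cysteines
#' with no adjacent doublet -- so none passes a strict scan.
#'
#' @param n number of sequences (>= 1).
#' @param seed integer seed.
#' @return A list: `sequences`, `truth` (data.frame id, defect).
#' @export
gen_negatives <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  defects <- rep_len(c("cys7", "cys9", "no_doublet"), n)
  base_spec <- class_spec("IB")
  seqs <- list(); truth <- list()
  for (i in seq_len(n)) {
    tmpl <- mutate_canonical(base_spec$template, base_spec)
    ch <- strsplit(tmpl, "")[[1]]
    cys <- which(ch == "C")
    s <- switch(defects[i],
      cys7 = paste(ch[-sample(cys, 1L)], collapse = ""),
      cys9 = {
        at <- sample(which(ch != "C" & c(ch[-1L], "Z") != "C" &
                           c("Z", ch[-length(ch)]) != "C"), 1L)
        paste0(substr(tmpl, 1L, at), "C", substr(tmpl, at + 1L, nchar(tmpl)))
      },
      no_doublet = {
        # pad one residue inside each doublet: no CC remains
        for (d in rev(cys[c(2L, 6L)])) {
          tmpl <- paste0(substr(tmpl, 1L, d),
                         sample(NONCYS, 1L),
                         substr(tmpl, d + 1L, nchar(tmpl)))
        }
        tmpl
      })
    id <- sprintf("neg_%03d", i)
    seqs[[id]] <- mature_sequence(id, s, class_annotation = "none")
    truth[[id]] <- data.frame(id = id, defect = defects[i],
                              stringsAsFactors = FALSE)
  }
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Simulate an AFM-like height image of rodlets
#'
#' Renders elongated rodlets as capsules (rectangle plus semicircular caps)
#' of sampled length/width/height on a flat background, lightly smooths
#' them (Gaussian, 1 px), and adds Gaussian background noise. Rod
#' length/width/height default to normal distributions centred at 15 nm,
#' 5 nm and 2 nm -- the field's typical Class I rodlet scales. Placement
#' retries to keep rods disjoint; rods that still overlap the border are
#' flagged `partial` in the truth table.
#'
#' @param n_rods number of rodlets (>= 0).
#' @param size_px image side length in pixels (default 512).
#' @param scale nm per pixel (default 0.5).
#' @param length_nm,width_nm,height_nm `c(mean, sd)` of the sampled
#'   dimensions (defaults `c(15, 3)`, `c(5, 1)`, `c(2, 0.4)`).
#' @param noise_sd background noise sd in nm (default 0.1).
#' @param smooth_sigma Gaussian smoothing of the rendered field, px.
#' @param seed integer seed.
#' @return A list: `image` (a [height_image()]), `truth` (data.frame per rod:
#'   id, length_nm, width_nm, height_nm, angle_rad, row, col, partial).
#' @export
gen_rod_image <- function(n_rods = 60L, size_px = 512L, scale = 0.5,
                          length_nm = c(15, 3), width_nm = c(5, 1),
                          height_nm = c(2, 0.4), noise_sd = 0.1,
                          smooth_sigma = 1, seed = 1L) {
  stopifnot(n_rods >= 0L, size_px >= 16L, scale > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- pmax(stats::rnorm(n_rods, length_nm[1L], length_nm[2L]), 4 * scale)
  W <- pmax(stats::rnorm(n_rods, width_nm[1L], width_nm[2L]), 2 * scale)
  H <- pmax(stats::rnorm(n_rods, height_nm[1L], height_nm[2L]), 0.2)
  if (n_rods > 0 &&
      sum(L * W) / (size_px * scale)^2 > 0.5)
    stop("rod density too high: area fraction exceeds 0.5")
  theta <- stats::runif(n_rods, 0, pi)
  field <- matrix(0, size_px, size_px)
  occupied <- matrix(FALSE, size_px, size_px)
  truth <- list()
  idx <- as.matrix(expand.grid(r = seq_len(size_px), c = seq_len(size_px)))
  for (i in seq_len(n_rods)) {
    half <- (L[i] / 2) / scale; halfw <- (W[i] / 2) / scale
    placed <- FALSE
    for (try_ in 1:50) {
      cr <- stats::runif(1, 1, size_px); cc <- stats::runif(1, 1, size_px)
      # capsule: distance to the central segment <= halfw
      ux <- cos(theta[i]); uy <- sin(theta[i])
      seg_half <- max(half - halfw, 0)
      dr <- idx[, 1L] - cr; dc <- idx[, 2L] - cc
      t_ <- pmin(pmax(dr * ux + dc * uy, -seg_half), seg_half)
      d2 <- (dr - t_ * ux)^2 + (dc - t_ * uy)^2
      inside <- d2 <= halfw^2
      if (!any(inside)) next
      if (any(occupied[idx[inside, , drop = FALSE]])) next
      field[idx[inside, , drop = FALSE]] <- H[i]
      # reserve a margin of 2 px around the rod
      buf <- d2 <= (halfw + 2)^2
      occupied[idx[buf, , drop = FALSE]] <- TRUE
      partial <- any(idx[inside, 1L] %in% c(1L, size_px)) ||
                 any(idx[inside, 2L] %in% c(1L, size_px))
      truth[[i]] <- data.frame(id = i, length_nm = L[i], width_nm = W[i],
                               height_nm = H[i], angle_rad = theta[i],
                               row = cr, col = cc, partial = partial,
                               stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      truth[[i]] <- data.frame(id = i, length_nm = L[i], width_nm = W[i],
                               height_nm = H[i], angle_rad = theta[i],
                               row = NA_real_, col = NA_real_, partial = NA,
                               stringsAsFactors = FALSE)
  }
  if (smooth_sigma > 0) field <- gaussian_blur(field, smooth_sigma)
  field <- field + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                          size_px, size_px)
  img <- height_image(field, scale,
                      metadata = list(seed = seed, source = "gen_rod_image"))
  list(image = img,
       truth = if (length(truth) > 0) do.call(rbind, truth)
               else data.frame())
}

#' Generate ideal-geometry toy structures
#'
#' Deterministic coordinate fixtures for surface-area and superposition
#' tests: `two_spheres` (two atoms a given distance apart), `helix` (an
#' ideal CA-trace alpha-helix: rise 1.5 A, 100 degrees per residue, radius
#' 2.3 A), `mini_sheet` (a flat grid of CA atoms).
#'
#' @param kind `"two_spheres"`, `"helix"` or `"mini_sheet"`.
#' @param distance two_spheres: centre distance in Angstrom (default 10).
#' @param elements two_spheres: the two element symbols (default C, C).
#' @param n_res helix/mini_sheet: residue count (default 10).
#' @param rise,twist_deg,radius helix geometry (defaults 1.5, 100, 2.3).
#' @param ncol_sheet mini_sheet: atoms per row (default 5).
#' @return A `structure_model`.
#' @export
gen_toy_structure <- function(kind = c("two_spheres", "helix", "mini_sheet"),
                              distance = 10, elements = c("C", "C"),
                              n_res = 10L, rise = 1.5, twist_deg = 100,
                              radius = 2.3, ncol_sheet = 5L) {
  kind <- match.arg(kind)
  atoms <- switch(kind,
    two_spheres = data.frame(
      name = c("C1", "C2"), element = toupper(elements),
      resno = 1:2, resname = "LIG", chain = "A",
      x = c(0, distance), y = 0, z = 0, stringsAsFactors = FALSE),
    helix = {
      i <- seq_len(n_res) - 1L
      ang <- i * twist_deg * pi / 180
      data.frame(name = "CA", element = "C", resno = i + 1L,
                 resname = "ALA", chain = "A",
                 x = radius * cos(ang), y = radius * sin(ang),
                 z = i * rise, stringsAsFactors = FALSE)
    },
    mini_sheet = {
      g <- expand.grid(col = seq_len(ncol_sheet),
                       row = seq_len(ceiling(n_res / ncol_sheet)))
      g <- g[seq_len(n_res), ]
      data.frame(name = "CA", element = "C", resno = seq_len(n_res),
                 resname = "GLY", chain = "A",
                 x = 3.8 * g$col, y = 4.8 * g$row, z = 0,
                 stringsAsFactors = FALSE)
    })
  new_structure_model(atoms)
}
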