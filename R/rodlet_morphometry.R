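#' Construct a calibrated height image
#'
#' @param heights numeric matrix of heights in nm.
#' @param scale nm per pixel (> 0).
#' @param metadata optional list (seed, source, ...).
#' @return An object of class `height_image`.
#' @export
height_image <- function(heights, scale, metadata = list()) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive nm/pixel value")
  structure(list(heights = heights, scale = scale, metadata = metadata),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("<height_image> %d x %d px at %g nm/px (%.0f x %.0f nm)\n",
              nrow(x$heights), ncol(x$heights), x$scale,
              nrow(x$heights) * x$scale, ncol(x$heights) * x$scale))
  invisible(x)
}

as_height_image <- function(img, template) {
  height_image(img, template$scale, template$metadata)
}

# separable Gaussian blur, replicate padding, kernel truncated at 4 sigma
gaussian_blur <- function(mat, sigma) {
  hw <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-hw:hw, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {   # along rows (dimension 1)
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in -hw:hw) {
      idx <- pmin.int(pmax.int(seq_len(nr) + o, 1L), nr)
      out <- out + k[o + hw + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Unsharp mask filter
#'
#' Sharpens a height image exactly as the classic unsharp mask:
#' `out = (img - weight * gaussian(img, sigma = radius)) / (1 - weight)`.
#' A constant image is returned unchanged; `weight = 0` is the identity.
#'
#' @param img a [height_image()].
#' @param radius Gaussian sigma in pixels (default 2).
#' @param weight mask weight in `[0, 1)` (default 0.6).
#' @return Filtered `height_image`.
#' @export
unsharp <- function(img, radius = 2, weight = 0.6) {
  if (weight < 0 || weight >= 1) stop("weight must be in [0, 1)")
  if (weight == 0) return(img)
  blur <- gaussian_blur(img$heights, radius)
  as_height_image((img$heights - weight * blur) / (1 - weight), img)
}

#' Despeckle (3x3 median filter)
#'
#' Median of each pixel's 3x3 neighbourhood with nearest-neighbour edge
#' padding; removes single-pixel spikes while preserving edges.
#'
#' @param img a [height_image()], at least 3x3.
#' @return Filtered `height_image`.
#' @export
despeckle <- function(img) {
  if (nrow(img$heights) < 3L || ncol(img$heights) < 3L)
    stop("image must be at least 3x3")
  as_height_image(median_filter3(img$heights), img)
}

#' Otsu threshold of a numeric image
#'
#' Maximises between-class variance over a binned histogram; returns the
#' threshold value (upper edge of the chosen bin).
#'
#' @param values numeric vector or matrix.
#' @param n_bins histogram bins (default 256).
#' @return Threshold on the value scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant image: automatic threshold undefined, use a fixed threshold")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin.int(findInterval(v, edges, rightmost.closed = TRUE),
                         n_bins), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1L]
}

#' Binarize a height image
#'
#' Foreground = pixels strictly above the threshold. The default automatic
#' method is Otsu's; pass `threshold` for a fixed cut.
#'
#' @param img a [height_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold in nm (required for `method = "fixed"`).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  t0 <- if (method == "otsu") otsu_threshold(img$heights)
        else {
          if (is.null(threshold)) stop("fixed method needs a threshold")
          threshold
        }
  img$heights > t0
}

# Moore boundary tracing perimeter: chain of boundary pixels, steps of 1
# (4-neighbour) or sqrt(2) (diagonal). Single-pixel components get 0.
trace_perimeter <- function(mask_sub) {
  nr <- nrow(mask_sub); nc <- ncol(mask_sub)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask_sub
  # start: first foreground pixel in column-major order
  start <- which(pad)[1L]
  si <- (start - 1L) %% nrow(pad) + 1L
  sj <- (start - 1L) %/% nrow(pad) + 1L
  # Moore neighbourhood in clockwise order starting west
  di <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_len <- sqrt(di^2 + dj^2)
  if (sum(pad) == 1L) return(0)
  per <- 0
  ci <- si; cj <- sj; backtrack <- 1L   # came from the west
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- (backtrack + s - 1L) %% 8L + 1L
      ni <- ci + di[k]; nj <- cj + dj[k]
      if (pad[ni, nj]) {
        per <- per + step_len[k]
        # new backtrack: direction pointing to the previous pixel,
        # rotated one step clockwise
        backtrack <- (k + 4L) %% 8L + 1L
        ci <- ni; cj <- nj
        found <- TRUE
        break
      }
    }
    if (!found) return(0)               # isolated pixel
    if (ci == si && cj == sj) break
  }
  per
}

#' Particle analysis of a binarized height image
#'
#' ImageJ-style particle analysis: 8-connected components of the mask; an
#' area-matched ellipse from second central moments gives major/minor axis
#' lengths; circularity `4 * pi * area / perimeter^2` (perimeter from Moore
#' boundary tracing with sqrt(2) diagonal steps, clipped to <= 1); mean
#' height above background (median of non-foreground pixels). Components are
#' kept when circularity lies in `circ_range` and area (nm^2) in
#' `size_range` -- the 0-0.7 circularity window retains elongated rodlets
#' and rejects round particles.
#'
#' @param mask logical matrix from [binarize()].
#' @param img the matching [height_image()].
#' @param circ_range inclusive circularity window (default `c(0, 0.7)`).
#' @param size_range inclusive area window in nm^2 (default `c(0, Inf)`).
#' @return data.frame, one row per retained particle: `label`, `area_nm2`,
#'   `major_axis_nm`, `minor_axis_nm`, `circularity`, `mean_height_nm`,
#'   `centroid_row`, `centroid_col`, `touches_edge`.
#' @export
measure_particles <- function(mask, img, circ_range = c(0, 0.7),
                              size_range = c(0, Inf)) {
  if (!identical(dim(mask), dim(img$heights)))
    stop("mask and image dimensions differ")
  if (!any(mask))
    return(empty_particles())
  lab <- label_components8(mask)
  nlab <- max(lab)
  background <- stats::median(img$heights[!mask])
  sc <- img$scale
  rows <- lapply(seq_len(nlab), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    npx <- nrow(px)
    area <- npx * sc^2
    cen <- colMeans(px)
    dr <- px[, 1L] - cen[1L]; dc <- px[, 2L] - cen[2L]
    # second central moments with the 1/12 px variance of a unit pixel
    mrr <- mean(dr^2) + 1 / 12; mcc <- mean(dc^2) + 1 / 12; mrc <- mean(dr * dc)
    tr2 <- (mrr + mcc) / 2
    det_ <- mrr * mcc - mrc^2
    disc <- sqrt(max(tr2^2 - det_, 0))
    l1 <- tr2 + disc; l2 <- max(tr2 - disc, 1e-12)
    ar <- sqrt(l1 / l2)
    semi_major <- sqrt(npx / pi * ar)
    semi_minor <- sqrt(npx / pi / ar)
    sub <- lab[min(px[, 1L]):max(px[, 1L]),
               min(px[, 2L]):max(px[, 2L]), drop = FALSE] == l
    per <- trace_perimeter(sub)
    circ <- if (per == 0) 1 else min(4 * pi * npx / per^2, 1)
    data.frame(label = l, area_nm2 = area,
               major_axis_nm = 2 * semi_major * sc,
               minor_axis_nm = 2 * semi_minor * sc,
               circularity = circ,
               mean_height_nm = mean(img$heights[lab == l]) - background,
               centroid_row = cen[1L], centroid_col = cen[2L],
               touches_edge = min(px) == 1L ||
                 max(px[, 1L]) == nrow(mask) || max(px[, 2L]) == ncol(mask))
  })
  out <- do.call(rbind, rows)
  keep <- out$circularity >= circ_range[1L] & out$circularity <= circ_range[2L] &
    out$area_nm2 >= size_range[1L] & out$area_nm2 <= size_range[2L]
  out[keep, , drop = FALSE]
}

empty_particles <- function() {
  data.frame(label = integer(0), area_nm2 = numeric(0),
             major_axis_nm = numeric(0), minor_axis_nm = numeric(0),
             circularity = numeric(0), mean_height_nm = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             touches_edge = logical(0))
}

#' Ellipse axes of an ideal capsule, and the inverse mapping
#'
#' `capsule_ellipse_axes` gives the major/minor axis lengths of the
#' area-matched second-moment ellipse of an ideal capsule (rectangle with
#' semicircular caps) of end-to-end length `L` and width `W` -- the quantity
#' an ImageJ-style "fit ellipse" reports for a rod-shaped particle. The
#' ellipse is a different shape with the same area and moment ratio, so its
#' major axis exceeds the capsule length by several percent at typical rod
#' aspect ratios. `capsule_from_ellipse` inverts the mapping numerically
#' (fixed-point), estimating the capsule dimensions that would produce the
#' measured ellipse.
#'
#' @param L,W capsule end-to-end length and width (same units), `L >= W`.
#' @return `capsule_ellipse_axes`: named vector `major`, `minor`.
#' @export
capsule_ellipse_axes <- function(L, W) {
  if (W > L) { tmp <- L; L <- W; W <- tmp }
  r <- W / 2; c <- L - W
  xs <- seq(-L / 2, L / 2, length.out = 2001L)
  w <- ifelse(abs(xs) <= c / 2, W,
              2 * sqrt(pmax(r^2 - (abs(xs) - c / 2)^2, 0)))
  dx <- xs[2L] - xs[1L]
  A <- sum(w) * dx
  vx <- sum(w * xs^2) * dx / A        # along-axis variance
  vy <- sum(w^3 / 12) * dx / A        # across-axis variance
  ar <- sqrt(vx / vy)
  a <- sqrt(A / pi * ar); b <- sqrt(A / pi / ar)
  c(major = 2 * a, minor = 2 * b)
}

#' @rdname capsule_ellipse_axes
#' @param major,minor measured ellipse axis lengths.
#' @return `capsule_from_ellipse`: named vector `length`, `width`.
#' @export
capsule_from_ellipse <- function(major, minor) {
  L <- major; W <- min(minor, L)
  for (it in 1:12) {
    ax <- capsule_ellipse_axes(L, W)
    L <- L * major / ax[["major"]]
    W <- W * minor / ax[["minor"]]
    if (W > L) W <- L
  }
  c(length = L, width = W)
}

#' Distribution summaries of particle measurements
#'
#' Reports mean, sd, n and a histogram for rodlet length, width and height.
#' With `shape = "ellipse"` (default) length and width are the raw ellipse
#' major/minor axes. With `shape = "capsule"` each particle's ellipse is
#' first inverted to the capsule (rod) dimensions that would produce it
#' (see [capsule_from_ellipse()]) -- the appropriate estimator when the
#' goal is to recover the physical rod dimensions rather than to report the
#' ellipse-convention measurement.
#'
#' @param measurements data.frame from [measure_particles()].
#' @param breaks histogram bin specification (passed to [hist()]).
#' @param shape `"ellipse"` or `"capsule"`, see above.
#' @return A list with elements `length`, `width`, `height`, each a list
#'   `mean`, `sd`, `n`, `histogram`; empty input gives `n = 0` and `NA`
#'   moments.
#' @export
summarize_particles <- function(measurements, breaks = "Sturges",
                                shape = c("ellipse", "capsule")) {
  shape <- match.arg(shape)
  one <- function(v) {
    if (length(v) == 0L)
      return(list(mean = NA_real_, sd = NA_real_, n = 0L, histogram = NULL))
    list(mean = mean(v), sd = stats::sd(v), n = length(v),
         histogram = graphics::hist(v, breaks = breaks, plot = FALSE))
  }
  len <- measurements$major_axis_nm
  wid <- measurements$minor_axis_nm
  if (shape == "capsule" && nrow(measurements) > 0L) {
    lw <- t(mapply(capsule_from_ellipse, len, wid))
    len <- lw[, "length"]; wid <- lw[, "width"]
  }
  list(length = one(len), width = one(wid),
       height = one(measurements$mean_height_nm))
}

#' Run the four-step rodlet analysis chain
#'
#' Convenience wrapper: unsharp mask (radius 2 px, weight 0.6), despeckle,
#' automatic binary threshold, particle analysis with the 0-0.7 circularity
#' window -- the standard chain for measuring hydrophobin rodlets in AFM
#' height images.
#'
#' @param img a [height_image()].
#' @param unsharp_radius,unsharp_weight unsharp parameters.
#' @param threshold_method,threshold passed to [binarize()].
#' @param circ_range,size_range passed to [measure_particles()].
#' @param exclude_edge drop particles touching the image edge (default TRUE;
#'   their lengths are censored).
#' @param shape summary convention, see [summarize_particles()].
#' @return List: `particles` (data.frame), `summary`
#'   (from [summarize_particles()]), `mask`.
#' @export
rodlet_chain <- function(img, unsharp_radius = 2, unsharp_weight = 0.6,
                         threshold_method = "otsu", threshold = NULL,
                         circ_range = c(0, 0.7), size_range = c(0, Inf),
                         exclude_edge = TRUE, shape = "ellipse") {
  f <- despeckle(unsharp(img, unsharp_radius, unsharp_weight))
  mask <- binarize(f, threshold_method, threshold)
  parts <- measure_particles(mask, img, circ_range, size_range)
  if (exclude_edge && nrow(parts) > 0L)
    parts <- parts[!parts$touches_edge, , drop = FALSE]
  list(particles = parts,
       summary = summarize_particles(parts, shape = shape), mask = mask)
}
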