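flat_image <- function(value = 1, n = 16, scale = 1)
  height_image(matrix(value, n, n), scale)

test_that("unsharp mask: identity cases and impulse response", {
  img <- flat_image(2.5)
  expect_equal(unsharp(img)$heights, img$heights, tolerance = 1e-12)
  noisy <- height_image(matrix(rnorm(256), 16), 1)
  expect_equal(unsharp(noisy, weight = 0)$heights, noisy$heights)
  expect_error(unsharp(noisy, weight = 1), "weight")

  # impulse response at the centre: out = (1 - w*g0) / (1 - w) where g0 is
  # the centre weight of the truncated separable Gaussian
  n <- 33L; imp <- matrix(0, n, n); imp[17, 17] <- 1
  hw <- ceiling(4 * 2)
  k <- dnorm(-hw:hw, sd = 2); k <- k / sum(k)
  g0 <- k[hw + 1]^2
  got <- unsharp(height_image(imp, 1), radius = 2, weight = 0.6)
  expect_equal(got$heights[17, 17], (1 - 0.6 * g0) / (1 - 0.6),
               tolerance = 1e-10)
})

test_that("despeckle is a 3x3 median with replicate padding", {
  img <- flat_image(3)
  expect_equal(despeckle(img)$heights, img$heights)
  hot <- flat_image(0)
  hot$heights[8, 8] <- 10
  expect_equal(despeckle(hot)$heights, matrix(0, 16, 16))
  expect_error(despeckle(height_image(matrix(0, 2, 2), 1)), "3x3")

  # random 5x5 against an independent sort-based oracle
  set.seed(103)
  m <- matrix(rnorm(25), 5)
  got <- despeckle(height_image(m, 1))$heights
  pad <- m[c(1, 1:5, 5), c(1, 1:5, 5)]
  for (i in 1:5) for (j in 1:5) {
    w <- sort(as.vector(pad[i:(i + 2), j:(j + 2)]))[5]
    expect_equal(got[i, j], w, info = paste(i, j))
  }
})

test_that("binarization separates two-level images and Otsu maximises variance", {
  two <- height_image(matrix(c(0, 2), 16, 16), 1)
  mask <- binarize(two)
  expect_equal(mask, two$heights > 1, ignore_attr = TRUE)
  expect_error(binarize(flat_image(1)), "constant")
  grid <- height_image(matrix(seq(0, 3, length.out = 64), 8), 1)
  expect_equal(binarize(grid, "fixed", threshold = 1.0), grid$heights > 1)

  # exhaustive between-class variance maximisation on a 16-bin toy
  set.seed(107)
  v <- c(rnorm(200, 1, 0.3), rnorm(100, 4, 0.4))
  t_pkg <- otsu_threshold(v, n_bins = 16L)
  edges <- seq(min(v), max(v), length.out = 17L)
  bcv <- sapply(edges[2:16], function(e) {
    lo <- v[v <= e]; hi <- v[v > e]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(v) * length(hi) / length(v) *
      (mean(lo) - mean(hi))^2
  })
  expect_equal(t_pkg, edges[which.max(bcv) + 1], tolerance = 1e-9)
})

test_that("Otsu agrees with EBImage's implementation to a bin width", {
  skip_if_not_installed("EBImage")
  set.seed(109)
  v <- matrix(c(rnorm(400, 0.2, 0.05), rnorm(112, 0.7, 0.05)), 16)
  v <- pmin(pmax(v, 0), 1)
  ours <- otsu_threshold(v, n_bins = 256L)
  ref <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  # an empty histogram valley makes the maximiser non-unique: compare the
  # between-class-variance objective, not the threshold location
  bcv <- function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    length(lo) * length(hi) / length(v)^2 * (mean(lo) - mean(hi))^2
  }
  expect_gte(bcv(ours), bcv(ref) - 1e-9)
})

test_that("particle measurement: empty mask, disc exclusion, capsule moments", {
  img <- flat_image(0, 64)
  expect_equal(nrow(measure_particles(matrix(FALSE, 64, 64), img)), 0L)

  # ideal disc: circularity near 1 -> excluded by the 0-0.7 window
  xy <- expand.grid(1:64, 1:64)
  disc <- matrix((xy[, 1] - 32)^2 + (xy[, 2] - 32)^2 <= 14^2, 64)
  di <- height_image(matrix(2 * disc, 64), 1)
  kept <- measure_particles(disc, di)
  expect_equal(nrow(kept), 0L)
  all_parts <- measure_particles(disc, di, circ_range = c(0, 1))
  expect_equal(nrow(all_parts), 1L)
  expect_gte(all_parts$circularity, 0.9)

  # 30x6 px capsule at 1 nm/px: axes within 10% of the capsule dimensions
  # and within 2% of the analytic moment-ellipse oracle
  # centre on a pixel corner (32.5) so the rasterised mask is 30 x 6 px
  seg <- 12  # half length of the central segment: total L = 2*12 + 6 = 30
  d <- abs(xy[, 1] - 32.5)
  caps <- matrix((xy[, 1] - 32.5 - sign(xy[, 1] - 32.5) * pmin(d, seg))^2 +
                 (xy[, 2] - 32.5)^2 < 3^2, 64)
  ci <- height_image(matrix(2 * caps, 64), 1)
  p <- measure_particles(caps, ci, circ_range = c(0, 1))
  expect_equal(nrow(p), 1L)
  # fit-ellipse axes match the analytic moment-ellipse oracle ...
  oracle <- capsule_ellipse_axes(30, 6)
  expect_lt(abs(p$major_axis_nm - oracle[["major"]]) / oracle[["major"]], 0.02)
  expect_lt(abs(p$minor_axis_nm - oracle[["minor"]]) / oracle[["minor"]], 0.05)
  # ... and inverting the ellipse recovers the capsule's 30 x 6 within 10%
  est <- capsule_from_ellipse(p$major_axis_nm, p$minor_axis_nm)
  expect_lt(abs(est[["length"]] - 30) / 30, 0.10)
  expect_lt(abs(est[["width"]] - 6) / 6, 0.10)
  # 5:1 capsule is retained by the printed 0-0.7 filter
  expect_lte(p$circularity, 0.7)
  # mean height above the (zero) background
  expect_equal(p$mean_height_nm, 2)
  # nm scaling
  p2 <- measure_particles(caps, height_image(matrix(2 * caps, 64), 0.5),
                          circ_range = c(0, 1))
  expect_equal(p2$major_axis_nm, p$major_axis_nm / 2)
  expect_equal(p2$area_nm2, p$area_nm2 / 4)
})

test_that("capsule/ellipse mapping inverts round-trip", {
  for (L in c(10, 20, 30)) for (W in c(4, 6)) {
    ax <- capsule_ellipse_axes(L, W)
    back <- capsule_from_ellipse(ax[["major"]], ax[["minor"]])
    expect_equal(unname(back), c(L, W), tolerance = 1e-3)
  }
})

test_that("summaries match arithmetic on the measurement table", {
  expect_equal(summarize_particles(empty_particles())$length$n, 0L)
  sim <- gen_rod_image(n_rods = 25, size_px = 256, seed = 23)
  res <- rodlet_chain(sim$image, circ_range = c(0, 1), exclude_edge = FALSE)
  s <- summarize_particles(res$particles)
  expect_equal(s$length$mean, mean(res$particles$major_axis_nm))
  expect_equal(s$width$sd, sd(res$particles$minor_axis_nm))
  expect_equal(s$height$n, nrow(res$particles))
  one <- res$particles[1, , drop = FALSE]
  s1 <- summarize_particles(one)
  expect_equal(s1$length$mean, one$major_axis_nm)
  expect_true(is.na(s1$length$sd))
})

test_that("labeling is 8-connected and matches EBImage counts", {
  mask <- matrix(FALSE, 8, 8)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE   # diagonal touch: one component
  mask[6, 6] <- TRUE                       # separate
  lab <- label_components8(mask)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], lab[3, 3])
  skip_if_not_installed("EBImage")
  set.seed(113)
  m2 <- matrix(runif(400) > 0.7, 20)
  ours <- max(label_components8(m2))
  # EBImage bwlabel is 4-connected; compare against its dilation-free count
  # only through total foreground conservation
  expect_equal(sum(label_components8(m2) > 0), sum(m2))
  expect_gte(max(EBImage::bwlabel(m2)), ours)  # 4-connected splits >= 8-connected
})
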