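proj_from_points <- function(xy, ids = NULL) {
  n <- nrow(xy)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  structure(list(eigenvalues = c(1, 1),
                 coordinates = matrix(as.numeric(xy), n, 2,
                                      dimnames = list(ids, c("PC1", "PC2"))),
                 component_count = 2L),
            class = "projection")
}

test_that("partition covers points exactly once and matches a counting oracle", {
  # all identical points fall in one cell
  p0 <- proj_from_points(matrix(rep(c(1, 2), each = 5), 5))
  g0 <- partition(p0, 3, 3)
  expect_equal(length(unique(g0$membership)), 1L)

  # 4 corner points, 2x2: one per cell
  pc <- proj_from_points(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  gc <- partition(pc, 2, 2)
  expect_equal(sort(unname(gc$membership)), 1:4)

  # 100 random points vs point-in-rectangle counting
  set.seed(51)
  xy <- matrix(rnorm(200), 100)
  pr <- proj_from_points(xy)
  gr <- partition(pr, 7, 2)
  expect_equal(length(gr$membership), 100L)
  counts <- table(factor(gr$membership, levels = gr$cells$index))
  for (k in gr$cells$index) {
    cell <- gr$cells[gr$cells$index == k, ]
    lastx <- cell$ix == gr$nx; lasty <- cell$iy == gr$ny
    inx <- xy[, 1] >= cell$x0 & (if (lastx) xy[, 1] <= cell$x1 else xy[, 1] < cell$x1)
    iny <- xy[, 2] >= cell$y0 & (if (lasty) xy[, 2] <= cell$y1 else xy[, 2] < cell$y1)
    expect_equal(unname(counts[as.character(k)]), sum(inx & iny), info = k)
  }
  expect_equal(sum(counts), 100L)
  # equal-sized cells
  expect_equal(diff(range(diff(seq(gr$bounds["x0"], gr$bounds["x1"],
                                   length.out = gr$nx + 1)))), 0)
  expect_error(partition(pr, 0, 2), "nx")
})

test_that("consensus follows majority-with-threshold and gap rules", {
  m <- new_msa(paste0("s", 1:4), c("ACDE", "ACDE", "ACDE", "ACDE"))
  cs <- region_consensus(m, 1:4)
  expect_equal(cs$letters, "ACDE")
  expect_equal(cs$support, rep(1, 4))

  # column {A:3, G:1}: winner A with support 0.75
  m2 <- new_msa(paste0("s", 1:4), c("A", "A", "A", "G"))
  cs2 <- region_consensus(m2, 1:4, threshold = 0.5)
  expect_equal(cs2$letters, "A")
  expect_equal(cs2$support, 0.75)
  # threshold 1.0 on a mixed column is forced to x
  expect_equal(region_consensus(m2, 1:4, threshold = 1.0)$letters, "x")

  # gap wins only as strict majority
  m3 <- new_msa(paste0("s", 1:4), c("-", "-", "A", "A"))
  expect_equal(region_consensus(m3, 1:4, threshold = 0.5)$letters, "A")
  m4 <- new_msa(paste0("s", 1:4), c("-", "-", "-", "A"))
  expect_equal(region_consensus(m4, 1:4, threshold = 0.5)$letters, "-")
  expect_error(region_consensus(m4, character(0)), "empty")
  expect_error(region_consensus(m4, "nope"), "not in MSA")
})

test_that("region summaries label by composition and match counting", {
  pts <- proj_from_points(matrix(c(rep(0, 6), rep(1, 6)), ncol = 2),
                          ids = paste0("s", 1:6))
  grid <- partition(pts, 1, 1)
  ann <- data.frame(id = paste0("s", 1:6),
                    phylum = rep("Basidiomycota", 6),
                    class_annotation = rep("I", 6))
  s <- summarize_region(grid, 1L, ann)
  expect_equal(s$label, "IB")
  expect_equal(s$n_sequences, 6L)
  expect_equal(unname(s$phylum_fractions[["Basidiomycota"]]), 1)

  ann2 <- ann; ann2$phylum <- rep(c("Ascomycota", "Basidiomycota"), 3)
  expect_equal(summarize_region(grid, 1L, ann2)$label, "mixed")
  ann3 <- ann; ann3$class_annotation <- "II"; ann3$phylum <- "Ascomycota"
  expect_equal(summarize_region(grid, 1L, ann3)$label, "II")
  ann4 <- ann; ann4$phylum <- "Ascomycota"
  expect_equal(summarize_region(grid, 1L, ann4)$label, "IA")

  # counting oracle on random labels
  set.seed(61)
  for (k in 1:10) {
    ph <- sample(c("Ascomycota", "Basidiomycota"), 6, TRUE)
    cl <- sample(c("I", "II"), 6, TRUE)
    annr <- data.frame(id = paste0("s", 1:6), phylum = ph,
                       class_annotation = cl)
    sr <- summarize_region(grid, 1L, annr)
    expect_equal(unname(sr$phylum_fractions[["Ascomycota"]]),
                 mean(ph == "Ascomycota"))
    expect_equal(unname(sr$class_fractions[["II"]]), mean(cl == "II"))
    expect_equal(sum(sr$phylum_fractions), 1)
  }

  # sparse: 2 mixed members in a cell
  pts2 <- proj_from_points(rbind(c(0, 0), c(0.1, 0)), ids = c("a", "b"))
  g2 <- partition(pts2, 1, 1)
  ann5 <- data.frame(id = c("a", "b"),
                     phylum = c("Ascomycota", "Basidiomycota"),
                     class_annotation = c("I", "I"))
  expect_equal(summarize_region(g2, 1L, ann5)$label, "sparse")
})

test_that("identity tables are symmetric column-identity without realignment", {
  m <- new_msa(c("a", "b", "c"),
               c("ACDEFGHIKL", "ACDEFGHIKV", "ACDEFGHIKL"))
  it <- identity_table(m, c("a", "b", "c"))
  expect_equal(it$matrix["a", "b"], 90)
  expect_equal(it$matrix["a", "c"], 100)
  expect_equal(it$matrix, t(it$matrix))
  expect_equal(it$mean, mean(c(90, 100, 90)))
  expect_error(identity_table(m, "a"), ">= 2")
  # both-gap columns are excluded from the denominator
  m2 <- new_msa(c("a", "b"), c("AC--", "AC--"))
  expect_equal(identity_table(m2, c("a", "b"))$matrix["a", "b"], 100)
})

test_that("synthetic classes land in distinct cells whose consensus recovers templates", {
  gen <- gen_sequences(list(class_spec("IA"), class_spec("IB"),
                            class_spec("II")), n = 12, seed = 19)
  msa <- progressive_msa(gen$sequences)
  proj <- eigen_project(pairwise_score_matrix(msa), 2)
  grid <- partition(proj, 2, 2)
  truth <- gen$truth$class_label[match(names(grid$membership), gen$truth$id)]
  # each class concentrated in one cell, and those cells are distinct
  main_cell <- tapply(grid$membership, truth, function(v)
    as.integer(names(which.max(table(v)))))
  expect_equal(length(unique(main_cell)), 3L)
  for (cl in names(main_cell)) {
    ids <- names(grid$membership)[grid$membership == main_cell[[cl]] &
                                  truth == cl]
    cons <- region_consensus(msa, ids)
    cons_seq <- gsub("[-x]", "", cons$letters)
    tmpl <- gen$truth$template[match(ids[1], gen$truth$id)]
    pid <- percent_identity(global_align(cons_seq, tmpl), "all")
    expect_gte(pid, 95)
  }
})
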