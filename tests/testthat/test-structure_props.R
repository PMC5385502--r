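pdb_line <- function(serial, name, resname, resno, x, y, z, element = "") {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resno, x, y, z, element)
}

write_toy_pdb <- function(lines, models = 1L) {
  path <- tempfile(fileext = ".pdb")
  out <- character(0)
  for (m in seq_len(models)) {
    if (models > 1L) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, lines)
    if (models > 1L) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  path
}

test_that("PDB reading yields one model per MODEL record with inferred elements", {
  one <- write_toy_pdb(pdb_line(1, "CA", "GLY", 1, 0, 0, 0, "C"))
  m1 <- read_structure(one)
  expect_length(m1, 1L)
  expect_equal(nrow(m1[[1]]$atoms), 1L)

  multi <- write_toy_pdb(c(pdb_line(1, "N", "CYS", 1, 0, 0, 0, "N"),
                           pdb_line(2, "SG", "CYS", 1, 1, 1, 1, "S")),
                         models = 20L)
  m20 <- read_structure(multi)
  expect_length(m20, 20L)

  # blank element column: inferred from the atom name
  noel <- write_toy_pdb(c(pdb_line(1, "CA", "GLY", 1, 0, 0, 0),
                          pdb_line(2, "N", "GLY", 1, 1.4, 0, 0),
                          pdb_line(3, "SG", "CYS", 2, 3, 0, 0),
                          pdb_line(4, "OXT", "GLY", 2, 5, 0, 0)))
  mi <- read_structure(noel)[[1]]
  expect_equal(mi$atoms$element, c("C", "N", "S", "O"))
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("SASA matches closed forms: isolated sphere, separated and fused pairs", {
  iso <- gen_toy_structure("two_spheres", distance = 100)
  s <- shrake_rupley_sasa(iso)
  full <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(s$area[1] - full) / full, 0.01)
  expect_equal(s$total, 2 * s$area[1])     # no occlusion when far apart

  near <- gen_toy_structure("two_spheres", distance = 3)
  sn <- shrake_rupley_sasa(near)
  exact <- oracle_two_sphere_sasa(1.7 + 1.4, 3)
  expect_lt(abs(sn$total - exact) / exact, 0.02)
  expect_true(all(sn$area >= 0))
  expect_true(all(sn$area <= full + 1e-9))
})

test_that("SASA is invariant under rigid motion", {
  set.seed(71)
  m <- gen_toy_structure("helix", n_res = 12)
  base <- shrake_rupley_sasa(m)$total
  for (k in 1:3) {
    R <- random_rotation(); t_ <- rnorm(3, 0, 10)
    m2 <- m
    m2$atoms[, c("x", "y", "z")] <- apply_rigid(atom_xyz(m), R, t_)
    moved <- shrake_rupley_sasa(m2)$total
    expect_lt(abs(moved - base) / base, 0.005)
  }
})

test_that("hydrophobic fraction is the carbon+sulfur share of the span", {
  c1 <- gen_toy_structure("two_spheres", distance = 100, elements = c("C", "C"))
  expect_equal(hydrophobic_fraction(shrake_rupley_sasa(c1), c(1, 1)), 100)
  n1 <- gen_toy_structure("two_spheres", distance = 100, elements = c("N", "N"))
  expect_equal(hydrophobic_fraction(shrake_rupley_sasa(n1), c(1, 1)), 0)
  mix <- gen_toy_structure("two_spheres", distance = 100, elements = c("C", "N"))
  sm <- shrake_rupley_sasa(mix)
  expect_equal(hydrophobic_fraction(sm),
               100 * sm$area[1] / sum(sm$area))
  expect_error(hydrophobic_fraction(sm, c(50, 60)), "empty")
})

test_that("disulfide detection pairs close SG atoms greedily and once each", {
  two_cys <- function(d) write_toy_pdb(c(
    pdb_line(1, "SG", "CYS", 1, 0, 0, 0, "S"),
    pdb_line(2, "SG", "CYS", 2, d, 0, 0, "S")))
  m <- read_structure(two_cys(2.05))[[1]]
  expect_equal(unname(detect_disulfides(m)), matrix(c(1L, 2L), 1))
  m4 <- read_structure(two_cys(4.0))[[1]]
  expect_equal(nrow(detect_disulfides(m4)), 0L)
})

test_that("geometric disulfides on a canonical-topology model match the family rule", {
  # synthetic model: SG atoms placed so that the canonical partners
  # (C1-C6, C2-C5, C3-C4, C7-C8) of the SC16 cysteine numbering are 2.03 A
  # apart and all other SG-SG distances are large
  pat <- new_cys_pattern(sc16_cys_positions)
  rule <- canonical_connectivity(pat)
  centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  lines <- character(0)
  for (k in 1:4) {
    lines <- c(lines,
      pdb_line(2 * k - 1, "SG", "CYS", rule[k, 1],
               centers[k, 1] - 1.015, centers[k, 2], centers[k, 3], "S"),
      pdb_line(2 * k, "SG", "CYS", rule[k, 2],
               centers[k, 1] + 1.015, centers[k, 2], centers[k, 3], "S"))
  }
  m <- read_structure(write_toy_pdb(lines))[[1]]
  geo <- detect_disulfides(m)
  expect_equal(unname(geo), unname(rule))
})

test_that("Kabsch RMSD is zero under rigid motion and matches the quaternion oracle", {
  set.seed(81)
  A <- as.matrix(gen_toy_structure("mini_sheet", n_res = 10)$atoms[, c("x","y","z")])
  expect_equal(kabsch_rmsd(A, A), 0)
  for (k in 1:5) {
    B <- apply_rigid(A, random_rotation(), rnorm(3, 0, 5))
    expect_lt(kabsch_rmsd(A, B), 1e-6)
  }
  # non-trivial case: noisy copy, compare to Horn quaternion method
  for (k in 1:5) {
    B <- apply_rigid(A + matrix(rnorm(length(A), 0, 0.5), ncol = 3),
                     random_rotation(), rnorm(3, 0, 5))
    expect_equal(kabsch_rmsd(A, B), oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
  # explicit pairing argument
  idx <- sample(nrow(A))
  expect_lt(kabsch_rmsd(A, A[idx, ], pairing = cbind(idx, seq_along(idx))),
            1e-9)
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(line, line), "degenerate")
})

test_that("molecular weight uses average residue masses plus water", {
  expect_equal(molecular_weight("GG", unit = "Da"), 2 * 57.0519 + 18.0153,
               tolerance = 1e-6)
  expect_equal(molecular_weight("GG"), 0.1)  # kDa to 0.1
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("ACB"), "nonstandard")
  # independent cross-check against seqinr's average-mass calculator
  set.seed(91)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    pep <- sample(aa, 50, replace = TRUE)
    ours <- molecular_weight(paste(pep, collapse = ""), unit = "Da")
    ref <- seqinr::pmw(pep)
    expect_equal(ours, ref, tolerance = 2e-4)
  }
})

test_that("bounding dimensions come from principal axes, sorted ascending", {
  two <- gen_toy_structure("two_spheres", distance = 10)
  expect_equal(bounding_dimensions(two), c(0, 0, 10))
  # axis-aligned cube corners: edge length on every axis
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 2.5
  mc <- new_structure_model(data.frame(name = "CA", element = "C",
                                       resno = 1:8, resname = "GLY", chain = "A",
                                       x = cube[, 1], y = cube[, 2], z = cube[, 3]))
  expect_equal(bounding_dimensions(mc), rep(2.5, 3), tolerance = 1e-6)
  # anisotropic box, arbitrarily rotated: principal axes recover the edges
  box <- as.matrix(expand.grid(0:1, 0:1, 0:1)) %*% diag(c(1, 2, 4))
  set.seed(93)
  rot <- apply_rigid(box, random_rotation(), c(3, -2, 9))
  m <- new_structure_model(data.frame(name = "CA", element = "C",
                                      resno = 1:8, resname = "GLY", chain = "A",
                                      x = rot[, 1], y = rot[, 2], z = rot[, 3]))
  expect_equal(bounding_dimensions(m), c(1, 2, 4), tolerance = 1e-6)
})

test_that("buried hydrophobic area: zero when separated, cap formula when touching", {
  # residues 1 and 2 are single carbons; far apart -> nothing buried
  far <- gen_toy_structure("two_spheres", distance = 50)
  expect_equal(buried_hydrophobic_area(far, c(1, 1), c(2, 2)), 0,
               tolerance = 1e-9)
  near <- gen_toy_structure("two_spheres", distance = 3)
  got <- buried_hydrophobic_area(near, c(1, 1), c(2, 2))
  R <- 1.7 + 1.4
  exact <- (2 * 4 * pi * R^2 - oracle_two_sphere_sasa(R, 3)) / 2
  expect_lt(abs(got - exact) / exact, 0.02)
  expect_error(buried_hydrophobic_area(near, c(1, 2), c(2, 2)), "overlap")
})

test_that("strand-span pair counting reproduces the barrel topology statement", {
  pairs <- canonical_connectivity(new_cys_pattern(sc16_cys_positions))
  expect_equal(count_pairs_within_spans(pairs, sc16_strand_spans), 2L)
})
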