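test_that("circumference and diameter follow the rollup-vector norm", {
  expect_equal(circumference(tubule_indices(10, 0)), 10)
  expect_equal(circumference(tubule_indices(1, 0)), 1)
  expect_equal(circumference(tubule_indices(9, 4)), sqrt(133))
  expect_equal(diameter(tubule_indices(10, 0)), 10 / pi)
  # strict monotonicity in the index norm
  norms <- c(); Ds <- c()
  for (m in 2:9) for (n in 0:m) {
    norms <- c(norms, sqrt(m^2 + m * n + n^2))
    Ds <- c(Ds, diameter(tubule_indices(m, n)))
  }
  o <- order(norms)
  expect_true(all(diff(Ds[o]) > 0 | diff(norms[o]) == 0))
})

test_that("invalid geometries are rejected", {
  expect_error(tubule_indices(0, 0), "invalid")
  expect_error(tubule_indices(3, 5), "n <= m")
  expect_error(ideal_embedding(tubule_indices(1, 0), 4), "invalid")
  expect_error(ideal_embedding(tubule_indices(2, 0), 4), "invalid")
})

test_that("ideal embeddings are exact equal-edge cylinders", {
  sheet <- ideal_embedding(tgt10, 6)
  expect_equal(nrow(sheet$triangles), 2 * 10 * (6 - 1))
  et <- edge_table(sheet)
  expect_lt(max(abs(et$length - 1)), 1e-8)
  expect_length(boundary_cycles(sheet), 2)
  validate_sheet(sheet)
})

test_that("ideal dihedrals: helical symmetry, flat limit, shrinking gaps", {
  th <- ideal_dihedrals(tgt10)
  expect_length(th, 3)
  # achiral (m,0): the two non-circumferential types are mirror-equal
  expect_equal(th[2], th[3], tolerance = 1e-9)
  # flat-sheet limit: all angles approach pi
  expect_lt(max(abs(ideal_dihedrals(tubule_indices(200, 0)) - pi)), 0.02)
  expect_lt(max(abs(ideal_dihedrals(tubule_indices(60, 0)) - pi)), 0.11)
  # ideal-angle gap between neighbouring geometries shrinks with diameter
  gap <- function(m) sum(abs(ideal_dihedrals(tubule_indices(m + 1, 0)) -
                               ideal_dihedrals(tubule_indices(m, 0))))
  expect_true(gap(6) > gap(10))
  expect_true(gap(10) > gap(14))
})

test_that("classification round-trips the construction", {
  for (m in c(3L, 5L, 8L, 12L, 14L)) for (n in unique(c(0L, 1L, min(m, 4L), m))) {
    mn <- tubule_indices(m, n)
    got <- classify_geometry(ideal_embedding(mn, max(4L, n + 3L)))
    expect_identical(c(got$m, got$n), c(m, n),
                     label = sprintf("(%d,%d)", m, n))
  }
})

test_that("mirror geometries permute the dihedral types 1 and 2", {
  a <- ideal_dihedrals(tubule_indices(9, 4))
  b <- ideal_dihedrals(tubule_indices(9, 4, handedness = -1))
  expect_equal(b, a[c(2, 1, 3)], tolerance = 1e-9)
  # a mirrored embedding classifies back to canonical (9,4)
  got <- classify_geometry(ideal_embedding(tubule_indices(9, 4, handedness = -1), 7))
  expect_identical(c(got$m, got$n), c(9L, 4L))
})

test_that("lattice disks are compact and topologically disk-like", {
  d1 <- build_disk(1)
  expect_equal(sum(edge_table(d1)$state == "free"), 3)
  d4 <- build_disk(4)
  et <- edge_table(d4)
  expect_length(boundary_cycles(d4), 1)
  expect_equal(nrow(d4$vertices) - nrow(et) + nrow(d4$triangles), 1)  # Euler
  d50 <- build_disk(50)
  perim <- sum(edge_table(d50)$state == "free")
  iso <- 2 * sqrt(pi * 50 * sqrt(3) / 4)
  expect_lt(abs(perim - iso) / iso, 0.2)
  # bent disk carries the target curvature but stays a disk
  db <- build_disk(30, tgt10)
  expect_length(boundary_cycles(db), 1)
  validate_sheet(db)
})
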