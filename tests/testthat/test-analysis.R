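test_that("geometry classification is noise- and motion-invariant", {
  mn <- tubule_indices(8, 3)
  base <- ideal_embedding(mn, 7)
  set.seed(2)
  noisy <- base
  noisy$vertices <- base$vertices + matrix(rnorm(length(base$vertices), 0, 0.05),
                                           ncol = 3)
  ang <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  noisy$vertices <- noisy$vertices %*% R + 5
  got <- classify_geometry(noisy)
  expect_identical(c(got$m, got$n), c(8L, 3L))
})

test_that("fixtures are classified into their declared categories", {
  tub <- make_fixture("ideal_tubule", tgt10, size = 6)
  expect_identical(classify_outcome(tub, closed = TRUE)$category, "defect_free")
  sp <- make_fixture("spiral_open", tgt10, size = 5)
  expect_identical(classify_outcome(sp, closed = FALSE)$category, "open")
  cr <- make_fixture("cracked_defective", tgt10, size = 6)
  expect_identical(classify_outcome(cr, closed = TRUE)$category, "defective")
  # unfinished trajectories are flagged and excluded
  expect_identical(classify_outcome(tub, TRUE, finished = FALSE)$category,
                   "unfinished")
})

test_that("a sheet gluing two different half-tubes is defective", {
  # (10,0) tube with its top half re-indexed to break the lattice: emulate by
  # cracking an interior edge, which leaves a slit (three boundary cycles)
  cr <- make_fixture("cracked_defective", tgt10, size = 6)
  expect_length(boundary_cycles(cr), 3)
  expect_identical(classify_outcome(cr, TRUE)$category, "defective")
})

test_that("length and diameter follow from area conservation", {
  ld <- measure_L_D(tgt10, 200)
  expect_equal(ld$D, 10 / pi, tolerance = 1e-12)
  expect_equal(ld$L, 200 * (sqrt(3) / 4) / 10, tolerance = 1e-12)
  expect_equal(ld$L, 8.660, tolerance = 1e-3)
  expect_equal(measure_L_D(tgt10, 400)$L, 2 * ld$L)
})

test_that("aggregation reproduces closed-form two-point statistics", {
  rec <- function(m, n, N = 150) {
    classify_outcome(ideal_embedding(tubule_indices(m, n), 4), TRUE,
                     N_close = 60)
  }
  r9 <- rec(9, 0); r11 <- rec(11, 0)
  # all identical
  s1 <- aggregate_outcomes(list(r9, r9, r9), tubule_indices(9, 0))
  expect_equal(s1$yield, s1$frac_defect_free)
  expect_equal(s1$Delta_D, 0)
  # 50/50 (9,0)/(11,0): D_mean = 10/pi, Delta_D = 1/pi
  s2 <- aggregate_outcomes(list(r9, r11, r9, r11), tubule_indices(10, 0))
  expect_equal(s2$D_mean, 10 / pi, tolerance = 1e-12)
  expect_equal(s2$Delta_D, 1 / pi, tolerance = 1e-12)
  expect_equal(s2$frac_defect_free + s2$frac_defective + s2$frac_open, 1)
  expect_equal(sum(s2$geometry_fractions), 1)
  expect_equal(s2$yield, 0)
})
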