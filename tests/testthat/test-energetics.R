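test_that("the target's own ideal embedding has zero elastic energy", {
  sheet <- ideal_embedding(tgt10, 5)
  e <- total_energy(sheet, p10)
  nb <- sum(edge_table(sheet)$state == "bound")
  expect_lt(e$E_bend / nb, 1e-10)
  expect_lt(e$E_stretch, 1e-10)
  expect_equal(e$E_bind, -p10$E_B * nb)
  expect_equal(e$E_total, e$E_stretch + e$E_bend + e$E_bind)
})

test_that("a relaxed free monomer has zero energy", {
  s <- triangulated_sheet(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                          matrix(1:3, 1))
  e <- total_energy(s, p10)
  expect_lt(abs(e$E_total), 1e-12)
})

test_that("off-target bending follows the per-edge ideal-angle sum", {
  sheet <- ideal_embedding(tubule_indices(9, 0), 5)
  e <- total_energy(sheet, p10)
  et <- edge_table(sheet)
  b <- et[et$state == "bound", ]
  th9 <- ideal_dihedrals(tubule_indices(9, 0))
  th10 <- ideal_dihedrals(tgt10)
  manual <- sum(p10$B / 2 * (th9[b$type] - th10[b$type])^2)
  expect_equal(e$E_bend, manual, tolerance = 1e-9)
})

test_that("energy terms are invariant under rigid motion and linear in moduli", {
  sheet <- make_fixture("bent_disk", tgt10, size = 20)
  set.seed(4)
  sheet$vertices <- sheet$vertices + matrix(rnorm(length(sheet$vertices), 0, 0.03),
                                            ncol = 3)
  e0 <- total_energy(sheet, p10)
  # rigid rotation + translation
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  s2 <- sheet
  s2$vertices <- sheet$vertices %*% R + matrix(rep(c(1, -2, 3), each = nrow(sheet$vertices)), ncol = 3)
  e1 <- total_energy(s2, p10)
  expect_lt(abs(e1$E_total - e0$E_total), 1e-9)
  # exact proportionality in B and k_S
  pB <- energy_params(E_B = p10$E_B, B = 2 * p10$B, k_S = p10$k_S, theta0 = p10$theta0)
  pK <- energy_params(E_B = p10$E_B, B = p10$B, k_S = 3 * p10$k_S, theta0 = p10$theta0)
  expect_equal(total_energy(sheet, pB)$E_bend, 2 * e0$E_bend)
  expect_equal(total_energy(sheet, pK)$E_stretch, 3 * e0$E_stretch)
  # binding is an integer multiple of -E_B
  expect_equal(e0$E_bind %% p10$E_B, 0)
})

test_that("incremental vertex energies match full recomputation", {
  sheet <- make_fixture("bent_disk", tgt10, size = 15)
  set.seed(11)
  for (rep in 1:12) {
    v <- sample.int(nrow(sheet$vertices), 1)
    new_pos <- sheet$vertices[v, ] + runif(3, -0.1, 0.1)
    dE <- energy_delta_vertex(sheet, v, new_pos, p10)
    s2 <- sheet
    s2$vertices[v, ] <- new_pos
    full <- total_energy(s2, p10)$E_total - total_energy(sheet, p10)$E_total
    expect_lt(abs(dE - full), 1e-9)
    sheet <- s2
  }
  # null move
  expect_equal(energy_delta_vertex(sheet, 1L, sheet$vertices[1L, ], p10), 0)
})

test_that("insertion at the preferred geometry costs exactly -E_B", {
  sheet <- ideal_embedding(tgt10, 5)
  et <- edge_table(sheet)
  fr <- which(et$state == "free")
  for (i in fr[c(1, 5, 9)]) {
    apex <- ideal_apex_position(sheet, et$tri1[i], et$corner1[i], p10)
    ins <- energy_delta_insertion(sheet, et$tri1[i], et$corner1[i], apex, p10)
    expect_lt(abs(ins$delta_E + p10$E_B), 1e-9)
    validate_sheet(ins$after)
  }
})

test_that("degenerate triangles raise an explicit dihedral error", {
  s <- triangulated_sheet(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0), c(2, 0, 0)),
    rbind(c(1L, 2L, 3L), c(2L, 1L, 4L)))  # second triangle collinear
  expect_error(total_energy(s, p10), "degenerate")
})
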