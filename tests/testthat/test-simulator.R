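# micro-system configuration: monomer <-> dimer exchange only (no fusion),
# flat preferred angles so the three dimer topologies are exactly symmetric
micro_cfg <- function(seed, sweeps, record_every = 2) {
  simulation_config(f_fusion = 0, p_seam = 0, seed = seed,
                    max_sweeps = sweeps, record_every = record_every)
}
run_micro <- function(mu, sweeps, seed, p = flat_params(), record_every = 2) {
  run_trajectory(tgt6, p, bath_conditions(mu = mu),
                 micro_cfg(seed, sweeps, record_every),
                 max_monomers = 2L, log_bound_types = TRUE)
}

test_that("trajectories are bit-identical for a fixed seed", {
  cfg <- simulation_config(seed = 77, max_sweeps = 3000)
  a <- run_trajectory(tgt6, p6, bath_conditions(), cfg)
  b <- run_trajectory(tgt6, p6, bath_conditions(), cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$events, b$events)
  expect_identical(a$sheet$vertices, b$sheet$vertices)
})

test_that("zero displacement width accepts trivially and moves nothing", {
  s <- single_monomer()
  r <- vertex_move(s, p6, simulation_config(delta_v = 0))
  expect_true(r$accepted)
  expect_identical(r$sheet$vertices, s$vertices)
})

test_that("the last monomer is never removable", {
  expect_length(removable_monomers(single_monomer()), 0)
  # a monomer with 2+ bound edges is not removable either
  sheet <- ideal_embedding(tgt6, 4)
  et <- edge_table(sheet)
  nb <- table(factor(c(et$tri1[et$state == "bound"],
                       et$tri2[et$state == "bound"]),
                     levels = seq_len(nrow(sheet$triangles))))
  expect_true(all(nb[removable_monomers(sheet)] == 1))
})

test_that("dimer occupancy matches the configurational-integral oracle", {
  mu <- -1; EB <- 4
  p <- flat_params(E_B = EB)
  # oracle: Z2/Z1 per bound type from the 3-D insertion integral averaged
  # over monomer configurations sampled with the reference R chain; the two
  # monomers of a dimer are interchangeable, hence the symmetry factor 1/2
  set.seed(5)
  s <- single_monomer()
  cfgv <- simulation_config(delta_v = 0.15)
  for (i in 1:1500) s <- vertex_move(s, p, cfgv)$sheet
  I_vals <- replicate(200, {
    for (j in 1:12) s <<- vertex_move(s, p, cfgv)$sheet
    u <- s$vertices[1, ]; v <- s$vertices[2, ]; o <- s$vertices[3, ]
    ctr <- ideal_apex_position(s, 1L, 1L, p)
    npts <- 3000; hw <- 0.9
    X <- sweep(matrix(runif(3 * npts, -hw, hw), ncol = 3), 2, ctr, "+")
    lu <- sqrt(rowSums(sweep(X, 2, u)^2)); lv <- sqrt(rowSums(sweep(X, 2, v)^2))
    dE <- p$k_S / 2 * ((lu - 1)^2 + (lv - 1)^2)
    n1 <- cross3(v - u, o - u); n1 <- n1 / sqrt(sum(n1^2))
    e <- (v - u) / sqrt(sum((v - u)^2))
    a <- matrix(rep(u - v, npts), ncol = 3, byrow = TRUE)
    bx <- sweep(X, 2, v)
    n2 <- cbind(a[, 2] * bx[, 3] - a[, 3] * bx[, 2],
                a[, 3] * bx[, 1] - a[, 1] * bx[, 3],
                a[, 1] * bx[, 2] - a[, 2] * bx[, 1])
    n2 <- n2 / sqrt(rowSums(n2^2))
    cx <- cbind(n1[2] * n2[, 3] - n1[3] * n2[, 2],
                n1[3] * n2[, 1] - n1[1] * n2[, 3],
                n1[1] * n2[, 2] - n1[2] * n2[, 1])
    th <- pi - atan2(cx %*% e, n2 %*% n1)
    dE <- dE + p$B / 2 * (th - pi)^2 - EB
    mean(exp(-dE)) * (2 * hw)^3
  })
  v_p <- 1
  ratio_attempt <- exp(mu) * 3 * mean(I_vals) / (2 * v_p)
  # series samples are time-weighted: one attempt lasts 1/W sweeps
  W1 <- 3 + 0.1 * 3; W2 <- 4 + 0.1 * 4
  predicted <- ratio_attempt * W1 / W2
  tr <- run_micro(mu, 4e5, seed = 9, p = p)
  f2 <- mean(tr$series$N == 2)
  measured <- f2 / (1 - f2)
  expect_lt(abs(measured - predicted) / predicted, 0.15)
})

test_that("the three dimer topologies are equally occupied under flat angles", {
  tr <- run_micro(-1, 1e6, seed = 21, record_every = 300)
  s <- tr$series
  tab <- table(factor(s$bound_type_code[s$N == 2], levels = c(1, 16, 256)))
  expect_gt(min(tab), 50)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("shifting mu shifts the dimer odds by exactly exp(d mu)", {
  f_at <- function(mu, seed) {
    s <- run_micro(mu, 4e5, seed)$series
    mean(s$N == 2)
  }
  f1 <- f_at(-1.0, 31); f2 <- f_at(-0.3, 32)
  odds_ratio <- (f2 / (1 - f2)) / (f1 / (1 - f1))
  expect_lt(abs(odds_ratio - exp(0.7)) / exp(0.7), 0.15)
})

test_that("fixed-sheet sampling satisfies equipartition", {
  sheet <- ideal_embedding(tgt6, 4)
  r <- .sample_fixed_topology_cpp(sheet$vertices, sheet$triangles, p6$theta0,
                                  p6$B, p6$k_S, p6$l0, 1.0, 0.0, integer(0),
                                  0.0, 400L, 3000L, 0.1, 3L, FALSE)
  nmodes <- 3 * nrow(sheet$vertices) - 6
  expect_lt(abs(mean(r$H_model) - nmodes / 2) / (nmodes / 2), 0.05)
})

test_that("nucleation requires binding energies above the threshold", {
  Ns <- function(EB) {
    p <- energy_params(E_B = EB, B = 20, target = tgt6)
    sapply(1:5, function(s) {
      run_trajectory(tgt6, p, bath_conditions(mu = -3),
                     simulation_config(seed = 400 + s, max_sweeps = 6000))$N_final
    })
  }
  expect_lte(median(Ns(3.5)), 3)          # sub-threshold: transient clusters
  expect_gt(median(Ns(6)), 50)            # well above: steady growth
})

test_that("reference fusion closes a crack and fission reopens it", {
  set.seed(8)
  sheet <- make_fixture("cracked_defective", tgt6, size = 5)
  expect_length(boundary_cycles(sheet), 3)
  p_weak <- energy_params(E_B = 1.2, B = 20, target = tgt6)
  cfg <- simulation_config(seed = 1)
  healed <- NULL
  for (i in 1:300) {
    r <- attempt_fusion_r(sheet, p_weak, cfg)
    if (r$accepted) { healed <- r$sheet; break }
  }
  expect_false(is.null(healed))
  expect_length(boundary_cycles(healed), 2)
  expect_identical(classify_outcome(healed, TRUE)$category, "defect_free")
  reopened <- NULL
  for (i in 1:2000) {
    r <- attempt_fission_r(healed, p_weak, cfg)
    if (r$accepted) { reopened <- r$sheet; break }
  }
  expect_false(is.null(reopened))
  # fusion adds bonds, the subsequent fission removes exactly one
  nb <- function(s) sum(edge_table(s)$state == "bound")
  expect_gt(nb(healed), nb(sheet))
  expect_identical(nb(reopened), nb(healed) - 1L)
  validate_sheet(reopened)
})

test_that("assembly stays a single connected structure", {
  tr <- run_trajectory(tgt6, p6, bath_conditions(),
                       simulation_config(seed = 5, max_sweeps = 15000))
  expect_gte(tr$N_final, 1)
  validate_sheet(tr$sheet)   # errors if not a single edge-connected sheet
})
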