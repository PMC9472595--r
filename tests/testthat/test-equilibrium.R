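test_that("bath relations are mutually inverse and match the stated values", {
  expect_equal(bath_concentration(-3, 1e-5), 1e-5 * exp(-3))
  expect_equal(bath_concentration(-3, 1e-5) * 1e9, 498, tolerance = 0.01)  # ~500 nM
  expect_equal(chemical_potential(1e-8, 1e-5), log(1e-3))
  expect_equal(chemical_potential(1e-8, 1e-5), -6.91, tolerance = 1e-3)
  expect_equal(chemical_potential(bath_concentration(-2.2), 1e-5), -2.2)
  expect_equal(chemical_potential(1e-5, 1e-5), 0)
  expect_error(bath_concentration(-3, 0), "nonpositive")
  expect_error(chemical_potential(-1, 1e-5), "nonpositive")
})

test_that("bulk free-energy density is -3 E_B / 2 - mu", {
  expect_equal(bulk_free_energy_density(6, -3), -6)
  expect_equal(bulk_free_energy_density(9, -7), -6.5)
  expect_equal(bulk_free_energy_density(0, 0), 0)
})

test_that("the discrete free energy separates line, binding, bending, entropy", {
  g_inf <- discrete_free_energy(tgt10, tgt10, B = 20, E_B = 6, L = Inf, s = 1.3)
  expect_equal(g_inf, -1.5 * 6 - 1.3)                 # zero bending at target
  g9 <- discrete_free_energy(tubule_indices(9, 0), tgt10, B = 20, E_B = 6,
                             L = Inf, s = 0.7)
  g10 <- discrete_free_energy(tgt10, tgt10, B = 20, E_B = 6, L = Inf, s = 0.7)
  expect_equal(g9 - g10,
               bending_energy_per_monomer(tubule_indices(9, 0), tgt10, 20))
  # line tension term decays as 1/L
  gL <- discrete_free_energy(tgt10, tgt10, 20, 6, L = 5, gamma = 2)
  expect_equal(gL - g_inf - 1.3, 2 * 2 * sqrt(3) / 4 / 5)
})

test_that("the lattice distribution is normalised with the right limits", {
  cand <- candidate_geometries(tgt10, width = 0.25)
  expect_true(all(c("m", "n", "multiplicity") %in% names(cand)))
  expect_true(any(cand$m == 10 & cand$n == 0))
  dB <- discrete_distribution(cand, N = 200, B = 1e5, target = tgt10)
  expect_equal(sum(dB$P), 1)
  expect_gt(dB$P[dB$m == 10 & dB$n == 0], 0.999)       # B -> inf: point mass
  d0 <- discrete_distribution(cand, N = 200, B = 0, target = tgt10)
  expect_equal(d0$P, cand$multiplicity / sum(cand$multiplicity))  # B = 0
  # two-candidate set against hand-evaluated Boltzmann factors
  two <- data.frame(m = c(10, 9), n = c(0, 1), multiplicity = c(1, 1))
  d2 <- discrete_distribution(two, N = 100, B = 20, target = tgt10)
  w <- exp(-100 * c(0, bending_energy_per_monomer(tubule_indices(9, 1), tgt10, 20)))
  expect_equal(d2$P, w / sum(w), tolerance = 1e-12)
  # monotone: raising B never favours an off-target over the target
  d20 <- discrete_distribution(cand, 200, 20, tgt10)
  d40 <- discrete_distribution(cand, 200, 40, tgt10)
  tgt_i <- which(d20$m == 10 & d20$n == 0)
  expect_true(all(d40$P[-tgt_i] / d40$P[tgt_i] <=
                    d20$P[-tgt_i] / d20$P[tgt_i] + 1e-12))
})

test_that("the Helfrich density has the cylinder-curvature form", {
  Bt <- discrete_to_continuum_modulus(20)
  D0 <- 10 / pi
  expect_equal(continuum_bend_density(D0, Bt, D0), 0)
  x <- 0.04   # symmetric in the curvature difference
  Dp <- 2 / (2 / D0 + x); Dm <- 2 / (2 / D0 - x)
  expect_equal(continuum_bend_density(Dp, Bt, D0),
               continuum_bend_density(Dm, Bt, D0))
  # quadratic expansion 2 B~ delta^2 / D0^4
  delta <- 1e-4
  expect_equal(continuum_bend_density(D0 + delta, Bt, D0),
               2 * Bt * delta^2 / D0^4, tolerance = 1e-3)
  expect_error(continuum_bend_density(-1, Bt, D0), "positive")
})

test_that("width fluctuations scale as the equipartition result", {
  Bt <- discrete_to_continuum_modulus(20)
  D0 <- 10 / pi; L <- 5
  dd <- continuum_width_fluctuation(Bt, D0, L)
  expect_equal(continuum_width_fluctuation(Bt, D0, 4 * L), dd / 2)
  expect_equal(continuum_width_fluctuation(4 * Bt, D0, L), dd / 2)
  # against direct quadrature of the full (non-quadratic) Boltzmann weight
  EofD <- function(D) pi * D * L * continuum_bend_density(D, Bt, D0)
  Z <- stats::integrate(function(D) exp(-EofD(D)), D0 / 2, 2 * D0)$value
  m1 <- stats::integrate(function(D) D * exp(-EofD(D)), D0 / 2, 2 * D0)$value / Z
  m2 <- stats::integrate(function(D) D^2 * exp(-EofD(D)), D0 / 2, 2 * D0)$value / Z
  expect_equal(sqrt(m2 - m1^2), dd, tolerance = 0.02)
})

test_that("the discrete-to-continuum modulus mapping is consistent", {
  expect_equal(discrete_to_continuum_modulus(0), 0)
  expect_equal(discrete_to_continuum_modulus(14), 7 * sqrt(3))
  # bending energy per area of an ideal (m,0) tubule relative to a flat
  # target matches the continuum density at its diameter for wide tubules
  flat <- c(pi, pi, pi)
  a0 <- sqrt(3) / 4
  for (m in c(10, 14)) {
    th <- ideal_dihedrals(tubule_indices(m, 0))
    disc <- sum(20 / 4 * (th - flat)^2) / a0
    cont <- continuum_bend_density(m / pi, discrete_to_continuum_modulus(20),
                                   Inf)
    expect_lt(abs(disc - cont) / cont, 0.1)
  }
})

test_that("TI free-energy differences match the lattice bending differences", {
  p <- energy_params(E_B = 6, B = 20, target = tgt10)
  fits <- lapply(c(9, 10, 11), function(m)
    thermodynamic_integration(tubule_indices(m, 0), 6L, p, seed = 101 + m))
  g <- vapply(fits, `[[`, numeric(1), "g")
  se <- vapply(fits, `[[`, numeric(1), "se")
  for (i in c(1, 3)) {
    m <- c(9, 10, 11)[i]
    dg <- g[i] - g[2]
    bend <- bending_energy_per_monomer(tubule_indices(m, 0), tgt10, 20)
    expect_gt(dg, 0)                      # off-targets cost free energy
    expect_lt(abs(dg - bend), 2 * sqrt(se[i]^2 + se[2]^2))
  }
})

test_that("the classical Einstein path is grid-stable on the target", {
  p <- energy_params(E_B = 6, B = 20, target = tgt10)
  r8 <- thermodynamic_integration(tgt10, 4L, p, method = "einstein",
                                  n_lambda = 16L, k_t = 40, seed = 5)
  r16 <- thermodynamic_integration(tgt10, 4L, p, method = "einstein",
                                   n_lambda = 32L, k_t = 40, seed = 6)
  shift <- abs(r8$F_total - r16$F_total)
  expect_lt(shift, 2 * sqrt((r8$se * r8$N)^2 + (r16$se * r16$N)^2))
})
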