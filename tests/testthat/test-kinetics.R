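kp20 <- kinetic_params(k0_grow = 1, k0_close = 1e-2, B = 20, target = tgt10,
                       N_max = 500L)

test_that("growth rate is proportional to the disk perimeter", {
  expect_equal(growth_rate(4 * 50, kp20), 2 * growth_rate(50, kp20))
  expect_equal(growth_rate(1, kp20), 2 * sqrt(pi * sqrt(3) / 4),
               tolerance = 1e-12)
  expect_equal(growth_rate(1, kp20), 2.331, tolerance = 1e-3)
  dt <- 1 / growth_rate(1:300, kp20)
  expect_true(all(diff(dt) < 0))
})

test_that("the closure indicator unlocks when the disk spans the circumference", {
  expect_identical(closure_indicator(tubule_indices(2, 0), 1, kp20), 0L)
  I <- closure_indicator(tgt10, 1:400, kp20)
  expect_true(all(diff(I) >= 0))           # once compatible, stays compatible
  Nstar <- which(I == 1L)[1L]
  expect_identical(Nstar, 182L)            # 2 sqrt(N a0 / pi) >= pi D(10,0)
})

test_that("closure rates carry the lattice bending barrier", {
  expect_equal(closure_rate(tgt10, 200, kp20),
               kp20$k0_close)              # zero barrier for the target
  # stiff lattice: off-target rates vanish, total reduces to the target term
  kpStiff <- kinetic_params(k0_close = 1e-2, B = 4000, target = tgt10)
  cand <- candidate_geometries(tgt10, width = 0.25)
  expect_equal(total_closure_rate(300, kpStiff, cand),
               kpStiff$k0_close, tolerance = 1e-6)
  # three-candidate hand sum
  three <- data.frame(m = c(10, 9, 11), n = c(0, 0, 0),
                      multiplicity = c(1, 1, 1))
  manual <- sum(vapply(c(10, 9, 11), function(m)
    closure_rate(tubule_indices(m, 0), 250, kp20), numeric(1)))
  expect_equal(total_closure_rate(250, kp20, three), manual)
})

test_that("the closure ledger conserves probability exactly", {
  tab <- solve_closure_table(kp20)
  expect_lt(abs(sum(tab$geometries$P) + tab$P_never - 1), 1e-12)
  expect_true(all(tab$geometries$P >= 0))
  # k0 -> 0: everything stays open; large k0: closes at first compatible size
  kp0 <- kinetic_params(k0_close = 1e-12, B = 20, target = tgt10, N_max = 500L)
  expect_gt(solve_closure_table(kp0)$P_never, 1 - 1e-6)
  kpInf <- kinetic_params(k0_close = 1e8, B = 20, target = tgt10, N_max = 500L)
  one <- data.frame(m = 10, n = 0, multiplicity = 1)
  tabInf <- solve_closure_table(kpInf, one)
  expect_lt(tabInf$P_never, 1e-12)
  first_open <- with(tabInf$sizes, N[which(k_close_total > 0)[1L]])
  expect_identical(first_open, 182L)       # the target unlock size
  expect_equal(tabInf$mean_N_close, first_open, tolerance = 1e-9)
})

test_that("a single constant-rate candidate follows the geometric closed form", {
  # freeze the growth interval by using a single size window
  kp <- kinetic_params(k0_grow = 1, k0_close = 5e-3, B = 20,
                       target = tubule_indices(3, 0), N0 = 60L, N_max = 260L)
  one <- data.frame(m = 3, n = 0, multiplicity = 1)
  tab <- solve_closure_table(kp, one)
  Ns <- tab$sizes$N
  lam <- kp$k0_close / growth_rate(Ns, kp)   # per-step closure probability
  manual_open <- cumprod(exp(-lam))
  expect_equal(tab$sizes$P_open,
               c(1, manual_open[-length(manual_open)]), tolerance = 1e-12)
  expect_equal(tab$P_never, manual_open[length(manual_open)], tolerance = 1e-12)
})

test_that("results are independent of the starting size below the unlock", {
  a <- solve_closure_table(kinetic_params(k0_close = 1e-2, B = 20,
                                          target = tgt10, N0 = 5L,
                                          N_max = 500L))
  b <- solve_closure_table(kinetic_params(k0_close = 1e-2, B = 20,
                                          target = tgt10, N0 = 60L,
                                          N_max = 500L))
  expect_equal(a$geometries$P, b$geometries$P, tolerance = 1e-12)
})

test_that("the Gillespie oracle converges to the deterministic ledger", {
  tab <- solve_closure_table(kp20)
  g <- gillespie_closure(kp20, n_trials = 20000L, seed = 3)
  tv <- 0.5 * (sum(abs(g$geometries$P - tab$geometries$P)) +
                 abs(g$P_never - tab$P_never))
  expect_lt(tv, 3 / sqrt(20000))
  # reproducible given the seed
  g2 <- gillespie_closure(kp20, n_trials = 2000L, seed = 9)
  g3 <- gillespie_closure(kp20, n_trials = 2000L, seed = 9)
  expect_identical(g2$geometries$P, g3$geometries$P)
})

test_that("phase-map trends: width falls with closure rate, narrows with B", {
  pm <- phase_map(c(5, 20), c(-3, -2, -1, 0), tgt10, N_max = 700L)
  for (B in c(5, 20)) {
    d <- pm[pm$B == B, ]
    d <- d[order(d$log_kratio), ]
    expect_true(all(diff(d$mean_D) <= 1e-9))       # mean width decreases
  }
  # fluctuations decrease with B, weakly dependent on the rate
  lo <- pm[pm$log_kratio == -2, ]
  expect_lt(lo$cv_D[lo$B == 20], lo$cv_D[lo$B == 5])
})

test_that("width fluctuations scale as B^(-1/2) in the quasi-continuum regime", {
  Bs <- c(1.25, 2.5, 5, 10)              # one decade, Delta_D above the
  dd <- vapply(Bs, function(B) {         # lattice spacing of diameters
    kp <- kinetic_params(k0_close = 0.1, B = B, target = tgt10, N_max = 700L)
    closure_summary(solve_closure_table(kp))$Delta_D
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(dd) ~ log(Bs)))[[2L]]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("kinetic rates are recovered from trajectories they generated", {
  # deterministic synthetic trajectories with known k0_grow and k0_close
  k0g <- 0.5; k0c <- 2e-2
  kp <- kinetic_params(k0_grow = k0g, k0_close = k0c, B = 20, target = tgt6,
                       N0 = 12L, N_max = 400L)
  set.seed(6)
  mk_traj <- function(seed) {
    g <- gillespie_closure(kp, data.frame(m = 6, n = 0, multiplicity = 1),
                           n_trials = 1L, seed = seed)
    ncl <- g$N_close[1L]
    Ns <- 12:(if (is.na(ncl)) 399L else ncl)
    tau <- c(0, cumsum(1 / growth_rate(Ns[-length(Ns)], kp)))
    list(series = data.frame(tau = tau, N = Ns),
         closed = !is.na(ncl), N_close = ncl)
  }
  trajs <- lapply(1:40, mk_traj)
  fit <- fit_kinetic_rates(trajs, tgt6)
  expect_lt(abs(fit$k0_grow - k0g) / k0g, 0.1)
  expect_lt(abs(log(fit$k0_close / k0c)), log(2.5))
})
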