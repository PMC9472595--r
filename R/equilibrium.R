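#' Bath concentration and chemical potential
#'
#' Mutually inverse maps between the free monomer concentration and the
#' chemical potential: `c0 = c_SS exp(mu / kBT)` and
#' `mu = kBT log(c0 / c_SS)`.
#'
#' @param mu chemical potential (kBT).
#' @param c0 free monomer concentration (same units as `c_SS`).
#' @param c_SS standard-state concentration (default 10 micromolar).
#' @return concentration (resp. chemical potential in kBT).
#' @export
bath_concentration <- function(mu, c_SS = 1e-5) {
  if (c_SS <= 0) stop("nonpositive concentration")
  c_SS * exp(mu)
}

#' @rdname bath_concentration
#' @export
chemical_potential <- function(c0, c_SS = 1e-5) {
  if (c0 <= 0 || c_SS <= 0) stop("nonpositive concentration")
  log(c0 / c_SS)
}

#' Bulk free-energy density of an assembled tubule
#'
#' Net free energy per monomer of tubule material relative to the bath,
#' `delta epsilon = -3 E_B / 2 - mu`: each monomer contributes three edges
#' shared between two monomers.
#'
#' @param E_B binding energy (kBT).
#' @param mu chemical potential (kBT).
#' @return free-energy density (kBT per monomer).
#' @export
bulk_free_energy_density <- function(E_B, mu) {
  -3 * E_B / 2 - mu
}

#' Per-monomer free energy of the discrete tubule model
#'
#' `g = 2 gamma a0 / L - (3/2) E_B + sum_i (B/4) (theta_i - theta0_i)^2 - T s`:
#' line tension at the two rims (vanishing as L grows), binding (three edges
#' shared by two monomers), bending (B/2 per bound edge, shared between two
#' monomers, so B/4 per monomer per edge type), and the per-monomer entropy.
#'
#' @param mn [tubule_indices()] of the geometry being scored.
#' @param target [tubule_indices()] of the target (defines `theta0`).
#' @param B bending modulus (kBT).
#' @param E_B binding energy (kBT).
#' @param L tubule length (l0); `Inf` drops the line-tension term.
#' @param gamma line tension (kBT / l0).
#' @param s per-monomer entropy (kB).
#' @param lat [lattice_constants()].
#' @return free energy per monomer (kBT).
#' @export
discrete_free_energy <- function(mn, target, B, E_B, L = Inf, gamma = 0,
                                 s = 0, lat = lattice_constants()) {
  stopifnot(L > 0)
  th <- ideal_dihedrals(mn, lat = lat)
  th0 <- ideal_dihedrals(target, lat = lat)
  line <- if (is.finite(L)) 2 * gamma * lat$a0 / L else 0
  line - 1.5 * E_B + sum(B / 4 * (th - th0)^2) - s
}

#' Per-monomer bending energy of a geometry relative to the target
#'
#' The geometry-dependent part of [discrete_free_energy()]:
#' `sum_i (B/4) (theta_i^{(m,n)} - theta_i^0)^2`.
#'
#' @inheritParams discrete_free_energy
#' @return bending energy per monomer (kBT).
#' @export
bending_energy_per_monomer <- function(mn, target, B, lat = lattice_constants()) {
  th <- ideal_dihedrals(mn, lat = lat)
  th0 <- ideal_dihedrals(target, lat = lat)
  sum(B / 4 * (th - th0)^2)
}

#' Candidate tubule geometries around a target
#'
#' All canonical `(m, n)` whose diameter lies within `width` of the target
#' diameter (relative), with a `multiplicity` column: 2 for chiral classes
#' (`1 <= n < m`, mirror pair) and 1 for achiral (`n = 0` or `n = m`).
#'
#' @param target [tubule_indices()].
#' @param width relative diameter window (default 0.4).
#' @param lat [lattice_constants()].
#' @return data.frame with `m`, `n`, `multiplicity`, `D`.
#' @export
candidate_geometries <- function(target, width = 0.4,
                                 lat = lattice_constants()) {
  D0 <- diameter(target, lat)
  out <- list()
  mmax <- ceiling((1 + width) * D0 * pi / lat$l0) + 1L
  for (m in 1:mmax) for (n in 0:m) {
    if (m * m + m * n + n * n < 7L) next
    D <- sqrt(m^2 + m * n + n^2) * lat$l0 / pi
    if (abs(D - D0) <= width * D0) {
      mult <- if (n == 0L || n == m) 1L else 2L
      out[[length(out) + 1L]] <- data.frame(m = m, n = n,
                                            multiplicity = mult, D = D)
    }
  }
  do.call(rbind, out)
}

#' Equilibrium geometry distribution of the discrete model
#'
#' `P(m, n) proportional to mult * exp[-N sum_i (B/4)(theta_i - theta0_i)^2]`,
#' normalized over the candidate set (per-monomer entropy assumed geometry
#' independent, so it cancels).  `N` may be a scalar (fixed structure size)
#' or `"fixed_L"` is emulated by passing per-candidate sizes.
#'
#' @param candidates data.frame from [candidate_geometries()] (or with
#'   columns `m`, `n`, optionally `multiplicity`).
#' @param N structure size in monomers: scalar, or vector matching
#'   `candidates` rows.
#' @param B bending modulus (kBT).
#' @param target [tubule_indices()].
#' @param lat [lattice_constants()].
#' @return data.frame `m`, `n`, `D`, `P` (sums to 1).
#' @export
discrete_distribution <- function(candidates, N, B, target,
                                  lat = lattice_constants()) {
  if (nrow(candidates) == 0L) stop("empty candidate set")
  mult <- if ("multiplicity" %in% names(candidates))
    candidates$multiplicity else rep(1L, nrow(candidates))
  Ns <- rep_len(N, nrow(candidates))
  eb <- vapply(seq_len(nrow(candidates)), function(i) {
    bending_energy_per_monomer(tubule_indices(candidates$m[i], candidates$n[i]),
                               target, B, lat)
  }, numeric(1))
  w <- log(mult) - Ns * eb
  w <- exp(w - max(w))
  data.frame(m = candidates$m, n = candidates$n,
             D = sqrt(candidates$m^2 + candidates$m * candidates$n +
                        candidates$n^2) * lat$l0 / pi,
             P = w / sum(w))
}

#' Helfrich bending energy density of a cylinder
#'
#' `(B_tilde / 2) (2/D - 2/D0)^2` per unit area: a cylinder of diameter `D`
#' has total curvature `2/D`, and the target structure `2/D0`.
#'
#' @param D cylinder diameter (l0), `> 0`.
#' @param B_tilde continuum bending modulus (kBT).
#' @param D0 target diameter (l0).
#' @return energy per unit area (kBT / l0^2).
#' @export
continuum_bend_density <- function(D, B_tilde, D0) {
  if (any(D <= 0)) stop("D must be positive")
  B_tilde / 2 * (2 / D - 2 / D0)^2
}

#' Equilibrium tubule width fluctuation (continuum model)
#'
#' Equipartition on the quadratic expansion of the total bending energy
#' `E(D) = pi D L x density(D)` gives
#' `Delta D / D0 = sqrt(kBT D0 / (4 pi B_tilde L))`: fluctuations shrink
#' with bending modulus and tubule length as `B^{-1/2}` and `L^{-1/2}` and
#' grow with target diameter as `D0^{1/2}`.
#'
#' @param B_tilde continuum bending modulus (kBT).
#' @param D0 target diameter (l0).
#' @param L tubule length (l0).
#' @return `Delta D` (l0).
#' @export
continuum_width_fluctuation <- function(B_tilde, D0, L) {
  stopifnot(B_tilde > 0, D0 > 0, L > 0)
  D0 * sqrt(D0 / (4 * pi * B_tilde * L))
}

#' Discrete-to-continuum bending modulus
#'
#' The standard triangulated-membrane mapping `B_tilde = (sqrt(3)/2) B` for
#' a dihedral-harmonic bending energy on an equilateral lattice.
#'
#' @param B discrete bending modulus (kBT), `>= 0`.
#' @return continuum modulus (kBT).
#' @export
discrete_to_continuum_modulus <- function(B) {
  stopifnot(B >= 0)
  sqrt(3) / 2 * B
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch on the Jacobi matrix)
gauss_legendre_01 <- function(n) {
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

#' Einstein-solid thermodynamic integration of a closed tubule lattice
#'
#' Computes the absolute free energy of a fixed-topology tubule along a
#' thermodynamic pathway anchored at an Einstein solid (independent Gaussian
#' tethers of spring `k_t` to the relaxed lattice).  Three well-separated
#' anchor vertices carry an additional constant tether `k_anchor` at every
#' stage, pinning rigid-body modes.  Binding energy is constant at fixed
#' topology and added analytically.  The configurational measure is one
#' factor `1/v_p` per vertex (the association proposal volume of the
#' simulator), so per-monomer free energies are directly comparable with the
#' bath chemical potential.
#'
#' Two methods are provided.  `"bridge"` (default) splits the pathway at the
#' harmonic (Hessian) expansion of the model about its minimum: the Einstein
#' solid to coupled-harmonic-crystal step is analytic (a ratio of Gaussian
#' determinants), and only the small anharmonic remainder is estimated
#' stochastically, by Bennett's acceptance-ratio bridge between exact
#' Gaussian draws and Metropolis samples of the full model.  `"einstein"` is
#' the classical single-path Gauss-Legendre integration of
#' `<H_model - H_ref>` over `H_lambda = lambda H_model + (1-lambda) H_ref`;
#' it is retained for cross-checks but resolves the soft modes of
#' prestressed (off-target) lattices poorly unless the node count is large.
#'
#' @param mn [tubule_indices()] of the lattice geometry.
#' @param rows lattice rows (sets `N = 2 m (rows - 1)` for achiral tubules).
#' @param p [energy_params()] (its `theta0` defines the target).
#' @param method `"bridge"` or `"einstein"`.
#' @param n_lambda Gauss-Legendre nodes (einstein path).
#' @param sweeps_eq,sweeps_sample equilibration / sampling sweeps (per node
#'   for the einstein path; for the model side of the bridge).
#' @param n_draws Gaussian draws for the harmonic side of the bridge.
#' @param k_t tether spring (kBT / l0^2).
#' @param k_anchor constant anchor spring (kBT / l0^2).
#' @param delta_v vertex move half-width.
#' @param seed RNG seed.
#' @param v_p configurational measure volume per vertex (l0^3).
#' @return list with `g` (free energy per monomer, kBT), `se`, `F_total`,
#'   `N`, `n_bound`, `E_bind`, `E_min`, and method-specific diagnostics.
#' @export
thermodynamic_integration <- function(mn, rows, p,
                                      method = c("bridge", "einstein"),
                                      n_lambda = 16L,
                                      sweeps_eq = 300L, sweeps_sample = 1500L,
                                      n_draws = 4000L,
                                      k_t = 200, k_anchor = 20,
                                      delta_v = 0.08, seed = 1L, v_p = 1) {
  method <- match.arg(method)
  sheet <- ideal_embedding(mn, rows, lattice_constants(p$l0))
  # relax to the minimum of the scored Hamiltonian: for off-target
  # geometries the ideal embedding is not the minimum (stretch and bend
  # trade off), and a shifted tether centre biases the integration
  sheet$vertices <- relax_sheet(sheet, p, seed)
  V <- nrow(sheet$vertices)
  N <- nrow(sheet$triangles)
  et <- edge_table(sheet)
  n_bound <- sum(et$state == "bound")
  anchors <- pick_anchors(sheet$vertices)
  E_bind <- -p$E_B * n_bound
  E_min <- .sheet_energy_cpp(sheet$vertices, sheet$triangles, p$theta0,
                             p$B, p$k_S, p$l0)
  if (method == "bridge") {
    out <- ti_bridge(sheet, p, anchors, k_anchor, E_min, n_draws,
                     sweeps_eq, sweeps_sample, delta_v, seed, v_p)
  } else {
    out <- ti_einstein(sheet, p, anchors, k_t, k_anchor, n_lambda,
                       sweeps_eq, sweeps_sample, delta_v, seed, v_p)
  }
  F_total <- out$F + E_bind
  c(list(g = F_total / N, se = out$se / N, F_total = F_total,
         N = N, V = V, n_bound = n_bound, E_bind = E_bind, E_min = E_min,
         anchors = anchors, seed = seed, method = method), out$extra)
}

# thorough relaxation: stochastic quench then quasi-Newton polish
relax_sheet <- function(sheet, p, seed = 1L) {
  v <- .quench_fixed_topology_cpp(sheet$vertices, sheet$triangles, p$theta0,
                                  p$B, p$k_S, p$l0, 800L, 0.05,
                                  as.integer(seed))
  tri <- sheet$triangles
  x0 <- as.vector(t(v))
  fn <- function(x) .sheet_energy_cpp(matrix(x, ncol = 3L, byrow = TRUE),
                                      tri, p$theta0, p$B, p$k_S, p$l0)
  gr <- function(x) fd_gradient(fn, x)
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 300L, factr = 1e4))
  matrix(opt$par, ncol = 3L, byrow = TRUE)
}

fd_gradient <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# numeric Hessian of the model energy about x0 (gradient differences)
fd_hessian <- function(fn, x0, h = 5e-5) {
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    H[i, ] <- (fd_gradient(fn, xp, h) - fd_gradient(fn, xm, h)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Einstein -> harmonic (analytic) -> full model (Bennett bridge)
ti_bridge <- function(sheet, p, anchors, k_anchor, E_min, n_draws,
                      sweeps_eq, sweeps_sample, delta_v, seed, v_p) {
  tri <- sheet$triangles
  x0 <- as.vector(t(sheet$vertices))
  n <- length(x0)
  fn <- function(x) .sheet_energy_cpp(matrix(x, ncol = 3L, byrow = TRUE),
                                      tri, p$theta0, p$B, p$k_S, p$l0)
  A <- fd_hessian(fn, x0)
  # anchor springs pin the six rigid-body modes
  aidx <- as.vector(rbind(3L * (anchors - 1L) + 1L, 3L * (anchors - 1L) + 2L,
                          3L * (anchors - 1L) + 3L))
  diag(A)[aidx] <- diag(A)[aidx] + k_anchor
  ev <- eigen(A, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < 1e-8)
    stop(sprintf("harmonic reference not positive definite (min eig %.3e): relaxation failed",
                 min(lam)))
  # F of the anchored harmonic crystal (measure dx / v_p per vertex)
  F_harm <- E_min + 0.5 * sum(log(lam / (2 * pi))) + (n / 3) * log(v_p)
  # Bennett bridge harmonic -> model (both with anchor springs included)
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  draws <- x0 + ev$vectors %*% (z / sqrt(lam))
  H_anchor <- function(xmat) 0.5 * k_anchor *
    colSums((xmat[aidx, , drop = FALSE] - x0[aidx])^2)
  quad_form <- function(xmat) {
    d <- xmat - x0
    y <- crossprod(ev$vectors, d)
    0.5 * colSums(y^2 * lam)
  }
  E_model_draws <- apply(draws, 2, fn) + H_anchor(draws)
  u_fwd <- E_model_draws - (E_min + quad_form(draws))   # H_model' - H_harm
  # model-side samples from the Metropolis sampler (anchored, lambda = 1)
  r <- .sample_fixed_topology_cpp(
    sheet$vertices, tri, p$theta0, p$B, p$k_S, p$l0,
    1.0, 0, as.integer(anchors), k_anchor,
    as.integer(sweeps_eq), as.integer(sweeps_sample), delta_v,
    as.integer(seed + 7919L), TRUE)
  xs <- r$positions                      # n x sweeps matrix
  E_model_samp <- r$H_model + H_anchor(xs)
  u_rev <- E_model_samp - (E_min + quad_form(xs))
  bar <- bennett_bar(u_fwd, u_rev)
  # model-side samples are autocorrelated: block bootstrap the estimate
  bar$se <- bar_block_se(u_fwd, u_rev)
  list(F = F_harm + bar$dF, se = bar$se,
       extra = list(F_harm = F_harm, dF_anh = bar$dF,
                    u_fwd_mean = mean(u_fwd), u_rev_mean = mean(u_rev),
                    min_eig = min(lam)))
}

# Bennett acceptance ratio for dF = F_1 - F_0 from u drawn in state 0
# (u_fwd = U1 - U0 on 0-samples) and state 1 (u_rev = U1 - U0 on 1-samples)
bennett_bar <- function(u_fwd, u_rev, tol = 1e-10) {
  n0 <- length(u_fwd); n1 <- length(u_rev)
  M <- log(n0 / n1)
  obj <- function(C) {
    mean(stats::plogis(-(u_fwd - C))) - mean(stats::plogis(u_rev - C))
  }
  lo <- min(u_fwd, u_rev) - 10; hi <- max(u_fwd, u_rev) + 10
  C <- stats::uniroot(obj, c(lo, hi), tol = tol)$root
  dF <- C - M
  # Bennett variance estimate
  f0 <- stats::plogis(-(u_fwd - C)); f1 <- stats::plogis(u_rev - C)
  var0 <- (mean(f0^2) / mean(f0)^2 - 1) / n0
  var1 <- (mean(f1^2) / mean(f1)^2 - 1) / n1
  list(dF = dF, se = sqrt(var0 + var1))
}

# standard error of the Bennett estimate by bootstrap: iid resampling of the
# Gaussian-side samples and moving-block resampling of the (autocorrelated)
# Metropolis-side samples
bar_block_se <- function(u_fwd, u_rev, block = 50L, reps = 200L) {
  n1 <- length(u_fwd); n2 <- length(u_rev)
  nb <- max(n2 %/% block, 1L)
  vals <- vapply(seq_len(reps), function(r) {
    uf <- u_fwd[sample.int(n1, n1, replace = TRUE)]
    starts <- sample.int(max(n2 - block + 1L, 1L), nb, replace = TRUE)
    ur <- unlist(lapply(starts, function(s)
      u_rev[s:min(s + block - 1L, n2)]))
    tryCatch(bennett_bar(uf, ur)$dF, error = function(e) NA_real_)
  }, numeric(1))
  stats::sd(vals, na.rm = TRUE)
}

# classical single-path Einstein integration (Gauss-Legendre in lambda)
ti_einstein <- function(sheet, p, anchors, k_t, k_anchor, n_lambda,
                        sweeps_eq, sweeps_sample, delta_v, seed, v_p) {
  V <- nrow(sheet$vertices)
  gl <- gauss_legendre_01(n_lambda)
  integrand <- numeric(n_lambda)
  ise <- numeric(n_lambda)
  for (i in seq_len(n_lambda)) {
    r <- .sample_fixed_topology_cpp(
      sheet$vertices, sheet$triangles, p$theta0, p$B, p$k_S, p$l0,
      gl$nodes[i], k_t, as.integer(anchors), k_anchor,
      as.integer(sweeps_eq), as.integer(sweeps_sample), delta_v,
      as.integer(seed + 1000L * i), FALSE)
    d <- r$H_model - r$H_ref
    integrand[i] <- mean(d)
    ise[i] <- blocked_se(d)
  }
  dF <- sum(gl$weights * integrand)
  springs <- rep(k_t, V)
  springs[anchors] <- springs[anchors] + k_anchor
  F_ref <- -sum(1.5 * log(2 * pi / springs)) + V * log(v_p)
  list(F = F_ref + dF, se = sqrt(sum((gl$weights * ise)^2)),
       extra = list(F_ref = F_ref, dF = dF,
                    nodes = data.frame(lambda = gl$nodes,
                                       weight = gl$weights,
                                       integrand = integrand, se = ise)))
}

# three well-separated, non-collinear anchor vertices
pick_anchors <- function(pos) {
  a1 <- 1L
  d1 <- rowSums(sweep(pos, 2, pos[a1, ])^2)
  a2 <- which.max(d1)
  e <- pos[a2, ] - pos[a1, ]
  e <- e / sqrt(sum(e^2))
  rel <- sweep(pos, 2, pos[a1, ])
  perp2 <- rowSums(rel^2) - (rel %*% e)^2
  a3 <- which.max(perp2)
  unique(c(a1, a2, a3))
}

blocked_se <- function(x, block = 50L) {
  nb <- length(x) %/% block
  if (nb < 2L) return(stats::sd(x) / sqrt(max(length(x), 2L)))
  bm <- vapply(seq_len(nb), function(i)
    mean(x[((i - 1L) * block + 1L):(i * block)]), numeric(1))
  stats::sd(bm) / sqrt(nb)
}

#' Binding-affinity threshold for assembly from TI
#'
#' The per-monomer free energy is linear in `E_B` (binding enters only as
#' `-E_B n_bound / N`), so a single TI run at `E_B = E_B0` gives the
#' threshold affinity at which `g` crosses the bath chemical potential:
#' the tubule phase out-competes free monomers for `E_B` above it.  Rim
#' (line-tension) effects are removed by extrapolating `g` linearly in
#' `1 / rows` from two lattice sizes.
#'
#' @param target [tubule_indices()].
#' @param p [energy_params()] at a reference `E_B`.
#' @param mu bath chemical potential (kBT).
#' @param rows_pair two lattice sizes for the rim extrapolation.
#' @param ... forwarded to [thermodynamic_integration()].
#' @return list with `E_B_threshold`, `g0_inf` (bulk `g` at `E_B = 0`), the
#'   two TI fits and propagated `se`.
#' @export
critical_binding_energy <- function(target, p, mu = -3,
                                    rows_pair = c(4L, 7L), ...) {
  fits <- lapply(rows_pair, function(r)
    thermodynamic_integration(target, r, p, ...))
  # remove binding, normalise to E_B = 0, per monomer
  g0 <- vapply(fits, function(f) (f$F_total - f$E_bind) / f$N, numeric(1))
  bpm <- vapply(fits, function(f) f$n_bound / f$N, numeric(1))
  x <- 1 / (rows_pair - 1)            # rim boundary fraction ~ 1 / length
  # linear extrapolation of g0 and bonds-per-monomer to the bulk limit
  g0_inf <- g0[2] + (g0[2] - g0[1]) / (x[2] - x[1]) * (0 - x[2])
  bpm_inf <- 1.5                       # every edge shared in the bulk limit
  se <- sqrt(sum(vapply(fits, function(f) f$se^2, numeric(1))))
  E_B_threshold <- (g0_inf - mu) / bpm_inf
  list(E_B_threshold = E_B_threshold, g0_inf = g0_inf, se = se,
       fits = fits, bonds_per_monomer = bpm)
}
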