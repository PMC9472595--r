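#' Kinetic growth-closure model parameters
#'
#' Parameters of the deterministic growth-closure competition: an open,
#' curved disk of `N` monomers grows at a rate proportional to its boundary
#' length and attempts to close into any geometrically compatible tubule
#' `(m, n)` at a rate suppressed exponentially by the elastic barrier of
#' bending the disk to that geometry's curvature.
#'
#' @param k0_grow intrinsic growth-rate prefactor (1/time); depends on the
#'   bending modulus and binding energy of the underlying dynamics.
#' @param k0_close closure attempt rate: the rate at which an isotropic open
#'   structure closes into the target geometry (zero barrier).
#' @param B discrete bending modulus (kBT); converted internally to the
#'   continuum modulus.
#' @param target [tubule_indices()].
#' @param N0 initial size (monomers); results are independent of `N0` as
#'   long as it is below the first closure-compatible size.
#' @param N_max truncation size.
#' @param lat [lattice_constants()].
#' @return list of class `kinetic_params`.
#' @export
kinetic_params <- function(k0_grow = 1, k0_close = 1e-3, B = 20,
                           target = tubule_indices(10, 0), N0 = 5L,
                           N_max = 600L, lat = lattice_constants()) {
  stopifnot(k0_grow >= 0, k0_close >= 0, N0 >= 1L, N0 < N_max)
  structure(list(k0_grow = k0_grow, k0_close = k0_close, B = B,
                 B_tilde = discrete_to_continuum_modulus(B),
                 target = target, N0 = as.integer(N0),
                 N_max = as.integer(N_max), lat = lat),
            class = "kinetic_params")
}

#' Growth rate of an open disk
#'
#' `k_grow(N) = k0_grow * P(N) / l0` with the isoperimetric disk perimeter
#' `P(N) = 2 sqrt(pi N a0)`: growth is proportional to the boundary length.
#'
#' @param N disk size (monomers), `>= 1`.
#' @param kp [kinetic_params()].
#' @return growth rate (1/time).
#' @export
growth_rate <- function(N, kp) {
  stopifnot(all(N >= 1))
  kp$k0_grow * 2 * sqrt(pi * N * kp$lat$a0) / kp$lat$l0
}

#' Closure compatibility indicator
#'
#' `1` when the disk is wide enough to span the `(m, n)` circumference:
#' `2 sqrt(N a0 / pi) >= pi D(m, n)`; monotone nondecreasing in `N`.
#'
#' @param mn [tubule_indices()].
#' @param N disk size(s).
#' @param kp [kinetic_params()].
#' @return 0/1 vector.
#' @export
closure_indicator <- function(mn, N, kp) {
  as.integer(2 * sqrt(N * kp$lat$a0 / pi) >= pi * diameter(mn, kp$lat))
}

#' Closure rate into one geometry, and the total over candidates
#'
#' `k^(m,n)(N) = k0_close * I^(m,n)(N) * exp(-dG(m,n,N))` with the barrier
#' `dG = N * sum_i (B/4)(theta_i^(m,n) - theta_i^0)^2`, the elastic cost of
#' bending the whole `N`-monomer disk from the stress-free (target) dihedral
#' angles to the `(m, n)` angles.  The discrete per-monomer bending energy
#' is used rather than its continuum (Helfrich) limit because geometries of
#' nearly equal diameter but different chirality still differ in their
#' dihedral pattern; the barrier is exactly zero for the target, consistent
#' with `k0_close` being defined as the target closure attempt rate, and the
#' resulting closed-geometry split at fixed `N` reproduces the equilibrium
#' lattice distribution at that size.
#'
#' @param mn [tubule_indices()].
#' @param N disk size(s).
#' @param kp [kinetic_params()].
#' @return rate(s) (1/time).
#' @export
closure_rate <- function(mn, N, kp) {
  dG <- N * bending_energy_per_monomer(mn, kp$target, kp$B, kp$lat)
  kp$k0_close * closure_indicator(mn, N, kp) * exp(-dG)
}

#' @rdname closure_rate
#' @param candidates data.frame from [candidate_geometries()].
#' @export
total_closure_rate <- function(N, kp, candidates) {
  tot <- 0
  for (i in seq_len(nrow(candidates))) {
    mn <- tubule_indices(candidates$m[i], candidates$n[i])
    mult <- if ("multiplicity" %in% names(candidates))
      candidates$multiplicity[i] else 1L
    tot <- tot + mult * closure_rate(mn, N, kp)
  }
  tot
}

#' Solve the deterministic growth-closure ledger
#'
#' The disk grows by one monomer at regular intervals `dt_N = 1/k_grow(N)`
#' (growth stochasticity ignored); while at size `N` it closes with total
#' rate `k_tot(N)`.  The recursion
#' `P_open(N+1) = P_open(N) exp(-k_tot(N) dt_N)` and
#' `P_close(N) = P_open(N) (1 - exp(-k_tot(N) dt_N))` conserves probability
#' exactly; the per-geometry split is the conditional
#' `P(m,n) = sum_N P_close(N) k^(m,n)(N) / k_tot(N)`.  Closed structures
#' never reopen.
#'
#' @param kp [kinetic_params()].
#' @param candidates data.frame of candidate geometries (default: diameters
#'   within 40 percent of the target, both chiralities via `multiplicity`).
#' @return list of class `closure_table`: per-size data.frame (`N`, `dt`,
#'   `t`, `k_close_total`, `P_open`, `P_close`), per-geometry data.frame
#'   (`m`, `n`, `D`, `P`), `P_never` (mass still open at `N_max`), and
#'   closure-size moments.
#' @export
solve_closure_table <- function(kp, candidates = NULL) {
  if (is.null(candidates)) candidates <- candidate_geometries(kp$target,
                                                              lat = kp$lat)
  Ns <- kp$N0:(kp$N_max - 1L)
  dt <- 1 / growth_rate(Ns, kp)
  mult <- if ("multiplicity" %in% names(candidates))
    candidates$multiplicity else rep(1L, nrow(candidates))
  # per-candidate rate matrix (candidates x N)
  K <- matrix(0, nrow(candidates), length(Ns))
  for (i in seq_len(nrow(candidates))) {
    K[i, ] <- mult[i] *
      closure_rate(tubule_indices(candidates$m[i], candidates$n[i]), Ns, kp)
  }
  ktot <- colSums(K)
  stay <- exp(-ktot * dt)
  P_open <- c(1, cumprod(stay))             # P_open[j] = open upon reaching Ns[j]
  P_close_N <- P_open[seq_along(Ns)] * (1 - stay)
  P_never <- P_open[length(P_open)]
  # conditional geometry split at each size
  Pmn <- numeric(nrow(candidates))
  for (j in seq_along(Ns)) {
    if (ktot[j] > 0 && P_close_N[j] > 0)
      Pmn <- Pmn + P_close_N[j] * K[, j] / ktot[j]
  }
  geo <- data.frame(m = candidates$m, n = candidates$n,
                    D = vapply(seq_len(nrow(candidates)), function(i)
                      diameter(tubule_indices(candidates$m[i],
                                              candidates$n[i]), kp$lat),
                      numeric(1)),
                    P = Pmn)
  sizes <- data.frame(N = Ns, dt = dt, t = cumsum(dt) - dt,
                      k_close_total = ktot,
                      P_open = P_open[seq_along(Ns)], P_close = P_close_N)
  Pc <- sum(P_close_N)
  mean_Nclose <- if (Pc > 0) sum(Ns * P_close_N) / Pc else NA_real_
  structure(list(sizes = sizes, geometries = geo, P_never = P_never,
                 P_closed = Pc, mean_N_close = mean_Nclose,
                 params = kp, candidates = candidates),
            class = "closure_table")
}

#' @export
print.closure_table <- function(x, ...) {
  cat(sprintf(
    "closure table: target %s, closed mass %.3f, never-closed %.3f, mean N_close %.1f\n",
    format(x$params$target), x$P_closed, x$P_never, x$mean_N_close))
  top <- x$geometries[order(-x$geometries$P), ][1:min(5, nrow(x$geometries)), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Summary statistics of a closure table
#'
#' Yield of the target (its absolute closure probability over the whole
#' population including never-closed mass), closed fraction, and the mean
#' and fluctuation of the closed-tubule diameter.
#'
#' @param tab a [solve_closure_table()] result.
#' @return one-row data.frame.
#' @export
closure_summary <- function(tab) {
  g <- tab$geometries
  tgt <- tab$params$target
  yield <- sum(g$P[g$m == tgt$m & g$n == tgt$n])
  Pc <- sum(g$P)
  if (Pc > 0) {
    Dbar <- sum(g$P * g$D) / Pc
    Dsd <- sqrt(pmax(sum(g$P * g$D^2) / Pc - Dbar^2, 0))
  } else {
    Dbar <- NA_real_; Dsd <- NA_real_
  }
  data.frame(yield = yield, closed_fraction = Pc, mean_D = Dbar,
             Delta_D = Dsd, cv_D = Dsd / Dbar)
}

#' Phase map of the kinetic model
#'
#' Evaluates the closure table over a grid of bending moduli and normalized
#' closure rates `log10(k0_close / k0_grow)`, reporting yield, closed
#' fraction, mean width and width fluctuation at each grid point.
#'
#' @param B_grid bending moduli (kBT).
#' @param log_kratio_grid `log10(k0_close / k0_grow)` values.
#' @param target [tubule_indices()].
#' @param N_max truncation size.
#' @param lat [lattice_constants()].
#' @return data.frame with one row per grid point.
#' @export
phase_map <- function(B_grid, log_kratio_grid,
                      target = tubule_indices(10, 0), N_max = 600L,
                      lat = lattice_constants()) {
  stopifnot(length(B_grid) > 0, length(log_kratio_grid) > 0)
  out <- list()
  for (B in B_grid) for (lk in log_kratio_grid) {
    kp <- kinetic_params(k0_grow = 1, k0_close = 10^lk, B = B,
                         target = target, N_max = N_max, lat = lat)
    s <- closure_summary(solve_closure_table(kp))
    out[[length(out) + 1L]] <- cbind(data.frame(B = B, log_kratio = lk), s)
  }
  do.call(rbind, out)
}

#' Stochastic (Gillespie) oracle for the growth-closure competition
#'
#' Simulates the continuous-time competition between growth (`N -> N + 1`
#' at rate `k_grow(N)`) and closure (absorbing, rates `k^(m,n)(N)`) exactly;
#' the empirical closure distribution converges to the deterministic table
#' in the limit where growth stochasticity is negligible (the table ignores
#' it by construction, so small systematic differences at strong closure
#' are expected).
#'
#' @param kp [kinetic_params()].
#' @param candidates candidate geometries (as in [solve_closure_table()]).
#' @param n_trials number of trajectories.
#' @param seed RNG seed.
#' @param deterministic_growth advance `N` at fixed intervals `1/k_grow`
#'   (matching the table's assumption) instead of exponential waiting times.
#' @return list with `geometries` (empirical `P`), `P_never`, `N_close`
#'   sample.
#' @export
gillespie_closure <- function(kp, candidates = NULL, n_trials = 1000L,
                              seed = 1L, deterministic_growth = TRUE) {
  stopifnot(n_trials >= 1)
  if (is.null(candidates)) candidates <- candidate_geometries(kp$target,
                                                              lat = kp$lat)
  set.seed(seed)
  mult <- if ("multiplicity" %in% names(candidates))
    candidates$multiplicity else rep(1L, nrow(candidates))
  Ns <- kp$N0:(kp$N_max - 1L)
  K <- matrix(0, nrow(candidates), length(Ns))
  for (i in seq_len(nrow(candidates))) {
    K[i, ] <- mult[i] *
      closure_rate(tubule_indices(candidates$m[i], candidates$n[i]), Ns, kp)
  }
  ktot <- colSums(K)
  kg <- growth_rate(Ns, kp)
  alive <- rep(TRUE, n_trials)
  which_geo <- rep(NA_integer_, n_trials)
  N_close <- rep(NA_integer_, n_trials)
  for (j in seq_along(Ns)) {
    n_alive <- sum(alive)
    if (n_alive == 0L) break
    if (deterministic_growth) {
      p_close_here <- 1 - exp(-ktot[j] / kg[j])
    } else {
      p_close_here <- ktot[j] / (ktot[j] + kg[j])
    }
    u <- stats::runif(n_alive)
    closes <- u < p_close_here
    if (any(closes)) {
      idx <- which(alive)[closes]
      which_geo[idx] <- sample.int(nrow(candidates), length(idx),
                                   replace = TRUE, prob = K[, j] / ktot[j])
      N_close[idx] <- Ns[j]
      alive[idx] <- FALSE
    }
  }
  P_emp <- tabulate(which_geo, nbins = nrow(candidates)) / n_trials
  list(geometries = data.frame(m = candidates$m, n = candidates$n,
                               P = P_emp),
       P_never = mean(alive), N_close = N_close, seed = seed)
}

#' Fit the intrinsic growth and closure rates from trajectories
#'
#' `k0_grow` is the slope of `dN/dtau` against the disk perimeter
#' `2 sqrt(pi N a0)` over the post-nucleation, pre-closure growth phase;
#' `k0_close` is estimated from the closure-size distribution of
#' target-forming runs by maximum likelihood under the deterministic
#' growth-closure recursion (only the target channel carries no barrier,
#' so target closures constrain `k0_close` directly).
#'
#' @param trajectories list of `trajectory_record`s.
#' @param target [tubule_indices()].
#' @param lat [lattice_constants()].
#' @return list with `k0_grow`, `k0_close`, `log10_kratio`, `n_used`.
#' @export
fit_kinetic_rates <- function(trajectories, target,
                              lat = lattice_constants()) {
  # growth: pooled regression of dN/dtau on perimeter/l0, through the origin
  xs <- c(); ys <- c()
  ncl <- c(); nend <- c()
  for (tr in trajectories) {
    s <- tr$series
    upto <- if (tr$closed) which(s$N >= tr$N_close)[1L] else nrow(s)
    if (is.na(upto) || upto < 3L) upto <- nrow(s)
    s <- s[seq_len(upto), ]
    if (tr$closed) ncl <- c(ncl, tr$N_close)
    else nend <- c(nend, max(s$N))
    nuc <- which(s$N >= 12L)[1L]          # skip the nucleation plateau
    if (is.na(nuc) || upto - nuc < 2L) next
    s <- s[nuc:upto, ]
    dN <- diff(s$N); dtau <- diff(s$tau)
    keep <- dtau > 0
    per <- 2 * sqrt(pi * s$N[-nrow(s)] * lat$a0) / lat$l0
    xs <- c(xs, per[keep]); ys <- c(ys, (dN / dtau)[keep])
  }
  if (length(xs) < 10L) stop("not enough growth-phase data to fit k0_grow")
  k0_grow <- sum(xs * ys) / sum(xs * xs)
  # closure: censored MLE of k0_close under the deterministic-growth survival
  # model restricted to the target channel; closed runs contribute their
  # closure-size density, never-closed runs the survival to their final size
  k0_close <- NA_real_
  if (length(ncl) >= 5L) {
    Nhi <- max(c(ncl, nend)) + 50L
    kp0 <- kinetic_params(k0_grow = k0_grow, k0_close = 1, B = 1,
                          target = target, N_max = Nhi, lat = lat)
    Ns <- kp0$N0:(kp0$N_max - 1L)
    I <- closure_indicator(target, Ns, kp0)
    dt <- 1 / growth_rate(Ns, kp0)
    cumI <- cumsum(I * dt)
    nll <- function(log_k) {
      k <- exp(log_k)
      s <- 0
      for (nc in ncl) {
        j <- match(nc, Ns)
        if (is.na(j)) j <- length(Ns)
        surv <- if (j > 1L) exp(-k * cumI[j - 1L]) else 1
        pj <- surv * (1 - exp(-k * I[j] * dt[j]))
        s <- s - log(max(pj, 1e-300))
      }
      for (ne in nend) {
        j <- match(ne, Ns)
        if (is.na(j)) j <- length(Ns)
        s <- s + k * cumI[j]
      }
      s
    }
    fit <- stats::optimize(nll, c(-14, 3))
    k0_close <- exp(fit$minimum)
  }
  list(k0_grow = k0_grow, k0_close = k0_close,
       log10_kratio = log10(k0_close / k0_grow),
       n_used = length(xs), n_closed = length(ncl))
}
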