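#' Bath conditions for grand-canonical assembly
#'
#' The structure exchanges monomers with a bath at fixed chemical potential
#' `mu`; the corresponding free monomer concentration is
#' `c0 = c_SS exp(mu / kBT)` with `c_SS` the standard-state concentration.
#'
#' @param mu chemical potential (kBT, default -3).
#' @param c_SS standard-state concentration (molar, default 10 micromolar).
#' @return list of class `bath_conditions` with derived `c0`.
#' @export
bath_conditions <- function(mu = -3, c_SS = 1e-5) {
  stopifnot(c_SS > 0)
  structure(list(mu = mu, c_SS = c_SS, c0 = c_SS * exp(mu), T = 1),
            class = "bath_conditions")
}

#' Simulation configuration
#'
#' Move-mix and stop-rule parameters of the kinetic Monte Carlo engine.
#' Attempt weights per elementary step are: vertex moves `N_v`, monomer
#' exchange `p_exchange * n_free_edges`, edge fusion/fission
#' `f_fusion * N_v`; one sweep is one attempted vertex move per vertex.
#'
#' @param f_fusion per-channel attempt frequency of closure-class fusion /
#'   fission moves (pairs of distant boundary edges; two vertex merges),
#'   relative to the vertex-move frequency (default 1e-3).  This is the
#'   closure-rate control parameter.
#' @param p_seam per-channel attempt frequency of seam-class fusion/fission
#'   moves (pairs sharing a vertex: growth notches and cracks), default 0.1:
#'   notch bonds form at the monomer-binding timescale.
#' @param p_exchange association/dissociation attempt frequency per free
#'   boundary edge, relative to vertex moves (default 0.1).
#' @param delta_v vertex displacement half-width (l0).
#' @param r_c fusion capture distance (l0): two free edges can fuse when
#'   both vertex pairs are within `r_c` per coordinate.
#' @param wp association proposal half-width: the new apex is drawn
#'   uniformly from a cube of half-width `wp` around the ideal position, so
#'   the proposal volume is `v_p = (2 wp)^3`.
#' @param L_end_factor stop when the structure length reaches this multiple
#'   of the target circumference (default 3).
#' @param max_sweeps hard sweep cap; trajectories that hit it without
#'   reaching the stop rule are flagged unfinished.
#' @param record_every sampling interval for the trajectory series (sweeps).
#' @param seed RNG seed (PCG32; every output embeds it).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(f_fusion = 1e-3, p_seam = 0.1,
                              p_exchange = 0.1,
                              delta_v = 0.12, r_c = 0.3, wp = 0.5,
                              L_end_factor = 3, max_sweeps = 2e5,
                              record_every = 25, seed = 1L) {
  stopifnot(f_fusion >= 0, p_seam >= 0, p_exchange >= 0, delta_v >= 0,
            r_c > 0, wp > 0, L_end_factor > 0, max_sweeps > 0)
  structure(list(f_fusion = f_fusion, p_seam = p_seam,
                 p_exchange = p_exchange,
                 delta_v = delta_v, r_c = r_c, wp = wp,
                 L_end_factor = L_end_factor, max_sweeps = max_sweeps,
                 record_every = record_every, seed = as.integer(seed)),
            class = "simulation_config")
}

# single flat equilateral monomer, the initial condition of every
# dynamical assembly trajectory
single_monomer <- function(l0 = 1) {
  triangulated_sheet(
    rbind(c(0, 0, 0), c(l0, 0, 0), c(l0 / 2, l0 * sqrt(3) / 2, 0)),
    matrix(c(1L, 2L, 3L), 1L))
}

#' Run one assembly trajectory
#'
#' Grand-canonical kinetic Monte Carlo from a single monomer until the
#' structure length reaches `L_end_factor` times the target circumference
#' (N reaches `L_end_factor * |C|^2 / a0`) or `max_sweeps` elapse.
#' Deterministic given `cfg$seed`.
#'
#' @param target [tubule_indices()] of the programmed geometry.
#' @param p [energy_params()]; its `theta0` should be the target's ideal
#'   dihedrals (the default when built with `target =`).
#' @param bath [bath_conditions()].
#' @param cfg [simulation_config()].
#' @param start optional starting [triangulated_sheet()] (default one
#'   monomer).
#' @param max_monomers optional cap on the monomer count (used by the
#'   enumerable micro-system tests); 0 = none.
#' @param log_bound_types record the per-type bound-edge counts with each
#'   series sample (micro-system tests).
#' @return list of class `trajectory_record`: `series` (data.frame of sweep,
#'   N, bound_edges, boundary_cycles), final `sheet`, `closed`, `N_close`,
#'   `tau_close`, `finished`, `events`, and the resolved config.
#' @export
run_trajectory <- function(target, p, bath = bath_conditions(),
                           cfg = simulation_config(), start = NULL,
                           max_monomers = 0L, log_bound_types = FALSE) {
  stopifnot(inherits(target, "tubule_indices"), inherits(p, "energy_params"))
  lat <- lattice_constants(p$l0)
  if (is.null(start)) start <- single_monomer(p$l0)
  Cc <- circumference(target, lat)
  stop_N <- if (max_monomers > 0L) 0L else
    as.integer(ceiling(cfg$L_end_factor * Cc^2 / lat$a0))
  res <- .run_trajectory_cpp(
    start$vertices, start$triangles, p$theta0, p$E_B, p$B, p$k_S, p$l0,
    bath$mu, cfg$f_fusion, cfg$p_seam, cfg$p_exchange, cfg$delta_v,
    cfg$r_c, cfg$wp,
    cfg$max_sweeps, stop_N, as.integer(max_monomers), cfg$record_every,
    cfg$seed, log_bound_types)
  sheet <- triangulated_sheet(res$mesh$vertices, res$mesh$triangles,
                              res$mesh$bound_pairs)
  series <- as.data.frame(res$series)
  structure(list(
    series = series, sheet = sheet, closed = res$closed,
    N_close = if (res$N_close > 0) res$N_close else NA_integer_,
    tau_close = if (res$tau_close >= 0) res$tau_close else NA_real_,
    tau_end = res$tau_end, finished = res$finished,
    N_final = res$N_final, boundary_cycles = res$boundary_cycles,
    events = res$events, energy = res$energy,
    target = target, config = cfg, bath = bath, params = p),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(
    "trajectory: N_final=%d after %.0f sweeps, %s%s, events i/d/f/x = %d/%d/%d/%d\n",
    x$N_final, x$tau_end,
    if (x$closed) sprintf("closed at N=%d", x$N_close) else "never closed",
    if (x$finished) "" else " [unfinished]",
    x$events[["insertions"]], x$events[["deletions"]],
    x$events[["fusions"]], x$events[["fissions"]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pure-R single moves.  These share the acceptance bookkeeping of the engine
# but recompute energies from scratch; they are the slow, obviously-correct
# counterparts used for unit tests and cross-checks.
# ---------------------------------------------------------------------------

# total attempt weight of the move mix for a sheet
move_weight <- function(sheet, cfg) {
  nv <- nrow(sheet$vertices)
  nf <- sum(edge_table(sheet)$state == "free")
  nv + cfg$p_exchange * nf + cfg$f_fusion * nv
}

#' Single Metropolis vertex move (reference implementation)
#'
#' Displaces one uniformly chosen vertex uniformly in a cube of half-width
#' `delta_v` and accepts with probability `min(1, exp(-delta E))`.
#'
#' @param sheet a [triangulated_sheet()].
#' @param p [energy_params()].
#' @param cfg [simulation_config()].
#' @return list `(sheet, accepted, delta_E)`.
#' @export
vertex_move <- function(sheet, p, cfg = simulation_config()) {
  v <- sample.int(nrow(sheet$vertices), 1L)
  d <- stats::runif(3, -cfg$delta_v, cfg$delta_v)
  new_pos <- sheet$vertices[v, ] + d
  dE <- energy_delta_vertex(sheet, v, new_pos, p)
  acc <- dE <= 0 || stats::runif(1) < exp(-dE)
  if (acc) sheet$vertices[v, ] <- new_pos
  list(sheet = sheet, accepted = acc, delta_E = if (acc) dE else 0)
}

# removable monomers: exactly one bound edge, unshared apex
removable_monomers <- function(sheet) {
  if (nrow(sheet$triangles) <= 1L) return(integer(0))
  et <- edge_table(sheet)
  nb <- integer(nrow(sheet$triangles))
  b <- et[et$state == "bound", ]
  for (i in seq_len(nrow(b))) {
    nb[b$tri1[i]] <- nb[b$tri1[i]] + 1L
    nb[b$tri2[i]] <- nb[b$tri2[i]] + 1L
  }
  cand <- which(nb == 1L)
  deg <- tabulate(sheet$triangles, nbins = nrow(sheet$vertices))
  keep <- vapply(cand, function(t) {
    kb <- which(vapply(1:3, function(k) {
      any(b$tri1 == t & b$corner1 == k) | any(b$tri2 == t & b$corner2 == k)
    }, logical(1)))
    apex <- sheet$triangles[t, c(3L, 1L, 2L)[kb]]
    deg[apex] == 1L
  }, logical(1))
  cand[keep]
}

#' Single association attempt (reference implementation)
#'
#' Chooses a free boundary edge uniformly, proposes a new monomer with its
#' apex drawn uniformly from the cube of half-width `wp` around the ideal
#' (preferred-dihedral, equilateral) position, and accepts with the
#' grand-canonical Metropolis ratio `exp(mu - dE)` times the exact
#' reverse/forward proposal ratio (free-edge and removable-monomer counts
#' and the total-weight ratio).  Exactly one bond is formed.
#'
#' @inheritParams vertex_move
#' @param bath [bath_conditions()].
#' @return list `(sheet, accepted, delta_E)`.
#' @export
attempt_association <- function(sheet, p, bath, cfg = simulation_config()) {
  et <- edge_table(sheet)
  fr <- which(et$state == "free")
  if (length(fr) == 0L) return(list(sheet = sheet, accepted = FALSE))
  pick <- et[fr[sample.int(length(fr), 1L)], ]
  center <- ideal_apex_position(sheet, pick$tri1, pick$corner1, p)
  apex <- center + stats::runif(3, -cfg$wp, cfg$wp)
  ins <- energy_delta_insertion(sheet, pick$tri1, pick$corner1, apex, p)
  W0 <- move_weight(sheet, cfg)
  W1 <- move_weight(ins$after, cfg)
  n_free1 <- length(fr) + 1L
  n_rem1 <- length(removable_monomers(ins$after))
  acc_p <- exp(bath$mu - ins$delta_E) * n_free1 * W0 / (W1 * n_rem1)
  acc <- stats::runif(1) < acc_p
  list(sheet = if (acc) ins$after else sheet, accepted = acc,
       delta_E = if (acc) ins$delta_E else 0)
}

#' Single dissociation attempt (reference implementation)
#'
#' Chooses a removable monomer (exactly one bound edge, unshared apex)
#' uniformly and removes it with the acceptance ratio that exactly reverses
#' [attempt_association()]; the apex must lie within the association
#' proposal cube around its ideal position, otherwise the reverse proposal
#' has zero density and the move is rejected.  Never removes the last
#' monomer and never disconnects the sheet.
#'
#' @inheritParams attempt_association
#' @return list `(sheet, accepted, delta_E)`.
#' @export
attempt_dissociation <- function(sheet, p, bath, cfg = simulation_config()) {
  rem <- removable_monomers(sheet)
  if (length(rem) == 0L) return(list(sheet = sheet, accepted = FALSE))
  t <- rem[sample.int(length(rem), 1L)]
  et <- edge_table(sheet)
  b <- et[et$state == "bound" & (et$tri1 == t | et$tri2 == t), ]
  # partner halfedge geometry survives the removal
  if (b$tri1[1L] == t) { pt <- b$tri2[1L]; pk <- b$corner2[1L] }
  else                 { pt <- b$tri1[1L]; pk <- b$corner1[1L] }
  kb <- if (b$tri1[1L] == t) b$corner1[1L] else b$corner2[1L]
  apex <- sheet$triangles[t, c(3L, 1L, 2L)[kb]]
  center <- ideal_apex_position(sheet, pt, pk, p)
  if (any(abs(sheet$vertices[apex, ] - center) > cfg$wp))
    return(list(sheet = sheet, accepted = FALSE))
  after <- remove_monomer(sheet, t)
  dE <- total_energy(after, p)$E_total - total_energy(sheet, p)$E_total
  W0 <- move_weight(sheet, cfg)
  W1 <- move_weight(after, cfg)
  n_free0 <- sum(et$state == "free")
  acc_p <- exp(-bath$mu - dE) * length(rem) * W0 / (W1 * n_free0)
  acc <- stats::runif(1) < acc_p
  list(sheet = if (acc) after else sheet, accepted = acc,
       delta_E = if (acc) dE else 0)
}

# drop triangle t and its (unshared) apex vertex, reindexing
remove_monomer <- function(sheet, t) {
  deg <- tabulate(sheet$triangles, nbins = nrow(sheet$vertices))
  verts_of_t <- sheet$triangles[t, ]
  drop_v <- verts_of_t[deg[verts_of_t] == 1L]
  tr <- sheet$triangles[-t, , drop = FALSE]
  keep <- setdiff(seq_len(nrow(sheet$vertices)), drop_v)
  remap <- integer(nrow(sheet$vertices))
  remap[keep] <- seq_along(keep)
  triangulated_sheet(sheet$vertices[keep, , drop = FALSE],
                     matrix(remap[tr], ncol = 3L))
}

#' Single fusion or fission attempt (reference implementation)
#'
#' With probability 1/2 attempts edge fusion (binding two free edges of
#' equal type whose vertex pairs lie within the capture distance `r_c`,
#' merging the vertices at averaged positions) and otherwise fission
#' (unbinding a boundary-adjacent bound edge, duplicating the endpoints
#' whose triangle fans separate, displaced by `+/- delta` drawn uniformly
#' within the capture cube).  Acceptance carries the Metropolis factor, the
#' reversible-jump volume ratio `(v_p / 8 r_c^3)^k` for `k` merged (or
#' split) vertices, and the reverse/forward selection-count ratio.
#'
#' @inheritParams vertex_move
#' @return list `(sheet, accepted, kind)`.
#' @export
attempt_fusion_fission <- function(sheet, p, cfg = simulation_config()) {
  if (stats::runif(1) < 0.5) attempt_fusion_r(sheet, p, cfg)
  else attempt_fission_r(sheet, p, cfg)
}

fusable_pairs_r <- function(sheet, r_c = 0.3) {
  he <- halfedges(sheet)
  key <- paste(pmin(he$from, he$to), pmax(he$from, he$to))
  fr <- which(table(key)[key] == 1L)
  out <- list()
  pos <- sheet$vertices
  if (length(fr) >= 2L) {
    for (a in seq_along(fr)) for (b in seq_along(fr)) {
      if (a >= b) next
      h1 <- fr[a]; h2 <- fr[b]
      if (he$type[h1] != he$type[h2] || he$tri[h1] == he$tri[h2]) next
      u <- he$from[h1]; v <- he$to[h1]; pp <- he$from[h2]; q <- he$to[h2]
      if (u == pp || v == q) next
      ok1 <- u == q || all(abs(pos[u, ] - pos[q, ]) < r_c)
      ok2 <- v == pp || all(abs(pos[v, ] - pos[pp, ]) < r_c)
      if (ok1 && ok2) out[[length(out) + 1L]] <- c(h1, h2)
    }
  }
  list(pairs = out, he = he)
}

attempt_fusion_r <- function(sheet, p, cfg) {
  fp <- fusable_pairs_r(sheet, cfg$r_c)
  if (length(fp$pairs) == 0L)
    return(list(sheet = sheet, accepted = FALSE, kind = "fusion"))
  pick <- fp$pairs[[sample.int(length(fp$pairs), 1L)]]
  he <- fp$he
  u <- he$from[pick[1L]]; v <- he$to[pick[1L]]
  pp <- he$from[pick[2L]]; q <- he$to[pick[2L]]
  pos <- sheet$vertices; tr <- sheet$triangles
  merges <- list()
  if (u != q) merges[[length(merges) + 1L]] <- c(u, q)
  if (v != pp) merges[[length(merges) + 1L]] <- c(v, pp)
  for (mg in merges) {
    pos[mg[1L], ] <- (pos[mg[1L], ] + pos[mg[2L], ]) / 2
    tr[tr == mg[2L]] <- mg[1L]
  }
  keep <- setdiff(seq_len(nrow(pos)), vapply(merges, `[`, integer(1), 2L))
  remap <- integer(nrow(pos)); remap[keep] <- seq_along(keep)
  after <- triangulated_sheet(pos[keep, , drop = FALSE],
                              matrix(remap[tr], ncol = 3L))
  ok <- tryCatch({ validate_sheet(after); TRUE }, error = function(e) FALSE)
  if (!ok) return(list(sheet = sheet, accepted = FALSE, kind = "fusion"))
  dE <- total_energy(after, p)$E_total - total_energy(sheet, p)$E_total
  k <- length(merges)
  v_p <- (2 * cfg$wp)^3
  n_fis1 <- length(fissionable_edges_r(after))
  if (n_fis1 == 0L)
    return(list(sheet = sheet, accepted = FALSE, kind = "fusion"))
  W0 <- move_weight(sheet, cfg); W1 <- move_weight(after, cfg)
  nv0 <- nrow(sheet$vertices); nv1 <- nrow(after$vertices)
  acc_p <- exp(-dE) * (v_p / (8 * cfg$r_c^3))^k *
    (nv1 * W0 * length(fp$pairs)) / (nv0 * W1 * n_fis1)
  acc <- stats::runif(1) < acc_p
  list(sheet = if (acc) after else sheet, accepted = acc, kind = "fusion")
}

fissionable_edges_r <- function(sheet) {
  et <- edge_table(sheet)
  he <- halfedges(sheet)
  key <- paste(pmin(he$from, he$to), pmax(he$from, he$to))
  fr <- which(table(key)[key] == 1L)
  bverts <- unique(c(he$from[fr], he$to[fr]))
  which(et$state == "bound" & (et$v_lo %in% bverts | et$v_hi %in% bverts))
}

attempt_fission_r <- function(sheet, p, cfg) {
  fis <- fissionable_edges_r(sheet)
  if (length(fis) == 0L)
    return(list(sheet = sheet, accepted = FALSE, kind = "fission"))
  et <- edge_table(sheet)
  e <- et[fis[sample.int(length(fis), 1L)], ]
  t1 <- e$tri1; t2 <- e$tri2
  splits <- list()
  for (x in c(e$v_lo, e$v_hi)) {
    comp <- vertex_fan_component(sheet, x, t2, exclude = c(t1, t2))
    if (!(t1 %in% comp)) splits[[length(splits) + 1L]] <- list(x = x, fan = comp)
  }
  if (length(splits) == 2L) {
    # both endpoints split: sheet must stay connected through another path
    if (!tris_connected_without(sheet, t1, t2, e)) {
      return(list(sheet = sheet, accepted = FALSE, kind = "fission"))
    }
  }
  pos <- sheet$vertices; tr <- sheet$triangles
  for (s in splits) {
    d <- stats::runif(3, -cfg$r_c / 2, cfg$r_c / 2)
    nx <- nrow(pos) + 1L
    pos <- rbind(pos, pos[s$x, ] - d)
    pos[s$x, ] <- pos[s$x, ] + d
    for (t in s$fan) tr[t, tr[t, ] == s$x] <- nx
  }
  after <- triangulated_sheet(pos, tr)
  ok <- tryCatch({ validate_sheet(after); TRUE }, error = function(e) FALSE)
  if (!ok) return(list(sheet = sheet, accepted = FALSE, kind = "fission"))
  dE <- total_energy(after, p)$E_total - total_energy(sheet, p)$E_total
  k <- length(splits)
  v_p <- (2 * cfg$wp)^3
  n_fus1 <- length(fusable_pairs_r(after, cfg$r_c)$pairs)
  if (n_fus1 == 0L)
    return(list(sheet = sheet, accepted = FALSE, kind = "fission"))
  W0 <- move_weight(sheet, cfg); W1 <- move_weight(after, cfg)
  nv0 <- nrow(sheet$vertices); nv1 <- nrow(after$vertices)
  acc_p <- exp(-dE) * ((8 * cfg$r_c^3) / v_p)^k *
    (nv1 * W0 * length(fis)) / (nv0 * W1 * n_fus1)
  acc <- stats::runif(1) < acc_p
  list(sheet = if (acc) after else sheet, accepted = acc, kind = "fission")
}

# triangles reachable from t0 around vertex x across bound edges, with the
# (t_ex1, t_ex2) shared edge removed
vertex_fan_component <- function(sheet, x, t0, exclude) {
  et <- edge_table(sheet)
  b <- et[et$state == "bound" & (et$v_lo == x | et$v_hi == x), ]
  drop <- (b$tri1 == exclude[1L] & b$tri2 == exclude[2L]) |
          (b$tri1 == exclude[2L] & b$tri2 == exclude[1L])
  b <- b[!drop, ]
  comp <- t0; stack <- t0
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    nb <- c(b$tri2[b$tri1 == t], b$tri1[b$tri2 == t])
    for (u in nb) if (!(u %in% comp)) { comp <- c(comp, u); stack <- c(stack, u) }
  }
  comp
}

tris_connected_without <- function(sheet, t1, t2, edge_row) {
  et <- edge_table(sheet)
  b <- et[et$state == "bound", ]
  drop <- (b$tri1 == t1 & b$tri2 == t2) | (b$tri1 == t2 & b$tri2 == t1)
  b <- b[!drop, ]
  comp <- t1; stack <- t1
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    if (t == t2) return(TRUE)
    nb <- c(b$tri2[b$tri1 == t], b$tri1[b$tri2 == t])
    for (u in nb) if (!(u %in% comp)) { comp <- c(comp, u); stack <- c(stack, u) }
  }
  t2 %in% comp
}
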