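#' Classify the tubule geometry of a closed sheet
#'
#' Recovers the rollup indices `(m, n)` of a closed (cylindrical) sheet from
#' its intrinsic lattice structure.  Triangles are 2-coloured into the two
#' lattice orientations by propagation across bound edges; every directed
#' edge then maps to a lattice step, and the steps around one rim sum to the
#' rollup vector, which is reduced to canonical form.  The result is
#' invariant under rigid-body motion and moderate vertex noise because only
#' the mesh topology enters.
#'
#' @param sheet a [triangulated_sheet()] with two boundary cycles.
#' @param strict if `TRUE` (default), error when the sheet is not a clean
#'   closed tubule; if `FALSE`, return `NULL` in that case.
#' @return a [tubule_indices()] (handedness not recovered: topology alone
#'   does not distinguish mirror images, so `+1` is reported).
#' @export
classify_geometry <- function(sheet, strict = TRUE) {
  fail <- function(msg) if (strict) stop(msg) else return(NULL)
  cyc <- boundary_cycles(sheet)
  if (length(cyc) != 2L)
    return(fail(sprintf("sheet is not closed: %d boundary cycle(s)", length(cyc))))
  col <- color_triangles(sheet)
  if (is.null(col)) return(fail("inconsistent lattice orientation (odd dual cycle)"))
  pq <- rollup_of_cycle(sheet, cyc[[1L]], col)
  if (all(pq == 0L)) return(fail("boundary loop does not wind around the tubule"))
  canonical_indices(pq[1L], pq[2L])
}

# 2-colour triangles into "up" (+1) / "down" (-1) lattice orientations via
# BFS over bound edges; NULL if an odd cycle makes the colouring impossible.
color_triangles <- function(sheet) {
  et <- edge_table(sheet)
  nt <- nrow(sheet$triangles)
  col <- rep(NA_integer_, nt)
  b <- et[et$state == "bound", ]
  adj <- lapply(seq_len(nt), function(i) integer(0))
  for (i in seq_len(nrow(b))) {
    adj[[b$tri1[i]]] <- c(adj[[b$tri1[i]]], b$tri2[i])
    adj[[b$tri2[i]]] <- c(adj[[b$tri2[i]]], b$tri1[i])
  }
  for (root in seq_len(nt)) {
    if (!is.na(col[root])) next
    col[root] <- 1L
    queue <- root
    while (length(queue)) {
      t <- queue[[1L]]; queue <- queue[-1L]
      for (u in adj[[t]]) {
        if (is.na(col[u])) {
          col[u] <- -col[t]
          queue <- c(queue, u)
        } else if (col[u] != -col[t]) {
          return(NULL)
        }
      }
    }
  }
  col
}

# lattice step of the directed edge at (tri, corner):
#   up triangle: corner 1 -> +a1, corner 2 -> a2 - a1, corner 3 -> -a2
# down triangles carry the opposite steps.
LATTICE_STEP <- rbind(c(1L, 0L), c(-1L, 1L), c(0L, -1L))

rollup_of_cycle <- function(sheet, cycle, col) {
  s <- c(0L, 0L)
  for (i in seq_len(nrow(cycle))) {
    t <- cycle[i, 1L]; k <- cycle[i, 2L]
    s <- s + col[t] * LATTICE_STEP[k, ]
  }
  s
}

#' Classify an assembly outcome
#'
#' Assigns the final structure of a trajectory to one of the three assembly
#' outcome categories: `open` (never closed before the stop rule; spirals
#' included), `defective` (closed, but with residual cracks — more than two
#' boundary cycles — or an inconsistent lattice: orientation conflicts,
#' interior vertices without six neighbours, or rims with different rollup
#' vectors), or `defect_free` (a clean tubule, with its `(m, n)` attached).
#'
#' @param sheet final [triangulated_sheet()] of the trajectory.
#' @param closed logical: did a closure event occur before the stop rule?
#' @param N_close monomer count at closure (NA if never closed).
#' @param finished logical: did the trajectory reach its stop rule?
#' @param lat [lattice_constants()].
#' @return list of class `outcome_record` with `category`, `mn`, `N_final`,
#'   `N_close`, `L`, `D`, `L_close`.
#' @export
classify_outcome <- function(sheet, closed, N_close = NA_integer_,
                             finished = TRUE, lat = lattice_constants()) {
  N_final <- nrow(sheet$triangles)
  rec <- list(category = NA_character_, mn = NULL, N_final = N_final,
              N_close = N_close, L = NA_real_, D = NA_real_,
              L_close = NA_real_, finished = finished)
  class(rec) <- "outcome_record"
  if (!finished) {
    rec$category <- "unfinished"
    return(rec)
  }
  cyc <- boundary_cycles(sheet)
  if (!isTRUE(closed) || length(cyc) < 2L) {
    rec$category <- "open"
    return(rec)
  }
  if (length(cyc) > 2L) {
    rec$category <- "defective"
    return(rec)
  }
  col <- color_triangles(sheet)
  if (is.null(col) || !interior_degrees_ok(sheet)) {
    rec$category <- "defective"
    return(rec)
  }
  pq1 <- rollup_of_cycle(sheet, cyc[[1L]], col)
  pq2 <- rollup_of_cycle(sheet, cyc[[2L]], col)
  if (all(pq1 == 0L) ||
      !identical(canonical_or_null(pq1), canonical_or_null(pq2))) {
    rec$category <- "defective"
    return(rec)
  }
  mn <- canonical_indices(pq1[1L], pq1[2L])
  rec$category <- "defect_free"
  rec$mn <- mn
  ld <- measure_L_D(mn, N_final, lat)
  rec$L <- ld$L; rec$D <- ld$D
  if (!is.na(N_close)) rec$L_close <- measure_L_D(mn, N_close, lat)$L
  rec
}

canonical_or_null <- function(pq) {
  if (all(pq == 0L)) return(NULL)
  x <- canonical_indices(pq[1L], pq[2L])
  c(x$m, x$n)    # handedness is not recoverable from topology; compare (m,n)
}

# every vertex not on a boundary must have exactly 6 incident triangles
# (a 5/7 disclination changes the tubule lattice and marks a defect)
interior_degrees_ok <- function(sheet) {
  he <- halfedges(sheet)
  partner <- halfedge_partners(sheet)
  code <- 3L * (he$tri - 1L) + he$corner
  freehe <- which(is.na(partner[code]))
  boundary_verts <- unique(c(he$from[freehe], he$to[freehe]))
  deg <- tabulate(sheet$triangles, nbins = nrow(sheet$vertices))
  interior <- setdiff(which(deg > 0L), boundary_verts)
  all(deg[interior] == 6L)
}

#' Tubule length and diameter from monomer count
#'
#' `D = circumference(m, n) / pi` and `L = N a0 / (pi D)`: the tubule length
#' follows from area conservation, `N` monomers of area `a0` tiling a
#' cylinder of circumference `pi D`.
#'
#' @param mn a [tubule_indices()].
#' @param N monomer count.
#' @param lat [lattice_constants()].
#' @return list with `L` and `D` (units of `l0`).
#' @export
measure_L_D <- function(mn, N, lat = lattice_constants()) {
  D <- diameter(mn, lat)
  list(L = N * lat$a0 / (pi * D), D = D)
}

#' Aggregate assembly outcomes into a distribution summary
#'
#' Per-geometry fractions within the defect-free population, category
#' fractions over the whole population, yield of the target (target-geometry
#' defect-free tubules over all finished trials), and width statistics
#' (mean diameter and its population standard deviation over the defect-free
#' set).  Unfinished trials are excluded and counted separately.
#'
#' @param records list of `outcome_record`s (see [classify_outcome()]).
#' @param target [tubule_indices()] of the target geometry.
#' @return list of class `distribution_summary`.
#' @export
aggregate_outcomes <- function(records, target) {
  finished <- Filter(function(r) !identical(r$category, "unfinished"), records)
  n_unfinished <- length(records) - length(finished)
  if (length(finished) == 0L) stop("no finished records to aggregate")
  cats <- vapply(finished, function(r) r$category, character(1))
  n <- length(finished)
  frac <- function(k) sum(cats == k) / n
  df <- finished[cats == "defect_free"]
  geom_frac <- numeric(0)
  D_mean <- NA_real_; D_sd <- NA_real_; yield <- 0
  if (length(df) > 0L) {
    labs <- vapply(df, function(r) sprintf("(%d,%d)", r$mn$m, r$mn$n), character(1))
    tab <- table(labs)
    geom_frac <- as.numeric(tab) / length(df)
    names(geom_frac) <- names(tab)
    Ds <- vapply(df, function(r) r$D, numeric(1))
    D_mean <- mean(Ds)
    D_sd <- sqrt(mean((Ds - D_mean)^2))      # population sd
    tgt <- sprintf("(%d,%d)", target$m, target$n)
    yield <- sum(labs == tgt) / n
  }
  structure(list(
    n_trials = n, n_unfinished = n_unfinished,
    frac_defect_free = frac("defect_free"),
    frac_defective = frac("defective"),
    frac_open = frac("open"),
    geometry_fractions = geom_frac,
    yield = yield,
    D_mean = D_mean, Delta_D = D_sd,
    target = sprintf("(%d,%d)", target$m, target$n)),
    class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "distribution over %d trials (target %s): defect-free %.1f%%, defective %.1f%%, open %.1f%%\n",
    x$n_trials, x$target, 100 * x$frac_defect_free, 100 * x$frac_defective,
    100 * x$frac_open))
  cat(sprintf("yield of target %.1f%%, D_mean %.4g, Delta_D %.4g\n",
              100 * x$yield, x$D_mean, x$Delta_D))
  if (length(x$geometry_fractions))
    print(round(sort(x$geometry_fractions, decreasing = TRUE), 4))
  invisible(x)
}
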