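#' Triangular-lattice constants
#'
#' Constants of the monomer lattice: stress-free edge length `l0`, monomer
#' area `a0 = (sqrt(3)/4) l0^2`, and the two unit lattice vectors at 60
#' degrees.  Edge types are tied to lattice directions: type 1 edges are
#' parallel to `a1`, type 2 to `a2`, type 3 to `a2 - a1`.
#'
#' @param l0 stress-free edge length (length unit, default 1).
#' @return list with `l0`, `a0`, `a1`, `a2`.
#' @export
lattice_constants <- function(l0 = 1) {
  stopifnot(is.numeric(l0), length(l0) == 1L, l0 > 0)
  list(l0 = l0,
       a0 = sqrt(3) / 4 * l0^2,
       a1 = c(l0, 0),
       a2 = c(l0 / 2, l0 * sqrt(3) / 2))
}

#' Tubule rollup indices (m, n)
#'
#' Names a tubule geometry by its rollup vector `m a1 + n a2`, the carbon
#' nanotube convention: `m` lattice sites around one helical turn, `n` along
#' the orthogonal direction.  Canonical form has `m >= 1`, `n >= 0`; for
#' chiral tubules (`n >= 1`, `m != n`) the mirror structure carries the same
#' `(m, n)` with `handedness = -1`.
#'
#' @param m,n integer indices, `(m, n) != (0, 0)`.
#' @param handedness `+1` or `-1`; achiral tubules (`n = 0` or `m = n`)
#'   always have `+1`.
#' @return object of class `tubule_indices`.
#' @export
tubule_indices <- function(m, n = 0L, handedness = 1L) {
  m <- as.integer(m); n <- as.integer(n)
  if (is.na(m) || is.na(n) || (m == 0L && n == 0L))
    stop("invalid tubule geometry: (m, n) must be a nonzero index pair")
  if (m < 1L || n < 0L)
    stop("canonical tubule indices require m >= 1, n >= 0")
  if (n > m)
    stop("canonical tubule indices require n <= m (use handedness for the mirror)")
  if (n == 0L || n == m) handedness <- 1L
  structure(list(m = m, n = n, handedness = as.integer(sign(handedness))),
            class = "tubule_indices")
}

#' @export
format.tubule_indices <- function(x, ...) {
  sprintf("(%d,%d)%s", x$m, x$n, if (x$handedness < 0) "*" else "")
}

#' @export
print.tubule_indices <- function(x, ...) {
  cat("tubule", format(x), "\n"); invisible(x)
}

#' Canonical reduction of an integer rollup vector
#'
#' Reduces an integer vector `(p, q)` in the `(a1, a2)` basis to canonical
#' tubule indices under the lattice point group: the six rotations map the
#' vector into the sector `p >= 1, q >= 0`, and a reflection (which flips
#' handedness) brings it to `n <= m`.
#'
#' @param p,q integers, not both zero.
#' @return a [tubule_indices()].
#' @export
canonical_indices <- function(p, q) {
  if (p == 0L && q == 0L) stop("zero rollup vector")
  for (r in 1:6) {
    tmp <- c(-q, p + q)                       # rotate by 60 degrees
    p <- tmp[1L]; q <- tmp[2L]
    if (p >= 1L && q >= 0L) break
  }
  if (!(p >= 1L && q >= 0L)) stop("canonical reduction failed")
  if (q > p) tubule_indices(q, p, handedness = -1L)
  else       tubule_indices(p, q, handedness = 1L)
}

#' Tubule circumference and diameter
#'
#' The circumference is the norm of the rollup vector,
#' `|C| = l0 sqrt(m^2 + m n + n^2)`; the diameter is `|C| / pi`.
#'
#' @param mn a [tubule_indices()].
#' @param lat [lattice_constants()].
#' @return length in units of `l0`.
#' @export
circumference <- function(mn, lat = lattice_constants()) {
  stopifnot(inherits(mn, "tubule_indices"))
  lat$l0 * sqrt(mn$m^2 + mn$m * mn$n + mn$n^2)
}

#' @rdname circumference
#' @export
diameter <- function(mn, lat = lattice_constants()) {
  circumference(mn, lat) / pi
}

# ---------------------------------------------------------------------------
# Helically symmetric ideal embedding.
#
# A defect-free (m,n) tubule with every edge exactly l0 is fixed by a linear
# map from lattice coordinates (i,j) to cylinder coordinates:
#   phi = A i + B j ,  z = Cz i + Dz j ,  position = (R cos phi, R sin phi, z)
# Unknowns (A, B, Cz, Dz, R) satisfy two closure constraints
#   m A + n B = 2 pi ,  m Cz + n Dz = 0
# and three chord-length constraints, one per lattice direction (1,0), (0,1),
# (-1,1):  4 R^2 sin^2(dphi/2) + dz^2 = l0^2.
# Solved by damped Newton iteration from the unrolled-cylinder start.
# ---------------------------------------------------------------------------

helical_map <- function(mn, lat = lattice_constants()) {
  m <- mn$m; n <- mn$n; l0 <- lat$l0
  if (m * m + m * n + n * n < 7L)
    stop(sprintf(
      "invalid tubule geometry %s: circumference below sqrt(7) l0 has no equal-edge embedding",
      format(mn)))
  cvec <- m * lat$a1 + n * lat$a2
  clen <- sqrt(sum(cvec^2))
  chat <- cvec / clen
  ahat <- c(-chat[2L], chat[1L])
  x0 <- c(A = 2 * pi * sum(lat$a1 * chat) / clen,
          B = 2 * pi * sum(lat$a2 * chat) / clen,
          Cz = sum(lat$a1 * ahat),
          Dz = sum(lat$a2 * ahat),
          R = clen / (2 * pi))
  dirs <- rbind(c(1, 0), c(0, 1), c(-1, 1))
  resid <- function(x) {
    A <- x[1L]; B <- x[2L]; Cz <- x[3L]; Dz <- x[4L]; R <- x[5L]
    dphi <- dirs[, 1L] * A + dirs[, 2L] * B
    dz <- dirs[, 1L] * Cz + dirs[, 2L] * Dz
    c(m * A + n * B - 2 * pi,
      m * Cz + n * Dz,
      4 * R^2 * sin(dphi / 2)^2 + dz^2 - l0^2)
  }
  x <- x0
  for (it in 1:200) {
    f <- resid(x)
    if (max(abs(f)) < 1e-13) break
    # numeric Jacobian (central differences)
    J <- matrix(0, 5L, 5L)
    for (k in 1:5) {
      h <- 1e-7 * max(1, abs(x[k]))
      xp <- x; xp[k] <- x[k] + h
      xm <- x; xm[k] <- x[k] - h
      J[, k] <- (resid(xp) - resid(xm)) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step))
      stop(sprintf("ideal embedding for %s did not converge (singular Jacobian)",
                   format(mn)))
    lam <- 1
    repeat {
      xn <- x - lam * step
      if (xn[5L] > 0 && sum(abs(resid(xn))) <= sum(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
  }
  f <- resid(x)
  if (max(abs(f)) > 1e-10)
    stop(sprintf(
      "ideal embedding for %s did not converge: max residual %.3e",
      format(mn), max(abs(f))))
  list(A = x[[1L]], B = x[[2L]], Cz = x[[3L]], Dz = x[[4L]], R = x[[5L]],
       residual = max(abs(f)))
}

# position of lattice vertex (i,j) under a helical map; the mirror image
# (handedness -1) flips z, and the caller must also reverse triangle corner
# order so that normals stay outward (this swaps edge types 1 and 2, the
# intrinsic relabelling of a reflected lattice).
helical_position <- function(hm, i, j, handedness = 1L) {
  phi <- hm$A * i + hm$B * j
  z <- (hm$Cz * i + hm$Dz * j) * handedness
  cbind(hm$R * cos(phi), hm$R * sin(phi), z)
}

#' Ideal tubule embedding
#'
#' Builds the closed cylindrical mesh of an `(m, n)` tubule with every edge
#' length equal to `l0` (to solver tolerance, well below `1e-8 l0`).  The
#' vertex set is the fundamental-domain slab `i in 0..m-1`, `j in 0..rows-1`
#' of the quotient lattice; triangles with all three vertices in the slab are
#' included, which for `(m, 0)` gives exactly `2 m (rows - 1)` triangles.
#'
#' @param mn a [tubule_indices()].
#' @param rows number of lattice rows along the tubule axis (`>= 2`).
#' @param lat [lattice_constants()].
#' @return a [triangulated_sheet()].
#' @export
ideal_embedding <- function(mn, rows, lat = lattice_constants()) {
  stopifnot(inherits(mn, "tubule_indices"), rows >= 2)
  m <- mn$m; n <- mn$n
  hm <- helical_map(mn, lat)
  id <- function(i, j) {
    k <- floor(i / m)
    i <- i - k * m; j <- j - k * n
    ifelse(j >= 0 & j <= rows - 1, 1L + i + m * j, NA_integer_)
  }
  # vertices
  ij <- expand.grid(i = 0:(m - 1L), j = 0:(rows - 1L))
  pos <- helical_position(hm, ij$i, ij$j, mn$handedness)
  # triangles: up (p, p+a1, p+a2) and down (p+a1+a2, p+a2, p+a1)
  tris <- list()
  for (j in 0:(rows - 2L)) {
    for (i in 0:(m - 1L)) {
      up <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
      if (!anyNA(up)) tris[[length(tris) + 1L]] <- up
      dn <- c(id(i + 1L, j + 1L), id(i, j + 1L), id(i + 1L, j))
      if (!anyNA(dn)) tris[[length(tris) + 1L]] <- dn
    }
  }
  tris <- do.call(rbind, tris)
  if (mn$handedness < 0L) tris <- tris[, c(1L, 3L, 2L), drop = FALSE]
  sheet <- triangulated_sheet(pos, tris)
  attr(sheet, "mn") <- mn
  attr(sheet, "helical_map") <- hm
  sheet
}

#' Ideal dihedral angles of a tubule geometry
#'
#' The three preferred dihedral angles, one per edge type, measured on the
#' ideal embedding.  By helical symmetry all bound edges of one type have the
#' same angle; the spread across edges is checked against `1e-6` rad.  Flat
#' sheet corresponds to all angles `= pi`; an outward-curved tubule has all
#' angles `< pi`.  Results are cached per `(m, n, handedness)`.
#'
#' @param mn a [tubule_indices()].
#' @param probe_rows rows used for the probe embedding (default just enough
#'   to expose interior edges of all three types).
#' @param lat [lattice_constants()].
#' @return numeric vector `theta[1:3]`, radians, indexed by edge type.
#' @export
ideal_dihedrals <- function(mn, probe_rows = NULL, lat = lattice_constants()) {
  stopifnot(inherits(mn, "tubule_indices"))
  key <- sprintf("%d_%d_%d_%g", mn$m, mn$n, mn$handedness, lat$l0)
  cached <- .tubulemc_cache$dihedrals[[key]]
  if (!is.null(cached)) return(cached)
  if (is.null(probe_rows)) probe_rows <- max(4L, mn$n + 3L)
  sheet <- ideal_embedding(mn, probe_rows, lat)
  dh <- bound_dihedrals(sheet)
  theta <- numeric(3)
  for (ty in 1:3) {
    th <- dh$theta[dh$type == ty]
    if (length(th) == 0L)
      stop(sprintf("no bound edge of type %d in probe embedding of %s; increase probe_rows",
                   ty, format(mn)))
    if (diff(range(th)) > 1e-6)
      stop(sprintf("dihedral spread %.2e rad for type %d breaks helical symmetry",
                   diff(range(th)), ty))
    theta[ty] <- mean(th)
  }
  .tubulemc_cache$dihedrals[[key]] <- theta
  theta
}

.tubulemc_cache <- new.env(parent = emptyenv())
.tubulemc_cache$dihedrals <- list()

#' Build a compact lattice disk
#'
#' A roughly circular, edge-connected patch of `N` triangles grown greedily
#' outward from the origin (candidates ordered by centroid radius in the
#' unrolled plane).  If `mn_target` is given the patch is bent to the target
#' curvature by mapping lattice coordinates through the target's helical map
#' without wrapping, so patches wider than one turn become open spirals.
#'
#' @param N number of triangles (`>= 1`).
#' @param mn_target optional [tubule_indices()] giving the curvature.
#' @param lat [lattice_constants()].
#' @return a [triangulated_sheet()].
#' @export
build_disk <- function(N, mn_target = NULL, lat = lattice_constants()) {
  stopifnot(N >= 1)
  # all candidate triangles in a window, ranked by centroid distance from the
  # patch centre (the centroid of the seed up-triangle): the N nearest form a
  # compact, connected, near-hexagonal patch
  w <- ceiling(sqrt(N)) + 2L
  cand <- expand.grid(i = -w:w, j = -w:w, up = c(1, 0))
  basis <- rbind(lat$a1, lat$a2)
  cx <- colMeans(rbind(c(0, 0), c(1, 0), c(0, 1)) %*% basis)
  rr <- numeric(nrow(cand))     # farthest-vertex distance: favours hexagons
  r2 <- numeric(nrow(cand))     # centroid distance breaks ties
  for (t in seq_len(nrow(cand))) {
    i <- cand$i[t]; j <- cand$j[t]
    p <- if (cand$up[t] == 1) rbind(c(i, j), c(i + 1, j), c(i, j + 1))
         else rbind(c(i + 1, j + 1), c(i, j + 1), c(i + 1, j))
    xy <- p %*% basis
    rr[t] <- sqrt(max(rowSums(sweep(xy, 2, cx)^2)))
    r2[t] <- sqrt(sum((colMeans(xy) - cx)^2))
  }
  ord <- order(rr, r2, cand$i, cand$j, cand$up)   # deterministic tie-break
  sel <- cand[ord[seq_len(N)], ]
  chosen <- lapply(seq_len(N), function(t) c(sel$i[t], sel$j[t], sel$up[t]))
  chosen <- smooth_patch(chosen)
  # assemble mesh
  vkeys <- character(0)
  vij <- list()
  vid <- function(i, j) {
    k <- paste(i, j)
    p <- match(k, vkeys)
    if (is.na(p)) {
      vkeys <<- c(vkeys, k)
      vij[[length(vij) + 1L]] <<- c(i, j)
      p <- length(vkeys)
    }
    p
  }
  tris <- matrix(0L, length(chosen), 3L)
  for (t in seq_along(chosen)) {
    i <- chosen[[t]][1]; j <- chosen[[t]][2]; up <- chosen[[t]][3] == 1
    tris[t, ] <- if (up) c(vid(i, j), vid(i + 1, j), vid(i, j + 1))
                 else    c(vid(i + 1, j + 1), vid(i, j + 1), vid(i + 1, j))
  }
  ijm <- do.call(rbind, vij)
  if (is.null(mn_target)) {
    xy <- ijm %*% rbind(lat$a1, lat$a2)
    pos <- cbind(xy, 0)
  } else {
    hm <- helical_map(mn_target, lat)
    pos <- helical_position(hm, ijm[, 1L], ijm[, 2L], mn_target$handedness)
    if (mn_target$handedness < 0L) tris <- tris[, c(1L, 3L, 2L), drop = FALSE]
  }
  triangulated_sheet(pos, tris)
}

# Deterministic boundary smoothing of a triangle patch: repeatedly move a
# "spike" (chosen triangle with two free edges) into a "notch" (unchosen slot
# with two or more chosen neighbours); each swap shortens the perimeter by at
# least two edges, so the loop terminates.
smooth_patch <- function(chosen) {
  if (length(chosen) < 3L) return(chosen)
  key <- function(t) paste(t[1], t[2], t[3])
  nbrs <- function(t) {
    i <- t[1]; j <- t[2]
    if (t[3] == 1) list(c(i, j, 0), c(i, j - 1, 0), c(i - 1, j, 0))
    else           list(c(i, j, 1), c(i, j + 1, 1), c(i + 1, j, 1))
  }
  inset <- new.env(parent = emptyenv())
  for (t in chosen) assign(key(t), TRUE, envir = inset)
  ndeg <- function(t) sum(vapply(nbrs(t), function(u)
    isTRUE(get0(key(u), envir = inset)), logical(1)))
  for (iter in seq_len(4L * length(chosen))) {
    keys <- vapply(chosen, key, character(1))
    o <- order(keys)
    spike <- NULL
    for (s in o) if (ndeg(chosen[[s]]) == 1L) { spike <- s; break }
    if (is.null(spike)) break
    # candidate notches: unchosen neighbours-of-neighbours with >= 2 chosen
    # neighbours once the spike is removed
    rm(list = key(chosen[[spike]]), envir = inset)
    notch <- NULL
    cand_n <- list()
    for (t in chosen[-spike]) for (u in nbrs(t))
      if (!isTRUE(get0(key(u), envir = inset)))
        cand_n[[key(u)]] <- u
    for (k in sort(names(cand_n)))
      if (ndeg(cand_n[[k]]) >= 2L) { notch <- cand_n[[k]]; break }
    if (is.null(notch)) {               # no improving swap: restore and stop
      assign(key(chosen[[spike]]), TRUE, envir = inset)
      break
    }
    chosen[[spike]] <- notch
    assign(key(notch), TRUE, envir = inset)
  }
  chosen
}
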