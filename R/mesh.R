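#' Triangulated sheet container
#'
#' A `triangulated_sheet` stores the assembling structure: vertex positions in
#' 3-space and oriented triangles.  Edge types are implicit in the corner
#' order: for a triangle stored as `(v1, v2, v3)` the directed edges
#' `(v1->v2)`, `(v2->v3)`, `(v3->v1)` have types 1, 3, 2 respectively, the
#' cyclic order in which the three inequivalent edge types appear when a
#' monomer is traversed counter-clockwise seen from outside.  Two monomers can
#' bind only along edges of equal type; a bound edge is a vertex pair shared
#' by exactly two triangles, a free edge belongs to one triangle.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z
#'   (lengths in units of the stress-free edge length \code{l0}).
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices in consistent (outward counter-clockwise) orientation.
#' @param bound_pairs optional integer matrix with columns
#'   `(tri1, corner1, tri2, corner2)` listing the bound halfedge pairs
#'   explicitly.  When absent, bound edges are inferred from shared vertex
#'   pairs; the explicit form is needed for structures containing zero-width
#'   cracks (two coincident free edges), which are otherwise
#'   indistinguishable from bound edges.
#' @return An object of class `triangulated_sheet`.
#' @export
triangulated_sheet <- function(vertices, triangles, bound_pairs = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (!is.null(bound_pairs)) {
    bound_pairs <- as.matrix(bound_pairs)
    storage.mode(bound_pairs) <- "integer"
    if (nrow(bound_pairs) > 0L && ncol(bound_pairs) != 4L)
      stop("bound_pairs must have 4 columns")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 bound_pairs = bound_pairs),
            class = "triangulated_sheet")
}

# halfedge partner codes: partner[h] = code of the opposite halfedge (codes
# are 3*(tri-1)+corner), NA for free halfedges; uses the explicit bound-pair
# table when present, else infers from shared vertex pairs
halfedge_partners <- function(sheet) {
  nt <- nrow(sheet$triangles)
  partner <- rep(NA_integer_, 3L * nt)
  if (!is.null(sheet$bound_pairs)) {
    bp <- sheet$bound_pairs
    if (nrow(bp) > 0L) {
      h1 <- 3L * (bp[, 1L] - 1L) + bp[, 2L]
      h2 <- 3L * (bp[, 3L] - 1L) + bp[, 4L]
      partner[h1] <- h2
      partner[h2] <- h1
    }
    return(partner)
  }
  he <- halfedges(sheet)
  key <- paste(pmin(he$from, he$to), pmax(he$from, he$to))
  idx <- split(seq_len(nrow(he)), key)
  for (ii in idx) {
    if (length(ii) == 1L) next
    if (length(ii) > 2L)
      stop("edge shared by more than two triangles (non-manifold)")
    h1 <- ii[1L]; h2 <- ii[2L]
    if (he$type[h1] != he$type[h2])
      stop("bound edge with mismatched types: only like-type edges bind")
    if (he$from[h2] != he$to[h1] || he$to[h2] != he$from[h1])
      stop("bound edge with inconsistent orientation")
    code1 <- 3L * (he$tri[h1] - 1L) + he$corner[h1]
    code2 <- 3L * (he$tri[h2] - 1L) + he$corner[h2]
    partner[code1] <- code2
    partner[code2] <- code1
  }
  partner
}

#' @export
print.triangulated_sheet <- function(x, ...) {
  et <- edge_table(x)
  cat(sprintf(
    "triangulated_sheet: %d vertices, %d triangles, %d bound / %d free edges, %d boundary cycle(s)\n",
    nrow(x$vertices), nrow(x$triangles), sum(et$state == "bound"),
    sum(et$state == "free"), length(boundary_cycles(x))))
  invisible(x)
}

# Type of the k-th directed edge (v_k -> v_{k+1}) of a triangle.
EDGE_TYPE_OF_CORNER <- c(1L, 3L, 2L)

# Directed halfedges of all triangles: data.frame with tri, corner, from, to.
halfedges <- function(sheet) {
  tr <- sheet$triangles
  nt <- nrow(tr)
  if (nt == 0L) {
    return(data.frame(tri = integer(), corner = integer(),
                      from = integer(), to = integer(), type = integer()))
  }
  data.frame(
    tri    = rep(seq_len(nt), 3L),
    corner = rep(1:3, each = nt),
    from   = c(tr[, 1L], tr[, 2L], tr[, 3L]),
    to     = c(tr[, 2L], tr[, 3L], tr[, 1L]),
    type   = rep(EDGE_TYPE_OF_CORNER, each = nt))
}

#' Edge table of a sheet
#'
#' Derives the edge records of a sheet: unordered vertex pair, edge type,
#' state (`bound` if shared by two triangles, `free` otherwise) and current
#' length.  Bound pairs must consist of two halfedges of equal type and
#' opposite direction; violations raise an error.
#'
#' @param sheet a [triangulated_sheet()].
#' @return data.frame with columns `v_lo`, `v_hi`, `type`, `state`, `length`,
#'   `tri1`, `corner1`, `tri2`, `corner2` (NA for free edges).
#' @export
edge_table <- function(sheet) {
  he <- halfedges(sheet)
  if (nrow(he) == 0L)
    return(data.frame(v_lo = integer(), v_hi = integer(), type = integer(),
                      state = character(), length = numeric(),
                      tri1 = integer(), corner1 = integer(),
                      tri2 = integer(), corner2 = integer()))
  partner <- halfedge_partners(sheet)
  code <- 3L * (he$tri - 1L) + he$corner
  pc <- partner[code]
  keep <- is.na(pc) | pc > code           # one record per edge
  heK <- he[keep, ]
  pcK <- pc[keep]
  pos <- sheet$vertices
  len <- sqrt(rowSums((pos[heK$from, , drop = FALSE] -
                         pos[heK$to, , drop = FALSE])^2))
  data.frame(
    v_lo = pmin(heK$from, heK$to), v_hi = pmax(heK$from, heK$to),
    type = heK$type,
    state = ifelse(is.na(pcK), "free", "bound"),
    length = len,
    tri1 = heK$tri, corner1 = heK$corner,
    tri2 = ifelse(is.na(pcK), NA_integer_, (pcK - 1L) %/% 3L + 1L),
    corner2 = ifelse(is.na(pcK), NA_integer_, (pcK - 1L) %% 3L + 1L))
}

#' Boundary cycles of a sheet
#'
#' Free (boundary) halfedges linked into ordered loops.  The walk from an
#' incoming free halfedge rotates through the triangle fan at its head vertex
#' until the outgoing free halfedge is found, so pinch vertices (two fans
#' meeting at one vertex) are traversed correctly, one cycle per fan.
#'
#' @param sheet a [triangulated_sheet()].
#' @return list of integer matrices, each with columns `tri`, `corner`
#'   ordering the free halfedges of one boundary loop.
#' @export
boundary_cycles <- function(sheet) {
  nt <- nrow(sheet$triangles)
  if (nt == 0L) return(list())
  partner <- halfedge_partners(sheet)         # indexed by code 3*(t-1)+k
  free <- which(is.na(partner))
  if (length(free) == 0L) return(list())
  next_corner <- c(2L, 3L, 1L)
  nextcode <- function(h) {                   # next corner within triangle
    t <- (h - 1L) %/% 3L
    3L * t + next_corner[(h - 1L) %% 3L + 1L]
  }
  visited <- rep(FALSE, 3L * nt)
  cycles <- list()
  for (h0 in free) {
    if (visited[h0]) next
    cyc <- integer(0)
    h <- h0
    repeat {
      visited[h] <- TRUE
      cyc <- c(cyc, h)
      # walk the triangle fan at head(h) to the outgoing free halfedge
      g <- nextcode(h)
      while (!is.na(partner[g])) g <- nextcode(partner[g])
      h <- g
      if (h == h0) break
      if (visited[h]) stop("boundary traversal error (revisited halfedge)")
    }
    cycles[[length(cycles) + 1L]] <-
      cbind(tri = (cyc - 1L) %/% 3L + 1L, corner = (cyc - 1L) %% 3L + 1L)
  }
  cycles
}

#' Validate sheet invariants
#'
#' Checks that every triangle has one edge of each type (guaranteed by the
#' corner convention), that edges are shared by at most two triangles with
#' consistent orientation and equal type, and that the sheet is a single
#' edge-connected component.
#'
#' @param sheet a [triangulated_sheet()].
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_sheet <- function(sheet) {
  et <- edge_table(sheet)  # errors on non-manifold / mismatched edges
  nt <- nrow(sheet$triangles)
  if (nt > 1L) {
    adj <- lapply(seq_len(nt), function(i) integer(0))
    b <- et[et$state == "bound", ]
    for (i in seq_len(nrow(b))) {
      adj[[b$tri1[i]]] <- c(adj[[b$tri1[i]]], b$tri2[i])
      adj[[b$tri2[i]]] <- c(adj[[b$tri2[i]]], b$tri1[i])
    }
    seen <- rep(FALSE, nt); stack <- 1L; seen[1L] <- TRUE
    while (length(stack)) {
      t <- stack[[1L]]; stack <- stack[-1L]
      for (u in adj[[t]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
    if (!all(seen))
      stop("sheet is not a single edge-connected component")
  }
  invisible(TRUE)
}

# Dihedral angle at a bound edge, measured through the material:
# flat sheet = pi, outward-bulging (convex) fold < pi.
# t1/c1 identify the halfedge (u -> v) in triangle t1; t2 the partner.
dihedral_angle <- function(pos, tri, t1, c1, t2) {
  i1 <- tri[t1, ]; i2 <- tri[t2, ]
  u <- i1[c1]; v <- i1[c(2L, 3L, 1L)[c1]]
  a <- pos[i1[1L], ]; b <- pos[i1[2L], ]; c <- pos[i1[3L], ]
  n1 <- cross3(b - a, c - a)
  a2 <- pos[i2[1L], ]; b2 <- pos[i2[2L], ]; c2 <- pos[i2[3L], ]
  n2 <- cross3(b2 - a2, c2 - a2)
  nn1 <- sqrt(sum(n1^2)); nn2 <- sqrt(sum(n2^2))
  if (nn1 < 1e-14 || nn2 < 1e-14)
    stop("degenerate triangle: dihedral angle undefined")
  n1 <- n1 / nn1; n2 <- n2 / nn2
  e <- pos[v, ] - pos[u, ]
  e <- e / sqrt(sum(e^2))
  phi <- atan2(sum(cross3(n1, n2) * e), sum(n1 * n2))
  pi - phi
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# All bound-edge dihedrals with their edge types.
bound_dihedrals <- function(sheet) {
  et <- edge_table(sheet)
  b <- et[et$state == "bound", ]
  if (nrow(b) == 0L)
    return(data.frame(type = integer(0), theta = numeric(0)))
  theta <- vapply(seq_len(nrow(b)), function(i) {
    dihedral_angle(sheet$vertices, sheet$triangles,
                   b$tri1[i], b$corner1[i], b$tri2[i])
  }, numeric(1))
  data.frame(type = b$type, theta = theta)
}
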