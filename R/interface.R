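#' Load a run configuration
#'
#' Reads a YAML configuration with dotted-section keys mirroring the
#' parameter containers ([energy_params()], [bath_conditions()],
#' [simulation_config()], trial counts, output paths).  Unknown keys and
#' out-of-range values are rejected; missing keys take the package defaults
#' (`mu = -3`, `k_S = 200`, `E_B = 6`, `f_fusion = 1e-3`, target `(10,0)`).
#'
#' @param path file path; an empty or missing-file path yields all defaults.
#' @return list of class `run_config` with elements `target`, `params`,
#'   `bath`, `sim`, `n_trials`, `out_dir`, `seed`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("target.m", "target.n", "energy.E_B", "energy.B", "energy.k_S",
             "energy.l0", "bath.mu", "bath.c_SS", "sim.f_fusion",
             "sim.p_seam", "sim.p_exchange", "sim.delta_v", "sim.r_c", "sim.wp",
             "sim.L_end_factor", "sim.max_sweeps", "sim.record_every",
             "n_trials", "out_dir", "seed")
  flat <- flatten_config(raw)
  bad <- setdiff(names(flat), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  gv <- function(key, default) if (key %in% names(flat)) flat[[key]] else default
  target <- tubule_indices(gv("target.m", 10L), gv("target.n", 0L))
  params <- energy_params(E_B = gv("energy.E_B", 6),
                          B = gv("energy.B", 20),
                          k_S = gv("energy.k_S", 200),
                          l0 = gv("energy.l0", 1),
                          target = target)
  bath <- bath_conditions(mu = gv("bath.mu", -3), c_SS = gv("bath.c_SS", 1e-5))
  sim <- simulation_config(f_fusion = gv("sim.f_fusion", 1e-3),
                           p_seam = gv("sim.p_seam", 0.1),
                           p_exchange = gv("sim.p_exchange", 0.1),
                           delta_v = gv("sim.delta_v", 0.12),
                           r_c = gv("sim.r_c", 0.3),
                           wp = gv("sim.wp", 0.5),
                           L_end_factor = gv("sim.L_end_factor", 3),
                           max_sweeps = gv("sim.max_sweeps", 2e5),
                           record_every = gv("sim.record_every", 25),
                           seed = gv("seed", 1L))
  structure(list(target = target, params = params, bath = bath, sim = sim,
                 n_trials = as.integer(gv("n_trials", 1L)),
                 out_dir = gv("out_dir", "."),
                 seed = as.integer(gv("seed", 1L))),
            class = "run_config")
}

flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) out <- c(out, flatten_config(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

#' Save a run configuration
#'
#' Writes the YAML counterpart of [load_config()]; `load_config(save_config
#' (cfg))` round-trips.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- list(
    target = list(m = cfg$target$m, n = cfg$target$n),
    energy = list(E_B = cfg$params$E_B, B = cfg$params$B,
                  k_S = cfg$params$k_S, l0 = cfg$params$l0),
    bath = list(mu = cfg$bath$mu, c_SS = cfg$bath$c_SS),
    sim = list(f_fusion = cfg$sim$f_fusion, p_seam = cfg$sim$p_seam,
               p_exchange = cfg$sim$p_exchange,
               delta_v = cfg$sim$delta_v, r_c = cfg$sim$r_c, wp = cfg$sim$wp,
               L_end_factor = cfg$sim$L_end_factor,
               max_sweeps = cfg$sim$max_sweeps,
               record_every = cfg$sim$record_every),
    n_trials = cfg$n_trials, out_dir = cfg$out_dir, seed = cfg$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Generate a test fixture structure
#'
#' Deterministic structures of a declared assembly-outcome category:
#' `ideal_tubule` (defect-free closed tubule), `bent_disk` (open patch at
#' the target curvature), `spiral_open` (an overwound open sheet resembling
#' a rolled strip whose rims never bound), and `cracked_defective` (a closed
#' tubule with one interior bound edge split into a zero-width crack).
#' Optional Gaussian vertex noise is applied after construction.
#'
#' @param kind one of `"ideal_tubule"`, `"bent_disk"`, `"spiral_open"`,
#'   `"cracked_defective"`.
#' @param mn [tubule_indices()] (geometry, or curvature for disks/spirals).
#' @param size rows (tubules) or triangles (disks/spirals).
#' @param noise vertex noise standard deviation (l0).
#' @param seed RNG seed for the noise.
#' @param lat [lattice_constants()].
#' @return a [triangulated_sheet()] with attribute `kind`.
#' @export
make_fixture <- function(kind = c("ideal_tubule", "bent_disk", "spiral_open",
                                  "cracked_defective"),
                         mn = tubule_indices(10, 0), size = 6L, noise = 0,
                         seed = 1L, lat = lattice_constants()) {
  kind <- match.arg(kind)
  sheet <- switch(kind,
    ideal_tubule = ideal_embedding(mn, size, lat),
    bent_disk = build_disk(size, mn, lat),
    spiral_open = spiral_sheet(mn, size, lat),
    cracked_defective = crack_tubule(ideal_embedding(mn, max(size, 5L), lat)))
  if (noise > 0) {
    set.seed(seed)
    sheet$vertices <- sheet$vertices +
      matrix(stats::rnorm(length(sheet$vertices), 0, noise),
             ncol = 3L)
  }
  attr(sheet, "kind") <- kind
  sheet
}

# open spiral: a strip wound past one full turn at slowly growing radius,
# so opposite rims overlap without binding ("rolled sheet")
spiral_sheet <- function(mn, rows, lat) {
  hm <- helical_map(mn, lat)
  m <- mn$m
  turns <- 1.6                              # winds past itself
  imax <- ceiling(turns * m)
  ij <- expand.grid(i = 0:imax, j = 0:(rows - 1L))
  phi <- hm$A * ij$i + hm$B * ij$j
  R <- hm$R * (1 + 0.12 * phi / (2 * pi))   # radius grows with winding
  z <- hm$Cz * ij$i + hm$Dz * ij$j
  pos <- cbind(R * cos(phi), R * sin(phi), z)
  id <- function(i, j) ifelse(i >= 0 & i <= imax & j >= 0 & j <= rows - 1,
                              1L + i + (imax + 1L) * j, NA_integer_)
  tris <- list()
  for (j in 0:(rows - 2L)) for (i in 0:(imax - 1L)) {
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
    tris[[length(tris) + 1L]] <- c(id(i + 1L, j + 1L), id(i, j + 1L),
                                   id(i + 1L, j))
  }
  triangulated_sheet(pos, do.call(rbind, tris))
}

# open a two-edge slit at an interior vertex: unbind two of its bound edges
# and duplicate the vertex for the fan arc between them, yielding a
# zero-width crack (third boundary cycle) with crack tips at the far ends
crack_tubule <- function(sheet) {
  he <- halfedges(sheet)
  partner <- halfedge_partners(sheet)
  code <- 3L * (he$tri - 1L) + he$corner
  freehe <- which(is.na(partner[code]))
  bverts <- unique(c(he$from[freehe], he$to[freehe]))
  deg <- tabulate(sheet$triangles, nbins = nrow(sheet$vertices))
  interior <- setdiff(which(deg == 6L), bverts)
  if (length(interior) == 0L) stop("no interior vertex to crack")
  et <- edge_table(sheet)
  # the slit must not touch the rims, or its boundary cycle merges with one
  x <- NA_integer_; bx <- NULL
  for (cand in interior) {
    b <- et[et$state == "bound" & (et$v_lo == cand | et$v_hi == cand), ]
    other <- ifelse(b$v_lo == cand, b$v_hi, b$v_lo)
    b <- b[other %in% interior, ]
    if (nrow(b) >= 2L) { x <- cand; bx <- b; break }
  }
  if (is.na(x)) stop("tubule too short to hold an interior slit")
  e1 <- bx[1L, ]; e2 <- bx[2L, ]
  # fan arc between the two removed edges, walked over the remaining bound
  # edges at x
  bx_all <- et[et$state == "bound" & (et$v_lo == x | et$v_hi == x), ]
  keep_rows <- !(rownames(bx_all) %in% rownames(bx)[1:2])
  bx_keep <- bx_all[keep_rows, ]
  comp <- e1$tri2; stack <- e1$tri2
  while (length(stack)) {
    t <- stack[[1L]]; stack <- stack[-1L]
    nb <- c(bx_keep$tri2[bx_keep$tri1 == t], bx_keep$tri1[bx_keep$tri2 == t])
    for (u in nb) if (!(u %in% comp)) { comp <- c(comp, u); stack <- c(stack, u) }
  }
  tr <- sheet$triangles; pos <- sheet$vertices
  nx <- nrow(pos) + 1L
  pos <- rbind(pos, pos[x, ])
  for (t in comp) tr[t, tr[t, ] == x] <- nx
  triangulated_sheet(pos, tr)
}

#' Run a batch of independent assembly trajectories
#'
#' Runs `n_trials` trajectories with per-trial seeds derived
#' deterministically from the master seed, classifies each outcome, and
#' aggregates the distribution summary.  Failed trials are counted and
#' excluded.
#'
#' @param target [tubule_indices()].
#' @param p [energy_params()].
#' @param bath [bath_conditions()].
#' @param cfg [simulation_config()]; its `seed` is the master seed.
#' @param n_trials number of independent trajectories.
#' @param keep_trajectories return the trajectory records too (memory!).
#' @return list of class `batch_result` with `summary`
#'   ([aggregate_outcomes()]), `outcomes` (list), `L_close_over_D0`
#'   (vector over defect-free closed trials), `n_failed`, `master_seed`.
#' @export
run_batch <- function(target, p, bath = bath_conditions(),
                      cfg = simulation_config(), n_trials = 10L,
                      keep_trajectories = FALSE) {
  outcomes <- vector("list", n_trials)
  trajs <- if (keep_trajectories) vector("list", n_trials) else NULL
  n_failed <- 0L
  lat <- lattice_constants(p$l0)
  D0 <- diameter(target, lat)
  lclose <- c()
  for (i in seq_len(n_trials)) {
    cfg_i <- cfg
    cfg_i$seed <- trial_seed(cfg$seed, i)
    res <- tryCatch({
      tr <- run_trajectory(target, p, bath, cfg_i)
      out <- classify_outcome(tr$sheet, tr$closed, tr$N_close, tr$finished,
                              lat)
      if (keep_trajectories) trajs[[i]] <- tr
      if (out$category == "defect_free" && !is.na(out$L_close))
        lclose <- c(lclose, out$L_close / D0)
      out
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      NULL
    })
    outcomes[[i]] <- res
  }
  outcomes <- Filter(Negate(is.null), outcomes)
  structure(list(summary = aggregate_outcomes(outcomes, target),
                 outcomes = outcomes, trajectories = trajs,
                 L_close_over_D0 = lclose, n_failed = n_failed,
                 master_seed = cfg$seed),
            class = "batch_result")
}

# deterministic per-trial seed below 2^31
trial_seed <- function(master, i) {
  as.integer((as.double(master) * 1103515245 + 12345 * as.double(i)) %%
               2147483647) + 1L
}

#' @export
print.batch_result <- function(x, ...) {
  print(x$summary)
  if (x$n_failed > 0L) cat(x$n_failed, "trial(s) failed\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mesh export/import: ASCII OFF and PLY for geometry, plus a sidecar CSV
# (v_lo, v_hi, type, state) carrying the edge records.
# ---------------------------------------------------------------------------

#' Write / read a sheet as OFF or PLY with an edge sidecar CSV
#'
#' The mesh geometry goes to an ASCII OFF or PLY file; edge types and
#' bound/free states are derivable from the corner convention but are also
#' written to `<path>.edges.csv` for interoperability (columns `v_lo`,
#' `v_hi`, `type`, `state`, 1-based).
#'
#' @param sheet a [triangulated_sheet()].
#' @param path output path; format from extension (`.off` or `.ply`).
#' @return `path` invisibly (writer); a [triangulated_sheet()] (reader).
#' @export
write_sheet <- function(sheet, path) {
  nv <- nrow(sheet$vertices); nt <- nrow(sheet$triangles)
  ext <- tolower(tools::file_ext(path))
  if (ext == "off") {
    lines <- c("OFF", paste(nv, nt, 0),
               apply(sheet$vertices, 1, function(r) paste(r, collapse = " ")),
               apply(sheet$triangles, 1, function(r)
                 paste(c(3L, r - 1L), collapse = " ")))
  } else if (ext == "ply") {
    lines <- c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property double x", "property double y", "property double z",
               paste("element face", nt),
               "property list uchar int vertex_indices", "end_header",
               apply(sheet$vertices, 1, function(r) paste(r, collapse = " ")),
               apply(sheet$triangles, 1, function(r)
                 paste(c(3L, r - 1L), collapse = " ")))
  } else stop("unsupported mesh format: ", ext)
  writeLines(lines, path)
  et <- edge_table(sheet)
  utils::write.csv(et[, c("v_lo", "v_hi", "type", "state")],
                   paste0(path, ".edges.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_sheet
#' @export
read_sheet <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    stopifnot(trimws(lines[1L]) == "OFF")
    hdr <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
    nv <- hdr[1L]; nt <- hdr[2L]
    body <- 3L
  } else if (ext == "ply") {
    endh <- which(trimws(lines) == "end_header")[1L]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1L]))
    nt <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1L]))
    body <- endh + 1L
  } else stop("unsupported mesh format: ", ext)
  verts <- do.call(rbind, lapply(lines[body:(body + nv - 1L)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]][1:3])))
  tris <- do.call(rbind, lapply(lines[(body + nv):(body + nv + nt - 1L)],
                                function(s) {
    f <- as.integer(strsplit(trimws(s), "\\s+")[[1L]])
    stopifnot(f[1L] == 3L)
    f[2:4] + 1L
  }))
  triangulated_sheet(verts, tris)
}
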