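test_that("configurations round-trip through YAML with validated keys", {
  cfg <- load_config(NULL)                       # all defaults
  expect_identical(c(cfg$target$m, cfg$target$n), c(10L, 0L))
  expect_equal(cfg$bath$mu, -3)
  expect_equal(cfg$params$k_S, 200)
  expect_equal(cfg$params$E_B, 6)
  expect_equal(cfg$sim$f_fusion, 1e-3)
  tmp <- tempfile(fileext = ".yaml")
  writeLines("", tmp)                            # empty file: defaults
  expect_equal(load_config(tmp)$bath$mu, -3)
  cfg$sim$f_fusion <- 5e-4
  cfg$n_trials <- 7L
  save_config(cfg, tmp)
  back <- load_config(tmp)
  expect_equal(back$sim$f_fusion, 5e-4)
  expect_identical(back$n_trials, 7L)
  expect_identical(back$target$m, cfg$target$m)
  # invalid values and unknown keys are rejected
  writeLines("sim:\n  f_fusion: -1", tmp)
  expect_error(load_config(tmp))
  writeLines("simulation:\n  nonsense: 3", tmp)
  expect_error(load_config(tmp), "unknown config keys")
})

test_that("fixtures satisfy their declared category invariants", {
  for (kind in c("ideal_tubule", "bent_disk", "spiral_open",
                 "cracked_defective")) {
    f <- make_fixture(kind, tgt10, size = 6, seed = 2)
    expect_identical(attr(f, "kind"), kind)
    validate_sheet(f)
  }
  # deterministic given the seed
  a <- make_fixture("ideal_tubule", tgt10, size = 5, noise = 0.03, seed = 9)
  b <- make_fixture("ideal_tubule", tgt10, size = 5, noise = 0.03, seed = 9)
  expect_identical(a$vertices, b$vertices)
})

test_that("meshes round-trip through OFF and PLY with edge sidecars", {
  sheet <- make_fixture("ideal_tubule", tubule_indices(7, 2), size = 6)
  for (ext in c("off", "ply")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_sheet(sheet, path)
    expect_true(file.exists(paste0(path, ".edges.csv")))
    back <- read_sheet(path)
    expect_equal(back$vertices, sheet$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back$triangles, sheet$triangles)
    got <- classify_geometry(back)
    expect_identical(c(got$m, got$n), c(7L, 2L))
    et <- utils::read.csv(paste0(path, ".edges.csv"))
    expect_identical(sort(unique(et$state)), c("bound", "free"))
    expect_true(all(et$type %in% 1:3))
  }
})

test_that("batches are reproducible and their fractions sum to one", {
  cfg <- simulation_config(seed = 11, max_sweeps = 8000)
  b1 <- run_batch(tgt6, p6, bath_conditions(), cfg, n_trials = 3)
  b2 <- run_batch(tgt6, p6, bath_conditions(), cfg, n_trials = 3)
  expect_identical(b1$summary$geometry_fractions, b2$summary$geometry_fractions)
  expect_identical(b1$summary$frac_open, b2$summary$frac_open)
  s <- b1$summary
  expect_equal(s$frac_defect_free + s$frac_defective + s$frac_open, 1)
  expect_identical(s$n_trials, 3L)
  expect_identical(b1$master_seed, 11L)
})
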