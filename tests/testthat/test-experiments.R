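ct <- cell_type_codes

test_that("fusion detection distinguishes separated and connected calcified sets", {
  cfg <- sim_config(spacing = 25)
  # two calcified blobs separated by a chondrocyte band two grid cells wide
  z <- seq(12.5, by = 25, length.out = 20)         # 0 .. 500 um
  cl <- mp_cloud(cbind(12.5, 12.5, z), V = 25^3)
  cl$type[] <- ct[["quiescent"]]
  cl$type[z < 100] <- ct[["matrix"]]               # POC trail
  cl$type[z > 400] <- ct[["apoptotic"]]            # SOC side
  cl$soc_seed <- z > 400
  expect_false(detect_fusion(cl, cfg))
  # erode the band: one connected calcified run from base to seed
  cl$type[] <- ifelse(seq_along(z) %% 2 == 0, ct[["matrix"]], ct[["apoptotic"]])
  expect_true(detect_fusion(cl, cfg))
  # bone collar alone never fuses the centers
  cl$type[z >= 100 & z <= 400] <- ct[["bone_collar"]]
  expect_false(detect_fusion(cl, cfg))
})

test_that("penetration flags chondrocytes inside the tracked resting band", {
  cfg <- sim_config()
  cl <- make_column(30, 10)
  cl$type[] <- ct[["quiescent"]]
  band <- cl$x[, 3] > 100 & cl$x[, 3] < 200
  cl$type[band] <- ct[["resting_pthrp"]]
  expect_false(detect_penetration(cl, cfg))
  i <- which(band)[4]
  cl$type[i] <- ct[["hypertrophic"]]
  expect_true(detect_penetration(cl, cfg))
  # an empty resting zone warns and reports no penetration
  cl$type[cl$type == ct[["resting_pthrp"]]] <- ct[["quiescent"]]
  expect_warning(expect_false(detect_penetration(cl, cfg)), "empty")
})

test_that("runs are deterministic under a fixed seed", {
  cfg <- preset_1d(seed = 123, days = 2.2)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$census, b$census)
  expect_identical(a$cloud$x, b$cloud$x)
  c2 <- run_simulation(preset_1d(seed = 124, days = 2.2))
  expect_false(identical(a$census, c2$census))
})

test_that("degenerate runs behave gracefully", {
  sim0 <- run_simulation(preset_1d(seed = 1, days = 0))
  expect_null(sim0$census)
  expect_false(sim0$outcome$fused)

  # without Ihh production nothing beyond the initial slab ever differentiates
  simq <- run_simulation(preset_1d(seed = 1, days = 1, P_ihh_max = 0))
  expect_true(all(simq$census$proliferative == 0))
  expect_true(all(simq$census$ihh_total == 0))
})

test_that("resting-zone production series follows the maturation ramp", {
  cfg <- sim_config(T_mat = 4)
  tt <- seq(0, 6, by = 0.5)
  ramp <- pthrp_production_resting(rep(cfg$ihh_max, length(tt)), tt, cfg)
  expect_equal(ramp, pmin(tt / 4, 1) * cfg$P_pthrp_max, tolerance = 1e-12)
})

test_that("maturation sweep tabulates outcomes with per-run seeds", {
  cfg <- preset_1d(seed = 7, days = 0.3)
  sw <- run_tmat_sweep(cfg, c(0.5, 2, Inf))
  expect_identical(nrow(sw$outcomes), 3L)
  expect_equal(sw$outcomes$slope, c(2, 0.5, 0))
  expect_true(all(!sw$outcomes$fused))
  sw0 <- run_tmat_sweep(cfg, numeric(0))
  expect_null(sw0$outcomes)
})

test_that("VTK snapshots and checkpoints round-trip", {
  cl <- make_block(3, 10)
  tmp <- tempfile(fileext = ".vtk")
  write_vtk_points(cl, tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("POINTS 27 float", lines)))
  expect_true(any(grepl("SCALARS cell_type int 1", lines)))
  cp <- tempfile(fileext = ".rds")
  save_checkpoint(cl, cp)
  expect_equal(load_checkpoint(cp)$x, cl$x)
})

test_that("configurations round-trip through YAML", {
  cfg <- preset_1d(seed = 42, T_mat = 3)
  tmp <- tempfile(fileext = ".yaml")
  write_config(cfg, tmp)
  cfg2 <- read_config(tmp)
  expect_equal(cfg2$T_mat, 3)
  expect_equal(cfg2$mode, "1d")
  expect_equal(cfg2$chem_h, cfg$chem_h)
  expect_error(sim_config(not_a_key = 1), "unknown config keys")
})
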