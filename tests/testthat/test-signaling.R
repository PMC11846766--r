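test_that("Ihh production ramp matches its closed form", {
  cfg <- sim_config()
  expect_identical(ihh_production(0, cfg), 0)
  expect_equal(ihh_production(0.5, cfg), 1.0, tolerance = 1e-12)
  expect_equal(ihh_production(0.75, cfg), 0.5, tolerance = 1e-12)
  expect_identical(ihh_production(1.0, cfg), 0)
  expect_identical(ihh_production(2.3, cfg), 0)
  expect_equal(ihh_production(0.25, cfg), 0.5, tolerance = 1e-12)
})

test_that("PTHrP production laws and their continuity at maturation", {
  cfg <- sim_config(T_mat = 4)
  expect_identical(pthrp_production_periarticular(0, cfg), 0)
  expect_equal(pthrp_production_periarticular(1.5e6, cfg), 1.0)
  expect_equal(pthrp_production_periarticular(7.5e5, cfg), 0.5)
  expect_identical(pthrp_production_resting(1.5e6, 0, cfg), 0)
  expect_equal(pthrp_production_resting(1.5e6, 2, cfg), 0.5)
  # at and beyond T_mat the resting level equals the periarticular level
  for (tt in c(4, 4 + 1e-9, 7))
    expect_equal(pthrp_production_resting(7.5e5, tt, cfg),
                 pthrp_production_periarticular(7.5e5, cfg))
  expect_error(pthrp_production_resting(1e5, -0.1, cfg), "before SOC")
  expect_error(pthrp_production_periarticular(-1, cfg), "non-negative")
})

test_that("total Ihh is the volume-weighted tissue sum", {
  cfg <- sim_config()
  f <- chemical_field(c(200, 200, 200), 50, cfg, far_field = "neumann")
  expect_identical(total_ihh(f, multiplicity = 1), 0)
  f$C_ihh[] <- 3
  V <- sum(f$node_vol)
  expect_equal(total_ihh(f, multiplicity = 1), 3 * V, tolerance = 1e-12)
  expect_equal(total_ihh(f, multiplicity = 8), 24 * V, tolerance = 1e-12)
  # checkerboard on equal volumes -> half the uniform total
  chk <- (rowSums(f$coords / 50) %% 2) == 0
  f$C_ihh[] <- ifelse(chk, 6, 0)
  vol_on <- sum(f$node_vol[chk])
  expect_equal(total_ihh(f, multiplicity = 1), 6 * vol_on, tolerance = 1e-12)
  # per-cell reporting units divide by the unit volume
  expect_equal(total_ihh(f, multiplicity = 1, unit_volume = 1000),
               6 * vol_on / 1000, tolerance = 1e-12)
})

test_that("reaction is integrated exactly: decay and sourced steady state", {
  cfg <- sim_config(D_um2_s = 1e-30)
  f <- chemical_field(c(0, 0, 400), 50, cfg)
  f$C_ihh[] <- 1
  f <- step_reaction_diffusion(f, numeric(f$nphys), numeric(f$nphys),
                               200 / 86400, substeps = 1)
  inner <- !f$dirichlet
  expect_equal(f$C_ihh[inner], rep(exp(-1), sum(inner)), tolerance = 1e-12)

  cfg2 <- sim_config()
  f2 <- chemical_field(c(0, 0, 400), 50, cfg2, far_field = "neumann")
  src <- rep(1, f2$nphys)
  for (i in 1:60) f2 <- step_reaction_diffusion(f2, src, src, 0.02, 4)
  expect_equal(f2$C_ihh, rep(200, f2$nphys), tolerance = 1e-8)
})

test_that("diffusion conserves mass with reflecting boundaries and no reaction", {
  cfg <- sim_config(k_s = 0)
  f <- chemical_field(c(0, 0, 600), 50, cfg, far_field = "neumann")
  set.seed(2)
  f$C_ihh <- runif(f$nphys)
  m0 <- sum(f$C_ihh * f$node_vol)
  for (i in 1:10) f <- step_reaction_diffusion(f, numeric(f$nphys),
                                               numeric(f$nphys), 0.02, 2)
  expect_equal(sum(f$C_ihh * f$node_vol), m0, tolerance = 1e-10)
  expect_true(all(f$C_ihh >= 0))
})

test_that("a steady point source decays with the screening length sqrt(D/k)", {
  cfg <- sim_config(chem_pad_cells = 10, column_area = 4)
  f <- chemical_field(c(0, 0, 250), 2, cfg)   # fine 1-D grid, h = 2 um
  src <- numeric(f$nphys); src[1] <- 1
  for (i in 1:80) f <- step_reaction_diffusion(f, src, src, 0.05, 2)
  z <- f$coords[, 3]
  win <- z >= 40 & z <= 120
  fit <- stats::lm(log(f$C_ihh[win]) ~ z[win])
  lambda <- -1 / coef(fit)[2]
  expect_equal(unname(lambda), sqrt(1 / 0.005), tolerance = 0.02)
})

test_that("pure diffusion of a Gaussian matches the analytic kernel to 1% L2", {
  cfg <- sim_config(k_s = 0, chem_pad_cells = 5, column_area = 4)
  h <- 2
  f <- chemical_field(c(0, 0, 500), h, cfg)
  z <- f$coords[, 3]
  s0 <- 20
  f$C_ihh <- exp(-z^2 / (2 * s0^2))   # even about the mirror plane at z = 0
  tsec <- 5000
  f <- step_reaction_diffusion(f, numeric(f$nphys), numeric(f$nphys),
                               tsec / 86400, substeps = 200)
  s1 <- sqrt(s0^2 + 2 * 1.0 * tsec)
  exact <- s0 / s1 * exp(-z^2 / (2 * s1^2))
  keep <- z < 400
  l2 <- sqrt(sum((f$C_ihh[keep] - exact[keep])^2) / sum(exact[keep]^2))
  expect_lt(l2, 0.01)
})

test_that("the explicit scheme matches the implicit one inside its stability bound", {
  cfg_i <- sim_config(chem_substeps = 1)
  cfg_e <- sim_config(chem_scheme = "explicit")
  fi <- chemical_field(c(0, 0, 500), 50, cfg_i)
  fe <- chemical_field(c(0, 0, 500), 50, cfg_e)
  src <- numeric(fi$nphys); src[3] <- 0.5
  nsub <- 600
  for (i in 1:3) {
    fi <- step_reaction_diffusion(fi, src, src, 0.02, nsub, "implicit")
    fe <- step_reaction_diffusion(fe, src, src, 0.02, nsub, "explicit")
  }
  expect_equal(fe$C_ihh, fi$C_ihh, tolerance = 0.02)
  # on a fine grid one full increment violates the explicit bound
  cfg_f <- sim_config(chem_scheme = "explicit", column_area = 4)
  ff <- chemical_field(c(0, 0, 300), 10, cfg_f)
  expect_error(step_reaction_diffusion(ff, numeric(ff$nphys), numeric(ff$nphys),
                                       0.02, 1, "explicit"),
               "stability")
})

test_that("point-field exchange conserves source mass and samples symmetrically", {
  cfg <- sim_config()
  f <- chemical_field(c(300, 300, 300), 50, cfg)
  cl <- make_block(3, 20)
  P <- rep(0.5, n_points(cl))
  ex <- exchange_with_points(cl, f, P, 0 * P)
  expect_equal(sum(ex$src_ihh * f$node_vol), sum(0.5 * cl$V), tolerance = 1e-9)
  expect_identical(ex$src_pthrp, numeric(f$nphys))
  expect_identical(ex$C_ihh, numeric(n_points(cl)))
})
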