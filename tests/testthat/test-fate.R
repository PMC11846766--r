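ct <- cell_type_codes

test_that("threshold transitions follow the differentiation table, strictly", {
  cfg <- sim_config()
  cl <- make_column(6, 10)
  cl$type <- c(ct[["quiescent"]], ct[["quiescent"]], ct[["proliferative"]],
               ct[["proliferative"]], ct[["proliferative"]], ct[["perichondrium"]])
  C_ihh <- c(1.5, 1.0, 31, 31, 29, 10.5)
  C_pthrp <- c(0, 0, 0.6, 0.4, 0.4, 0)
  out <- update_fate(cl, C_ihh, C_pthrp, 0.02, cfg)
  expect_identical(unname(out$type),
                   unname(c(ct[["proliferative"]],  # 1.5 > 1.0
                            ct[["quiescent"]],      # threshold is strict
                            ct[["proliferative"]],  # PTHrP gate closed (0.6)
                            ct[["prehypertrophic"]],# 31 > 30 and 0.4 < 0.5
                            ct[["proliferative"]],  # 29 < 30
                            ct[["bone_collar"]])))  # 10.5 > 10
  expect_equal(out$t_H[4], 0)
  # a freshly proliferative cell starts cycling
  expect_true(out$cycling[1])
  expect_equal(out$t_cycle[1], 0)
})

test_that("perturbing Ihh across a threshold flips exactly that transition", {
  cfg <- sim_config()
  for (eps in c(-1e-9, 1e-9)) {
    cl <- make_column(1, 10)
    out <- update_fate(cl, cfg$c_th_ihh_prolif + eps, 0, 0.02, cfg)
    expect_identical(unname(out$type), unname(
      if (eps > 0) ct[["proliferative"]] else ct[["quiescent"]]))
  }
})

test_that("timed maturation and the 50/50 terminal split", {
  cfg <- sim_config()
  n <- 1e4
  cl <- make_column(2, 10)
  cl$type <- c(ct[["prehypertrophic"]], ct[["hypertrophic"]])
  cl$t_H <- c(0.49, 1.49)
  out <- update_fate(cl, c(0, 0), c(0, 0), 0.02, cfg)
  expect_identical(unname(out$type[1]), ct[["hypertrophic"]])   # t_H passed 0.5
  expect_true(out$type[2] %in% c(ct[["apoptotic"]], ct[["matrix"]]))

  big <- make_column(n, 10)
  big$type[] <- ct[["hypertrophic"]]
  big$t_H[] <- 1.51
  set.seed(9)
  big <- update_fate(big, numeric(n), numeric(n), 0.02, cfg)
  frac <- mean(big$type == ct[["matrix"]])
  expect_true(all(big$type %in% c(ct[["matrix"]], ct[["apoptotic"]])))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("apoptotic and matrix states are absorbing", {
  cfg <- sim_config()
  cl <- make_column(2, 10)
  cl$type <- c(ct[["apoptotic"]], ct[["matrix"]])
  cl$t_fate <- c(0.2, 0.2)
  for (s in 1:50) cl <- update_fate(cl, c(1e3, 1e3), c(0, 0), 0.02, cfg)
  expect_identical(unname(cl$type), unname(c(ct[["apoptotic"]], ct[["matrix"]])))
})

test_that("material properties ramp log-linearly to exact endpoints", {
  cfg <- sim_config()
  p0 <- transition_properties(ct[["matrix"]], 0, cfg)
  expect_equal(p0$E, 1); expect_equal(p0$nu, 0.4)
  p1 <- transition_properties(ct[["matrix"]], 1.0, cfg)
  expect_identical(p1$E, 1000); expect_identical(p1$nu, 0.3)
  pm <- transition_properties(ct[["matrix"]], 0.5, cfg)
  expect_equal(pm$E, 10^1.5, tolerance = 1e-12)
  pb <- transition_properties(ct[["bone_collar"]], 2.0, cfg)
  expect_identical(pb$E, 100)
  expect_error(transition_properties(ct[["matrix"]], -0.1, cfg), "non-negative")
})

test_that("a closed PTHrP gate freezes the growth plate after Ihh decays", {
  # gate threshold 0 can never be satisfied (C < 0 is impossible), so no
  # proliferative cell ever becomes prehypertrophic
  z <- run_simulation(preset_1d(seed = 2, days = 2.5, c_th_pthrp_prehyp = 0))
  cc <- z$census
  expect_true(any(cc$proliferative > 0))
  # the only (pre)hypertrophic cells ever present descend from the initial
  # primary-center slab, which has fully matured by t > 1.5 days
  late <- cc$day > 2
  expect_true(all(cc$prehypertrophic[late] == 0))
  expect_true(all(cc$hypertrophic[late] == 0))
})

test_that("ossification-center initiation events", {
  spec <- capsule_spec(spacing = 25)
  cl <- assign_initial_types(build_capsule(spec)$points, spec)
  cl <- initiate_poc(cl, 25)
  slab <- cl$x[, 3] <= 25
  expect_true(all(cl$type[slab] == ct[["prehypertrophic"]]))
  expect_true(all(cl$t_H[slab] == 0))
  n_pre <- sum(cl$type == ct[["prehypertrophic"]])
  cl2 <- initiate_poc(cl, 25)  # idempotent
  expect_identical(sum(cl2$type == ct[["prehypertrophic"]]), n_pre)
  expect_error(initiate_poc(cl, -5), "no points")

  soc <- initiate_soc(cl2)
  expect_equal(soc$t_SOC, 0)
  expect_true(all(soc$cloud$type[soc$cloud$soc_seed] == ct[["prehypertrophic"]]))
  expect_error(initiate_soc(soc$cloud, state = list(t_SOC = 0)),
               "already initiated")
})

test_that("resting zone tagging is the quiescent band between plate and SOC", {
  cl <- make_column(40, 10)                      # z = 5 .. 395
  cl$type[] <- ct[["quiescent"]]
  cl$type[cl$x[, 3] >= 100 & cl$x[, 3] <= 150] <- ct[["proliferative"]]
  cl$type[5] <- ct[["perichondrium"]]
  cl$soc_seed <- cl$x[, 3] >= 300 & cl$x[, 3] <= 350
  out <- define_resting_zone(cl)
  tagged <- out$type == ct[["resting_pthrp"]]
  expect_true(all(out$x[tagged, 3] > 150 & out$x[tagged, 3] < 300))
  expect_gt(sum(tagged), 0)
  # exclusive: proliferative and perichondrial points are never tagged
  expect_true(all(out$type[out$x[, 3] <= 150] != ct[["resting_pthrp"]]))

  # empty band -> warning and no tags
  cl2 <- make_column(10, 10)
  cl2$type[] <- ct[["proliferative"]]
  cl2$soc_seed <- cl2$x[, 3] > 80
  expect_warning(out2 <- define_resting_zone(cl2), "empty")
  expect_true(all(out2$type != ct[["resting_pthrp"]]))
})
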