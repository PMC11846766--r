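test_that("growth tensors: identity, volume doubling, rank-one stretch", {
  expect_equal(apply_growth_tensor(diag(3), 1, "isotropic"), diag(3))
  expect_equal(apply_growth_tensor(diag(3), 1, "unidirectional", c(0, 0, 1)),
               diag(3))
  Fg <- apply_growth_tensor(diag(3), 1.2599, "isotropic")
  expect_equal(det(Fg), 2, tolerance = 1e-3)
  Fg <- apply_growth_tensor(diag(3), 2, "unidirectional", c(0, 0, 1))
  expect_equal(Fg, diag(c(1, 1, 2)))
  expect_error(apply_growth_tensor(diag(3), 0.5, "isotropic"), ">= 1")
  expect_error(apply_growth_tensor(diag(3), 2, "unidirectional"), "axis")
})

test_that("G0 sampling is exponential with rate R_prolif", {
  expect_identical(sample_g0_duration(5, 0), 0)
  expect_equal(sample_g0_duration(5, 0.5), log(2) / 5, tolerance = 1e-12)
  expect_error(sample_g0_duration(5, 1), "resample")
  set.seed(11)
  draws <- sample_g0_duration(5, runif(1e5))
  expect_equal(mean(draws), 0.2, tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(sample_g0_duration(5, runif(1e4)),
                                        stats::pexp, rate = 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("division direction follows the Ihh gradient with deterministic tie-break", {
  expect_equal(division_direction(c(0, 0, 3)), c(0, 0, 1))
  g <- c(1, 2, 2)
  expect_equal(division_direction(g), g / 3)
  expect_equal(division_direction(c(0, 0, 0), prev = c(0, 1, 0)), c(0, 1, 0))
  set.seed(3)
  v <- division_direction(c(0, 0, 0))
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("splitting a point conserves volume and places children symmetrically", {
  cl <- make_column(1, 10)
  cl$V <- 1000; cl$V0 <- 1000
  kids <- split_point(cl, c(1, 0, 0), offset = 3)
  expect_equal(kids$V, c(500, 500))
  expect_equal(sum(kids$V), cl$V)
  expect_equal(kids$x[, 1], c(5 - 3, 5 + 3))
  expect_equal(kids$x[, 3], c(5, 5))
  expect_error(split_point(cl, c(NA, NA, NA)), "unset")
})

test_that("cycle engine divides at mid-cycle and respects quiescence", {
  cfg <- sim_config()
  cl <- make_column(1, 10)
  cl$type[] <- cell_type_codes[["proliferative"]]
  cl$cycling[] <- TRUE
  cl$t_cycle[] <- 0.49
  cl$ns[1, ] <- c(0, 0, 1)
  adv <- advance_cycle(cl, 0.02, cfg)
  expect_identical(n_points(adv$cloud), 2L)
  expect_identical(nrow(adv$divisions), 1L)
  expect_equal(sum(adv$cloud$V), sum(cl$V), tolerance = 1e-9)

  # a quiescent (G0) cell only counts down its timer
  cl2 <- make_column(1, 10)
  cl2$type[] <- cell_type_codes[["proliferative"]]
  cl2$cycling[] <- TRUE
  cl2$T_g0[] <- 0.5
  adv2 <- advance_cycle(cl2, 0.02, cfg)
  expect_identical(n_points(adv2$cloud), 1L)
  expect_null(adv2$divisions)
  expect_equal(adv2$cloud$T_g0, 0.48)

  # a prehypertrophic cell that differentiated in G0 never divides
  cl3 <- make_column(1, 10)
  cl3$type[] <- cell_type_codes[["prehypertrophic"]]
  cl3$t_H[] <- 0.1
  cl3$cycling[] <- FALSE
  for (s in 1:60) cl3 <- advance_cycle(cl3, 0.02, cfg)$cloud
  expect_identical(n_points(cl3), 1L)
})

test_that("columnar growth stretch is monotone within a cycle and frozen in G0", {
  cfg <- sim_config(R_prolif = 1e9)  # negligible quiescence
  cl <- make_column(1, 10)
  cl$type[] <- cell_type_codes[["proliferative"]]
  cl$cycling[] <- TRUE; cl$t_cycle[] <- 0; cl$ns[1, ] <- c(0, 0, 1)
  set.seed(1)
  th <- numeric(0)
  for (s in 1:30) {
    cl <- subset_cloud_first(advance_cycle(cl, 0.02, cfg)$cloud)
    th <- c(th, cl$Fg[1, 9])
  }
  expect_true(all(diff(th) > -1e-12))
})

test_that("an isolated colony doubles every cycle-plus-quiescence period", {
  cfg <- sim_config()
  n0 <- 200
  cl <- make_column(n0, 10)
  cl$type[] <- cell_type_codes[["proliferative"]]
  cl$cycling[] <- TRUE
  set.seed(5)
  cl$T_g0 <- sample_g0_duration(cfg$R_prolif, runif(n0))  # desynchronized start
  cl$ns[] <- rep(c(0, 0, 1), each = n0)
  days <- 6
  for (s in seq_len(days / 0.02)) cl <- advance_cycle(cl, 0.02, cfg)$cloud
  doubling <- days / log2(n_points(cl) / n0)
  expect_equal(doubling, cfg$T_cycle + 1 / cfg$R_prolif, tolerance = 0.05)
})
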