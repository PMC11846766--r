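test_that("Lame conversion and its guards", {
  lp <- lame_parameters(1, 0.4)
  expect_equal(lp$lambda, 0.4 / (1.4 * 0.2))
  expect_equal(lp$mu, 1 / 2.8)
  expect_error(lame_parameters(-1, 0.3), "positive")
  expect_error(lame_parameters(1, 0.5), "0.5")
})

test_that("neo-Hookean density: rest state, hand-computed value, J^g scaling", {
  lp <- lame_parameters(1, 0.4)
  expect_identical(strain_energy_density(diag(3), diag(3), lp), 0)
  # F^e = diag(2,1,1): I1 = 6, I3 = 4
  psi <- strain_energy_density(diag(c(2, 1, 1)), diag(3), lp)
  oracle <- lp$lambda / 8 * log(4)^2 + lp$mu / 2 * (6 - 3 - log(4))
  expect_equal(psi, oracle, tolerance = 1e-14)
  expect_equal(psi, 0.6313, tolerance = 1e-4)
  # same elastic state with F^g = 2I scales by J^g = 8 exactly
  psi8 <- strain_energy_density(diag(c(2, 1, 1)) %*% (2 * diag(3)), 2 * diag(3), lp)
  expect_equal(psi8, 8 * psi, tolerance = 1e-12)
  expect_error(strain_energy_density(diag(3), matrix(0, 3, 3), lp), "singular")
})

test_that("stress vanishes at the undeformed elastic state", {
  lp <- lame_parameters(2, 0.3)
  eps <- 1e-6
  for (m in seq_len(9)) {
    dF <- matrix(0, 3, 3); dF[m] <- eps
    dpsi <- strain_energy_density(diag(3) + dF, diag(3), lp) -
            strain_energy_density(diag(3) - dF, diag(3), lp)
    expect_lt(abs(dpsi / (2 * eps)), 1e-5)
  }
})

test_that("equilibrium: no load gives zero displacement, uniform growth is stress-free", {
  cl <- make_block(4, 10)
  s <- solve_equilibrium(cl)
  expect_equal(max(abs(s$u)), 0)

  th <- 1.05
  cl$Fg <- cl$Fg * th
  s <- solve_equilibrium(cl, maxit = 500, pgtol = 1e-6)
  cl2 <- update_points(cl, s$grid, s$u)
  ce_err <- vapply(seq_len(n_points(cl2)), function(i) {
    F <- matrix(cl2$F[i, ], 3, 3, byrow = TRUE)
    Fg <- matrix(cl2$Fg[i, ], 3, 3, byrow = TRUE)
    Fe <- F %*% solve(Fg)
    max(abs(crossprod(Fe) - diag(3)))
  }, numeric(1))
  expect_lt(max(ce_err), 5e-3)
  # stress-free growth maps x -> theta x against the slip planes
  expect_equal(cl2$x, cl$x * th, tolerance = 0.02)
})

test_that("columnar growth against the basal slip plane stretches the column tip", {
  cl <- make_column(20, 10)
  th <- 1.1
  for (i in seq_len(n_points(cl)))
    cl <- set_tensor(cl, "Fg", i, diag(c(1, 1, th)))
  s <- solve_equilibrium(cl, maxit = 800, pgtol = 1e-7)
  cl2 <- update_points(cl, s$grid, s$u)
  expect_equal(max(cl2$x[, 3]), th * 195, tolerance = 1e-3)
  # volumes follow det F^g
  expect_equal(cl2$V, rep(th * 1000, 20), tolerance = 1e-3)
})

test_that("point update: rigid translation and uniform dilation", {
  cl <- make_block(3, 10)
  g <- ossiforge:::mech_grid(cl$x, 50)
  co <- ossiforge:::grid_coords(g)
  # rigid translation: F and V unchanged, x shifted
  u <- matrix(rep(c(3, -2, 1), each = nrow(co)), ncol = 3)
  cl2 <- update_points(cl, g, u)
  expect_equal(cl2$x, sweep(cl$x, 2, c(3, -2, 1), "+"), tolerance = 1e-10)
  expect_equal(cl2$F, cl$F, tolerance = 1e-12)
  expect_equal(sum(cl2$V), sum(cl$V), tolerance = 1e-10)
  # uniform grad u = 0.1 I: every volume is multiplied by 1.1^3
  cl3 <- update_points(cl, g, 0.1 * co)
  expect_equal(cl3$V, cl$V * 1.331, tolerance = 1e-9)
})
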