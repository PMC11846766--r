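#' Lame parameters from Young's modulus and Poisson ratio
#'
#' @param E Young's modulus (kPa), `E > 0`.
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return list with `lambda` and `mu` (kPa), vectorized over inputs.
#' @export
lame_parameters <- function(E, nu) {
  if (any(E <= 0)) stop("E must be positive")
  if (any(nu < 0 | nu >= 0.5)) stop("nu must lie in [0, 0.5)")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Growth-decomposed neo-Hookean strain energy density
#'
#' Evaluates the compressible neo-Hookean density in the multiplicative
#' elastic-growth decomposition F = F^e F^g:
#' psi = J^g (lambda/8 ln^2 I3 + mu/2 (I1 - 3 - ln I3)), where J^g = det F^g
#' and I1, I3 are the first and third invariants of C^e = F^e' F^e with
#' F^e = F (F^g)^-1. psi vanishes iff the elastic state is undeformed.
#'
#' @param F total deformation gradient (3 x 3), det F > 0.
#' @param Fg growth part (3 x 3), det Fg > 0.
#' @param lame Lame parameters from [lame_parameters()].
#' @return energy density in kPa (energy per unit reference volume).
#' @export
strain_energy_density <- function(F, Fg, lame) {
  dg <- det(Fg)
  if (!is.finite(dg) || abs(dg) < 1e-12)
    stop("singular growth tensor")
  if (det(F) <= 0 || dg <= 0) stop("deformation gradients must have positive determinant")
  Fe <- F %*% solve(Fg)
  Ce <- t(Fe) %*% Fe
  I1 <- sum(diag(Ce)); I3 <- det(Ce)
  dg * (lame$lambda / 8 * log(I3)^2 + lame$mu / 2 * (I1 - 3 - log(I3)))
}

#' Solve quasi-static grid equilibrium for one increment
#'
#' Minimizes the total elastic energy sum_p psi_p V0_p over grid node
#' displacements with L-BFGS-B, subject to the mirror/slip constraints of the
#' grid's symmetry planes (zero normal displacement on x = 0, y = 0, z = 0;
#' ghost nodes slaved to their images). The incremental displacement starts
#' from zero each increment; growth committed to `Fg` since the previous
#' solve provides the driving imbalance.
#'
#' @param cloud an `mp_cloud` with positive `E`, `nu` set.
#' @param grid optional [background_grid()]; built from the cloud if `NULL`.
#' @param maxit,pgtol,factr optimizer controls (projected-gradient tolerance
#'   in kPa um^2; `factr` is relative-energy machine-precision units).
#' @param con precomputed [grid_constraints] of `grid` (rebuilt if `NULL`).
#' @param par0 warm-start parameter vector from a previous increment.
#' @return list with `u` (node displacement matrix), `grid`, `energy`,
#'   `par` (for warm starts), `converged`, `iterations`.
#' @export
solve_equilibrium <- function(cloud, grid = NULL, maxit = 200,
                              pgtol = 2.5e-3, factr = 4.5e7,
                              con = NULL, par0 = NULL) {
  if (any(!is.finite(cloud$E)) || any(cloud$E <= 0))
    stop("cloud moduli must be set before solving")
  if (is.null(grid)) grid <- mech_grid(cloud$x, h = 50)
  lam <- lame_parameters(cloud$E, cloud$nu)
  if (is.null(con)) con <- grid_constraints(grid)
  S <- con$S
  fn <- function(th) {
    u <- as.numeric(S %*% th)
    cpp_energy(u, cloud$x, cloud$F, cloud$Fg, cloud$V0,
               lam$lambda, lam$mu, grid$origin, grid$h, grid$dims,
               want_grad = FALSE)$E
  }
  gr <- function(th) {
    u <- as.numeric(S %*% th)
    g <- cpp_energy(u, cloud$x, cloud$F, cloud$Fg, cloud$V0,
                    lam$lambda, lam$mu, grid$origin, grid$h, grid$dims,
                    want_grad = TRUE)$grad
    as.numeric(Matrix::crossprod(S, g))
  }
  th0 <- if (!is.null(par0) && length(par0) == con$n_free) par0
         else numeric(con$n_free)
  fit <- optim(th0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = pgtol, factr = factr))
  if (!fit$convergence %in% c(0L, 1L))
    stop("equilibrium solve failed: ", fit$message)
  u <- matrix(as.numeric(S %*% fit$par), ncol = 3, byrow = TRUE)
  list(u = u, grid = grid, energy = fit$value, par = fit$par,
       converged = fit$convergence == 0L,
       iterations = fit$counts[["function"]])
}

#' Advect material points through a solved displacement field
#'
#' Applies x <- x + u(x), F <- (I + grad u) F with B-spline-interpolated
#' displacement gradients, and updates volumes from V = det(F) V0. Total
#' point volume is therefore changed only by growth (det F^g) and by
#' division, never by interpolation alone.
#'
#' @param cloud an `mp_cloud`.
#' @param grid the grid used by the solve.
#' @param u node displacement matrix (n_nodes x 3).
#' @return the updated cloud.
#' @export
update_points <- function(cloud, grid, u) {
  uv <- as.numeric(t(u))  # node-major layout
  res <- cpp_update_points(uv, cloud$x, cloud$F, grid$origin, grid$h, grid$dims)
  if (any(res$detF <= 0))
    stop("inverted element: det(F) <= 0 after update")
  cloud$x <- res$X
  cloud$F <- res$F
  cloud$V <- res$detF * cloud$V0
  cloud
}
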