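#' Ihh production schedule of a maturing chondrocyte
#'
#' Production ramps linearly from zero to `P_ihh_max` while the cell is
#' prehypertrophic (duration `T_prehyp`), falls linearly back to zero over
#' the first half of hypertrophy, and is zero afterwards. `t_H` is the time
#' the cell has spent in the prehypertrophic/hypertrophic states.
#'
#' @param t_H days in the (pre)hypertrophic state, `>= 0`; vectorized.
#' @param cfg an `oss_config` (uses `P_ihh_max`, `T_prehyp`, `T_hyp`).
#' @return production in pM/um^3/s.
#' @export
ihh_production <- function(t_H, cfg) {
  Tp <- cfg$T_prehyp; Th <- cfg$T_hyp; Pm <- cfg$P_ihh_max
  up <- Pm * t_H / Tp
  down <- Pm * (1 - (t_H - Tp) / (Th / 2))
  out <- ifelse(t_H <= Tp, up, ifelse(t_H <= Tp + Th / 2, down, 0))
  out[t_H < 0] <- 0
  out
}

#' PTHrP production by periarticular chondrocytes
#'
#' Concentration-dependent Ihh feedback: production scales with the current
#' total tissue Ihh relative to the normalization constant `ihh_max`, and is
#' capped at the maximum production `P_pthrp_max`.
#'
#' @param ihh_total current total tissue Ihh (see [total_ihh()]), `>= 0`.
#' @param cfg an `oss_config`.
#' @return production in pM/um^3/s.
#' @export
pthrp_production_periarticular <- function(ihh_total, cfg) {
  if (any(ihh_total < 0)) stop("ihh_total must be non-negative")
  cfg$P_pthrp_max * pmin(ihh_total / cfg$ihh_max, 1)
}

#' PTHrP production by resting-zone chondrocytes
#'
#' After the onset of secondary ossification, resting-zone production ramps
#' from zero to the periarticular level over the maturation time `T_mat`:
#' the periarticular rate is multiplied by `min(t_SOC / T_mat, 1)`.
#'
#' @param ihh_total current total tissue Ihh.
#' @param t_SOC days since SOC initiation; must be `>= 0` (the SOC clock).
#' @param cfg an `oss_config` (uses `T_mat` and the periarticular rule).
#' @return production in pM/um^3/s.
#' @export
pthrp_production_resting <- function(ihh_total, t_SOC, cfg) {
  if (any(is.na(t_SOC)) || any(t_SOC < 0))
    stop("resting-zone production requested before SOC onset")
  pthrp_production_periarticular(ihh_total, cfg) * pmin(t_SOC / cfg$T_mat, 1)
}

# ---------------------------------------------------------------------------
# Chemistry grid

#' Chemistry field on a regular grid
#'
#' Concentrations of Ihh and PTHrP on a regular grid of spacing `h` with a
#' mirror (zero-flux) plane at coordinate zero on each symmetric axis and a
#' zero-concentration far field. The constructor sizes the grid to an
#' extent, adds `pad` cells of clearance beyond it, and pre-builds the
#' discrete Laplacian. Axes with `extent = 0` are collapsed (the 1-D column
#' keeps only z).
#'
#' @param extent numeric length-3 upper coordinate bound per axis (um); 0
#'   collapses an axis.
#' @param h grid spacing (um).
#' @param cfg an `oss_config` (uses `D_um2_s`, `k_s`, `chem_pad_cells`,
#'   `column_area`).
#' @param far_field `"dirichlet"` (zero concentration, the model's condition)
#'   or `"neumann"` (reflecting; used to verify conservation).
#' @return list of class `chemical_field`.
#' @export
chemical_field <- function(extent, h, cfg, far_field = c("dirichlet", "neumann")) {
  far_field <- match.arg(far_field)
  pad <- cfg$chem_pad_cells
  dims <- integer(3); sym <- logical(3)
  for (a in 1:3) {
    if (extent[a] <= 0) { dims[a] <- 1L; sym[a] <- FALSE }
    else { dims[a] <- as.integer(ceiling(extent[a] / h) + pad + 1L); sym[a] <- TRUE }
  }
  active <- dims > 1L
  nphys <- prod(dims)

  # full cpp grid: two ghost layers beyond each mirror plane
  originF <- ifelse(active, -2 * h, 0)
  dimsF <- ifelse(active, dims + 2L, 1L)
  # fold map: full node -> physical node (|coordinate| on symmetric axes)
  axF <- lapply(1:3, function(a) if (active[a]) abs(seq_len(dimsF[a]) - 3L) else 0L)
  ii <- rep(axF[[1]], times = dimsF[2] * dimsF[3])
  jj <- rep(rep(axF[[2]], each = dimsF[1]), times = dimsF[3])
  kk <- rep(axF[[3]], each = dimsF[1] * dimsF[2])
  phys_of_full <- 1L + ii + dims[1] * (jj + dims[2] * kk)
  nfull <- prod(dimsF)
  M <- Matrix::sparseMatrix(i = seq_len(nfull), j = phys_of_full, x = 1,
                            dims = c(nfull, nphys))

  # physical node index grids and volumes (half cells on mirror planes)
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - 1L)
  I <- rep(ax[[1]], times = dims[2] * dims[3])
  J <- rep(rep(ax[[2]], each = dims[1]), times = dims[3])
  K <- rep(ax[[3]], each = dims[1] * dims[2])
  base_vol <- if (sum(active) == 1) h * cfg$column_area else h^sum(active)
  halves <- (active[1] & I == 0L) + (active[2] & J == 0L) + (active[3] & K == 0L)
  if (far_field == "neumann")  # reflecting far edges are half cells too
    halves <- halves + (active[1] & I == dims[1] - 1L) +
      (active[2] & J == dims[2] - 1L) + (active[3] & K == dims[3] - 1L)
  node_vol <- base_vol / 2^halves

  dirichlet <- rep(FALSE, nphys)
  if (far_field == "dirichlet") {
    if (active[1]) dirichlet <- dirichlet | I == dims[1] - 1L
    if (active[2]) dirichlet <- dirichlet | J == dims[2] - 1L
    if (active[3]) dirichlet <- dirichlet | K == dims[3] - 1L
  }

  # Laplacian (1/h^2 units folded in): mirror plane doubles the inward
  # coefficient; a reflecting far edge drops the outward term.
  idx <- function(i, j, k) 1L + i + dims[1] * (j + dims[2] * k)
  rows <- list(); cols <- list(); vals <- list()
  here <- idx(I, J, K)
  diagv <- numeric(nphys)
  for (a in 1:3) {
    if (!active[a]) next
    pos <- list(I, J, K)[[a]]
    for (s in c(-1L, 1L)) {
      nb <- pos + s
      coef <- rep(1, nphys)
      mirror <- nb < 0L                 # across the symmetry plane
      nb[mirror] <- 1L
      beyond <- nb > dims[a] - 1L       # beyond the far edge
      if (far_field == "neumann") nb[beyond] <- dims[a] - 2L  # reflect
      keep <- !beyond | far_field == "neumann"
      P2 <- list(I, J, K); P2[[a]] <- nb
      nbi <- idx(P2[[1]], P2[[2]], P2[[3]])
      diagv <- diagv - coef             # outward flux drains (or reflects)
      rows[[length(rows) + 1L]] <- here[keep]
      cols[[length(cols) + 1L]] <- nbi[keep]
      vals[[length(vals) + 1L]] <- coef[keep]
    }
  }
  L <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), x = unlist(vals),
                            dims = c(nphys, nphys))
  L <- L + Matrix::Diagonal(nphys, diagv)
  L <- L / h^2
  # Dirichlet nodes are held at zero: zero their rows and columns (their
  # concentration is zero, so dropping incoming couplings changes nothing and
  # keeps the volume-weighted operator symmetric)
  if (any(dirichlet)) {
    D <- Matrix::Diagonal(nphys, ifelse(dirichlet, 0, 1))
    L <- D %*% L %*% D
  }

  structure(list(
    dims = dims, h = h, sym = sym, active = active, nphys = nphys,
    originF = originF, dimsF = as.integer(dimsF), M = M,
    node_vol = node_vol, dirichlet = dirichlet, L = L,
    coords = cbind(I, J, K) * h,
    D_day = cfg$D_um2_s * 86400, k_day = cfg$k_s * 86400,
    C_ihh = numeric(nphys), C_pthrp = numeric(nphys),
    solver = new.env(parent = emptyenv())
  ), class = "chemical_field")
}

# Points beyond the chemistry grid sit in the zero far field (screening keeps
# concentrations there at zero); they read zero and contribute no source.
chem_supported <- function(field, X) {
  lo <- field$originF + 1.01 * field$h
  hi <- field$originF + (field$dimsF - 2.01) * field$h
  ok <- rep(TRUE, nrow(X))
  for (a in 1:3) {
    if (field$dimsF[a] == 1L) next
    ok <- ok & X[, a] >= lo[a] & X[, a] <= hi[a]
  }
  ok
}

# scatter per-point amounts onto physical nodes (ghost contributions folded)
chem_scatter <- function(field, X, amt) {
  ok <- chem_supported(field, X)
  full <- cpp_scatter(X[ok, , drop = FALSE], amt[ok],
                      field$originF, field$h, field$dimsF)
  as.numeric(Matrix::crossprod(field$M, full))
}

# interpolate a physical node vector at point positions
chem_interp <- function(field, X, vals) {
  ok <- chem_supported(field, X)
  out <- numeric(nrow(X))
  out[ok] <- cpp_field_interp(X[ok, , drop = FALSE],
                              as.numeric(field$M %*% vals),
                              field$originF, field$h, field$dimsF)
  out
}

# gradient of a physical node vector at point positions (N x 3)
chem_grad <- function(field, X, vals) {
  ok <- chem_supported(field, X)
  out <- matrix(0, nrow(X), 3)
  out[ok, ] <- cpp_field_grad(X[ok, , drop = FALSE],
                              as.numeric(field$M %*% vals),
                              field$originF, field$h, field$dimsF)
  out
}

#' Couple material points to the chemistry grid
#'
#' Spreads per-point production (amount rate = production x point volume)
#' onto grid nodes through the B-spline weights, converting to a volumetric
#' source density, and samples the current concentrations back at the
#' points.
#'
#' @param cloud an `mp_cloud`.
#' @param field a [chemical_field()].
#' @param P_ihh,P_pthrp per-point production rates (pM/um^3/s).
#' @param volumes producing volumes (um^3); defaults to the points' current
#'   volumes. The 1-D column driver passes the axial footprint volume
#'   instead, which is the consistent reduction of a laterally homogeneous
#'   slab (lateral enlargement leaves the in-column volume fraction at one).
#' @return list with `src_ihh`, `src_pthrp` (node densities, pM/um^3/s),
#'   `C_ihh`, `C_pthrp` (per-point concentrations).
#' @export
exchange_with_points <- function(cloud, field, P_ihh, P_pthrp,
                                 volumes = cloud$V) {
  list(
    src_ihh   = chem_scatter(field, cloud$x, P_ihh * volumes) / field$node_vol,
    src_pthrp = chem_scatter(field, cloud$x, P_pthrp * volumes) / field$node_vol,
    C_ihh   = chem_interp(field, cloud$x, field$C_ihh),
    C_pthrp = chem_interp(field, cloud$x, field$C_pthrp)
  )
}

#' Total tissue Ihh
#'
#' Volume-weighted sum of the Ihh concentration over tissue-occupied nodes,
#' multiplied by the symmetry multiplicity (8 for the one-eighth model) so
#' the value refers to the whole tissue, and divided by `unit_volume`. With
#' the default `unit_volume = 1` this is the raw integral of C over the
#' tissue; the simulation forms the production feedback ratio in per-cell
#' units (`unit_volume` = initial point volume, 10^3 um^3), the convention
#' under which the normalization constant `ihh_max` is stated.
#'
#' @param field a [chemical_field()].
#' @param occupied logical vector of tissue-occupied nodes (e.g. positive
#'   scattered point volume); `NULL` means all nodes.
#' @param multiplicity mirror-image count (8 = whole tissue from one octant).
#' @param unit_volume reporting unit volume (um^3).
#' @return total Ihh (pM when `unit_volume` matches the concentration unit).
#' @export
total_ihh <- function(field, occupied = NULL, multiplicity = 8, unit_volume = 1) {
  w <- field$node_vol
  if (!is.null(occupied)) w <- w * as.numeric(occupied)
  sum(field$C_ihh * w) * multiplicity / unit_volume
}

#' Advance the reaction-diffusion fields
#'
#' Exponential-integrator update of dC/dt = D lap(C) + P - k C for both
#' species. With a = exp(-k dt) and g = (1 - a)/k, each substep solves
#' (I - g D L) C_new = a C + g P with the 7-point Laplacian L. The scheme
#' is unconditionally stable and preserves non-negativity; it reduces to
#' the exact exponential decay when D = 0 and its fixed point satisfies the
#' exact screened steady state D lap(C) + P = k C for any substep size.
#' The explicit variant applies the same reaction factors with a forward
#' Laplacian and enforces the usual stability bound. The far field is held
#' at zero concentration.
#'
#' @param field a [chemical_field()].
#' @param src_ihh,src_pthrp node source densities (pM/um^3/s).
#' @param dt_days total time to advance (days).
#' @param substeps number of equal substeps.
#' @param scheme `"implicit"` or `"explicit"`.
#' @return the field with updated concentrations.
#' @export
step_reaction_diffusion <- function(field, src_ihh, src_pthrp, dt_days,
                                    substeps = 1L,
                                    scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  dt <- dt_days / substeps
  k <- field$k_day
  src_ihh <- src_ihh * 86400    # to per-day
  src_pthrp <- src_pthrp * 86400
  decay <- exp(-k * dt)
  gain <- if (k > 0) (1 - decay) / k else dt

  rhs <- function(C, P) C * decay + P * gain

  if (scheme == "implicit") {
    # Volume-weighted form: W A = W (I - g D L) is symmetric positive
    # definite (mirror planes halve node volumes) and strongly diagonally
    # dominant, so Jacobi-preconditioned conjugate gradients converge in a
    # few dozen matrix-vector products with no factorization.
    vol <- field$node_vol
    gD <- gain * field$D_day
    Amul <- function(v) vol * (v - gD * as.numeric(field$L %*% v))
    dL <- Matrix::diag(field$L)
    precon <- vol * (1 - gD * dL)
    cgsolve <- function(b, x) {
      b2 <- sum(b * b)
      if (b2 == 0) return(numeric(length(b)))
      r <- b - Amul(x)
      if (sum(r * r) <= 1e-24 * b2) return(x)
      z <- r / precon
      p <- z
      rz <- sum(r * z)
      for (it in 1:400) {
        Ap <- Amul(p)
        pAp <- sum(p * Ap)
        if (!is.finite(pAp) || pAp <= 0) break
        alpha <- rz / pAp
        x <- x + alpha * p
        r <- r - alpha * Ap
        if (sum(r * r) <= 1e-24 * b2) break
        z <- r / precon
        rz2 <- sum(r * z)
        p <- z + (rz2 / rz) * p
        rz <- rz2
      }
      x
    }
    for (s in seq_len(substeps)) {
      ci <- rhs(field$C_ihh, src_ihh)
      cp <- rhs(field$C_pthrp, src_pthrp)
      ci[field$dirichlet] <- 0; cp[field$dirichlet] <- 0
      field$C_ihh <- cgsolve(ci * vol, field$C_ihh)
      field$C_pthrp <- cgsolve(cp * vol, field$C_pthrp)
    }
  } else {
    nact <- sum(field$active)
    bound_g <- field$h^2 / (2 * nact * field$D_day)
    if (gain > bound_g)
      stop(sprintf(
        "explicit step %.3g days exceeds its stability bound; use more substeps",
        dt))
    for (s in seq_len(substeps)) {
      ci <- rhs(field$C_ihh, src_ihh)
      cp <- rhs(field$C_pthrp, src_pthrp)
      field$C_ihh <- ci + gain * field$D_day * as.numeric(field$L %*% field$C_ihh)
      field$C_pthrp <- cp + gain * field$D_day * as.numeric(field$L %*% field$C_pthrp)
      field$C_ihh[field$dirichlet] <- 0
      field$C_pthrp[field$dirichlet] <- 0
    }
  }
  if (any(field$C_ihh < -1e-9) || any(field$C_pthrp < -1e-9))
    stop("negative concentration produced by the diffusion step")
  field$C_ihh[field$C_ihh < 0] <- 0
  field$C_pthrp[field$C_pthrp < 0] <- 0
  field
}
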