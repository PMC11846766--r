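#' Capsule geometry specification
#'
#' Analytic description of the distal-metatarsal bone capsule: a cylinder of
#' radius 300 um and height 300 um capped by a dome that rises 340 um above
#' the cylinder top. The dome is the portion of an ellipsoid with x/y
#' semi-axes 330 um and z semi-axis 250 um whose center sits 90 um above the
#' cylinder top, so the total dome rise is 340 um; between the cylinder top
#' and the ellipsoid equator the dome overhangs the shaft slightly (the
#' bulbous metatarsal head). Only the x >= 0, y >= 0, z >= 0 octant is
#' discretized; the mirror planes carry slip/symmetry conditions.
#'
#' @param cyl_radius,cyl_height cylinder radius and height (um).
#' @param dome_height dome rise above the cylinder top (um).
#' @param dome_rxy,dome_rz dome ellipsoid semi-axes (um).
#' @param spacing material-point lattice spacing (um).
#' @param Vp0 initial material-point volume (um^3).
#' @return list of class `capsule_spec`.
#' @export
capsule_spec <- function(cyl_radius = 300, cyl_height = 300,
                         dome_height = 340, dome_rxy = 330, dome_rz = 250,
                         spacing = 10, Vp0 = spacing^3) {
  if (any(c(cyl_radius, cyl_height, dome_height, dome_rxy, dome_rz,
            spacing, Vp0) <= 0))
    stop("all capsule dimensions must be positive")
  if (dome_height <= dome_rz)
    stop("dome height must exceed the z semi-axis under the raised-center ",
         "interpretation (center at cyl_height + dome_height - dome_rz)")
  structure(list(cyl_radius = cyl_radius, cyl_height = cyl_height,
                 dome_height = dome_height, dome_rxy = dome_rxy,
                 dome_rz = dome_rz, spacing = spacing, Vp0 = Vp0,
                 dome_center_z = cyl_height + dome_height - dome_rz),
            class = "capsule_spec")
}

# membership predicate for the capsule solid (vectorized, inclusive bounds)
capsule_inside <- function(spec, x, y, z) {
  r2 <- x^2 + y^2
  in_cyl <- z >= 0 & z <= spec$cyl_height & r2 <= spec$cyl_radius^2
  t <- (z - spec$dome_center_z) / spec$dome_rz
  in_dome <- z > spec$cyl_height &
    r2 / spec$dome_rxy^2 + t^2 <= 1
  in_cyl | in_dome
}

# dome radius at height z (um); 0 outside the dome's z-range
dome_radius_at <- function(spec, z) {
  t <- (z - spec$dome_center_z) / spec$dome_rz
  spec$dome_rxy * sqrt(pmax(0, 1 - t^2))
}

#' Discretize the capsule into material points and boundary points
#'
#' Material points are placed on a cell-centered cubic lattice (coordinates at
#' half-spacing offsets) and kept when they satisfy the inclusive membership
#' predicate of the analytic solid. Under the default 10 um spacing this
#' yields 42,861 points in the octant. Boundary points are a deterministic
#' equal-area sampling of the three analytic surface patches (cylinder wall,
#' overhang annulus, dome cap) at a frozen density of one point per
#' `boundary_spacing^2` of surface, 5,491 points at the default spacing of
#' 7.8308 um. Boundary points are massless surface markers advected with the
#' displacement field; they carry outward normals for surface metrics.
#'
#' @param spec a [capsule_spec()].
#' @param boundary_spacing linear surface-sampling pitch (um).
#' @return list with `points` (an `mp_cloud`, see [mp_cloud()]) and
#'   `boundary` (list of `x` positions and `normal` outward unit normals),
#'   plus the counts `n_points`, `n_boundary`.
#' @export
build_capsule <- function(spec = capsule_spec(), boundary_spacing = 7.8308) {
  sp <- spec$spacing
  zmax <- spec$dome_center_z + spec$dome_rz
  g <- seq(sp / 2, max(spec$dome_rxy, zmax), by = sp)
  zs <- g[g <= zmax]
  pts <- vector("list", length(zs))
  for (iz in seq_along(zs)) {
    z <- zs[iz]
    rmax <- if (z <= spec$cyl_height) spec$cyl_radius else dome_radius_at(spec, z)
    if (rmax <= 0) next
    xs <- g[g <= rmax]
    rows <- lapply(xs, function(x) {
      ymax2 <- rmax^2 - x^2
      ys <- g[g * g <= ymax2]
      if (!length(ys)) return(NULL)
      cbind(x, ys, z)
    })
    pts[[iz]] <- do.call(rbind, rows)
  }
  X <- do.call(rbind, pts)
  colnames(X) <- c("x", "y", "z")
  bnd <- sample_capsule_surface(spec, boundary_spacing)
  cloud <- mp_cloud(X, V = spec$Vp0)
  list(points = cloud, boundary = bnd,
       n_points = nrow(X), n_boundary = nrow(bnd$x), spec = spec)
}

# golden-ratio low-discrepancy sequence on [0,1)
.golden <- function(n) ((seq_len(n) - 1) * 0.6180339887498949) %% 1

# Deterministic equal-area sampling of the octant surface. Patch areas are
# computed by fixed trapezoidal quadrature; point counts are allocated by
# largest remainder so the total is exactly round(A_total / s^2).
sample_capsule_surface <- function(spec, s) {
  a <- spec$dome_rxy; cc <- spec$dome_rz; zc <- spec$dome_center_z
  z0 <- spec$cyl_height; z1 <- zc + cc
  r_eq <- dome_radius_at(spec, z0)

  A_cyl <- spec$cyl_radius * (pi / 2) * spec$cyl_height
  A_ann <- (pi / 4) * max(0, r_eq^2 - spec$cyl_radius^2)
  # dome ring element: (pi/2) sqrt(rho^2 + (rho rho')^2) dz, rho rho' = -a^2 t/c
  zq <- seq(z0, z1, length.out = 2001)
  tq <- (zq - zc) / cc
  fq <- (pi / 2) * sqrt(a^2 * (1 - tq^2) + a^4 * tq^2 / cc^2)
  cum <- c(0, cumsum((fq[-1] + fq[-length(fq)]) / 2 * diff(zq)))
  A_dome <- cum[length(cum)]

  A <- A_cyl + A_ann + A_dome
  n_total <- round(A / s^2)
  raw <- n_total * c(A_cyl, A_ann, A_dome) / A
  n <- floor(raw)
  rem <- order(raw - n, decreasing = TRUE)
  short <- n_total - sum(n)
  if (short > 0) n[rem[seq_len(short)]] <- n[rem[seq_len(short)]] + 1

  out_x <- list(); out_n <- list()
  phi_of <- function(u) u * pi / 2

  if (n[1] > 0) { # cylinder wall
    t <- (seq_len(n[1]) - 0.5) / n[1]
    ph <- phi_of(.golden(n[1]))
    out_x$cyl <- cbind(spec$cyl_radius * cos(ph), spec$cyl_radius * sin(ph),
                       t * spec$cyl_height)
    out_n$cyl <- cbind(cos(ph), sin(ph), 0)
  }
  if (n[2] > 0) { # overhang annulus (outward normal -z)
    t <- (seq_len(n[2]) - 0.5) / n[2]
    r <- sqrt(spec$cyl_radius^2 + t * (r_eq^2 - spec$cyl_radius^2))
    ph <- phi_of(.golden(n[2]))
    out_x$ann <- cbind(r * cos(ph), r * sin(ph), rep(z0, n[2]))
    out_n$ann <- cbind(0, 0, rep(-1, n[2]))
  }
  if (n[3] > 0) { # dome cap, area-uniform in z via the cumulative ring area
    t <- (seq_len(n[3]) - 0.5) / n[3] * A_dome
    z <- approx(cum, zq, xout = t, rule = 2)$y
    rho <- dome_radius_at(spec, z)
    ph <- phi_of(.golden(n[3]))
    x <- rho * cos(ph); y <- rho * sin(ph)
    nv <- cbind(x / a^2, y / a^2, (z - zc) / cc^2)
    nv <- nv / sqrt(rowSums(nv^2))
    out_x$dome <- cbind(x, y, z)
    out_n$dome <- nv
  }
  x <- do.call(rbind, out_x); nv <- do.call(rbind, out_n)
  dimnames(x) <- list(NULL, c("x", "y", "z")); dimnames(nv) <- dimnames(x)
  list(x = x, normal = nv)
}

#' Assign initial cell types to a freshly built capsule
#'
#' Points within one lattice spacing of the lateral (cylinder wall plus
#' overhang) surface become perichondrium; points within one spacing of the
#' articular dome cap become periarticular PTHrP producers (precedence:
#' periarticular over perichondrium). All interior points start quiescent.
#' Points within `soc_seed_radius` of the epiphysis centroid on the axis are
#' flagged as the future secondary ossification center. The primary-center
#' slab itself is applied later by [initiate_poc()].
#'
#' @param cloud an `mp_cloud` from [build_capsule()].
#' @param spec the matching [capsule_spec()].
#' @param soc_seed_radius radius (um) of the future-SOC cluster.
#' @return the cloud with `type` and flag columns set.
#' @export
assign_initial_types <- function(cloud, spec, soc_seed_radius = 4 * spec$spacing) {
  X <- cloud$x
  sp <- spec$spacing
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  z <- X[, 3]

  # distance to the lateral wall (cylinder below the top, dome profile above)
  rmax <- ifelse(z <= spec$cyl_height, spec$cyl_radius, dome_radius_at(spec, z))
  lateral <- (rmax - r) <= sp & z <= spec$dome_center_z
  # articular cap: within one spacing of the dome surface, above the equator
  tt <- (z - spec$dome_center_z) / spec$dome_rz
  ell <- sqrt(r^2 / spec$dome_rxy^2 + tt^2)
  # signed approach to the ellipsoid surface along the local radius
  cap <- z > spec$dome_center_z & (1 - ell) * spec$dome_rz <= sp * 1.5

  cloud$type[] <- .ct[["quiescent"]]
  cloud$type[lateral] <- .ct[["perichondrium"]]
  cloud$type[cap] <- .ct[["periarticular_pthrp"]]

  # epiphysis centroid (dome region points), future-SOC cluster on the axis
  dome_pts <- z > spec$cyl_height
  zc <- if (any(dome_pts)) mean(z[dome_pts]) else spec$dome_center_z
  d2 <- X[, 1]^2 + X[, 2]^2 + (z - zc)^2
  cloud$soc_seed <- d2 <= soc_seed_radius^2 & cloud$type == .ct[["quiescent"]]
  if (!any(cloud$soc_seed))
    warning("future-SOC seed is empty; increase soc_seed_radius")
  cloud$E[] <- NA_real_  # set by the driver from config
  cloud
}
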