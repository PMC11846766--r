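#' Quadratic B-spline interpolation weight
#'
#' Weight of one background-grid node at position `x`, for the interior
#' quadratic B-spline basis on a regular grid of spacing `h`. The weights of
#' the (at most three per axis) supporting nodes form a C1-continuous
#' partition of unity at any interior point.
#'
#' @param node node coordinate(s): scalar for 1-D, length-3 for 3-D.
#' @param x evaluation position, same length as `node`.
#' @param h grid spacing (um).
#' @return scalar weight in \[0, 3/4\]^d.
#' @export
bspline_weight <- function(node, x, h) {
  r <- (x - node) / h
  w <- vapply(r, function(ri) {
    a <- abs(ri)
    if (a < 0.5) 0.75 - a^2 else if (a < 1.5) 0.5 * (1.5 - a)^2 else 0
  }, numeric(1))
  prod(w)
}

#' Background grid descriptor
#'
#' A regular Eulerian grid identified by its node origin, spacing and node
#' counts per axis. Symmetric axes (`sym`) have a mirror plane at coordinate
#' zero: the grid holds ghost layers beyond the plane and slave-maps them to
#' their mirror images so that slip (zero normal displacement) and zero-flux
#' conditions hold exactly.
#'
#' @param origin node coordinates of the first node per axis (um).
#' @param dims integer node counts per axis.
#' @param h spacing (um).
#' @param sym logical length-3, mirror plane at 0 on that axis.
#' @export
background_grid <- function(origin, dims, h, sym = c(TRUE, TRUE, TRUE)) {
  structure(list(origin = as.numeric(origin), dims = as.integer(dims),
                 h = h, sym = sym, n_nodes = prod(dims)),
            class = "background_grid")
}

# node coordinate arrays (list of per-axis vectors)
grid_axes <- function(g) {
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$dims[a]) - 1) * g$h)
}

# full node coordinate matrix (n_nodes x 3), index = i + nx(j + ny k), 0-based
grid_coords <- function(g) {
  ax <- grid_axes(g)
  cbind(rep(ax[[1]], times = g$dims[2] * g$dims[3]),
        rep(rep(ax[[2]], each = g$dims[1]), times = g$dims[3]),
        rep(ax[[3]], each = g$dims[1] * g$dims[2]))
}

# Build a mechanics grid covering the particle bounding box with ghost margin.
# Two ghost layers beyond each mirror plane, two spare cells on free sides.
mech_grid <- function(X, h, sym = c(TRUE, TRUE, TRUE), margin = 2L) {
  lo <- hi <- numeric(3); dims <- integer(3)
  for (a in 1:3) {
    lo[a] <- if (sym[a]) -margin * h else (floor(min(X[, a]) / h) - margin) * h
    hi[a] <- (ceiling(max(X[, a]) / h) + margin) * h
    dims[a] <- round((hi[a] - lo[a]) / h) + 1L
  }
  background_grid(lo, dims, h, sym)
}

# Mirror/slip constraint map for a mechanics grid: returns, per node, the
# master node index and the per-component sign, plus which components are
# pinned to zero (normal components on the mirror planes). Encoded as a
# sparse expansion matrix S with u_full = S %*% u_free and g_free = t(S) g_full.
grid_constraints <- function(g) {
  co <- grid_coords(g)
  n <- g$n_nodes
  mast <- co
  sgn <- matrix(1, n, 3)
  fixed <- matrix(FALSE, n, 3)
  for (a in 1:3) {
    if (!g$sym[a]) next
    neg <- co[, a] < 0
    mast[neg, a] <- -co[neg, a]
    sgn[neg, a] <- -1
    fixed[abs(co[, a]) < g$h / 2, a] <- TRUE  # nodes on the plane: u_n = 0
  }
  # master node linear index (0-based axes -> 1-based id)
  ia <- round((mast[, 1] - g$origin[1]) / g$h)
  ja <- round((mast[, 2] - g$origin[2]) / g$h)
  ka <- round((mast[, 3] - g$origin[3]) / g$h)
  mid <- 1L + ia + g$dims[1] * (ja + g$dims[2] * ka)
  is_master <- mid == seq_len(n)
  # fixed status propagates from master, sign flips pin ghosts consistently
  fixed <- fixed | fixed[mid, , drop = FALSE]

  free <- which(t(!fixed[mid, , drop = FALSE] & matrix(is_master[mid], n, 3)) != 0)
  # dof numbering: node-major (3*(g-1)+a) to match the C++ layout
  dof_master <- 3L * (mid - 1L)                     # base of master node
  full_i <- integer(0); free_j <- integer(0); s_x <- numeric(0)
  # map each full dof to its master dof if that master dof is free
  master_dof_id <- matrix(0L, n, 3)
  cnt <- 0L
  for (a in 1:3) {
    sel <- is_master & !fixed[, a]
    ids <- integer(n)
    ids[sel] <- cnt + seq_len(sum(sel))
    cnt <- cnt + sum(sel)
    master_dof_id[, a] <- ids
  }
  for (a in 1:3) {
    j <- master_dof_id[mid, a]
    keep <- j > 0L & !fixed[, a]
    full_i <- c(full_i, 3L * (which(keep) - 1L) + a)
    free_j <- c(free_j, j[keep])
    s_x <- c(s_x, sgn[keep, a])
  }
  S <- Matrix::sparseMatrix(i = full_i, j = free_j, x = s_x,
                            dims = c(3L * n, cnt))
  list(S = S, n_free = cnt)
}

#' Interpolate grid displacements at arbitrary positions
#'
#' Evaluates u(x) = sum_g u_g N_g(x) with the quadratic B-spline basis.
#'
#' @param grid a [background_grid()].
#' @param u node displacement matrix (n_nodes x 3).
#' @param X positions (N x 3); must lie inside the grid's support region.
#' @return N x 3 matrix of displacements.
#' @export
interpolate_displacement <- function(grid, u, X) {
  X <- matrix(as.numeric(X), ncol = 3)
  out <- matrix(0, nrow(X), 3)
  for (a in 1:3)
    out[, a] <- cpp_field_interp(X, u[, a], grid$origin, grid$h, grid$dims)
  out
}
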