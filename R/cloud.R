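#' Material-point cloud
#'
#' Struct-of-arrays container for the Lagrangian state: positions, total and
#' growth deformation gradients (row-major 3x3 per point), volumes, moduli,
#' cell type, cell-cycle state and timers. All tensor invariants
#' (det F > 0, det F^g > 0, V > 0) are maintained by the update routines.
#'
#' @param X numeric matrix (N x 3) of positions in um.
#' @param V initial point volume(s), um^3.
#' @param type initial cell-type code(s), see [cell_type_codes].
#' @return list of class `mp_cloud`.
#' @export
mp_cloud <- function(X, V = 1000, type = cell_type_codes[["quiescent"]]) {
  X <- as.matrix(X)
  if (ncol(X) != 3) stop("X must have 3 columns")
  n <- nrow(X)
  I9 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), nrow = n)
  structure(list(
    x = unname(X),
    F = I9, Fg = I9, Fg0 = I9,
    V = rep_len(V, n), V0 = rep_len(V, n),
    E = rep(NA_real_, n), nu = rep(NA_real_, n),
    type = rep_len(as.integer(type), n),
    t_H = rep(NA_real_, n),        # days in (pre)hypertrophic state
    t_fate = rep(NA_real_, n),     # days since terminal transition began
    cycling = rep(FALSE, n),
    final_cycle = rep(FALSE, n),   # differentiated mid-cycle: finish, then stop
    t_cycle = rep(NA_real_, n),
    T_g0 = rep(NA_real_, n),       # remaining quiescence, days
    ns = matrix(NA_real_, n, 3),   # division / columnar growth axis
    soc_seed = rep(FALSE, n),
    id = seq_len(n)
  ), class = "mp_cloud")
}

#' @export
print.mp_cloud <- function(x, ...) {
  tab <- table(cell_type_name(x$type))
  cat("<mp_cloud>", length(x$V), "points;",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud an `mp_cloud`.
#' @export
n_points <- function(cloud) length(cloud$V)

# row-subset every per-point field
subset_cloud <- function(cloud, idx) {
  out <- cloud
  for (f in names(out)) {
    v <- out[[f]]
    out[[f]] <- if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  }
  out
}

# concatenate two clouds (used when divisions append children)
bind_cloud <- function(a, b) {
  out <- a
  for (f in names(out)) {
    va <- a[[f]]; vb <- b[[f]]
    out[[f]] <- if (is.matrix(va)) rbind(va, vb) else c(va, vb)
  }
  out
}

# 3x3 determinant of row-major rows of a N x 9 matrix (vectorized)
det_rows <- function(M) {
  M[, 1] * (M[, 5] * M[, 9] - M[, 6] * M[, 8]) -
  M[, 2] * (M[, 4] * M[, 9] - M[, 6] * M[, 7]) +
  M[, 3] * (M[, 4] * M[, 8] - M[, 5] * M[, 7])
}
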