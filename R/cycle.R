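#' Growth part of the deformation gradient from a growth stretch
#'
#' Isotropic growth scales the committed growth tensor by theta; columnar
#' (unidirectional) growth applies the rank-one stretch
#' (I + (theta - 1) n (x) n) along the division axis.
#'
#' @param Fg0 committed growth tensor at the onset of the episode (3 x 3).
#' @param theta growth stretch, `theta >= 1`.
#' @param mode `"isotropic"` or `"unidirectional"`.
#' @param ns unit axis (length 3), required for unidirectional growth.
#' @return the updated growth tensor (3 x 3).
#' @export
apply_growth_tensor <- function(Fg0, theta, mode = c("isotropic", "unidirectional"),
                                ns = NULL) {
  mode <- match.arg(mode)
  if (theta < 1) stop("theta must be >= 1")
  if (mode == "isotropic") return(theta * Fg0)
  if (is.null(ns) || any(!is.finite(ns)))
    stop("unidirectional growth requires a division axis")
  ns <- ns / sqrt(sum(ns^2))
  (diag(3) + (theta - 1) * tcrossprod(ns)) %*% Fg0
}

# vectorized growth-tensor rebuild for many points (row-major N x 9 tensors)
grow_rows <- function(Fg0, theta, iso, ns) {
  n <- nrow(Fg0)
  out <- Fg0 * 1
  if (any(iso)) out[iso, ] <- Fg0[iso, , drop = FALSE] * theta[iso]
  uni <- which(!iso & theta > 1)
  if (length(uni)) {
    f0 <- Fg0[uni, , drop = FALSE]
    nv <- ns[uni, , drop = FALSE]
    th <- theta[uni] - 1
    for (b in 1:3) {
      # s_b = sum_c n_c Fg0[c, b]
      s <- nv[, 1] * f0[, b] + nv[, 2] * f0[, 3 + b] + nv[, 3] * f0[, 6 + b]
      for (a in 1:3) out[uni, 3 * (a - 1) + b] <-
          f0[, 3 * (a - 1) + b] + th * nv[, a] * s
    }
  }
  out
}

#' Sample a quiescence (G0) duration
#'
#' Inverse-CDF draw from the exponential quiescence model
#' T_G0 = -log(1 - r) / R_prolif.
#'
#' @param R_prolif proliferation rate parameter (1/day).
#' @param r uniform draw(s) in \[0, 1).
#' @return duration(s) in days.
#' @export
sample_g0_duration <- function(R_prolif, r) {
  if (R_prolif <= 0) stop("R_prolif must be positive")
  if (any(r < 0 | r >= 1)) stop("invalid uniform draw; resample in [0, 1)")
  -log(1 - r) / R_prolif
}

#' Division direction from the Ihh gradient
#'
#' The columnar growth and division axis follows the local Indian hedgehog
#' concentration gradient. Below a gradient norm of 1e-12 the cell's previous
#' axis is reused; failing that, a seeded random unit vector breaks the tie.
#'
#' @param grad numeric length-3 Ihh gradient at the cell.
#' @param prev previous axis (length-3 or `NA`s).
#' @return unit length-3 axis.
#' @export
division_direction <- function(grad, prev = c(NA, NA, NA)) {
  nrm <- sqrt(sum(grad^2))
  if (is.finite(nrm) && nrm > 1e-12) return(grad / nrm)
  if (all(is.finite(prev))) return(prev / sqrt(sum(prev^2)))
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Split a dividing material point into two children
#'
#' Children inherit the parent's deformation state and cell type, each takes
#' half the parent's volume, and they are placed symmetrically about the
#' parent along the division axis.
#'
#' @param parent single-point `mp_cloud` (see subset_cloud usage in the
#'   driver); exposed for testing via a one-row cloud.
#' @param ns unit division axis.
#' @param offset half-distance between the children (um); default half the
#'   child's equivalent cube edge.
#' @return two-point `mp_cloud`.
#' @export
split_point <- function(parent, ns, offset = NULL) {
  if (n_points(parent) != 1) stop("split_point expects a single parent point")
  if (any(!is.finite(ns))) stop("division axis is unset")
  ns <- ns / sqrt(sum(ns^2))
  if (is.null(offset)) offset <- (parent$V / 2)^(1 / 3) / 2
  kids <- bind_cloud(parent, parent)
  kids$x[1, ] <- parent$x[1, ] - offset * ns
  kids$x[2, ] <- parent$x[1, ] + offset * ns
  kids$V <- rep(parent$V / 2, 2)
  kids$V0 <- rep(parent$V0 / 2, 2)
  kids$id <- c(parent$id, NA_integer_)  # driver assigns fresh ids
  kids
}

#' Advance cell-cycle state for one increment
#'
#' Vectorized engine for the S/G2/M/G1/G0 machine. Within a cycle,
#' `t_cycle` runs from 0 (S onset) to `T_cycle`; crossing half of `T_cycle`
#' emits one division event; completing the cycle enters G0 with an
#' exponentially sampled duration, after which a new cycle begins (columnar
#' cells re-sample their axis from the Ihh gradient). Growth stretch for
#' columnar cells ramps linearly so the growth determinant reaches
#' `prolif_volume_multiple` over one full cycle; stretch is frozen in G0.
#' Cells flagged `final_cycle` (differentiated while cycling) finish the
#' current cycle, dividing at most once, and do not re-enter.
#'
#' @param cloud an `mp_cloud`.
#' @param dt time increment (days), positive.
#' @param cfg an `oss_config`.
#' @param ihh_grad N x 3 matrix of Ihh gradients at the points (for axis
#'   re-sampling), or `NULL` for no re-sampling.
#' @return list: `cloud` (updated, children appended), `divisions`
#'   (data.frame of parent id, child ids, axis), `next_id`.
#' @export
advance_cycle <- function(cloud, dt, cfg, ihh_grad = NULL) {
  if (dt <= 0) stop("dt must be positive")
  Tc <- cfg$T_cycle
  half <- 0.5 * Tc

  # --- G0 countdown and cycle re-entry -------------------------------------
  ing0 <- cloud$cycling & !is.na(cloud$T_g0) & cloud$T_g0 > 0
  cloud$T_g0[ing0] <- cloud$T_g0[ing0] - dt
  reenter <- which(ing0 & cloud$T_g0 <= 0 & !cloud$final_cycle)
  if (length(reenter)) {
    cloud$T_g0[reenter] <- NA_real_
    cloud$t_cycle[reenter] <- 0
    cloud$Fg0[reenter, ] <- cloud$Fg[reenter, , drop = FALSE]
    for (i in reenter) {
      g <- if (is.null(ihh_grad)) c(0, 0, 0) else ihh_grad[i, ]
      cloud$ns[i, ] <- division_direction(g, cloud$ns[i, ])
    }
  }

  # --- advance in-flight cycles --------------------------------------------
  act <- which(cloud$cycling & !is.na(cloud$t_cycle))
  dividers <- integer(0)
  if (length(act)) {
    t0 <- cloud$t_cycle[act]
    t1 <- t0 + dt
    dividers <- act[t0 < half & t1 >= half]
    done <- t1 >= Tc
    cloud$t_cycle[act] <- ifelse(done, NA_real_, t1)
    fin <- act[done]
    if (length(fin)) {
      # columnar cells complete the episode at the full stretch, then commit;
      # cells already in an isotropic episode keep their own baseline
      col_fin <- fin[is.na(cloud$t_H[fin])]
      if (length(col_fin)) {
        cloud$Fg[col_fin, ] <- grow_rows(
          cloud$Fg0[col_fin, , drop = FALSE],
          rep(cfg$prolif_volume_multiple, length(col_fin)),
          rep(FALSE, length(col_fin)),
          cloud$ns[col_fin, , drop = FALSE])
        cloud$Fg0[col_fin, ] <- cloud$Fg[col_fin, , drop = FALSE]
      }
      stopped <- fin[cloud$final_cycle[fin]]
      rest <- setdiff(fin, stopped)
      cloud$cycling[stopped] <- FALSE
      if (length(rest))
        cloud$T_g0[rest] <- sample_g0_duration(cfg$R_prolif,
                                               runif(length(rest)))
    }
  }

  # --- rebuild growth tensors from stretch schedules -----------------------
  # columnar: theta in [1, m) across the cycle; frozen outside a cycle
  colmn <- cloud$cycling & !is.na(cloud$t_cycle) & is.na(cloud$t_H)
  th <- rep(1, n_points(cloud))
  th[colmn] <- 1 + (cfg$prolif_volume_multiple - 1) *
    pmin(cloud$t_cycle[colmn] / Tc, 1)
  # isotropic: theta ramps to hyp_volume_multiple^(1/3) across prehypertrophy
  # plus hypertrophy (both phases enlarge)
  iso <- !is.na(cloud$t_H) & cloud$type %in% c(.ct[["prehypertrophic"]],
                                               .ct[["hypertrophic"]])
  th_max <- cfg$hyp_volume_multiple^(1 / 3)
  th[iso] <- 1 + (th_max - 1) * pmin(cloud$t_H[iso] / (cfg$T_prehyp + cfg$T_hyp), 1)
  upd <- which((colmn | iso) & th > 1)
  if (length(upd))
    cloud$Fg[upd, ] <- grow_rows(cloud$Fg0[upd, , drop = FALSE], th[upd],
                                 iso[upd], cloud$ns[upd, , drop = FALSE])

  # --- divisions ------------------------------------------------------------
  div_log <- NULL
  if (length(dividers)) {
    dividers <- sort(dividers)
    next_id <- max(cloud$id, na.rm = TRUE)
    kid_list <- vector("list", length(dividers))
    for (m in seq_along(dividers)) {
      i <- dividers[m]
      kids <- split_point(subset_cloud(cloud, i), cloud$ns[i, ])
      kids$id <- next_id + c(1L, 2L)
      next_id <- next_id + 2L
      kid_list[[m]] <- kids
    }
    div_log <- data.frame(
      parent = cloud$id[dividers],
      child_a = vapply(kid_list, function(k) k$id[1], integer(1)),
      child_b = vapply(kid_list, function(k) k$id[2], integer(1)),
      nx = cloud$ns[dividers, 1], ny = cloud$ns[dividers, 2],
      nz = cloud$ns[dividers, 3])
    keep <- subset_cloud(cloud, setdiff(seq_len(n_points(cloud)), dividers))
    cloud <- Reduce(bind_cloud, kid_list, accumulate = FALSE, init = keep)
  }
  list(cloud = cloud, divisions = div_log)
}
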