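#' Detect fusion of the primary and secondary ossification centers
#'
#' Voxelizes the calcified occupancy (matrix and apoptotic points; the bone
#' collar is excluded) on the background-grid spacing and flood-fills
#' 6-connected components. Each point occupies every voxel overlapped by its
#' material cube (edge V^(1/3)), not just the voxel under its center, so
#' enlarged calcified cells register as solid occupancy. The centers are
#' fused when the component reaching the diaphyseal base (the lowest
#' calcified voxel) also contains a calcified point descended from the SOC
#' seed -- equivalently, no axial band of non-calcified chondrocytes
#' separates the two centers.
#'
#' @param cloud an `mp_cloud`.
#' @param cfg an `oss_config` (uses `grid_h`).
#' @return logical.
#' @export
detect_fusion <- function(cloud, cfg) {
  calc <- cloud$type %in% .calcified_codes
  if (!any(calc)) return(FALSE)
  soc_calc <- calc & cloud$soc_seed
  if (!any(soc_calc)) return(FALSE)
  h <- cfg$grid_h
  X <- cloud$x[calc, , drop = FALSE]
  half <- cloud$V[calc]^(1 / 3) / 2
  # voxels covered by each material cube (at most 2 per axis for half < h)
  vox <- NULL; owner <- NULL
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    v <- cbind(floor((X[, 1] + (2 * cx - 1) * half) / h),
               floor((X[, 2] + (2 * cy - 1) * half) / h),
               floor((X[, 3] + (2 * cz - 1) * half) / h))
    vox <- rbind(vox, v)
    owner <- c(owner, seq_len(nrow(X)))
  }
  comp_all <- flood_components(vox)
  poc_comp <- comp_all[which.min(vox[, 3])]
  soc_rows <- owner %in% which(cloud$soc_seed[calc])
  any(comp_all[soc_rows] == poc_comp)
}

# 6-connected components of a set of integer voxels (rows). Returns a
# component label per input row. Neighbor lookups are vectorized through an
# integer voxel encoding; labels are spread by repeated label-minimization.
flood_components <- function(vox) {
  B <- 4096L; off <- 1024L
  enc <- function(v) (v[, 1] + off) + B * ((v[, 2] + off) + B * (v[, 3] + off))
  key <- enc(vox)
  uk <- unique(key)
  row_of <- match(key, uk)
  m <- length(uk)
  uvox <- vox[match(uk, key), , drop = FALSE]
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbr <- matrix(NA_integer_, m, 6)
  for (s in 1:6)
    nbr[, s] <- match(enc(sweep(uvox, 2, shifts[s, ], "+")), uk)
  lab <- seq_len(m)
  repeat {
    new <- lab
    for (s in 1:6) {
      has <- !is.na(nbr[, s])
      new[has] <- pmin(new[has], lab[nbr[has, s]])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, unique(lab))[row_of]
}

#' Detect penetration of the resting zone
#'
#' True when a proliferative, prehypertrophic or hypertrophic point lies
#' strictly inside the materially tracked resting zone: within the band
#' spanned by the remaining resting producers, and with resting material
#' both below and above it in its own lateral column (xy-distance at most
#' twice the point spacing). The column requirement distinguishes genuine
#' intrusion between resting cells from ordinary consumption of the band's
#' lower edge by the advancing (possibly curved) growth-plate front.
#'
#' @param cloud an `mp_cloud`.
#' @param cfg an `oss_config`.
#' @param quiet suppress the empty-resting-zone warning.
#' @return logical.
#' @export
detect_penetration <- function(cloud, cfg, quiet = FALSE) {
  rest <- cloud$type == .ct[["resting_pthrp"]]
  if (!any(rest)) {
    if (!quiet) warning("resting zone is empty; penetration undefined (FALSE)")
    return(FALSE)
  }
  sp <- cfg$spacing
  zlo <- min(cloud$x[rest, 3]) + sp / 2
  zhi <- max(cloud$x[rest, 3]) - sp / 2
  if (zhi <= zlo) return(FALSE)
  pen <- which(cloud$type %in% .penetrating_codes &
               cloud$x[, 3] > zlo & cloud$x[, 3] < zhi)
  if (!length(pen)) return(FALSE)
  RX <- cloud$x[rest, , drop = FALSE]
  rad <- 2 * sp
  for (i in pen) {
    d2 <- (RX[, 1] - cloud$x[i, 1])^2 + (RX[, 2] - cloud$x[i, 2])^2
    near <- d2 <= rad^2
    if (any(near & RX[, 3] < cloud$x[i, 3] - sp / 4) &&
        any(near & RX[, 3] > cloud$x[i, 3] + sp / 4)) return(TRUE)
  }
  FALSE
}

#' Resting-zone PTHrP production time series
#'
#' Per-increment mean production over resting-zone producers, as logged by
#' [run_simulation()]. Early in SOC maturation the series rises with slope
#' approximately `P_pthrp_max * (Ihh_total/ihh_max) / T_mat` and later
#' fluctuates with the total Ihh.
#'
#' @param sim an `oss_sim`.
#' @return data.frame with `day` and `resting_P` (pM/um^3/s).
#' @export
measure_pthrp_production <- function(sim) {
  sim$census[, c("day", "resting_P")]
}

#' Sweep the SOC maturation time
#'
#' Runs one simulation per `T_mat` value (per-run seed = `cfg$seed` + index
#' - 1) and tabulates the outcome: fusion and resting-zone penetration with
#' their first days, and the maturation slope `1/T_mat`. `T_mat = Inf` is
#' the no-resting-zone-PTHrP counterfactual (resting production disabled).
#' Individual run failures are recorded and the sweep continues.
#'
#' @param cfg base `oss_config`.
#' @param tmats numeric vector of maturation times (days).
#' @return list of class `oss_sweep`: `outcomes` data.frame, `series` list
#'   of resting-production time series, `sims` list.
#' @export
run_tmat_sweep <- function(cfg, tmats) {
  n <- length(tmats)
  out <- vector("list", n); series <- vector("list", n); sims <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- tmats[i]
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    if (is.finite(tm)) ci$T_mat <- tm else ci$resting_enabled <- FALSE
    res <- tryCatch(run_simulation(ci), error = function(e) e)
    if (inherits(res, "error")) {
      out[[i]] <- data.frame(T_mat = tm, slope = 1 / tm, fused = NA,
                             fusion_day = NA_real_, penetrated = NA,
                             penetration_day = NA_real_,
                             error = conditionMessage(res))
      next
    }
    sims[[i]] <- res
    series[[i]] <- measure_pthrp_production(res)
    out[[i]] <- data.frame(T_mat = tm, slope = 1 / tm,
                           fused = res$outcome$fused,
                           fusion_day = res$outcome$fusion_day,
                           penetrated = res$outcome$penetrated,
                           penetration_day = res$outcome$penetration_day,
                           error = NA_character_)
  }
  structure(list(outcomes = do.call(rbind, out), series = series, sims = sims),
            class = "oss_sweep")
}

#' @export
print.oss_sweep <- function(x, ...) {
  print(x$outcomes[, setdiff(names(x$outcomes), "error")])
  invisible(x)
}
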