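#' Threshold-driven cell differentiation for one increment
#'
#' Applies the differentiation rules on a snapshot of the local Ihh and
#' PTHrP concentrations (strict inequalities throughout; at most one
#' transition per cell per increment):
#' \itemize{
#'   \item quiescent (or resting producer) -> proliferative when
#'     `C_Ihh > c_th_ihh_prolif`;
#'   \item proliferative -> prehypertrophic when `C_Ihh > c_th_ihh_prehyp`
#'     and `C_PTHrP < c_th_pthrp_prehyp` (the PTHrP gate);
#'   \item prehypertrophic -> hypertrophic when `t_H > T_prehyp`;
#'   \item hypertrophic -> apoptotic or matrix with probability one half
#'     each when `t_H > T_prehyp + T_hyp` (both states are absorbing);
#'   \item perichondrial types -> bone collar when `C_Ihh > c_th_ihh_bc`.
#' }
#' Timers (`t_H`, terminal `t_fate`) are advanced here, and moduli of points
#' in a terminal or bone-collar transition follow
#' [transition_properties()].
#'
#' @param cloud an `mp_cloud`.
#' @param C_ihh,C_pthrp per-point concentrations (pM/um^3).
#' @param dt increment (days).
#' @param cfg an `oss_config`.
#' @param ihh_grad optional N x 3 Ihh gradient matrix used to orient the
#'   first cycle of newly proliferative cells.
#' @return the updated cloud.
#' @export
update_fate <- function(cloud, C_ihh, C_pthrp, dt, cfg, ihh_grad = NULL) {
  type0 <- cloud$type

  # advance maturation and terminal-transition clocks
  inH <- !is.na(cloud$t_H)
  cloud$t_H[inH] <- cloud$t_H[inH] + dt
  inT <- !is.na(cloud$t_fate)
  cloud$t_fate[inT] <- cloud$t_fate[inT] + dt

  # quiescent-like -> proliferative
  eligible <- type0 %in% .quiescent_like
  if (!cfg$resting_can_proliferate)
    eligible <- eligible & type0 != .ct[["resting_pthrp"]]
  go <- which(eligible & C_ihh > cfg$c_th_ihh_prolif)
  if (length(go)) {
    cloud$type[go] <- .ct[["proliferative"]]
    cloud$cycling[go] <- TRUE
    cloud$t_cycle[go] <- 0
    cloud$T_g0[go] <- NA_real_
    cloud$Fg0[go, ] <- cloud$Fg[go, , drop = FALSE]
    for (i in go) {
      g <- if (is.null(ihh_grad)) c(0, 0, 0) else ihh_grad[i, ]
      cloud$ns[i, ] <- division_direction(g, cloud$ns[i, ])
    }
  }

  # proliferative -> prehypertrophic (Ihh threshold AND PTHrP gate)
  go <- which(type0 == .ct[["proliferative"]] &
              C_ihh > cfg$c_th_ihh_prehyp &
              C_pthrp < cfg$c_th_pthrp_prehyp)
  if (length(go)) {
    cloud$type[go] <- .ct[["prehypertrophic"]]
    cloud$t_H[go] <- 0
    cloud$Fg0[go, ] <- cloud$Fg[go, , drop = FALSE]  # isotropic episode begins
    midcycle <- go[!is.na(cloud$t_cycle[go])]
    cloud$final_cycle[midcycle] <- TRUE              # finish, divide once
    idle <- go[is.na(cloud$t_cycle[go])]             # in G0: never re-enter
    cloud$cycling[idle] <- FALSE
    cloud$T_g0[idle] <- NA_real_
  }

  # prehypertrophic -> hypertrophic (timed)
  go <- which(type0 == .ct[["prehypertrophic"]] & cloud$t_H > cfg$T_prehyp)
  cloud$type[go] <- .ct[["hypertrophic"]]

  # hypertrophic -> apoptotic | matrix, equal probability
  go <- which(type0 == .ct[["hypertrophic"]] &
              cloud$t_H > cfg$T_prehyp + cfg$T_hyp)
  if (length(go)) {
    tomatrix <- runif(length(go)) < 0.5
    cloud$type[go] <- ifelse(tomatrix, .ct[["matrix"]], .ct[["apoptotic"]])
    cloud$t_fate[go] <- 0
    cloud$cycling[go] <- FALSE
    cloud$Fg0[go, ] <- cloud$Fg[go, , drop = FALSE]  # growth frozen
  }

  # perichondrial lineage -> bone collar
  go <- which(type0 %in% .perichondrial_like & C_ihh > cfg$c_th_ihh_bc)
  if (length(go)) {
    cloud$type[go] <- .ct[["bone_collar"]]
    cloud$t_fate[go] <- 0
  }

  # material-property transitions in progress
  ramp <- which(!is.na(cloud$t_fate))
  if (length(ramp)) {
    pr <- transition_properties(cloud$type[ramp], cloud$t_fate[ramp], cfg)
    cloud$E[ramp] <- pr$E
    cloud$nu[ramp] <- pr$nu
  }
  cloud
}

#' Material-property schedule during calcification transitions
#'
#' Young's modulus ramps log-linearly (the stiffness change spans up to
#' three decades) from the chondrocyte value to the target of the new state
#' -- bone matrix stiffness for matrix and apoptotic points (both belong to
#' the calcified zones), bone-collar stiffness for the collar -- over
#' `T_calcif` (matrix, collar) or `T_apop` (apoptotic). The Poisson ratio
#' ramps linearly. Endpoint values are exact at the end of the schedule.
#'
#' @param type cell-type code(s) (matrix, apoptotic or bone_collar).
#' @param elapsed days since the transition began, `>= 0`.
#' @param cfg an `oss_config`.
#' @return list with vectors `E` (kPa) and `nu`.
#' @export
transition_properties <- function(type, elapsed, cfg) {
  if (any(elapsed < 0)) stop("elapsed must be non-negative")
  Etarget <- ifelse(type == .ct[["bone_collar"]], cfg$E_bc, cfg$E_calcif)
  nutarget <- ifelse(type == .ct[["bone_collar"]], cfg$nu_bc, cfg$nu_calcif)
  Tdur <- ifelse(type == .ct[["apoptotic"]], cfg$T_apop, cfg$T_calcif)
  f <- pmin(elapsed / Tdur, 1)
  list(E = 10^((1 - f) * log10(cfg$E_cell) + f * log10(Etarget)),
       nu = (1 - f) * cfg$nu_cell + f * nutarget)
}

#' Initiate the primary ossification center
#'
#' Converts the layer of cells spanning the diaphysis center (the slab
#' `z <= slab` at the base of the capsule) to the prehypertrophic type with
#' maturation clock zero. Idempotent: points already prehypertrophic are
#' left untouched.
#'
#' @param cloud an `mp_cloud`.
#' @param slab slab thickness in um (default one point spacing is set by the
#'   driver).
#' @return the updated cloud.
#' @export
initiate_poc <- function(cloud, slab) {
  sel <- cloud$x[, 3] <= slab
  if (!any(sel)) stop("POC slab contains no points; check geometry/config")
  sel <- sel & cloud$type != .ct[["prehypertrophic"]]
  cloud$type[sel] <- .ct[["prehypertrophic"]]
  cloud$t_H[sel] <- 0
  cloud$Fg0[sel, ] <- cloud$Fg[sel, , drop = FALSE]
  cloud
}

#' Initiate the secondary ossification center
#'
#' Converts the flagged future-SOC cluster in the epiphysis to the
#' prehypertrophic type and starts the SOC maturation clock (`t_SOC = 0`).
#' Must be called exactly once.
#'
#' @param cloud an `mp_cloud` with `soc_seed` flags.
#' @param state a simulation-state environment/list carrying `t_SOC`
#'   (`NA` before onset); pass `NULL` when using the return value only.
#' @return list: `cloud`, `t_SOC = 0`.
#' @export
initiate_soc <- function(cloud, state = NULL) {
  if (!is.null(state) && !is.na(state$t_SOC))
    stop("secondary ossification already initiated")
  sel <- cloud$soc_seed & !cloud$type %in% .calcified_codes
  conv <- sel & cloud$type != .ct[["prehypertrophic"]]
  cloud$type[conv] <- .ct[["prehypertrophic"]]
  cloud$t_H[conv] <- 0
  cloud$cycling[conv] <- FALSE
  cloud$Fg0[conv, ] <- cloud$Fg[conv, , drop = FALSE]
  list(cloud = cloud, t_SOC = 0)
}

#' Tag the resting zone at SOC onset
#'
#' Quiescent points lying strictly between the top of the proliferative zone
#' and the bottom of the SOC seed, within the proliferative zone's radial
#' footprint, become resting-zone PTHrP producers.
#'
#' @param cloud an `mp_cloud` at the moment of SOC initiation.
#' @param margin radial slack added to the proliferative footprint (um).
#' @return the updated cloud (possibly with an empty tag set and a warning).
#' @export
define_resting_zone <- function(cloud, margin = 5) {
  prolif <- cloud$type == .ct[["proliferative"]]
  soc <- cloud$soc_seed
  if (!any(soc)) { warning("no SOC seed; resting zone not defined"); return(cloud) }
  z_top <- if (any(prolif)) max(cloud$x[prolif, 3]) else -Inf
  z_soc <- min(cloud$x[soc, 3])
  r_ext <- if (any(prolif)) max(sqrt(rowSums(cloud$x[prolif, 1:2, drop = FALSE]^2)))
           else Inf
  r <- sqrt(cloud$x[, 1]^2 + cloud$x[, 2]^2)
  sel <- cloud$type == .ct[["quiescent"]] &
    cloud$x[, 3] > z_top & cloud$x[, 3] < z_soc & r <= r_ext + margin
  if (!any(sel)) {
    warning("resting zone is empty; simulation proceeds without resting PTHrP")
    return(cloud)
  }
  cloud$type[sel] <- .ct[["resting_pthrp"]]
  cloud
}
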