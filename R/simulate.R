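# exact stress-free state of a laterally free 1-D column: segments stack from
# the z = 0 slip plane, each with axial stretch Fg_zz; F = Fg, V = V0 det Fg
column_relax <- function(cloud, cfg) {
  ord <- order(cloud$x[, 3])
  cloud <- subset_cloud(cloud, ord)
  l <- cloud$V0 / cfg$column_area * cloud$Fg[, 9]
  z <- cumsum(l) - l / 2
  cloud$x[, 1] <- 0; cloud$x[, 2] <- 0; cloud$x[, 3] <- z
  cloud$F <- cloud$Fg
  cloud$V <- cloud$V0 * det_rows(cloud$Fg)
  cloud
}

# per-point production rates for the current state
point_production <- function(cloud, cfg, ihh_tot, t_SOC) {
  n <- n_points(cloud)
  P_ihh <- numeric(n)
  src <- cloud$type %in% c(.ct[["prehypertrophic"]], .ct[["hypertrophic"]])
  if (any(src)) P_ihh[src] <- ihh_production(cloud$t_H[src], cfg)
  P_pthrp <- numeric(n)
  peri <- cloud$type == .ct[["periarticular_pthrp"]]
  if (any(peri)) P_pthrp[peri] <- pthrp_production_periarticular(ihh_tot, cfg)
  rest <- cloud$type == .ct[["resting_pthrp"]]
  if (any(rest) && !is.na(t_SOC))
    P_pthrp[rest] <- pthrp_production_resting(ihh_tot, t_SOC, cfg)
  list(ihh = P_ihh, pthrp = P_pthrp)
}

#' Growth-plate zone metrics
#'
#' Axial extents of the proliferative, prehypertrophic and hypertrophic
#' zones. In 1-D mode extents are exact sums of point segment lengths; in
#' 3-D they are z-spans of each type's point set. The combined length is the
#' sum of the three constituent spans. The subarticular thickness is the
#' minimum distance from periarticular producers to the nearest cell that
#' has differentiated beyond proliferation (prehypertrophic onward) --
#' proliferative cells are still undifferentiated cartilage.
#'
#' @param cloud an `mp_cloud`.
#' @param cfg an `oss_config`.
#' @return one-row data.frame of extents in um.
#' @export
zone_metrics <- function(cloud, cfg) {
  zt <- function(code) {
    sel <- cloud$type == code
    if (!any(sel)) return(0)
    if (cfg$mode == "1d")
      sum(cloud$V0[sel] / cfg$column_area * cloud$Fg[sel, 9])
    else diff(range(cloud$x[sel, 3])) + cfg$spacing
  }
  prolif <- zt(.ct[["proliferative"]])
  prehyp <- zt(.ct[["prehypertrophic"]])
  hyp <- zt(.ct[["hypertrophic"]])
  peri <- cloud$type == .ct[["periarticular_pthrp"]]
  diffd <- cloud$type %in% c(.ct[["prehypertrophic"]], .ct[["hypertrophic"]],
                             .ct[["apoptotic"]], .ct[["matrix"]])
  sub <- if (any(peri) && any(diffd)) {
    A <- cloud$x[peri, , drop = FALSE]; B <- cloud$x[diffd, , drop = FALSE]
    min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  } else NA_real_
  data.frame(prolif = prolif, prehyp = prehyp, hyp = hyp,
             combined = prolif + prehyp + hyp, subarticular = sub)
}

#' Run an ossification simulation
#'
#' Integrates the coupled model from Day 0 (primary ossification center
#' initiation) for `cfg$days` days with increments of `cfg$dt_days`. Each
#' increment performs, in order: the quasi-static mechanics solve, the point
#' advection/update, the reaction-diffusion substeps, threshold-driven fate
#' updates, and the cell-cycle/division step. Secondary ossification is
#' initiated when the clock reaches `cfg$soc_day`, at which moment the
#' resting zone is tagged (unless `resting_enabled` is `FALSE`). The run is
#' deterministic for a fixed `cfg$seed`.
#'
#' @param cfg an `oss_config` (see [sim_config()], [preset_1d()],
#'   [preset_coarse()], [preset_full()]).
#' @param progress print a line every simulated half day.
#' @return list of class `oss_sim`: final `cloud`, `field`, per-increment
#'   `census` data.frame (type counts, total Ihh, resting-zone production,
#'   zone metrics, fusion/penetration flags), `divisions` log, `outcome`
#'   (fusion/penetration days), `t_SOC`, `config`.
#' @export
run_simulation <- function(cfg, progress = FALSE) {
  set.seed(cfg$seed)
  dt <- cfg$dt_days

  if (cfg$mode == "1d") {
    sp <- cfg$spacing
    z <- seq(sp / 2, cfg$column_length, by = sp)
    cloud <- mp_cloud(cbind(0, 0, z), V = cfg$Vp0)
    extent <- c(0, 0, cfg$column_length * cfg$chem_headroom)
  } else {
    spec <- capsule_spec(cyl_radius = cfg$cyl_radius, cyl_height = cfg$cyl_height,
                         dome_height = cfg$dome_height, dome_rxy = cfg$dome_rxy,
                         dome_rz = cfg$dome_rz, spacing = cfg$spacing,
                         Vp0 = cfg$Vp0)
    cap <- build_capsule(spec)
    cloud <- assign_initial_types(cap$points, spec,
                                  soc_seed_radius = cfg$soc_seed_radius)
    zmax <- spec$dome_center_z + spec$dome_rz
    extent <- c(cfg$dome_rxy * 2.7, cfg$dome_rxy * 2.7,
                zmax * cfg$chem_headroom)
  }
  cloud$E[] <- cfg$E_cell
  cloud$nu[] <- cfg$nu_cell
  field <- chemical_field(extent, cfg$chem_h, cfg)

  cloud <- initiate_poc(cloud, cfg$poc_slab)
  mgrid <- mcon <- mpar <- NULL
  if (cfg$mode != "1d") {
    mgrid <- mech_grid(cloud$x, cfg$grid_h, margin = 3L)
    mcon <- grid_constraints(mgrid)
  }
  t_SOC <- NA_real_
  ihh_tot <- 0
  nsteps <- max(0L, round(cfg$days / dt))
  census <- vector("list", nsteps)
  divlog <- list()
  fusion_day <- NA_real_; penetration_day <- NA_real_

  for (step in seq_len(nsteps)) {
    day <- step * dt

    ## mechanics
    if (cfg$mode == "1d") {
      cloud <- column_relax(cloud, cfg)
    } else {
      # extend the background grid when particles near its edge
      lim_lo <- mgrid$origin + 1.6 * mgrid$h
      lim_hi <- mgrid$origin + (mgrid$dims - 2.6) * mgrid$h
      if (any(apply(cloud$x, 2, min) < lim_lo[1:3] & !mgrid$sym) ||
          any(apply(cloud$x, 2, max) > lim_hi)) {
        mgrid <- mech_grid(cloud$x, cfg$grid_h, margin = 4L)
        mcon <- grid_constraints(mgrid)
        mpar <- NULL
      }
      sol <- solve_equilibrium(cloud, mgrid, maxit = cfg$solver_maxit,
                               pgtol = cfg$solver_pgtol,
                               factr = cfg$solver_factr,
                               con = mcon, par0 = mpar)
      upd <- try(update_points(cloud, mgrid, sol$u), silent = TRUE)
      if (inherits(upd, "try-error")) {
        # an increment that would invert F locally is applied damped; the
        # remaining imbalance relaxes over the following quasi-static steps
        for (damp in c(0.5, 0.25, 0.125, 0.0625)) {
          upd <- try(update_points(cloud, mgrid, damp * sol$u), silent = TRUE)
          if (!inherits(upd, "try-error")) break
        }
        if (inherits(upd, "try-error"))
          stop("inverted element persists after damped update")
      }
      mpar <- sol$par
      cloud <- upd
    }

    ## chemistry
    prod <- point_production(cloud, cfg, ihh_tot, t_SOC)
    pvol <- if (cfg$mode == "1d") cloud$V0 * cloud$Fg[, 9] else cloud$V
    ex <- exchange_with_points(cloud, field, prod$ihh, prod$pthrp, pvol)
    field <- step_reaction_diffusion(field, ex$src_ihh, ex$src_pthrp, dt,
                                     substeps = cfg$chem_substeps,
                                     scheme = cfg$chem_scheme)
    occupied <- chem_scatter(field, cloud$x, cloud$V) > 1e-9
    ihh_tot <- total_ihh(field, occupied, cfg$ihh_multiplicity,
                         cfg$ihh_unit_volume)
    C_ihh <- chem_interp(field, cloud$x, field$C_ihh)
    C_pthrp <- chem_interp(field, cloud$x, field$C_pthrp)
    grad <- chem_grad(field, cloud$x, field$C_ihh)

    ## events: secondary ossification
    if (is.na(t_SOC) && day >= cfg$soc_day && cfg$soc_day <= cfg$days &&
        any(cloud$soc_seed)) {
      soc <- initiate_soc(cloud)
      cloud <- soc$cloud
      t_SOC <- 0
      if (cfg$resting_enabled) cloud <- define_resting_zone(cloud)
    }

    ## fate, then cycle/division
    cloud <- update_fate(cloud, C_ihh, C_pthrp, dt, cfg, grad)
    adv <- advance_cycle(cloud, dt, cfg, grad)
    cloud <- adv$cloud
    if (!is.null(adv$divisions)) {
      adv$divisions$day <- day
      divlog[[length(divlog) + 1L]] <- adv$divisions
    }
    if (cfg$mode == "1d") cloud <- column_relax(cloud, cfg)
    if (!is.na(t_SOC)) t_SOC <- t_SOC + dt

    ## bookkeeping
    if (step %% cfg$census_every == 0L || step == nsteps) {
      zm <- zone_metrics(cloud, cfg)
      fus <- if (cfg$mode == "3d") detect_fusion(cloud, cfg) else FALSE
      pen <- detect_penetration(cloud, cfg, quiet = TRUE)
      if (fus && is.na(fusion_day)) fusion_day <- day
      if (pen && is.na(penetration_day)) penetration_day <- day
      cnt <- tabulate(cloud$type, nbins = 10L)
      rest <- cloud$type == .ct[["resting_pthrp"]]
      restP <- if (any(rest) && !is.na(t_SOC))
        mean(pthrp_production_resting(ihh_tot, t_SOC, cfg)) else 0
      census[[step]] <- data.frame(
        day = day, n = n_points(cloud), t(setNames(cnt, names(.ct))),
        ihh_total = ihh_tot, resting_P = restP, zm,
        fused = fus, penetrated = pen)
    }
    if (progress && step %% round(0.5 / dt) == 0)
      message(sprintf("day %.2f: %d points, Ihh_total %.3g", day,
                      n_points(cloud), ihh_tot))
  }

  census <- do.call(rbind, census[!vapply(census, is.null, logical(1))])
  out <- list(cloud = cloud, field = field, census = census,
              divisions = if (length(divlog)) do.call(rbind, divlog) else NULL,
              outcome = list(fused = !is.na(fusion_day),
                             fusion_day = fusion_day,
                             penetrated = !is.na(penetration_day),
                             penetration_day = penetration_day),
              t_SOC = t_SOC, config = cfg)
  class(out) <- "oss_sim"
  if (!is.null(cfg$out_dir)) write_outputs(out, cfg$out_dir)
  out
}

#' @export
print.oss_sim <- function(x, ...) {
  cat("<oss_sim>", x$config$mode, "run to day",
      if (is.null(x$census)) 0 else max(x$census$day), "--",
      n_points(x$cloud), "points; fused:", x$outcome$fused,
      "penetrated:", x$outcome$penetrated, "\n")
  invisible(x)
}

#' One-dimensional growth-plate calibration run
#'
#' Simulates a single column of cells with a primary center at its base and
#' reports the steady combined proliferative + hypertrophic length as the
#' time average after the transient (`cfg$transient_days`).
#'
#' @param cfg an `oss_config`, typically [preset_1d()].
#' @return list of class `oss_zones`: `combined_steady` (um), per-zone
#'   steady means, the per-increment `metrics`, and the full `sim`.
#' @export
run_1d_growth_plate <- function(cfg = preset_1d()) {
  if (cfg$mode != "1d") stop("run_1d_growth_plate expects a 1-D config")
  sim <- run_simulation(cfg)
  m <- sim$census
  win <- m$day > cfg$transient_days
  if (!any(win)) {
    warning("no post-transient window; reporting the final value")
    win <- seq_len(nrow(m)) == nrow(m)
  }
  structure(list(
    combined_steady = mean(m$combined[win]),
    prolif_steady = mean(m$prolif[win]),
    prehyp_steady = mean(m$prehyp[win]),
    hyp_steady = mean(m$hyp[win]),
    metrics = m[, c("day", "prolif", "prehyp", "hyp", "combined")],
    sim = sim), class = "oss_zones")
}

#' @export
print.oss_zones <- function(x, ...) {
  cat(sprintf(
    "<oss_zones> steady combined proliferative+hypertrophic length: %.0f um\n",
    x$combined_steady))
  cat(sprintf("  (proliferative %.0f, prehypertrophic %.0f, hypertrophic %.0f)\n",
              x$prolif_steady, x$prehyp_steady, x$hyp_steady))
  invisible(x)
}
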