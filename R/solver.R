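# 1D steady-flow pressure solver. Pressure is marched from the inlet along
# the discretised centreline: healthy points follow the reduced Navier-Stokes
# (Poiseuille + optional momentum-correction advection) gradient with axial
# flow depleted by the leakage model; stenosed intervals apply an empirically
# lumped pressure-drop sub-model and carry no leak. Pressure-coupled leakage
# models (conductance, porosity) wrap the march in a fixed-point iteration.

#' Boundary conditions for a vFFR simulation
#'
#' @param pa_mmhg aortic pressure (mmHg).
#' @param mvr_wu microvascular resistance (Wood units, mmHg.min/L).
#' @param q_bounds admissible inlet-flow interval (mL/min); the inlet-flow
#'   optimiser clamps (and flags) at these bounds.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(pa_mmhg, mvr_wu, q_bounds = c(50, 450)) {
  if (pa_mmhg <= 0) stop_domain("aortic pressure must be positive")
  if (mvr_wu <= 0) stop_domain("microvascular resistance must be positive")
  if (q_bounds[1] >= q_bounds[2]) stop_domain("invalid flow bounds")
  structure(list(pa_mmhg = pa_mmhg, mvr_wu = mvr_wu, q_bounds = q_bounds),
            class = "boundary_conditions")
}

#' Lumped stenosis sub-model configuration
#'
#' In stenosed sections the healthy 1D model assumptions break down; the
#' pressure drop is instead the sum of a viscous term (Poiseuille
#' integrated over the interval's actual radii) and an expansion-loss term
#' `kt * (rho/2) * (A_healthy/A_min - 1)^2 * (Q/A_healthy)^2`, the
#' classical empirically derived lumped form for focal stenoses.
#'
#' @param kt dimensionless expansion-loss coefficient (default 1.52).
#' @return An object of class `stenosis_model_config`.
#' @export
stenosis_model_config <- function(kt = 1.52) {
  if (kt < 0) stop_domain("kt must be >= 0")
  structure(list(kt = kt), class = "stenosis_model_config")
}

#' Solver configuration
#'
#' @param ptol relative pressure-change tolerance for fixed-point
#'   iteration of pressure-coupled leakage models.
#' @param max_iterations iteration cap for those fixed points.
#' @param advection include the momentum-correction advection term
#'   (`alpha * rho * d(u^2)`) in the healthy-segment gradient.
#' @param alpha momentum-correction coefficient (4/3 for a parabolic
#'   velocity profile).
#' @param flow_tol relative tolerance on the MVR residual in
#'   [optimise_inlet_flow].
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(ptol = 1e-6, max_iterations = 100,
                          advection = TRUE, alpha = 4 / 3,
                          flow_tol = 1e-6) {
  structure(list(ptol = ptol, max_iterations = max_iterations,
                 advection = advection, alpha = alpha, flow_tol = flow_tol),
            class = "solver_config")
}

#' Healthy-segment pressure gradient
#'
#' The negative axial pressure gradient of the reduced 1D steady-flow
#' model at one point: the Poiseuille term `8 mu q / (pi r^4)`. When
#' `advection` is on, the marcher additionally applies the
#' momentum-correction term between nodes as
#' `(alpha / 2) * rho * q^2 * d(1/A^2)` with the axial flow frozen at the
#' segment mean: flow leaving through the porous wall carries its axial
#' momentum with it, so only calibre-driven velocity changes convert to
#' pressure. This function returns the viscous part; the advection
#' differences live in the marcher so the discretisation stays
#' consistent.
#'
#' @param r lumen radius (m).
#' @param q axial flow (m^3/s).
#' @param fluid a [fluid_properties].
#' @return `-dP/ds` in Pa/m (viscous part).
#' @export
healthy_pressure_gradient <- function(r, q, fluid = fluid_properties()) {
  8 * fluid$mu * q / (pi * r^4)
}

#' Lumped stenosis pressure drop
#'
#' @param r radii across the stenosed interval (m).
#' @param s arc-length positions matching `r` (m).
#' @param r_healthy healthy reference radii for the interval (m).
#' @param q axial flow through the stenosis (m^3/s).
#' @param fluid a [fluid_properties].
#' @param cfg a [stenosis_model_config].
#' @return Pressure drop (Pa), `>= 0`.
#' @export
stenosis_pressure_drop <- function(r, s, r_healthy, q, fluid = fluid_properties(),
                                   cfg = stenosis_model_config()) {
  if (q < 0) stop_domain("flow must be non-negative")
  if (any(r <= 0)) stop_domain("stenosis radii must be positive")
  visc <- trapz(s, 8 * fluid$mu * q / (pi * r^4))
  a <- pi * r^2
  imin <- which.min(a)
  a_min <- a[imin]
  a_h <- pi * r_healthy[imin]^2
  exp_loss <- cfg$kt * (fluid$rho / 2) * (a_h / a_min - 1)^2 * (q / a_h)^2
  visc + exp_loss
}

# One pressure march along the profile for a fixed per-point leak density
# q_leak (m^3/s per m). Returns list(p, qflow, ok, reason).
march_once <- function(profile, seg, q_leak, q_in, fluid, pa,
                       sten_cfg, solver_cfg) {
  s <- profile$s
  r <- profile$r
  n <- profile$n_points
  # axial flow: inlet flow minus cumulative leak (trapezoidal)
  leak_cum <- c(0, cumsum((q_leak[-1] + q_leak[-n]) * diff(s) / 2))
  qf <- q_in - leak_cum
  if (any(qf <= 0)) {
    return(list(p = rep(NA_real_, n), qflow = qf, ok = FALSE,
                reason = "non-positive axial flow"))
  }
  grad <- healthy_pressure_gradient(r, qf, fluid)
  dp <- (grad[-1] + grad[-n]) * diff(s) / 2      # trapezoidal viscous drop
  healthy <- !seg$stenosed_mask
  if (solver_cfg$advection) {
    # momentum-correction advection: fluid leaving through side branches
    # carries its axial momentum away, so only the calibre-driven part of
    # the velocity change converts to pressure; the axial flow is frozen
    # at the segment mean so leak-induced deceleration is not credited
    # as recovery
    a2 <- (pi * r^2)^2
    q_seg <- (qf[-1] + qf[-n]) / 2
    pair_ok <- healthy[-n] & healthy[-1]         # kinetic terms inside
    dp <- dp + ifelse(pair_ok,                    # stenoses are lumped
                      (solver_cfg$alpha / 2) * fluid$rho * q_seg^2 *
                        (1 / a2[-1] - 1 / a2[-n]), 0)
  }
  # lumped expansion losses at stenosis exits
  iv <- seg$stenosis_intervals
  if (nrow(iv) > 0) {
    for (k in seq_len(nrow(iv))) {
      a <- iv[k, 1]; b <- iv[k, 2]                # [a, b) stenosed
      idx <- a:(b - 1)
      drop_tot <- stenosis_pressure_drop(r[idx], s[idx], seg$r_healthy[idx],
                                         qf[a], fluid, sten_cfg)
      visc_part <- if (length(idx) > 1) {
        trapz(s[idx], 8 * fluid$mu * qf[a] / (pi * r[idx]^4))
      } else 0
      at <- min(b - 1, n - 1)                     # transition out of the throat
      dp[at] <- dp[at] + max(drop_tot - visc_part, 0)
    }
  }
  p <- pa - c(0, cumsum(dp))
  list(p = p, qflow = qf, ok = all(p > 0),
       reason = if (all(p > 0)) NA_character_ else "negative pressure")
}

new_result <- function(profile, model, p, qflow, q_in, status, reason = NA,
                       iterations = 1L, flags = character(), leak = NULL) {
  vffr <- if (status == "converged") p[length(p)] / p[1] else NA_real_
  structure(
    list(case_id = profile$case_id, model_id = model, s = profile$s,
         p = p, qflow = qflow, q_in = q_in, vffr = vffr, status = status,
         reason = reason, iterations = iterations, flags = flags,
         leak = leak),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  if (x$status == "converged") {
    cat(sprintf("<simulation_result> %s [%s]: vFFR %.3f, q_in %.1f mL/min (%d iter)%s\n",
                x$case_id, x$model_id, x$vffr, m3s_to_mlmin(x$q_in),
                x$iterations,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  } else {
    cat(sprintf("<simulation_result> %s [%s]: FAILED (%s)\n",
                x$case_id, x$model_id, x$reason))
  }
  invisible(x)
}

# fixed-point iteration for pressure-coupled leakage: q = flux_fn(p_prev)
coupled_march <- function(profile, seg, flux_fn, p0, q_in, fluid, pa,
                          sten_cfg, solver_cfg, model) {
  p_prev <- p0
  res <- NULL
  for (it in seq_len(solver_cfg$max_iterations)) {
    q_leak <- flux_fn(p_prev)
    res <- march_once(profile, seg, q_leak, q_in, fluid, pa,
                      sten_cfg, solver_cfg)
    if (!res$ok) {
      return(new_result(profile, model, res$p, res$qflow, q_in,
                        "failed", res$reason, iterations = it,
                        leak = new_leakage_profile(q_leak, profile$s, model)))
    }
    delta <- max(abs(res$p - p_prev)) / pa
    p_prev <- res$p
    if (delta < solver_cfg$ptol) {
      return(new_result(profile, model, res$p, res$qflow, q_in,
                        "converged", iterations = it,
                        leak = new_leakage_profile(q_leak, profile$s, model)))
    }
  }
  new_result(profile, model, res$p, res$qflow, q_in, "failed",
             "fixed point did not converge",
             iterations = solver_cfg$max_iterations)
}

# calibrate the porosity Darcy conductance on the stenosis-free geometry so
# the unstenosed vessel reproduces the Huo-Kassab budget; returns k(s)
calibrate_porosity <- function(profile, seg, q_in, fluid, pa,
                               sten_cfg, solver_cfg, poro_cfg) {
  total <- leak_budget(seg, q_in)
  healthy_prof <- profile
  healthy_prof$r <- seg$r_healthy
  seg_h <- seg
  seg_h$stenosed_mask <- rep(FALSE, profile$n_points)
  seg_h$stenosis_intervals <- seg$stenosis_intervals[0, , drop = FALSE]
  w <- localized_weight(healthy_prof, seg_h)
  wi <- trapz(profile$s, w)
  if (total <= 0 || wi <= 0) {
    return(list(k = numeric(profile$n_points), w = w))
  }
  beta <- poro_cfg$forchheimer_coefficient
  cc <- total / (pa * wi)
  for (it in seq_len(poro_cfg$calibration_iterations)) {
    run <- coupled_march(healthy_prof, seg_h,
                         function(p) porosity_flux(p, cc * w, beta),
                         rep(pa, profile$n_points), q_in, fluid, pa,
                         sten_cfg, solver_cfg, "porosity")
    if (run$status != "converged") break
    got <- run$leak$total_leak
    if (abs(got / total - 1) < poro_cfg$calibration_tolerance) break
    cc <- cc * total / got
  }
  list(k = cc * w, w = w)
}

#' March pressure along a vessel for one leakage model
#'
#' Runs the 1D solver at a fixed inlet flow: pressure starts at the aortic
#' value and is lost point-to-point to viscous friction (and optionally
#' advection) in healthy sections and to the lumped stenosis sub-model in
#' stenosed intervals, while axial flow is depleted by the selected
#' leakage model. Conductance and porosity leakage couple to the pressure
#' field and are iterated to a fixed point. A pressure crossing zero marks
#' the run failed with reason `"negative pressure"` — it never throws, so
#' batch runs can account failures per model.
#'
#' @param profile a [centreline_profile] (resampled; typically 200 points).
#' @param seg a `healthy_segmentation` from [segment_vessel].
#' @param model one of `"none"`, `"homogenous"`, `"localized"`,
#'   `"conductance"`, `"porosity"`.
#' @param q_in inlet flow (m^3/s).
#' @param pa aortic pressure (Pa).
#' @param fluid a [fluid_properties].
#' @param sten_cfg a [stenosis_model_config].
#' @param solver_cfg a [solver_config].
#' @param poro_cfg a [porosity_config].
#' @return A `simulation_result`.
#' @export
march_pressure <- function(profile, seg, model, q_in, pa,
                           fluid = fluid_properties(),
                           sten_cfg = stenosis_model_config(),
                           solver_cfg = solver_config(),
                           poro_cfg = porosity_config()) {
  model <- match.arg(model, c("none", "homogenous", "localized",
                              "conductance", "porosity"))
  if (model %in% c("none", "homogenous", "localized")) {
    lp <- switch(model,
      none = leak_none(profile),
      homogenous = leak_homogenous(profile, seg, q_in),
      localized = leak_localized(profile, seg, q_in)
    )
    res <- march_once(profile, seg, lp$q, q_in, fluid, pa,
                      sten_cfg, solver_cfg)
    return(new_result(profile, model, res$p, res$qflow, q_in,
                      if (res$ok) "converged" else "failed",
                      res$reason, flags = lp$flags, leak = lp))
  }
  if (model == "conductance") {
    # Wall conductances g = q_localized / p_reference, with the reference
    # pressure taken from a localized-leakage simulation of the
    # stenosis-free (healthy-lumen) geometry. Regions of equal taper then
    # share equal conductance, and the actual pressure field — initialized
    # from a localized simulation of the real vessel — damps leakage
    # distal to stenosis-induced pressure loss via q = g * P.
    init <- march_pressure(profile, seg, "localized", q_in, pa, fluid,
                           sten_cfg, solver_cfg, poro_cfg)
    if (init$status != "converged") {
      init$model_id <- "conductance"
      return(init)
    }
    healthy_prof <- profile
    healthy_prof$r <- seg$r_healthy
    seg_h <- seg
    seg_h$stenosed_mask <- rep(FALSE, profile$n_points)
    seg_h$stenosis_intervals <- seg$stenosis_intervals[0, , drop = FALSE]
    ref <- march_pressure(healthy_prof, seg_h, "localized", q_in, pa, fluid,
                          sten_cfg, solver_cfg, poro_cfg)
    if (ref$status != "converged") {
      ref$model_id <- "conductance"
      return(ref)
    }
    g <- init$leak$q / ref$p
    return(coupled_march(profile, seg, function(p) pmax(g * p, 0),
                         init$p, q_in, fluid, pa, sten_cfg, solver_cfg,
                         "conductance"))
  }
  # porosity: Darcy-Forchheimer wall flux, calibrated on the stenosis-free
  # geometry, then coupled to the stenosed vessel's pressure field
  cal <- calibrate_porosity(profile, seg, q_in, fluid, pa,
                            sten_cfg, solver_cfg, poro_cfg)
  k <- cal$k
  k[seg$stenosed_mask] <- 0                     # no leak in stenosed sections
  beta <- poro_cfg$forchheimer_coefficient
  coupled_march(profile, seg,
                function(p) porosity_flux(p, k, beta),
                rep(pa, profile$n_points), q_in, fluid, pa,
                sten_cfg, solver_cfg, "porosity")
}

#' Optimise inlet flow against microvascular resistance
#'
#' Finds the inlet flow whose simulated distal pressure satisfies
#' `Pd / Q_in = MVR`, by bisection of the monotone residual over the
#' admissible flow interval (default 50-450 mL/min). MVR is referenced to
#' inlet flow because the invasive assessment (continuous-thermodilution)
#' measures total vessel flow, and the whole territory the vessel feeds —
#' side branches included — drains that flow. If the root lies outside
#' the bounds the flow is clamped to the nearer bound and the result
#' flagged `"flow clamped"`.
#'
#' @param profile a [centreline_profile].
#' @param seg a `healthy_segmentation`.
#' @param model leakage model id (see [march_pressure]).
#' @param bc a [boundary_conditions].
#' @param fluid a [fluid_properties].
#' @param sten_cfg,solver_cfg,poro_cfg sub-model configurations.
#' @return A `simulation_result` at the optimised flow.
#' @export
optimise_inlet_flow <- function(profile, seg, model, bc,
                                fluid = fluid_properties(),
                                sten_cfg = stenosis_model_config(),
                                solver_cfg = solver_config(),
                                poro_cfg = porosity_config()) {
  pa <- mmhg_to_pa(bc$pa_mmhg)
  mvr <- wu_to_si(bc$mvr_wu)
  run <- function(q) march_pressure(profile, seg, model, q, pa, fluid,
                                    sten_cfg, solver_cfg, poro_cfg)
  resid <- function(res) {
    if (res$status != "converged") return(NA_real_)
    n <- length(res$p)
    # MVR is referenced to the vessel's measured (inlet) flow: the whole
    # myocardial territory fed by the vessel, side branches included,
    # drains the flow that enters it
    res$p[n] / res$qflow[1] - mvr
  }
  lo <- mlmin_to_m3s(bc$q_bounds[1])
  hi <- mlmin_to_m3s(bc$q_bounds[2])
  r_lo_res <- run(lo); f_lo <- resid(r_lo_res)
  if (is.na(f_lo)) {
    # the minimum admissible flow already fails to simulate
    r_lo_res$flags <- c(r_lo_res$flags, "flow optimisation failed")
    return(r_lo_res)
  }
  # residual decreases with flow: Pd falls and Q_out rises
  if (f_lo < 0) {
    r_lo_res$flags <- c(r_lo_res$flags, "flow clamped")
    return(r_lo_res)
  }
  r_hi_res <- run(hi); f_hi <- resid(r_hi_res)
  if (is.na(f_hi)) {
    # high flows drive the pressure negative; shrink to the largest
    # feasible flow (failure is monotone in flow) before root finding
    flo <- lo
    for (it in seq_len(40)) {
      mid <- (flo + hi) / 2
      r_mid <- run(mid)
      f_mid <- resid(r_mid)
      if (is.na(f_mid)) hi <- mid else {
        flo <- mid
        r_hi_res <- r_mid
        f_hi <- f_mid
        if (f_hi < 0) break       # root is bracketed inside [lo, flo]
      }
    }
    if (is.na(f_hi)) {
      r_lo_res$flags <- c(r_lo_res$flags, "flow optimisation failed")
      return(r_lo_res)
    }
    hi <- flo
    if (f_hi > 0) {
      # the MVR target is unreachable before simulation failure
      r_hi_res$flags <- c(r_hi_res$flags, "flow limited by simulation failure")
      return(r_hi_res)
    }
  } else if (f_hi > 0) {
    r_hi_res$flags <- c(r_hi_res$flags, "flow clamped")
    return(r_hi_res)
  }
  best <- r_hi_res
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    r_mid <- run(mid)
    f_mid <- resid(r_mid)
    if (is.na(f_mid)) {           # shrink away from an infeasible pocket
      hi <- mid
      next
    }
    best <- r_mid
    if (abs(f_mid) / mvr < solver_cfg$flow_tol) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  best
}

#' Extract the vFFR value from a simulation result
#'
#' vFFR is the simulated distal-to-aortic pressure ratio `p[last]/p[1]`.
#'
#' @param res a `simulation_result`.
#' @return The vFFR value in `(0, 1]`.
#' @export
compute_vffr <- function(res) {
  stopifnot(inherits(res, "simulation_result"))
  if (res$status != "converged") {
    stop(errorCondition(
      sprintf("vFFR unavailable: simulation failed (%s)", res$reason),
      class = c("vffr_unavailable", "vffr1d_error")))
  }
  res$p[length(res$p)] / res$p[1]
}

#' Simulate vFFR for one vessel
#'
#' High-level entry point: resamples the profile to the working grid,
#' estimates the healthy lumen, segments stenoses, and runs the selected
#' leakage model. Inlet flow is either optimised against microvascular
#' resistance (give `mvr_wu`) or fixed (give `q_in_mlmin`).
#'
#' @param profile a [centreline_profile].
#' @param pa_mmhg aortic pressure (mmHg).
#' @param mvr_wu microvascular resistance (Wood units); mutually exclusive
#'   with `q_in_mlmin`.
#' @param q_in_mlmin fixed inlet flow (mL/min).
#' @param model leakage model id.
#' @param fluid a [fluid_properties].
#' @param filtration a [filtration_config].
#' @param sten_cfg,solver_cfg,poro_cfg sub-model configurations.
#' @param n_points working grid size (default 200).
#' @param q_bounds admissible flow interval for the optimiser (mL/min).
#' @return A `simulation_result`.
#' @examples
#' v <- generate_vessel(vessel_spec(stenoses = data.frame(
#'   centre = 0.5, ds = 0.55, width_mm = 2)))
#' simulate_vessel(v, pa_mmhg = 90, mvr_wu = 361, model = "localized")
#' @export
simulate_vessel <- function(profile, pa_mmhg, mvr_wu = NULL,
                            q_in_mlmin = NULL,
                            model = c("none", "homogenous", "localized",
                                      "conductance", "porosity"),
                            fluid = fluid_properties(),
                            filtration = filtration_config(),
                            sten_cfg = stenosis_model_config(),
                            solver_cfg = solver_config(),
                            poro_cfg = porosity_config(),
                            n_points = 200, q_bounds = c(50, 450)) {
  model <- match.arg(model)
  if (is.null(mvr_wu) == is.null(q_in_mlmin)) {
    stop_domain("give exactly one of mvr_wu or q_in_mlmin")
  }
  if (profile$n_points != n_points) profile <- resample_profile(profile, n_points)
  seg <- segment_vessel(profile, filtration)
  if (!is.null(q_in_mlmin)) {
    march_pressure(profile, seg, model, mlmin_to_m3s(q_in_mlmin),
                   mmhg_to_pa(pa_mmhg), fluid, sten_cfg, solver_cfg, poro_cfg)
  } else {
    optimise_inlet_flow(profile, seg, model,
                        boundary_conditions(pa_mmhg, mvr_wu, q_bounds),
                        fluid, sten_cfg, solver_cfg, poro_cfg)
  }
}
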