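# Side-branch leakage models. Vessel taper implies flow lost to unresolved
# daughter branches; the Huo-Kassab morphometric scaling law converts the
# inlet/outlet calibre ratio into a total side-branch flow budget, and each
# model distributes that budget along the vessel as a wall outflow per unit
# length q(s) >= 0. No leak ever occurs inside stenosed sections.

#' Huo-Kassab inlet/outlet flow ratio
#'
#' Morphometric scaling law linking vessel taper to the flow carried by
#' intervening side branches: `Q_in / Q_out = (r_in / r_out)^(7/3)`.
#'
#' @param r_in,r_out inlet and outlet radii (any common unit).
#' @return The dimensionless flow ratio.
#' @examples
#' huo_kassab_flow_ratio(1.35, 0.95)   # ~2.27: leak ~ outlet flow
#' @export
huo_kassab_flow_ratio <- function(r_in, r_out) {
  if (any(r_in <= 0) || any(r_out <= 0)) stop_domain("radii must be positive")
  (r_in / r_out)^(7 / 3)
}

# trapezoidal quadrature on possibly non-uniform s
trapz <- function(s, y) {
  n <- length(s)
  sum((y[-1] + y[-n]) * diff(s)) / 2
}

# side-branch flow budget from the healthy (filtered) lumen endpoints;
# the filtered radius drives the budget so stenoses do not masquerade as taper
leak_budget <- function(seg, q_in) {
  n <- length(seg$r_healthy)
  ratio <- huo_kassab_flow_ratio(seg$r_healthy[1], seg$r_healthy[n])
  q_in * (1 - 1 / ratio)
}

new_leakage_profile <- function(q, s, model_id, flags = character()) {
  structure(
    list(q = q, total_leak = trapz(s, q), model_id = model_id, flags = flags),
    class = "leakage_profile"
  )
}

#' @export
print.leakage_profile <- function(x, ...) {
  cat(sprintf("<leakage_profile> %s: total leak %.3f mL/min%s\n",
              x$model_id, m3s_to_mlmin(x$total_leak),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' No-leak model
#'
#' The simplest representation: side-branch flow is ignored and axial flow
#' is conserved along the whole vessel.
#'
#' @param profile a [centreline_profile].
#' @return A `leakage_profile` with `q` identically zero.
#' @export
leak_none <- function(profile) {
  new_leakage_profile(numeric(profile$n_points), profile$s, "none")
}

#' Homogenous leakage model
#'
#' The total Huo-Kassab side-branch budget is distributed uniformly over
#' all healthy (unstenosed) points; stenosed points do not leak.
#'
#' @param profile a [centreline_profile].
#' @param seg a `healthy_segmentation` for the same profile.
#' @param q_in inlet flow (m^3/s).
#' @return A `leakage_profile`.
#' @export
leak_homogenous <- function(profile, seg, q_in) {
  healthy <- !seg$stenosed_mask
  if (!any(healthy)) {
    stop(errorCondition("entire vessel is stenosed; no healthy length to leak over",
                        class = c("leakage_error", "vffr1d_error")))
  }
  total <- leak_budget(seg, q_in)
  w <- as.numeric(healthy)
  q <- total * w / trapz(profile$s, w)
  new_leakage_profile(q, profile$s, "homogenous")
}

# taper weight: leakage localizes where the healthy lumen narrows; the
# gradient of r_healthy^(7/3) ties the local weight to the same scaling law
# that sets the budget. Non-decreasing (radius-recovery) regions and
# stenosed points carry zero weight.
localized_weight <- function(profile, seg) {
  x <- seg$r_healthy^(7 / 3)
  n <- length(x)
  # central differences, one-sided at the ends
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (profile$s[2] - profile$s[1])
  d[n] <- (x[n] - x[n - 1]) / (profile$s[n] - profile$s[n - 1])
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (profile$s[i + 1] - profile$s[i - 1])
  w <- pmax(0, -d)
  w[seg$stenosed_mask] <- 0
  w
}

#' Localized (taper-proportional) leakage model
#'
#' Side-branch flow is focused where the healthy lumen tapers: the
#' per-point weight is the negative gradient of `r_healthy^(7/3)`,
#' clipped at zero so regions with downstream radius recovery do not
#' leak, and zeroed inside stenoses. The weights are normalised to the
#' total Huo-Kassab budget. If the vessel has no tapering healthy region
#' at all while the budget is positive, the model falls back to the
#' homogenous distribution and flags the result.
#'
#' @inheritParams leak_homogenous
#' @return A `leakage_profile`.
#' @export
leak_localized <- function(profile, seg, q_in) {
  healthy <- !seg$stenosed_mask
  if (!any(healthy)) {
    stop(errorCondition("entire vessel is stenosed; no healthy length to leak over",
                        class = c("leakage_error", "vffr1d_error")))
  }
  total <- leak_budget(seg, q_in)
  if (total <= 0) {
    return(new_leakage_profile(numeric(profile$n_points), profile$s, "localized"))
  }
  w <- localized_weight(profile, seg)
  wi <- trapz(profile$s, w)
  if (wi <= 0) {
    out <- leak_homogenous(profile, seg, q_in)
    out$model_id <- "localized"
    out$flags <- c(out$flags, "homogenous fallback: no tapering healthy region")
    return(out)
  }
  new_leakage_profile(total * w / wi, profile$s, "localized")
}

#' Porosity configuration for the Darcy-Forchheimer leakage model
#'
#' The vessel wall is treated as a porous medium whose transmural
#' pressure-flux relation has a linear (Darcy) and quadratic
#' (Forchheimer) term. The per-point linear permeability is assigned from
#' the local healthy taper and scaled by a calibration constant chosen so
#' that the stenosis-free geometry reproduces the Huo-Kassab inlet/outlet
#' flow ratio; the quadratic coefficient defaults to zero and is exposed
#' for sensitivity work.
#'
#' @param forchheimer_coefficient quadratic (inertial) term coefficient
#'   (Pa per (m^3/s/m)^2), `>= 0`.
#' @param calibration_iterations fixed-point iterations for the budget
#'   calibration on the healthy geometry.
#' @param calibration_tolerance relative budget mismatch accepted.
#' @return An object of class `porosity_config`.
#' @export
porosity_config <- function(forchheimer_coefficient = 0,
                            calibration_iterations = 50,
                            calibration_tolerance = 1e-8) {
  if (forchheimer_coefficient < 0) stop_domain("coefficients must be >= 0")
  structure(list(forchheimer_coefficient = forchheimer_coefficient,
                 calibration_iterations = calibration_iterations,
                 calibration_tolerance = calibration_tolerance),
            class = "porosity_config")
}

# per-point wall flux from the Darcy-Forchheimer relation
#   P = a(s)^-1-scaled linear term + beta quadratic term, i.e.
#   P = q / k(s) + beta * q^2  (k = darcy conductance per unit length)
# solved for q >= 0; k = 0 gives q = 0.
porosity_flux <- function(p, k, beta) {
  q <- numeric(length(p))
  pos <- k > 0 & p > 0
  if (beta <= 0) {
    q[pos] <- k[pos] * p[pos]
  } else {
    a <- 1 / k[pos]
    q[pos] <- (-a + sqrt(a^2 + 4 * beta * p[pos])) / (2 * beta)
  }
  q
}
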