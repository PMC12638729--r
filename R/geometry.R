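#' Centreline radius profile of a single coronary vessel
#'
#' A `centreline_profile` holds the arc length `s` (m) and lumen radius `r`
#' (m) of one reconstructed vessel, stored inlet to outlet. Index 1 is the
#' aortic-pressure (Pa) measurement location and the last index the distal
#' (Pd) location, so the simulated distal/aortic pressure ratio is read off
#' the ends of this object. Profiles are created from clinical-unit inputs
#' (mm) and converted to SI on construction.
#'
#' @param s_mm numeric vector of arc-length positions (mm), strictly
#'   increasing, starting at 0.
#' @param r_mm numeric vector of lumen radii (mm), all positive, same
#'   length as `s_mm`.
#' @param case_id character label for the vessel.
#' @return An object of class `centreline_profile`: a list with elements
#'   `s` (m), `r` (m), `n_points` and `case_id`.
#' @examples
#' p <- centreline_profile(c(0, 15, 30), c(1.35, 1.2, 0.95))
#' p$n_points
#' @export
centreline_profile <- function(s_mm, r_mm, case_id = "vessel") {
  if (!is.numeric(s_mm) || !is.numeric(r_mm)) {
    stop_malformed("arc length and radius must be numeric")
  }
  if (length(s_mm) != length(r_mm)) {
    stop_malformed("arc length and radius must have equal length")
  }
  if (length(s_mm) < 2) {
    stop_malformed("a profile needs at least 2 points")
  }
  if (anyNA(s_mm) || anyNA(r_mm)) {
    stop_malformed("profile contains missing values")
  }
  if (any(diff(s_mm) <= 0)) {
    stop_malformed("arc length must be strictly increasing")
  }
  if (any(r_mm <= 0)) {
    stop_malformed("all radii must be positive")
  }
  structure(
    list(
      s = mm_to_m(s_mm - s_mm[1]),
      r = mm_to_m(r_mm),
      n_points = length(s_mm),
      case_id = as.character(case_id)
    ),
    class = "centreline_profile"
  )
}

#' @export
print.centreline_profile <- function(x, ...) {
  cat(sprintf(
    "<centreline_profile> %s: %d points, length %.1f mm, r %.2f -> %.2f mm\n",
    x$case_id, x$n_points, m_to_mm(x$s[x$n_points]),
    m_to_mm(x$r[1]), m_to_mm(x$r[x$n_points])
  ))
  invisible(x)
}

stop_malformed <- function(msg) {
  stop(errorCondition(msg, class = c("malformed_geometry", "vffr1d_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("format_error", "vffr1d_error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("domain_error", "vffr1d_error")))
}

#' Resample a centreline profile to uniformly spaced points
#'
#' Piecewise-linear interpolation of radius against arc length onto `n`
#' uniformly spaced points spanning the original vessel, endpoints
#' preserved. The solver operates on 200-point profiles; resampling an
#' already-uniform profile of the requested size is an identity up to
#' floating-point round-off.
#'
#' @param profile a [centreline_profile].
#' @param n number of points after resampling (default 200).
#' @return A [centreline_profile] with `n` uniformly spaced points.
#' @export
resample_profile <- function(profile, n = 200) {
  stopifnot(inherits(profile, "centreline_profile"))
  if (n < 2) stop_domain("resample size must be at least 2")
  s_new <- seq(profile$s[1], profile$s[profile$n_points], length.out = n)
  r_new <- stats::approx(profile$s, profile$r, xout = s_new)$y
  out <- profile
  out$s <- s_new
  out$r <- r_new
  out$n_points <- n
  out
}

#' Read a centreline geometry CSV
#'
#' The geometry dialect is a UTF-8 CSV with header columns `s_mm` and
#' `r_mm`, one row per centreline point, arc length strictly increasing
#' from 0. The profile is converted to SI and linearly resampled to
#' `resample_n` uniformly spaced points.
#'
#' @param path path to the CSV file.
#' @param resample_n points after resampling (default 200); `NA` keeps the
#'   file's own sampling.
#' @param case_id label; defaults to the file name without extension.
#' @return A [centreline_profile].
#' @export
read_profile <- function(path, resample_n = 200, case_id = NULL) {
  if (!file.exists(path)) stop_format(sprintf("geometry file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("s_mm", "r_mm") %in% names(df))) {
    stop_format("geometry CSV must have columns s_mm and r_mm")
  }
  if (is.null(case_id)) case_id <- sub("\\.[^.]*$", "", basename(path))
  p <- centreline_profile(df$s_mm, df$r_mm, case_id = case_id)
  if (!is.na(resample_n)) p <- resample_profile(p, resample_n) else p
}

#' Write a centreline geometry CSV
#'
#' Emits the same dialect [read_profile] consumes (`s_mm,r_mm` header,
#' decimal point, full precision) so that a read/write round trip
#' reproduces the profile to write precision.
#'
#' @param profile a [centreline_profile].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "centreline_profile"))
  df <- data.frame(
    s_mm = sprintf("%.17g", m_to_mm(profile$s)),
    r_mm = sprintf("%.17g", m_to_mm(profile$r))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Blood fluid properties
#'
#' Standard simulation parameters are a dynamic viscosity of 0.0035 Pa.s
#' and density 1050 kg/m^3. When a haematocrit fraction is supplied the
#' viscosity is personalised with [personalised_viscosity].
#'
#' @param mu dynamic viscosity (Pa.s).
#' @param rho density (kg/m^3).
#' @param hct optional haematocrit fraction in `[0, 1)`; when given, `mu`
#'   is replaced by the personalised value.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 0.0035, rho = 1050, hct = NULL) {
  if (!is.null(hct)) mu <- personalised_viscosity(hct)
  if (!is.numeric(mu) || mu <= 0) stop_domain("viscosity must be positive")
  if (!is.numeric(rho) || rho <= 0) stop_domain("density must be positive")
  structure(list(mu = mu, rho = rho, hct = hct), class = "fluid_properties")
}

#' Haematocrit-personalised blood viscosity
#'
#' Linear personalisation of dynamic viscosity to haematocrit,
#' `mu = 0.0014 + 0.0035 * hct` (Pa.s), where 0.0014 Pa.s is an assumed
#' plasma viscosity and the second term the erythrocyte contribution. At
#' hct = 0.60 this coincides with the standard viscosity of 0.0035 Pa.s.
#'
#' @param hct haematocrit fraction in `[0, 1)`.
#' @return Dynamic viscosity in Pa.s.
#' @examples
#' personalised_viscosity(0.42)
#' @export
personalised_viscosity <- function(hct) {
  if (!is.numeric(hct) || anyNA(hct) || any(hct < 0) || any(hct >= 1)) {
    stop_domain("haematocrit must lie in [0, 1)")
  }
  0.0014 + 0.0035 * hct
}
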