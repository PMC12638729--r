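# Healthy-lumen estimation by Fourier filtration and stenosis segmentation.
# The hypothetical disease-free lumen is a low-frequency envelope of the
# cross-sectional area signal; stenosed regions are the points whose
# reconstructed area falls strictly below 80% of that estimate.

#' Filtration configuration
#'
#' @param n_harmonics low-pass cutoff: number of mirror-even Fourier
#'   harmonics kept in the healthy-lumen fit (the single
#'   quality-of-filtration parameter). The default of 4 keeps the cutoff
#'   wavelength well above the extent of focal lesions on vessels a few
#'   centimetres long, so stenoses cannot be absorbed into the fit.
#' @param max_iterations cap on upper-envelope iterations.
#' @param tolerance relative-change convergence criterion for the envelope.
#' @param area_threshold stenosis threshold on the area ratio
#'   `A / A_healthy` (strictly below flags the point; default 0.80).
#' @param min_run shortest run of flagged points kept as a stenosis.
#' @return An object of class `filtration_config`.
#' @export
filtration_config <- function(n_harmonics = 4, max_iterations = 50,
                              tolerance = 1e-8, area_threshold = 0.80,
                              min_run = 2) {
  if (n_harmonics < 1) stop_domain("n_harmonics must be at least 1")
  if (area_threshold <= 0 || area_threshold >= 1) {
    stop_domain("area_threshold must lie in (0, 1)")
  }
  structure(list(n_harmonics = n_harmonics, max_iterations = max_iterations,
                 tolerance = tolerance, area_threshold = area_threshold,
                 min_run = min_run),
            class = "filtration_config")
}

# least-squares fit of the low-frequency basis {1, s, cos(j*pi*s/L)}:
# the mirror-even Fourier modes of the signal plus a linear trend so a
# tapered baseline is represented without Gibbs flattening at the ends.
# Zero-weight points do not pull on the fit.
lowfreq_fit <- function(s, a, n_harmonics, weights, tau = NULL) {
  L <- s[length(s)] - s[1]
  X <- cbind(1, s, vapply(seq_len(n_harmonics),
                          function(j) cos(j * pi * (s - s[1]) / L),
                          numeric(length(s))))
  if (is.null(tau)) {
    co <- stats::lm.wfit(X, a, weights)$coefficients
  } else {
    keep <- weights > 0
    co <- rq_irls(X[keep, , drop = FALSE], a[keep], tau)
  }
  co[is.na(co)] <- 0
  drop(X %*% co)
}

#' Estimate the hypothetical healthy lumen radius
#'
#' Fourier filtration of the cross-sectional area signal: the area
#' profile is fitted with its lowest `n_harmonics` mirror-even Fourier
#' modes (plus a linear trend representing baseline taper), and the fit
#' is iterated as a robust upper envelope — points whose observed area
#' falls clearly below the current fit are excluded before re-fitting —
#' until the excluded set and the fit stabilise. A plain low-pass would
#' dip into stenoses; the exclusion loop makes the fit interpolate the
#' healthy calibre across them.
#'
#' @param profile a [centreline_profile] (typically 200 points).
#' @param cfg a [filtration_config].
#' @return Numeric vector of healthy radii (m) with attributes
#'   `converged` (logical) and `iterations`. A non-converged envelope
#'   triggers a `filtration_warning` and returns the last iterate.
#' @export
estimate_healthy <- function(profile, cfg = filtration_config()) {
  stopifnot(inherits(profile, "centreline_profile"))
  a <- pi * profile$r^2
  s <- profile$s
  n <- profile$n_points
  min_keep <- 2 * cfg$n_harmonics + 4
  include <- rep(TRUE, n)
  # one-sided residual scale from points above the fit: lesions only ever
  # sit below the healthy envelope, so the upper residuals estimate the
  # healthy-vessel variability uncontaminated by disease
  sigma_up <- function(res, inc) {
    pos <- res[inc & res > 0]
    if (length(pos) == 0) 0 else stats::median(pos) / 0.6745
  }
  # warm start with an upper-quantile fit of the trend alone: a fit this
  # coarse cannot follow a lesion, and the asymmetric loss keeps it on
  # the healthy flanks however wide the lesion is, so lesion points are
  # excluded before the harmonics are allowed to bend the fit into them
  Xlin <- cbind(1, s)
  fit <- drop(Xlin %*% rq_irls(Xlin, a, 0.9))
  res0 <- a - fit
  include <- res0 >= -pmax(2 * sigma_up(res0, include), 0.005 * a)
  fit <- lowfreq_fit(s, a, cfg$n_harmonics, as.numeric(include), tau = 0.9)
  converged <- FALSE
  it <- 1L
  while (it < cfg$max_iterations) {
    res <- a - fit
    # a point is stenotic (excluded) when it sits far below the fit;
    # the 0.5%-of-area floor keeps numerical ripple from being excluded
    thresh <- pmax(2 * sigma_up(res, include), 0.005 * a)
    include_new <- res >= -thresh
    if (sum(include_new) < min_keep) {
      include_new <- rank(-res, ties.method = "first") <= min_keep
    }
    fit_new <- lowfreq_fit(s, a, cfg$n_harmonics, as.numeric(include_new),
                           tau = 0.9)
    delta <- max(abs(fit_new - fit)) / max(abs(fit))
    stable <- identical(include_new, include)
    include <- include_new
    fit <- fit_new
    it <- it + 1L
    if (stable && delta < cfg$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(warningCondition(
      "healthy-lumen envelope did not converge; returning last iterate",
      class = c("filtration_warning", "vffr1d_warning")))
  }
  fit <- pmax(fit, 1e-12)           # guard against non-physical area
  r_healthy <- sqrt(fit / pi)
  attr(r_healthy, "converged") <- converged
  attr(r_healthy, "iterations") <- it
  r_healthy
}

#' Segment a vessel into healthy and stenosed regions
#'
#' Computes the per-point area ratio `(r / r_healthy)^2` and flags points
#' where it falls strictly below the area threshold (default 0.80, i.e.
#' "area decreased below 80% of estimated healthy area"). Morphological
#' cleanup: single-point gaps inside a flagged run are bridged, then runs
#' shorter than `min_run` points are dropped.
#'
#' @param profile a [centreline_profile].
#' @param r_healthy healthy radius vector from [estimate_healthy].
#' @param cfg a [filtration_config].
#' @return An object of class `healthy_segmentation`: list with
#'   `r_healthy`, `area_ratio`, `stenosed_mask`, and `stenosis_intervals`
#'   (two-column matrix of half-open `[start, end)` index ranges).
#' @export
segment_stenoses <- function(profile, r_healthy, cfg = filtration_config()) {
  stopifnot(inherits(profile, "centreline_profile"),
            length(r_healthy) == profile$n_points)
  area_ratio <- (profile$r / r_healthy)^2
  mask <- area_ratio < cfg$area_threshold   # strict: exactly 80% is healthy
  mask <- bridge_gaps(mask)
  mask <- drop_short_runs(mask, cfg$min_run)
  structure(
    list(r_healthy = as.numeric(r_healthy), area_ratio = area_ratio,
         stenosed_mask = mask, stenosis_intervals = mask_to_intervals(mask)),
    class = "healthy_segmentation"
  )
}

#' @export
print.healthy_segmentation <- function(x, ...) {
  cat(sprintf("<healthy_segmentation> %d points, %d stenosed, %d interval(s)\n",
              length(x$stenosed_mask), sum(x$stenosed_mask),
              nrow(x$stenosis_intervals)))
  invisible(x)
}

# fill isolated single FALSE points flanked by TRUE on both sides
bridge_gaps <- function(mask) {
  n <- length(mask)
  if (n < 3) return(mask)
  i <- 2:(n - 1)
  gap <- !mask[i] & mask[i - 1] & mask[i + 1]
  mask[i][gap] <- TRUE
  mask
}

# remove contiguous TRUE runs shorter than min_run
drop_short_runs <- function(mask, min_run) {
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# half-open [start, end) intervals covering the TRUE entries of mask
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Convenience wrapper: filtration plus segmentation
#'
#' @inheritParams segment_stenoses
#' @inheritParams estimate_healthy
#' @return A `healthy_segmentation` (see [segment_stenoses]).
#' @export
segment_vessel <- function(profile, cfg = filtration_config()) {
  segment_stenoses(profile, estimate_healthy(profile, cfg), cfg)
}

#' Export a segmentation report as CSV
#'
#' @param profile a [centreline_profile].
#' @param seg a `healthy_segmentation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(profile, seg, path) {
  df <- data.frame(
    s_mm = m_to_mm(profile$s),
    r_mm = m_to_mm(profile$r),
    r_healthy_mm = m_to_mm(seg$r_healthy),
    area_ratio = seg$area_ratio,
    stenosed = as.integer(seg$stenosed_mask)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
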