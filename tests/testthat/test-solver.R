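test_that("healthy gradient follows the Poiseuille law", {
  fl <- fluid_properties()
  expect_equal(healthy_pressure_gradient(1.5e-3, 0, fl), 0)
  g1 <- healthy_pressure_gradient(1.5e-3, 2e-6, fl)
  expect_equal(g1, 8 * 0.0035 * 2e-6 / (pi * (1.5e-3)^4), tolerance = 1e-12)
  # halving the radius multiplies the gradient by 16
  expect_equal(healthy_pressure_gradient(0.75e-3, 2e-6, fl) / g1, 16,
               tolerance = 1e-12)
})

test_that("a uniform tube reproduces the closed-form Poiseuille drop", {
  # 1.5 mm radius, 10 mm long, 2 mL/s, advection off: drop ~35.2 Pa
  p <- tube_profile(r_mm = 1.5, length_mm = 10)
  res <- simulate_vessel(p, pa_mmhg = 90, q_in_mlmin = 120, model = "none",
                         solver_cfg = solver_config(advection = FALSE))
  drop_cf <- 8 * 0.0035 * 10e-3 * mlmin_to_m3s(120) / (pi * (1.5e-3)^4)
  expect_equal(mmhg_to_pa(90) - res$p[200], drop_cf, tolerance = 1e-9)
  expect_equal(res$vffr, 1 - drop_cf / mmhg_to_pa(90), tolerance = 1e-9)
  expect_equal(35.21, 8 * 0.0035 * 10e-3 * 2e-6 / (pi * (1.5e-3)^4),
               tolerance = 1e-3)
})

test_that("the lumped stenosis drop matches a direct quadrature oracle", {
  fl <- fluid_properties()
  cfg <- stenosis_model_config(kt = 1.52)
  s <- seq(0, 6e-3, length.out = 41)
  r_h <- rep(1.2e-3, 41)
  r <- r_h * (1 - 0.5 * exp(-(s - 3e-3)^2 / (2 * (1e-3)^2)))
  q <- 2e-6
  got <- stenosis_pressure_drop(r, s, r_h, q, fl, cfg)
  # oracle: independently summed trapezoid of the viscous integrand plus
  # the analytic expansion term at the throat
  y <- 8 * fl$mu * q / (pi * r^4)
  visc <- sum((y[-1] + y[-41]) * diff(s)) / 2
  a_min <- pi * min(r)^2
  a_h <- pi * 1.2e-3^2
  expt <- 1.52 * (fl$rho / 2) * (a_h / a_min - 1)^2 * (q / a_h)^2
  expect_equal(got, visc + expt, tolerance = 1e-9)
  # sanity against a mesh-refined quadrature of the same radius profile
  s_f <- seq(0, 6e-3, length.out = 4001)
  r_f <- approx(s, r, xout = s_f)$y
  y_f <- 8 * fl$mu * q / (pi * r_f^4)
  visc_f <- sum((y_f[-1] + y_f[-4001]) * diff(s_f)) / 2
  expect_equal(visc, visc_f, tolerance = 5e-3)
  # trivial limits
  expect_equal(stenosis_pressure_drop(r, s, r_h, 0, fl, cfg), 0)
  expect_equal(stenosis_pressure_drop(r_h, s, r_h, q, fl, cfg),
               8 * fl$mu * q * 6e-3 / (pi * (1.2e-3)^4), tolerance = 1e-9)
})

test_that("pressure is non-increasing and mass is conserved on converged runs", {
  p <- resample_profile(generate_vessel(stenosed_spec(0.5)), 2000)
  seg <- segment_vessel(p)
  for (m in c("none", "localized", "porosity")) {
    res <- march_pressure(p, seg, m, mlmin_to_m3s(150), mmhg_to_pa(90),
                          solver_cfg = solver_config(advection = FALSE))
    expect_equal(res$status, "converged")
    expect_true(all(diff(res$p) <= 1e-12))
    expect_true(all(res$p > 0))
    leaked <- vffr1d:::trapz(res$s, res$leak$q)
    expect_equal(res$qflow[2000] + leaked, res$qflow[1], tolerance = 1e-8)
  }
})

test_that("vFFR approaches one in the zero-flow limit", {
  p <- taper_profile()
  res <- simulate_vessel(p, pa_mmhg = 90, q_in_mlmin = 0.01, model = "none")
  expect_gt(res$vffr, 0.99999)
})

test_that("grid refinement converges with shrinking steps of order >= 1", {
  # fixed analytic segmentation isolates the marching scheme's own order
  vffr_at <- function(n) {
    p <- resample_profile(centreline_profile(c(0, 30), c(1.35, 0.95)), n)
    march_pressure(p, manual_segmentation(p), "localized",
                   mlmin_to_m3s(150), mmhg_to_pa(90))$vffr
  }
  v <- vapply(c(200, 400, 800, 1600), vffr_at, 0)
  steps <- abs(diff(v))
  expect_true(all(diff(steps) < 0))
  order_emp <- log2(steps[1] / steps[2])
  expect_gte(order_emp, 1)
  # end-to-end (envelope included): coarse and fine grids agree closely
  sp <- stenosed_spec(0.5, width_mm = 2)
  v200 <- simulate_vessel(generate_vessel(sp), pa_mmhg = 90,
                          q_in_mlmin = 150, model = "localized")$vffr
  v2000 <- simulate_vessel(generate_vessel(sp, n_points = 2000), pa_mmhg = 90,
                           q_in_mlmin = 150, model = "localized",
                           n_points = 2000)$vffr
  expect_lt(abs(v200 - v2000), 5e-3)
})

test_that("inlet-flow optimisation hits the MVR target", {
  # untapered healthy tube: demand is approximately Pa / MVR
  p <- tube_profile(r_mm = 1.5, length_mm = 30)
  res <- simulate_vessel(p, pa_mmhg = 90, mvr_wu = 361, model = "none")
  expect_equal(res$status, "converged")
  q_ml <- m3s_to_mlmin(res$q_in)
  expect_gt(q_ml, 50); expect_lt(q_ml, 450)
  expect_equal(q_ml, 90 / 361 * 1000, tolerance = 0.02)
  mvr_si <- wu_to_si(361)
  expect_lt(abs(res$p[200] / res$qflow[1] - mvr_si) / mvr_si, 1e-6)
  # brute-force scan oracle: residual changes sign at the returned flow
  resid <- function(q) {
    r <- simulate_vessel(p, pa_mmhg = 90, q_in_mlmin = q, model = "none")
    r$p[200] / r$qflow[1] - mvr_si
  }
  expect_gt(resid(q_ml - 5), 0)
  expect_lt(resid(q_ml + 5), 0)
})

test_that("flow clamps at the admissible bounds and responds to MVR", {
  p <- tube_profile()
  hi_mvr <- simulate_vessel(p, pa_mmhg = 90, mvr_wu = 5000, model = "none")
  expect_equal(m3s_to_mlmin(hi_mvr$q_in), 50)
  expect_true("flow clamped" %in% hi_mvr$flags)
  lo_mvr <- simulate_vessel(p, pa_mmhg = 90, mvr_wu = 100, model = "none")
  expect_equal(m3s_to_mlmin(lo_mvr$q_in), 450)
  expect_true("flow clamped" %in% lo_mvr$flags)
  # doubling MVR on a fixed vessel reduces the optimised flow
  q1 <- simulate_vessel(p, pa_mmhg = 90, mvr_wu = 300, model = "none")$q_in
  q2 <- simulate_vessel(p, pa_mmhg = 90, mvr_wu = 600, model = "none")$q_in
  expect_lt(q2, q1)
})

test_that("vFFR decreases strictly as a stenosis deepens", {
  vffr <- vapply(seq(0.3, 0.75, by = 0.15), function(ds) {
    simulate_vessel(generate_vessel(stenosed_spec(ds)), pa_mmhg = 90,
                    mvr_wu = 361, model = "none")$vffr
  }, 0)
  expect_true(all(diff(vffr) < 0))
})

test_that("failed runs carry status and refuse a vFFR value", {
  v <- generate_vessel(stenosed_spec(0.9, width_mm = 2))
  res <- simulate_vessel(v, pa_mmhg = 90, q_in_mlmin = 400, model = "none")
  expect_equal(res$status, "failed")
  expect_equal(res$reason, "negative pressure")
  expect_true(is.na(res$vffr))
  expect_error(compute_vffr(res), class = "vffr_unavailable")
})
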