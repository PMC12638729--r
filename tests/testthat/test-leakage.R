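test_that("Huo-Kassab scaling reproduces its analytic special cases", {
  expect_equal(huo_kassab_flow_ratio(1.2, 1.2), 1)
  expect_equal(huo_kassab_flow_ratio(2^(3 / 7), 1), 2)
  # the clinical mean calibres split flow roughly evenly between outlet
  # and side branches
  r <- huo_kassab_flow_ratio(1.35, 0.95)
  expect_equal(r, (1.35 / 0.95)^(7 / 3), tolerance = 1e-12)
  expect_gt(r, 2); expect_lt(r, 2.6)
  expect_error(huo_kassab_flow_ratio(-1, 1), class = "domain_error")
})

test_that("the no-leak model keeps axial flow constant", {
  p <- taper_profile()
  lp <- leak_none(p)
  expect_true(all(lp$q == 0))
  expect_equal(lp$total_leak, 0)
  res <- simulate_vessel(p, pa_mmhg = 90, q_in_mlmin = 120, model = "none")
  expect_equal(diff(range(res$qflow)), 0)
})

test_that("homogenous leakage renormalises over the healthy length", {
  q_in <- mlmin_to_m3s(150)
  # untapered: zero budget
  pt <- tube_profile()
  expect_true(all(leak_homogenous(pt, manual_segmentation(pt), q_in)$q == 0))
  # tapered, unstenosed: uniform density totalling the budget
  p <- taper_profile()
  seg <- segment_vessel(p)
  lp <- leak_homogenous(p, seg, q_in)
  total <- q_in * (1 - 1 / huo_kassab_flow_ratio(seg$r_healthy[1],
                                                 seg$r_healthy[200]))
  expect_equal(diff(range(lp$q)), 0, tolerance = 1e-20)
  expect_equal(lp$total_leak, total, tolerance = 1e-10)
  # stenosed middle third: density renormalised over the healthy two thirds
  p2 <- p
  seg2 <- seg
  seg2$stenosed_mask[67:133] <- TRUE
  seg2$stenosis_intervals <- cbind(start = 67L, end = 134L)
  lp2 <- leak_homogenous(p2, seg2, q_in)
  expect_true(all(lp2$q[67:133] == 0))
  L <- p$s[200]
  healthy_len <- L - (p$s[133] - p$s[67])
  # direct quadrature oracle
  expect_equal(max(lp2$q), total / healthy_len, tolerance = 0.02)
  expect_equal(lp2$total_leak, total, tolerance = 1e-8)
})

test_that("localized leakage concentrates at steps and spares recovery", {
  q_in <- mlmin_to_m3s(150)
  # untapered: zero everywhere
  pt <- tube_profile()
  expect_true(all(leak_localized(pt, manual_segmentation(pt), q_in)$q == 0))
  # single mid-vessel step (healthy radius known exactly): all leak mass
  # sits at the step's points
  ps <- resample_profile(centreline_profile(
    c(0, 14.9, 15.1, 30), c(1.35, 1.35, 0.95, 0.95)), 200)
  lps <- leak_localized(ps, manual_segmentation(ps), q_in)
  near <- abs(ps$s - 15e-3) < 1e-3
  frac_near <- sum(lps$q[near]) / sum(lps$q)
  expect_gt(frac_near, 0.99)
  # radius recovery region does not leak
  pr <- resample_profile(centreline_profile(
    c(0, 10, 20, 30), c(1.35, 1.0, 1.2, 0.95)), 200)
  lpr <- leak_localized(pr, manual_segmentation(pr), q_in)
  recovery <- pr$s > 10.2e-3 & pr$s < 19.8e-3   # radius increasing stretch
  expect_true(all(lpr$q[recovery] == 0))
})

test_that("every leakage model conserves the flow budget on a fine grid", {
  p <- resample_profile(generate_vessel(stenosed_spec(0.5)), 2000)
  seg <- segment_vessel(p)
  for (m in c("none", "homogenous", "localized", "conductance", "porosity")) {
    res <- march_pressure(p, seg, m, mlmin_to_m3s(150), mmhg_to_pa(90))
    expect_equal(res$status, "converged")
    leaked <- vffr1d:::trapz(res$s, res$leak$q)
    expect_equal(res$qflow[1] - res$qflow[length(res$qflow)], leaked,
                 tolerance = 1e-8)
    expect_true(all(res$leak$q >= 0))
    expect_true(all(res$leak$q[seg$stenosed_mask] == 0))
  }
})

test_that("without taper all five models collapse to the no-leak solution", {
  p <- tube_profile()
  seg <- segment_vessel(p)
  base <- march_pressure(p, seg, "none", mlmin_to_m3s(150), mmhg_to_pa(90))
  for (m in c("homogenous", "localized", "conductance", "porosity")) {
    res <- march_pressure(p, seg, m, mlmin_to_m3s(150), mmhg_to_pa(90))
    expect_lt(max(abs(res$p - base$p)) / mmhg_to_pa(90), 1e-6)
  }
})

test_that("pressure-coupled models reproduce the Huo-Kassab budget when unstenosed", {
  p <- taper_profile()
  seg <- segment_vessel(p)
  ratio <- huo_kassab_flow_ratio(seg$r_healthy[1], seg$r_healthy[200])
  for (m in c("homogenous", "localized", "conductance", "porosity")) {
    res <- march_pressure(p, seg, m, mlmin_to_m3s(150), mmhg_to_pa(90))
    expect_equal(res$qflow[1] / res$qflow[200], ratio, tolerance = 5e-3)
  }
})

test_that("conductance damps leak distal to a stenosis, never exceeding localized", {
  p <- resample_profile(generate_vessel(stenosed_spec(0.65, centre = 0.4)), 200)
  seg <- segment_vessel(p)
  q_in <- mlmin_to_m3s(150)
  rl <- march_pressure(p, seg, "localized", q_in, mmhg_to_pa(90))
  rc <- march_pressure(p, seg, "conductance", q_in, mmhg_to_pa(90))
  distal <- seq(round(0.55 * 200), 200)
  expect_true(all(rc$leak$q[distal] <= rl$leak$q[distal] + 1e-16))
  # some genuine damping happened
  expect_lt(sum(rc$leak$q[distal]), 0.95 * sum(rl$leak$q[distal]))
})

test_that("two equal steps straddling a stenosis leak in pressure proportion", {
  ps <- resample_profile(centreline_profile(
    c(0, 7.4, 7.6, 22.4, 22.6, 30), c(1.5, 1.5, 1.25, 1.25, 1.0, 1.0)), 200)
  # superimpose a severe focal stenosis between the steps
  mid <- 15e-3
  ps$r <- ps$r * (1 - 0.65 * exp(-(ps$s - mid)^2 / (2 * (1.5e-3)^2)))
  seg <- segment_vessel(ps)
  rc <- march_pressure(ps, seg, "conductance", mlmin_to_m3s(150), mmhg_to_pa(90))
  expect_equal(rc$status, "converged")
  prox <- which(abs(ps$s - 7.5e-3) < 2e-3)
  dist <- which(abs(ps$s - 22.5e-3) < 2e-3)
  q_prox <- sum(rc$leak$q[prox]); q_dist <- sum(rc$leak$q[dist])
  p_ratio <- mean(rc$p[dist]) / mean(rc$p[prox])
  expect_lt(q_dist / q_prox, 1)
  rl <- march_pressure(ps, seg, "localized", mlmin_to_m3s(150), mmhg_to_pa(90))
  ql_prox <- sum(rl$leak$q[prox]); ql_dist <- sum(rl$leak$q[dist])
  # relative to the taper-only model, damping follows the pressure ratio
  expect_equal((q_dist / ql_dist) / (q_prox / ql_prox), p_ratio,
               tolerance = 0.15)
})

test_that("porosity failure on an extreme stenosis is a status, not an error", {
  v <- generate_vessel(stenosed_spec(0.85))
  res <- simulate_vessel(v, pa_mmhg = 90, q_in_mlmin = 300, model = "porosity")
  expect_equal(res$status, "failed")
  expect_equal(res$reason, "negative pressure")
  expect_error(compute_vffr(res), class = "vffr_unavailable")
})
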