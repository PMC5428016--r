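test_that("Stokes velocity matches hand evaluation and scales with density contrast", {
  med <- medium_properties()
  expect_equal(stokes_settling_velocity(ref_tissue(1020), med), 6.8125e-4,
               tolerance = 1e-10)
  expect_equal(stokes_settling_velocity(ref_tissue(1010), med), 3.40625e-4,
               tolerance = 1e-10)
  expect_error(stokes_settling_velocity(ref_tissue(1000), med),
               "never settles")
  expect_error(stokes_settling_velocity(ref_tissue(990), med), "never settles")
})

test_that("wall-correction factor matches the polynomial and is monotone", {
  expect_equal(wall_correction_factor(0), 1)
  expect_equal(wall_correction_factor(0.5), 5.716377, tolerance = 1e-6)
  expect_equal(wall_correction_factor(0.3), 2.359136, tolerance = 1e-6)
  # strictly increasing over the physically meaningful range; the fit
  # rolls over near the edge of its validity (above ~0.83)
  lam <- seq(0, 0.8, by = 0.005)
  expect_true(all(diff(wall_correction_factor(lam)) > 0))
  expect_error(wall_correction_factor(0.9), "validity")
  expect_error(wall_correction_factor(-0.1), ">= 0")
})

test_that("confined settling velocity is drag-corrected Stokes", {
  med <- medium_properties()
  s <- settling_velocity(ref_tissue(1010), ref_trap(), med)
  expect_equal(s$v_set, 3.40625e-4 / 5.716377, tolerance = 1e-6)
  expect_lte(s$v_set, s$v_stokes)
  expect_equal(s$t_settle, ref_trap()$h / s$v_set)

  # unconfined limit: K - 1 ~ 2.1 lam, so the relative error is ~2e-4 at
  # lam = 1e-4 and < 1e-6 by lam = 1e-7
  wide <- trap_geometry(w = 250e-6 / 1e-4, h = 500e-6)
  s0 <- settling_velocity(ref_tissue(1010), wide, med)
  expect_equal(s0$v_set, s0$v_stokes, tolerance = 3e-4)
  huge <- trap_geometry(w = 250e-6 / 1e-7, h = 500e-6)
  s00 <- settling_velocity(ref_tissue(1010), huge, med)
  expect_equal(s00$v_set, s00$v_stokes, tolerance = 1e-6)

  # heavy confinement still finite, well below Stokes
  tight <- trap_geometry(w = 250e-6 / 0.85, h = 500e-6)
  st <- settling_velocity(ref_tissue(1010), tight, med)
  expect_true(is.finite(st$v_set) && st$v_set < 0.1 * st$v_stokes)
})

test_that("settling time reproduces the density-sensitivity reference values", {
  med <- medium_properties()
  expect_equal(settling_time(ref_tissue(1010), ref_trap(), med), 8.391012,
               tolerance = 1e-6)
  # ten-fold density contrast, ten-fold faster
  expect_equal(settling_time(ref_tissue(1100), ref_trap(), med), 0.8391012,
               tolerance = 1e-6)
})

test_that("settling time scales exactly as 1/w at fixed d/w and density", {
  med <- medium_properties()
  set.seed(41)
  for (i in 1:5) {
    w <- runif(1, 100e-6, 2000e-6)
    lam <- runif(1, 0.2, 0.8)
    t1 <- settling_time(tissue_sample(lam * w, rho_T = 1015),
                        trap_geometry(w, w), med)
    t2 <- settling_time(tissue_sample(lam * w / 2, rho_T = 1015),
                        trap_geometry(w / 2, w / 2), med)
    expect_equal(t2 / t1, 2, tolerance = 1e-12)
  }
})

test_that("the settling optimum lies in (0.3, 0.7) and matches the grid oracle", {
  opt <- optimal_trap_ratio()
  expect_gt(opt, 0.3)
  expect_lt(opt, 0.7)
  expect_equal(opt, grid_scan_optimum(), tolerance = 1e-3)
  # scale-free: the bracket does not move the optimum
  expect_equal(optimal_trap_ratio(lower = 0.1, upper = 0.8), opt,
               tolerance = 1e-6)
  expect_error(optimal_trap_ratio(lower = 0), "bracket")
})

test_that("critical shear flow matches hand evaluation and scales as w^3", {
  med <- medium_properties()
  expect_equal(critical_shear_flow(ref_trap(), med, 1), 1.302083e-8,
               tolerance = 1e-6)
  expect_equal(critical_shear_flow(trap_geometry(12e-6, 12e-6), med, 1),
               1.8e-13, tolerance = 1e-6)
  # exact cubic scaling (log-log slope)
  set.seed(42)
  w <- sort(runif(4, 50e-6, 2000e-6))
  Q <- vapply(w, function(wi)
    critical_shear_flow(trap_geometry(wi, wi), med, 1), numeric(1))
  expect_equal(diff(log(Q)) / diff(log(w)), rep(3, 3), tolerance = 1e-12)
  expect_warning(critical_shear_flow(trap_geometry(500e-6, 100e-6), med),
                 "cubic")
})

test_that("critical lift flow matches Table-3-scale values and scales as sqrt(d) w^2", {
  med <- medium_properties()
  Q <- critical_lift_flow(ref_tissue(1010), ref_trap(), med)
  expect_equal(Q, 1.429598e-9, tolerance = 1e-6)
  expect_equal(Q * 6e7, 0.08577587, tolerance = 1e-6)  # mL/min
  expect_equal(critical_lift_flow(ref_tissue(1020), ref_trap(), med) * 6e7,
               0.1213054, tolerance = 1e-6)
  # quadrupling the density excess doubles Q_lift
  Q4 <- critical_lift_flow(ref_tissue(1040), ref_trap(), med)
  expect_equal(Q4 / Q, 2, tolerance = 1e-12)
  # exact scaling in d and w
  set.seed(43)
  for (i in 1:3) {
    d <- runif(1, 50e-6, 400e-6); w <- runif(1, 500e-6, 2000e-6); k <- runif(1, 1.1, 3)
    t0 <- critical_lift_flow(tissue_sample(d, 1015), trap_geometry(w, w), med)
    expect_equal(critical_lift_flow(tissue_sample(k * d, 1015),
                                    trap_geometry(w, w), med) / t0,
                 sqrt(k), tolerance = 1e-12)
    expect_equal(critical_lift_flow(tissue_sample(d, 1015),
                                    trap_geometry(k * w, k * w), med) / t0,
                 k^2, tolerance = 1e-12)
  }
  expect_error(critical_lift_flow(ref_tissue(1000), ref_trap(), med),
               "no lift threshold")
})

test_that("minimum trap width matches the published value and density scaling", {
  med <- medium_properties()
  expect_equal(minimum_trap_width(med, 1.02, 1) * 1e6, 11.9682,
               tolerance = 1e-6)
  expect_equal(minimum_trap_width(med, 1.1, 1) * 1e6, 59.841,
               tolerance = 1e-6)
  # linear in the density excess
  expect_equal(minimum_trap_width(med, 1.04, 1) /
                 minimum_trap_width(med, 1.02, 1), 2, tolerance = 1e-12)
  expect_error(minimum_trap_width(med, 0.99), "exceed 1")
  expect_error(minimum_trap_width(med, 1.02, tau_max = 0), "positive")
})

test_that("minimum trap width is the crossing of the two critical-flow curves", {
  med <- medium_properties()
  rho_ratio <- 1.02
  # independent bisection oracle on Q_shear(w) - Q_lift(w) with d = w/2
  gap <- function(w)
    critical_shear_flow(trap_geometry(w, w), med, 1) -
      critical_lift_flow(tissue_sample(w / 2, rho_T = rho_ratio * 1000),
                         trap_geometry(w, w), med)
  w_cross <- uniroot(gap, c(1e-6, 1e-3), tol = 1e-15)$root
  w_exact <- minimum_trap_width(med, rho_ratio, 1, exact = TRUE)
  expect_equal(w_exact, w_cross, tolerance = 1e-9)
  # at the exact crossing the two critical flows agree to 1e-9
  Qs <- critical_shear_flow(trap_geometry(w_exact, w_exact), med, 1)
  Ql <- critical_lift_flow(tissue_sample(w_exact / 2, rho_ratio * 1000),
                           trap_geometry(w_exact, w_exact), med)
  expect_equal(Qs / Ql, 1, tolerance = 1e-9)
  # the conventional coefficient is the same crossing within its rounding
  expect_equal(minimum_trap_width(med, rho_ratio, 1), w_cross,
               tolerance = 8e-3)
})

test_that("operating window classifies flow regimes with conservative boundaries", {
  med <- medium_properties()
  win <- operating_window(ref_tissue(1020), ref_trap(), med, tau_max = 1)
  expect_true(win$has_safe_ejection)
  expect_equal(win$Q_shear / win$Q_lift, 6.440356, tolerance = 1e-6)
  expect_equal(classify_flow(win, win$Q_lift * 0.99), "trapped_safe")
  expect_equal(classify_flow(win, win$Q_lift), "ejected_safe")
  expect_equal(classify_flow(win, win$Q_shear * 0.99), "ejected_safe")
  expect_equal(classify_flow(win, win$Q_shear), "damaging")
  expect_equal(classify_flow(win, "0.01 mL/min"), "trapped_safe")

  # below w_min: no safe-ejection window, damage before lift
  tiny <- trap_geometry(5e-6, 5e-6)
  win2 <- operating_window(tissue_sample(2.5e-6, 1020), tiny, med, 1)
  expect_false(win2$has_safe_ejection)
  expect_equal(classify_flow(win2, win2$Q_shear * 2), "damaging")
  expect_equal(classify_flow(win2, win2$Q_shear * 0.5), "trapped_safe")
})
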