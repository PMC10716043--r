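test_that("1/e rule recovers tau exactly on a noiseless exponential", {
  t <- seq(0, 60, by = 0.25)
  tr <- relax_trace(t, 5 * exp(-t / 10))
  fit <- relaxation_time_1e(tr)
  expect_equal(fit$tau, 10, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["sigma0"]), 5)
  expect_equal(fit$method, "one_over_e")
})

test_that("non-relaxing traces raise a not-relaxed error with the bound", {
  t <- seq(0, 100, by = 1)
  expect_error(relaxation_time_1e(relax_trace(t, rep(5, length(t)))),
               "tau > 100")
})

test_that("noisy synthetic traces are recovered within tolerance", {
  tr <- gen_relaxation_trace(sigma0 = 100, tau = 120, noise_sd = 2,
                             t_max = 600, dt = 2, seed = 42)
  truth <- attr(tr, "truth")
  expect_lt(abs(relaxation_time_1e(tr)$tau - truth$tau) / truth$tau, 0.05)
  expect_lt(abs(fit_maxwell(tr)$tau - truth$tau) / truth$tau, 0.05)
})

test_that("least-squares and 1/e agree on clean exponentials and flag misfit", {
  t <- seq(0, 500, by = 1)
  tr <- relax_trace(t, 80 * exp(-t / 75))
  f1 <- relaxation_time_1e(tr)
  f2 <- fit_maxwell(tr)
  expect_lt(abs(f1$tau - f2$tau) / f1$tau, 1e-3)
  expect_lt(f2$rmse, 1e-9)
  # tau is invariant to uniform stress rescaling
  tr10 <- relax_trace(t, 10 * (80 * exp(-t / 75)))
  expect_equal(fit_maxwell(tr10)$tau, f2$tau, tolerance = 1e-9)
  expect_equal(relaxation_time_1e(tr10)$tau, f1$tau, tolerance = 1e-9)
  # bi-exponential trace: rmse exposes the single-mode misfit
  bi <- relax_trace(t, 50 * exp(-t / 10) + 50 * exp(-t / 400))
  expect_gt(fit_maxwell(bi)$rmse, 1)
  # degenerate trace
  expect_error(fit_maxwell(relax_trace(t, rep(3, length(t)))), "degenerate")
})

test_that("maxwell_fit behaves like a fitted model object", {
  tr <- gen_relaxation_trace(seed = 8)
  fit <- fit_maxwell(tr)
  expect_named(coef(fit), c("sigma0", "tau"))
  expect_length(residuals(fit), nrow(tr))
  expect_equal(predict(fit, 0), fit$sigma0, tolerance = 1e-12)
})

test_that("phase angle covers the elastic-to-viscous range", {
  expect_equal(phase_angle(5, 0), 0)
  expect_equal(phase_angle(3, 3), 45)
  expect_equal(phase_angle(1, 3.49), 74, tolerance = 0.1)
  expect_equal(phase_angle(0, 2), 90)
  expect_error(phase_angle(0, 0), "undefined")
  expect_error(phase_angle(-1, 2), "non-negative")
})

test_that("gel melting point is the first G'/G'' crossover, interpolated", {
  sw <- gen_temp_sweep(tm_gel = 60, width = 2, seed = 1)
  mp <- gel_melting_point(sw)
  expect_equal(mp$melting_point_C, 60, tolerance = 0.1)
  expect_identical(mp$direction, "heating")
  # invariant to multiplying both channels by a constant
  sw2 <- oscillatory_trace(sw$abscissa, 7 * sw$Gp_Pa, 7 * sw$Gpp_Pa,
                           "temperature")
  expect_equal(gel_melting_point(sw2)$melting_point_C, mp$melting_point_C)
  solid <- oscillatory_trace(seq(20, 80, 1), rep(100, 61), rep(5, 61),
                             "temperature")
  expect_error(gel_melting_point(solid), "no G'/G'' crossover")
})

test_that("recovery ratio compares first and last healing plateaus", {
  tr0 <- gen_recovery_trace(loss_per_cycle = 0, n_cycles = 10, seed = 2)
  expect_equal(recovery_ratio(tr0), 100, tolerance = 1e-9)
  tr <- gen_recovery_trace(loss_per_cycle = 0.005, n_cycles = 10, seed = 2)
  expect_equal(recovery_ratio(tr), 100 * 0.995^9, tolerance = 1e-6)
  # unit invariance
  tr2 <- tr
  tr2$Gp_Pa <- tr2$Gp_Pa * 1e3
  expect_equal(recovery_ratio(tr2), recovery_ratio(tr), tolerance = 1e-9)
  unl <- oscillatory_trace(1:10, rep(1, 10), rep(1, 10), "time")
  expect_error(recovery_ratio(unl), "labels")
})

test_that("efficiency-versus-temperature inherits the kB*T denominator", {
  p <- polymer_spec(anchors_per_backbone = 20, anchor_conc = 75e-6)
  T_ <- seq(10, 70, by = 5)
  const <- oscillatory_trace(T_, rep(50, length(T_)), rep(1, length(T_)),
                             "temperature")
  eff <- efficiency_vs_temperature(const, p)
  expect_true(all(diff(eff$efficiency) < 0))  # 1/T from the denominator
  # G' pinned at the affine limit gives a flat efficiency of 1
  gmax <- vapply(T_ + 273.15, function(tk) theoretical_max_modulus(p, tk),
                 numeric(1))
  pinned <- oscillatory_trace(T_, gmax, rep(1, length(T_)), "temperature")
  expect_equal(efficiency_vs_temperature(pinned, p)$efficiency,
               rep(1, length(T_)), tolerance = 1e-12)
  # synthetic two-state melt: efficiency is sigmoidal with midpoint at Tm
  sw <- gen_temp_sweep(tm_gel = 55, width = 2, g_solid = 70,
                       t_range = c(20, 80), seed = 3)
  ef <- efficiency_vs_temperature(sw, p)
  mid <- (max(ef$efficiency) + min(ef$efficiency)) / 2
  t_mid <- ef$temp_C[which.min(abs(ef$efficiency - mid))]
  expect_equal(t_mid, 55, tolerance = 1.5)
})

test_that("trace constructors reject malformed inputs", {
  expect_error(relax_trace(c(0, 1, 1, 2, 3, 4, 5, 6, 7, 8), rep(1, 10)),
               "strictly increasing")
  expect_error(relax_trace(0:5, rep(1, 6)), "at least 10")
  expect_error(oscillatory_trace(1:3, c(1, -1, 1), c(1, 1, 1)), "non-negative")
})
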