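test_that("double referencing cancels common-mode signal", {
  t <- seq(0, 50, 0.1)
  mk <- function(y) sensorgram(t, y, 5, 35)
  binding <- ifelse(t >= 5 & t <= 35, 10, 0)

  # active = reference, no blank -> identically zero
  z <- double_reference(mk(binding), mk(binding))
  expect_equal(z$response_RU, rep(0, length(t)))

  # a constant offset common to active and reference cancels
  a <- mk(binding + 3)
  r <- mk(rep(3, length(t)))
  corrected <- double_reference(a, r)
  expect_equal(corrected$response_RU, binding)
})

test_that("a blank equal to the systematic artifact restores pure binding", {
  sched <- injection_schedule()
  surf <- surface_def("C1r", 92000, 9200)
  art <- artifact_model(dmso_actual = 5.4, noise_sd = 0, drift = 0.02)
  prof <- compound_profile("X", "clean_binder", mw = 276,
                           kinetics = kinetic_model(1e3, 0.5))
  blank_prof <- compound_profile("blank", "non_binder", mw = 1)
  cyc <- simulate_cycle(prof, 5e-4, surf, sched, art)
  blank <- simulate_cycle(blank_prof, 0, surf, sched, art)
  corrected <- double_reference(cyc, blank)
  pure <- double_reference(
    simulate_cycle(prof, 5e-4, surf, sched, artifact_model(noise_sd = 0))
  )
  expect_equal(corrected$response_RU, pure$response_RU, tolerance = 1e-9)
})

test_that("the correction pipeline is linear in the traces", {
  t <- seq(0, 50, 0.1)
  set.seed(1)
  mk <- function() sensorgram(t, rnorm(length(t)), 5, 35)
  a1 <- mk(); a2 <- mk(); r <- mk(); ba <- mk(); br <- mk()
  sum_in <- sensorgram(t, a1$response_RU + a2$response_RU, 5, 35)
  lhs <- double_reference(sum_in, r, ba, br)$response_RU
  rhs <- double_reference(a1, r, ba, br)$response_RU +
    double_reference(a2, sensorgram(t, rep(0, length(t)), 5, 35),
                     sensorgram(t, rep(0, length(t)), 5, 35))$response_RU
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("mismatched grids error unless interpolation is enabled", {
  a <- sensorgram(seq(0, 50, 0.1), rep(1, 501), 5, 35)
  b <- sensorgram(seq(0, 50, 0.2), rep(1, 251), 5, 35)
  expect_error(double_reference(a, b), "interpolate")
  z <- double_reference(a, b, interpolate = TRUE)
  expect_equal(z$response_RU, rep(0, 501))
})

test_that("report points average the right windows", {
  t <- seq(0, 50, 0.1)
  s <- sensorgram(t, rep(7.5, length(t)), 5, 35)
  expect_equal(report_point(s, "binding_late_association")$value, 7.5)
  expect_equal(report_point(s, "residual_post_injection")$value, 7.5)
  expect_equal(report_point(s, "residual_post_injection", width = 4)$value, 7.5)
  expect_error(report_point(s, "residual_post_injection", residual_offset = 30),
               "outside")
})

test_that("binding report point recovers the closed-form plateau", {
  kd_eq <- 2e-4
  conc <- 5e-4
  cyc <- make_clean_cycle(kd_eq = kd_eq, conc = conc)
  corrected <- double_reference(cyc)
  surf <- surface_def("C1r", 92000, 9200)
  req <- conc * theoretical_rmax(surf, 276) / (conc + kd_eq)
  # window sits just before t_stop; kobs ~ 1.75/s, so within 1e-3 of Req
  expect_equal(report_point(corrected, "binding_late_association")$value,
               req, tolerance = 2e-3)
})

test_that("residual of a fast-dissociating clean binder decays to ~0", {
  cyc <- make_clean_cycle(kd_eq = 5e-4)
  corrected <- double_reference(cyc)
  r_stop <- corrected$response_RU[which.min(abs(corrected$time_s - 35))]
  res <- report_point(corrected, "residual_post_injection")$value
  # kd_rate = 0.5/s: 10 s post injection only e^-5 of the signal remains
  expect_lt(res, r_stop * exp(-5) * 1.5)
  expect_lt(res, 0.1)
})

test_that("report-point extraction commutes with double referencing", {
  art <- artifact_model(dmso_actual = 5.3, noise_sd = 0.2)
  cyc <- make_clean_cycle(noise_sd = 0.2, dmso_actual = 5.3, seed = 8)
  rp_after <- report_point(double_reference(cyc), "binding_late_association")$value
  rp_before <- report_point(cyc$active, "binding_late_association")$value -
    report_point(cyc$reference, "binding_late_association")$value
  expect_equal(rp_after, rp_before, tolerance = 1e-12)
})

test_that("solvent calibration recovers a known mismatch polynomial", {
  sched <- injection_schedule()
  surf <- surface_def("C1r", 92000, 9200)
  poly_true <- c(0.2, 0.04, 3e-4)
  blank_prof <- compound_profile("blank", "non_binder", mw = 1)
  calib <- lapply(seq(4, 5.5, by = 0.25), function(d) {
    simulate_cycle(blank_prof, 0, surf, sched,
                   artifact_model(dmso_actual = d, excess_poly = poly_true,
                                  noise_sd = 0))
  })
  cal <- fit_solvent_calibration(calib)
  expect_equal(cal$coefficients, poly_true, tolerance = 0.01)
  # bulk range spans the calibrated DMSO mismatch (-1% to +0.5% of nominal)
  expect_equal(cal$range, c(-100, 50), tolerance = 0.02)
})

test_that("zero-offset calibration is the identity and range flags work", {
  sched <- injection_schedule()
  surf <- surface_def("C1r", 92000, 9200)
  blank_prof <- compound_profile("blank", "non_binder", mw = 1)
  calib <- lapply(c(4, 4.75, 5.5), function(d) {
    simulate_cycle(blank_prof, 0, surf, sched,
                   artifact_model(dmso_actual = d, excess_poly = c(0, 0, 0),
                                  noise_sd = 0))
  })
  cal <- fit_solvent_calibration(calib)
  out <- apply_solvent_correction(12.3, mean(cal$range), cal)
  expect_equal(out$corrected, 12.3, tolerance = 1e-8)
  expect_true(out$in_range)
  expect_false(apply_solvent_correction(12.3, cal$range[2] + 5, cal)$in_range)

  expect_error(fit_solvent_calibration(calib[1:2]), "at least 3")
  same <- lapply(c(5.2, 5.2, 5.2), function(d) {
    simulate_cycle(blank_prof, 0, surf, sched,
                   artifact_model(dmso_actual = d, noise_sd = 0))
  })
  expect_error(fit_solvent_calibration(same), "degenerate")
})

test_that("solvent correction removes the DMSO mismatch artifact", {
  # paired cycles with and without mismatch; corrected report point should
  # land within numerical noise of the artifact-free twin
  sched <- injection_schedule()
  surf <- surface_def("C1r", 92000, 9200)
  blank_prof <- compound_profile("blank", "non_binder", mw = 1)
  calib <- lapply(seq(4, 5.5, by = 0.25), function(d) {
    simulate_cycle(blank_prof, 0, surf, sched,
                   artifact_model(dmso_actual = d, noise_sd = 0))
  })
  cal <- fit_solvent_calibration(calib)

  cyc_mis <- make_clean_cycle(dmso_actual = 4.5)
  cyc_free <- make_clean_cycle(dmso_actual = 5)
  rp_mis <- report_point(double_reference(cyc_mis), "binding_late_association")$value
  rp_free <- report_point(double_reference(cyc_free), "binding_late_association")$value
  rb <- sprfrag:::bulk_response(cyc_mis$reference)
  corrected <- apply_solvent_correction(rp_mis, rb, cal)
  expect_true(corrected$in_range)
  expect_gt(abs(rp_mis - rp_free), 1) # artifact is material before correction
  expect_equal(corrected$corrected, rp_free, tolerance = 1e-6)
})
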