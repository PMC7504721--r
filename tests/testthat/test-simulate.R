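test_that("zero analyte and zero noise give a flat corrected trace", {
  prof <- compound_profile("X", "clean_binder", mw = 276,
                           kinetics = kinetic_model(1e3, 0.5))
  cyc <- simulate_cycle(prof, 0, surface_def("C1r", 92000, 9200),
                        artifacts = artifact_model(noise_sd = 0))
  corrected <- double_reference(cyc)
  expect_equal(corrected$response_RU, rep(0, nrow(corrected)))
})

test_that("plateau reaches half the effective Rmax at C = KD", {
  # fast kinetics so the association end is at equilibrium
  kd_eq <- 1e-4
  prof <- compound_profile("X", "clean_binder", mw = 276,
                           kinetics = kinetic_model(ka = 1e5, kd_rate = 10))
  surf <- surface_def("C1r", 92000, 9200)
  cyc <- simulate_cycle(prof, kd_eq, surf,
                        artifacts = artifact_model(noise_sd = 0))
  rmax <- theoretical_rmax(surf, 276)
  plateau <- cyc$active$response_RU[which.min(abs(cyc$active$time_s - 35))]
  expect_equal(plateau, rmax / 2, tolerance = 1e-9)
})

test_that("closed-form association matches numeric ODE integration", {
  # frozen oracle: lsoda integration of dR/dt = ka C (Rmax - R) - kd R
  # with ka = 1e3, kd = 1, C = 1e-3, Rmax = 20 gives R(1 s) = 8.646647
  sched <- injection_schedule(t_start = 0, t_stop = 30, t_dissoc_end = 50)
  prof <- compound_profile("X", "clean_binder", mw = 200,
                           kinetics = kinetic_model(ka = 1e3, kd_rate = 1))
  surf <- surface_def("L", 200, 20) # Rmax = 20 RU at mw parity
  cyc <- simulate_cycle(prof, 1e-3, surf, sched,
                        artifact_model(noise_sd = 0))
  r1 <- cyc$active$response_RU[which.min(abs(cyc$active$time_s - 1))]
  expect_equal(r1, 8.646647, tolerance = 1e-6)
  skip_if_not_installed("deSolve")
  ode <- deSolve::ode(
    y = c(R = 0), times = c(0, 1),
    func = function(t, R, p) list(1e3 * 1e-3 * (20 - R) - R),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  expect_equal(r1, unname(ode[2, "R"]), tolerance = 1e-7)
})

test_that("dissociation is log-linear with slope -kd_rate", {
  kd_rate <- 0.8
  prof <- compound_profile("X", "clean_binder", mw = 276,
                           kinetics = kinetic_model(ka = 1e4, kd_rate = kd_rate))
  cyc <- simulate_cycle(prof, 5e-4, surface_def("C1r", 92000, 9200),
                        artifacts = artifact_model(noise_sd = 0))
  act <- cyc$active
  dis <- act[act$time_s > 35 & act$time_s <= 45, ]
  slope <- unname(coef(lm(log(response_RU) ~ time_s, data = dis))[2])
  expect_equal(slope, -kd_rate, tolerance = 1e-6)
})

test_that("seeded simulations are bit-reproducible and seeds decorrelate", {
  lib <- synthetic_library(20, seed = 2)
  c1 <- simulate_campaign(lib, seed = 9)
  c2 <- simulate_campaign(lib, seed = 9)
  expect_identical(c1$sensorgrams, c2$sensorgrams)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_campaign(lib, seed = 10)
  expect_false(identical(c1$sensorgrams$response_RU, c3$sensorgrams$response_RU))
})

test_that("all-non-binder campaign yields zero corrected report points", {
  lib <- synthetic_library(15, seed = 4)
  camp <- simulate_campaign(
    lib, class_fractions = c(clean_binder = 0, non_binder = 1,
                             sticky = 0, superstoichiometric = 0),
    artifacts = artifact_model(noise_sd = 0), seed = 5
  )
  rp <- process_campaign(camp)
  expect_equal(rp$binding_RU, rep(0, nrow(rp)), tolerance = 1e-8)
  expect_equal(rp$residual_RU, rep(0, nrow(rp)), tolerance = 1e-8)
})

test_that("planted sticky compounds are exactly the ones above threshold", {
  lib <- synthetic_library(60, seed = 6)
  camp <- simulate_campaign(
    lib, class_fractions = c(clean_binder = 0, non_binder = 0.9,
                             sticky = 0.1, superstoichiometric = 0),
    sticky_residual_ru = 8, artifacts = artifact_model(noise_sd = 0), seed = 6
  )
  rp <- process_campaign(camp)
  above <- rp$compound_id[rp$residual_RU > 5]
  planted <- camp$truth$compound_id[camp$truth$class == "sticky"]
  expect_setequal(above, planted)
})

test_that("empty library and bad fractions are rejected", {
  lib <- synthetic_library(5, seed = 1)
  expect_error(simulate_campaign(lib[0, ]), "empty")
  expect_error(
    simulate_campaign(lib, class_fractions = c(clean_binder = 0.5, non_binder = 0.2,
                                               sticky = 0, superstoichiometric = 0)),
    "sum to 1"
  )
})

test_that("default dose series is seven two-fold dilutions from 500 uM", {
  s <- dose_series_default()
  expect_length(s, 7)
  expect_equal(max(s), 500e-6)
  expect_equal(min(s), 500e-6 / 64) # 7.8125 uM
  expect_equal(s[-1] / s[-length(s)], rep(2, 6))
})

test_that("dose series replicates are independent but noise-free identical", {
  prof <- compound_profile("X", "clean_binder", mw = 276,
                           kinetics = kinetic_model(1e3, 0.5))
  ds0 <- simulate_dose_series(prof, replicates = 2,
                              artifacts = artifact_model(noise_sd = 0), seed = 3)
  rp0 <- process_campaign(ds0)
  r1 <- rp0[rp0$replicate == 1, ]
  r2 <- rp0[rp0$replicate == 2, ]
  expect_equal(r1$binding_RU, r2$binding_RU, tolerance = 1e-12)
  # plateaus strictly increase with concentration for a clean binder
  expect_true(all(diff(r1$binding_RU[order(r1$conc_M)]) > 0))

  ds1 <- simulate_dose_series(prof, replicates = 2,
                              artifacts = artifact_model(noise_sd = 0.5), seed = 3)
  rp1 <- process_campaign(ds1)
  expect_false(identical(rp1$binding_RU[rp1$replicate == 1],
                         rp1$binding_RU[rp1$replicate == 2]))
  expect_error(simulate_dose_series(prof, replicates = 0), ">= 1")
})

test_that("ELISA plate generator hits the half-maximal and control identities", {
  ic50 <- 500e-6
  plate <- simulate_elisa_plate(ic50, hill = 1,
                                concentrations = c(0, 1e-5, ic50, 1e-1),
                                noise_cv = 0, seed = 1)
  pct <- percent_activity(plate)
  at <- function(conc) mean(pct$pct_activity[pct$role == "sample" &
                                               pct$conc_M == conc])
  expect_equal(at(ic50), 50, tolerance = 1e-9)
  expect_equal(at(0), 100, tolerance = 1e-9)
  # far above IC50 the activity approaches the constrained bottom of 0
  expect_lt(at(1e-1), 1)
  expect_error(simulate_elisa_plate(-1), "positive")
})
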