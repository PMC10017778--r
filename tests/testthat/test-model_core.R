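test_that("zero dose is stationary and initial conditions split the dose by F", {
  p <- pbk_params()
  d0 <- dose_spec("SEN", 0)
  sys <- build_odes(p, d0)
  expect_equal(unname(unlist(sys$rhs(0, sys$y0))), rep(0, 20))

  s0 <- pbk_simulate(p, d0)
  expect_equal(max(abs(s0$states)), 0)
  expect_equal(auc(s0, "CB_SEN"), 0)

  d <- dose_spec("SENO", 55, BW = 0.25, F = 0.082)
  sim <- pbk_simulate(p, d, t_end = 1)
  expect_equal(amount_at(sim, "ASI_SENO", 0), 0.082 * 55 * 0.25)
  expect_equal(amount_at(sim, "AFeces", 0), (1 - 0.082) * 55 * 0.25)
  expect_equal(amount_at(sim, "ALM4", 0), 0)
  expect_equal(sim$time[1], 0)
})

test_that("invalid parameters are rejected by name", {
  expect_error(pbk_params(kb1 = -1), "kb1")
  expect_error(pbk_params(residual_kcat_frac = 1.5), "residual_kcat_frac")
  expect_error(pbk_params(nonsense = 2), "unknown parameter")
  # flow balance holds by construction
  d <- derive_params(pbk_params(FQL = 0.3, FQR = 0.2, FQF = 0.1))
  expect_equal(d$QL + d$QR + d$QS + d$QF, d$QC, tolerance = 1e-12)
  # scaled kcat is recomputed from its factors
  expect_equal(derive_params(pbk_params())$kcat_invivo,
               0.0023 * 143 * 34 * 0.25 * 60 / 1000)
})

test_that("doubling the dose doubles every trajectory in the linear regime", {
  pl <- linearize_params(pbk_params())
  for (cmp in c("SEN", "SENO")) {
    sA <- pbk_simulate(pl, dose_spec(cmp, 10))
    sB <- pbk_simulate(pl, dose_spec(cmp, 20))
    big <- abs(sB$states) > 1e-12
    expect_lt(max(abs(2 * sA$states - sB$states)[big] /
                    abs(sB$states)[big]), 1e-6)
    expect_equal(2 * auc(sA, "CB_SEN"), auc(sB, "CB_SEN"),
                 tolerance = 1e-7)
  }
})

test_that("7-GS-DHP is a pure observer: compound kinetics are untouched by its kcat", {
  d <- dose_spec("SEN", 55)
  s_full <- pbk_simulate(pbk_params(residual_kcat_frac = 1), d)
  s_depl <- pbk_simulate(pbk_params(residual_kcat_frac = 0.46), d)
  s_nok  <- pbk_simulate(pbk_params(Lslope2c = 1e-12), d)

  expect_identical(s_full$observables[, "CB_SEN"],
                   s_depl$observables[, "CB_SEN"])
  expect_identical(s_full$states[, "AUCB_SEN"], s_depl$states[, "AUCB_SEN"])
  expect_identical(s_full$observables[, "CB_SEN"],
                   s_nok$observables[, "CB_SEN"])
  # the observer itself scales with the residual fraction
  expect_equal(terminal(s_depl, "ALM4") / terminal(s_full, "ALM4"), 0.46,
               tolerance = 1e-12)
})

test_that("cumulative ALM4 equals scaled kcat times the CVL integral", {
  p <- pbk_params()
  sim <- pbk_simulate(p, dose_spec("SEN", 55), n_out = 100001)
  cvl <- sim$observables[, "CVL_SEN"]
  trap <- sum(diff(sim$time) * (head(cvl, -1) + tail(cvl, -1)) / 2)
  expect_equal(derive_params(p)$kcat_invivo * trap, terminal(sim, "ALM4"),
               tolerance = 1e-6)
  # cumulative states never decrease
  for (st in c("ALM1", "ALM2", "ALM4", "AUCB_SEN"))
    expect_true(all(diff(sim$states[, st]) >= 0))
})

test_that("mass balance holds at every output time for both compounds", {
  p <- pbk_params()
  for (cmp in c("SENO", "SEN")) for (dd in c(0.5, 55)) {
    sim <- pbk_simulate(p, dose_spec(cmp, dd))
    expect_lt(sim$diagnostics$mass_balance_max_rel, 1e-6)
  }
})

test_that("linear configuration matches the closed-form zero-frequency gain", {
  pl <- linearize_params(pbk_params())
  dose <- dose_spec("SEN", 55)
  sim <- pbk_simulate(pl, dose, t_end = 2000, n_out = 2001)
  clint <- derive_params(pl)$VmaxLM2 / pl$KmLM2
  input <- dose$F * dose$dose_total
  # all absorbed SEN is eventually cleared hepatically ...
  expect_equal(terminal(sim, "ALM2"), input, tolerance = 1e-8)
  # ... so the CVL integral is input / intrinsic clearance,
  expect_equal(amount_at(sim, "ICVL_SEN", 2000), input / clint,
               tolerance = 1e-6)
  # ... and with all systemic entry via the liver, AUC_blood = AUC_CVL
  expect_equal(terminal(sim, "AUCB_SEN"), input / clint,
               tolerance = 1e-6)
})

test_that("adaptive solution agrees with a fixed-step RK4 oracle on the reduced model", {
  p <- reduced_params()
  dose <- dose_spec("SEN", 55)
  sim <- pbk_simulate(p, dose)
  cb_oracle <- rk4_reduced_cb_sen(p, dose, t_end = 24, h = 1e-4)
  expect_equal(amount_at(sim, "CB_SEN", 24), cb_oracle,
               tolerance = 1e-4)
})

test_that("auc and amount_at honour their contracts", {
  sim <- pbk_simulate(pbk_params(), dose_spec("SEN", 55))
  expect_equal(auc(sim, "CB_SEN", 0, 24), terminal(sim, "AUCB_SEN"))
  expect_equal(auc(sim, "CB_SEN", 0, 10) + auc(sim, "CB_SEN", 10, 24),
               auc(sim, "CB_SEN", 0, 24), tolerance = 1e-12)
  expect_error(auc(sim, "NOT_A_STATE"), "unknown")
  expect_error(amount_at(sim, "AB_SEN", 25))
  # exact at grid points
  i <- 500
  expect_equal(amount_at(sim, "AB_SEN", sim$time[i]),
               unname(sim$states[i, "AB_SEN"]))
  # a constant series integrates to length times level
  fake <- structure(list(time = seq(0, 24, length.out = 241),
                         states = matrix(3.5, 241, 1,
                                         dimnames = list(NULL, "X")),
                         observables = matrix(numeric(0), 241, 0),
                         t_end = 24), class = "pbk_sim")
  expect_equal(auc(fake, "X", 0, 24), 24 * 3.5)
})
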