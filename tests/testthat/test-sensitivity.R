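test_that("normalized SC has the defining values on analytic outputs", {
  p <- pbk_params()
  expect_equal(normalized_sc(function(q) q$KmLM2, p, "KmLM2"), 1.0)
  expect_equal(normalized_sc(function(q) q$KmLM2, p, "kb1"), 0)
  # quadratic output: forward SC at +5% is 2 + delta, central at 1% is 2
  expect_equal(normalized_sc(function(q) q$KmLM2^2, p, "KmLM2"), 2.05)
  expect_equal(normalized_sc(function(q) q$KmLM2^2, p, "KmLM2",
                             delta = 0.01, method = "central"),
               2, tolerance = 1e-9)
  expect_error(normalized_sc(function(q) 0, p, "KmLM2"), "undefined")
  expect_error(normalized_sc(function(q) 1, p, "bogus"), "unknown")
})

test_that("the 7-GS-DHP kcat has zero sensitivity on the blood SEN AUC", {
  p <- pbk_params()
  auc_out <- function(q) {
    sim <- pbk_simulate(q, dose_spec("SEN", 55))
    amount_at(sim, "AUCB_SEN", 24)
  }
  expect_identical(normalized_sc(auc_out, p, "Lslope2c"), 0)
})

test_that("sensitivity report: signs, sign flip between endpoints, determinism", {
  p <- pbk_params(residual_kcat_frac = 0.63)
  pars <- c("Lslope2c", "VmaxLM2c", "KmLM2")
  rp <- sensitivity_report(p, parameters = pars)
  # more conjugation -> fewer protein adducts, in both arms
  sc_l <- rp$sc[rp$parameter == "Lslope2c"]
  expect_true(all(sc_l < 0))
  # parameters negatively related to 7-GS-DHP are positively related to
  # protein adducts and vice versa
  ra <- sensitivity_report(p, output = "a7gsdhp", parameters = pars)
  m <- merge(rp, ra, by = c("parameter", "arm"))
  big <- abs(m$sc.x) > 1e-4 & abs(m$sc.y) > 1e-4
  expect_true(all(sign(m$sc.x[big]) == -sign(m$sc.y[big])))
  # deterministic given params and dose
  expect_identical(rp, sensitivity_report(p, parameters = pars))
  # empty registry -> empty report
  expect_equal(nrow(sensitivity_report(p, parameters = character())), 0)
  expect_error(sensitivity_report(p, parameters = "bogus"), "unknown")
})

test_that("forward SC at 5% agrees with central SC at 1% for smooth outputs", {
  p <- pbk_params(residual_kcat_frac = 0.63)
  pars <- c("VmaxLM2c", "KmLM2")
  fwd <- sensitivity_report(p, parameters = pars, delta = 0.05)
  ctr <- sensitivity_report(p, parameters = pars, delta = 0.01,
                            method = "central")
  m <- merge(fwd, ctr, by = c("parameter", "arm"))
  expect_true(all(abs(m$sc.x - m$sc.y) <= 0.10 * abs(m$sc.y)))
})

test_that("normalized SC is dose-invariant in the fully linear configuration", {
  pl <- linearize_params(pbk_params())
  out_at <- function(dd) function(q) {
    sim <- pbk_simulate(q, dose_spec("SEN", dd))
    amount_at(sim, "AUCB_SEN", 24)
  }
  for (par in c("QCc", "kb1")) {
    sc1 <- normalized_sc(out_at(10), pl, par)
    sc2 <- normalized_sc(out_at(20), pl, par)
    # agreement limited by solver tolerance amplified by the 5% step
    expect_lt(abs(sc1 - sc2), 1e-4)
  }
})
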