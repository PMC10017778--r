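test_that("REP ratios reproduce the in vivo endpoint values and handle edge cases", {
  expect_equal(round(rep_method1(15.11, 17.24), 2), 0.88)
  expect_equal(round(rep_method2(384.98, 628.48), 2), 0.61)
  expect_equal(rep_method1(3.2, 3.2), 1.0)
  expect_equal(rep_method2(5, 5), 1.0)
  expect_equal(rep_method1(0, 17.24), 0)
  expect_equal(rep_method2(0, 628.48), 0)
  expect_error(rep_method1(1, 0), "undefined")
  expect_error(rep_method2(1, 0), "undefined")
})

test_that("adduct partition is the budget remainder and rejects overshoot", {
  budget <- 0.082 * 0.20 * 13.75           # F * f * dose_total = 0.2255
  expect_equal(adduct_partition(budget, 0.11275), 0.11275)  # 1:1 split
  expect_equal(adduct_partition(budget, budget), 0)
  expect_equal(adduct_partition(budget, 0), budget)
  expect_error(adduct_partition(budget, budget * 1.01), "kcat")
})

test_that("residual conjugation capacity is piecewise linear through the anchors", {
  expect_equal(residual_kcat_fraction(55), 0.63)
  expect_equal(residual_kcat_fraction(0.1), 1.0)
  expect_equal(residual_kcat_fraction(200), 0.0001)
  expect_equal(residual_kcat_fraction(27.55), 0.815)  # segment midpoint
  expect_equal(residual_kcat_fraction(0.01), 1.0)     # clamped low
  expect_equal(residual_kcat_fraction(500), 0.0001)   # clamped high
  expect_error(residual_kcat_fraction(-1), "non-negative")
  # 63% residual of the measured kcat
  expect_equal(signif(residual_kcat_fraction(55) * 0.0023, 3), 0.00145)
})

test_that("paired simulation: budget conservation and kcat-invariance of Method 1", {
  p <- pbk_params()
  reps <- lapply(c(1.0, 0.63, 0.46), function(r)
    run_rep_pair(p, 55, residual_kcat_frac = r))

  for (rp in reps) {
    for (arm in c("SENO", "SEN")) {
      expect_equal(rp$amount_7gsdhp[[arm]] + rp$amount_protein[[arm]],
                   rp$budget[[arm]], tolerance = 1e-9)
    }
  }
  # Method-1 REP is bit-identical across residual fractions
  expect_identical(reps[[1]]$rep_method1, reps[[2]]$rep_method1)
  expect_identical(reps[[1]]$rep_method1, reps[[3]]$rep_method1)
  # Method-2 REP decreases with increasing depletion, and is below
  # Method 1 whenever the residual fraction is < 1
  r2 <- vapply(reps, `[[`, 0, "rep_method2")
  expect_true(all(diff(r2) < 0))
  expect_lt(reps[[2]]$rep_method2, reps[[2]]$rep_method1)
  expect_lt(reps[[3]]$rep_method2, reps[[3]]$rep_method1)
})

test_that("REP endpoints coincide under linear kinetics without depletion", {
  pl <- linearize_params(pbk_params())
  rp <- run_rep_pair(pl, 55, residual_kcat_frac = 1, t_end = 500)
  expect_equal(rp$rep_method2, rp$rep_method1, tolerance = 1e-6)
})

test_that("REP is invariant under AUC unit conversion", {
  rp <- run_rep_pair(pbk_params(), 55, residual_kcat_frac = 0.63)
  conv <- function(x) auc_convert(x, "SEN", "uM.h", "min.ug.mL")
  expect_equal(rep_method1(conv(rp$auc_seno_arm), conv(rp$auc_sen_arm)),
               rp$rep_method1, tolerance = 1e-12)
})

test_that("fraction-bioactivated scan: monotone REP2, consistency at f = 0.2, infeasibility flagged", {
  p <- pbk_params()
  scan <- fraction_bioactivated_scan(p, f_grid = c(0.05, 0.125, 0.2, 0.3, 0.4))
  expect_false(scan$feasible[scan$f == 0.05])   # protein would go negative
  expect_true(is.na(scan$rep_method2[scan$f == 0.05]))
  ok <- scan[scan$feasible, ]
  expect_true(all(diff(ok$rep_method2) > 0))    # increases with f
  expect_true(all(scan$rep_method1 == scan$rep_method1[1]))
  rp <- run_rep_pair(p, 55, f = 0.2, residual_kcat_frac = 0.63)
  expect_equal(ok$rep_method2[ok$f == 0.2], rp$rep_method2,
               tolerance = 1e-9)
})

test_that("dose scan: endpoints agree at low dose, diverge at the study dose", {
  p <- pbk_params()
  scan <- dose_scan(p, c(0.01, 0.1, 55))
  low <- scan[scan$dose <= 0.1, ]
  expect_true(all(abs(low$rep_method2 - low$rep_method1) < 1e-3))
  hi <- scan[scan$dose == 55, ]
  expect_gt(hi$rep_method1, hi$rep_method2)
  # pointwise computation: refining the grid changes nothing at shared doses
  scan2 <- dose_scan(p, c(0.1, 20, 55))
  expect_equal(scan2[scan2$dose %in% c(0.1, 55), ],
               scan[scan$dose %in% c(0.1, 55), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})
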