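test_that("blank correction computes rates and clips negatives with a warning", {
  rec <- data.frame(substrate_uM = c(5, 5, 10),
                    conc_full_uM = c(2, 2, 6),
                    conc_blank_uM = c(2, 0, 0),
                    replicate = c(1, 2, 1))
  r <- blank_correct_rates(rec)
  expect_equal(r$rate_nmol_min_mg[1], 0)            # full == blank
  # 6 uM in 0.1 mL over 60 min with 0.1 mg S9 -> 0.1 nmol/min/mg
  expect_equal(r$rate_nmol_min_mg[3], 0.1)
  expect_equal(attr(r, "n_clipped"), 0)

  rec$conc_blank_uM[2] <- 3                          # negative corrected
  expect_warning(r2 <- blank_correct_rates(rec), "clipped")
  expect_equal(r2$rate_nmol_min_mg[2], 0)
  expect_equal(attr(r2, "n_clipped"), 1)

  rec$conc_blank_uM[1] <- NA
  expect_error(blank_correct_rates(rec), "missing blank")
  expect_error(blank_correct_rates(rec[, -1]), "substrate_uM")
})

test_that("replication invariance: repeating the table leaves per-replicate rates unchanged", {
  tbl <- generate_incubation_dataset(seed = 7)
  r1 <- blank_correct_rates(tbl)
  r3 <- blank_correct_rates(rbind(tbl, tbl, tbl))
  expect_equal(r3$rate_nmol_min_mg, rep(r1$rate_nmol_min_mg, 3))
  expect_equal(mean(r3$rate_nmol_min_mg), mean(r1$rate_nmol_min_mg))
})

test_that("fit_kcat recovers exact linear data and matches the closed-form slope", {
  S <- exp(seq(log(0.5), log(50), length.out = 8))
  exact <- data.frame(substrate_uM = S, rate_nmol_min_mg = 0.0023 * S)
  fit <- fit_kcat(exact)
  expect_equal(fit$kcat_invitro, 0.0023, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  noisy <- blank_correct_rates(
    generate_incubation_dataset(cv = 0.10, seed = 11))
  fitn <- fit_kcat(noisy)
  expect_equal(fitn$kcat_invitro,
               slope_through_origin(noisy$substrate_uM,
                                    noisy$rate_nmol_min_mg),
               tolerance = 1e-12)
  expect_gt(fitn$se, 0)
  expect_equal(fitn$n_points, 24)
  expect_equal(unname(coef(fitn)["kcat_invivo"]),
               scale_kcat(fitn$kcat_invitro), tolerance = 1e-12)
  # free-intercept comparison fit reports an intercept
  fiti <- fit_kcat(noisy, intercept = TRUE)
  expect_true(is.finite(fiti$intercept))
})

test_that("fit_kcat degenerate and error cases", {
  S <- c(1, 2, 5)
  expect_warning(
    f0 <- fit_kcat(data.frame(substrate_uM = S,
                              rate_nmol_min_mg = c(0, 0, 0))),
    "degenerate")
  expect_equal(f0$kcat_invitro, 0)
  expect_error(fit_kcat(data.frame(substrate_uM = c(1, 1, 1),
                                   rate_nmol_min_mg = c(1, 2, 3))),
               "3 distinct")
})

test_that("in vitro to in vivo scaling is the product of its factors and is linear", {
  expect_equal(round(scale_kcat(0.0023, 143, 34, 0.25), 4), 0.1677)
  expect_equal(scale_kcat(0.001, 143, 34, 0.25), 0.07293, tolerance = 1e-10)
  expect_equal(scale_kcat(0), 0)
  a <- runif(1, 0.5, 2)
  expect_equal(scale_kcat(a * 0.0023), a * scale_kcat(0.0023),
               tolerance = 1e-12)
  expect_error(scale_kcat(0.0023, s9_yield = -1), "positive")
})

test_that("fitted slope lies within 3 SE of truth in almost all replicate datasets", {
  hits <- 0L
  for (seed in 1:200) {
    r <- blank_correct_rates(
      generate_incubation_dataset(true_kcat = 0.0023, cv = 0.10,
                                  n_replicates = 3, seed = seed))
    f <- fit_kcat(r)
    if (abs(f$kcat_invitro - 0.0023) <= 3 * f$se) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})
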