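#' REP value by Method 1 (AUC of the parent alkaloid)
#'
#' Ratio of the blood-SEN AUC after dosing the N-oxide to the AUC after
#' an equimolar dose of the parent alkaloid.  Unit-free, provided both
#' AUCs are in the same units.
#'
#' @param auc_seno_arm AUC of SEN upon SENO dosing (>= 0).
#' @param auc_sen_arm AUC of SEN upon SEN dosing (> 0).
#' @return the REP value.
#' @examples
#' rep_method1(15.11, 17.24)  # 0.88
#' @export
rep_method1 <- function(auc_seno_arm, auc_sen_arm) {
  stopifnot(is.numeric(auc_seno_arm), is.numeric(auc_sen_arm),
            all(auc_seno_arm >= 0))
  if (any(auc_sen_arm <= 0))
    stop("REP undefined: AUC of the SEN-dosing arm must be > 0",
         call. = FALSE)
  auc_seno_arm / auc_sen_arm
}

#' REP value by Method 2 (pyrrole-protein adducts)
#'
#' Ratio of the amount (or AUC) of pyrrole-protein adducts after dosing
#' the N-oxide to that after an equimolar dose of the parent alkaloid.
#' Because the model includes no clearance of the adducts, amount and AUC
#' give the same ratio.
#'
#' @param amount_no_arm adduct amount/AUC upon SENO dosing (>= 0).
#' @param amount_pa_arm adduct amount/AUC upon SEN dosing (> 0).
#' @return the REP value.
#' @examples
#' rep_method2(384.98, 628.48)  # 0.61
#' @export
rep_method2 <- function(amount_no_arm, amount_pa_arm) {
  stopifnot(is.numeric(amount_no_arm), is.numeric(amount_pa_arm),
            all(amount_no_arm >= 0))
  if (any(amount_pa_arm <= 0))
    stop("REP undefined: adduct amount of the SEN-dosing arm must be > 0",
         call. = FALSE)
  amount_no_arm / amount_pa_arm
}

#' Partition the bioactivated budget into conjugate and protein adducts
#'
#' The fraction of the dose bioactivated to reactive pyrroles not binding
#' DNA ends up either as the glutathione conjugate 7-GS-DHP or as
#' pyrrole-protein adducts:
#' `amount_7GSDHP + amount_protein = F * f * (REP1 *) dose`.
#' Given the budget and the simulated 7-GS-DHP amount at 24 h, the
#' protein-adduct amount is the remainder.
#'
#' @param total_budget `F * f * dose_total` (times Method-1 REP for the
#'   SENO arm), umol.
#' @param amount_7GSDHP simulated 7-GS-DHP amount at 24 h, umol.
#' @return `amount_protein` (umol, >= 0).
#' @export
adduct_partition <- function(total_budget, amount_7GSDHP) {
  stopifnot(is.numeric(total_budget), is.numeric(amount_7GSDHP),
            all(total_budget >= 0), all(amount_7GSDHP >= 0))
  if (any(amount_7GSDHP > total_budget))
    stop("7-GS-DHP amount exceeds the bioactivated budget; check the ",
         "bioavailability F, fraction bioactivated f, and the ",
         "conjugation kcat (Lslope2c / residual_kcat_frac)",
         call. = FALSE)
  total_budget - amount_7GSDHP
}

#' Dose-dependent residual conjugation capacity
#'
#' Piecewise-linear residual kcat fraction mimicking glutathione
#' depletion: 100% of the original kcat at 0.1 umol kg^-1 bw, linearly
#' decreasing to 63% at 55 umol kg^-1 bw, then linearly down to 0.01% at
#' 200 umol kg^-1 bw; clamped at 1 below 0.1 and at 0.0001 above 200.
#' Interpolation is linear in dose (not log-dose).
#'
#' @param dose_per_bw dose(s), umol kg^-1 bw (>= 0).
#' @return residual kcat fraction(s) in (0, 1].
#' @examples
#' residual_kcat_fraction(c(0.1, 55, 200))
#' @export
residual_kcat_fraction <- function(dose_per_bw) {
  stopifnot(is.numeric(dose_per_bw))
  if (any(dose_per_bw < 0))
    stop("dose must be non-negative", call. = FALSE)
  stats::approx(x = c(0.1, 55, 200), y = c(1, 0.63, 0.0001),
                xout = dose_per_bw, rule = 2)$y
}

#' Paired SENO/SEN simulations and both REP endpoints
#'
#' Runs the PBK model at an equimolar oral dose of SENO and of SEN,
#' computes the Method-1 REP from the blood-SEN AUCs (0 to `t_end`), the
#' 7-GS-DHP amounts at `t_end` per arm, the protein-adduct amounts via
#' the bioactivation budget, and the Method-2 REP from the latter.  The
#' residual-kcat multiplier mimicking glutathione depletion is applied to
#' the SEN-dosing arm; the SENO arm runs at full kcat (set
#' `depletion_arm = "both"` for symmetric depletion).
#'
#' @param params a [pbk_params()] object (its `residual_kcat_frac` is
#'   overridden per arm as described).
#' @param dose_per_bw equimolar oral dose, umol kg^-1 bw.
#' @param f fraction of the dose bioactivated to reactive pyrroles not
#'   binding DNA (default 0.20).
#' @param F oral bioavailability fraction (default 0.082).
#' @param BW body weight, kg.
#' @param residual_kcat_frac residual conjugation fraction for the
#'   SEN arm (default: taken from `params`).
#' @param t_end AUC window, h (default 24).
#' @param depletion_arm `"SEN"` (default) or `"both"`.
#' @param ... further arguments to [pbk_simulate()].
#' @return object of class `rep_pair`: both simulations, AUCs, 7-GS-DHP
#'   and protein-adduct amounts per arm, `rep_method1`, `rep_method2`.
#' @examples
#' \donttest{
#' rp <- run_rep_pair(pbk_params(), 55, residual_kcat_frac = 0.63)
#' rp$rep_method1; rp$rep_method2
#' }
#' @export
run_rep_pair <- function(params, dose_per_bw, f = 0.20, F = 0.082,
                         BW = params$BW,
                         residual_kcat_frac = params$residual_kcat_frac,
                         t_end = 24, depletion_arm = c("SEN", "both"),
                         ...) {
  stopifnot(inherits(params, "pbk_params"), f > 0, f <= 1)
  depletion_arm <- match.arg(depletion_arm)

  res_seno <- if (depletion_arm == "both") residual_kcat_frac else 1
  p_seno <- do.call(pbk_params,
                    utils::modifyList(unclass(params),
                                      list(BW = BW,
                                           residual_kcat_frac = res_seno)))
  p_sen <- do.call(pbk_params,
                   utils::modifyList(unclass(params),
                                     list(BW = BW,
                                          residual_kcat_frac =
                                            residual_kcat_frac)))

  sim_no <- pbk_simulate(p_seno, dose_spec("SENO", dose_per_bw, BW, F),
                         t_end = t_end, ...)
  sim_pa <- pbk_simulate(p_sen, dose_spec("SEN", dose_per_bw, BW, F),
                         t_end = t_end, ...)

  auc_no <- amount_at(sim_no, "AUCB_SEN", t_end)
  auc_pa <- amount_at(sim_pa, "AUCB_SEN", t_end)
  rep1 <- rep_method1(auc_no, auc_pa)

  a7_no <- amount_at(sim_no, "ALM4", t_end)
  a7_pa <- amount_at(sim_pa, "ALM4", t_end)

  dose_total <- dose_per_bw * BW
  budget_pa <- F * f * dose_total
  budget_no <- F * f * rep1 * dose_total
  protein_no <- adduct_partition(budget_no, a7_no)
  protein_pa <- adduct_partition(budget_pa, a7_pa)
  stopifnot(abs((a7_no + protein_no) - budget_no) <=
              1e-9 * max(budget_no, .Machine$double.eps),
            abs((a7_pa + protein_pa) - budget_pa) <=
              1e-9 * max(budget_pa, .Machine$double.eps))
  rep2 <- rep_method2(protein_no, protein_pa)

  structure(list(
    dose_per_bw = dose_per_bw, BW = BW, F = F, f = f, t_end = t_end,
    residual_kcat_frac = residual_kcat_frac, depletion_arm = depletion_arm,
    sim_seno = sim_no, sim_sen = sim_pa,
    auc_seno_arm = auc_no, auc_sen_arm = auc_pa,
    amount_7gsdhp = c(SENO = a7_no, SEN = a7_pa),
    budget = c(SENO = budget_no, SEN = budget_pa),
    amount_protein = c(SENO = protein_no, SEN = protein_pa),
    rep_method1 = rep1, rep_method2 = rep2
  ), class = "rep_pair")
}

#' @export
print.rep_pair <- function(x, ...) {
  cat(sprintf("REP of SENO relative to SEN at %.4g umol/kg bw (F = %.3g, f = %.3g)\n",
              x$dose_per_bw, x$F, x$f))
  cat(sprintf("  residual conjugation kcat (SEN arm): %.3g\n",
              x$residual_kcat_frac))
  cat(sprintf("  AUC blood SEN   SENO arm %.6g | SEN arm %.6g uM h\n",
              x$auc_seno_arm, x$auc_sen_arm))
  cat(sprintf("  7-GS-DHP        SENO arm %.6g | SEN arm %.6g umol\n",
              x$amount_7gsdhp[["SENO"]], x$amount_7gsdhp[["SEN"]]))
  cat(sprintf("  protein adducts SENO arm %.6g | SEN arm %.6g umol\n",
              x$amount_protein[["SENO"]], x$amount_protein[["SEN"]]))
  cat(sprintf("  REP Method 1 (AUC):      %.4g\n", x$rep_method1))
  cat(sprintf("  REP Method 2 (adducts):  %.4g\n", x$rep_method2))
  invisible(x)
}

#' Method-2 REP as a function of the fraction bioactivated
#'
#' Scans the fraction bioactivated `f` holding the 7-GS-DHP amounts fixed
#' at their values computed once at `f = 0.200` (with full conjugation
#' kcat in the SENO arm and the residual kcat in the SEN arm).  For each
#' `f` the protein-adduct amount per arm is the budget remainder; grid
#' points where it would be negative are flagged infeasible (`NA` REP)
#' and the scan continues.  The Method-1 REP does not depend on `f`.
#'
#' @param params a [pbk_params()] object.
#' @param f_grid grid of fractions bioactivated (default 0.125-0.400).
#' @param dose_per_bw equimolar dose, umol kg^-1 bw (default 55).
#' @param F bioavailability (default 0.082).
#' @param BW body weight, kg.
#' @param residual_kcat_frac residual conjugation fraction for the SEN
#'   arm at the reference dose (default 0.63).
#' @param t_end AUC window, h.
#' @param ... further arguments to [pbk_simulate()].
#' @return data.frame: `f`, `rep_method1`, `rep_method2`,
#'   `protein_seno`, `protein_sen`, `feasible`.
#' @export
fraction_bioactivated_scan <- function(params,
                                       f_grid = seq(0.125, 0.400, by = 0.025),
                                       dose_per_bw = 55, F = 0.082,
                                       BW = params$BW,
                                       residual_kcat_frac = 0.63,
                                       t_end = 24, ...) {
  stopifnot(all(f_grid > 0), all(f_grid <= 1))
  ref <- run_rep_pair(params, dose_per_bw, f = 0.200, F = F, BW = BW,
                      residual_kcat_frac = residual_kcat_frac,
                      t_end = t_end, ...)
  a7_no <- ref$amount_7gsdhp[["SENO"]]
  a7_pa <- ref$amount_7gsdhp[["SEN"]]
  rep1 <- ref$rep_method1
  dose_total <- dose_per_bw * BW

  out <- data.frame(f = f_grid, rep_method1 = rep1, rep_method2 = NA_real_,
                    protein_seno = NA_real_, protein_sen = NA_real_,
                    feasible = FALSE)
  for (i in seq_along(f_grid)) {
    f <- f_grid[i]
    pr_no <- F * f * rep1 * dose_total - a7_no
    pr_pa <- F * f * dose_total - a7_pa
    out$protein_seno[i] <- pr_no
    out$protein_sen[i] <- pr_pa
    if (pr_no > 0 && pr_pa > 0) {
      out$feasible[i] <- TRUE
      out$rep_method2[i] <- rep_method2(pr_no, pr_pa)
    }
  }
  attr(out, "reference") <- ref
  out
}

#' Dose-dependent REP values by both methods
#'
#' For each dose on the grid, the residual conjugation kcat fraction is
#' obtained from [residual_kcat_fraction()] and applied to the SEN-dosing
#' arm (the SENO arm keeps the full kcat unless
#' `depletion_arm = "both"`); a paired simulation then yields both REP
#' endpoints.  Each dose is computed independently, so refining the grid
#' does not change values at shared doses.
#'
#' @param params a [pbk_params()] object.
#' @param dose_grid doses, umol kg^-1 bw.
#' @param f fraction bioactivated (default 0.20).
#' @param F bioavailability (default 0.082).
#' @param BW body weight, kg.
#' @param t_end AUC window, h.
#' @param depletion_arm `"SEN"` (default) or `"both"`.
#' @param ... further arguments to [pbk_simulate()].
#' @return data.frame: `dose`, `residual_kcat_frac`, `rep_method1`,
#'   `rep_method2`, `a7_seno`, `a7_sen`, `protein_seno`, `protein_sen`.
#' @export
dose_scan <- function(params, dose_grid, f = 0.20, F = 0.082,
                      BW = params$BW, t_end = 24,
                      depletion_arm = c("SEN", "both"), ...) {
  depletion_arm <- match.arg(depletion_arm)
  stopifnot(all(dose_grid > 0))
  rows <- lapply(dose_grid, function(dd) {
    res <- residual_kcat_fraction(dd)
    rp <- run_rep_pair(params, dd, f = f, F = F, BW = BW,
                       residual_kcat_frac = res, t_end = t_end,
                       depletion_arm = depletion_arm, ...)
    data.frame(dose = dd, residual_kcat_frac = res,
               rep_method1 = rp$rep_method1, rep_method2 = rp$rep_method2,
               a7_seno = rp$amount_7gsdhp[["SENO"]],
               a7_sen = rp$amount_7gsdhp[["SEN"]],
               protein_seno = rp$amount_protein[["SENO"]],
               protein_sen = rp$amount_protein[["SEN"]])
  })
  do.call(rbind, rows)
}
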