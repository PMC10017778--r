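# Shared fixtures: a nearly-reduced parameter set for oracle comparisons,
# and a fixed-step RK4 integrator for the reduced three-pool system.

# Reduce the model to an effective 3-pool system (gut, liver, blood) by
# making the non-hepatic tissue flows and the intestinal transit
# negligible and all kinetics linear.  All parameters stay strictly
# positive, so the full model accepts them.
reduced_params <- function() {
  linearize_params(pbk_params(
    FQR = 1e-8, FQF = 1e-8,
    kt = 1e-9, ka_SENO = 1e-9, kb2 = 1e-9,
    PL_SEN = 1, PR_SEN = 1, PS_SEN = 1, PF_SEN = 1,
    PL_SENO = 1, PR_SENO = 1, PS_SENO = 1, PF_SENO = 1
  ))
}

# Independent fixed-step classical RK4 for the reduced SEN-only system:
#   ASI' = -kb1 ASI
#   AL'  = QL (AB/VB - AL/VL) + kb1 ASI - CLint AL/VL
#   AB'  = QL (AL/VL - AB/VB)
# (partition coefficients 1; intrinsic clearance CLint = VmaxLM2/KmLM2)
rk4_reduced_cb_sen <- function(p, dose, t_end = 24, h = 1e-4) {
  d <- derive_params(p)
  QL <- d$QL; VL <- d$VL; VB <- d$VB
  kb1 <- p$kb1
  clint <- d$VmaxLM2 / p$KmLM2
  asi <- dose$F * dose$dose_total; al <- 0; ab <- 0
  f <- function(asi, al, ab) {
    cvl <- al / VL; cb <- ab / VB
    c(-kb1 * asi,
      QL * (cb - cvl) + kb1 * asi - clint * cvl,
      QL * (cvl - cb))
  }
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    k1 <- f(asi, al, ab)
    k2 <- f(asi + h / 2 * k1[1], al + h / 2 * k1[2], ab + h / 2 * k1[3])
    k3 <- f(asi + h / 2 * k2[1], al + h / 2 * k2[2], ab + h / 2 * k2[3])
    k4 <- f(asi + h * k3[1], al + h * k3[2], ab + h * k3[3])
    inc <- (k1 + 2 * k2 + 2 * k3 + k4) * h / 6
    asi <- asi + inc[1]; al <- al + inc[2]; ab <- ab + inc[3]
  }
  ab / VB  # CB_SEN at t_end, uM
}

# Through-origin least-squares slope, the closed-form oracle for fit_kcat
slope_through_origin <- function(S, v) sum(S * v) / sum(S^2)

terminal <- function(sim, state) unname(sim$states[nrow(sim$states), state])
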