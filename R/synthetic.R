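# evaluate `expr` under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic S9 incubation dataset
#'
#' Emulates the in vitro measurement of 7-GS-DHP formation from SEN in
#' rat liver S9: a log-spaced substrate grid spanning the assayed range,
#' replicate full incubations and NADPH-free blanks, and first-order
#' product formation `C_full = kcat [S] t m_S9 / V + blank + noise`.
#' Noise is Gaussian on the measured metabolite concentration with
#' relative standard deviation `cv`, truncated at zero — the way
#' replicate scatter enters an LC-MS/MS quantification workflow.
#' Generation is a pure function of the arguments and the seed.
#'
#' @param true_kcat generating catalytic efficiency, mL min^-1 mg^-1 S9
#'   (default 0.0023).
#' @param substrate_grid substrate concentrations, uM (default 8
#'   log-spaced levels from 0.5 to 50).
#' @param n_replicates replicates per level (default 3).
#' @param cv relative SD of the concentration noise (default 0.10).
#' @param blank_uM background level present in full and blank
#'   incubations (default 0).
#' @param incubation_time_min,s9_mg_ml,volume_ml incubation constants
#'   (60 min, 1 mg/mL, 0.1 mL).
#' @param seed RNG seed (required for reproducibility).
#' @return data.frame with columns `substrate_uM`, `conc_full_uM`,
#'   `conc_blank_uM`, `replicate`, ready for [blank_correct_rates()].
#' @examples
#' tbl <- generate_incubation_dataset(seed = 42)
#' fit_kcat(blank_correct_rates(tbl))
#' @export
generate_incubation_dataset <- function(true_kcat = 0.0023,
                                        substrate_grid =
                                          exp(seq(log(0.5), log(50),
                                                  length.out = 8)),
                                        n_replicates = 3, cv = 0.10,
                                        blank_uM = 0,
                                        incubation_time_min = 60,
                                        s9_mg_ml = 1, volume_ml = 0.1,
                                        seed) {
  stopifnot(true_kcat >= 0, all(substrate_grid > 0),
            !is.unsorted(substrate_grid, strictly = TRUE),
            n_replicates >= 1, cv >= 0, blank_uM >= 0,
            incubation_time_min > 0, s9_mg_ml > 0, volume_ml > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)

  s9_mass_mg <- s9_mg_ml * volume_ml
  S <- rep(substrate_grid, each = n_replicates)
  # formed concentration after t minutes (uM)
  formed <- true_kcat * S * incubation_time_min * s9_mass_mg / volume_ml
  .with_seed(seed, {
    full <- pmax(0, (formed + blank_uM) *
                   (1 + stats::rnorm(length(S), 0, cv)))
    blank <- pmax(0, blank_uM * (1 + stats::rnorm(length(S), 0, cv)))
    data.frame(substrate_uM = S,
               conc_full_uM = full,
               conc_blank_uM = blank,
               replicate = rep(seq_len(n_replicates),
                               times = length(substrate_grid)))
  })
}

#' Generate a noisy in vivo-like blood concentration profile
#'
#' Simulates the PBK model and overlays multiplicative lognormal noise on
#' the blood-SEN concentration, as a fixture for I/O and AUC round-trip
#' checks.  The underlying mean profile is deterministic; only the noise
#' depends on the seed.
#'
#' @param params a [pbk_params()] object.
#' @param dose a [dose_spec()] object.
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.10; 0 gives the noise-free profile).
#' @param seed RNG seed.
#' @param t_end simulation horizon, h.
#' @param ... further arguments to [pbk_simulate()].
#' @return data.frame with `time_h`, `cb_sen_uM` (noisy) and
#'   `cb_sen_true_uM`.
#' @export
generate_invivo_profile <- function(params, dose, cv = 0.10, seed,
                                    t_end = 24, ...) {
  stopifnot(cv >= 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  sim <- pbk_simulate(params, dose, t_end = t_end, ...)
  cb <- sim$observables[, "CB_SEN"]
  noisy <- if (cv == 0) cb else {
    sdlog <- sqrt(log(1 + cv^2))
    .with_seed(seed,
               cb * stats::rlnorm(length(cb), -sdlog^2 / 2, sdlog))
  }
  data.frame(time_h = sim$time, cb_sen_uM = noisy, cb_sen_true_uM = cb)
}
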