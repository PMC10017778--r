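.molar_mass <- c(SEN = 335.44, SENO = 351.44)  # g/mol

#' Oral dose specification
#'
#' @param compound `"SENO"` or `"SEN"`.
#' @param dose_per_bw oral dose, umol kg^-1 bw (>= 0).
#' @param BW body weight, kg.
#' @param F oral bioavailability fraction in (0, 1]; 0.082 is the
#'   literature value for SEN, 1 serves for comparison.  The absorbed
#'   fraction `F * dose` is deposited in the dosed compound's
#'   small-intestine pool at t = 0; `(1 - F) * dose` goes to the feces
#'   pool, keeping the simulated exposure and the adduct budget arithmetic
#'   consistent.
#' @return an object of class `dose_spec`.
#' @examples
#' dose_spec("SENO", 55)
#' @export
dose_spec <- function(compound = c("SENO", "SEN"), dose_per_bw,
                      BW = 0.25, F = 0.082) {
  compound <- match.arg(compound)
  stopifnot(is.numeric(dose_per_bw), length(dose_per_bw) == 1L,
            is.finite(dose_per_bw), dose_per_bw >= 0,
            is.numeric(BW), BW > 0,
            is.numeric(F), F > 0, F <= 1)
  structure(list(compound = compound, dose_per_bw = dose_per_bw,
                 BW = BW, F = F, dose_total = dose_per_bw * BW),
            class = "dose_spec")
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf("Oral %s dose: %.4g umol/kg bw (%.4g mg/kg), BW %.3g kg, F %.3g\n",
              x$compound, x$dose_per_bw,
              convert_dose(x$dose_per_bw, x$compound), x$BW, x$F))
  invisible(x)
}

#' Convert a molar dose to a mass dose
#'
#' @param dose_per_bw dose, umol kg^-1 bw.
#' @param compound `"SEN"` (335.44 g/mol) or `"SENO"` (351.44 g/mol).
#' @return dose in mg kg^-1 bw.
#' @examples
#' convert_dose(55, "SEN")   # 18.45
#' convert_dose(55, "SENO")  # 19.33
#' @export
convert_dose <- function(dose_per_bw, compound) {
  if (!all(compound %in% names(.molar_mass)))
    stop("unknown compound: ",
         paste(setdiff(compound, names(.molar_mass)), collapse = ", "),
         call. = FALSE)
  stopifnot(is.numeric(dose_per_bw), all(dose_per_bw >= 0))
  unname(dose_per_bw * .molar_mass[compound] / 1000)
}

#' Convert an AUC between molar and mass-based units
#'
#' Internal AUCs are in uM h (umol h L^-1); in vivo reports commonly use
#' min ug mL^-1.  1 uM h of a compound of molar mass M equals
#' `M * 60 / 1000` min ug mL^-1.  REP values, being ratios of like AUCs,
#' are invariant under this conversion.
#'
#' @param x AUC value(s).
#' @param compound `"SEN"` or `"SENO"`.
#' @param from,to `"uM.h"` or `"min.ug.mL"`.
#' @return converted AUC value(s).
#' @export
auc_convert <- function(x, compound = "SEN",
                        from = c("uM.h", "min.ug.mL"),
                        to = c("min.ug.mL", "uM.h")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!compound %in% names(.molar_mass))
    stop("unknown compound: ", compound, call. = FALSE)
  if (from == to) return(x)
  k <- .molar_mass[[compound]] * 60 / 1000  # uM.h -> min.ug/mL
  if (from == "uM.h") x * k else x / k
}
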