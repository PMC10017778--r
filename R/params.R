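#' Parameter set for the rat SENO/SEN PBK model
#'
#' Builds the full registry of physiological, partitioning, kinetic and
#' scaling constants used by [pbk_simulate()].  Every value can be
#' overridden by name; the result is validated before it is returned.
#'
#' The physiological defaults (cardiac output, flow and volume fractions)
#' follow standard reference rat physiology; the partition coefficients and
#' the uptake, microbial-reduction and hepatic kinetic constants are
#' documented placeholder values on the scale reported for pyrrolizidine
#' alkaloids.  None of the reported REP, kcat or dose-conversion quantities
#' depends on them.  The in vitro catalytic efficiency of 7-GS-DHP
#' formation (`Lslope2c`) and its scaling factors (`S9_yield`,
#' `liver_wt_frac`, `BW`) are the measured quantities of the workflow.
#'
#' Tissue blood flows are stored as fractions of cardiac output with the
#' slowly perfused flow taken as the remainder, so the flow balance
#' `QL + QR + QS + QF = QC` holds by construction.  Derived quantities
#' (absolute flows and volumes, the scaled in vivo kcat) are always
#' recomputed from these primitives, never stored.
#'
#' @param ... named overrides of any parameter listed below.
#'
#' @section Parameters:
#' \describe{
#'   \item{BW}{body weight, kg (0.25).}
#'   \item{QCc}{cardiac output coefficient, L h^-1 kg^-0.74; QC = QCc * BW^0.74.}
#'   \item{FQL, FQR, FQF}{fractions of QC perfusing liver, richly perfused
#'     and fat; the slowly perfused fraction is 1 - FQL - FQR - FQF.}
#'   \item{VLc, VBc, VRc, VSc, VFc}{compartment volumes as L kg^-1 bw
#'     (liver, blood, richly perfused, slowly perfused, fat).}
#'   \item{PL_SEN, PR_SEN, PS_SEN, PF_SEN}{tissue:blood partition
#'     coefficients for SEN.}
#'   \item{PL_SENO, PR_SENO, PS_SENO, PF_SENO}{idem for SENO.}
#'   \item{ka_SENO}{first-order small-intestine to liver uptake of SENO, h^-1.}
#'   \item{kb1}{first-order small-intestine to liver uptake of SEN, h^-1.}
#'   \item{kb2}{first-order large-intestine to liver uptake of SEN, h^-1.}
#'   \item{kt}{first-order small-to-large intestine transit, h^-1.}
#'   \item{V_LI_lumen}{large-intestine luminal volume, L.}
#'   \item{Vmax_LI_red, Km_LI_red}{microbial SENO to SEN reduction in the
#'     large-intestine lumen, umol h^-1 and uM.}
#'   \item{VmaxLM1, KmLM1}{hepatic SENO to SEN reduction, umol h^-1 and uM.}
#'   \item{VmaxLM2c, KmLM2}{hepatic total SEN clearance: Vmax scaled per kg
#'     bw (umol h^-1 kg^-1) and Km (uM).}
#'   \item{CLu_SENO}{first-order renal clearance of SENO from blood, L h^-1.}
#'   \item{Lslope2c}{in vitro kcat for 7-GS-DHP formation, mL min^-1 mg^-1 S9.}
#'   \item{S9_yield}{S9 protein yield, mg g^-1 liver (143).}
#'   \item{liver_wt_frac}{liver weight, g kg^-1 bw (34).}
#'   \item{residual_kcat_frac}{multiplier in (0, 1] applied to `Lslope2c`
#'     to mimic glutathione depletion.}
#' }
#'
#' @return an object of class `pbk_params` (a named list of scalars).
#' @seealso [derive_params()], [linearize_params()], [pbk_simulate()]
#' @examples
#' p <- pbk_params(BW = 0.3, residual_kcat_frac = 0.63)
#' derive_params(p)$kcat_invivo
#' @export
pbk_params <- function(...) {
  p <- list(
    BW = 0.25,
    QCc = 15,
    FQL = 0.183, FQR = 0.327, FQF = 0.07,
    VLc = 0.034, VBc = 0.074, VRc = 0.05, VSc = 0.679, VFc = 0.07,
    PL_SEN = 2.0, PR_SEN = 2.0, PS_SEN = 1.5, PF_SEN = 1.2,
    PL_SENO = 1.0, PR_SENO = 1.0, PS_SENO = 0.8, PF_SENO = 0.3,
    ka_SENO = 0.3, kb1 = 1.0, kb2 = 0.2, kt = 1.5,
    V_LI_lumen = 0.01,
    Vmax_LI_red = 2.0, Km_LI_red = 20,
    VmaxLM1 = 1.2, KmLM1 = 20,
    VmaxLM2c = 52, KmLM2 = 10,
    CLu_SENO = 0.8,
    Lslope2c = 0.0023, S9_yield = 143, liver_wt_frac = 34,
    residual_kcat_frac = 1.0
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "pbk_params")
  validate_pbk_params(p)
  p
}

validate_pbk_params <- function(p) {
  for (nm in names(unclass(p))) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  if (p$residual_kcat_frac > 1)
    stop("residual_kcat_frac must lie in (0, 1]", call. = FALSE)
  if (p$FQL + p$FQR + p$FQF >= 1)
    stop("flow fractions FQL + FQR + FQF must sum to < 1", call. = FALSE)
  if (p$VLc + p$VBc + p$VRc + p$VSc + p$VFc > 1)
    stop("volume fractions must sum to <= 1 L kg^-1", call. = FALSE)
  d <- derive_params(p)
  stopifnot(abs((d$QL + d$QR + d$QS + d$QF) - d$QC) <= 1e-9 * d$QC)
  invisible(p)
}

#' Derived physiological and kinetic quantities
#'
#' Recomputes absolute flows (L h^-1), compartment volumes (L), the
#' bw-scaled hepatic SEN clearance Vmax (umol h^-1) and the in vivo scaled
#' kcat for 7-GS-DHP formation (L h^-1) from a parameter set.  The scaled
#' kcat is `Lslope2c * S9_yield * liver_wt_frac * BW * 60 / 1000`; it is
#' never stored independently, so it can never drift out of step with its
#' factors.
#'
#' @param p a [pbk_params()] object.
#' @return named list: `QC`, `QL`, `QR`, `QS`, `QF`, `VL`, `VB`, `VR`,
#'   `VS`, `VF`, `VmaxLM2`, `kcat_invivo`.
#' @export
derive_params <- function(p) {
  stopifnot(inherits(p, "pbk_params"))
  QC <- p$QCc * p$BW^0.74
  list(
    QC = QC,
    QL = p$FQL * QC,
    QR = p$FQR * QC,
    QF = p$FQF * QC,
    QS = (1 - p$FQL - p$FQR - p$FQF) * QC,
    VL = p$VLc * p$BW,
    VB = p$VBc * p$BW,
    VR = p$VRc * p$BW,
    VS = p$VSc * p$BW,
    VF = p$VFc * p$BW,
    VmaxLM2 = p$VmaxLM2c * p$BW,
    kcat_invivo = p$Lslope2c * p$S9_yield * p$liver_wt_frac * p$BW * 60 / 1000
  )
}

#' Force all saturable kinetics into their linear (first-order) regime
#'
#' Multiplies every Michaelis constant by `factor` while co-scaling the
#' corresponding Vmax, so each Michaelis-Menten flux keeps its first-order
#' limit Vmax/Km but is pushed far below saturation.  Used to study the
#' linear regime in which dose-proportionality and the equality of the two
#' REP endpoints hold exactly.
#'
#' @param p a [pbk_params()] object.
#' @param factor multiplier for the Km values (default 1e6).
#' @return a [pbk_params()] object.
#' @export
linearize_params <- function(p, factor = 1e6) {
  stopifnot(inherits(p, "pbk_params"), factor > 0)
  pbk_params(
    BW = p$BW, QCc = p$QCc, FQL = p$FQL, FQR = p$FQR, FQF = p$FQF,
    VLc = p$VLc, VBc = p$VBc, VRc = p$VRc, VSc = p$VSc, VFc = p$VFc,
    PL_SEN = p$PL_SEN, PR_SEN = p$PR_SEN, PS_SEN = p$PS_SEN,
    PF_SEN = p$PF_SEN, PL_SENO = p$PL_SENO, PR_SENO = p$PR_SENO,
    PS_SENO = p$PS_SENO, PF_SENO = p$PF_SENO,
    ka_SENO = p$ka_SENO, kb1 = p$kb1, kb2 = p$kb2, kt = p$kt,
    V_LI_lumen = p$V_LI_lumen,
    Vmax_LI_red = p$Vmax_LI_red * factor, Km_LI_red = p$Km_LI_red * factor,
    VmaxLM1 = p$VmaxLM1 * factor, KmLM1 = p$KmLM1 * factor,
    VmaxLM2c = p$VmaxLM2c * factor, KmLM2 = p$KmLM2 * factor,
    CLu_SENO = p$CLu_SENO,
    Lslope2c = p$Lslope2c, S9_yield = p$S9_yield,
    liver_wt_frac = p$liver_wt_frac,
    residual_kcat_frac = p$residual_kcat_frac
  )
}

#' @export
print.pbk_params <- function(x, ...) {
  d <- derive_params(x)
  cat("Rat PBK parameter set (SENO with SEN submodel)\n")
  cat(sprintf("  BW %.3g kg, QC %.3g L/h (liver %.3g, rich %.3g, slow %.3g, fat %.3g)\n",
              x$BW, d$QC, d$QL, d$QR, d$QS, d$QF))
  cat(sprintf("  in vitro kcat 7-GS-DHP %.4g mL/min/mg S9 -> in vivo %.4g L/h",
              x$Lslope2c, d$kcat_invivo))
  if (x$residual_kcat_frac < 1)
    cat(sprintf(" (residual fraction %.3g)", x$residual_kcat_frac))
  cat("\n")
  cat(sprintf("  hepatic SEN clearance Vmax %.3g umol/h, Km %.3g uM\n",
              d$VmaxLM2, x$KmLM2))
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' Plain-text `key = value` format; lines starting with `#` and bracketed
#' `[section]` headers are ignored on read (sections are cosmetic).
#' Unknown keys are an error, so a stale config cannot silently drift from
#' the parameter registry.
#'
#' @param path file path.
#' @return `read_params_file()` returns a [pbk_params()] object;
#'   `write_params_file()` returns `path` invisibly.
#' @export
read_params_file <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "[")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  do.call(pbk_params, as.list(stats::setNames(vals, keys)))
}

#' @rdname read_params_file
#' @param p a [pbk_params()] object to write.
#' @export
write_params_file <- function(p, path) {
  stopifnot(inherits(p, "pbk_params"))
  u <- unclass(p)
  writeLines(c("# senopbk PBK parameter configuration",
               sprintf("%s = %.17g", names(u), unlist(u))), path)
  invisible(path)
}
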