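.perturb_param <- function(params, parameter_name, factor) {
  if (!parameter_name %in% names(unclass(params)))
    stop("unknown parameter: '", parameter_name, "'", call. = FALSE)
  p <- unclass(params)
  p[[parameter_name]] <- p[[parameter_name]] * factor
  do.call(pbk_params, p)
}

#' Normalized local sensitivity coefficient
#'
#' One-at-a-time sensitivity of a scalar model output to a parameter:
#' `SC = ((C' - C) / C) / ((P' - P) / P)` with `P' = (1 + delta) P` and
#' all other parameters at baseline.  The default is the forward
#' difference at a 5% increase; a central difference (at +/- delta) is
#' available for diagnostics.
#'
#' @param model_output_fn function taking a [pbk_params()] object and
#'   returning a scalar output.
#' @param params baseline [pbk_params()] object.
#' @param parameter_name name of the parameter to perturb.
#' @param delta relative perturbation (default 0.05).
#' @param method `"forward"` (default) or `"central"`.
#' @return the unitless sensitivity coefficient.
#' @examples
#' # output equal to the parameter itself has SC = 1
#' normalized_sc(function(p) p$KmLM2, pbk_params(), "KmLM2")
#' @export
normalized_sc <- function(model_output_fn, params, parameter_name,
                          delta = 0.05, method = c("forward", "central")) {
  method <- match.arg(method)
  stopifnot(is.function(model_output_fn), delta > 0)
  C0 <- model_output_fn(params)
  if (!is.finite(C0) || C0 == 0)
    stop("sensitivity coefficient undefined: baseline output is ",
         C0, call. = FALSE)
  p_up <- .perturb_param(params, parameter_name, 1 + delta)
  if (method == "forward") {
    ((model_output_fn(p_up) - C0) / C0) / delta
  } else {
    p_dn <- .perturb_param(params, parameter_name, 1 - delta)
    ((model_output_fn(p_up) - model_output_fn(p_dn)) / C0) / (2 * delta)
  }
}

#' Sensitivity report across the parameter registry
#'
#' Computes normalized sensitivity coefficients of a model output —
#' the pyrrole-protein adduct amount at `t_end` (the Method-2 endpoint,
#' via the bioactivation budget, so sensitivities on 7-GS-DHP propagate
#' with flipped sign), the blood-SEN AUC (the Method-1 endpoint), or the
#' 7-GS-DHP amount — for both the SENO- and SEN-dosing arms, one
#' parameter at a time at a +5% perturbation.  Rows are sorted by |SC|.
#'
#' `residual_kcat_frac` is treated as a scenario setting rather than a
#' model parameter and is not in the default registry; pass it in
#' `parameters` explicitly to include it.
#'
#' @param params baseline [pbk_params()] object (its
#'   `residual_kcat_frac` defines the SEN-arm depletion scenario).
#' @param dose_per_bw equimolar dose, umol kg^-1 bw (default 55).
#' @param output `"protein_adducts"`, `"auc_sen"` or `"a7gsdhp"`.
#' @param parameters character vector of parameter names (default: all
#'   registered parameters except `residual_kcat_frac`).
#' @param f fraction bioactivated (default 0.20).
#' @param F bioavailability (default 0.082).
#' @param delta relative perturbation (default 0.05).
#' @param method `"forward"` or `"central"`.
#' @param t_end output time, h.
#' @param ... further arguments to [pbk_simulate()].
#' @return data.frame: `parameter`, `arm`, `sc`, sorted by |sc|
#'   (decreasing), with the settings in attributes.
#' @export
sensitivity_report <- function(params, dose_per_bw = 55,
                               output = c("protein_adducts", "auc_sen",
                                          "a7gsdhp"),
                               parameters = NULL, f = 0.20, F = 0.082,
                               delta = 0.05,
                               method = c("forward", "central"),
                               t_end = 24, ...) {
  output <- match.arg(output)
  method <- match.arg(method)
  if (is.null(parameters))
    parameters <- setdiff(names(unclass(params)), "residual_kcat_frac")
  if (length(parameters) == 0L)
    return(data.frame(parameter = character(), arm = character(),
                      sc = numeric()))
  unknown <- setdiff(parameters, names(unclass(params)))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  extract <- function(p) {
    rp <- run_rep_pair(p, dose_per_bw, f = f, F = F, BW = p$BW,
                       residual_kcat_frac = p$residual_kcat_frac,
                       t_end = t_end, ...)
    switch(output,
           protein_adducts = rp$amount_protein,
           auc_sen = c(SENO = rp$auc_seno_arm, SEN = rp$auc_sen_arm),
           a7gsdhp = rp$amount_7gsdhp)
  }

  C0 <- extract(params)
  if (any(!is.finite(C0) | C0 == 0))
    stop("baseline output is zero in at least one arm; SC undefined",
         call. = FALSE)
  sc_one <- function(nm, factor) {
    (extract(.perturb_param(params, nm, factor)) - C0) / C0
  }
  rows <- lapply(parameters, function(nm) {
    sc <- if (method == "forward") sc_one(nm, 1 + delta) / delta
          else (sc_one(nm, 1 + delta) - sc_one(nm, 1 - delta)) / (2 * delta)
    data.frame(parameter = nm, arm = names(C0), sc = unname(sc))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$sc)), ]
  rownames(out) <- NULL
  attr(out, "settings") <- list(dose_per_bw = dose_per_bw, output = output,
                                f = f, F = F, delta = delta,
                                method = method, t_end = t_end,
                                residual_kcat_frac =
                                  params$residual_kcat_frac)
  out
}
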