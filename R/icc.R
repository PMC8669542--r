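#' Interrater intraclass correlation from a fitted single-instrument model
#'
#' The proportion of latent-scale variation attributable to patients,
#' `sigma2_patient / (sigma2_patient + sigma2_rater)`; a value near 1 means
#' raters contribute little variation, i.e. good interrater reliability.
#' With `include_residual = TRUE` the logistic residual variance `pi^2 / 3`
#' is added to the denominator (both conventions exist in the literature;
#' the default attributes the non-patient share to raters only).
#'
#' @param fit A [fit_glmm()] result from a single-instrument model with
#'   patient and rater random intercepts.
#' @param include_residual Add `pi^2 / 3` to the denominator?
#' @return A list classed `"icc_result"`: `icc`, `sigma2_patient`,
#'   `sigma2_rater`, `includes_residual`, and `instrument` when the fit
#'   records it.
#' @export
compute_icc <- function(fit, include_residual = FALSE) {
  stopifnot(inherits(fit, "glmm_fit"))
  vc <- fit$variance_components
  if (is.null(vc$sigma2_patient) || is.null(vc$sigma2_rater))
    stop("compute_icc needs a fit with patient and rater random intercepts")
  s2p <- vc$sigma2_patient
  s2r <- vc$sigma2_rater
  denom <- s2p + s2r + if (include_residual) pi^2 / 3 else 0
  if (denom == 0)
    stop("undefined ICC: both variance components are zero")
  out <- list(instrument = attr(fit, "instrument"),
              icc = s2p / denom,
              sigma2_patient = s2p, sigma2_rater = s2r,
              includes_residual = include_residual)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (proportion of variation by patients%s): %.3f\n",
              if (x$includes_residual) ", residual-inclusive" else "",
              x$icc))
  cat(sprintf("  sigma2_patient %.4f, sigma2_rater %.4f\n",
              x$sigma2_patient, x$sigma2_rater))
  invisible(x)
}

#' Per-instrument interrater reliability
#'
#' Fits, for each instrument separately, the patient + rater random
#' intercept model on the instrument's own assessments and returns the ICC.
#'
#' @param tab A validated assessment table.
#' @param response Response column (default overall delirium).
#' @param include_residual Passed to [compute_icc()].
#' @param control A [glmm_control()].
#' @return Named list of `"icc_result"` (one per instrument), each carrying
#'   the underlying fit as attribute `"fit"`.
#' @export
instrument_reliability <- function(tab, response = "delirium",
                                   include_residual = FALSE,
                                   control = glmm_control()) {
  tab <- as.data.frame(tab)
  out <- list()
  for (ins in INSTRUMENTS) {
    sub <- tab[tab$instrument == ins, , drop = FALSE]
    spec <- glmm_spec(response = response, fixed = "intercept",
                      random = c("patient_intercept", "rater_intercept"))
    fit <- fit_glmm(sub, spec, control)
    attr(fit, "instrument") <- ins
    res <- compute_icc(fit, include_residual)
    attr(res, "fit") <- fit
    out[[ins]] <- res
  }
  out
}
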