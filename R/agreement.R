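#' Per-patient latent method pairs
#'
#' For each patient in a fitted two-instrument agreement model, the pair of
#' model-estimated continuous delirium outcomes: the latent linear
#' predictors for CAM and 3D-CAM (fixed effects plus empirical-Bayes
#' patient and patient-by-method modes, rater effects at 0), with the
#' corresponding probabilities and natural-log probabilities.
#'
#' @param fit A [fit_glmm()] result whose fixed effects include the method
#'   indicator.
#' @return A `data.frame` classed `"latent_pairs"` with columns
#'   `patient_id`, `eta_cam`, `eta_3dcam`, `p_cam`, `p_3dcam`, `log_p_cam`,
#'   `log_p_3dcam`.
#' @export
extract_latent_pairs <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!"method" %in% names(fit$beta))
    stop("fit lacks the method fixed effect; refit with fixed = ",
         "c('intercept', 'method')")
  pr_cam <- vapply(fit$patients, function(p)
    predict_latent(fit, p, "CAM")$eta, numeric(1))
  pr_d3 <- vapply(fit$patients, function(p)
    predict_latent(fit, p, "3DCAM")$eta, numeric(1))
  out <- data.frame(patient_id = fit$patients,
                    eta_cam = unname(pr_cam), eta_3dcam = unname(pr_d3),
                    stringsAsFactors = FALSE)
  out$p_cam <- plogis(out$eta_cam)
  out$p_3dcam <- plogis(out$eta_3dcam)
  out$log_p_cam <- log(out$p_cam)
  out$log_p_3dcam <- log(out$p_3dcam)
  class(out) <- c("latent_pairs", "data.frame")
  out
}

#' Repeated-measures Bland-Altman analysis of latent pairs
#'
#' One (average, difference) point per patient, with the difference
#' oriented CAM minus 3D-CAM, on the requested scale.  The mean difference
#' carries a normal-approximation CI (`mean +/- 1.96 SD / sqrt(n)`, one
#' pair per patient so independence is reasonable) and 95% limits of
#' agreement (`mean +/- 1.96 SD`).
#'
#' @param pairs A [extract_latent_pairs()] result (or any data.frame with
#'   the same columns).
#' @param scale `"log_probability"` (default; enables the probability-ratio
#'   transform) or `"probability"`.
#' @param level Confidence level for the mean-difference CI.
#' @return A list classed `"ba_result"`: `scale`, `points` (data.frame
#'   `patient_id`, `average`, `difference`), `mean_diff`, `mean_diff_ci`,
#'   `sd_diff`, `loa`, `n`.
#' @export
bland_altman <- function(pairs, scale = c("log_probability", "probability"),
                         level = 0.95) {
  scale <- match.arg(scale)
  if (nrow(pairs) < 2)
    stop("Bland-Altman needs at least 2 pairs (SD undefined otherwise)")
  a <- switch(scale, log_probability = pairs$log_p_cam,
              probability = pairs$p_cam)
  b <- switch(scale, log_probability = pairs$log_p_3dcam,
              probability = pairs$p_3dcam)
  if (scale == "log_probability" && any(!is.finite(a) | !is.finite(b)))
    stop("log-probability scale requires all probabilities > 0")
  diff <- a - b
  avg <- (a + b) / 2
  md <- mean(diff)
  s <- sd(diff)
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(scale = scale,
              points = data.frame(patient_id = pairs$patient_id,
                                  average = avg, difference = diff,
                                  stringsAsFactors = FALSE),
              mean_diff = md,
              mean_diff_ci = c(md - z * s / sqrt(length(diff)),
                               md + z * s / sqrt(length(diff))),
              sd_diff = s,
              loa = c(md - 1.96 * s, md + 1.96 * s),
              n = length(diff), level = level)
  class(out) <- "ba_result"
  out
}

#' Construct a Bland-Altman summary from reported numbers
#'
#' Low-level constructor for a mean difference and CI obtained elsewhere
#' (e.g. a published table), so the ratio transform of
#' [probability_ratio()] can be applied to it.
#'
#' @param mean_diff Mean difference (CAM minus 3D-CAM).
#' @param ci_low,ci_high Confidence interval for the mean difference.
#' @param scale `"log_probability"` or `"probability"`.
#' @return A `"ba_result"` (without points).
#' @export
ba_summary <- function(mean_diff, ci_low, ci_high,
                       scale = c("log_probability", "probability")) {
  scale <- match.arg(scale)
  out <- list(scale = scale, points = NULL, mean_diff = mean_diff,
              mean_diff_ci = c(ci_low, ci_high), sd_diff = NA_real_,
              loa = c(NA_real_, NA_real_), n = NA_integer_, level = 0.95)
  class(out) <- "ba_result"
  out
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s scale, CAM - 3DCAM), n = %s\n",
              x$scale, x$n))
  cat(sprintf("  mean difference %.3f (%.0f%% CI %.3f to %.3f)\n",
              x$mean_diff, 100 * x$level, x$mean_diff_ci[1],
              x$mean_diff_ci[2]))
  if (is.finite(x$loa[1]))
    cat(sprintf("  95%% limits of agreement %.3f to %.3f\n",
                x$loa[1], x$loa[2]))
  invisible(x)
}

round2 <- function(x) round(x, 2)

#' Probability ratio from a log-scale Bland-Altman mean difference
#'
#' `ratio = exp(mean_diff)` is the probability of a positive CAM relative
#' to a positive 3D-CAM, with CI `exp(mean_diff_ci)`.  The inverse ratio
#' (3D-CAM relative to CAM) follows the reporting convention of taking the
#' reciprocal of the two-decimal rounded forward values (so a forward
#' ratio printed as 0.36 inverts to 2.78), with CI endpoints swapped.
#'
#' @param ba A `"ba_result"` on the `log_probability` scale.
#' @return A list classed `"ratio_result"`: `ratio`, `ratio_ci`,
#'   `inverse_ratio`, `inverse_ratio_ci`.
#' @export
probability_ratio <- function(ba) {
  stopifnot(inherits(ba, "ba_result"))
  if (ba$scale != "log_probability")
    stop("probability_ratio requires the log_probability scale; on the ",
         "probability scale report mean_diff directly")
  ratio <- exp(ba$mean_diff)
  ci <- exp(ba$mean_diff_ci)
  out <- list(ratio = ratio, ratio_ci = ci,
              inverse_ratio = round2(1 / round2(ratio)),
              inverse_ratio_ci = c(round2(1 / round2(ci[2])),
                                   round2(1 / round2(ci[1]))))
  class(out) <- "ratio_result"
  out
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("P(CAM+) / P(3DCAM+): %.2f (95%% CI %.2f to %.2f)\n",
              x$ratio, x$ratio_ci[1], x$ratio_ci[2]))
  cat(sprintf("  inverse: %.2f (95%% CI %.2f to %.2f)\n",
              x$inverse_ratio, x$inverse_ratio_ci[1], x$inverse_ratio_ci[2]))
  invisible(x)
}

#' Default Bland-Altman scale policy per response
#'
#' The overall delirium outcome and the rare altered-level-of-consciousness
#' feature are analyzed on the log-probability scale (their latent
#' differences are closer to normal there, and the exp transform yields a
#' probability ratio); the remaining three features stay on the probability
#' scale.
#'
#' @return Named character vector mapping response to scale.
#' @export
default_scale_policy <- function() {
  c(delirium = "log_probability",
    acute_change = "probability",
    inattention = "probability",
    disorganized_thinking = "probability",
    aloc = "log_probability")
}

# Advisory normality check: strong skewness suggests the log scale.
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Method agreement for one cardinal feature
#'
#' Fits the two-instrument agreement model on a feature response, extracts
#' the per-patient latent pairs, and runs the Bland-Altman analysis on the
#' policy-selected scale; the exp-transformed probability ratio is reported
#' only for log-scale analyses.  A skewness pre-check (|g1| > 1 on the
#' probability-scale differences suggests the log scale) is advisory only:
#' it is messaged, never auto-applied.
#'
#' @param tab A validated assessment table.
#' @param feature One of the four cardinal features (or `"delirium"` for
#'   the overall outcome).
#' @param scale_policy Named vector mapping response to scale; see
#'   [default_scale_policy()].
#' @param control A [glmm_control()].
#' @param random Random terms for the agreement model.
#' @return A list classed `"agreement_result"` with `feature`, `scale`,
#'   `fit`, `test` (method fixed effect), `pairs`, `ba`, and `ratio`
#'   (log-scale analyses only).
#' @export
feature_agreement <- function(tab, feature,
                              scale_policy = default_scale_policy(),
                              control = glmm_control(),
                              random = c("patient_intercept",
                                         "rater_intercept",
                                         "patient_by_method")) {
  stopifnot(feature %in% c("delirium", FEATURES))
  scale <- unname(scale_policy[[feature]])
  spec <- glmm_spec(response = feature, fixed = c("intercept", "method"),
                    random = random)
  fit <- tryCatch(fit_glmm(tab, spec, control), error = function(e)
    stop("agreement fit for '", feature, "' failed: ", conditionMessage(e)))
  test <- wald_test_fixed(fit, "method")
  pairs <- extract_latent_pairs(fit)
  g1 <- skewness(pairs$p_cam - pairs$p_3dcam)
  if (abs(g1) > 1 && scale == "probability")
    message("feature '", feature, "': probability-scale differences are ",
            "skewed (g1 = ", round(g1, 2),
            "); the log scale may be more appropriate (not auto-applied)")
  ba <- bland_altman(pairs, scale)
  out <- list(feature = feature, scale = scale, fit = fit, test = test,
              pairs = pairs, ba = ba)
  if (scale == "log_probability") out$ratio <- probability_ratio(ba)
  class(out) <- "agreement_result"
  out
}

#' Write Bland-Altman points as TSV
#'
#' @param ba A `"ba_result"` with points.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ba_points <- function(ba, path) {
  stopifnot(inherits(ba, "ba_result"), !is.null(ba$points))
  write.table(ba$points, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
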