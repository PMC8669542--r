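#' Dichotomize latent method pairs
#'
#' Maps each instrument's model-estimated probability to a binary outcome:
#' 1 iff `p >= threshold` (ties map to positive).
#'
#' @param pairs A [extract_latent_pairs()] result.
#' @param threshold Probability cutoff in (0, 1); default 0.5.
#' @return Data frame with `patient_id`, `cam`, `d3cam` (0/1).
#' @export
dichotomize_pairs <- function(pairs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  data.frame(patient_id = pairs$patient_id,
             cam = as.integer(pairs$p_cam >= threshold),
             d3cam = as.integer(pairs$p_3dcam >= threshold),
             stringsAsFactors = FALSE)
}

#' Cohen kappa for binary method pairs
#'
#' Standard 2x2 chance-corrected agreement over one pair per patient:
#' `kappa = (p_observed - p_expected) / (1 - p_expected)` with the
#' expected agreement from the marginal products.
#'
#' @param binary A [dichotomize_pairs()] result (columns `cam`, `d3cam`),
#'   or a length-4 count vector `c(both_pos, cam_only, d3cam_only,
#'   both_neg)`.
#' @param bands Interpretation bands for [interpret_kappa()].
#' @return A list classed `"kappa_result"`: `kappa`, `p_observed`,
#'   `p_expected`, `table2x2` (named counts), `label`, `n`; `ci` is `NULL`
#'   until filled by [kappa_ci()].
#' @export
cohen_kappa <- function(binary, bands = kappa_bands()) {
  if (is.numeric(binary) && length(binary) == 4) {
    counts <- as.numeric(binary)
  } else {
    stopifnot(nrow(binary) >= 1)
    counts <- c(sum(binary$cam == 1 & binary$d3cam == 1),
                sum(binary$cam == 1 & binary$d3cam == 0),
                sum(binary$cam == 0 & binary$d3cam == 1),
                sum(binary$cam == 0 & binary$d3cam == 0))
  }
  names(counts) <- c("both_pos", "cam_only", "d3cam_only", "both_neg")
  n <- sum(counts)
  po <- (counts[["both_pos"]] + counts[["both_neg"]]) / n
  p_cam <- (counts[["both_pos"]] + counts[["cam_only"]]) / n
  p_d3 <- (counts[["both_pos"]] + counts[["d3cam_only"]]) / n
  pe <- p_cam * p_d3 + (1 - p_cam) * (1 - p_d3)
  if (pe >= 1 - 1e-12)
    stop("undefined kappa: expected agreement is 1 (both methods constant)")
  kap <- (po - pe) / (1 - pe)
  out <- list(kappa = kap, ci = NULL, p_observed = po, p_expected = pe,
              table2x2 = as.list(counts), n = n,
              label = interpret_kappa(kap, bands))
  class(out) <- "kappa_result"
  out
}

#' Bootstrap confidence interval for the latent-pair kappa
#'
#' `pair_bootstrap` resamples patients' latent pairs with replacement and
#' recomputes kappa (percentile interval); `refit_bootstrap` resamples
#' patients' full assessment records, refits the agreement GLMM per
#' replicate, and recomputes the latent-pair kappa (much more expensive).
#' Replicates with undefined kappa (both methods constant) are redrawn, up
#' to `10 * B` draws.  An identical seed yields an identical interval.
#'
#' @param tab The assessment table the model was fitted to.
#' @param fit The fitted agreement model.
#' @param method `"pair_bootstrap"` (default) or `"refit_bootstrap"`.
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @param threshold Dichotomization cutoff.
#' @param level Confidence level.
#' @return Numeric `(low, high)`, with the replicate kappas as attribute
#'   `"replicates"`.
#' @export
kappa_ci <- function(tab, fit, method = c("pair_bootstrap", "refit_bootstrap"),
                     B = 2000L, seed = 1L, threshold = 0.5, level = 0.95) {
  method <- match.arg(method)
  if (B < 200) stop("B must be >= 200")
  set.seed(seed)
  pairs <- extract_latent_pairs(fit)
  np <- nrow(pairs)
  kaps <- numeric(B)
  draws <- 0L
  b <- 1L
  tab <- as.data.frame(tab)
  by_patient <- if (method == "refit_bootstrap")
    split(tab, tab$patient_id)[pairs$patient_id]
  while (b <= B) {
    draws <- draws + 1L
    if (draws > 10L * B)
      stop("bootstrap failed: more than 10*B replicates had undefined kappa")
    idx <- sample.int(np, np, replace = TRUE)
    k <- tryCatch({
      if (method == "pair_bootstrap") {
        cohen_kappa(dichotomize_pairs(pairs[idx, ], threshold))$kappa
      } else {
        rows <- by_patient[idx]
        for (j in seq_along(rows))
          rows[[j]]$patient_id <- sprintf("B%05d", j)
        boot_tab <- do.call(rbind, rows)
        refit <- fit_glmm(boot_tab, fit$spec, fit$control)
        cohen_kappa(dichotomize_pairs(extract_latent_pairs(refit),
                                      threshold))$kappa
      }
    }, error = function(e) NA_real_)
    if (is.na(k)) next
    kaps[b] <- k
    b <- b + 1L
  }
  alpha <- 1 - level
  ci <- unname(quantile(kaps, c(alpha / 2, 1 - alpha / 2)))
  attr(ci, "replicates") <- kaps
  ci
}

#' Default kappa interpretation bands
#'
#' Landis-Koch-style bands as used in this analysis: values over 0.75 are
#' "substantial", 0.40 to 0.75 "moderate", below 0.40 "poor".  The band
#' table is configurable (breaks are left-open: a kappa equal to a break
#' falls in the lower band).
#'
#' @param breaks Increasing interior cut points.
#' @param labels Labels, one more than breaks, low to high.
#' @return A list with `breaks` and `labels`.
#' @export
kappa_bands <- function(breaks = c(0.40, 0.75),
                        labels = c("poor", "moderate", "substantial")) {
  stopifnot(length(labels) == length(breaks) + 1, !is.unsorted(breaks))
  list(breaks = breaks, labels = labels)
}

#' Interpret a kappa value
#'
#' @param kappa Value in `[-1, 1]`.
#' @param bands A [kappa_bands()] table.
#' @return Character label.
#' @export
interpret_kappa <- function(kappa, bands = kappa_bands()) {
  stopifnot(kappa >= -1, kappa <= 1)
  bands$labels[[findInterval(kappa, bands$breaks, left.open = TRUE) + 1L]]
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen kappa: %.2f (%s)", x$kappa, x$label))
  if (!is.null(x$ci))
    cat(sprintf(", 95%% CI %.2f to %.2f", x$ci[1], x$ci[2]))
  cat(sprintf("\n  p_observed %.3f, p_expected %.3f, n = %d\n",
              x$p_observed, x$p_expected, x$n))
  cat(sprintf("  2x2: both+ %d | CAM+ only %d | 3DCAM+ only %d | both- %d\n",
              x$table2x2$both_pos, x$table2x2$cam_only,
              x$table2x2$d3cam_only, x$table2x2$both_neg))
  invisible(x)
}
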