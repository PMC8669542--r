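#' Configure the end-to-end agreement analysis
#'
#' @param input Path to a long-format assessment table, or a validated
#'   table/data.frame used directly.
#' @param responses Responses to analyze: the overall `"delirium"` outcome
#'   and/or any of the four cardinal features.
#' @param scale_policy Named response-to-scale map; see
#'   [default_scale_policy()].
#' @param icc_include_residual Use the residual-inclusive ICC denominator?
#' @param kappa_threshold Dichotomization cutoff for the latent-pair kappa.
#' @param ci_method Kappa CI method (see [kappa_ci()]).
#' @param B Bootstrap replicates for the kappa CI.
#' @param seed Integer seed governing all randomness in the pipeline.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @param control A [glmm_control()].
#' @return A list classed `"analysis_config"`.
#' @export
analysis_config <- function(input,
                            responses = c("delirium", FEATURES),
                            scale_policy = default_scale_policy(),
                            icc_include_residual = FALSE,
                            kappa_threshold = 0.5,
                            ci_method = "pair_bootstrap",
                            B = 2000L, seed = 1L, out_dir = NULL,
                            control = glmm_control()) {
  responses <- match.arg(responses, c("delirium", FEATURES),
                         several.ok = TRUE)
  missing_scale <- setdiff(responses, names(scale_policy))
  if (length(missing_scale))
    stop("scale_policy lacks response(s): ",
         paste(missing_scale, collapse = ", "))
  out <- list(input = input, responses = responses,
              scale_policy = scale_policy,
              icc_include_residual = icc_include_residual,
              kappa_threshold = kappa_threshold, ci_method = ci_method,
              B = as.integer(B), seed = as.integer(seed), out_dir = out_dir,
              control = control)
  class(out) <- "analysis_config"
  out
}

stage <- function(name, expr, manifest_env) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest_env$completed <- c(manifest_env$completed, name)
  res
}

#' Run the full agreement analysis pipeline
#'
#' read -> pair -> per-instrument reliability fits (ICC) -> agreement fit,
#' latent pairs, Bland-Altman and ratio -> kappa, for the overall delirium
#' outcome and each configured feature.  Deterministic given the config
#' seed.  When `out_dir` is set, the JSON report, per-response
#' Bland-Altman point TSVs, and a MANIFEST recording the config and the
#' completed stages are written there; partial outputs are retained on
#' failure.
#'
#' @param config An [analysis_config()].
#' @return A list classed `"study_report"` with `cohort`, `icc`,
#'   `responses` (per response: `test`, `ba`, `ratio` where applicable,
#'   `kappa`), and a `provenance` block (package version, config echo,
#'   per-fit convergence diagnostics).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  menv <- new.env(parent = emptyenv())
  menv$completed <- character(0)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  write_manifest <- function(status) {
    if (is.null(out_dir)) return(invisible())
    manifest <- list(status = status, completed_stages = menv$completed,
                     config = config_provenance(config),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  on.exit(write_manifest("incomplete"))

  tab <- stage("read", {
    if (is.character(config$input)) read_assessments(config$input)
    else validate_assessments(config$input)
  }, menv)
  pairs_view <- stage("pair", suppressMessages(pair_assessments(tab)), menv)
  cohort <- stage("summarize", summarize_cohort(tab), menv)
  icc <- stage("reliability", instrument_reliability(
    tab, include_residual = config$icc_include_residual,
    control = config$control), menv)

  diagnostics <- list()
  for (ins in INSTRUMENTS) {
    f <- attr(icc[[ins]], "fit")
    diagnostics[[paste0("reliability_", ins)]] <- fit_diagnostics(f)
  }

  responses <- list()
  for (resp in config$responses) {
    agr <- stage(paste0("agreement_", resp),
                 feature_agreement(tab, resp,
                                   scale_policy = config$scale_policy,
                                   control = config$control), menv)
    diagnostics[[paste0("agreement_", resp)]] <- fit_diagnostics(agr$fit)
    kap <- stage(paste0("kappa_", resp), {
      k <- cohen_kappa(dichotomize_pairs(agr$pairs, config$kappa_threshold))
      k$ci <- as.numeric(kappa_ci(tab, agr$fit, method = config$ci_method,
                                  B = config$B, seed = config$seed,
                                  threshold = config$kappa_threshold))
      k$label <- interpret_kappa(k$kappa)
      k
    }, menv)
    responses[[resp]] <- list(scale = agr$scale, test = agr$test,
                              ba = agr$ba, ratio = agr$ratio, kappa = kap)
    if (!is.null(out_dir))
      write_ba_points(agr$ba,
                      file.path(out_dir, paste0("ba_points_", resp, ".tsv")))
  }

  report <- list(cohort = cohort,
                 orphans = nrow(attr(pairs_view, "orphans")),
                 icc = icc,
                 responses = responses,
                 provenance = list(
                   package = "camagree",
                   version = as.character(packageVersion("camagree")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config = config_provenance(config),
                   diagnostics = diagnostics))
  class(report) <- "study_report"
  if (!is.null(out_dir)) {
    writeLines(render_report(report, "json"),
               file.path(out_dir, "report.json"))
    writeLines(render_report(report, "text"),
               file.path(out_dir, "report.txt"))
  }
  on.exit()
  write_manifest("complete")
  report
}

fit_diagnostics <- function(fit) {
  list(method = fit$method, converged = fit$converged,
       boundary = fit$boundary,
       boundary_upper = isTRUE(fit$boundary_upper), loglik = fit$loglik,
       gradient_norm = fit$gradient_norm, n_evaluations = fit$n_iter)
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory table>"
  cfg$control <- unclass(cfg$control)
  cfg$scale_policy <- as.list(cfg$scale_policy)
  cfg
}

report_to_list <- function(report) {
  resp_list <- lapply(report$responses, function(r) {
    out <- list(
      scale = r$scale,
      fixed_effect = list(estimate = r$test$estimate,
                          std_error = r$test$std_error,
                          ci = c(r$test$ci_low, r$test$ci_high),
                          p_value = r$test$p_value),
      bland_altman = list(mean_diff = r$ba$mean_diff,
                          mean_diff_ci = r$ba$mean_diff_ci,
                          sd_diff = r$ba$sd_diff, loa = r$ba$loa,
                          n = r$ba$n),
      kappa = list(kappa = r$kappa$kappa, ci = r$kappa$ci,
                   p_observed = r$kappa$p_observed,
                   p_expected = r$kappa$p_expected,
                   table2x2 = r$kappa$table2x2, label = r$kappa$label))
    if (!is.null(r$ratio))
      out$ratio <- list(ratio = r$ratio$ratio, ratio_ci = r$ratio$ratio_ci,
                        inverse_ratio = r$ratio$inverse_ratio,
                        inverse_ratio_ci = r$ratio$inverse_ratio_ci)
    out
  })
  list(cohort = unclass(report$cohort),
       orphan_occasions = report$orphans,
       icc = lapply(report$icc, function(ic)
         list(icc = ic$icc, sigma2_patient = ic$sigma2_patient,
              sigma2_rater = ic$sigma2_rater,
              includes_residual = ic$includes_residual)),
       responses = resp_list,
       provenance = report$provenance)
}

#' Render a study report
#'
#' @param report A [run_pipeline()] result.
#' @param format `"json"` or `"text"`.  The text view states each kappa
#'   with its interpretation label and each log-scale mean difference
#'   alongside its exp-transformed probability ratio; sections absent from
#'   the report are rendered with a "skipped" marker.
#' @return A character vector of lines (text) or a JSON string.
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, null = "null")))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Method agreement report: CAM vs 3D-CAM")
  add("=======================================")
  if (is.null(report$cohort)) {
    add("Cohort: skipped (no summary)")
  } else {
    co <- report$cohort
    add("Cohort: %d patients, %d concurrent assessment pairs, %d raters",
        co$n_patients, co$n_pairs, co$n_raters)
  }
  if (is.null(report$icc) || !length(report$icc)) {
    add("Interrater reliability: skipped")
  } else {
    for (ins in names(report$icc))
      add("Interrater reliability %s: ICC %.2f (patient share of latent variation)",
          ins, report$icc[[ins]]$icc)
  }
  if (is.null(report$responses) || !length(report$responses)) {
    add("Agreement analyses: skipped")
  } else {
    for (resp in names(report$responses)) {
      r <- report$responses[[resp]]
      add("")
      add("Response: %s (%s scale)", resp, r$scale)
      add("  method fixed-effect difference %.2f (95%% CI %.2f to %.2f), P = %.3g",
          r$test$estimate, r$test$ci_low, r$test$ci_high, r$test$p_value)
      add("  Bland-Altman mean difference (CAM - 3DCAM) %.2f (95%% CI %.2f to %.2f)",
          r$ba$mean_diff, r$ba$mean_diff_ci[1], r$ba$mean_diff_ci[2])
      if (!is.null(r$ratio))
        add("  probability of a positive CAM %.2f (95%% CI %.2f to %.2f) times the 3D-CAM; inverse %.2f (%.2f to %.2f)",
            r$ratio$ratio, r$ratio$ratio_ci[1], r$ratio$ratio_ci[2],
            r$ratio$inverse_ratio, r$ratio$inverse_ratio_ci[1],
            r$ratio$inverse_ratio_ci[2])
      if (is.null(r$kappa)) {
        add("  kappa: skipped")
      } else {
        ci_txt <- if (!is.null(r$kappa$ci))
          sprintf(" (95%% CI %.2f to %.2f)", r$kappa$ci[1], r$kappa$ci[2])
        else ""
        add("  Cohen kappa %.2f%s - %s agreement", r$kappa$kappa, ci_txt,
            r$kappa$label)
      }
    }
  }
  ln
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
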