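#!/usr/bin/env Rscript

# Method agreement, overall and per cardinal feature: the two-instrument
# agreement GLMM, per-patient latent pairs, repeated-measures Bland-Altman
# on the policy scale, and the probability-ratio transform for log-scale
# analyses.  Bland-Altman point clouds go to TSV for plotting.

library(camagree)

tab <- read_assessments("results/cohort.csv")
responses <- c("delirium", "acute_change", "inattention",
               "disorganized_thinking", "aloc")

out <- list()
for (resp in responses) {
  agr <- suppressMessages(feature_agreement(tab, resp))
  cat("\n==", resp, "(", agr$scale, "scale ) ==\n")
  print(agr$test)
  print(agr$ba)
  if (!is.null(agr$ratio)) print(agr$ratio)
  write_ba_points(agr$ba, sprintf("results/ba_points_%s.tsv", resp))
  out[[resp]] <- list(
    scale = agr$scale,
    fixed_effect = list(estimate = agr$test$estimate,
                        ci = c(agr$test$ci_low, agr$test$ci_high),
                        p_value = agr$test$p_value),
    mean_diff = agr$ba$mean_diff, mean_diff_ci = agr$ba$mean_diff_ci,
    loa = agr$ba$loa,
    ratio = if (!is.null(agr$ratio)) agr$ratio$ratio)
}

jsonlite::write_json(out, "results/agreement.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nWritten to results/agreement.json (+ per-response TSV point files)\n")
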