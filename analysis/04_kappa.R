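#!/usr/bin/env Rscript

# Chance-corrected agreement: the per-patient latent pairs are dichotomized
# at 0.5 and summarized with Cohen kappa, a patient-resampling bootstrap CI,
# and the over-0.75-substantial interpretation bands.

library(camagree)

tab <- read_assessments("results/cohort.csv")
responses <- c("delirium", "acute_change", "inattention",
               "disorganized_thinking", "aloc")

out <- list()
for (resp in responses) {
  agr <- suppressMessages(feature_agreement(tab, resp))
  k <- cohen_kappa(dichotomize_pairs(agr$pairs))
  k$ci <- as.numeric(kappa_ci(tab, agr$fit, B = 2000, seed = 1))
  cat("\n==", resp, "==\n")
  print(k)
  out[[resp]] <- list(kappa = k$kappa, ci = k$ci, label = k$label,
                      table2x2 = k$table2x2)
}

jsonlite::write_json(out, "results/kappa.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nWritten to results/kappa.json\n")
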