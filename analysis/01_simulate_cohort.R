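#!/usr/bin/env Rscript
# Simulate the study cohort: 355 adolescents answering the 23-item health
# literacy battery (6 functional + 10 interactive dichotomous items, 7
# critical items with 5 partial-credit), with a left-skewed ability
# distribution, demographic covariates, two criterion behaviors, and a
# 6-item convergent screener. Writes the input tables every later step reads.

suppressPackageStartupMessages(library(raschval))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_config(seed = 20220325))

write_responses(cohort$responses, file.path(out, "responses.csv"))
write_item_specs(cohort$responses$specs, file.path(out, "item_specs.csv"))
write.csv(cohort$covariates, file.path(out, "covariates.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = cohort$truth$seed,
       difficulty = as.list(cohort$truth$difficulty),
       thresholds = cohort$truth$thresholds,
       scale = as.list(cohort$truth$scale)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

raw <- raw_totals(cohort$responses)
cat(sprintf("simulated %d persons x %d items -> %s\n",
            nrow(cohort$responses$scores), ncol(cohort$responses$scores), out))
cat(sprintf("composite raw scores: mean %.1f, sd %.1f (attainable 0-30)\n",
            mean(raw), sd(raw)))
cat(sprintf("screener scores: mean %.1f; behavior prevalences: %s\n",
            mean(cohort$covariates$nvs_score),
            paste(sprintf("%s %.0f%%", c("questions online", "reads instructions"),
                          100 * colMeans(cohort$covariates[, c("beh_questions_online",
                                                               "beh_reads_instructions")])),
                  collapse = ", ")))
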