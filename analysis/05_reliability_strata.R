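#!/usr/bin/env Rscript
# Reliability and performance levels: item-separation reliability and KR-20
# per scale, then the Wright strata walk on each score-to-measure table
# (SEs inflated 10%, new level when a score sits two joint SEs above the
# current level's first score), giving raw-score cutoffs and the
# sample-independent reliability n^2/(1+n^2).

suppressPackageStartupMessages(library(raschval))

out <- "results"
cohort_dir <- file.path(out, "cohort")
specs <- read_item_specs(file.path(cohort_dir, "item_specs.csv"))
responses <- read_responses(file.path(cohort_dir, "responses.csv"), specs)
truth <- jsonlite::fromJSON(file.path(cohort_dir, "truth.json"))
scale_of <- unlist(truth$scale)

summary_rows <- list()
for (sc in c("fhl", "ihl", "chl", "composite")) {
  sub <- if (sc == "composite") responses else
    subset_responses(responses, items = names(scale_of)[scale_of == sc])
  cal <- estimate_jmle(sub)
  st <- score_to_measure_table(cal)
  strata <- wright_strata(st)
  write_strata(strata, file.path(out, paste0("strata_", sc, ".json")))
  cuts <- paste(sprintf("%s %d-%d", strata$level_cutoffs$label,
                        strata$level_cutoffs$min_score,
                        strata$level_cutoffs$max_score), collapse = "; ")
  cat(sprintf("%s: item separation %.2f, KR-20 %.2f, %d level(s) [%s], sample-independent reliability %.2f\n",
              toupper(sc), item_separation_reliability(cal), kr20(sub),
              strata$n_levels, cuts, strata$sample_independent_reliability))
  summary_rows[[sc]] <- data.frame(
    scale = sc,
    item_separation = item_separation_reliability(cal),
    person_separation = person_separation_reliability(cal),
    kr20 = kr20(sub),
    n_levels = strata$n_levels,
    sample_independent_reliability = strata$sample_independent_reliability)
}
write.csv(do.call(rbind, summary_rows), file.path(out, "reliability.csv"),
          row.names = FALSE)
cat("reliability table ->", file.path(out, "reliability.csv"), "\n")
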