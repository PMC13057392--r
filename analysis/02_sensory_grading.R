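#!/usr/bin/env Rscript
# Stage 2 -- fuzzy-mathematics sensory grading.
#
# Derives criterion weights from a strict pairwise-importance ranking of the
# four appearance criteria (sectional color > chrysanthemum pattern >
# oil spots > number per kilogram), converts the evaluator counts of stage 1
# into membership matrices, and scores every batch as B = w'MV with level
# values (90, 70, 50, 30). Scores of 60-80 band as Grade I, 40-60 as
# Grade II.

library(amrgrade)

counts_path <- file.path("results", "data", "evaluator_counts.csv")
counts <- readr::read_csv(counts_path, show_col_types = FALSE)

w <- binary_comparison_weights(ranking_wins(c(
  "sectional_color", "chrysanthemum_pattern", "oil_spots", "number_per_kg"
)))
cat("Criterion weights:\n")
print(round(w, 3))

scores <- score_batches(counts, w = w, panel_size = 10L)
readr::write_csv(scores, file.path("results", "sensory_scores.csv"))

grp <- sub("-[0-9]+$", "", scores$batch_id)
cat("\nScore range by group:\n")
print(vapply(split(scores$score, grp), range, numeric(2)))
zj <- scores$score[grp == "ZJ"]
cat(sprintf("\n%d/%d ZJ batches score inside 70-80, the genuine-origin band.\n",
            sum(zj >= 70 & zj <= 80), length(zj)))
print(table(grp, scores$grade))
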