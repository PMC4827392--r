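#!/usr/bin/env Rscript
# Head-to-head cross-validation of the non-local PLSR model against the
# local patch baseline, under two planted regimes:
#   - disjoint x/y component supports (non-local correlation): PLSR should
#     dominate, since no local patch carries information about the target;
#   - coincident supports (purely local correlation): the patch baseline
#     becomes competitive and the gap shrinks.
# Each repeat draws a fresh stratified 60-subject training set, fits both
# models on it, and evaluates regional absolute error on the 60 held-out
# subjects, with a paired t-test across subjects.

library(nonlocalpls)

out_dir <- "results/model_comparison"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

run_condition <- function(coincident, label, seed0) {
  rows <- lapply(1:3, function(r) {
    spec <- phantom_spec(subjects_per_group = c(40L, 40L, 40L),
                         seed = seed0 + r)
    if (coincident) spec$component_centers_y <- spec$component_centers_x
    cohort <- sample_cohort(spec)
    cfg <- experiment_config(train_per_group = c(20L, 20L, 20L),
                             n_components = 10L, n_repeats = 1L,
                             seed = seed0 + r)
    tab <- run_experiment(cohort, cfg)$mae_table
    cbind(condition = label, tab)
  })
  do.call(rbind, rows)
}

tab <- rbind(run_condition(FALSE, "disjoint (non-local)", 100L),
             run_condition(TRUE, "coincident (local)", 200L))
write.csv(tab, file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
print(tab[, c("condition", "plsr_mae", "pm_mae", "p_value",
              "cor_plsr", "cor_pm")], row.names = FALSE)

cat("\nmean regional MAE gap (PM - PLSR):\n")
for (cond in unique(tab$condition))
  cat(sprintf("  %-22s %.4f\n", cond,
              mean(tab$pm_mae[tab$condition == cond] -
                   tab$plsr_mae[tab$condition == cond])))
cat("correlation with the noiseless reference regional values follows",
    "the same pattern (cor_plsr vs cor_pm columns)\n")
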