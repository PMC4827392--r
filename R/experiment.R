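#' Configuration of the cross-validation experiment
#'
#' Bundles the design parameters of a repeated stratified train/test
#' experiment: per-group training counts, latent dimension, repeat count,
#' master seed, patch-baseline parameters and the group comparisons for the
#' discriminability analysis. Per-repeat seeds are derived deterministically
#' from the master seed so repeats are independent yet reproducible.
#'
#' @param train_per_group Integer vector of subjects drawn per group for
#'   training (recycled across groups if length 1).
#' @param n_components Latent dimension of the PLSR fit.
#' @param n_repeats Number of repeats with different training draws.
#' @param seed Master seed.
#' @param patch_side,search_radius,aggregate Patch-baseline parameters, see
#'   [build_patch_db()] / [synthesize_target()].
#' @param comparisons List of ordered label pairs for the LDA analysis;
#'   `NULL` derives all pairwise comparisons from the data.
#' @param top_k Number of top discriminative components kept per repeat.
#' @param match_threshold Absolute-correlation threshold for cross-repeat
#'   component matching.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(train_per_group = c(20L, 20L, 20L),
                              n_components = 10L,
                              n_repeats = 3L,
                              seed = 1L,
                              patch_side = 5L,
                              search_radius = 0L,
                              aggregate = c("center", "mean"),
                              comparisons = NULL,
                              top_k = 5L,
                              match_threshold = 0.5) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(train_per_group = as.integer(train_per_group),
                 n_components = as.integer(n_components),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 patch_side = as.integer(patch_side),
                 search_radius = as.integer(search_radius),
                 aggregate = match.arg(aggregate),
                 comparisons = comparisons,
                 top_k = as.integer(top_k),
                 match_threshold = match_threshold),
            class = "experiment_config")
}

stratified_train_indices <- function(labels, train_per_group) {
  lev <- levels(labels)
  npg <- rep_len(train_per_group, length(lev))
  idx <- integer(0)
  for (g in seq_along(lev)) {
    pool <- which(labels == lev[g])
    if (length(pool) <= npg[g])
      stop("group '", lev[g], "' has ", length(pool),
           " subjects; need more than train_per_group = ", npg[g])
    idx <- c(idx, sample(pool, npg[g]))
  }
  sort(idx)
}

# Noiseless reference regional values for phantom cohorts: regional means of
# the planted Y-modality signal (the stand-in for independently reported
# reference uptake values).
truth_reference_regional <- function(truth, idx, atlas, mask) {
  signal_y <- truth$loadings[idx, , drop = FALSE] %*% t(truth$components_y)
  regional_means(signal_y, atlas, mask)
}

run_one_repeat <- function(dataset, truth, atlas, config, repeat_index) {
  set.seed(derive_seed(config$seed, repeat_index))
  train_idx <- stratified_train_indices(dataset$group_labels,
                                        config$train_per_group)
  test_idx <- setdiff(seq_len(n_subjects(dataset)), train_idx)
  train <- subset_subjects(dataset, train_idx)
  test <- subset_subjects(dataset, test_idx)
  if (config$n_components > n_subjects(train) - 1L)
    stop("n_components must be <= training size - 1")

  model <- fit_pls(center_dataset(train), config$n_components)
  yhat_pls <- predict(model, test$X)
  db <- build_patch_db(train, config$patch_side, config$search_radius)
  yhat_pm <- synthesize_target(test$X, db, config$aggregate)$yhat

  rep_pls <- regional_report(yhat_pls, test$Y, atlas, dataset$mask)
  rep_pm <- regional_report(yhat_pm, test$Y, atlas, dataset$mask)
  mae_test <- paired_error_test(rep_pls$mean_abs_error, rep_pm$mean_abs_error)

  reference <- NULL
  cor_pls <- cor_pm <- NULL
  if (!is.null(truth)) {
    reference <- truth_reference_regional(truth, test_idx, atlas, dataset$mask)
    cor_pls <- correlation_with_reference(as.vector(rep_pls$predicted),
                                          as.vector(reference))
    cor_pm <- correlation_with_reference(as.vector(rep_pm$predicted),
                                         as.vector(reference))
  }

  scores_test <- project_scores(model, test$X)
  comparisons <- config$comparisons %||%
    utils::combn(levels(dataset$group_labels), 2L, simplify = FALSE)
  disc <- lapply(comparisons, function(pair) {
    tryCatch(lda_loo_auc(scores_test, test$group_labels, pair),
             error = function(e) structure(list(comparison = pair,
                                                error = conditionMessage(e)),
                                           class = "discriminability_skipped"))
  })
  names(disc) <- vapply(comparisons, paste, "", collapse = "_vs_")

  list(repeat_index = repeat_index,
       seed = derive_seed(config$seed, repeat_index),
       train_idx = train_idx, test_idx = test_idx,
       model = model,
       maps = rbind(model$W, model$C),
       regional_pls = rep_pls, regional_pm = rep_pm,
       mae_test = mae_test,
       cor_pls = cor_pls, cor_pm = cor_pm,
       discriminability = disc,
       test_labels = test$group_labels)
}

#' Run the repeated cross-validation experiment
#'
#' For each repeat: draws a stratified training set without replacement,
#' fits the PLSR model and builds the patch database on the *same* training
#' subjects, predicts the held-out subjects with both methods, summarises
#' regional absolute errors (with a paired t-test between methods),
#' correlates predicted regional values with the phantom's noiseless
#' reference values when ground truth is available, and runs leave-one-out
#' LDA discriminability of the held-out latent scores per group comparison.
#' After all repeats, the top discriminative components are matched across
#' repeats to quantify their reproducibility.
#'
#' @param cohort A list with `dataset` (and optionally `truth`) as returned
#'   by [sample_cohort()], or a bare [multimodal_dataset()].
#' @param config An [experiment_config()].
#' @param atlas Region-label atlas volume; defaults to the phantom truth
#'   atlas when available.
#' @param out_dir Optional directory: result tables are written as CSV.
#' @return An object of class `experiment_result`: per-repeat results,
#'   summary tables (`mae_table`, `auc_table`, `effect_table`) and
#'   per-comparison reproducibility counts.
#' @export
run_experiment <- function(cohort, config, atlas = NULL, out_dir = NULL) {
  if (inherits(cohort, "multimodal_dataset"))
    cohort <- list(dataset = cohort, truth = NULL)
  dataset <- cohort$dataset
  truth <- cohort$truth
  if (is.null(atlas)) {
    if (is.null(truth)) stop("an atlas is required when no truth is available")
    atlas <- truth$atlas
  }

  repeats <- lapply(seq_len(config$n_repeats), function(r)
    run_one_repeat(dataset, truth, atlas, config, r))

  mae_table <- do.call(rbind, lapply(repeats, function(r)
    data.frame(repeat_index = r$repeat_index,
               plsr_mae = mean(r$regional_pls$mean_abs_error),
               pm_mae = mean(r$regional_pm$mean_abs_error),
               t_statistic = r$mae_test$statistic,
               p_value = r$mae_test$p,
               cor_plsr = if (is.null(r$cor_pls)) NA_real_ else r$cor_pls$r,
               cor_pm = if (is.null(r$cor_pm)) NA_real_ else r$cor_pm$r)))

  auc_rows <- list(); eff_rows <- list()
  for (r in repeats) {
    for (nm in names(r$discriminability)) {
      d <- r$discriminability[[nm]]
      if (inherits(d, "discriminability_skipped")) next
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        repeat_index = r$repeat_index, comparison = nm, auc = d$auc,
        top_components = paste(d$top_components, collapse = ";"))
      pair <- d$comparison
      ga <- r$test_labels == pair[1]; gb <- r$test_labels == pair[2]
      for (method in c("plsr", "pm")) {
        vals <- rowMeans(if (method == "plsr") r$regional_pls$predicted
                         else r$regional_pm$predicted)
        eff_rows[[length(eff_rows) + 1L]] <- data.frame(
          repeat_index = r$repeat_index, comparison = nm, method = method,
          effect_size = effect_size(vals[ga], vals[gb]))
      }
    }
  }
  auc_table <- if (length(auc_rows)) do.call(rbind, auc_rows) else NULL
  effect_table <- if (length(eff_rows)) do.call(rbind, eff_rows) else NULL

  reproducibility <- NULL
  if (config$n_repeats >= 2L && !is.null(auc_table)) {
    comps <- unique(auc_table$comparison)
    reproducibility <- lapply(stats::setNames(nm = comps), function(nm) {
      rr <- lapply(repeats, function(r) {
        d <- r$discriminability[[nm]]
        if (inherits(d, "discriminability_skipped")) NULL
        else list(maps = r$maps, top = d$top_components)
      })
      rr <- Filter(Negate(is.null), rr)
      if (length(rr) < 2L) return(NULL)
      reproducibility_counts(rr, reference = 1L,
                             threshold = config$match_threshold)
    })
  }

  out <- structure(list(config = config, repeats = repeats,
                        mae_table = mae_table, auc_table = auc_table,
                        effect_table = effect_table,
                        reproducibility = reproducibility),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", x$config$n_repeats, "repeats,",
      x$config$n_components, "components\n\n")
  print(x$mae_table, row.names = FALSE)
  if (!is.null(x$auc_table)) { cat("\n"); print(x$auc_table, row.names = FALSE) }
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$mae_table,
                   file.path(out_dir, "model_comparison.csv"), row.names = FALSE)
  if (!is.null(result$auc_table))
    utils::write.csv(result$auc_table,
                     file.path(out_dir, "discriminability.csv"), row.names = FALSE)
  if (!is.null(result$effect_table))
    utils::write.csv(result$effect_table,
                     file.path(out_dir, "effect_sizes.csv"), row.names = FALSE)
  if (!is.null(result$reproducibility)) {
    rows <- list()
    for (nm in names(result$reproducibility)) {
      rc <- result$reproducibility[[nm]]
      if (is.null(rc)) next
      rows[[nm]] <- data.frame(comparison = nm,
                               component = seq_along(rc$counts),
                               count = rc$counts, n_repeats = rc$n_repeats)
    }
    if (length(rows))
      utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
                       file.path(out_dir, "reproducibility.csv"),
                       row.names = FALSE)
  }
  cfg <- result$config
  writeLines(paste0(names(unclass(cfg)), " = ",
                    vapply(unclass(cfg), function(v)
                      paste(format(unlist(v) %||% "NULL"), collapse = " "), "")),
             file.path(out_dir, "config.txt"))
  seeds <- data.frame(repeat_index = vapply(result$repeats, `[[`, 0L, "repeat_index"),
                      seed = vapply(result$repeats, `[[`, 0L, "seed"))
  utils::write.csv(seeds, file.path(out_dir, "seeds.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Patch baseline with a leave-one-out atlas database
#'
#' The non-parametric counterpart of the full experiment: every subject in
#' the cohort is synthesised from all remaining subjects, and the same
#' regional evaluation is produced.
#'
#' @param cohort A list with `dataset` (and optionally `truth`), or a bare
#'   [multimodal_dataset()].
#' @param config An [experiment_config()] (patch parameters are used).
#' @param atlas Region-label atlas; defaults to the truth atlas.
#' @return List with `yhat`, the [regional_report()], per-group error maps
#'   and (when truth is available) the correlation with the noiseless
#'   reference regional values.
#' @export
run_pm_loo <- function(cohort, config, atlas = NULL) {
  if (inherits(cohort, "multimodal_dataset"))
    cohort <- list(dataset = cohort, truth = NULL)
  dataset <- cohort$dataset
  truth <- cohort$truth
  if (is.null(atlas)) {
    if (is.null(truth)) stop("an atlas is required when no truth is available")
    atlas <- truth$atlas
  }
  syn <- leave_one_out_synthesis(dataset, config$patch_side,
                                 config$search_radius, config$aggregate)
  rep_pm <- regional_report(syn$yhat, dataset$Y, atlas, dataset$mask)
  cor_pm <- NULL
  if (!is.null(truth)) {
    reference <- truth_reference_regional(truth, seq_len(n_subjects(dataset)),
                                          atlas, dataset$mask)
    cor_pm <- correlation_with_reference(as.vector(rep_pm$predicted),
                                         as.vector(reference))
  }
  list(yhat = syn$yhat, winner = syn$winner, regional = rep_pm,
       error_maps = absolute_error_map(syn$yhat, dataset$Y,
                                       dataset$group_labels),
       cor_reference = cor_pm)
}
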