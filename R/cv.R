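#' Grouped cross-validation configuration
#'
#' Folds partition whole cases (patients), so no slice from a validation
#' case ever enters training — the leakage-safe reading of per-set
#' splitting. With as many folds as cases this is leave-one-case-out.
#' Pooling is by summed confusion counts (a single pooled confusion matrix,
#' not the mean of fold metrics).
#'
#' @param k Number of folds; must not exceed the number of cases.
#' @param seed Master seed; per-fold model seeds derive from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 14L, seed = 1L) {
  check_scalar_num(k, "k", lower = 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' Assign groups to folds
#'
#' Deterministically shuffles the (sorted) unique group ids with the
#' configured seed and deals them round-robin, so fold sizes differ by at
#' most one, every group lands in exactly one validation fold, and the
#' assignment is invariant to the input order of `group_ids`.
#'
#' @param group_ids Character/factor vector of group (case) ids, one per
#'   observation or unique.
#' @param cfg A [cv_config()].
#' @return A tibble `(group_id, fold)` with one row per unique group.
#' @export
make_folds <- function(group_ids, cfg = cv_config()) {
  groups <- sort(unique(as.character(group_ids)))
  if (length(groups) < cfg$k) {
    stop_rcm(sprintf("Need at least k = %d groups; got %d.",
                     cfg$k, length(groups)), "too_few_groups")
  }
  shuffled <- withr::with_seed(cfg$seed, sample(groups))
  tibble::tibble(group_id = shuffled,
                 fold = rep(seq_len(cfg$k), length.out = length(groups))) |>
    dplyr::arrange(.data$group_id)
}

pad_mask_like <- function(mask, cfg) {
  if (cfg$evaluate_on_padded_canvas) mirror_pad(mask, cfg) else mask
}

#' Run the full grouped cross-validation pipeline
#'
#' For each fold: tile the training cases into labelled patches, train a
#' fresh patch classifier (per-fold seed derived from the master seed),
#' expand it into a dense predictor, predict and postprocess every
#' validation slice, and tally pixel confusion counts and per-slice lesion
#' recalls. Validation cases are never visible during training (asserted).
#' Pooled metrics come from the summed counts; stack and case detection
#' rates from the per-slice recalls.
#'
#' @param dataset A dataset tibble from [generate_dataset()].
#' @param spec A [backbone_spec()].
#' @param rule A [patch_rule()].
#' @param train_cfg A [train_config()].
#' @param augment An [augment_config()] or `NULL`.
#' @param expansion_cfg An [expansion_config()]. When
#'   `evaluate_on_padded_canvas` is set (default), truth masks are padded
#'   with the same mirror geometry as the images.
#' @param post_cfg A [postprocess_config()].
#' @param cv_cfg A [cv_config()].
#' @param criteria A [stack_criteria()].
#' @return An `rcm_cv` object: per-fold table, per-slice table, pooled
#'   counts/metrics and detection rates. `tidy()` gives per-fold metrics,
#'   `glance()` the pooled summary.
#' @export
run_cv <- function(dataset, spec = tiny_backbone_spec(),
                   rule = patch_rule(), train_cfg = train_config(),
                   augment = NULL, expansion_cfg = expansion_config(),
                   post_cfg = postprocess_config(), cv_cfg = cv_config(),
                   criteria = stack_criteria()) {
  folds <- make_folds(dataset$case_id, cv_cfg)
  fold_rows <- list()
  slice_rows <- list()
  for (f in seq_len(cv_cfg$k)) {
    val_cases <- folds$group_id[folds$fold == f]
    train_cases <- folds$group_id[folds$fold != f]
    if (length(intersect(train_cases, val_cases)) > 0) {
      stop_rcm(sprintf("fold %d: train/validation groups overlap", f),
               "leakage")
    }
    train_data <- dataset[dataset$case_id %in% train_cases, ]
    val_data <- dataset[dataset$case_id %in% val_cases, ]
    patches <- tile_dataset(train_data, rule)
    fold_train_cfg <- train_cfg
    fold_train_cfg$seed <- derive_seed(cv_cfg$seed, f, 11L)
    model <- tryCatch({
      m <- build_patch_model(spec, seed = derive_seed(cv_cfg$seed, f, 7L),
                             patch_size = rule$patch_size)
      train_patch_model(m, patches, fold_train_cfg, augment = augment)
    }, error = function(e) {
      stop_rcm(sprintf("fold %d failed during training: %s", f,
                       conditionMessage(e)), "fold_failed")
    })
    dense <- expand_model(model, expansion_cfg)
    fold_counts <- list()
    for (i in seq_len(nrow(val_data))) {
      hm <- predict_heatmap(dense, val_data$image[[i]])
      if (!expansion_cfg$evaluate_on_padded_canvas) hm <- crop_heatmap(hm)
      pred <- run_postprocess(hm, post_cfg)
      truth <- pad_mask_like(val_data$mask[[i]], expansion_cfg)
      cc <- confusion_counts(pred, truth)
      fold_counts[[length(fold_counts) + 1L]] <- cc
      slice_rows[[length(slice_rows) + 1L]] <- tibble::tibble(
        fold = f, case_id = val_data$case_id[i],
        stack_id = val_data$stack_id[i],
        slice_index = val_data$slice_index[i],
        tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
        recall = slice_lesion_recall(pred, truth)
      )
    }
    fc <- sum_counts(fold_counts)
    pm <- pixel_metrics(fc)
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      train_cases = list(sort(train_cases)),
      val_cases = list(sort(val_cases)),
      n_train_patches = nrow(patches),
      n_val_slices = nrow(val_data),
      tp = fc$tp, fp = fc$fp, tn = fc$tn, fn = fc$fn,
      sensitivity = pm$sensitivity, specificity = pm$specificity
    )
  }
  slices <- dplyr::bind_rows(slice_rows)
  pooled_counts <- sum_counts(lapply(fold_rows, function(r)
    new_confusion_counts(r$tp, r$fp, r$tn, r$fn)))
  rates <- aggregate_rates(slices, criteria)
  structure(
    list(folds = dplyr::bind_rows(fold_rows),
         slices = slices,
         pooled_counts = pooled_counts,
         pooled_metrics = pixel_metrics(pooled_counts),
         stacks = rates$stacks, cases = rates$cases,
         stack_rate = rates$stack_rate, case_rate = rates$case_rate,
         criteria = criteria, cv_cfg = cv_cfg),
    class = "rcm_cv"
  )
}

#' @export
print.rcm_cv <- function(x, ...) {
  cat(sprintf("<rcm_cv> %d folds, %d validation slices\n",
              nrow(x$folds), nrow(x$slices)))
  cat(sprintf("  pooled sensitivity %.3f, specificity %.3f\n",
              x$pooled_metrics$sensitivity, x$pooled_metrics$specificity))
  cat(sprintf("  stack detection rate %.2f, case detection rate %.2f\n",
              x$stack_rate, x$case_rate))
  invisible(x)
}

#' @export
tidy.rcm_cv <- function(x, ...) {
  dplyr::select(x$folds, "fold", "n_train_patches", "n_val_slices",
                "tp", "fp", "tn", "fn", "sensitivity", "specificity")
}

#' @export
glance.rcm_cv <- function(x, ...) {
  tibble::tibble(
    k = x$cv_cfg$k,
    sensitivity = x$pooled_metrics$sensitivity,
    specificity = x$pooled_metrics$specificity,
    stack_rate = x$stack_rate,
    case_rate = x$case_rate,
    tp = x$pooled_counts$tp, fp = x$pooled_counts$fp,
    tn = x$pooled_counts$tn, fn = x$pooled_counts$fn
  )
}
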