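#' Pixel-level confusion counts
#'
#' Tallies TP (both masks malignant), FP (predicted malignant, truth
#' healthy), TN (both healthy) and FN (predicted healthy, truth malignant)
#' over aligned binary masks. Counts always sum to the number of evaluated
#' pixels.
#'
#' @param pred,truth Binary 0/1 matrices of equal shape (1 = malignant).
#' @return A `confusion_counts` object (fields `tp`, `fp`, `tn`, `fn`).
#' @export
confusion_counts <- function(pred, truth) {
  check_binary_matrix(pred, "pred")
  check_binary_matrix(truth, "truth")
  if (!identical(dim(pred), dim(truth))) {
    stop_rcm("`pred` and `truth` must have identical shapes.", "bad_shape")
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  new_confusion_counts(tp, fp, tn, fn)
}

#' @rdname confusion_counts
#' @param tp,fp,tn,fn Non-negative pixel tallies (e.g. published totals).
#' @export
new_confusion_counts <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(vals < 0) || any(!is.finite(vals))) {
    stop_rcm("Confusion counts must be finite and non-negative.", "bad_arg")
  }
  structure(as.list(vals), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %s  FP %s  TN %s  FN %s (total %s)\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$tn, big.mark = ","), format(x$fn, big.mark = ","),
              format(x$tp + x$fp + x$tn + x$fn, big.mark = ",")))
  invisible(x)
}

#' Sum confusion counts
#'
#' @param ... `confusion_counts` objects (or a list of them).
#' @return Their element-wise sum.
#' @export
sum_counts <- function(...) {
  items <- list(...)
  if (length(items) == 1L && !inherits(items[[1]], "confusion_counts")) {
    items <- items[[1]]
  }
  new_confusion_counts(
    sum(vapply(items, `[[`, numeric(1), "tp")),
    sum(vapply(items, `[[`, numeric(1), "fp")),
    sum(vapply(items, `[[`, numeric(1), "tn")),
    sum(vapply(items, `[[`, numeric(1), "fn"))
  )
}

#' Headline pixel metrics from confusion counts
#'
#' Sensitivity is `TP / (TP + FN)`, specificity `TN / (TN + FP)` (the
#' proportion of truly healthy pixels predicted healthy). The
#' row-normalised confusion matrix has rows (truth = healthy, truth =
#' malignant) and columns (predicted healthy, predicted malignant), each
#' row summing to 1. A metric whose denominator is zero is returned as `NA`
#' with the `undefined` field naming it — never silently 0 or 1.
#'
#' @param counts A `confusion_counts` object.
#' @return A `pixel_metrics` object: `sensitivity`, `specificity`,
#'   `row_normalized` (2x2 matrix), `undefined` (character vector).
#' @export
pixel_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  undefined <- character(0)
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  sens <- if (pos > 0) counts$tp / pos else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (neg > 0) counts$tn / neg else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  rn <- matrix(NA_real_, 2, 2,
               dimnames = list(truth = c("healthy", "malignant"),
                               predicted = c("healthy", "malignant")))
  if (neg > 0) rn[1, ] <- c(counts$tn, counts$fp) / neg
  if (pos > 0) rn[2, ] <- c(counts$fn, counts$tp) / pos
  structure(list(sensitivity = sens, specificity = spec,
                 row_normalized = rn, counts = counts,
                 undefined = undefined),
            class = "pixel_metrics")
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("<pixel_metrics> sensitivity %.3f  specificity %.3f\n",
              x$sensitivity, x$specificity))
  print(round(x$row_normalized, 3))
  if (length(x$undefined)) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.pixel_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity"),
    estimate = c(x$sensitivity, x$specificity)
  )
}

#' @export
glance.pixel_metrics <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 tp = x$counts$tp, fp = x$counts$fp, tn = x$counts$tn,
                 fn = x$counts$fn)
}

#' Per-slice lesion recall
#'
#' The fraction of a slice's true lesion pixels recovered by the predicted
#' mask, `TP / (TP + FN)` on that slice alone. Slices without lesion pixels
#' have no defined recall and return `NA` (they are excluded from the
#' stack criterion).
#'
#' @param pred,truth Aligned binary masks.
#' @return A fraction in `[0, 1]`, or `NA` for a lesion-free truth mask.
#' @export
slice_lesion_recall <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  pos <- cc$tp + cc$fn
  if (pos == 0) return(NA_real_)
  cc$tp / pos
}

#' Stack- and case-level detection criteria
#'
#' A stack counts as detected when the model recovers at least
#' `lesion_recall_threshold` (default 40%) of the lesion pixels in at least
#' `min_positive_slices` (default 3) of its slices; comparison with the
#' threshold is inclusive. A case counts as detected when at least one of
#' its stacks is detected.
#'
#' @param lesion_recall_threshold Per-slice recall needed for a slice to
#'   count, in (0, 1].
#' @param min_positive_slices Minimum number of qualifying slices.
#' @return A `stack_criteria` list.
#' @export
stack_criteria <- function(lesion_recall_threshold = 0.40,
                           min_positive_slices = 3L) {
  check_scalar_num(lesion_recall_threshold, "lesion_recall_threshold",
                   lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_num(min_positive_slices, "min_positive_slices", lower = 1)
  structure(list(lesion_recall_threshold = lesion_recall_threshold,
                 min_positive_slices = as.integer(min_positive_slices)),
            class = "stack_criteria")
}

#' @rdname stack_criteria
#' @param recalls Per-slice lesion recalls of one stack (`NA` for
#'   lesion-free slices).
#' @param criteria A [stack_criteria()].
#' @return `stack_detected()`: `TRUE`/`FALSE`, or `NA` when no slice in the
#'   stack is evaluable (non-evaluable stacks are excluded from rates).
#' @export
stack_detected <- function(recalls, criteria = stack_criteria()) {
  evaluable <- recalls[!is.na(recalls)]
  if (length(evaluable) == 0L) return(NA)
  sum(evaluable >= criteria$lesion_recall_threshold) >=
    criteria$min_positive_slices
}

#' @rdname stack_criteria
#' @param stack_flags Logical detection flags of one case's stacks (`NA` =
#'   non-evaluable stack).
#' @return `case_detected()`: `TRUE` iff any evaluable stack is detected;
#'   `NA` when no stack is evaluable.
#' @export
case_detected <- function(stack_flags) {
  evaluable <- stack_flags[!is.na(stack_flags)]
  if (length(evaluable) == 0L) return(NA)
  any(evaluable)
}

#' Aggregate detection rates over a per-slice result table
#'
#' Applies the stack criterion per (case, stack), the case criterion per
#' case, and reports the fractions of evaluable stacks and cases detected.
#'
#' @param slice_results Tibble with `case_id`, `stack_id` and per-slice
#'   `recall` columns (as produced by [run_cv()]).
#' @param criteria A [stack_criteria()].
#' @return A list: `stacks` and `cases` tibbles with detection flags, and
#'   scalar `stack_rate`, `case_rate` (detected / evaluable).
#' @export
aggregate_rates <- function(slice_results, criteria = stack_criteria()) {
  stacks <- slice_results |>
    dplyr::group_by(.data$case_id, .data$stack_id) |>
    dplyr::summarise(
      n_slices = dplyr::n(),
      n_evaluable = sum(!is.na(.data$recall)),
      detected = stack_detected(.data$recall, criteria),
      .groups = "drop"
    )
  cases <- stacks |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(detected = case_detected(.data$detected),
                     .groups = "drop")
  list(
    stacks = stacks,
    cases = cases,
    stack_rate = mean(stacks$detected, na.rm = TRUE),
    case_rate = mean(cases$detected, na.rm = TRUE)
  )
}
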