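test_that("confusion counts behave on degenerate mask pairs", {
  ones <- matrix(1L, 10, 10)
  cc <- confusion_counts(ones, ones)
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(100L, 0L, 0L, 0L))
  cc2 <- confusion_counts(1L - ones, ones)
  expect_identical(cc2$tp, 0L)
  expect_identical(cc2$tn, 0L)
  expect_error(confusion_counts(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               class = "rcmseg_bad_shape")
  expect_error(confusion_counts(matrix(0.2, 3, 3), matrix(0L, 3, 3)),
               class = "rcmseg_bad_mask")
})

test_that("confusion counts equal a naive double-loop tally", {
  tally <- function(pred, truth) {
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(ncol(pred))) {
        if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
        else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
        else if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1L
        else fn <- fn + 1L
      }
    }
    c(tp, fp, tn, fn)
  }
  withr::with_seed(15L, {
    for (rep in 1:20) {
      pred <- matrix(rbinom(256, 1, runif(1)), 16, 16)
      truth <- matrix(rbinom(256, 1, runif(1)), 16, 16)
      cc <- confusion_counts(pred, truth)
      expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), tally(pred, truth))
      expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 256L)
    }
  })
})

test_that("pooling counts over slices equals confusion on concatenation", {
  withr::with_seed(8L, {
    preds <- replicate(4, matrix(rbinom(64, 1, 0.3), 8, 8),
                       simplify = FALSE)
    truths <- replicate(4, matrix(rbinom(64, 1, 0.4), 8, 8),
                        simplify = FALSE)
  })
  summed <- sum_counts(purrr::map2(preds, truths, confusion_counts))
  concat <- confusion_counts(do.call(rbind, preds), do.call(rbind, truths))
  expect_equal(unlist(summed), unlist(concat), ignore_attr = TRUE)
})

test_that("sensitivity and specificity follow their defining ratios", {
  pm <- pixel_metrics(new_confusion_counts(tp = 30, fp = 10, tn = 40,
                                           fn = 20))
  expect_equal(pm$sensitivity, 30 / 50)
  expect_equal(pm$specificity, 40 / 50)
  expect_equal(rowSums(pm$row_normalized), c(healthy = 1, malignant = 1),
               tolerance = 1e-9)
  # symmetric and perfect edge cases
  expect_equal(pixel_metrics(new_confusion_counts(5, 0, 5, 5))$sensitivity,
               0.5)
  perfect <- pixel_metrics(new_confusion_counts(50, 0, 50, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("empty classes surface as flagged NA, never as 0 or 1", {
  pm <- pixel_metrics(new_confusion_counts(tp = 0, fp = 3, tn = 7, fn = 0))
  expect_true(is.na(pm$sensitivity))
  expect_identical(pm$undefined, "sensitivity")
  expect_false(is.na(pm$specificity))
})

test_that("per-slice lesion recall and its edge cases", {
  truth <- matrix(0L, 10, 10)
  truth[3:7, 3:7] <- 1L
  expect_equal(slice_lesion_recall(matrix(1L, 10, 10), truth), 1)
  expect_equal(slice_lesion_recall(matrix(0L, 10, 10), truth), 0)
  # exactly 40% of lesion pixels covered -> recall 0.40, counts as detected
  pred <- matrix(0L, 10, 10)
  pred[which(truth == 1L)[1:10]] <- 1L
  expect_equal(slice_lesion_recall(pred, truth), 0.4)
  expect_true(0.4 >= stack_criteria()$lesion_recall_threshold)
  expect_true(is.na(slice_lesion_recall(pred, matrix(0L, 10, 10))))
})

test_that("the stack criterion needs 40% recall in at least three slices", {
  crit <- stack_criteria()
  expect_true(stack_detected(c(0.5, 0.5, 0.5, rep(0, 7)), crit))
  expect_false(stack_detected(c(1.0, 1.0, rep(0, 8)), crit))
  expect_true(stack_detected(c(0.4, 0.4, 0.4), crit))  # inclusive threshold
  expect_false(stack_detected(c(0.39, 0.8, 0.8, NA), crit))
  expect_true(stack_detected(c(0.39, 0.8, 0.8, 0.41), crit))
  expect_true(is.na(stack_detected(c(NA, NA), crit)))
})

test_that("a case is detected when any evaluable stack is", {
  expect_true(case_detected(c(TRUE, FALSE)))
  expect_false(case_detected(c(FALSE, FALSE, NA)))
  expect_true(is.na(case_detected(c(NA, NA))))
})

test_that("aggregate rates count detected over evaluable units", {
  slice_results <- tibble::tibble(
    case_id = rep(sprintf("c%02d", 1:9), each = 4),
    stack_id = "s1",
    recall = c(rep(0.5, 4),  rep(0.5, 4),  rep(0.5, 4),  rep(0.5, 4),
               rep(0.5, 4),  rep(0.5, 4),  rep(0.5, 4),
               rep(0.1, 4),  c(0.9, 0.9, 0.1, 0.1))
  )
  rates <- aggregate_rates(slice_results, stack_criteria())
  expect_equal(rates$case_rate, 7 / 9)
  expect_equal(rates$stack_rate, 7 / 9)
  expect_identical(nrow(rates$stacks), 9L)
})
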