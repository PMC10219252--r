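#' Confusion matrix at a risk-factor cut-off
#'
#' A patient is predicted positive when `risk_factor >= cutoff`. True labels
#' must be `"FD-positive"` or `"control"` for every row.
#'
#' @param profiles Data frame with `risk_factor` and `true_label` columns.
#' @param cutoff Integer cut-off.
#' @return List of class `fd_confusion` with integer fields `TP`, `FP`,
#'   `TN`, `FN` and the `cutoff`.
#' @export
confusion_at_cutoff <- function(profiles, cutoff) {
  lab <- profiles$true_label
  if (is.null(lab) || any(is.na(lab))) {
    stop("confusion_at_cutoff(): every profile needs a true label")
  }
  bad <- setdiff(unique(lab), c("FD-positive", "control"))
  if (length(bad) > 0L) stop("confusion_at_cutoff(): unknown label(s): ",
                             paste(bad, collapse = ", "))
  pos <- profiles$risk_factor >= cutoff
  case <- lab == "FD-positive"
  structure(list(TP = sum(pos & case), FP = sum(pos & !case),
                 TN = sum(!pos & !case), FN = sum(!pos & case),
                 cutoff = as.integer(cutoff)),
            class = "fd_confusion")
}

#' @export
print.fd_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (cutoff %d):\n", x$cutoff))
  cat(sprintf("  TP %6d   FN %6d\n  FP %6d   TN %6d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP); recall
#' (sensitivity) = TP/(TP+FN); specificity = TN/(TN+FP); F1 = harmonic mean
#' of precision and recall. A metric whose denominator is zero is returned
#' as `NA` (undefined) rather than an error.
#'
#' @param matrix An `fd_confusion` (or list with TP/FP/TN/FN).
#' @return List with `accuracy`, `precision`, `recall`, `specificity`, `f1`.
#' @export
screen_metrics <- function(matrix) {
  TP <- matrix$TP; FP <- matrix$FP; TN <- matrix$TN; FN <- matrix$FN
  total <- TP + FP + TN + FN
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(accuracy = safe_div(TP + TN, total),
       precision = precision,
       recall = recall,
       specificity = safe_div(TN, TN + FP),
       f1 = f1)
}

#' Sensitivity/specificity sweep over integer cut-offs
#'
#' @param profiles Labeled profile data frame.
#' @param cutoffs Integer vector of cut-offs (default 3 to 11).
#' @return Data frame with one row per cut-off: the confusion counts,
#'   sensitivity and specificity. Sensitivity is non-increasing and
#'   specificity non-decreasing in the cut-off.
#' @export
sweep_cutoffs <- function(profiles, cutoffs = 3:11) {
  if (length(cutoffs) == 0L) stop("sweep_cutoffs(): empty cutoff range")
  rows <- lapply(cutoffs, function(co) {
    cm <- confusion_at_cutoff(profiles, co)
    m <- screen_metrics(cm)
    data.frame(cutoff = co, TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
               sensitivity = m$recall, specificity = m$specificity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC and precision-recall curves for a labeled cohort
#'
#' ROC points are generated at every distinct score threshold (predicted
#' positive at score >= threshold) and the ROC area is the trapezoidal
#' integral. The PR area follows the step-wise precision-at-recall
#' convention (sum of precision times recall increment over thresholds of
#' increasing recall).
#'
#' @param profiles Labeled profile data frame (both classes required).
#' @return List with `roc_points` (fpr, tpr), `pr_points` (recall,
#'   precision), `auc_roc`, `auc_pr`.
#' @export
roc_pr_curves <- function(profiles) {
  lab <- profiles$true_label
  case <- lab == "FD-positive"
  nP <- sum(case); nN <- sum(!case)
  if (nP == 0L || nN == 0L) stop("roc_pr_curves(): both classes must be present")
  s <- profiles$risk_factor
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- numeric(length(thr)); fpr <- numeric(length(thr))
  prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- s >= thr[i]
    tp <- sum(pos & case); fp <- sum(pos & !case)
    tpr[i] <- tp / nP
    fpr[i] <- fp / nN
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc_roc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  pr <- data.frame(recall = c(0, tpr), precision = c(1, prec))
  auc_pr <- sum(diff(pr$recall) * pr$precision[-1])
  list(roc_points = roc, pr_points = pr, auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Enrichment of the flagged group over the population rate
#'
#' The flagged group's case:control ratio is 1:k with k = round(FP/TP); the
#' fold enrichment compares it with a 1-in-N population rate. The fold is
#' reported as the integer part of N/k (`fold`), alongside the exact value
#' (`fold_exact`).
#'
#' @param matrix An `fd_confusion`.
#' @param population_rate_n Population prevalence as 1-in-N (default 40000).
#' @return List with `k`, `fold`, `fold_exact`, `population_n` and an
#'   `all_true_positive` flag for the FP = 0 edge case.
#' @export
enrichment_ratio <- function(matrix, population_rate_n = 40000) {
  if (matrix$TP == 0L) stop("enrichment_ratio(): undefined when TP = 0")
  k <- round(matrix$FP / matrix$TP)
  if (k == 0) {
    return(list(k = 0L, fold = NA_integer_, fold_exact = NA_real_,
                population_n = population_rate_n, all_true_positive = TRUE))
  }
  fe <- population_rate_n / k
  list(k = as.integer(k), fold = as.integer(trunc(fe)), fold_exact = fe,
       population_n = population_rate_n, all_true_positive = FALSE)
}

#' Compare case and control cohort characteristics
#'
#' Table-1-style group comparison: numeric attributes are compared with the
#' Mann-Whitney (Wilcoxon rank-sum) test; binary/categorical attributes
#' with the chi-squared test when all expected counts are at least 5 and
#' Fisher's exact test otherwise. A binary attribute with zero incidence in
#' either group is reported untested.
#'
#' @param cases Data frame of case attributes.
#' @param controls Data frame of control attributes (same columns).
#' @param attributes Columns to compare (default: all shared columns).
#' @return Data frame with `attribute`, `test`, `p_value`, `tested`.
#' @export
compare_cohort_characteristics <- function(cases, controls,
                                           attributes = intersect(names(cases), names(controls))) {
  if (nrow(cases) == 0L || nrow(controls) == 0L) {
    stop("compare_cohort_characteristics(): both groups must be non-empty")
  }
  rows <- lapply(attributes, function(a) {
    x <- cases[[a]]; y <- controls[[a]]
    if (is.numeric(x) && !is.logical(x)) {
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      return(data.frame(attribute = a, test = "mann_whitney", p_value = p,
                        tested = TRUE, stringsAsFactors = FALSE))
    }
    xf <- factor(as.character(x)); yf <- factor(as.character(y))
    lev <- union(levels(xf), levels(yf))
    tab <- rbind(table(factor(x, levels = lev)), table(factor(y, levels = lev)))
    if (length(lev) < 2L || any(rowSums(tab) == 0L)) {
      return(data.frame(attribute = a, test = "none", p_value = NA_real_,
                        tested = FALSE, stringsAsFactors = FALSE))
    }
    if (is.logical(x) || all(lev %in% c("TRUE", "FALSE"))) {
      # zero incidence of the trait in a group: untested (as for a sign
      # absent from one cohort)
      if (any(tab[, colnames(tab) == "TRUE"] == 0L)) {
        return(data.frame(attribute = a, test = "none", p_value = NA_real_,
                          tested = FALSE, stringsAsFactors = FALSE))
      }
    }
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
    if (all(expected >= 5)) {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi_squared"
    } else {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher_exact"
    }
    data.frame(attribute = a, test = test, p_value = p, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
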