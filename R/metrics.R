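#' Discretize a voxel-wise probability volume into labels
#'
#' Each voxel carries a probability vector over N classes (class 0 =
#' background "nothing"). A voxel is assigned the non-background class with
#' the highest probability among those strictly exceeding \code{threshold};
#' if no non-background probability exceeds it, the voxel is assigned label
#' 0. Exact ties resolve to the lowest class index.
#'
#' @param pred 4-D array shaped (classes, x, y, z); every voxel's
#'   probability vector must be non-negative and sum to 1 within 1e-6.
#' @param threshold probability threshold in (0, 1); 0.8 is the convention
#'   for U-Net secondary-structure output (0.4 for nucleotide-group
#'   predictors).
#' @return integer label array shaped (x, y, z).
#' @export
discretize <- function(pred, threshold = 0.8) {
  stopifnot(is.array(pred), length(dim(pred)) == 4,
            threshold > 0, threshold < 1)
  k <- dim(pred)[1]
  flat <- matrix(pred, nrow = k)   # classes x voxels
  if (any(flat < -1e-9) || any(abs(colSums(flat) - 1) > 1e-6))
    stopf("discretize: probability vectors must be non-negative and sum to 1")
  lab <- integer(ncol(flat))
  if (k > 1) {
    fg <- flat[-1, , drop = FALSE]            # classes 1..k-1
    above <- fg > threshold
    masked <- ifelse(above, fg, -Inf)
    has <- colSums(above) > 0
    # which.max returns the first maximum: lowest class index on exact ties
    lab[has] <- apply(masked[, has, drop = FALSE], 2, which.max)
  }
  array(lab, dim = dim(pred)[-1])
}

#' One-vs-rest confusion table per label
#'
#' For every label k: TP = voxels predicted and truly k; FP = predicted k
#' but truly not; FN = truly k but predicted otherwise; TN = the rest.
#' TP + FP + FN + TN equals the voxel count for every label.
#'
#' @param pred,truth integer label arrays of equal shape.
#' @param labels labels to tabulate (default: all non-zero labels present
#'   in either volume; include 0 explicitly if wanted).
#' @return data frame of class \code{"confusion_table"} with one row per
#'   label and columns label, tp, fp, fn, tn.
#' @export
confusion <- function(pred, truth, labels = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stopf("confusion: prediction and truth shapes differ")
  p <- as.vector(pred); t <- as.vector(truth)
  if (is.null(labels)) labels <- sort(setdiff(unique(c(p, t)), 0))
  n <- length(p)
  rows <- lapply(labels, function(k) {
    tp <- sum(p == k & t == k)
    fp <- sum(p == k & t != k)
    fn <- sum(p != k & t == k)
    data.frame(label = k, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  })
  ct <- do.call(rbind, rows)
  attr(ct, "n_voxels") <- n
  attr(ct, "overall_agreement") <- sum(p == t) / n
  class(ct) <- c("confusion_table", "data.frame")
  ct
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Accuracy, precision, recall and F1 from a confusion table
#'
#' Per label: accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R). Zero-denominator metrics are reported as 0
#' with \code{undefined = TRUE}. The aggregate row pools TP/FP/FN over the
#' non-background labels (micro average); aggregate accuracy is the overall
#' multi-class voxel agreement when the confusion table carries it.
#'
#' @param ct a \code{\link{confusion}} table (or any data frame with label,
#'   tp, fp, fn, tn columns).
#' @return data frame with one row per label plus an \code{"aggregate"}
#'   row; columns label, accuracy, precision, recall, f1, undefined.
#' @export
score_metrics <- function(ct) {
  stopifnot(all(c("label", "tp", "fp", "fn", "tn") %in% names(ct)))
  one <- function(label, tp, fp, fn, tn, acc = NULL) {
    p <- safe_ratio(tp, tp + fp)
    r <- safe_ratio(tp, tp + fn)
    f1 <- safe_ratio(2 * p * r, p + r)
    data.frame(label = as.character(label),
               accuracy = acc %||% safe_ratio(tp + tn, tp + tn + fp + fn),
               precision = p, recall = r, f1 = f1,
               undefined = (tp + fp == 0) || (tp + fn == 0) || (p + r == 0),
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i)
    one(ct$label[i], ct$tp[i], ct$fp[i], ct$fn[i], ct$tn[i])))
  fg <- ct[ct$label != 0, , drop = FALSE]
  agg <- one("aggregate", sum(fg$tp), sum(fg$fp), sum(fg$fn), sum(fg$tn),
             acc = attr(ct, "overall_agreement"))
  rbind(per, agg)
}

#' Evaluate a probability volume against ground-truth labels
#'
#' Convenience wrapper: discretize, tabulate confusion, score.
#'
#' @inheritParams discretize
#' @param truth integer ground-truth label array shaped (x, y, z).
#' @param labels labels to score (default: non-zero labels present).
#' @return the \code{\link{score_metrics}} data frame.
#' @export
evaluate_prediction <- function(pred, truth, threshold = 0.8, labels = NULL) {
  score_metrics(confusion(discretize(pred, threshold), truth, labels))
}
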