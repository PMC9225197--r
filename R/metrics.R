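#' One-vs-rest confusion counts for a class
#'
#' Counts, over all pixels, true positives (predicted c and labelled c),
#' false positives (predicted c, labelled otherwise), false negatives
#' (labelled c, predicted otherwise) and true negatives; the four counts sum
#' to the pixel count.
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param class_id the class to score.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred, truth, class_id) {
  if (!all(dim(pred) == dim(truth))) stop("pred and truth shapes differ")
  p <- pred == class_id
  t <- truth == class_id
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  c(TP = tp, FP = fp, FN = fn, TN = length(pred) - tp - fp - fn)
}

#' Accuracy, Jaccard and Dice from confusion counts
#'
#' Acc = (TP+TN)/(TP+FP+FN+TN), J = TP/(TP+FP+FN), D = 2TP/(2TP+FP+FN), so
#' that D = 2J/(1+J) and J <= D always.  When a class is absent from both
#' masks (TP = FP = FN = 0) J and D are defined as 1: perfect agreement on
#' absence.
#'
#' @param counts named vector as returned by [confusion_counts()].
#' @return named numeric vector `c(accuracy, jaccard, dice)`, fractions in
#'   `[0, 1]`.
#' @export
seg_scores <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion counts")
  j <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  d <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = (tp + tn) / total, jaccard = j, dice = d)
}

#' Per-class metrics over a test set
#'
#' With `aggregate = "micro"` (default) confusion counts are summed over all
#' images before scoring; `"macro"` scores each image separately and averages
#' the per-image metrics.
#'
#' @param preds,truths lists of paired label matrices (a single matrix is
#'   promoted to a list of one).
#' @param classes integer vector of class ids to score.
#' @param aggregate `"micro"` or `"macro"`.
#' @return a data frame of class `cardionet_metrics` with columns `class`,
#'   `accuracy`, `jaccard`, `dice` (fractions).
#' @export
class_metrics <- function(preds, truths, classes,
                          aggregate = c("micro", "macro")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  if (length(preds) != length(truths)) stop("pred/truth lists differ in length")
  rows <- lapply(classes, function(cl) {
    if (aggregate == "micro") {
      tot <- Reduce(`+`, Map(function(p, t) confusion_counts(p, t, cl),
                             preds, truths))
      sc <- seg_scores(tot)
    } else {
      per <- Map(function(p, t) seg_scores(confusion_counts(p, t, cl)),
                 preds, truths)
      sc <- colMeans(do.call(rbind, per))
    }
    data.frame(class = cl, accuracy = sc[["accuracy"]],
               jaccard = sc[["jaccard"]], dice = sc[["dice"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cardionet_metrics", "data.frame")
  out
}

#' Average the metrics of two cross-validation folds
#'
#' Arithmetic mean per metric per class; both folds must score the same
#' classes.
#'
#' @param fold1,fold2 `cardionet_metrics` data frames.
#' @return a `cardionet_metrics` data frame.
#' @export
two_fold_average <- function(fold1, fold2) {
  if (!identical(fold1$class, fold2$class)) {
    stop("folds score different classes")
  }
  out <- fold1
  for (col in c("accuracy", "jaccard", "dice")) {
    out[[col]] <- (fold1[[col]] + fold2[[col]]) / 2
  }
  out
}

#' Write a per-fold evaluation report as CSV
#'
#' One row per class per fold plus the averaged rows, metrics in percent to
#' two decimals.
#'
#' @param fold1,fold2 `cardionet_metrics` for the two folds.
#' @param path output CSV path.
#' @param class_names optional names for the class ids.
#' @return the report data frame, invisibly.
#' @export
write_metrics_report <- function(fold1, fold2, path, class_names = NULL) {
  avg <- two_fold_average(fold1, fold2)
  fmt <- function(df, label) {
    data.frame(
      fold = label,
      class = if (is.null(class_names)) df$class else class_names[df$class + 1L],
      accuracy = sprintf("%.2f", 100 * df$accuracy),
      jaccard = sprintf("%.2f", 100 * df$jaccard),
      dice = sprintf("%.2f", 100 * df$dice)
    )
  }
  rep <- rbind(fmt(fold1, "fold1"), fmt(fold2, "fold2"), fmt(avg, "average"))
  utils::write.csv(rep, path, row.names = FALSE, quote = FALSE)
  invisible(rep)
}
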