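ratio_or_zero <- function(num, den, what) {
  if (den > 0) return(num / den)
  warning(what, " is 0/0 (no positives on either side); reporting 0")
  0
}

#' Pixel-level segmentation metrics
#'
#' Precision, recall, F1 (Dice) and IoU (Jaccard) between a predicted and a
#' ground-truth binary foreground. 0/0 cases (an empty side) are reported
#' as 0 with a warning rather than 1.
#'
#' @param pred,gt binary rasters (logical, or numeric where nonzero =
#'   foreground) of identical shape; instance masks may be passed directly
#'   and are reduced to their foreground union.
#' @return Named list: `precision`, `recall`, `f1`, `iou`, and the pixel
#'   counts `tp`, `fp`, `fn`.
#' @export
#' @examples
#' gt <- matrix(1, 10, 10); pred <- gt; pred[, 6:10] <- 0
#' pixel_metrics(pred, gt)[c("precision", "recall", "f1", "iou")]
pixel_metrics <- function(pred, gt) {
  pred <- as.matrix(pred) != 0
  gt <- as.matrix(gt) != 0
  if (!identical(dim(pred), dim(gt)))
    stop("prediction (", paste(dim(pred), collapse = "x"),
         ") and ground truth (", paste(dim(gt), collapse = "x"),
         ") shapes differ")
  tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
  precision <- ratio_or_zero(tp, tp + fp, "precision")
  recall <- ratio_or_zero(tp, tp + fn, "recall")
  f1 <- ratio_or_zero(2 * tp, 2 * tp + fp + fn, "F1")
  iou <- ratio_or_zero(tp, tp + fp + fn, "IoU")
  list(precision = precision, recall = recall, f1 = f1, iou = iou,
       tp = tp, fp = fp, fn = fn)
}

#' Nucleus-level confusion matrix
#'
#' @param pred,gt equal-length vectors of intensity classes (levels of
#'   [ihc_classes()]).
#' @return 4x4 integer matrix, rows = ground truth, columns = predicted,
#'   classes ordered Strong, Moderate, Weak, Negative.
#' @export
#' @examples
#' class_confusion(c("Weak", "Strong"), c("Moderate", "Strong"))
class_confusion <- function(pred, gt) {
  pred <- as_ihc_class(pred); gt <- as_ihc_class(gt)
  if (length(pred) != length(gt))
    stop("pred and gt have different lengths")
  m <- table(gt = gt, pred = pred)
  matrix(as.integer(m), 4L, 4L,
         dimnames = list(gt = ihc_classes(), pred = ihc_classes()))
}

#' Macro-averaged F1 and per-class metrics from a confusion matrix
#'
#' One-vs-rest precision, recall and F1 per class; the macro-F1 is the
#' unweighted mean over classes that occur in the ground truth or the
#' prediction. Classes absent from both sides carry no evidence and are
#' dropped from the average with a warning; a class present on one side
#' only contributes F1 = 0.
#'
#' @param conf square confusion matrix (rows = ground truth), e.g. from
#'   [class_confusion()].
#' @return List with `macro_f1` and `per_class` (`data.frame`: `class`,
#'   `precision`, `recall`, `f1`, `support`).
#' @export
#' @examples
#' cm <- class_confusion(rep(ihc_classes(), 3), rep(ihc_classes(), 3))
#' macro_f1(cm)$macro_f1
macro_f1 <- function(conf) {
  conf <- as.matrix(conf)
  if (nrow(conf) != ncol(conf)) stop("confusion matrix must be square")
  if (any(conf < 0)) stop("confusion matrix entries must be non-negative")
  if (sum(conf) == 0) stop("confusion matrix is all zero")
  classes <- rownames(conf)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(conf)))
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  present <- (rowSums(conf) + colSums(conf)) > 0
  if (!all(present))
    warning("class(es) absent from ground truth and prediction dropped ",
            "from the macro average: ",
            paste(classes[!present], collapse = ", "))
  list(macro_f1 = mean(f1[present]),
       per_class = data.frame(class = classes, precision = precision,
                              recall = recall, f1 = f1,
                              support = as.integer(rowSums(conf)),
                              row.names = NULL))
}

#' Instance-level matched F1 (auxiliary)
#'
#' Object-level counterpart to [pixel_metrics()]: predicted and
#' ground-truth instances are matched greedily by descending IoU, a pair
#' counting as a true positive when its IoU reaches `iou_threshold`.
#' Reported separately from the pixel-level metrics, which are the
#' package's default segmentation measure.
#'
#' @param pred,gt integer instance masks of identical shape.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return Named list: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`
#'   (instance counts).
#' @export
matched_instance_f1 <- function(pred, gt, iou_threshold = 0.5) {
  pred <- validate_mask(pred); gt <- validate_mask(gt)
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  np <- length(unique(pred[pred > 0L])); ng <- length(unique(gt[gt > 0L]))
  if (np == 0L || ng == 0L) {
    tp <- 0L
  } else {
    both <- pred > 0L & gt > 0L
    if (any(both)) {
      ov <- table(pred = pred[both], gt = gt[both])
      pa <- tabulate(pred[pred > 0L], max(pred))
      ga <- tabulate(gt[gt > 0L], max(gt))
      inter <- as.data.frame(ov, stringsAsFactors = FALSE)
      inter <- inter[inter$Freq > 0, ]
      pi <- as.integer(inter$pred); gi <- as.integer(inter$gt)
      iou <- inter$Freq / (pa[pi] + ga[gi] - inter$Freq)
      ord <- order(-iou)
      used_p <- integer(0); used_g <- integer(0); tp <- 0L
      for (k in ord) {
        if (iou[k] < iou_threshold) break
        if (pi[k] %in% used_p || gi[k] %in% used_g) next
        used_p <- c(used_p, pi[k]); used_g <- c(used_g, gi[k])
        tp <- tp + 1L
      }
    } else tp <- 0L
  }
  fp <- np - tp; fn <- ng - tp
  list(precision = ratio_or_zero(tp, np, "instance precision"),
       recall = ratio_or_zero(tp, ng, "instance recall"),
       f1 = ratio_or_zero(2 * tp, 2 * tp + fp + fn, "instance F1"),
       tp = tp, fp = fp, fn = fn)
}
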