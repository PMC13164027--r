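test_that("pixel metrics on constructed masks match set arithmetic", {
  full <- matrix(1, 10, 10)
  expect_equal(pixel_metrics(full, full)[1:4],
               list(precision = 1, recall = 1, f1 = 1, iou = 1))
  half <- full; half[, 6:10] <- 0
  m <- pixel_metrics(half, full)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$iou, 0.5)
  # disjoint masks: every metric collapses to zero
  a <- matrix(0, 6, 6); a[1:3, ] <- 1
  b <- matrix(0, 6, 6); b[4:6, ] <- 1
  md <- pixel_metrics(a, b)
  expect_equal(unlist(md[1:4]), c(precision = 0, recall = 0, f1 = 0, iou = 0))
  # two empty masks have no defined metrics: 0 with a warning per ratio
  me <- NULL
  w <- capture_warnings(me <- pixel_metrics(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_true(all(grepl("0/0", w)) && length(w) == 4L)
  expect_equal(unlist(me[1:4]), c(precision = 0, recall = 0, f1 = 0, iou = 0))
  expect_error(pixel_metrics(matrix(1, 2, 2), matrix(1, 3, 3)),
               "shapes differ")
})

test_that("pixel metrics agree with a brute-force oracle on random masks", {
  set.seed(11)
  for (i in 1:100) {
    pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
    gt <- matrix(sample(0:1, 64, TRUE), 8, 8)
    # oracle: explicit pixel-set arithmetic
    P <- which(pred == 1); G <- which(gt == 1)
    tp <- length(intersect(P, G))
    fp <- length(setdiff(P, G)); fn <- length(setdiff(G, P))
    m <- suppressWarnings(pixel_metrics(pred, gt))
    expect_equal(m$tp, tp); expect_equal(m$fp, fp); expect_equal(m$fn, fn)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    if (tp + fp + fn > 0) {
      expect_equal(m$iou, tp / (tp + fp + fn))
      expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
    }
    # Dice dominates Jaccard; equal only at the extremes
    expect_lte(m$iou, m$f1 + 1e-12)
    if (!m$f1 %in% c(0, 1)) expect_lt(m$iou, m$f1)
    # harmonic-mean identity
    if (m$precision + m$recall > 0)
      expect_equal(m$f1 * (m$precision + m$recall),
                   2 * m$precision * m$recall)
  }
})

test_that("confusion matrix tallies are exact and order-invariant", {
  pred <- c("Strong", "Weak", "Moderate", "Strong")
  gt <- c("Strong", "Weak", "Weak", "Moderate")
  cm <- class_confusion(pred, gt)
  expect_equal(sum(cm), 4)
  expect_equal(cm["Strong", "Strong"], 1L)
  expect_equal(cm["Weak", "Moderate"], 1L)
  expect_equal(cm["Moderate", "Strong"], 1L)
  expect_equal(rowSums(cm), c(Strong = 1, Moderate = 1, Weak = 2,
                              Negative = 0), ignore_attr = TRUE)
  shuffle <- c(3, 1, 4, 2)
  expect_identical(class_confusion(pred[shuffle], gt[shuffle]), cm)
  # perfect prediction is diagonal
  cmd <- class_confusion(gt, gt)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  expect_error(class_confusion("Strongish", "Strong"), "unknown class")
  expect_error(class_confusion(pred, gt[1:3]), "lengths")
})

test_that("macro-F1 averages per-class F1 over classes with evidence", {
  cm <- class_confusion(rep(ihc_classes(), 5), rep(ihc_classes(), 5))
  expect_equal(macro_f1(cm)$macro_f1, 1.0)
  # balanced 2-class block; the two unobserved classes are dropped with a
  # warning and the macro averages the populated ones
  cm2 <- matrix(0L, 4, 4, dimnames = list(gt = ihc_classes(),
                                          pred = ihc_classes()))
  cm2["Strong", "Strong"] <- 8L; cm2["Strong", "Moderate"] <- 2L
  cm2["Moderate", "Strong"] <- 2L; cm2["Moderate", "Moderate"] <- 8L
  expect_warning(r2 <- macro_f1(cm2), "dropped")
  expect_equal(r2$macro_f1, 0.8)
  expect_equal(r2$per_class$f1[1:2], c(0.8, 0.8))
  # a fully misclassified class contributes F1 = 0 and drags the macro
  cm3 <- cm
  cm3["Weak", ] <- c(15L, 0L, 0L, 0L)   # every Weak called Strong
  r3 <- macro_f1(cm3)
  expect_equal(r3$per_class$f1[r3$per_class$class == "Weak"], 0)
  others <- r3$per_class$f1[r3$per_class$class != "Weak"]
  expect_lt(r3$macro_f1, mean(others))
  expect_error(macro_f1(matrix(0, 4, 4)), "all zero")
  expect_error(macro_f1(matrix(1, 2, 3)), "square")
})

test_that("macro-F1 is equivariant under class relabeling", {
  set.seed(5)
  gt <- sample(ihc_classes(), 200, TRUE)
  pred <- ifelse(runif(200) < 0.8, gt, sample(ihc_classes(), 200, TRUE))
  base <- macro_f1(class_confusion(pred, gt))$macro_f1
  # swap Strong and Negative everywhere: macro-F1 unchanged
  swap <- function(x) ifelse(x == "Strong", "Negative",
                      ifelse(x == "Negative", "Strong", x))
  swapped <- macro_f1(class_confusion(swap(pred), swap(gt)))$macro_f1
  expect_equal(swapped, base)
})

test_that("instance-level matched F1 behaves on identical and disjoint masks", {
  tile <- generate_tile(synthetic_spec(n_per_class = c(2, 2, 0, 0),
                                       height = 96, width = 96, seed = 13))
  r <- matched_instance_f1(tile$mask, tile$mask)
  expect_equal(r$f1, 1)
  expect_equal(r$tp, 4L)
  empty <- matrix(0L, 96, 96)
  r0 <- suppressWarnings(matched_instance_f1(empty, tile$mask))
  expect_equal(r0$f1, 0)
  expect_equal(r0$fn, 4L)
})
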