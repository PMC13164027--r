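#' Four-class nucleus count table
#'
#' @param strong,moderate,weak,negative non-negative integer nucleus counts.
#' @return Object of class `count_table` with the four counts and `total`.
#' @export
#' @examples
#' count_table(176, 51, 33, 19)
count_table <- function(strong, moderate, weak, negative) {
  cts <- c(strong = strong, moderate = moderate, weak = weak,
           negative = negative)
  if (!is.numeric(cts) || anyNA(cts) || any(cts < 0) ||
      any(abs(cts - round(cts)) > 1e-9))
    stop("counts must be non-negative integers")
  cts <- as.integer(round(cts))
  structure(list(strong = cts[[1]], moderate = cts[[2]], weak = cts[[3]],
                 negative = cts[[4]], total = sum(cts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("nuclei: %d (Strong %d, Moderate %d, Weak %d, Negative %d)\n",
              x$total, x$strong, x$moderate, x$weak, x$negative))
  invisible(x)
}

as_count_table <- function(x) {
  if (inherits(x, "count_table")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(count_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("expected a count_table or a numeric vector ",
       "(strong, moderate, weak, negative)")
}

#' Percentage of positively stained nuclei
#'
#' `100 * (strong + moderate + weak) / total`, computed in full floating
#' precision. An image with zero nuclei has no defined percentage and is an
#' error (callers must decide how to report an empty region; a silent 0%
#' would fabricate a negative result).
#'
#' @param counts a [count_table()] (or length-4 numeric vector
#'   strong, moderate, weak, negative).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' positive_percentage(count_table(176, 51, 33, 19))  # 93.189...
positive_percentage <- function(counts) {
  counts <- as_count_table(counts)
  if (counts$total == 0L)
    stop("no nuclei detected: positive percentage is undefined for an ",
         "empty region")
  100 * (counts$strong + counts$moderate + counts$weak) / counts$total
}

#' Proportion score P from the positive percentage
#'
#' Maps the positive-nucleus percentage to the 0-5 proportion score:
#' P = 0 for exactly 0%; 1 for (0, 1)%; 2 for \[1, 10\]%; 3 for (10, 33\]%;
#' 4 for (33, 66\]%; 5 above 66%. The published bin labels are integer
#' ranges ("1-10%", "11-33%", "34-66%", ">= 67%"); the right-closed real
#' intervals used here are the unique simple completion consistent with
#' every row of the bundled reference table (e.g. 65.79% -> 4 but
#' 66.08% -> 5).
#'
#' @param positive_pct percentage in \[0, 100\].
#' @return Integer score 0-5.
#' @export
#' @examples
#' proportion_score(93.18)
proportion_score <- function(positive_pct) {
  if (!is.numeric(positive_pct) || length(positive_pct) != 1L ||
      is.na(positive_pct) || positive_pct < 0 || positive_pct > 100)
    stop("positive_pct must be a single percentage in [0, 100]")
  if (positive_pct == 0) 0L
  else if (positive_pct < 1) 1L
  else if (positive_pct <= 10) 2L
  else if (positive_pct <= 33) 3L
  else if (positive_pct <= 66) 4L
  else 5L
}

#' Intensity score I from the dominant positive class
#'
#' I = 0 when no nucleus is positive; otherwise the score of the positive
#' class (Strong = 3, Moderate = 2, Weak = 1) holding the maximum count,
#' with ties broken toward the stronger intensity.
#'
#' @param counts a [count_table()] (or length-4 numeric vector).
#' @return Integer score 0-3.
#' @export
#' @examples
#' intensity_score(count_table(4, 16, 16, 80))  # moderate/weak tie -> 2
intensity_score <- function(counts) {
  counts <- as_count_table(counts)
  pos <- c(counts$strong, counts$moderate, counts$weak)
  if (sum(pos) == 0L) return(0L)
  c(3L, 2L, 1L)[which.max(pos)]   # first max: tie goes to the stronger class
}

#' Allred score and treatment recommendation
#'
#' Composes [positive_percentage()], [proportion_score()] and
#' [intensity_score()] into the clinical Allred result: total = P + I
#' (0 or 2-8; 1 is unreachable because P = 0 and I = 0 coincide), with
#' totals 0 and 2 reported as negative (endocrine therapy not indicated)
#' and 3-8 as positive.
#'
#' @param counts a [count_table()] (or length-4 numeric vector); must
#'   contain at least one nucleus.
#' @return Object of class `allred_result` with elements `counts`,
#'   `positive_pct`, `P`, `I`, `total`, `recommendation`.
#' @export
#' @examples
#' allred(count_table(176, 51, 33, 19))
allred <- function(counts) {
  counts <- as_count_table(counts)
  pct <- positive_percentage(counts)   # errors on an empty region
  p <- proportion_score(pct)
  i <- intensity_score(counts)
  total <- p + i
  structure(list(counts = counts, positive_pct = pct, P = p, I = i,
                 total = total,
                 recommendation = if (total >= 3L) "positive" else "negative"),
            class = "allred_result")
}

#' @export
print.allred_result <- function(x, ...) {
  cat(sprintf("positive: %.2f%%  P = %d  I = %d  Allred = %d (%s)\n",
              x$positive_pct, x$P, x$I, x$total, x$recommendation))
  invisible(x)
}

#' Score a table of per-image nucleus counts
#'
#' Vectorised scoring over a data frame with columns `strong`, `moderate`,
#' `weak`, `negative` (one row per image). Rows with zero nuclei get `NA`
#' scores and status `"undefined"`.
#'
#' @param counts_df data frame of per-image counts.
#' @return The input with appended columns `total`, `positive_pct`
#'   (rounded to 2 decimals), `P`, `I`, `allred`, `recommendation`,
#'   `status`.
#' @export
score_counts <- function(counts_df) {
  need <- c("strong", "moderate", "weak", "negative")
  if (!all(need %in% names(counts_df)))
    stop("counts table must have columns ", paste(need, collapse = ", "))
  n <- nrow(counts_df)
  out <- counts_df
  out$total <- NA_integer_; out$positive_pct <- NA_real_
  out$P <- NA_integer_; out$I <- NA_integer_; out$allred <- NA_integer_
  out$recommendation <- NA_character_; out$status <- "ok"
  for (r in seq_len(n)) {
    ct <- count_table(counts_df$strong[r], counts_df$moderate[r],
                      counts_df$weak[r], counts_df$negative[r])
    out$total[r] <- ct$total
    if (ct$total == 0L) { out$status[r] <- "undefined"; next }
    res <- allred(ct)
    out$positive_pct[r] <- round(res$positive_pct, 2)
    out$P[r] <- res$P; out$I[r] <- res$I; out$allred[r] <- res$total
    out$recommendation[r] <- res$recommendation
  }
  out
}

#' Bundled reference scoring table
#'
#' Fifty per-image nucleus count tables with their expert-validated scoring
#' components (proportion score P, intensity score I, Allred total),
#' spanning all-negative images, low-positive images near the P = 1/2
#' boundary, tie cases for the dominant-intensity rule, and percentages
#' falling between the integer edges of the published proportion bins.
#' Used as the scoring oracle in the test suite.
#'
#' @return `data.frame` with columns `image`, `total`, `strong`,
#'   `moderate`, `weak`, `negative`, `P`, `I`, `allred`.
#' @export
#' @examples
#' head(allred_reference_counts())
allred_reference_counts <- function() {
  m <- matrix(c(
    # total strong moderate weak negative P I allred
    279, 176, 51, 33,  19, 5, 3, 8,
    217,  33, 41, 51,  92, 4, 1, 5,
    148,   0,  0,  0, 148, 0, 0, 0,
    115,   0,  0,  0, 115, 0, 0, 0,
    135,  42, 38, 33,  22, 5, 3, 8,
    132,  69, 33, 13,  17, 5, 3, 8,
    116,   4, 16, 16,  80, 3, 2, 5,
    123,  19, 14, 19,  71, 4, 3, 7,
    123,   0,  0,  0, 123, 0, 0, 0,
    219,  32,  8,  6, 173, 3, 3, 6,
    162,  23, 15, 14, 110, 3, 3, 6,
     82,  42,  6,  7,  27, 5, 3, 8,
     56,   0,  0,  1,  55, 2, 1, 3,
    245,  82, 50, 59,  54, 5, 3, 8,
    243,  31, 55, 76,  81, 5, 1, 6,
     39,   0,  0, 19,  20, 4, 1, 5,
    134,  53, 18, 24,  39, 5, 3, 8,
    155,  31, 26, 56,  42, 5, 1, 6,
    114,  20, 21, 34,  39, 4, 1, 5,
    279, 233, 36,  4,   6, 5, 3, 8,
    129,  42, 11, 25,  51, 4, 3, 7,
    139,  30, 12, 18,  79, 4, 3, 7,
    144,   0,  0, 23, 121, 3, 1, 4,
    100,  73, 16,  1,  10, 5, 3, 8,
    119,   1,  1,  2, 115, 2, 1, 3,
     67,   0,  0,  2,  65, 2, 1, 3,
    176,  35, 65, 38,  38, 5, 2, 7,
     84,   0,  0,  0,  84, 0, 0, 0,
    214,  78, 22,  3, 111, 4, 3, 7,
     40,   0,  0,  1,  39, 2, 1, 3,
    113,   3,  0, 18,  92, 3, 1, 4,
    132,   7, 15, 39,  71, 4, 1, 5,
     92,  64,  6,  1,  21, 5, 3, 8,
    131,  47, 26, 20,  38, 5, 3, 8,
     97,   0,  0,  0,  97, 0, 0, 0,
    130, 107,  5,  5,  13, 5, 3, 8,
    106,  98,  5,  0,   3, 5, 3, 8,
    212, 133, 43, 31,   5, 5, 3, 8,
     84,  22, 18, 20,  24, 5, 3, 8,
    160,   0,  0,  0, 160, 0, 0, 0,
    196, 148, 27,  6,  15, 5, 3, 8,
    189, 136, 37,  6,  10, 5, 3, 8,
     88,   0,  0,  0,  88, 0, 0, 0,
     47,   0,  0,  0,  47, 0, 0, 0,
    138,   0,  0,  0, 138, 0, 0, 0,
    207,  92, 77, 31,   7, 5, 3, 8,
    155, 126, 17,  6,   6, 5, 3, 8,
     78,  35, 18, 14,  11, 5, 3, 8,
     86,  75,  1,  1,   9, 5, 3, 8,
    171,  88, 14, 11,  58, 5, 3, 8), ncol = 8L, byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- c("total", "strong", "moderate", "weak", "negative",
                 "P", "I", "allred")
  data.frame(image = seq_len(nrow(df)), df)
}
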