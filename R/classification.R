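#' Classification thresholds for the four intensity grades
#'
#' Holds the three class boundaries `(tau1, tau2, tau3)` on the inverted
#' mean-DAB scale, with `0 < tau1 < tau2 < tau3 < 1`. The defaults
#' (0.89, 0.94, 0.975) are the calibrated values used for PR-IHC tiles at
#' the default DAB normalisation; [calibrate_thresholds()] re-derives them
#' for other scanners or stain bases.
#'
#' @param tau1,tau2,tau3 class boundaries (dimensionless, same scale as the
#'   per-nucleus statistic `mu`).
#' @return Object of class `class_thresholds`.
#' @export
#' @examples
#' class_thresholds()
class_thresholds <- function(tau1 = 0.89, tau2 = 0.94, tau3 = 0.975) {
  taus <- c(tau1 = tau1, tau2 = tau2, tau3 = tau3)
  if (!is.numeric(taus) || anyNA(taus))
    stop("thresholds must be numeric")
  if (!(0 < tau1 && tau1 < tau2 && tau2 < tau3 && tau3 < 1))
    stop("thresholds must satisfy 0 < tau1 < tau2 < tau3 < 1, got (",
         paste(signif(taus, 6), collapse = ", "), ")")
  structure(as.list(taus), class = "class_thresholds")
}

#' @export
print.class_thresholds <- function(x, ...) {
  cat(sprintf("intensity thresholds: tau1 = %g, tau2 = %g, tau3 = %g\n",
              x$tau1, x$tau2, x$tau3))
  invisible(x)
}

#' Per-nucleus inverted mean DAB statistic
#'
#' For each nucleus region the mean of the normalised DAB channel over its
#' pixels is computed and inverted: `mu_i = 1 - mean(DAB)` over the region.
#' Darker (stronger) staining therefore gives lower `mu`; unstained nuclei
#' approach 1.0.
#'
#' @param dab H x W matrix of normalised DAB values in \[0, 1\]
#'   (see [normalize_dab()]).
#' @param labels integer instance mask of the same shape.
#' @return `data.frame` with one row per nucleus, columns `id`, `area_px`,
#'   `mu`, sorted by `id`. Empty mask gives zero rows.
#' @export
#' @examples
#' dab <- matrix(0.05, 4, 4); m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
#' mean_inverted_dab(dab, m)
mean_inverted_dab <- function(dab, labels) {
  dab <- as.matrix(dab)
  labels <- validate_mask(labels)
  if (!identical(dim(dab), dim(labels)))
    stop("DAB map (", paste(dim(dab), collapse = "x"), ") and mask (",
         paste(dim(labels), collapse = "x"), ") shapes differ")
  if (any(dab < -1e-9) || any(dab > 1 + 1e-9))
    stop("DAB map values must lie in [0, 1]; run normalize_dab() first")
  pos <- labels > 0L
  if (!any(pos))
    return(data.frame(id = integer(0), area_px = integer(0), mu = numeric(0)))
  ids <- labels[pos]
  sums <- rowsum(dab[pos], ids)
  cnts <- rowsum(rep(1L, length(ids)), ids)
  ord <- as.integer(rownames(sums))
  data.frame(id = ord, area_px = as.integer(cnts[, 1]),
             mu = clip01(1 - sums[, 1] / cnts[, 1]), row.names = NULL)
}

#' Assign intensity classes from the inverted mean-DAB statistic
#'
#' Total, mutually exclusive partition of \[0, 1\]:
#' Strong if `mu < tau1`; Moderate if `tau1 <= mu < tau2`; Weak if
#' `tau2 <= mu < tau3`; Negative if `mu >= tau3`. A boundary value belongs
#' to the weaker class.
#'
#' @param mu numeric vector of per-nucleus statistics in \[0, 1\].
#' @param thresholds a [class_thresholds()].
#' @return Factor with levels `ihc_classes()`.
#' @export
#' @examples
#' classify_mu(c(0.88, 0.89, 0.94, 0.975))
classify_mu <- function(mu, thresholds = class_thresholds()) {
  if (!inherits(thresholds, "class_thresholds"))
    stop("`thresholds` must be a class_thresholds object")
  if (!is.numeric(mu) || anyNA(mu) || any(mu < 0) || any(mu > 1))
    stop("mu must be numeric in [0, 1]")
  cuts <- c(thresholds$tau1, thresholds$tau2, thresholds$tau3)
  idx <- findInterval(mu, cuts) + 1L   # boundary joins the weaker class
  factor(ihc_classes()[idx], levels = ihc_classes())
}

#' Tally a class factor into a count table
#'
#' @param classes factor/character vector of intensity classes.
#' @return A [count_table()].
#' @export
tally_classes <- function(classes) {
  tb <- table(as_ihc_class(classes))
  count_table(strong = tb[["Strong"]], moderate = tb[["Moderate"]],
              weak = tb[["Weak"]], negative = tb[["Negative"]])
}

#' Classify every nucleus in an image
#'
#' Composition of the stain and classification stages: deconvolve the RGB
#' tile, normalise the DAB channel, compute the per-nucleus inverted mean
#' DAB over the instance mask, and threshold into the four intensity
#' grades.
#'
#' @param rgb path or H x W x 3 array of 8-bit RGB values.
#' @param labels integer instance mask (already postprocessed).
#' @param model a [stain_model()].
#' @param thresholds a [class_thresholds()].
#' @return List with `records` (`data.frame`: `id`, `area_px`, `mu`,
#'   `class`, sorted by id) and `counts` (a [count_table()]).
#' @export
classify_image <- function(rgb, labels, model = stain_model(),
                           thresholds = class_thresholds()) {
  labels <- validate_mask(labels)
  dec <- deconvolve(rgb, model)
  dab <- normalize_dab(dec$dab, model$od_reference)
  rec <- mean_inverted_dab(dab, labels)
  rec$class <- classify_mu(rec$mu, thresholds)
  list(records = rec, counts = tally_classes(rec$class))
}

#' Render the four-colour class overlay
#'
#' Colours each nucleus by its intensity grade on a black background:
#' Strong = red (255,0,0), Moderate = yellow (255,255,0), Weak = green
#' (0,255,0), Negative = blue (0,0,255).
#'
#' @param labels integer instance mask.
#' @param records `data.frame` with columns `id` and `class` covering every
#'   label present in the mask.
#' @return H x W x 3 array of 8-bit RGB values.
#' @export
render_class_overlay <- function(labels, records) {
  labels <- validate_mask(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (!all(ids %in% records$id))
    stop("mask labels without a matching record: ",
         paste(setdiff(ids, records$id), collapse = ", "))
  palette <- rbind(Strong   = c(255, 0, 0),
                   Moderate = c(255, 255, 0),
                   Weak     = c(0, 255, 0),
                   Negative = c(0, 0, 255))
  out <- array(0, c(nrow(labels), ncol(labels), 3L))
  pos <- labels > 0L
  if (any(pos)) {
    cls <- as.character(records$class[match(labels[pos], records$id)])
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[pos] <- palette[cls, ch]
      out[, , ch] <- plane
    }
  }
  out
}
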