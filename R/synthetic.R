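#' Specification for a synthetic IHC tile
#'
#' Describes a chromogenic IHC tile rendered through the Beer-Lambert
#' forward model: elliptical nuclei with constant hematoxylin counterstain,
#' class-specific DAB optical density chosen so the per-nucleus inverted
#' mean-DAB statistic falls strictly inside the intended class band, and a
#' faintly counterstained background. Defaults give a 256x256 tile with
#' five nuclei per class, radii 6-11 px (comfortably above the 20 px
#' small-object floor), no overlap, and DAB bands mapping to mu of roughly
#' \[0.80, 0.85\] (Strong), \[0.90, 0.93\] (Moderate), \[0.95, 0.97\]
#' (Weak) and \[0.98, 1.0\] (Negative) under the default thresholds.
#'
#' @param height,width tile size in pixels.
#' @param n_per_class 4 non-negative integers (Strong, Moderate, Weak,
#'   Negative).
#' @param radius_range min/max ellipse semi-axis in pixels (min >= 3).
#' @param overlap_fraction allowed fractional overlap of two nuclei's
#'   radii in \[0, 1): 0 enforces fully disjoint nuclei.
#' @param class_dab_od named list of DAB od intervals per class.
#' @param hematoxylin_od interval of nuclear hematoxylin od.
#' @param background_hematoxylin_od faint counterstain od of the background
#'   (default 0.02).
#' @param background_dab_od amplitude of uniform background DAB noise
#'   (default 0; set > 0 to emulate background-brown contamination).
#' @param texture_sd standard deviation of optional Gaussian od texture on
#'   nuclei (default 0 = constant od, keeping mu analytically predictable).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 256, width = 256,
                           n_per_class = c(Strong = 5, Moderate = 5,
                                           Weak = 5, Negative = 5),
                           radius_range = c(6, 11),
                           overlap_fraction = 0,
                           class_dab_od = list(Strong = c(0.15, 0.20),
                                               Moderate = c(0.07, 0.10),
                                               Weak = c(0.03, 0.05),
                                               Negative = c(0.00, 0.02)),
                           hematoxylin_od = c(0.35, 0.65),
                           background_hematoxylin_od = 0.02,
                           background_dab_od = 0,
                           texture_sd = 0,
                           seed = 1) {
  n_per_class <- rep(as.integer(n_per_class), length.out = 4L)
  names(n_per_class) <- ihc_classes()
  if (any(n_per_class < 0)) stop("n_per_class must be non-negative")
  if (length(radius_range) != 2L || radius_range[1] < 3 ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be (min, max) with min >= 3 px")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (!all(ihc_classes() %in% names(class_dab_od)))
    stop("class_dab_od must name all four classes")
  if (height < 4 * radius_range[2] || width < 4 * radius_range[2])
    stop("tile too small for the requested nucleus radii")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_per_class = n_per_class,
                 radius_range = radius_range,
                 overlap_fraction = overlap_fraction,
                 class_dab_od = class_dab_od[ihc_classes()],
                 hematoxylin_od = hematoxylin_od,
                 background_hematoxylin_od = background_hematoxylin_od,
                 background_dab_od = background_dab_od,
                 texture_sd = texture_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# pixels of an ellipse at (cy, cx), semi-axes (a, b), rotation theta,
# restricted to the tile; returns linear indices (column-major)
ellipse_pixels <- function(cy, cx, a, b, theta, h, w) {
  r0 <- max(1L, floor(cy - max(a, b))); r1 <- min(h, ceiling(cy + max(a, b)))
  c0 <- max(1L, floor(cx - max(a, b))); c1 <- min(w, ceiling(cx + max(a, b)))
  rr <- r0:r1; cc <- c0:c1
  y <- rep(rr, times = length(cc)) - cy
  x <- rep(cc, each = length(rr)) - cx
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  (cols - 1L) * h + rows
}

#' Generate a synthetic IHC tile with ground truth
#'
#' Places elliptical nuclei by rejection sampling under the spec's overlap
#' constraint, assigns each a hematoxylin od and a class-specific DAB od,
#' renders the tile with [forward_mix()], and verifies internally that the
#' statistic recovered by the analysis path ([deconvolve()] +
#' [mean_inverted_dab()]) classifies every nucleus as intended, redrawing
#' the DAB od of any violator (at most 100 rounds). Identical seeds give
#' bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @param model a [stain_model()] (also the model the analysis should use).
#' @param thresholds a [class_thresholds()] defining the target mu bands.
#' @return List of class `synthetic_tile`: `rgb` (H x W x 3, 8-bit),
#'   `mask` (integer instance labels), `classes` (factor per nucleus id),
#'   `mu` (realised statistic per nucleus), `spec`.
#' @export
#' @examples
#' tile <- generate_tile(synthetic_spec(n_per_class = c(1, 1, 1, 1),
#'                                      height = 96, width = 96, seed = 7))
#' table(tile$classes)
generate_tile <- function(spec = synthetic_spec(), model = stain_model(),
                          thresholds = class_thresholds()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    classes <- rep(ihc_classes(), times = spec$n_per_class)
    n <- length(classes)
    mask <- matrix(0L, h, w)
    if (n == 0L)
      return(structure(list(
        rgb = forward_mix(matrix(spec$background_hematoxylin_od, h, w),
                          matrix(0, h, w), model = model),
        mask = mask, classes = as_ihc_class(character(0)),
        mu = numeric(0), spec = spec), class = "synthetic_tile"))

    # rejection-sample ellipse placements honouring the overlap budget
    cen <- matrix(NA_real_, n, 2); ax <- matrix(NA_real_, n, 2)
    rot <- numeric(n); reff <- numeric(n)
    attempts <- 0L
    for (i in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("could not place ", n, " nuclei in 10000 attempts; ",
               "use a larger tile or fewer/smaller nuclei")
        a <- runif(1, spec$radius_range[1], spec$radius_range[2])
        b <- runif(1, spec$radius_range[1], spec$radius_range[2])
        r <- max(a, b)
        cy <- runif(1, r + 2, h - r - 1)
        cx <- runif(1, r + 2, w - r - 1)
        if (i > 1L) {
          d <- sqrt((cen[1:(i - 1), 1] - cy)^2 + (cen[1:(i - 1), 2] - cx)^2)
          lim <- (1 - spec$overlap_fraction) * (reff[1:(i - 1)] + r) +
                 if (spec$overlap_fraction == 0) 2 else 0
          if (any(d < lim)) next
        }
        cen[i, ] <- c(cy, cx); ax[i, ] <- c(a, b)
        rot[i] <- runif(1, 0, pi); reff[i] <- r
        break
      }
    }
    pix <- vector("list", n)
    for (i in seq_len(n)) {
      pix[[i]] <- ellipse_pixels(cen[i, 1], cen[i, 2], ax[i, 1], ax[i, 2],
                                 rot[i], h, w)
      mask[pix[[i]]] <- i          # later nuclei own contested pixels
    }
    own <- lapply(seq_len(n), function(i) pix[[i]][mask[pix[[i]]] == i])
    if (any(lengths(own) == 0L))
      stop("a nucleus was fully occluded; lower overlap_fraction")

    h_od_nuc <- runif(n, spec$hematoxylin_od[1], spec$hematoxylin_od[2])
    draw_dab <- function(cls) {
      iv <- spec$class_dab_od[[cls]]
      runif(1, iv[1], iv[2])
    }
    d_od_nuc <- vapply(classes, draw_dab, numeric(1))

    render <- function() {
      H <- matrix(spec$background_hematoxylin_od, h, w)
      D <- if (spec$background_dab_od > 0)
        matrix(runif(h * w, 0, spec$background_dab_od), h, w)
      else matrix(0, h, w)
      for (i in seq_len(n)) {
        hv <- h_od_nuc[i]; dv <- d_od_nuc[i]
        if (spec$texture_sd > 0) {
          hv <- pmax(0, hv + rnorm(length(own[[i]]), 0, spec$texture_sd))
          dv <- pmax(0, dv + rnorm(length(own[[i]]), 0, spec$texture_sd))
        }
        H[own[[i]]] <- hv
        D[own[[i]]] <- dv
      }
      forward_mix(H, D, model = model)
    }

    # verify through the analysis path; redraw DAB od of any nucleus whose
    # realised mu falls outside its class band
    for (round in seq_len(100L)) {
      rgb <- render()
      res <- classify_image(rgb, mask, model, thresholds)
      mu <- res$records$mu[match(seq_len(n), res$records$id)]
      ok <- as.character(res$records$class[match(seq_len(n),
                                                 res$records$id)]) == classes
      if (all(ok)) break
      if (round == 100L)
        stop("could not realise the requested class bands after 100 redraws")
      d_od_nuc[!ok] <- vapply(classes[!ok], draw_dab, numeric(1))
    }
    structure(list(rgb = rgb, mask = mask, classes = as_ihc_class(classes),
                   mu = mu, spec = spec),
              class = "synthetic_tile")
  })
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat(sprintf("synthetic IHC tile %dx%d, %d nuclei (seed %d)\n",
              x$spec$height, x$spec$width, max(x$mask), x$spec$seed))
  print(table(x$classes))
  invisible(x)
}

#' Generate random per-image count tables
#'
#' Draws per-image four-class nucleus counts from a three-component
#' mixture emulating the spread seen in clinical test sets: all-negative
#' images, low-positive images (a few mostly-weak positives), and strongly
#' positive images dominated by strong staining. Reproducible from `seed`.
#'
#' @param n_images number of images.
#' @param weights mixture weights, named `negative`, `low`, `high`
#'   (normalised internally).
#' @param total_range range of total nuclei per image (default 40-280).
#' @param seed integer seed.
#' @return `data.frame` with columns `strong`, `moderate`, `weak`,
#'   `negative`.
#' @export
#' @examples
#' generate_count_table(3, seed = 42)
generate_count_table <- function(n_images,
                                 weights = c(negative = 0.25, low = 0.25,
                                             high = 0.5),
                                 total_range = c(40, 280), seed = 1) {
  if (n_images < 1) stop("n_images must be >= 1")
  stopifnot(all(c("negative", "low", "high") %in% names(weights)),
            all(weights >= 0), sum(weights) > 0)
  w <- weights[c("negative", "low", "high")] / sum(weights)
  with_seed(seed, {
    comp <- sample(c("negative", "low", "high"), n_images, replace = TRUE,
                   prob = w)
    total <- round(runif(n_images, total_range[1], total_range[2]))
    out <- data.frame(strong = integer(n_images), moderate = integer(n_images),
                      weak = integer(n_images), negative = integer(n_images))
    for (i in seq_len(n_images)) {
      if (comp[i] == "negative") {
        out$negative[i] <- total[i]
      } else if (comp[i] == "low") {
        npos <- rbinom(1, total[i], runif(1, 0.005, 0.08))
        split <- rmultinom(1, npos, c(0.1, 0.2, 0.7))
        out$strong[i] <- split[1]; out$moderate[i] <- split[2]
        out$weak[i] <- split[3]; out$negative[i] <- total[i] - npos
      } else {
        npos <- rbinom(1, total[i], runif(1, 0.35, 0.98))
        split <- rmultinom(1, npos, c(0.6, 0.25, 0.15))
        out$strong[i] <- split[1]; out$moderate[i] <- split[2]
        out$weak[i] <- split[3]; out$negative[i] <- total[i] - npos
      }
    }
    out
  })
}

#' Generate a labelled calibration set from known thresholds
#'
#' Samples per-nucleus statistics uniformly on `[lo, hi]`, discarding
#' values closer than `margin` to any generating threshold, and labels
#' them with [classify_mu()] under those thresholds. Used to exercise
#' threshold recovery by [calibrate_thresholds()].
#'
#' @param n number of calibration pairs.
#' @param thresholds the generating [class_thresholds()].
#' @param margin exclusion half-width around each threshold (default one
#'   default grid step, 0.005).
#' @param lo,hi sampling range (defaults 0.5, 1).
#' @param seed integer seed.
#' @return `data.frame` with columns `mu`, `class`.
#' @export
generate_calibration_pairs <- function(n = 2000,
                                       thresholds = class_thresholds(),
                                       margin = 0.005, lo = 0.5, hi = 1,
                                       seed = 1) {
  taus <- c(thresholds$tau1, thresholds$tau2, thresholds$tau3)
  with_seed(seed, {
    mu <- runif(n, lo, hi)
    repeat {
      bad <- vapply(mu, function(m) any(abs(m - taus) < margin), logical(1))
      if (!any(bad)) break
      mu[bad] <- runif(sum(bad), lo, hi)
    }
    data.frame(mu = mu, class = classify_mu(mu, thresholds))
  })
}
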