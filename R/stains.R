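#' Default hematoxylin / DAB stain vectors
#'
#' Unit optical-density vectors for the standard H-DAB stain pair
#' (Ruifrok-Johnston values), with the residual channel completed per
#' channel as `sqrt(max(0, 1 - H^2 - D^2))` and renormalised, so all
#' components are non-negative and the matrix is well conditioned.
#'
#' @return 3x3 numeric matrix; columns `hematoxylin`, `dab`, `residual`,
#'   rows R, G, B. Each column has unit Euclidean norm.
#' @export
#' @examples
#' hdab_stain_vectors()
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- sqrt(pmax(0, 1 - h^2 - d^2))
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, dab = d, residual = r)
  rownames(m) <- c("R", "G", "B")
  m
}

#' Construct a stain model for deconvolution and forward mixing
#'
#' Bundles the 3x3 stain-vector basis (columns: hematoxylin, DAB, residual,
#' each a unit vector in optical-density space), the transmitted background
#' light level `I0`, and the DAB optical density mapped to 1.0 on the
#' normalised DAB scale.
#'
#' @param vectors 3x3 matrix of stain vectors (columns = stains, rows =
#'   R,G,B). Columns are renormalised to unit length. Default:
#'   [hdab_stain_vectors()].
#' @param background_intensity transmitted light level per channel
#'   (scalar or length-3, default 255).
#' @param od_reference positive scalar; DAB optical density mapped to 1.0
#'   by [normalize_dab()] (default 1.0).
#' @return Object of class `stain_model` with elements `vectors`,
#'   `inverse`, `background_intensity`, `od_reference`.
#' @export
#' @examples
#' m <- stain_model()
#' round(m$vectors, 3)
stain_model <- function(vectors = NULL, background_intensity = 255,
                        od_reference = 1.0) {
  if (is.null(vectors)) vectors <- hdab_stain_vectors()
  vectors <- as.matrix(vectors)
  if (!all(dim(vectors) == c(3L, 3L)) || !is.numeric(vectors))
    stop("stain vectors must form a numeric 3x3 matrix (columns = stains)")
  if (any(vectors < 0))
    stop("stain vector components must be non-negative")
  norms <- sqrt(colSums(vectors^2))
  if (any(norms <= 0)) stop("stain vectors must be non-zero")
  vectors <- sweep(vectors, 2, norms, "/")
  coshd <- sum(vectors[, 1] * vectors[, 2])
  if (abs(coshd) > 1 - 1e-6)
    stop("hematoxylin and DAB vectors are collinear; stain matrix is degenerate")
  k <- kappa(vectors, exact = TRUE)
  if (!is.finite(k) || k > 1e8)
    stop("stain matrix is numerically singular (condition number ", format(k), ")")
  if (!is.numeric(background_intensity) ||
      !length(background_intensity) %in% c(1L, 3L) ||
      any(background_intensity <= 0))
    stop("background_intensity must be a positive scalar or length-3 vector")
  if (!is.numeric(od_reference) || length(od_reference) != 1L || od_reference <= 0)
    stop("od_reference must be a positive scalar")
  if (is.null(colnames(vectors)))
    colnames(vectors) <- c("hematoxylin", "dab", "residual")
  structure(list(vectors = vectors,
                 inverse = solve(vectors),
                 background_intensity = rep(background_intensity, length.out = 3L),
                 od_reference = od_reference),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("H-DAB stain model\n")
  print(round(x$vectors, 4))
  cat("background intensity:", paste(x$background_intensity, collapse = "/"),
      " od reference:", x$od_reference, "\n")
  invisible(x)
}

# coerce an image argument to an H x W x 3 numeric array of 0-255 values
as_rgb_array <- function(rgb) {
  if (is.character(rgb)) rgb <- read_rgb_image(rgb)
  rgb <- unclass(rgb)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("expected an RGB raster with 3 channels, got dimensions ",
         paste(dim(rgb), collapse = "x"))
  storage.mode(rgb) <- "double"
  rgb
}

#' Convert 8-bit RGB values to optical density
#'
#' Beer-Lambert transform `od = -log10((rgb + 1) / (I0 + 1))`. The +1 offset
#' on both numerator and denominator avoids `log(0)` at black pixels, maps a
#' pure background pixel (`rgb = I0`) to exactly zero absorbance, and makes
#' the transform the exact inverse of [forward_mix()]'s intensity model up
#' to 8-bit rounding.
#'
#' @param rgb H x W x 3 array (or numeric vector/matrix, transformed
#'   elementwise) of 8-bit values in \[0, 255\].
#' @param background_intensity transmitted light `I0`, scalar or length 3
#'   (per channel), default 255.
#' @return Optical density raster of the same shape (dimensionless, >= 0
#'   wherever `rgb <= I0`), strictly decreasing in each channel value.
#' @export
#' @examples
#' rgb_to_od(c(0, 127, 255))
rgb_to_od <- function(rgb, background_intensity = 255) {
  if (any(background_intensity <= 0)) stop("background_intensity must be > 0")
  if (is.array(rgb) && length(dim(rgb)) == 3L) {
    if (dim(rgb)[3] != 3L)
      stop("expected an RGB raster with 3 channels, got ",
           dim(rgb)[3], " channel(s)")
    i0 <- rep(background_intensity, length.out = 3L)
    od <- rgb
    for (ch in 1:3) od[, , ch] <- -log10((rgb[, , ch] + 1) / (i0[ch] + 1))
    return(od)
  }
  -log10((rgb + 1) / (background_intensity[1] + 1))
}

#' Unmix an RGB image into per-stain optical densities
#'
#' Converts the image to optical density and solves the linear Beer-Lambert
#' mixture `od = M c` per pixel via the inverse of the stain matrix.
#' Negative concentrations (numerical leakage) are clipped to zero.
#'
#' @param rgb path or H x W x 3 array of 8-bit RGB values.
#' @param model a [stain_model()].
#' @return List with H x W matrices `hematoxylin`, `dab`, `residual`
#'   (per-stain optical densities, >= 0).
#' @export
#' @examples
#' tile <- forward_mix(matrix(0.5, 4, 4), matrix(0.3, 4, 4))
#' d <- deconvolve(tile)
#' round(d$dab[1, 1], 2)
deconvolve <- function(rgb, model = stain_model()) {
  if (!inherits(model, "stain_model")) stop("`model` must be a stain_model")
  rgb <- as_rgb_array(rgb)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  od <- rgb_to_od(rgb, model$background_intensity)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- model$inverse %*% odm
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[1, ], h, w),
       dab         = matrix(conc[2, ], h, w),
       residual    = matrix(conc[3, ], h, w))
}

#' Render per-stain optical densities to an 8-bit RGB image
#'
#' Beer-Lambert forward model: channel od `u = M c`, transmitted intensity
#' `rgb = round((I0 + 1) * 10^(-u) - 1)` clipped to \[0, 255\]. Zero optical
#' density renders as pure background (white at the default `I0 = 255`);
#' [deconvolve()] recovers the stain densities up to 8-bit quantisation
#' wherever the transmitted signal stays above the quantisation floor.
#'
#' @param hematoxylin,dab H x W matrices of per-stain optical density (>= 0).
#' @param residual optional H x W matrix for the residual stain (default 0).
#' @param model a [stain_model()].
#' @return H x W x 3 integer-valued array of 8-bit RGB values.
#' @export
#' @examples
#' forward_mix(matrix(0, 1, 1), matrix(0, 1, 1))[1, 1, ]
forward_mix <- function(hematoxylin, dab, residual = NULL,
                        model = stain_model()) {
  if (!inherits(model, "stain_model")) stop("`model` must be a stain_model")
  hematoxylin <- as.matrix(hematoxylin); dab <- as.matrix(dab)
  if (is.null(residual)) residual <- matrix(0, nrow(hematoxylin), ncol(hematoxylin))
  residual <- as.matrix(residual)
  dims <- dim(hematoxylin)
  if (!identical(dims, dim(dab)) || !identical(dims, dim(residual)))
    stop("stain od rasters must share the same shape")
  if (min(hematoxylin, dab, residual) < 0)
    stop("stain od rasters must be non-negative")
  conc <- rbind(as.vector(hematoxylin), as.vector(dab), as.vector(residual))
  odch <- model$vectors %*% conc
  i0 <- model$background_intensity
  out <- array(0, c(dims[1], dims[2], 3L))
  for (ch in 1:3) {
    v <- round((i0[ch] + 1) * 10^(-odch[ch, ]) - 1)
    out[, , ch] <- matrix(pmin(pmax(v, 0), 255), dims[1], dims[2])
  }
  out
}

#' Normalise a DAB optical-density map to \[0, 1\]
#'
#' Divides by `od_reference` (the DAB optical density that maps to 1.0) and
#' clips to \[0, 1\]. Monotone non-decreasing and idempotent on
#' already-clipped inputs. The resulting map is the `DAB(x, y)` channel on
#' which the per-nucleus inverted mean statistic is computed.
#'
#' @param dab_od H x W matrix of DAB optical density (>= 0).
#' @param od_reference positive scalar (default 1.0).
#' @return Matrix of the same shape with values in \[0, 1\] and attribute
#'   `od_reference`.
#' @export
#' @examples
#' normalize_dab(matrix(c(0, 0.05, 2), 1, 3))
normalize_dab <- function(dab_od, od_reference = 1.0) {
  if (!is.numeric(od_reference) || length(od_reference) != 1L || od_reference <= 0)
    stop("od_reference must be a positive scalar")
  out <- clip01(as.matrix(dab_od) / od_reference)
  attr(out, "od_reference") <- od_reference
  out
}
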