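# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# adjacencies are merged afterwards with a union-find pass so that blobs
# touching only at corners form a single object (the convention used for
# nuclei throughout the package).
label8 <- function(bin) {
  bin <- bin != 0
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  lab <- matrix(as.integer(round(lab)), nrow(bin), ncol(bin))
  n <- max(lab, 0L)
  if (n <= 1L || nrow(lab) < 2L || ncol(lab) < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),  # down-right diag
    cbind(as.vector(lab[-nr, -1]),  as.vector(lab[-1, -nc]))) # down-left diag
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(n)
    findr <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      a <- findr(pairs[r, 1]); b <- findr(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), findr, integer(1))
    pos <- lab > 0L
    lab[pos] <- root[lab[pos]]
  }
  lab
}

# unique unordered pairs of distinct positive labels that touch under
# 8-connectivity
adjacent_label_pairs <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  ps <- list()
  if (nc >= 2L) ps[[length(ps) + 1L]] <-
    cbind(as.vector(lab[, -nc]), as.vector(lab[, -1]))          # right
  if (nr >= 2L) ps[[length(ps) + 1L]] <-
    cbind(as.vector(lab[-nr, ]), as.vector(lab[-1, ]))          # down
  if (nr >= 2L && nc >= 2L) {
    ps[[length(ps) + 1L]] <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
    ps[[length(ps) + 1L]] <- cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  }
  if (!length(ps)) return(matrix(integer(0), 0, 2))
  p <- do.call(rbind, ps)
  p <- p[p[, 1] > 0L & p[, 2] > 0L & p[, 1] != p[, 2], , drop = FALSE]
  if (!nrow(p)) return(matrix(integer(0), 0, 2))
  unique(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}

# fill interior holes of each labeled object, claiming only background
# pixels; existing foreground labels are never overwritten
fill_label_holes <- function(lab) {
  filled <- EBImage::imageData(EBImage::fillHull(lab))
  filled <- matrix(as.integer(round(filled)), nrow(lab), ncol(lab))
  pos <- lab > 0L
  filled[pos] <- lab[pos]
  filled
}

validate_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (!is.numeric(labels)) stop("instance mask must be a numeric label matrix")
  if (any(labels < 0)) stop("instance mask labels must be non-negative")
  if (any(abs(labels - round(labels)) > 1e-9))
    stop("instance mask labels must be integers")
  storage.mode(labels) <- "integer"
  labels
}

#' Postprocess a nucleus instance mask
#'
#' Cleans an instance label raster the way the inference pipeline expects:
#' spurious objects with area strictly below `min_area` are removed,
#' interior holes of each object are filled, and fragments that carry the
#' same input label and are 8-connected-adjacent after filling are merged
#' into one object. Surviving objects are relabeled 1..N in raster-scan
#' order (left-to-right within each row, rows top to bottom) of their first
#' pixel. The operation is idempotent.
#'
#' Objects are 8-connected components of a single input label; non-adjacent
#' fragments of one input label become distinct output labels.
#'
#' @param labels integer label matrix (0 = background).
#' @param min_area minimum object area in pixels (default 20); objects with
#'   area `< min_area` are removed, area `== min_area` survives.
#' @param fill_holes fill interior holes (default `TRUE`).
#' @param merge_fragments merge adjacent same-label fragments (default
#'   `TRUE`).
#' @return Integer label matrix with contiguous labels 1..N.
#' @export
#' @examples
#' m <- matrix(0L, 8, 8); m[2:6, 2:6] <- 1L; m[4, 4] <- 0L  # 24 px + hole
#' range(postprocess_instances(m))
postprocess_instances <- function(labels, min_area = 20, fill_holes = TRUE,
                                  merge_fragments = TRUE) {
  if (!is.numeric(min_area) || length(min_area) != 1L || min_area < 1)
    stop("min_area must be a positive number of pixels (>= 1)")
  labels <- validate_mask(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  empty <- matrix(0L, nr, nc)
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(empty)

  # split every input label into its 8-connected fragments
  frag <- matrix(0L, nr, nc)
  frag_origin <- integer(0)
  nfrag <- 0L
  for (lb in ids) {
    hit <- labels == lb
    rows <- range(which(rowSums(hit) > 0))
    cols <- range(which(colSums(hit) > 0))
    sub <- hit[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    fl <- label8(sub)
    k <- max(fl)
    tmp <- frag[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    tmp[sub] <- nfrag + fl[sub]
    frag[rows[1]:rows[2], cols[1]:cols[2]] <- tmp
    frag_origin <- c(frag_origin, rep(lb, k))
    nfrag <- nfrag + k
  }

  # small-object removal (strict inequality: area == min_area survives)
  areas <- tabulate(frag[frag > 0L], nbins = nfrag)
  small <- which(areas < min_area)
  if (length(small)) frag[frag %in% small] <- 0L
  if (!any(frag > 0L)) return(empty)

  if (fill_holes) frag <- fill_label_holes(frag)

  # merge fragments of the same original label that touch after filling
  group <- seq_len(nfrag)
  if (merge_fragments) {
    prs <- adjacent_label_pairs(frag)
    if (nrow(prs)) {
      prs <- prs[frag_origin[prs[, 1]] == frag_origin[prs[, 2]], , drop = FALSE]
      findr <- function(i) {
        while (group[i] != i) { group[i] <<- group[group[i]]; i <- group[i] }
        i
      }
      for (r in seq_len(nrow(prs))) {
        a <- findr(prs[r, 1]); b <- findr(prs[r, 2])
        if (a != b) group[max(a, b)] <- min(a, b)
      }
      group <- vapply(seq_len(nfrag), findr, integer(1))
    }
  }
  pos <- frag > 0L
  out <- matrix(0L, nr, nc)
  out[pos] <- group[frag[pos]]
  # a merged object may enclose a new interior hole; fill again so the
  # operation is a fixed point of itself
  if (fill_holes && merge_fragments) out <- fill_label_holes(out)

  # relabel 1..N by raster-scan first occurrence
  pos <- out > 0L
  scan_rank <- (row(out)[pos] - 1L) * nc + col(out)[pos]
  first <- tapply(scan_rank, out[pos], min)
  old <- as.integer(names(first))[order(first)]
  remap <- integer(max(old))
  remap[old] <- seq_along(old)
  out[pos] <- remap[out[pos]]
  out
}

#' Segment nuclei with a classical threshold + watershed pipeline
#'
#' Self-contained reference segmenter: the combined nuclear optical density
#' (hematoxylin + DAB after deconvolution) is smoothed, thresholded by
#' Otsu's method, and split into instances by a watershed on the distance
#' transform seeded at local maxima. The result is passed through
#' [postprocess_instances()]. Deterministic for fixed input and settings.
#'
#' @param rgb path or H x W x 3 array of 8-bit RGB values.
#' @param model a [stain_model()].
#' @param min_area,fill_holes,merge_fragments passed to
#'   [postprocess_instances()].
#' @param watershed_tolerance minimum depth separating two catchment basins
#'   before they are split (pixels of distance-map height, default 1).
#' @param seed_radius neighbourhood radius for local-maximum seed detection
#'   (pixels, default 2); larger values suppress close seeds.
#' @param smoothing_sigma Gaussian smoothing of the od map before
#'   thresholding (pixels, default 1; 0 disables).
#' @param min_od absolute optical-density floor for foreground (default
#'   0.1); a blank tile yields an empty mask rather than an error.
#' @return Integer label matrix (possibly all zero).
#' @export
fallback_segment <- function(rgb, model = stain_model(), min_area = 20,
                             fill_holes = TRUE, merge_fragments = TRUE,
                             watershed_tolerance = 1, seed_radius = 2,
                             smoothing_sigma = 1, min_od = 0.1) {
  rgb <- as_rgb_array(rgb)
  dec <- deconvolve(rgb, model)
  nuc <- dec$hematoxylin + dec$dab
  if (smoothing_sigma > 0)
    nuc <- EBImage::imageData(EBImage::gblur(EBImage::Image(nuc),
                                             sigma = smoothing_sigma))
  empty <- matrix(0L, nrow(nuc), ncol(nuc))
  mx <- max(nuc)
  if (mx <= min_od) return(empty)
  th <- EBImage::otsu(EBImage::Image(nuc / mx), range = c(0, 1)) * mx
  bin <- nuc > max(th, min_od)
  if (!any(bin)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance,
                           ext = seed_radius)
  labels <- matrix(as.integer(round(EBImage::imageData(ws))),
                   nrow(nuc), ncol(nuc))
  postprocess_instances(labels, min_area = min_area, fill_holes = fill_holes,
                        merge_fragments = merge_fragments)
}

#' Run an external instance segmenter through an adapter
#'
#' Bridges to an optional external nucleus segmenter (e.g. a flow-based
#' deep model run out of process). The adapter receives the RGB array and
#' must return an integer label raster of the same height/width; its output
#' is then passed through exactly the same [postprocess_instances()] step
#' as every other mask source. If no adapter is configured, a clear
#' optional-dependency error is raised (condition class
#' `ihc_optional_dependency_error`) rather than a crash.
#'
#' @param rgb path or H x W x 3 array of 8-bit RGB values.
#' @param adapter function of one argument (the RGB array) returning a
#'   label matrix, or `NULL` if the external tool is not installed.
#' @param min_area,fill_holes,merge_fragments passed to
#'   [postprocess_instances()].
#' @return Integer label matrix with contiguous labels 1..N.
#' @export
run_external_segmenter <- function(rgb, adapter = NULL, min_area = 20,
                                   fill_holes = TRUE, merge_fragments = TRUE) {
  if (is.null(adapter) || !is.function(adapter))
    stop(errorCondition(paste(
      "no external segmenter is configured: this is an optional dependency;",
      "supply `adapter` as a function(rgb) returning a label matrix,",
      "or use segmenter = 'fallback'"),
      class = c("ihc_optional_dependency_error", "error", "condition")))
  rgb <- as_rgb_array(rgb)
  labels <- validate_mask(adapter(rgb))
  if (!identical(dim(labels), dim(rgb)[1:2]))
    stop("adapter returned a mask of shape ",
         paste(dim(labels), collapse = "x"), " for an image of shape ",
         paste(dim(rgb)[1:2], collapse = "x"))
  postprocess_instances(labels, min_area = min_area, fill_holes = fill_holes,
                        merge_fragments = merge_fragments)
}
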