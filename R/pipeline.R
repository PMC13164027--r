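config_schema <- function() {
  list(
    stains = c("vectors", "background_intensity", "od_reference"),
    segmentation = c("source", "min_area", "fill_holes", "merge_fragments",
                     "watershed_tolerance", "seed_radius", "smoothing_sigma",
                     "min_od"),
    classification = c("tau1", "tau2", "tau3"),
    output = c("mu_digits", "pct_digits"),
    seed = NULL,
    log_level = NULL)
}

#' Default pipeline configuration
#'
#' @return Nested named list covering the stain model, segmentation source
#'   and postprocessing, classification thresholds, output formatting,
#'   seed and log level.
#' @export
default_config <- function() {
  list(
    stains = list(vectors = NULL, background_intensity = 255,
                  od_reference = 1.0),
    segmentation = list(source = "file", min_area = 20, fill_holes = TRUE,
                        merge_fragments = TRUE, watershed_tolerance = 1,
                        seed_radius = 2, smoothing_sigma = 1, min_od = 0.1),
    classification = list(tau1 = 0.89, tau2 = 0.94, tau3 = 0.975),
    output = list(mu_digits = 4, pct_digits = 2),
    seed = 1,
    log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Checks the nested configuration against the package schema; unknown
#' keys at either level are rejected so that typos cannot silently fall
#' back to defaults. Missing keys are filled from [default_config()].
#'
#' @param config nested named list (e.g. from [load_config()]).
#' @return The completed, validated configuration.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  base <- default_config()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (is.null(schema[[sec]])) next       # scalar key
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown configuration key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
    base[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  for (sec in intersect(names(config), c("seed", "log_level")))
    base[[sec]] <- config[[sec]]
  if (!base$segmentation$source %in% c("file", "fallback", "external"))
    stop("segmentation.source must be one of file/fallback/external")
  class_thresholds(base$classification$tau1, base$classification$tau2,
                   base$classification$tau3)   # validates ordering
  base
}

#' Load a YAML pipeline configuration
#'
#' @param path YAML file; keys override [default_config()], unknown keys
#'   are rejected.
#' @return Validated configuration list.
#' @export
load_config <- function(path) validate_config(yaml::read_yaml(path))

#' Save a configuration (or thresholds) to YAML
#'
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_model <- function(config) {
  stain_model(vectors = config$stains$vectors,
              background_intensity = config$stains$background_intensity,
              od_reference = config$stains$od_reference)
}

config_thresholds <- function(config) {
  class_thresholds(config$classification$tau1, config$classification$tau2,
                   config$classification$tau3)
}

#' Score a single IHC image
#'
#' End-to-end per-image pipeline: obtain an instance mask (from file, from
#' the built-in [fallback_segment()]er, or from an external adapter), apply
#' the shared [postprocess_instances()] step, classify every nucleus, and
#' derive the Allred result. Optionally writes the per-nucleus CSV, the
#' four-colour overlay PNG and a JSON report.
#'
#' @param image path to a PNG/TIFF tile, or an H x W x 3 8-bit array.
#' @param mask path to a label raster, an integer matrix, or `NULL` to use
#'   the segmenter named by `config$segmentation$source`.
#' @param config validated configuration (see [default_config()]).
#' @param output_dir directory for `<id>_nuclei.csv`, `<id>_overlay.png`,
#'   `<id>_report.json`; `NULL` writes nothing.
#' @param image_id identifier used in the report and file names.
#' @param adapter optional external-segmenter adapter for
#'   `source = "external"` (see [run_external_segmenter()]).
#' @return Object of class `ihc_report`: `image_id`, `n_nuclei`, `records`,
#'   `counts`, `thresholds`, `allred` (`NULL` when no nuclei), `status`
#'   (`"ok"` or `"undefined"`).
#' @export
score_image <- function(image, mask = NULL, config = default_config(),
                        output_dir = NULL, image_id = NULL, adapter = NULL) {
  config <- validate_config(config)
  if (is.null(image_id))
    image_id <- if (is.character(image))
      tools::file_path_sans_ext(basename(image)) else "image"
  model <- config_model(config)
  thresholds <- config_thresholds(config)
  rgb <- as_rgb_array(image)
  seg <- config$segmentation

  labels <-
    if (!is.null(mask)) {
      m <- if (is.character(mask)) load_instance_mask(mask) else validate_mask(mask)
      postprocess_instances(m, seg$min_area, seg$fill_holes,
                            seg$merge_fragments)
    } else if (seg$source == "fallback") {
      fallback_segment(rgb, model, min_area = seg$min_area,
                       fill_holes = seg$fill_holes,
                       merge_fragments = seg$merge_fragments,
                       watershed_tolerance = seg$watershed_tolerance,
                       seed_radius = seg$seed_radius,
                       smoothing_sigma = seg$smoothing_sigma,
                       min_od = seg$min_od)
    } else if (seg$source == "external") {
      run_external_segmenter(rgb, adapter, min_area = seg$min_area,
                             fill_holes = seg$fill_holes,
                             merge_fragments = seg$merge_fragments)
    } else {
      stop("segmentation.source is 'file' but no mask was supplied")
    }
  if (!identical(dim(labels), dim(rgb)[1:2]))
    stop("mask shape ", paste(dim(labels), collapse = "x"),
         " does not match image shape ", paste(dim(rgb)[1:2], collapse = "x"))

  res <- classify_image(rgb, labels, model, thresholds)
  n <- res$counts$total
  report <- structure(list(
    image_id = image_id,
    n_nuclei = n,
    records = res$records,
    counts = res$counts,
    thresholds = thresholds,
    allred = if (n > 0L) allred(res$counts) else NULL,
    status = if (n > 0L) "ok" else "undefined"), class = "ihc_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    recs <- res$records
    recs$mu <- round(recs$mu, config$output$mu_digits)
    utils::write.csv(recs, file.path(output_dir,
                                     paste0(image_id, "_nuclei.csv")),
                     row.names = FALSE)
    write_rgb_image(render_class_overlay(labels, res$records),
                    file.path(output_dir, paste0(image_id, "_overlay.png")))
    save_report(report, file.path(output_dir,
                                  paste0(image_id, "_report.json")),
                mu_digits = config$output$mu_digits,
                pct_digits = config$output$pct_digits)
  }
  report
}

#' @export
print.ihc_report <- function(x, ...) {
  cat("image:", x$image_id, "-", x$status, "\n")
  print(x$counts)
  if (!is.null(x$allred)) print(x$allred)
  invisible(x)
}

#' Serialise an image report to JSON
#'
#' @param report an `ihc_report` from [score_image()].
#' @param path output path.
#' @param mu_digits,pct_digits fixed decimal precision for `mu` and the
#'   positive percentage (defaults 4 and 2), keeping re-runs byte-identical.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path, mu_digits = 4, pct_digits = 2) {
  recs <- report$records
  obj <- list(
    image_id = report$image_id,
    status = report$status,
    n_nuclei = report$n_nuclei,
    thresholds = list(tau1 = report$thresholds$tau1,
                      tau2 = report$thresholds$tau2,
                      tau3 = report$thresholds$tau3),
    counts = list(strong = report$counts$strong,
                  moderate = report$counts$moderate,
                  weak = report$counts$weak,
                  negative = report$counts$negative,
                  total = report$counts$total),
    nuclei = list(id = recs$id, area_px = recs$area_px,
                  mu = round(recs$mu, mu_digits),
                  class = as.character(recs$class)),
    allred = if (is.null(report$allred)) NULL else list(
      positive_pct = round(report$allred$positive_pct, pct_digits),
      P = report$allred$P, I = report$allred$I,
      total = report$allred$total,
      recommendation = report$allred$recommendation))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load an image report saved by [save_report()]
#'
#' @param path JSON file.
#' @return An `ihc_report` (with `mu` at the serialised precision).
#' @export
load_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- count_table(obj$counts$strong, obj$counts$moderate,
                        obj$counts$weak, obj$counts$negative)
  nuc <- obj$nuclei
  records <- data.frame(id = as.integer(nuc$id),
                        area_px = as.integer(nuc$area_px),
                        mu = as.numeric(nuc$mu),
                        class = as_ihc_class(nuc$class))
  if (!nrow(records))
    records <- data.frame(id = integer(0), area_px = integer(0),
                          mu = numeric(0),
                          class = as_ihc_class(character(0)))
  structure(list(
    image_id = obj$image_id,
    n_nuclei = as.integer(obj$n_nuclei),
    records = records,
    counts = counts,
    thresholds = class_thresholds(obj$thresholds$tau1, obj$thresholds$tau2,
                                  obj$thresholds$tau3),
    allred = if (is.null(obj$allred)) NULL else {
      a <- allred(counts)
      a$positive_pct <- as.numeric(obj$allred$positive_pct)
      a
    },
    status = obj$status), class = "ihc_report")
}

#' Score a batch of images or count tables
#'
#' Runs [score_image()] over a manifest of image (and optional mask) paths,
#' or routes a counts-only manifest (columns `strong`, `moderate`, `weak`,
#' `negative`) through the scoring module directly. Failures are isolated
#' per row and recorded in the `status` column.
#'
#' @param manifest data frame or CSV path. Image mode: columns `image`
#'   (paths) and optionally `mask`; counts mode: the four count columns.
#' @param config validated configuration.
#' @param output_dir optional directory for per-image artifacts and
#'   `summary.csv`.
#' @return Summary `data.frame` with columns `image`, `total`, `strong`,
#'   `moderate`, `weak`, `negative`, `positive_pct`, `P`, `I`, `allred`,
#'   `recommendation`, `status`.
#' @export
score_batch <- function(manifest, config = default_config(),
                        output_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (!nrow(manifest)) stop("manifest is empty")
  config <- validate_config(config)
  counts_mode <- all(c("strong", "moderate", "weak", "negative") %in%
                     names(manifest))
  if (counts_mode) {
    scored <- score_counts(manifest)
    summary <- data.frame(
      image = if ("image" %in% names(manifest)) manifest$image
              else seq_len(nrow(manifest)),
      total = scored$total, strong = scored$strong,
      moderate = scored$moderate, weak = scored$weak,
      negative = scored$negative, positive_pct = scored$positive_pct,
      P = scored$P, I = scored$I, allred = scored$allred,
      recommendation = scored$recommendation, status = scored$status)
  } else {
    if (!"image" %in% names(manifest))
      stop("manifest needs an 'image' column (or the four count columns)")
    rows <- lapply(seq_len(nrow(manifest)), function(r) {
      id <- tools::file_path_sans_ext(basename(manifest$image[r]))
      tryCatch({
        rep_ <- score_image(manifest$image[r],
                            mask = if ("mask" %in% names(manifest) &&
                                       nzchar(manifest$mask[r]))
                                     manifest$mask[r] else NULL,
                            config = config, output_dir = output_dir,
                            image_id = id)
        ct <- rep_$counts
        data.frame(image = id, total = ct$total, strong = ct$strong,
                   moderate = ct$moderate, weak = ct$weak,
                   negative = ct$negative,
                   positive_pct = if (is.null(rep_$allred)) NA_real_
                                  else round(rep_$allred$positive_pct,
                                             config$output$pct_digits),
                   P = if (is.null(rep_$allred)) NA_integer_ else rep_$allred$P,
                   I = if (is.null(rep_$allred)) NA_integer_ else rep_$allred$I,
                   allred = if (is.null(rep_$allred)) NA_integer_
                            else rep_$allred$total,
                   recommendation = if (is.null(rep_$allred)) NA_character_
                                    else rep_$allred$recommendation,
                   status = rep_$status)
      }, error = function(e) {
        data.frame(image = id, total = NA_integer_, strong = NA_integer_,
                   moderate = NA_integer_, weak = NA_integer_,
                   negative = NA_integer_, positive_pct = NA_real_,
                   P = NA_integer_, I = NA_integer_, allred = NA_integer_,
                   recommendation = NA_character_,
                   status = paste0("error: ", conditionMessage(e)))
      })
    })
    summary <- do.call(rbind, rows)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  summary
}
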