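# Labelmap / image PNG interchange and config serialisation.
#
# Labelmaps travel as 8-bit single-channel PNG whose pixel value IS the
# class id (integer-exact, lossless); phantom intensities as grayscale
# PNG. Both are written by the png package.

#' Read a labelmap from a single-channel PNG
#'
#' The pixel value is interpreted as the class id. Multi-channel (RGB/RGBA)
#' files are rejected: a labelmap must be index-valued, and collapsing
#' colour channels would silently invent classes.
#'
#' @param path PNG file path.
#' @param class_set Optional [class_set()]; inferred (background 0) when
#'   omitted. Values outside a supplied class set are an error.
#' @return A [labelmap()].
#' @export
read_labelmap <- function(path, class_set = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L)
    stop("labelmap PNG must be single-channel, got ", dim(a)[3], " channels")
  labelmap(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)), class_set)
}

#' Write a labelmap to a single-channel PNG
#'
#' @param lab A [labelmap()] with class ids in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(lab, path) {
  stopifnot(inherits(lab, "labelmap"))
  v <- unclass(lab)
  if (any(v < 0 | v > 255)) stop("class ids must lie in 0..255 for PNG output")
  png::writePNG(v / 255, path)
  invisible(path)
}

#' Write a phantom intensity image to grayscale PNG
#'
#' Intensities are clipped to \[0, 1\].
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' Emits one grayscale PNG per image, one labelmap PNG per slice, and a
#' manifest CSV (`patient`, `slice`, `image`, `labelmap`, `seed`).
#'
#' @param records Cohort from [generate_patient_series()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Manifest data frame, invisibly.
#' @export
write_cohort <- function(records, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    base <- sprintf("%s_s%02d", r$patient, r$slice)
    ip <- file.path(dir, paste0(base, "_img.png"))
    lp <- file.path(dir, paste0(base, "_lab.png"))
    write_image_png(r$image, ip)
    write_labelmap(r$labelmap, lp)
    data.frame(patient = r$patient, slice = r$slice,
               image = ip, labelmap = lp, seed = seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Serialise a loss spec to a plain list (for YAML configs)
#'
#' @param spec A [loss_spec()].
#' @return Named list of the spec's fields.
#' @export
loss_spec_to_config <- function(spec) {
  stopifnot(inherits(spec, "loss_spec"))
  out <- list(family = spec$family, alpha = spec$alpha, beta = spec$beta,
              include_background = spec$include_background, eps = spec$eps)
  if (!is.null(spec$class_weights))
    out$class_weights <- as.numeric(spec$class_weights)
  out
}

#' Rebuild a loss spec from a config list
#'
#' Unknown keys are an error (configs fail fast rather than silently
#' ignoring typos).
#'
#' @param cfg Named list as produced by [loss_spec_to_config()].
#' @return A [loss_spec()].
#' @export
loss_spec_from_config <- function(cfg) {
  known <- c("family", "alpha", "beta", "include_background",
             "class_weights", "eps")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown loss config keys: ", paste(extra, collapse = ", "))
  loss_spec(family = cfg$family,
            alpha = if (is.null(cfg$alpha)) 1 else cfg$alpha,
            beta = if (is.null(cfg$beta)) 2 - (if (is.null(cfg$alpha)) 1 else cfg$alpha) else cfg$beta,
            include_background = if (is.null(cfg$include_background)) TRUE else cfg$include_background,
            class_weights = cfg$class_weights,
            eps = if (is.null(cfg$eps)) 1e-6 else cfg$eps)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path.
#' @return The configuration list, with a `config_hash` attribute (md5 of
#'   the file) for traceability of outputs.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}

#' Bundled reference fold table
#'
#' Loads the per-fold mean-IoU table of a published 5-fold MRI multi-organ
#' segmentation benchmark comparing four loss conditions (crossE, dice,
#' iou11, iou0515), shipped with the package as a CSV. Used to exercise
#' [fold_stats()] against independently reported summary statistics.
#'
#' @return Data frame with columns `condition`, `fold`, `iou`.
#' @export
reference_fold_table <- function() {
  path <- system.file("extdata", "mri_fold_iou.csv", package = "segloss")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
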