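# File-format plumbing: 8-bit PNG images, single-channel PNG label maps
# (codes 0-3), JSON sidecars and CSV manifests.

#' Read an RGB image
#' @param path PNG file path.
#' @return H x W x 3 numeric array with values in 0-255.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write an RGB image as 8-bit PNG
#' @param image H x W x 3 array, 0-255.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  stopifnot_image(image)
  png::writePNG(clip01(image / 255), path)
  invisible(path)
}

#' Write an integer label map as a single-channel PNG
#'
#' Class codes (0 background, 1 epithelial, 2 granulation, 3 necrotic)
#' are stored verbatim in the 8-bit gray channel, so the file is both a
#' machine-readable mask and inspectable with any image viewer.
#'
#' @param labels integer matrix of class codes (0-255).
#' @param path output path.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(all(labels >= 0), all(labels <= 255))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read an integer label map written by [write_label_png()]
#' @param path PNG path.
#' @return integer matrix.
#' @export
read_label_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write a scene (image, masks, truth) to a directory
#'
#' @param scene a `wound_scene`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  stopifnot(inherits(scene, "wound_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_lab <- file.path(dir, paste0(stem, "_labels.png"))
  p_wnd <- file.path(dir, paste0(stem, "_wound.png"))
  p_json <- file.path(dir, paste0(stem, "_truth.json"))
  write_image(scene$image, p_img)
  write_label_png(scene$tissue_labels, p_lab)
  write_label_png(scene$wound_mask, p_wnd)
  tr <- scene$truth
  jsonlite::write_json(list(
    mm_per_px = tr$mm_per_px, cast = tr$cast,
    pixel_counts = as.list(tr$pixel_counts),
    seed = tr$params$seed, px_per_mm = tr$params$px_per_mm,
    tissue_weights = as.list(tr$params$tissue_weights)),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, labels = p_lab, wound = p_wnd, truth = p_json))
}

#' Write a cohort to disk with a CSV manifest
#'
#' @param cohort a `wound_cohort`.
#' @param dir output directory.
#' @return path of the manifest CSV (columns subject_id, visit, image,
#'   labels, wound, truth).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wound_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (i in seq_along(cohort)) {
    r <- cohort[[i]]
    stem <- sprintf("%s_v%02d", r$subject_id, r$visit)
    paths <- write_scene(r$scene, dir, stem)
    rows <- rbind(rows, data.frame(subject_id = r$subject_id,
                                   visit = r$visit,
                                   image = paths[["image"]],
                                   labels = paths[["labels"]],
                                   wound = paths[["wound"]],
                                   truth = paths[["truth"]]))
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(rows, manifest, row.names = FALSE)
  manifest
}

# JSON run manifest recording how an artifact was produced.
write_run_manifest <- function(path, command, config, seed) {
  jsonlite::write_json(list(
    command = command, seed = seed, config = config,
    package_version = as.character(utils::packageVersion("woundmetry")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
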