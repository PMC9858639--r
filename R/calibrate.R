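# Automatic color and measurement calibration: sample the 24 chart patch
# colors through the fitted homography, fit the least-squares (Moore-
# Penrose pseudo-inverse) linear map onto the reference palette, apply it
# to the whole image, and estimate the mm-per-pixel scale from the marker
# geometry. The whole chain runs without user interaction.

#' Sample the 24 patch colors of the chart
#'
#' Projects each patch centre through the chart-to-image homography and
#' averages the RGB values over a window covering the central 40% of the
#' patch side (sampled on a grid in chart coordinates, so perspective is
#' handled exactly). Colors are returned row-major in the palette's
#' canonical order.
#'
#' @param image RGB image (H x W x 3, 0-255).
#' @param homography 3x3 chart(mm)-to-image(px) map.
#' @param spec a [chart_spec()].
#' @param window_frac fraction of the patch side covered by the sampling
#'   window (default 0.4; large enough to average sensor noise, small
#'   enough to avoid edge bleed).
#' @return 24 x 3 numeric matrix of mean patch RGB values.
#' @export
sample_patch_colors <- function(image, homography, spec = chart_spec(),
                                window_frac = 0.4) {
  stopifnot_image(image)
  geo <- chart_geometry(spec)
  half <- window_frac * spec$patch_side_mm / 2
  g <- seq(-half, half, length.out = 7)
  offs <- as.matrix(expand.grid(dx = g, dy = g))
  out <- matrix(0, nrow(geo$patch_centers_mm), 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  for (k in seq_len(nrow(out))) {
    pts_mm <- sweep(offs, 2, geo$patch_centers_mm[k, ], "+")
    p <- apply_homography(homography, pts_mm)
    if (any(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h))
      stop(sprintf("patch %d projects outside the image", k), call. = FALSE)
    for (ch in 1:3)
      out[k, ch] <- mean(bilinear_sample(image[, , ch], p[, 1], p[, 2]))
  }
  out
}

#' Fit a linear color-correction transform
#'
#' Computes the 3x3 matrix `M = pinv(source) %*% target`, the
#' least-squares linear map (via the Moore-Penrose pseudo-inverse) taking
#' observed patch colors (RGB row vectors) to their reference values.
#' There is no intercept term: the correction is purely linear in device
#' RGB, so black maps to black.
#'
#' @param source,target 24 x 3 matrices of observed and reference RGB.
#' @return An object of class `color_transform`: `matrix` (3x3),
#'   `fit_residual` (RMS over all patch channels), `source_colors`,
#'   `target_colors`, and `color_space_tag`.
#' @export
fit_color_transform <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3, ncol(target) == 3,
            nrow(source) == nrow(target))
  if (!all(is.finite(source)) || !all(is.finite(target)))
    stop("non-finite patch colors", call. = FALSE)
  sv <- svd(source)
  tol <- max(dim(source)) * max(sv$d) * .Machine$double.eps
  if (sum(sv$d > tol) < 3)
    stop("ill-conditioned fit: source colors are rank-deficient",
         call. = FALSE)
  pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  M <- pinv %*% target
  resid <- source %*% M - target
  structure(list(matrix = M,
                 fit_residual = sqrt(mean(resid^2)),
                 source_colors = source, target_colors = target,
                 color_space_tag = "sRGB-8bit"),
            class = "color_transform")
}

#' @export
print.color_transform <- function(x, ...) {
  cat("3x3 linear color transform, RMS fit residual",
      sprintf("%.3f", x$fit_residual), "\n")
  invisible(x)
}

identity_color_transform <- function() {
  pal <- reference_palette()$colors
  structure(list(matrix = diag(3), fit_residual = 0,
                 source_colors = pal, target_colors = pal,
                 color_space_tag = "sRGB-8bit"),
            class = "color_transform")
}

#' Apply a color transform to an image
#'
#' Maps every pixel's RGB row vector through the transform matrix and
#' clips the result to the 8-bit range.
#'
#' @param image RGB image (H x W x 3, 0-255).
#' @param transform a [fit_color_transform()] result.
#' @return Corrected image of the same size.
#' @export
apply_color_transform <- function(image, transform) {
  stopifnot_image(image)
  stopifnot(inherits(transform, "color_transform"))
  d <- dim(image)
  flat <- matrix(image, d[1] * d[2], 3) %*% transform$matrix
  array(clip255(flat), dim = d)
}

#' Fully automatic chart calibration of a photograph
#'
#' Runs the complete calibration chain on an image containing the chart:
#' marker detection, orientation/homography recovery, patch color
#' sampling, pseudo-inverse color-transform fit against the reference
#' palette, image correction, and metric scale estimation. Fails with a
#' chart-not-found error (naming the missing marker IDs) when fewer than
#' four markers decode — a partial chart would silently corrupt downstream
#' mm^2 measurements.
#'
#' @param image RGB image (H x W x 3, 0-255) containing the entire chart.
#' @param spec a [chart_spec()].
#' @param palette reference palette to calibrate against (defaults to the
#'   canonical chart palette; pass a measured one if available).
#' @return A list with `image` (the corrected image) and `result`, a
#'   `calibration_result` holding `transform`, `mm_per_px`, `homography`,
#'   and `diagnostics` (markers found, sampling window).
#' @examples
#' ch <- render_chart(chart_spec(), px_per_mm = 4)
#' cal <- calibrate(ch$image)
#' cal$result$mm_per_px
#' @export
calibrate <- function(image, spec = chart_spec(),
                      palette = reference_palette()) {
  dets <- detect_markers(image, spec)
  H <- normalize_orientation(dets, spec)
  src <- sample_patch_colors(image, H, spec)
  tr <- fit_color_transform(src, palette$colors)
  corrected <- apply_color_transform(image, tr)
  mm_per_px <- estimate_scale(H, spec)
  result <- structure(list(
    transform = tr, mm_per_px = mm_per_px, homography = H,
    diagnostics = list(n_markers = length(dets$markers),
                       marker_ids = vapply(dets$markers, `[[`, integer(1), "id"),
                       window_frac = 0.4)),
    class = "calibration_result")
  list(image = corrected, result = result)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: %d markers, mm/px = %.4f, color RMS residual = %.2f\n",
              x$diagnostics$n_markers, x$mm_per_px, x$transform$fit_residual))
  invisible(x)
}

#' Write a calibration result to a JSON sidecar
#'
#' @param result a `calibration_result`.
#' @param path output file path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  obj <- list(matrix = result$transform$matrix,
              fit_residual = result$transform$fit_residual,
              mm_per_px = result$mm_per_px,
              homography = result$homography,
              diagnostics = result$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
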