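# Planar projective geometry: direct linear transform (DLT) estimation of
# the 3x3 homography mapping chart-plane mm coordinates to image pixels,
# with Hartley normalization for conditioning.

# Apply a 3x3 homography to an n x 2 matrix of points (row vectors).
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2] / ph[, 3]
}

normalize_pts <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  Tm <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  list(T = Tm, pts = apply_homography(Tm, pts))
}

# Least-squares homography from >= 4 point correspondences (DLT + SVD).
fit_homography <- function(src, dst) {
  src <- matrix(src, ncol = 2); dst <- matrix(dst, ncol = 2)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4)
  ns <- normalize_pts(src); nd <- normalize_pts(dst)
  x <- ns$pts[, 1]; y <- ns$pts[, 2]
  u <- nd$pts[, 1]; v <- nd$pts[, 2]
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  # smallest right singular vector of A (eigenvector of A'A so the
  # null-space vector exists even in the minimal 4-point case)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12 || !all(is.finite(H)) || abs(det(H)) < 1e-12)
    stop("degenerate homography", call. = FALSE)
  H / H[3, 3]
}

#' Estimate the chart-to-image homography from detected markers
#'
#' Combines the sixteen detected marker corners with their known physical
#' positions on the chart to fit the projective map from chart-plane mm
#' coordinates to image pixels. The marker ID to corner assignment fixes
#' the in-plane orientation, so a photograph taken upside down yields the
#' same chart frame.
#'
#' @param dets marker detections from [detect_markers()].
#' @param spec the [chart_spec()] the chart was printed from.
#' @return A 3x3 homography matrix (mm -> px).
#' @export
normalize_orientation <- function(dets, spec = chart_spec()) {
  stopifnot(inherits(dets, "marker_detections"))
  found <- vapply(dets$markers, function(m) m$id, integer(1))
  missing <- setdiff(spec$marker_ids, found)
  if (length(missing))
    stop("chart not found: missing marker ID(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  geo <- chart_geometry(spec)
  src <- NULL; dst <- NULL
  for (m in dets$markers) {
    if (!(m$id %in% spec$marker_ids)) next
    src <- rbind(src, geo$marker_corners_mm[[as.character(m$id)]])
    dst <- rbind(dst, m$corners)
  }
  fit_homography(src, dst)
}

#' Estimate the metric scale (mm per pixel) in the chart plane
#'
#' Projects the four marker outlines through the fitted homography and
#' compares each projected side length in pixels with the known physical
#' marker side. The scale is the mean over all sixteen marker sides and is
#' valid in the plane of the chart.
#'
#' @param homography 3x3 chart(mm)-to-image(px) homography.
#' @param spec the [chart_spec()].
#' @return `mm_per_px`, a positive scalar.
#' @export
estimate_scale <- function(homography, spec = chart_spec()) {
  if (abs(det(homography)) < 1e-12)
    stop("degenerate homography", call. = FALSE)
  geo <- chart_geometry(spec)
  sides_px <- unlist(lapply(geo$marker_corners_mm, function(cm) {
    p <- apply_homography(homography, cm)
    d <- p[c(2, 3, 4, 1), ] - p
    sqrt(rowSums(d^2))
  }))
  if (any(!is.finite(sides_px)) || any(sides_px <= 0))
    stop("degenerate homography", call. = FALSE)
  mean(spec$marker_side_mm / sides_px)
}
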