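# Fiducial marker detection: threshold dark square candidates, extract
# their boundaries, fit quadrilaterals with sub-pixel edge refinement, and
# decode the inner 4x4 bit matrix against the marker dictionary. This is
# the standard square-fiducial pipeline (candidate squares by thresholding
# and contour analysis, then binary decoding), implemented on top of
# EBImage's connected-component labelling.

#' Detect chart fiducial markers in an image
#'
#' Finds the square binary markers of the calibration chart and reports,
#' for each decoded marker, its ID and four corner coordinates (sub-pixel,
#' ordered top-left, top-right, bottom-right, bottom-left in the marker's
#' own canonical frame, so orientation is recovered regardless of how the
#' photograph was rotated). Markers whose IDs are not in `spec$marker_ids`
#' are ignored. An image without a chart yields zero detections, not an
#' error.
#'
#' @param image RGB image, H x W x 3 numeric array with values in 0-255.
#' @param spec a [chart_spec()] naming the expected IDs and dictionary.
#' @return An object of class `marker_detections`: list with `markers`
#'   (each: `id`, `corners` 4x2, `confidence`) and `image_size`.
#' @export
detect_markers <- function(image, spec = chart_spec()) {
  stopifnot_image(image)
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  dict <- marker_dictionary(spec$marker_dictionary_name)
  markers <- list()
  # Two threshold guesses: half the median (robust when the chart is a
  # small part of a brighter scene) and the midpoint of the intensity
  # range (robust for dark scenes). First pass that decodes 4 wins.
  thrs <- unique(c(0.5 * median(gray),
                   (min(gray) + max(gray)) / 2))
  for (thr in thrs) {
    markers <- find_markers_at_threshold(gray, thr, spec, dict)
    if (length(markers) == 4L) break
  }
  structure(list(markers = markers, image_size = dim(gray)),
            class = "marker_detections")
}

#' @export
print.marker_detections <- function(x, ...) {
  ids <- vapply(x$markers, function(m) m$id, integer(1))
  cat(sprintf("%d marker(s) detected%s\n", length(ids),
              if (length(ids)) paste0(": IDs ", paste(sort(ids), collapse = ", "))
              else ""))
  invisible(x)
}

find_markers_at_threshold <- function(gray, thr, spec, dict) {
  bw <- gray < thr
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(bw * 1)
  n <- max(lab)
  if (n == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = n)
  min_area <- 80                       # marker side >= ~12 px
  max_area <- 0.25 * length(gray)
  markers <- list()
  for (i in which(areas >= min_area & areas <= max_area)) {
    px <- which(lab == i, arr.ind = TRUE)
    quad <- quad_from_component(px, lab, i)
    if (is.null(quad)) next
    dec <- decode_marker(gray, quad, dict)
    if (is.null(dec)) next
    id <- spec$marker_ids[dec$index]
    if (!(id %in% spec$marker_ids)) next
    if (any(vapply(markers, function(m) m$id == id, logical(1)))) next
    markers[[length(markers) + 1L]] <-
      list(id = id, corners = dec$corners, confidence = dec$margin)
  }
  markers
}

# Rough quadrilateral from a labelled component: convex hull of pixel
# centres, greedy selection of 4 extreme corners, then sub-pixel
# refinement by fitting lines to the component's outer boundary pixels.
quad_from_component <- function(px, lab, i) {
  x <- px[, 2] - 0.5; y <- px[, 1] - 0.5
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  if (length(hull) < 4) return(NULL)
  ctr <- c(mean(hx), mean(hy))
  c1 <- which.max((hx - ctr[1])^2 + (hy - ctr[2])^2)
  c2 <- which.max((hx - hx[c1])^2 + (hy - hy[c1])^2)
  tri <- abs((hx[c2] - hx[c1]) * (hy - hy[c1]) - (hy[c2] - hy[c1]) * (hx - hx[c1]))
  c3 <- which.max(tri)
  # fourth corner: maximize the total quad area over remaining hull points
  quad_area <- function(ix) {
    xs <- hx[c(c1, c2, c3, ix)]; ys <- hy[c(c1, c2, c3, ix)]
    o <- order(atan2(ys - mean(ys), xs - mean(xs)))
    xs <- xs[o]; ys <- ys[o]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }
  c4 <- which.max(vapply(seq_along(hull), quad_area, numeric(1)))
  corners <- cbind(hx[c(c1, c2, c3, c4)], hy[c(c1, c2, c3, c4)])
  if (nrow(unique(corners)) < 4) return(NULL)
  # order clockwise in image coordinates (y down)
  o <- order(atan2(corners[, 2] - mean(corners[, 2]),
                   corners[, 1] - mean(corners[, 1])))
  corners <- corners[o, ]
  # reject degenerate / non-convex shapes: quad area must be a reasonable
  # fraction of the hull's bounding region and sides non-trivial
  side_len <- sqrt(rowSums((corners[c(2, 3, 4, 1), ] - corners)^2))
  if (min(side_len) < 6 || max(side_len) / min(side_len) > 4) return(NULL)
  refine_quad(corners, px, lab, i)
}

# Sub-pixel refinement: collect the component's outer boundary pixels,
# assign each to the nearest quad side (excluding the corner zones), fit a
# total-least-squares line per side, push it outward by half a pixel
# (boundary pixel centres sit ~0.5 px inside the true edge), and intersect
# adjacent lines.
refine_quad <- function(corners, px, lab, i) {
  h <- nrow(lab); w <- ncol(lab)
  r <- px[, 1]; c <- px[, 2]
  at <- function(rr, cc) {
    out <- rr < 1 | rr > h | cc < 1 | cc > w
    v <- rep(0L, length(rr))
    v[!out] <- lab[cbind(rr[!out], cc[!out])]
    v
  }
  boundary <- at(r - 1, c) != i | at(r + 1, c) != i |
              at(r, c - 1) != i | at(r, c + 1) != i
  bx <- c[boundary] - 0.5; by <- r[boundary] - 0.5
  ctr <- colMeans(corners)
  lines <- vector("list", 4)
  for (k in 1:4) {
    a <- corners[k, ]; b <- corners[if (k == 4) 1 else k + 1, ]
    ab <- b - a; len <- sqrt(sum(ab^2)); u <- ab / len
    tpar <- (bx - a[1]) * u[1] + (by - a[2]) * u[2]
    dist <- abs((bx - a[1]) * u[2] - (by - a[2]) * u[1])
    sel <- dist < 1.5 & tpar > 0.15 * len & tpar < 0.85 * len
    if (sum(sel) >= 2) {
      mx <- mean(bx[sel]); my <- mean(by[sel])
      cv <- cbind(bx[sel] - mx, by[sel] - my)
      ev <- eigen(crossprod(cv), symmetric = TRUE)$vectors[, 1]
      nrm <- c(-ev[2], ev[1])
    } else { mx <- mean(c(a[1], b[1])); my <- mean(c(a[2], b[2]))
             nrm <- c(-u[2], u[1]) }
    # orient the normal away from the quad centre, shift line out 0.5 px
    if (sum(nrm * (c(mx, my) - ctr)) < 0) nrm <- -nrm
    p0 <- c(mx, my) + 0.5 * nrm
    lines[[k]] <- list(n = nrm, d = sum(nrm * p0))  # n . x = d
  }
  out <- corners
  for (k in 1:4) {
    l1 <- lines[[if (k == 1) 4 else k - 1]]; l2 <- lines[[k]]
    A <- rbind(l1$n, l2$n)
    if (abs(det(A)) < 1e-8) next
    out[k, ] <- solve(A, c(l1$d, l2$d))
  }
  if (any(sqrt(rowSums((out - corners)^2)) > 3)) corners else out
}

# Decode the 4x4 bit pattern inside a candidate quad. Returns NULL unless
# the black border verifies and the bits match a dictionary entry under
# some rotation; otherwise the dictionary index, the corners re-ordered so
# row 1 is the marker's canonical top-left corner, and a contrast margin.
decode_marker <- function(gray, corners, dict) {
  Hm <- tryCatch(
    fit_homography(rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6)), corners),
    error = function(e) NULL)
  if (is.null(Hm)) return(NULL)
  ctrs <- expand.grid(cx = (1:6) - 0.5, cy = (1:6) - 0.5)
  # average a tiny 3x3 cluster of samples per cell for noise robustness
  off <- expand.grid(dx = c(-0.15, 0, 0.15), dy = c(-0.15, 0, 0.15))
  vals <- matrix(0, 36, nrow(off))
  for (s in seq_len(nrow(off))) {
    p <- apply_homography(Hm, cbind(ctrs$cx + off$dx[s], ctrs$cy + off$dy[s]))
    vals[, s] <- bilinear_sample(gray, p[, 1], p[, 2])
  }
  cellv <- matrix(rowMeans(vals), 6, 6, byrow = TRUE)  # [row, col] cells
  thr <- (min(cellv) + max(cellv)) / 2
  if (!all(cellv[1, ] < thr, cellv[6, ] < thr,
           cellv[, 1] < thr, cellv[, 6] < thr)) return(NULL)
  bits <- (cellv[2:5, 2:5] >= thr) * 1
  margin <- min(abs(cellv - thr)) / max(1, max(cellv) - min(cellv))
  for (idx in seq_along(dict)) {
    b <- bits
    for (rot in 0:3) {
      if (all(b == dict[[idx]])) {
        # bits match after rotating the *sampled* pattern `rot` times CW,
        # so the canonical TL corner sits `rot` steps back along the quad
        ord <- ((0:3 - rot) %% 4) + 1
        return(list(index = idx, corners = corners[ord, , drop = FALSE],
                    margin = margin))
      }
      b <- rot90cw(b)
    }
  }
  NULL
}
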