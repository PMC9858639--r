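#' Calibration chart specification
#'
#' Describes the physical geometry of the combined fiducial-marker /
#' color-reference chart: a 75 x 35 mm card carrying four square binary
#' fiducial markers (12.7 mm side) at its corners and a 6 x 4 grid of
#' 24 color patches (6.35 mm side) — the classic 24-patch color rendition
#' chart — centred between them. The chart doubles as a ruler: the known
#' marker side length anchors the mm-per-pixel scale of a photograph.
#'
#' @param chart_width_mm,chart_height_mm physical card size in mm.
#' @param marker_side_mm side length of each corner fiducial marker, mm.
#' @param patch_side_mm side length of each color patch, mm.
#' @param marker_margin_mm gap between the card edge and each marker, mm.
#' @param marker_ids integer IDs of the four markers in corner order
#'   top-left, top-right, bottom-right, bottom-left.
#' @param marker_dictionary_name name of the 4 x 4 bit dictionary used to
#'   encode marker IDs (only `"wm4x4"`, the built-in dictionary, is known).
#' @return An object of class `chart_spec`.
#' @examples
#' spec <- chart_spec()
#' spec$chart_width_mm
#' @export
chart_spec <- function(chart_width_mm = 75, chart_height_mm = 35,
                       marker_side_mm = 12.7, patch_side_mm = 6.35,
                       marker_margin_mm = 2,
                       marker_ids = c(0L, 1L, 2L, 3L),
                       marker_dictionary_name = "wm4x4") {
  grid_rows <- 4L; grid_cols <- 6L
  stopifnot(chart_width_mm > 0, chart_height_mm > 0, marker_side_mm > 0,
            patch_side_mm > 0, marker_margin_mm >= 0)
  if (length(marker_ids) != 4L || anyDuplicated(marker_ids))
    stop("marker_ids must be four distinct IDs", call. = FALSE)
  if (grid_cols * patch_side_mm > chart_width_mm ||
      grid_rows * patch_side_mm > chart_height_mm)
    stop("patch grid does not fit on the chart", call. = FALSE)
  structure(list(
    chart_width_mm = chart_width_mm, chart_height_mm = chart_height_mm,
    marker_side_mm = marker_side_mm, patch_side_mm = patch_side_mm,
    marker_margin_mm = marker_margin_mm,
    grid_rows = grid_rows, grid_cols = grid_cols,
    marker_ids = as.integer(marker_ids),
    marker_dictionary_name = marker_dictionary_name
  ), class = "chart_spec")
}

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf("calibration chart %g x %g mm; %d markers (%g mm), %dx%d patches (%g mm)\n",
              x$chart_width_mm, x$chart_height_mm, length(x$marker_ids),
              x$marker_side_mm, x$grid_rows, x$grid_cols, x$patch_side_mm))
  invisible(x)
}

#' Reference palette of the 24-patch color chart
#'
#' The canonical sRGB coordinates of the 24 patches of the classic color
#' rendition chart, in row-major order starting at the patch nearest the
#' top-left marker (row 1: dark skin ... bluish green; row 4: white ...
#' black). Values are 8-bit device sRGB, not linearized; substitute a
#' measured palette here if your printed chart was profiled.
#'
#' @return An object of class `reference_palette`: a list with `colors`
#'   (24 x 3 integer matrix, 0-255) and `color_space_tag` (`"sRGB-8bit"`).
#' @examples
#' pal <- reference_palette()
#' nrow(pal$colors)
#' @export
reference_palette <- function() {
  colors <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52),
    ncol = 3, byrow = TRUE)
  rownames(colors) <- c(
    "dark skin", "light skin", "blue sky", "foliage", "blue flower",
    "bluish green", "orange", "purplish blue", "moderate red", "purple",
    "yellow green", "orange yellow", "blue", "green", "red", "yellow",
    "magenta", "cyan", "white", "neutral 8", "neutral 6.5", "neutral 5",
    "neutral 3.5", "black")
  structure(list(colors = colors, color_space_tag = "sRGB-8bit"),
            class = "reference_palette")
}

# Built-in 4 x 4 marker bit dictionary ("wm4x4"). Entry value 1 = white
# cell, 0 = black. All 16 rotations of the four patterns are pairwise
# distinct, so the in-plane orientation of the chart is recoverable from
# any single decoded marker.
marker_dictionary <- function(name = "wm4x4") {
  if (!identical(name, "wm4x4"))
    stop("unknown marker dictionary: ", name, call. = FALSE)
  list(
    matrix(c(1,0,0,0, 0,1,1,0, 0,0,1,0, 1,1,0,1), 4, 4, byrow = TRUE),
    matrix(c(0,1,1,1, 1,0,0,0, 1,0,1,1, 0,0,1,0), 4, 4, byrow = TRUE),
    matrix(c(1,1,0,0, 0,0,1,1, 0,1,0,1, 1,0,1,0), 4, 4, byrow = TRUE),
    matrix(c(0,0,1,0, 1,1,0,1, 1,0,0,0, 0,1,1,1), 4, 4, byrow = TRUE))
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# Chart-frame geometry, all in mm with the origin at the card's top-left
# corner, x right / y down. Markers sit marker_margin_mm in from the card
# corners; the patch grid is centred on the card (it clears the marker
# columns for the default dimensions). Returned corner order per marker is
# TL, TR, BR, BL in the chart frame.
chart_geometry <- function(spec) {
  m <- spec$marker_margin_mm; s <- spec$marker_side_mm
  w <- spec$chart_width_mm; h <- spec$chart_height_mm
  marker_tl <- list(c(m, m), c(w - m - s, m), c(w - m - s, h - m - s),
                    c(m, h - m - s))
  corners <- lapply(marker_tl, function(tl) {
    rbind(tl, tl + c(s, 0), tl + c(s, s), tl + c(0, s))
  })
  names(corners) <- as.character(spec$marker_ids)
  gw <- spec$grid_cols * spec$patch_side_mm
  gh <- spec$grid_rows * spec$patch_side_mm
  grid_origin <- c((w - gw) / 2, (h - gh) / 2)
  centers <- matrix(0, spec$grid_rows * spec$grid_cols, 2)
  k <- 1L
  for (i in seq_len(spec$grid_rows)) for (j in seq_len(spec$grid_cols)) {
    centers[k, ] <- grid_origin +
      c((j - 0.5) * spec$patch_side_mm, (i - 0.5) * spec$patch_side_mm)
    k <- k + 1L
  }
  list(marker_corners_mm = corners, patch_centers_mm = centers,
       grid_origin_mm = grid_origin,
       margins_mm = c(left = grid_origin[1] - (m + s), top = grid_origin[2]))
}

# Fill an axis-aligned mm rectangle [x0,x1) x [y0,y1) with a color.
# Rasterization convention: the pixel at row r, column c covers
# [(c-1)/ppm, c/ppm) x [(r-1)/ppm, r/ppm) mm; a pixel is painted when its
# centre falls inside the rectangle.
fill_rect_mm <- function(img, x0, x1, y0, y1, ppm, col) {
  cs <- seq_len(dim(img)[2]); rs <- seq_len(dim(img)[1])
  cc <- cs[(cs - 0.5) / ppm >= x0 & (cs - 0.5) / ppm < x1]
  rr <- rs[(rs - 0.5) / ppm >= y0 & (rs - 0.5) / ppm < y1]
  if (length(cc) && length(rr)) for (ch in 1:3) img[rr, cc, ch] <- col[ch]
  img
}

#' Render the calibration chart to pixels
#'
#' Rasterizes the chart at a requested resolution and returns both the
#' image and exact ground-truth pixel coordinates of every marker corner
#' and patch centre (useful for synthetic scenes and for verifying the
#' detector). Pixel coordinates follow the convention that the centre of
#' pixel `[r, c]` is at `(c - 0.5, r - 0.5)`, so a physical point at
#' `(x, y)` mm maps to pixel coordinate `(x, y) * px_per_mm`.
#'
#' @param spec a [chart_spec()].
#' @param px_per_mm rendering resolution; must be at least 2 so that each
#'   marker bit cell spans at least ~4 px and remains decodable.
#' @return A list with `image` (H x W x 3 array, 0-255) and `truth`
#'   (marker corners and patch centres in px, the palette, `px_per_mm`,
#'   derived layout margins, and an echo of `spec`).
#' @examples
#' ch <- render_chart(chart_spec(), px_per_mm = 4)
#' dim(ch$image)
#' @export
render_chart <- function(spec = chart_spec(), px_per_mm = 10) {
  stopifnot(inherits(spec, "chart_spec"))
  if (px_per_mm < 2)
    stop("px_per_mm must be >= 2: marker bit cells would be unresolvable",
         call. = FALSE)
  W <- round(spec$chart_width_mm * px_per_mm)
  H <- round(spec$chart_height_mm * px_per_mm)
  img <- array(255, dim = c(H, W, 3))
  geo <- chart_geometry(spec)
  dict <- marker_dictionary(spec$marker_dictionary_name)
  cell <- spec$marker_side_mm / 6   # 1-cell black border + 4x4 bits
  for (k in 1:4) {
    tl <- geo$marker_corners_mm[[k]][1, ]
    bits <- dict[[spec$marker_ids[k] + 1L]]
    for (i in 1:6) for (j in 1:6) {
      inner <- i >= 2 && i <= 5 && j >= 2 && j <= 5
      v <- if (inner && bits[i - 1, j - 1] == 1) 255 else 0
      if (v == 0 || inner)
        img <- fill_rect_mm(img, tl[1] + (j - 1) * cell, tl[1] + j * cell,
                            tl[2] + (i - 1) * cell, tl[2] + i * cell,
                            px_per_mm, rep(v, 3))
    }
  }
  pal <- reference_palette()
  half <- spec$patch_side_mm / 2
  for (k in seq_len(nrow(geo$patch_centers_mm))) {
    ctr <- geo$patch_centers_mm[k, ]
    img <- fill_rect_mm(img, ctr[1] - half, ctr[1] + half,
                        ctr[2] - half, ctr[2] + half, px_per_mm,
                        pal$colors[k, ])
  }
  truth <- list(
    marker_corners_px = lapply(geo$marker_corners_mm, function(m) m * px_per_mm),
    patch_centers_px = geo$patch_centers_mm * px_per_mm,
    palette = pal, px_per_mm = px_per_mm,
    margins_mm = geo$margins_mm, spec = spec)
  list(image = img, truth = truth)
}
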