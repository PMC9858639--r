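# Data augmentation for segmentation training. Geometric operations are
# applied identically to the image and every mask (masks with
# nearest-neighbour sampling so they stay integer-valued); photometric
# operations touch the image only. With all toggles off the function is
# the identity.

#' Training-time augmentation of an image and its masks
#'
#' Applies the enabled operations in a fixed order: central crop,
#' horizontal flip, vertical flip, grid distortion, brightness shift,
#' contrast scaling, additive Gaussian noise. Flips and crop are
#' deterministic; distortion, brightness, contrast and noise draw their
#' magnitudes from the current RNG state.
#'
#' @param image RGB image (H x W x 3, 0-255).
#' @param masks named list of integer matrices (e.g. `wound_mask`,
#'   `tissue_labels`) transformed alongside the image.
#' @param ops list of toggles/magnitudes: `crop` (target side in px or
#'   NULL), `hflip`, `vflip`, `grid_distortion` (logical), `brightness`
#'   (max absolute shift, 0 disables), `contrast` (max relative change,
#'   0 disables), `gaussian_noise` (noise SD, 0 disables),
#'   `distort_strength` (control-node displacement as a fraction of a
#'   grid cell, default 0.3. The field is divergence-free (a stream-function
#'   warp), so it perturbs contours while leaving per-class pixel counts
#'   approximately unchanged, which the class-weighted loss relies on).
#' @return list with `image` and `masks`.
#' @export
augment <- function(image, masks, ops = list()) {
  stopifnot_image(image)
  o <- modifyList(list(crop = NULL, hflip = FALSE, vflip = FALSE,
                       grid_distortion = FALSE, brightness = 0,
                       contrast = 0, gaussian_noise = 0,
                       distort_strength = 0.3), ops)
  if (!is.null(o$crop)) {
    h <- dim(image)[1]; w <- dim(image)[2]
    if (h < o$crop || w < o$crop)
      stop("image smaller than the requested crop", call. = FALSE)
    r0 <- floor((h - o$crop) / 2); c0 <- floor((w - o$crop) / 2)
    rr <- r0 + seq_len(o$crop); cc <- c0 + seq_len(o$crop)
    image <- image[rr, cc, , drop = FALSE]
    masks <- lapply(masks, function(m) m[rr, cc, drop = FALSE])
  }
  if (isTRUE(o$hflip)) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    masks <- lapply(masks, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
  }
  if (isTRUE(o$vflip)) {
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
    masks <- lapply(masks, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  }
  if (isTRUE(o$grid_distortion)) {
    gd <- grid_distortion_field(dim(image)[1], dim(image)[2],
                                strength = o$distort_strength)
    image <- warp_field(image, gd, interp = "bilinear")
    masks <- lapply(masks, function(m) warp_field_mask(m, gd))
  }
  if (o$brightness > 0)
    image <- clip255(image + runif(1, -o$brightness, o$brightness))
  if (o$contrast > 0) {
    f <- 1 + runif(1, -o$contrast, o$contrast)
    image <- clip255((image - 127.5) * f + 127.5)
  }
  if (o$gaussian_noise > 0)
    image <- clip255(image + array(rnorm(length(image), 0, o$gaussian_noise),
                                   dim(image)))
  list(image = image, masks = masks)
}

# Smooth random displacement field from a coarse control grid. The field
# is the rotated gradient of a random stream function (dx = dpsi/dy,
# dy = -dpsi/dx), so its discrete divergence is exactly zero: the warp
# bends contours without inflating or shrinking regions, keeping
# per-class pixel counts (and hence the class statistics the weighted
# loss depends on) approximately invariant. `strength` is the peak
# displacement as a fraction of a grid cell.
grid_distortion_field <- function(h, w, n_cells = 4, strength = 0.3) {
  psi_c <- matrix(rnorm((n_cells + 1)^2), n_cells + 1)
  # constant border => zero tangential flow through the frame edge
  psi_c[c(1, n_cells + 1), ] <- 0; psi_c[, c(1, n_cells + 1)] <- 0
  ry <- (seq_len(h) - 0.5) / h * n_cells + 0.5   # position in grid units
  cx <- (seq_len(w) - 0.5) / w * n_cells + 0.5
  psi <- matrix(bilinear_sample(psi_c, matrix(cx, h, w, byrow = TRUE),
                                matrix(ry, h, w)), h, w)
  dpsi_dy <- (rbind(psi[-1, ], psi[h, ]) - rbind(psi[1, ], psi[-h, ])) / 2
  dpsi_dx <- (cbind(psi[, -1], psi[, w]) - cbind(psi[, 1], psi[, -w])) / 2
  mx <- max(abs(c(dpsi_dy, dpsi_dx)), 1e-9)
  sc <- strength * min(h, w) / n_cells / mx
  list(dx = dpsi_dy * sc, dy = -dpsi_dx * sc)
}

warp_field <- function(img, field, interp = "bilinear") {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE) + field$dx
  ys <- matrix(seq_len(h) - 0.5, h, w) + field$dy
  out <- img
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], xs, ys), h, w)
  out
}

warp_field_mask <- function(m, field) {
  h <- nrow(m); w <- ncol(m)
  xs <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE) + field$dx
  ys <- matrix(seq_len(h) - 0.5, h, w) + field$dy
  cc <- pmin(pmax(round(xs + 0.5), 1), w)
  rr <- pmin(pmax(round(ys + 0.5), 1), h)
  matrix(m[cbind(as.vector(rr), as.vector(cc))], h, w)
}

#' Scale-and-crop an image to a square working size
#'
#' Standardizes arbitrarily sized photographs for the network: scales the
#' shorter side to `size` (preserving aspect ratio) and centrally crops a
#' `size` x `size` square.
#'
#' @param image RGB image (H x W x 3, 0-255).
#' @param size target side in px.
#' @return `size` x `size` x 3 image.
#' @export
center_square_resize <- function(image, size = 1280) {
  stopifnot_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  f <- size / min(h, w)
  nh <- round(h * f); nw <- round(w * f)
  res <- EBImage::resize(aperm(image, c(2, 1, 3)) / 255, w = nw, h = nh)
  img <- aperm(res * 255, c(2, 1, 3))
  r0 <- floor((nh - size) / 2); c0 <- floor((nw - size) / 2)
  img[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}
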