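#' @useDynLib woundmetry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic package code funnels
# through this so a seed in a config fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

stopifnot_image <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop("expected an RGB image as an H x W x 3 numeric array", call. = FALSE)
  invisible(img)
}

# Bilinear interpolation of a single-channel matrix at continuous pixel
# coordinates (x right, y down; the centre of pixel [r, c] sits at
# x = c - 0.5, y = r - 0.5). Points outside the image clamp to the border.
bilinear_sample <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  cx <- pmin(pmax(x + 0.5, 1), w)   # continuous column index
  cy <- pmin(pmax(y + 0.5, 1), h)
  c0 <- pmin(floor(cx), w - 1L); r0 <- pmin(floor(cy), h - 1L)
  fx <- cx - c0; fy <- cy - r0
  i00 <- (c0 - 1) * h + r0
  v00 <- mat[i00]; v10 <- mat[i00 + 1]
  v01 <- mat[i00 + h]; v11 <- mat[i00 + h + 1]
  (1 - fx) * ((1 - fy) * v00 + fy * v10) + fx * ((1 - fy) * v01 + fy * v11)
}

# Inverse-mapped perspective warp of an RGB image: for every output pixel,
# sample the source at H^-1 (x, y) with bilinear interpolation.
warp_perspective <- function(img, H, out_h = dim(img)[1], out_w = dim(img)[2],
                             fill = 0) {
  stopifnot_image(img)
  Hi <- solve(H)
  xy <- expand.grid(x = seq_len(out_w) - 0.5, y = seq_len(out_h) - 0.5)
  src <- apply_homography(Hi, cbind(xy$x, xy$y))
  inside <- src[, 1] >= 0 & src[, 1] <= dim(img)[2] &
            src[, 2] >= 0 & src[, 2] <= dim(img)[1]
  out <- array(fill, dim = c(out_h, out_w, 3))
  for (ch in 1:3) {
    v <- bilinear_sample(img[, , ch], src[, 1], src[, 2])
    v[!inside] <- fill
    out[, , ch] <- matrix(v, out_h, out_w, byrow = TRUE)
  }
  out
}

rotate_image_90 <- function(img, times = 1L) {
  stopifnot_image(img)
  times <- ((times %% 4) + 4) %% 4
  for (i in seq_len(times)) {
    h <- dim(img)[1]; w <- dim(img)[2]
    out <- array(0, dim = c(w, h, 3))
    for (ch in 1:3) out[, , ch] <- t(img[h:1, , ch])
    img <- out
  }
  img
}
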