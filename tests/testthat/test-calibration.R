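test_that("markers on a rendered chart are detected with sub-pixel corners", {
  for (ppm in c(5, 10)) {
    ch <- chart_at(ppm)
    dets <- detect_markers(ch$image, chart_spec())
    expect_length(dets$markers, 4L)
    ids <- sort(vapply(dets$markers, `[[`, integer(1), "id"))
    expect_equal(ids, 0:3)
    for (m in dets$markers) {
      tru <- ch$truth$marker_corners_px[[as.character(m$id)]]
      expect_lt(max(sqrt(rowSums((m$corners - tru)^2))), 1)
    }
  }
})

test_that("detection is equivariant to in-plane rotation and ignores blank images", {
  ch <- chart_at(5)
  h <- dim(ch$image)[1]
  rot <- woundmetry:::rotate_image_90(ch$image, 1)
  dets <- detect_markers(rot, chart_spec())
  expect_length(dets$markers, 4L)
  for (m in dets$markers) {
    tru <- ch$truth$marker_corners_px[[as.character(m$id)]]
    tru_rot <- cbind(h - tru[, 2], tru[, 1])   # 90 deg CW map
    expect_lt(max(sqrt(rowSums((m$corners - tru_rot)^2))), 1)
  }
  blank <- array(255, c(64, 64, 3))
  expect_length(detect_markers(blank, chart_spec())$markers, 0L)
})

test_that("orientation recovery needs all four markers and reports the missing", {
  ch <- chart_at(5)
  dets <- detect_markers(ch$image, chart_spec())
  dets$markers <- dets$markers[vapply(dets$markers, `[[`, integer(1), "id") != 2L]
  expect_error(normalize_orientation(dets, chart_spec()), "missing marker ID\\(s\\) 2")
})

test_that("homography matches the rendering transform and survives perspective", {
  ch <- chart_at(10)
  H <- normalize_orientation(detect_markers(ch$image, chart_spec()), chart_spec())
  # frontal: similarity with scale = px/mm
  pts <- rbind(c(0, 0), c(75, 0), c(75, 35), c(0, 35), c(37.5, 17.5))
  expect_lt(max(abs(woundmetry:::apply_homography(H, pts) - pts * 10)), 0.5)
  # known projective warp is recovered within 0.5 px reprojection
  Hw <- rbind(c(0.95, 0.08, 30), c(-0.05, 1.02, 40), c(1e-4, 5e-5, 1))
  warped <- woundmetry:::warp_perspective(ch$image, Hw, out_h = 520,
                                          out_w = 900, fill = 210)
  H2 <- normalize_orientation(detect_markers(warped, chart_spec()), chart_spec())
  Htrue <- Hw %*% rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 1))
  err <- sqrt(rowSums((woundmetry:::apply_homography(H2, pts) -
                       woundmetry:::apply_homography(Htrue, pts))^2))
  expect_lt(max(err), 0.5)
})

test_that("patch sampling returns palette colors, tolerates noise, rejects off-image grids", {
  ch <- chart_at(10)
  spec <- chart_spec()
  H <- normalize_orientation(detect_markers(ch$image, spec), spec)
  pal <- reference_palette()$colors
  expect_lt(max(abs(sample_patch_colors(ch$image, H, spec) - pal)), 1)
  withr::with_seed(7, {
    noisy <- woundmetry:::clip255(ch$image +
      array(rnorm(length(ch$image), 0, 5), dim(ch$image)))
    expect_lt(max(abs(sample_patch_colors(noisy, H, spec) - pal)), 3)
  })
  H_off <- H; H_off[1, 3] <- H_off[1, 3] + 1e5
  expect_error(sample_patch_colors(ch$image, H_off, spec), "outside")
})

test_that("pseudo-inverse color fit recovers known linear maps", {
  pal <- reference_palette()$colors
  tr <- fit_color_transform(pal, pal)
  expect_equal(tr$matrix, diag(3), tolerance = 1e-8)
  expect_lt(tr$fit_residual, 1e-8)
  withr::with_seed(3, {
    M <- diag(3) + matrix(runif(9, -0.2, 0.2), 3)
    src <- pal %*% M
    tr2 <- fit_color_transform(src, pal)
    expect_equal(tr2$matrix, solve(M), tolerance = 1e-6)
    expect_lt(max(abs(src %*% tr2$matrix - pal)), 1e-6)
  })
  expect_error(fit_color_transform(matrix(1, 24, 3), pal), "ill-conditioned")
})

test_that("pseudo-inverse fit equals the normal-equations least squares solution", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      S <- matrix(runif(72, 0, 255), 24, 3)
      T <- matrix(runif(72, 0, 255), 24, 3)
      M <- fit_color_transform(S, T)$matrix
      M_ne <- solve(crossprod(S), crossprod(S, T))  # independent route
      expect_lt(max(abs(M - M_ne)), 1e-8)
    }
    # residual equals the brute-force least-squares residual when one
    # row is perturbed
    pal <- reference_palette()$colors
    src <- pal; src[5, ] <- src[5, ] + c(30, -20, 10)
    tr <- fit_color_transform(src, pal)
    resid_bf <- sqrt(mean((src %*% solve(crossprod(src), crossprod(src, pal)) - pal)^2))
    expect_equal(tr$fit_residual, resid_bf, tolerance = 1e-10)
  })
})

test_that("applying a transform maps pixels linearly with clipping", {
  img <- array(runif(300, 0, 255), c(10, 10, 3))
  idt <- woundmetry:::identity_color_transform()
  expect_equal(apply_color_transform(img, idt), img)
  big <- idt; big$matrix <- diag(3) * 3
  out <- apply_color_transform(img, big)
  expect_true(all(out <= 255) && all(out >= 0))
  expect_equal(out[img < 85], (img * 3)[img < 85], tolerance = 1e-10)
})

test_that("metric scale is exact frontally, stable under rescaling and rotation", {
  ch <- chart_at(10)
  spec <- chart_spec()
  H <- normalize_orientation(detect_markers(ch$image, spec), spec)
  s <- estimate_scale(H, spec)
  expect_lt(abs(s - 0.1) / 0.1, 0.01)
  # reported marker side = estimate * projected side in px = 12.7 mm
  c0 <- woundmetry:::apply_homography(H, woundmetry:::chart_geometry(spec)$marker_corners_mm[["0"]])
  side_px <- sqrt(sum((c0[2, ] - c0[1, ])^2))
  expect_equal(s * side_px, 12.7, tolerance = 0.01)
  # downscaling the photograph 2x doubles mm per pixel
  half <- aperm(EBImage::resize(aperm(ch$image / 255, c(2, 1, 3)),
                                w = 375, h = 175), c(2, 1, 3)) * 255
  H2 <- normalize_orientation(detect_markers(half, spec), spec)
  expect_lt(abs(estimate_scale(H2, spec) - 0.2) / 0.2, 0.01)
  # in-plane rotations change the estimate by < 1%
  for (t in 1:3) {
    rot <- woundmetry:::rotate_image_90(ch$image, t)
    Hr <- normalize_orientation(detect_markers(rot, spec), spec)
    expect_lt(abs(estimate_scale(Hr, spec) - s) / s, 0.01)
  }
  expect_error(estimate_scale(matrix(0, 3, 3), spec), "degenerate")
})

test_that("full calibration round-trips casts and is idempotent", {
  ch <- chart_at(5)
  spec <- chart_spec()
  pal <- reference_palette()$colors
  M <- random_cast(0.7, seed = 21)
  castimg <- array(woundmetry:::clip255(matrix(ch$image, ncol = 3) %*% M),
                   dim(ch$image))
  cal <- calibrate(castimg, spec)
  got <- sample_patch_colors(cal$image, cal$result$homography, spec)
  expect_lt(max(abs(got - pal)), 2)
  expect_gt(cor(as.vector(got), as.vector(pal)), 0.999)
  # second calibration of the corrected image is a near-identity
  cal2 <- calibrate(cal$image, spec)
  drift <- abs(got %*% cal2$result$transform$matrix - got)
  expect_lt(max(drift), 2)
  # an image without a chart fails loudly
  expect_error(calibrate(array(180, c(64, 64, 3)), spec), "chart not found")
})
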