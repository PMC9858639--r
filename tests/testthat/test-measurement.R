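test_that("mask areas convert pixels to mm^2", {
  m <- matrix(0, 20, 20); m[1:10, 1:10] <- 1
  expect_equal(mask_area_mm2(m, 1), 100)
  expect_equal(mask_area_mm2(m, 0.5), 25)
  expect_equal(mask_area_mm2(matrix(0, 5, 5), 1), 0)
  expect_error(mask_area_mm2(matrix(2, 2, 2), 1), "binary")
  expect_error(mask_area_mm2(m, 0))
})

test_that("exclusive class areas sum to the union area", {
  s <- tiny_scene(4, 64)
  areas <- tissue_areas_mm2(s, s$truth$mm_per_px)
  expect_equal(areas[["epithelial"]] + areas[["granulation"]] +
                 areas[["necrotic"]], areas[["wound"]])
})

test_that("area is stable when the photograph is rescaled and re-calibrated", {
  M <- random_cast(0.3, seed = 5)
  s <- generate_scene(scene_params(seed = 12, cast = M))
  cal <- calibrate(s$image, chart_spec())
  a1 <- mask_area_mm2(s$wound_mask, cal$result$mm_per_px)
  # downscale the whole photograph 2x; re-estimating the scale from the
  # smaller chart must keep the area within 2%
  half_img <- aperm(EBImage::resize(aperm(s$image / 255, c(2, 1, 3)),
                                    w = dim(s$image)[2] / 2,
                                    h = dim(s$image)[1] / 2), c(2, 1, 3)) * 255
  half_mask <- s$wound_mask[seq(1, nrow(s$wound_mask), 2),
                            seq(1, ncol(s$wound_mask), 2)]
  cal2 <- calibrate(half_img, chart_spec())
  a2 <- mask_area_mm2(half_mask, cal2$result$mm_per_px)
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("longitudinal series order visits, difference areas, and flag direction", {
  co7 <- generate_cohort(1, 7,
                         scene_params(include_chart = FALSE, width_px = 128,
                                      height_px = 128,
                                      wound_center_px = c(64, 64)),
                         seed = 2)
  recs <- do.call(rbind, lapply(co7, function(r)
    visit_record(r$subject_id, r$visit,
                 tissue_areas_mm2(r$scene, r$scene$truth$mm_per_px),
                 r$scene$truth$mm_per_px)))
  ls <- longitudinal_series(recs[sample(nrow(recs)), ])   # order-agnostic
  expect_equal(nrow(ls$series), 7L)
  expect_equal(ls$series$visit, 1:7)
  # areas in the table equal the per-scene truths exactly
  truth_areas <- vapply(co7, function(r)
    r$scene$truth$pixel_counts[["wound"]] * r$scene$truth$mm_per_px^2,
    numeric(1))
  expect_equal(ls$series$wound_mm2, truth_areas)
  expect_true(all(ls$deltas$wound_mm2 < 0))
  expect_equal(unname(ls$direction["wound"]), "decreasing")
  # degenerate inputs
  one <- longitudinal_series(recs[1, ])
  expect_equal(nrow(one$deltas), 0L)
  dup <- rbind(recs[1, ], recs[1, ])
  expect_error(longitudinal_series(dup), "duplicate visit")
})
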