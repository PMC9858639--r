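test_that("scenes are deterministic, exclusive and internally consistent", {
  p <- scene_params(seed = 7)
  a <- generate_scene(p); b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$tissue_labels, b$tissue_labels)
  # tissue classes live only inside the wound mask and are exclusive
  expect_true(all(a$tissue_labels[a$wound_mask == 0] == 0))
  expect_true(all(a$tissue_labels[a$wound_mask == 1] %in% 1:3))
  # recorded counts equal counts recomputed from the maps
  pc <- a$truth$pixel_counts
  expect_equal(unname(pc["wound"]), sum(a$wound_mask))
  for (k in 0:3)
    expect_equal(unname(pc[k + 1]), sum(a$tissue_labels == k))
})

test_that("degenerate mixtures produce single-class wound beds", {
  s <- generate_scene(scene_params(seed = 3, tissue_weights = c(0, 1, 0),
                                   include_chart = FALSE,
                                   width_px = 96, height_px = 96))
  expect_true(all(s$tissue_labels[s$wound_mask == 1] == 2))
  expect_equal(sum(s$tissue_labels %in% c(1, 3)), 0)
  s2 <- generate_scene(scene_params(seed = 3, tissue_weights = c(1, 0, 0),
                                    include_chart = FALSE,
                                    width_px = 96, height_px = 96))
  expect_true(all(s2$tissue_labels[s2$wound_mask == 1] == 1))
})

test_that("a wound placed over the chart is rejected", {
  p <- scene_params(seed = 1, wound_center_px = c(80, 40))
  expect_error(generate_scene(p), "overlaps")
  expect_error(scene_params(cast = matrix(0, 3, 3)), "invertible")
})

test_that("calibration recovers a scene's scale and cast", {
  M <- random_cast(0.6, seed = 13)
  s <- generate_scene(scene_params(seed = 9, cast = M, noise_sd = 0))
  cal <- calibrate(s$image, chart_spec())
  expect_lt(abs(cal$result$mm_per_px - s$truth$mm_per_px) / s$truth$mm_per_px,
            0.01)
  got <- sample_patch_colors(cal$image, cal$result$homography, chart_spec())
  expect_lt(max(abs(got - reference_palette()$colors)), 2)
})

test_that("cohorts are grouped, sized and longitudinally monotone", {
  p <- scene_params(include_chart = FALSE, width_px = 64, height_px = 64,
                    wound_center_px = c(32, 32), wound_radius_px = 18)
  visits <- c(rep(2L, 11), rep(1L, 9))        # 31 images, 20 subjects
  coh <- generate_cohort(20, visits, p, seed = 5)
  expect_length(coh, 31L)
  expect_length(unique(cohort_subjects(coh)), 20L)
  coh2 <- generate_cohort(20, visits, p, seed = 5)
  expect_identical(coh[[31]]$scene$image, coh2[[31]]$scene$image)
  # one subject, 7 visits: true wound area strictly decreasing
  p7 <- scene_params(include_chart = FALSE, width_px = 128, height_px = 128,
                     wound_center_px = c(64, 64))
  co7 <- generate_cohort(1, 7, p7, seed = 2)
  areas <- vapply(co7, function(r) r$scene$truth$pixel_counts[["wound"]],
                  numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("random casts are invertible and gamut-preserving", {
  for (s in 1:10) {
    M <- random_cast(0.8, seed = s)
    expect_gt(abs(det(M)), 0.05)
    expect_true(all(M >= 0))
    expect_true(all(colSums(M) <= 1 + 1e-12))
  }
})
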