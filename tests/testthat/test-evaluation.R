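test_that("confusion counts match an exhaustive per-pixel tally", {
  pred <- matrix(c(1, 1, 0, 0,  1, 0, 0, 0,  0, 0, 1, 1,  0, 1, 1, 0), 4)
  truth <- matrix(c(1, 0, 0, 1,  1, 1, 0, 0,  0, 0, 1, 0,  1, 1, 0, 0), 4)
  cc <- confusion_counts(pred, truth)
  bf <- brute_confusion(pred, truth)
  expect_equal(cc$tp, bf$tp); expect_equal(cc$tn, bf$tn)
  expect_equal(cc$fp, bf$fp); expect_equal(cc$fn, bf$fn)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 16)
  # degenerate agreements
  same <- confusion_counts(pred, pred)
  expect_equal(same$fp + same$fn, 0)
  inv <- confusion_counts(pred, 1 - pred)
  expect_equal(inv$tp + inv$tn, 0)
  expect_error(confusion_counts(pred, truth[1:3, ]), "shapes")
})

test_that("pixel accuracy and IoU follow their definitions", {
  cc <- structure(list(tp = 2, tn = 6, fp = 1, fn = 1),
                  class = "confusion_counts")
  expect_equal(pixel_accuracy(cc), 0.8)
  cc2 <- structure(list(tp = 2, tn = 0, fp = 1, fn = 1),
                   class = "confusion_counts")
  expect_equal(iou(cc2), 0.5)
  perfect <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(pixel_accuracy(perfect), 1)
  expect_equal(iou(perfect), 1)
  disjoint <- confusion_counts(diag(2), 1 - diag(2))
  expect_equal(iou(disjoint), 0)
  # class absent from both masks: documented 0/0 convention = 1, flagged
  empty <- confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(iou(empty), 1)
  expect_false(iou_defined(empty))
  expect_equal(pixel_accuracy(empty), 1)
})

test_that("metrics agree with brute force on random masks", {
  withr::with_seed(2, {
    for (r in 1:20) {
      pred <- matrix(sample(0:1, 256, TRUE), 16)
      truth <- matrix(sample(0:1, 256, TRUE), 16)
      cc <- confusion_counts(pred, truth)
      bf <- brute_confusion(pred, truth)
      expect_equal(iou(cc), bf$tp / (bf$tp + bf$fp + bf$fn), tolerance = 1e-12)
      expect_equal(pixel_accuracy(cc), (bf$tp + bf$tn) / 256, tolerance = 1e-12)
      expect_true(iou(cc) >= 0 && iou(cc) <= 1)
    }
  })
})

test_that("nested CV splits partition subjects and keep them grouped", {
  sids <- rep(sprintf("S%02d", 1:20), times = c(rep(2, 11), rep(1, 9)))
  expect_length(sids, 31L)
  plan <- nested_cv_split(sids, outer = 10, inner = 9, seed = 4)
  expect_length(plan$outer_folds, 10L)
  test_sets <- lapply(plan$outer_folds, `[[`, "test")
  # partition: union is all subjects, pairwise disjoint, sizes differ <= 1
  expect_setequal(unlist(test_sets), unique(sids))
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  sizes <- lengths(test_sets)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (of in plan$outer_folds) {
    expect_length(of$inner, 9L)
    expect_length(intersect(of$test, of$trainval), 0L)
    for (inn in of$inner) {
      expect_setequal(c(inn$train, inn$val), of$trainval)
      expect_length(intersect(inn$train, inn$val), 0L)
    }
  }
  # grouping: all images of a subject get the same outer fold
  f <- outer_fold_of(plan)
  for (s in unique(sids))
    expect_length(unique(f[sids == s]), 1L)
  # determinism
  expect_identical(plan$outer_folds,
                   nested_cv_split(sids, 10, 9, seed = 4)$outer_folds)
  expect_error(nested_cv_split(sids[1:5], outer = 10), "outer folds")
})

test_that("inter-rater agreement reproduces hand-computed pairwise IoUs", {
  # three raters, two 4x4 images, one class
  r1 <- list(matrix(c(rep(1, 8), rep(0, 8)), 4), matrix(rep(c(1, 0), 8), 4))
  r2 <- list(matrix(c(rep(1, 4), rep(0, 12)), 4), matrix(rep(c(1, 0), 8), 4))
  r3 <- list(matrix(0, 4, 4), matrix(rep(c(0, 1), 8), 4))
  res <- inter_rater_agreement(list(A = r1, B = r2, C = r3), c(cls = 1))
  # A vs B: img1 IoU 4/8, img2 IoU 1 -> mean 0.75
  ab <- res$pairs[res$pairs$rater_a == "A" & res$pairs$rater_b == "B", ]
  expect_equal(ab$mean_iou, 0.75)
  expect_equal(ab$sd_iou, sd(c(0.5, 1)))
  # A vs C: img1 empty-vs-nonempty -> 0; img2 disjoint -> 0
  ac <- res$pairs[res$pairs$rater_a == "A" & res$pairs$rater_b == "C", ]
  expect_equal(ac$mean_iou, 0)
  # overall per-class mean is the unweighted mean over the three pairs
  bc_iou <- mean(c(0, 0))
  expect_equal(res$overall$mean_iou,
               mean(c(0.75, 0, bc_iou)))
  # identical raters agree perfectly
  same <- inter_rater_agreement(list(r1, r1), c(cls = 1))
  expect_equal(same$pairs$mean_iou, 1)
  expect_equal(same$pairs$sd_iou, 0)
  # missing annotations are excluded with a warning and counted
  r2b <- r2; r2b[2] <- list(NULL)
  expect_warning(res2 <- inter_rater_agreement(list(r1, r2b), c(cls = 1)),
                 "excluded")
  expect_equal(res2$pairs$n_excluded, 1L)
  expect_equal(res2$pairs$n_images, 1L)
  expect_error(inter_rater_agreement(list(r1), c(cls = 1)), "two raters")
})

test_that("evaluation reports aggregate exactly and demand full coverage", {
  coh <- tiny_cohort(4, 32)
  truths <- lapply(coh, `[[`, "scene")
  preds <- lapply(truths, function(s)
    list(wound_mask = s$wound_mask, tissue_labels = s$tissue_labels))
  rep <- evaluate_run(preds, truths)
  expect_true(all(rep$summary$mean_iou == 1))
  expect_true(all(rep$summary$sd_iou == 0))
  expect_true(all(rep$summary$mean_pixel_accuracy == 1))
  # per-class means equal brute-force recomputation from per-image rows
  for (cl in unique(rep$per_image$class)) {
    d <- rep$per_image[rep$per_image$class == cl, ]
    expect_equal(rep$summary$mean_iou[rep$summary$class == cl], mean(d$iou))
    expect_equal(rep$summary$sd_iou[rep$summary$class == cl],
                 if (nrow(d) > 1) sd(d$iou) else 0)
  }
  expect_error(evaluate_run(preds[1:3], truths), "coverage gap")
})
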