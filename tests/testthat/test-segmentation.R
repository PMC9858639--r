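test_that("model configs enforce the two-branch channel contract", {
  cfg <- network_config("efficientnet_b2_style", input_size = 1024)
  expect_equal(cfg$wound_branch_classes, 2L)    # wound area + background
  expect_equal(cfg$tissue_branch_classes, 4L)   # three tissues + background
  m <- build_model(cfg, seed = 1)
  expect_equal(ncol(m$params$head_wound_w), 2L)
  expect_equal(ncol(m$params$head_tissue_w), 4L)
  expect_error(network_config("tiny_test", input_size = 67), "divisible")
})

test_that("forward pass keeps shapes and normalized probabilities", {
  cfg <- network_config("tiny_test", input_size = 64)
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(64 * 64 * 3, 0, 0.3), c(64, 64, 3))
  out <- woundmetry:::forward_net(m, x)
  expect_equal(dim(out$prob_wound), c(64L, 64L, 2L))
  expect_equal(dim(out$prob_tissue), c(64L, 64L, 4L))
  sums <- apply(out$prob_tissue, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_error(woundmetry:::forward_net(m, x[1:63, , , drop = FALSE]),
               "downsampling")
})

test_that("MBConv encoders build and forward at small size", {
  for (kind in c("mobilenet_v2_style", "efficientnet_b2_style")) {
    cfg <- network_config(kind, input_size = 32,
                          widths = c(4, 6, 8), blocks = c(1, 2, 1))
    m <- build_model(cfg, seed = 2)
    out <- woundmetry:::forward_net(m, array(0.1, c(32, 32, 3)))
    expect_equal(dim(out$prob_wound), c(32L, 32L, 2L))
  }
})

test_that("weighted cross entropy matches its closed forms", {
  # perfect one-hot prediction -> ~0
  p <- array(0, c(2, 2, 4)); lab <- matrix(c(0, 1, 2, 3), 2)
  for (i in 1:2) for (j in 1:2) p[i, j, lab[i, j] + 1] <- 1
  expect_lt(weighted_ce_loss(p, lab), 1e-10)
  # uniform prediction over 4 classes with unit weights -> log(4)
  u <- array(0.25, c(3, 3, 4))
  expect_equal(weighted_ce_loss(u, matrix(0L, 3, 3)), log(4), tolerance = 1e-12)
  # doubling one class's weight doubles its pixels' contribution
  p2 <- array(c(0.7, 0.2, 0.3, 0.8), c(1, 2, 2))   # two pixels, two classes
  lab2 <- matrix(c(0L, 1L), 1)
  l_base <- weighted_ce_loss(p2, lab2, c(1, 1))
  l_w <- weighted_ce_loss(p2, lab2, c(2, 1))
  contrib0 <- -log(0.7) / 2
  expect_equal(l_w - l_base, contrib0, tolerance = 1e-12)
  expect_error(weighted_ce_loss(p2 * NaN, lab2), "non-finite")
})

test_that("backpropagation matches finite differences on the tiny network", {
  cfg <- network_config("tiny_test", input_size = 16,
                        widths = c(4, 6, 8), blocks = c(1, 1, 1))
  m <- build_model(cfg, seed = 2)
  withr::with_seed(1, {
    x <- array(rnorm(16 * 16 * 3, 0, 0.3), c(16, 16, 3))
    labw <- matrix(sample(0:1, 256, TRUE), 16)
    labt <- matrix(sample(0:3, 256, TRUE), 16)
  })
  ww <- c(1, 1.7); wt <- c(1, 2, 0.5, 3)
  lossfn <- function(params) {
    m$params <- params
    out <- woundmetry:::forward_net(m, x)
    weighted_ce_loss(out$prob_wound, labw, ww) +
      weighted_ce_loss(out$prob_tissue, labt, wt)
  }
  out <- woundmetry:::forward_net(m, x, keep_cache = TRUE)
  g <- woundmetry:::backward_net(
    m, out$cache,
    woundmetry:::ce_logit_grad(out$prob_wound, labw, ww),
    woundmetry:::ce_logit_grad(out$prob_tissue, labt, wt))
  eps <- 1e-5
  withr::with_seed(4, {
    for (nm in c("stem_w", "enc2_b1_c1_w", "enc3_b1_c2_w", "up1_w",
                 "dec1_w", "head_tissue_w", "dec2_b")) {
      for (t in sample(length(m$params[[nm]]), 3)) {
        p2 <- m$params; p2[[nm]][t] <- p2[[nm]][t] + eps
        p3 <- m$params; p3[[nm]][t] <- p3[[nm]][t] - eps
        fd <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
        expect_equal(g[[nm]][t], fd, tolerance = 1e-4)
      }
    }
  })
})

test_that("augmentation honours its contracts", {
  s <- tiny_scene(1, 32)
  masks <- list(wound = s$wound_mask, tissue = s$tissue_labels)
  # all toggles off -> identity
  a0 <- augment(s$image, masks, list())
  expect_identical(a0$image, s$image)
  expect_identical(a0$masks, masks)
  # hflip is an involution, applied identically to image and masks
  a1 <- augment(s$image, masks, list(hflip = TRUE))
  a2 <- augment(a1$image, a1$masks, list(hflip = TRUE))
  expect_equal(a2$image, s$image)
  expect_identical(a2$masks$tissue, masks$tissue)
  expect_false(identical(a1$masks$tissue, masks$tissue))
  # crop errors when the image is too small
  expect_error(augment(s$image, masks, list(crop = 64)), "smaller")
  # grid distortion keeps masks integer and per-class counts within 2%
  # (stated for a large mask, where boundary resampling is relatively small)
  big <- tiny_scene(2, 192)
  withr::with_seed(9, {
    ad <- augment(big$image, list(tissue = big$tissue_labels),
                  list(grid_distortion = TRUE))
  })
  expect_true(all(ad$masks$tissue %in% 0:3))
  n0 <- sum(big$tissue_labels > 0); n1 <- sum(ad$masks$tissue > 0)
  expect_lt(abs(n1 - n0) / n0, 0.02)
})

test_that("training is deterministic, inert at lr 0, and validates splits", {
  coh <- tiny_cohort(4, 32)
  cfg <- network_config("tiny_test", input_size = 32)
  m <- build_model(cfg, seed = 3)
  tc0 <- train_config(learning_rate = 0, epochs = 2, batch_size = 2,
                      augment_ops = list(), seed = 1)
  fit0 <- train(m, coh, tc0)
  expect_identical(fit0$model$params, m$params)   # optimizer sanity
  tc <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 2,
                     augment_ops = list(hflip = TRUE), seed = 1)
  h1 <- train(m, coh, tc)$history
  h2 <- train(m, coh, tc)$history
  expect_identical(h1, h2)                         # same seed, same history
  expect_true(all(diff(h1$train_loss) < 0))        # it is actually learning
  expect_error(train(m, list(), tc), "empty")
  expect_error(train(m, coh, tc, val_subjects = cohort_subjects(coh)),
               "empty train")
})

test_that("prediction handles degenerate inputs and identity calibration", {
  cfg <- network_config("tiny_test", input_size = 32)
  m <- build_model(cfg, seed = 3)
  flat <- array(128, c(32, 32, 3))
  pr <- predict_wound(m, flat)
  expect_true(all(pr$tissue_labels %in% 0:3))
  expect_lt(max(abs(apply(pr$prob_wound, c(1, 2), sum) - 1)), 1e-5)
  idc <- structure(list(transform = woundmetry:::identity_color_transform()),
                   class = "calibration_result")
  pr2 <- predict_wound(m, flat, calibration = idc)
  expect_identical(pr$wound_mask, pr2$wound_mask)
  # masked tissue view never labels tissue outside the predicted wound
  expect_true(all(pr$tissue_labels_in_wound[pr$wound_mask == 0] == 0))
})
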