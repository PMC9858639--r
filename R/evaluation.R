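# Segmentation metrics (pixel accuracy, intersection over union),
# subject-grouped nested cross-validation splits, inter-rater agreement,
# and the cross-validated evaluation report.

#' Pixel confusion counts for one class on one image
#'
#' @param pred,truth binary matrices (0/1) of identical shape.
#' @return An object of class `confusion_counts` with `tp`, `tn`, `fp`,
#'   `fn` (summing to the pixel count).
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth shapes differ", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`: the fraction of pixels labelled
#' correctly.
#'
#' @param c a [confusion_counts()].
#' @return value in `[0, 1]`.
#' @export
pixel_accuracy <- function(c) {
  n <- c$tp + c$tn + c$fp + c$fn
  if (n == 0) stop("empty image", call. = FALSE)
  (c$tp + c$tn) / n
}

#' Intersection over union
#'
#' `TP / (TP + FP + FN)`, the standard overlap measure between a
#' predicted and a reference mask. When the class is absent from both
#' masks (0/0) the convention value 1 is returned — correctly predicting
#' absence should not be penalized — and can be detected via
#' [iou_defined()].
#'
#' @param c a [confusion_counts()].
#' @return value in `[0, 1]`.
#' @export
iou <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1)
  c$tp / den
}

#' Is the IoU denominator non-degenerate?
#' @param c a [confusion_counts()].
#' @return FALSE when the class is absent from both masks.
#' @export
iou_defined <- function(c) (c$tp + c$fp + c$fn) > 0

#' Subject-grouped nested cross-validation plan
#'
#' Partitions subjects into `outer` folds of near-equal size (differing
#' by at most one subject); within each outer fold the remaining
#' subjects are partitioned into `inner` folds, each inner split using
#' one fold for validation and the rest for training. All images of a
#' subject stay together in every role, so no subject ever appears on
#' both sides of a split. Deterministic given `seed`.
#'
#' @param subject_ids character vector, one entry per image.
#' @param outer,inner fold counts (10 and 9 reproduce the standard
#'   nested scheme in which every image is tested exactly once).
#' @param seed RNG seed for the subject shuffle.
#' @return An object of class `fold_plan`: per outer fold the test
#'   subjects, the train+validation subjects, and the inner
#'   train/validation subject splits; plus the image-to-subject map.
#' @export
nested_cv_split <- function(subject_ids, outer = 10L, inner = 9L,
                            seed = 1L) {
  subjects <- sort(unique(as.character(subject_ids)))
  if (length(subjects) < outer)
    stop(sprintf("%d subjects cannot fill %d outer folds",
                 length(subjects), outer), call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(subjects)
    outer_assign <- rep(seq_len(outer), length.out = length(shuffled))
    outer_folds <- vector("list", outer)
    for (k in seq_len(outer)) {
      test <- shuffled[outer_assign == k]
      rest <- shuffled[outer_assign != k]
      inner_assign <- rep(seq_len(inner), length.out = length(rest))
      inner_folds <- lapply(seq_len(inner), function(j)
        list(train = rest[inner_assign != j], val = rest[inner_assign == j]))
      outer_folds[[k]] <- list(test = test, trainval = rest,
                               inner = inner_folds)
    }
    structure(list(outer_folds = outer_folds, outer = outer, inner = inner,
                   subject_ids = as.character(subject_ids), seed = seed),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("nested CV plan: %d outer x %d inner folds over %d subjects (%d images)\n",
              x$outer, x$inner, length(unique(x$subject_ids)),
              length(x$subject_ids)))
  invisible(x)
}

#' Which outer fold tests each image
#' @param plan a [nested_cv_split()] plan.
#' @return integer vector of outer-fold indices, one per image.
#' @export
outer_fold_of <- function(plan) {
  f <- integer(length(plan$subject_ids))
  for (k in seq_along(plan$outer_folds))
    f[plan$subject_ids %in% plan$outer_folds[[k]]$test] <- k
  f
}

#' Inter-rater agreement by pairwise IoU
#'
#' For every unordered pair of raters and every class, computes the IoU
#' between the two raters' masks on each image, then the mean and SD
#' across images, plus the per-class mean over pairs. Images missing an
#' annotation from either rater of a pair are excluded from that pair
#' with a warning.
#'
#' @param annotations named list of raters, each a list of integer label
#'   maps (one per image, aligned across raters; `NULL` marks a missing
#'   annotation).
#' @param classes named integer vector of class codes to compare (e.g.
#'   `c(wound = 1)` for binary wound masks).
#' @return list with `pairs` (data frame: class, rater_a, rater_b,
#'   mean_iou, sd_iou, n_images, n_excluded) and `overall` (data frame:
#'   class, mean_iou — the unweighted mean over pairs).
#' @export
inter_rater_agreement <- function(annotations, classes) {
  R <- length(annotations)
  if (R < 2) stop("need at least two raters", call. = FALSE)
  if (is.null(names(annotations)))
    names(annotations) <- LETTERS[seq_len(R)]
  n_img <- unique(vapply(annotations, length, integer(1)))
  if (length(n_img) != 1)
    stop("raters annotated different numbers of images", call. = FALSE)
  rows <- NULL
  for (a in seq_len(R - 1)) for (b in (a + 1):R) {
    for (cl in seq_along(classes)) {
      ious <- numeric(0); excl <- 0L
      for (i in seq_len(n_img)) {
        ma <- annotations[[a]][[i]]; mb <- annotations[[b]][[i]]
        if (is.null(ma) || is.null(mb)) { excl <- excl + 1L; next }
        cc <- confusion_counts(ma == classes[cl], mb == classes[cl])
        ious <- c(ious, iou(cc))
      }
      if (excl > 0)
        warning(sprintf("pair %s-%s: %d image(s) missing an annotation, excluded",
                        names(annotations)[a], names(annotations)[b], excl),
                call. = FALSE)
      rows <- rbind(rows, data.frame(
        class = names(classes)[cl],
        rater_a = names(annotations)[a], rater_b = names(annotations)[b],
        mean_iou = mean(ious), sd_iou = if (length(ious) > 1) sd(ious) else 0,
        n_images = length(ious), n_excluded = excl))
    }
  }
  overall <- aggregate(mean_iou ~ class, rows, mean)
  list(pairs = rows, overall = overall)
}

#' Evaluate cross-validated predictions against ground truth
#'
#' Computes, for the wound mask and each tissue class, the IoU and pixel
#' accuracy of every image's prediction (each produced by the model of
#' the outer fold that holds that image out), and aggregates mean and SD
#' across images — the layout of a standard segmentation results table.
#' A per-fold breakdown and a summary restricted to images where the
#' class is present (IoU defined) are also reported.
#'
#' @param predictions list of `wound_prediction`s (or lists with
#'   `wound_mask` and `tissue_labels`), one per image.
#' @param truths list of `wound_scene`s (or lists with `wound_mask` and
#'   `tissue_labels`), aligned with `predictions`.
#' @param plan optional [nested_cv_split()] plan for the per-fold
#'   breakdown; its image count must match.
#' @return An object of class `eval_report`: `per_image` (long data
#'   frame), `summary` (per class mean/SD of IoU and pixel accuracy),
#'   `summary_present_only`, and `per_fold` when a plan is given.
#' @export
evaluate_run <- function(predictions, truths, plan = NULL) {
  if (length(predictions) != length(truths))
    stop(sprintf("coverage gap: %d predictions for %d images",
                 length(predictions), length(truths)), call. = FALSE)
  classes <- c(wound = 0L, epithelial = 1L, granulation = 2L, necrotic = 3L)
  rows <- NULL
  for (i in seq_along(predictions)) {
    pr <- predictions[[i]]; tr <- truths[[i]]
    for (cl in names(classes)) {
      if (cl == "wound") {
        cc <- confusion_counts(pr$wound_mask == 1, tr$wound_mask == 1)
      } else {
        cc <- confusion_counts(pr$tissue_labels == classes[cl],
                               tr$tissue_labels == classes[cl])
      }
      rows <- rbind(rows, data.frame(
        image = i, class = cl, iou = iou(cc),
        pixel_accuracy = pixel_accuracy(cc),
        class_present = iou_defined(cc),
        fold = if (!is.null(plan)) outer_fold_of(plan)[i] else NA_integer_))
    }
  }
  agg <- function(df) {
    out <- NULL
    for (cl in names(classes)) {
      d <- df[df$class == cl, ]
      out <- rbind(out, data.frame(
        class = cl, mean_iou = mean(d$iou),
        sd_iou = if (nrow(d) > 1) sd(d$iou) else 0,
        mean_pixel_accuracy = mean(d$pixel_accuracy),
        sd_pixel_accuracy = if (nrow(d) > 1) sd(d$pixel_accuracy) else 0,
        n_images = nrow(d)))
    }
    out
  }
  per_fold <- NULL
  if (!is.null(plan)) {
    for (k in sort(unique(rows$fold))) {
      pf <- agg(rows[rows$fold == k, ])
      pf$fold <- k
      per_fold <- rbind(per_fold, pf)
    }
  }
  structure(list(per_image = rows, summary = agg(rows),
                 summary_present_only = agg(rows[rows$class_present, ]),
                 per_fold = per_fold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("segmentation evaluation (mean +/- SD across images):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s IoU %.4f +/- %.4f   pixel acc %.4f +/- %.4f  (n=%d)\n",
                s$class[i], s$mean_iou[i], s$sd_iou[i],
                s$mean_pixel_accuracy[i], s$sd_pixel_accuracy[i],
                s$n_images[i]))
  invisible(x)
}
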