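# Training loop: Adam with weight decay on the summed two-branch
# weighted cross entropy, random augmentation, subject-disjoint
# train/validation split, checkpointing the lowest-validation-loss
# parameters. Deterministic given the config seed.

#' Training configuration
#'
#' Defaults follow the standard recipe for this kind of model: Adam with
#' learning rate 1e-3, weight decay 1e-4, batch size 4, 100 epochs,
#' pixel-wise weighted cross entropy, and random crop/flip/distortion/
#' photometric augmentation; the checkpoint kept is the one with the
#' lowest validation loss. Scale `epochs`/`batch_size` down for
#' CPU-sized experiments.
#'
#' @param learning_rate,weight_decay,batch_size,epochs optimizer settings.
#' @param class_weights `"inverse"` (per-branch inverse pixel frequency
#'   computed on the training fold, normalized to mean 1) or a list with
#'   numeric vectors `wound` (length 2) and `tissue` (length 4).
#' @param augment_ops toggles passed to [augment()]; each enabled
#'   operation is applied with probability 1/2 per training image.
#' @param resize_px,crop_px standardization sizes for full-size
#'   photographs (shorter side scaled to `resize_px`, then a central
#'   `crop_px` crop); skipped when the training images are already at
#'   the network's input size.
#' @param val_fraction fraction of subjects held out for validation when
#'   no explicit split is given.
#' @param seed RNG seed controlling initialization order, shuffling and
#'   augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         batch_size = 4L, epochs = 100L,
                         class_weights = "inverse",
                         augment_ops = list(hflip = TRUE, vflip = TRUE,
                                            grid_distortion = TRUE,
                                            brightness = 20, contrast = 0.15,
                                            gaussian_noise = 4),
                         resize_px = 1280L, crop_px = 1024L,
                         val_fraction = 0.25, seed = 1L) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 0, crop_px <= resize_px)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), class_weights = class_weights,
                 augment_ops = augment_ops, resize_px = resize_px,
                 crop_px = crop_px, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Per-branch inverse-pixel-frequency class weights over a set of scenes,
# normalized to mean 1; classes absent from the fold get the largest
# observed weight.
inverse_class_weights <- function(scenes, n_wound = 2, n_tissue = 4) {
  cw <- numeric(n_wound); ct <- numeric(n_tissue)
  for (s in scenes) {
    cw <- cw + tabulate(as.integer(s$wound_mask) + 1L, n_wound)
    ct <- ct + tabulate(as.integer(s$tissue_labels) + 1L, n_tissue)
  }
  inv <- function(cnt) {
    w <- ifelse(cnt > 0, 1 / pmax(cnt, 1), NA)
    w[is.na(w)] <- max(w, na.rm = TRUE)
    w / mean(w)
  }
  list(wound = inv(cw), tissue = inv(ct))
}

scene_list <- function(cohort) {
  if (inherits(cohort, "wound_cohort"))
    lapply(cohort, function(r) c(r["subject_id"], r["visit"], r$scene))
  else
    lapply(seq_along(cohort), function(i) {
      s <- cohort[[i]]
      if (inherits(s, "wound_scene"))
        c(list(subject_id = sprintf("S%02d", i), visit = 1L), s)
      else s
    })
}

#' Train the two-branch segmentation model
#'
#' Minimizes the sum of the two branches' pixel-wise weighted cross
#' entropies with Adam. The training/validation split is by subject
#' (images of one subject never straddle the split). Each epoch shuffles
#' the training images, applies random augmentation, accumulates
#' gradients over `batch_size` images per step, and evaluates the
#' validation loss; the returned model carries the parameters of the
#' epoch with the lowest validation loss.
#'
#' @param model a [build_model()] object.
#' @param cohort a `wound_cohort` or list of `wound_scene`s.
#' @param cfg a [train_config()].
#' @param val_subjects optional character vector of subject IDs to hold
#'   out; when NULL the last `val_fraction` of subjects (in ID order) is
#'   used.
#' @return list with `model` (best checkpoint), `history` (data frame of
#'   per-epoch train/validation loss), and `class_weights`.
#' @export
train <- function(model, cohort, cfg = train_config(), val_subjects = NULL) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  scenes <- scene_list(cohort)
  if (length(scenes) == 0) stop("empty cohort", call. = FALSE)
  sids <- vapply(scenes, `[[`, character(1), "subject_id")
  if (is.null(val_subjects)) {
    us <- sort(unique(sids))
    n_val <- max(1L, round(cfg$val_fraction * length(us)))
    if (n_val >= length(us)) stop("no subjects left for training", call. = FALSE)
    val_subjects <- tail(us, n_val)
  }
  tr_idx <- which(!(sids %in% val_subjects))
  va_idx <- which(sids %in% val_subjects)
  if (!length(tr_idx) || !length(va_idx))
    stop("empty train or validation split", call. = FALSE)
  cw <- if (identical(cfg$class_weights, "inverse"))
    inverse_class_weights(scenes[tr_idx],
                          model$cfg$wound_branch_classes,
                          model$cfg$tissue_branch_classes)
  else cfg$class_weights
  prep <- function(s, ops = NULL) {
    img <- s$image
    masks <- list(wound = s$wound_mask, tissue = s$tissue_labels)
    if (!is.null(ops)) {
      a <- augment(img, masks, ops)
      img <- a$image; masks <- a$masks
    }
    list(x = img / 255 - 0.5, wound = masks$wound, tissue = masks$tissue)
  }
  loss_of <- function(out, d) {
    weighted_ce_loss(out$prob_wound, d$wound, cw$wound) +
      weighted_ce_loss(out$prob_tissue, d$tissue, cw$tissue)
  }
  params <- model$params
  m1 <- lapply(params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        i <- i + cfg$batch_size
        acc <- NULL
        bl <- 0
        for (j in batch) {
          ops <- random_ops(cfg$augment_ops)
          d <- prep(scenes[[j]], ops)
          model$params <- params
          out <- forward_net(model, d$x, keep_cache = TRUE)
          bl <- bl + loss_of(out, d)
          gw <- ce_logit_grad(out$prob_wound, d$wound, cw$wound)
          gt <- ce_logit_grad(out$prob_tissue, d$tissue, cw$tissue)
          g <- backward_net(model, out$cache, gw, gt)
          acc <- if (is.null(acc)) g
                 else mapply(`+`, acc, g[names(acc)], SIMPLIFY = FALSE)
        }
        nb <- nb + 1L
        ep_loss <- ep_loss + bl / length(batch)
        tstep <- tstep + 1
        lr_t <- cfg$learning_rate *
          sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
        for (nm in names(params)) {
          gr <- acc[[nm]] / length(batch) + cfg$weight_decay * params[[nm]]
          m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * gr
          m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * gr^2
          params[[nm]] <- params[[nm]] -
            lr_t * m1[[nm]] / (sqrt(m2[[nm]]) + eps)
        }
      }
      model$params <- params
      vl <- 0
      for (j in va_idx) {
        d <- prep(scenes[[j]])
        vl <- vl + loss_of(forward_net(model, d$x), d)
      }
      vl <- vl / length(va_idx)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / max(nb, 1), val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params)
    }
  })
  model$params <- best$params
  list(model = model, history = history, class_weights = cw,
       val_subjects = val_subjects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw a random realization of the augmentation toggles: each enabled
# geometric op is applied with probability 1/2; photometric magnitudes
# pass through (augment() draws their values).
random_ops <- function(ops) {
  if (is.null(ops) || !length(ops)) return(NULL)
  o <- list()
  for (nm in c("hflip", "vflip", "grid_distortion"))
    if (isTRUE(ops[[nm]])) o[[nm]] <- runif(1) < 0.5
  for (nm in c("brightness", "contrast", "gaussian_noise"))
    if (!is.null(ops[[nm]]) && ops[[nm]] > 0)
      o[[nm]] <- if (runif(1) < 0.5) ops[[nm]] else 0
  if (!is.null(ops$crop)) o$crop <- ops$crop
  o
}
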