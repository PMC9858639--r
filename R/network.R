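# Two-branch U-Net for joint wound-area and wound-tissue segmentation.
# A shared encoder-decoder produces full-resolution features; two 1x1
# convolution heads emit per-pixel class probabilities, one binary branch
# (wound / background) and one 4-class branch (background, epithelial,
# granulation, necrotic). Encoders are assembled from either plain
# double-conv blocks (tiny test configuration) or MBConv inverted
# residual blocks (expand 1x1 -> depthwise 3x3 -> squeeze 1x1) following
# the stage layouts of the EfficientNet-B2 / MobileNetV2 families.
# Forward and backward passes are exact and hand-derived, running on the
# compiled conv/pool primitives, so training is deterministic given a
# seed.

#' Network configuration
#'
#' @param encoder_kind `"tiny_test"` (3 levels, <= 64 channels; intended
#'   for CPU-sized experiments and the package tests),
#'   `"mobilenet_v2_style"` or `"efficientnet_b2_style"` (5 levels of
#'   MBConv stages following those architectures' width/depth layouts).
#' @param input_size input image side in px; must be divisible by the
#'   encoder's total downsampling factor (4 for tiny, 16 otherwise).
#' @param wound_branch_classes,tissue_branch_classes output channels of
#'   the two heads (2 and 4 for wound/background and the three tissue
#'   types plus background).
#' @param widths,blocks,expansion optional overrides of the per-level
#'   channel widths, block counts and MBConv expansion ratio.
#' @return An object of class `network_config`.
#' @export
network_config <- function(encoder_kind = c("tiny_test", "mobilenet_v2_style",
                                            "efficientnet_b2_style"),
                           input_size = 1024,
                           wound_branch_classes = 2L,
                           tissue_branch_classes = 4L,
                           widths = NULL, blocks = NULL, expansion = NULL) {
  encoder_kind <- match.arg(encoder_kind)
  preset <- switch(encoder_kind,
    tiny_test = list(widths = c(8, 16, 32), blocks = c(1, 1, 1),
                     block_type = "double_conv", expansion = 1),
    mobilenet_v2_style = list(widths = c(16, 24, 32, 96, 320),
                              blocks = c(1, 2, 3, 4, 3),
                              block_type = "mbconv", expansion = 6),
    efficientnet_b2_style = list(widths = c(16, 24, 48, 120, 352),
                                 blocks = c(2, 3, 3, 4, 2),
                                 block_type = "mbconv", expansion = 6))
  if (!is.null(widths)) preset$widths <- widths
  if (!is.null(blocks)) preset$blocks <- blocks
  if (!is.null(expansion)) preset$expansion <- expansion
  stopifnot(length(preset$widths) == length(preset$blocks))
  L <- length(preset$widths)
  ds <- 2^(L - 1)
  if (input_size %% ds != 0)
    stop(sprintf("input_size %d is not divisible by the downsampling factor %d",
                 input_size, ds), call. = FALSE)
  structure(list(encoder_kind = encoder_kind, input_size = input_size,
                 wound_branch_classes = as.integer(wound_branch_classes),
                 tissue_branch_classes = as.integer(tissue_branch_classes),
                 widths = preset$widths, blocks = preset$blocks,
                 block_type = preset$block_type, expansion = preset$expansion,
                 downsampling = ds),
            class = "network_config")
}

he_init <- function(n_in, dims) array(rnorm(prod(dims), 0, sqrt(2 / n_in)), dims)

#' Build a two-branch segmentation model
#'
#' Allocates and initializes (He-normal, seeded) all parameters of the
#' U-shaped network described by `cfg`: a stem convolution, encoder
#' stages with 2x2 max-pool downsampling (each level halves the spatial
#' size and increases the channel count), a decoder of 2x2 transposed
#' convolutions with skip concatenation from the encoder level of
#' matching resolution, and the two softmax output heads.
#'
#' @param cfg a [network_config()].
#' @param seed RNG seed for the parameter initialization.
#' @return An object of class `seg_model` holding `cfg` and the named
#'   parameter list.
#' @examples
#' m <- build_model(network_config("tiny_test", input_size = 64), seed = 1)
#' length(m$params)
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  W <- cfg$widths; L <- length(W)
  params <- list()
  add_conv3 <- function(name, cin, cout) {
    params[[paste0(name, "_w")]] <<- he_init(9 * cin, c(9 * cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_conv1 <- function(name, cin, cout) {
    params[[paste0(name, "_w")]] <<- he_init(cin, c(cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  add_dw <- function(name, c) {
    params[[paste0(name, "_k")]] <<- he_init(9, c(3, 3, c))
    params[[paste0(name, "_b")]] <<- numeric(c)
  }
  add_tconv <- function(name, cin, cout) {
    params[[paste0(name, "_w")]] <<- he_init(cin, c(cin, cout, 4))
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  with_seed(seed, {
    add_conv3("stem", 3L, W[1])
    for (l in seq_len(L)) {
      cin <- if (l == 1) W[1] else W[l - 1]
      for (b in seq_len(cfg$blocks[l])) {
        nm <- sprintf("enc%d_b%d", l, b)
        bin <- if (b == 1) cin else W[l]
        if (cfg$block_type == "double_conv") {
          add_conv3(paste0(nm, "_c1"), bin, W[l])
          add_conv3(paste0(nm, "_c2"), W[l], W[l])
        } else {
          e <- round(cfg$expansion * bin)
          add_conv1(paste0(nm, "_exp"), bin, e)
          add_dw(paste0(nm, "_dw"), e)
          add_conv1(paste0(nm, "_sq"), e, W[l])
        }
      }
    }
    for (l in rev(seq_len(L - 1))) {
      add_tconv(sprintf("up%d", l), W[l + 1], W[l])
      add_conv3(sprintf("dec%d", l), 2 * W[l], W[l])
    }
    add_conv1("head_wound", W[1], cfg$wound_branch_classes)
    add_conv1("head_tissue", W[1], cfg$tissue_branch_classes)
  })
  structure(list(cfg = cfg, params = params), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("two-branch U-Net (%s): %d parameter arrays, %s weights\n",
              x$cfg$encoder_kind, length(x$params), format(n, big.mark = ",")))
  invisible(x)
}

## ---- primitive layers (R side) -------------------------------------------

relu_fwd <- function(x) { m <- x > 0; list(y = x * m, mask = m) }

conv1_fwd <- function(x, w, b) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% w
  y <- sweep(y, 2, b, "+")
  array(y, c(d[1], d[2], ncol(w)))
}

conv1_bwd <- function(x, w, gy) {
  d <- dim(x)
  G <- matrix(gy, d[1] * d[2], dim(gy)[3])
  X <- matrix(x, d[1] * d[2], d[3])
  list(dx = array(G %*% t(w), d), dw = crossprod(X, G), db = colSums(G))
}

# 2x2 stride-2 transposed convolution: each input pixel emits a 2x2
# output block; w is cin x cout x 4 with offset order (dy,dx) in
# (0,0),(1,0),(0,1),(1,1).
tconv_fwd <- function(x, w, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; cout <- dim(w)[2]
  X <- matrix(x, H * Wd, d[3])
  out <- array(0, c(2 * H, 2 * Wd, cout))
  rs <- seq_len(H) * 2; cs <- seq_len(Wd) * 2
  offs <- list(c(-1, -1), c(0, -1), c(-1, 0), c(0, 0))
  for (k in 1:4) {
    y <- X %*% w[, , k]
    out[rs + offs[[k]][1], cs + offs[[k]][2], ] <- array(y, c(H, Wd, cout))
  }
  sweep(out, 3, b, "+")
}

tconv_bwd <- function(x, w, gy) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  X <- matrix(x, H * Wd, d[3])
  rs <- seq_len(H) * 2; cs <- seq_len(Wd) * 2
  offs <- list(c(-1, -1), c(0, -1), c(-1, 0), c(0, 0))
  dw <- array(0, dim(w)); dX <- matrix(0, H * Wd, d[3])
  for (k in 1:4) {
    G <- matrix(gy[rs + offs[[k]][1], cs + offs[[k]][2], , drop = FALSE],
                H * Wd, dim(gy)[3])
    dw[, , k] <- crossprod(X, G)
    dX <- dX + G %*% t(w[, , k])
  }
  list(dx = array(dX, d), dw = dw,
       db = colSums(matrix(gy, length(gy) / dim(gy)[3], dim(gy)[3])))
}

softmax3 <- function(logits) {
  d <- dim(logits)
  m <- apply(logits, c(1, 2), max)
  e <- exp(logits - array(m, d))
  s <- array(0, c(d[1], d[2]))
  for (c in seq_len(d[3])) s <- s + e[, , c]
  e / array(s, d)
}

## ---- blocks ---------------------------------------------------------------

block_fwd <- function(params, nm, type, x) {
  if (type == "double_conv") {
    z1 <- conv3_fwd(x, params[[paste0(nm, "_c1_w")]], params[[paste0(nm, "_c1_b")]])
    a1 <- relu_fwd(z1)
    z2 <- conv3_fwd(a1$y, params[[paste0(nm, "_c2_w")]], params[[paste0(nm, "_c2_b")]])
    a2 <- relu_fwd(z2)
    list(y = a2$y, cache = list(x = x, a1 = a1$y, m1 = a1$mask, m2 = a2$mask))
  } else {
    z1 <- conv1_fwd(x, params[[paste0(nm, "_exp_w")]], params[[paste0(nm, "_exp_b")]])
    a1 <- relu_fwd(z1)
    z2 <- dwconv3_fwd(a1$y, params[[paste0(nm, "_dw_k")]], params[[paste0(nm, "_dw_b")]])
    a2 <- relu_fwd(z2)
    z3 <- conv1_fwd(a2$y, params[[paste0(nm, "_sq_w")]], params[[paste0(nm, "_sq_b")]])
    res <- identical(dim(x), dim(z3))
    list(y = if (res) z3 + x else z3,
         cache = list(x = x, a1 = a1$y, m1 = a1$mask, a2 = a2$y,
                      m2 = a2$mask, res = res))
  }
}

block_bwd <- function(params, nm, type, cache, gy, grads) {
  if (type == "double_conv") {
    g2 <- gy * cache$m2
    b2 <- conv3_bwd(cache$a1, params[[paste0(nm, "_c2_w")]], g2)
    grads[[paste0(nm, "_c2_w")]] <- b2$dw; grads[[paste0(nm, "_c2_b")]] <- b2$db
    g1 <- b2$dx * cache$m1
    b1 <- conv3_bwd(cache$x, params[[paste0(nm, "_c1_w")]], g1)
    grads[[paste0(nm, "_c1_w")]] <- b1$dw; grads[[paste0(nm, "_c1_b")]] <- b1$db
    list(dx = b1$dx, grads = grads)
  } else {
    g3 <- gy
    b3 <- conv1_bwd(cache$a2, params[[paste0(nm, "_sq_w")]], g3)
    grads[[paste0(nm, "_sq_w")]] <- b3$dw; grads[[paste0(nm, "_sq_b")]] <- b3$db
    g2 <- b3$dx * cache$m2
    b2 <- dwconv3_bwd(cache$a1, params[[paste0(nm, "_dw_k")]], g2)
    grads[[paste0(nm, "_dw_k")]] <- b2$dk; grads[[paste0(nm, "_dw_b")]] <- b2$db
    g1 <- b2$dx * cache$m1
    b1 <- conv1_bwd(cache$x, params[[paste0(nm, "_exp_w")]], g1)
    grads[[paste0(nm, "_exp_w")]] <- b1$dw; grads[[paste0(nm, "_exp_b")]] <- b1$db
    dx <- b1$dx
    if (cache$res) dx <- dx + gy
    list(dx = dx, grads = grads)
  }
}

## ---- full network ---------------------------------------------------------

# Forward pass. x: H x W x 3 array already normalized to roughly [-0.5, 0.5].
forward_net <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  L <- length(cfg$widths)
  d <- dim(x)
  if (d[1] %% cfg$downsampling != 0 || d[2] %% cfg$downsampling != 0)
    stop("input size incompatible with the network's downsampling factor",
         call. = FALSE)
  cache <- list(levels = vector("list", L), dec = vector("list", L))
  z <- conv3_fwd(x, p$stem_w, p$stem_b)
  a <- relu_fwd(z)
  cache$x <- x; cache$stem_mask <- a$mask
  h <- a$y
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    blocks <- vector("list", cfg$blocks[l])
    for (b in seq_len(cfg$blocks[l])) {
      bf <- block_fwd(p, sprintf("enc%d_b%d", l, b), cfg$block_type, h)
      h <- bf$y; blocks[[b]] <- bf$cache
    }
    skips[[l]] <- h
    cache$levels[[l]] <- list(blocks = blocks)
    if (l < L) {
      mp <- maxpool2_fwd(h)
      cache$levels[[l]]$pool_idx <- mp$idx
      cache$levels[[l]]$pool_in_dim <- dim(h)
      h <- mp$y
    }
  }
  for (l in rev(seq_len(L - 1))) {
    up <- tconv_fwd(h, p[[sprintf("up%d_w", l)]], p[[sprintf("up%d_b", l)]])
    cat_in <- array(0, c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[l]])[3]))
    cat_in[, , seq_len(dim(skips[[l]])[3])] <- skips[[l]]
    cat_in[, , dim(skips[[l]])[3] + seq_len(dim(up)[3])] <- up
    z <- conv3_fwd(cat_in, p[[sprintf("dec%d_w", l)]], p[[sprintf("dec%d_b", l)]])
    a <- relu_fwd(z)
    cache$dec[[l]] <- list(low_in = h, cat_in = cat_in, mask = a$mask,
                           n_skip = dim(skips[[l]])[3])
    h <- a$y
  }
  logit_w <- conv1_fwd(h, p$head_wound_w, p$head_wound_b)
  logit_t <- conv1_fwd(h, p$head_tissue_w, p$head_tissue_b)
  cache$feat <- h
  out <- list(prob_wound = softmax3(logit_w), prob_tissue = softmax3(logit_t))
  if (keep_cache) out$cache <- cache
  out
}

# Backward pass from head-logit gradients; returns the named gradient list.
backward_net <- function(model, cache, g_logit_w, g_logit_t) {
  cfg <- model$cfg; p <- model$params
  L <- length(cfg$widths)
  grads <- list()
  bw <- conv1_bwd(cache$feat, p$head_wound_w, g_logit_w)
  bt <- conv1_bwd(cache$feat, p$head_tissue_w, g_logit_t)
  grads$head_wound_w <- bw$dw; grads$head_wound_b <- bw$db
  grads$head_tissue_w <- bt$dw; grads$head_tissue_b <- bt$db
  # walk the decoder from the output end down to the bottleneck,
  # collecting each level's skip gradient on the way
  g <- bw$dx + bt$dx
  for (l in seq_len(L - 1)) {
    dc <- cache$dec[[l]]
    gz <- g * dc$mask
    bb <- conv3_bwd(dc$cat_in, p[[sprintf("dec%d_w", l)]], gz)
    grads[[sprintf("dec%d_w", l)]] <- bb$dw
    grads[[sprintf("dec%d_b", l)]] <- bb$db
    ns <- dc$n_skip
    cache$levels[[l]]$g_skip <- bb$dx[, , seq_len(ns), drop = FALSE]
    g_up <- bb$dx[, , ns + seq_len(dim(bb$dx)[3] - ns), drop = FALSE]
    tb <- tconv_bwd(dc$low_in, p[[sprintf("up%d_w", l)]], g_up)
    grads[[sprintf("up%d_w", l)]] <- tb$dw
    grads[[sprintf("up%d_b", l)]] <- tb$db
    g <- tb$dx            # gradient w.r.t. the next-lower decoder output
  }
  cache$levels[[L]]$g_from_below <- g   # bottleneck gradient
  # unwind the encoder from the deepest level up; each level receives the
  # gradient through the pool below it plus its decoder skip gradient
  for (l in rev(seq_len(L))) {
    lev <- cache$levels[[l]]
    g_here <- if (l == L) lev$g_from_below else {
      maxpool2_bwd(lev$pool_idx, lev$g_from_below,
                   lev$pool_in_dim[1], lev$pool_in_dim[2]) + lev$g_skip
    }
    for (b in rev(seq_len(cfg$blocks[l]))) {
      bb <- block_bwd(p, sprintf("enc%d_b%d", l, b), cfg$block_type,
                      lev$blocks[[b]], g_here, grads)
      grads <- bb$grads; g_here <- bb$dx
    }
    if (l == 1) {
      gz <- g_here * cache$stem_mask
      sb <- conv3_bwd(cache$x, p$stem_w, gz)
      grads$stem_w <- sb$dw; grads$stem_b <- sb$db
    } else {
      cache$levels[[l - 1]]$g_from_below <- g_here
    }
  }
  # conform every gradient to its parameter's shape (compiled code
  # returns vectors as n x 1 matrices)
  for (nm in names(grads)) {
    pd <- dim(p[[nm]])
    grads[[nm]] <- if (is.null(pd)) as.numeric(grads[[nm]])
                   else array(as.numeric(grads[[nm]]), pd)
  }
  grads
}

#' Per-pixel weighted cross-entropy loss
#'
#' Mean over pixels of `-w[class] * log p[class]`, the pixel-wise
#' weighted cross entropy used to counter class imbalance (rare classes
#' such as necrotic tissue receive larger weights). The total training
#' loss is the sum of this quantity over the two output branches.
#'
#' @param probs H x W x C array of class probabilities (each pixel sums
#'   to 1).
#' @param labels H x W integer matrix of class codes in `0:(C-1)`.
#' @param weights positive per-class weight vector of length C.
#' @return scalar loss.
#' @export
weighted_ce_loss <- function(probs, labels, weights = NULL) {
  d <- dim(probs)
  C <- d[3]
  if (is.null(weights)) weights <- rep(1, C)
  stopifnot(all(weights > 0), length(weights) == C,
            all(dim(labels) == d[1:2]))
  if (!all(is.finite(probs))) stop("non-finite probabilities", call. = FALSE)
  idx <- cbind(seq_len(d[1] * d[2]),
               as.integer(labels) + 1L)
  pmat <- matrix(probs, d[1] * d[2], C)
  p <- pmat[idx]
  mean(-weights[idx[, 2]] * log(pmax(p, 1e-12)))
}

# Gradient of weighted_ce_loss with respect to the pre-softmax logits.
ce_logit_grad <- function(probs, labels, weights) {
  d <- dim(probs)
  C <- d[3]
  n <- d[1] * d[2]
  lab <- as.integer(labels) + 1L
  wpix <- weights[lab]
  g <- matrix(probs, n, C) * wpix
  g[cbind(seq_len(n), lab)] <- g[cbind(seq_len(n), lab)] - wpix
  array(g / n, d)
}

#' Run the segmentation model on an image
#'
#' Normalizes the image, optionally applies a color calibration first
#' (the assessment pipeline corrects colors before inference), runs the
#' network, and returns per-branch probability maps and argmax label
#' maps. Ties at the argmax resolve to the lowest class index. The
#' `tissue_labels_in_wound` view masks tissue predictions by the wound
#' branch, since tissue classes outside a predicted wound are
#' contradictory.
#'
#' @param model a trained [build_model()] object.
#' @param image RGB image (H x W x 3, 0-255); its sides must be divisible
#'   by the network's downsampling factor.
#' @param calibration optional `calibration_result` whose color transform
#'   is applied before inference.
#' @return An object of class `wound_prediction`: `wound_mask`,
#'   `tissue_labels`, `tissue_labels_in_wound`, `prob_wound`,
#'   `prob_tissue`.
#' @export
predict_wound <- function(model, image, calibration = NULL) {
  stopifnot(inherits(model, "seg_model"))
  stopifnot_image(image)
  if (!is.null(calibration))
    image <- apply_color_transform(image, calibration$transform)
  x <- image / 255 - 0.5
  out <- forward_net(model, x)
  structure(list(
    wound_mask = argmax3(out$prob_wound) - 1L,
    tissue_labels = argmax3(out$prob_tissue) - 1L,
    tissue_labels_in_wound = (argmax3(out$prob_tissue) - 1L) *
      (argmax3(out$prob_wound) - 1L > 0),
    prob_wound = out$prob_wound, prob_tissue = out$prob_tissue),
    class = "wound_prediction")
}

# argmax over the third dimension, lowest index wins ties; returns 1-based
argmax3 <- function(p) {
  d <- dim(p)
  best <- p[, , 1]
  arg <- matrix(1L, d[1], d[2])
  for (c in seq_len(d[3])[-1]) {
    better <- p[, , c] > best
    best[better] <- p[, , c][better]
    arg[better] <- c
  }
  arg
}

#' @export
print.wound_prediction <- function(x, ...) {
  cat(sprintf("wound prediction: %d wound px, tissue px (epi/gran/necr) %d/%d/%d\n",
              sum(x$wound_mask), sum(x$tissue_labels == 1),
              sum(x$tissue_labels == 2), sum(x$tissue_labels == 3)))
  invisible(x)
}
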