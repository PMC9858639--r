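# Synthetic wound-scene generator. Emulates the capture conditions of a
# smartphone wound photograph: a skin-toned background, a smooth closed
# wound whose bed is partitioned into granulation / necrotic tissue with
# an epithelial rim advancing from the edge, the calibration chart
# composited in-plane at a known scale, and a known invertible color cast
# plus sensor noise applied to the whole frame. Ground truth (label maps,
# cast, mm/px, per-class pixel counts) is retained so that every other
# module can be tested without clinical data.

#' Parameters of a synthetic wound scene
#'
#' @param width_px,height_px scene size in pixels.
#' @param px_per_mm physical resolution of the scene plane (the chart is
#'   rendered at this same resolution, so it needs `px_per_mm >= 2` when
#'   `include_chart = TRUE`).
#' @param seed RNG seed; a fixed seed reproduces the scene byte for byte.
#' @param skin_color,skin_noise_sd background skin tone (RGB, 0-255) and
#'   its per-pixel texture noise SD.
#' @param wound_center_px,wound_radius_px wound centroid (x, y) and mean
#'   radius in px; defaults place the wound below the chart.
#' @param tissue_weights named mixture weights over
#'   `c(epithelial, granulation, necrotic)` controlling the share of the
#'   wound bed given to each class. The epithelial share becomes a rim at
#'   the wound margin (epithelium regrows from the edge toward the
#'   centre); necrotic tissue appears as small scattered patches, keeping
#'   the class rare and small as in real wound photographs.
#' @param cast 3x3 invertible color-cast matrix applied to RGB row
#'   vectors of the finished scene (see [random_cast()]); identity by
#'   default.
#' @param noise_sd additive Gaussian sensor noise SD (8-bit scale),
#'   applied after the cast.
#' @param include_chart composite the calibration chart into the frame.
#' @param chart_origin_px chart top-left position (x, y) in px.
#' @param spec chart geometry, a [chart_spec()].
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(width_px = 256, height_px = 192, px_per_mm = 2,
                         seed = 1L,
                         skin_color = c(224, 172, 138), skin_noise_sd = 5,
                         wound_center_px = NULL, wound_radius_px = NULL,
                         tissue_weights = c(epithelial = 0.15,
                                            granulation = 0.75,
                                            necrotic = 0.10),
                         cast = diag(3), noise_sd = 2,
                         include_chart = TRUE,
                         chart_origin_px = c(4, 4),
                         spec = chart_spec()) {
  cast <- as.matrix(cast)
  stopifnot(width_px >= 32, height_px >= 32, px_per_mm > 0,
            length(tissue_weights) == 3, all(tissue_weights >= 0),
            sum(tissue_weights) > 0, all(dim(cast) == c(3, 3)))
  if (abs(det(cast)) < 1e-8)
    stop("cast matrix must be invertible", call. = FALSE)
  chart_h_px <- spec$chart_height_mm * px_per_mm
  if (is.null(wound_center_px)) {
    top <- if (include_chart) chart_origin_px[2] + chart_h_px else 0
    wound_center_px <- c(width_px / 2, (top + height_px) / 2)
  }
  if (is.null(wound_radius_px))
    wound_radius_px <- 0.22 * min(width_px, height_px)
  structure(list(
    width_px = width_px, height_px = height_px, px_per_mm = px_per_mm,
    seed = as.integer(seed), skin_color = skin_color,
    skin_noise_sd = skin_noise_sd, wound_center_px = wound_center_px,
    wound_radius_px = wound_radius_px,
    tissue_weights = tissue_weights / sum(tissue_weights),
    cast = cast, noise_sd = noise_sd, include_chart = include_chart,
    chart_origin_px = chart_origin_px, chart_spec = spec
  ), class = "scene_params")
}

#' Draw a random gamut-preserving color cast
#'
#' Samples a random invertible 3x3 cast matrix with non-negative entries
#' and column sums at most one, i.e. a mixing of channels that models an
#' illuminant/sensor shift while keeping every 8-bit color in gamut (so
#' the cast remains exactly invertible by a linear correction; casts that
#' clip saturated channels destroy information no linear map can
#' recover).
#'
#' @param strength in (0, 1]; larger values give stronger channel
#'   attenuation and cross-talk. 0.4 is a mild indoor-lighting shift,
#'   0.8 a strong one.
#' @param seed optional RNG seed.
#' @return 3x3 cast matrix.
#' @export
random_cast <- function(strength = 0.4, seed = NULL) {
  with_seed(seed, {
    repeat {
      M <- diag(runif(3, 1 - 0.6 * strength, 1))
      M[row(M) != col(M)] <- runif(6, 0, 0.12 * strength)
      cs <- colSums(M)
      M <- sweep(M, 2, pmax(cs, 1), "/")
      if (abs(det(M)) > 0.05) break
    }
    M
  })
}

# Tissue color models: truncated Gaussians in device RGB around the
# qualitative clinical descriptions -- granulation beefy red, epithelium
# deep pink, necrosis dark yellow-brown (slough/eschar).
tissue_color_models <- function() {
  list(skin        = list(mean = c(224, 172, 138), sd = 5),
       epithelial  = list(mean = c(230, 140, 160), sd = 10),
       granulation = list(mean = c(185,  50,  55), sd = 12),
       necrotic    = list(mean = c(105,  82,  40), sd = 14))
}

#' Generate a synthetic wound scene with ground truth
#'
#' Builds a scene according to `params`: a skin background, a smooth
#' random closed wound contour (a low-order Fourier perturbation of an
#' ellipse), a wound bed partitioned into granulation and necrotic
#' regions by seeded nearest-seed growth with an epithelial rim at the
#' margin, the calibration chart composited frontally at the known scale,
#' and finally the color cast and sensor noise applied to the whole
#' frame. Label maps and per-class counts refer to the pre-cast scene.
#'
#' @param params a [scene_params()].
#' @return An object of class `wound_scene`: `image` (H x W x 3, 0-255
#'   integers, cast applied), `wound_mask` (H x W, 0/1), `tissue_labels`
#'   (H x W integer map: 0 background, 1 epithelial, 2 granulation,
#'   3 necrotic), and `truth` (params echo, `mm_per_px`, exact per-class
#'   pixel counts, the cast, and chart placement when present).
#' @examples
#' sc <- generate_scene(scene_params(seed = 7, include_chart = FALSE,
#'                                   width_px = 96, height_px = 96))
#' sc$truth$pixel_counts
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  w <- params$width_px; h <- params$height_px
  spec <- params$chart_spec
  chart <- NULL
  if (params$include_chart) {
    if (params$px_per_mm < 2)
      stop("px_per_mm must be >= 2 to composite a decodable chart",
           call. = FALSE)
    chart <- render_chart(spec, params$px_per_mm)
    cw <- dim(chart$image)[2]; chh <- dim(chart$image)[1]
    o <- params$chart_origin_px
    if (o[1] < 0 || o[2] < 0 || o[1] + cw > w || o[2] + chh > h)
      stop("chart does not fit in the scene at this resolution",
           call. = FALSE)
  }
  with_seed(params$seed, {
    xs <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
    ys <- matrix(seq_len(h) - 0.5, h, w)
    cx <- params$wound_center_px[1]; cy <- params$wound_center_px[2]
    aspect <- runif(1, 0.75, 1.3)
    rx <- params$wound_radius_px * sqrt(aspect)
    ry <- params$wound_radius_px / sqrt(aspect)
    u <- (xs - cx) / rx; v <- (ys - cy) / ry
    rad <- sqrt(u^2 + v^2); theta <- atan2(v, u)
    amp <- rnorm(3, 0, 0.06); phase <- runif(3, 0, 2 * pi)
    edge <- 1 + amp[1] * cos(2 * theta + phase[1]) +
      amp[2] * cos(3 * theta + phase[2]) + amp[3] * cos(4 * theta + phase[3])
    wound <- rad < edge
    if (!is.null(chart)) {
      o <- params$chart_origin_px
      cw <- dim(chart$image)[2]; chh <- dim(chart$image)[1]
      chart_box <- xs >= o[1] - 2 & xs <= o[1] + cw + 2 &
                   ys >= o[2] - 2 & ys <= o[2] + chh + 2
      if (any(wound & chart_box))
        stop("wound placement overlaps the calibration chart",
             call. = FALSE)
    }
    tw <- params$tissue_weights
    labels <- matrix(0L, h, w)
    # epithelial rim: radial band at the wound margin whose width gives
    # the requested area share (outer fraction f of radius has area share
    # ~ 1 - (1-f)^2)
    interior <- wound
    if (tw[1] > 0) {
      f <- 1 - sqrt(max(0, 1 - tw[1]))
      rim <- wound & rad >= (1 - f) * edge
      labels[rim] <- 1L
      interior <- wound & !rim
    }
    gn <- tw[2:3]
    if (sum(gn) == 0) {             # epithelial-only wound
      labels[interior] <- 1L
    } else if (any(interior)) {
      gn <- gn / sum(gn)
      n_seed <- 6L
      cls <- integer(0)
      if (gn[1] > 0) cls <- c(cls, 2L)
      if (gn[2] > 0) cls <- c(cls, 3L)
      if (length(cls) == 1L) {
        labels[interior] <- cls
      } else {
        # multiplicatively weighted Voronoi: necrotic seeds reach ~1/k^2
        # of the area a granulation seed does (small scattered patches),
        # compensated in the seed-class probabilities so the expected
        # area shares still follow the mixture weights
        k_shrink <- 1.8
        pcls <- c(gn[1], gn[2] * k_shrink^2)
        seed_cls <- c(cls, sample(c(2L, 3L), n_seed - length(cls),
                                  replace = TRUE, prob = pcls))
        idx <- which(interior)
        pick <- sample(idx, length(seed_cls), replace = length(idx) < length(seed_cls))
        sx <- xs[pick]; sy <- ys[pick]
        mult <- ifelse(seed_cls == 3L, k_shrink, 1)
        px <- xs[idx]; py <- ys[idx]
        dmat <- vapply(seq_along(seed_cls), function(s)
          mult[s] * sqrt((px - sx[s])^2 + (py - sy[s])^2), numeric(length(idx)))
        assign_cls <- seed_cls[max.col(-dmat, ties.method = "first")]
        labels[idx] <- assign_cls
      }
    }
    wound_mask <- (labels > 0L) * 1L
    # paint the scene
    cm <- tissue_color_models()
    cm$skin$mean <- params$skin_color; cm$skin$sd <- params$skin_noise_sd
    img <- array(0, dim = c(h, w, 3))
    class_of <- labels + 1L  # 1 = skin
    means <- rbind(cm$skin$mean, cm$epithelial$mean, cm$granulation$mean,
                   cm$necrotic$mean)
    sds <- c(cm$skin$sd, cm$epithelial$sd, cm$granulation$sd, cm$necrotic$sd)
    for (ch in 1:3) {
      base <- means[class_of, ch]
      img[, , ch] <- matrix(base, h, w) +
        matrix(rnorm(h * w, 0, sds[class_of]), h, w)
    }
    if (!is.null(chart)) {
      o <- params$chart_origin_px
      rr <- seq_len(dim(chart$image)[1]) + o[2]
      cc <- seq_len(dim(chart$image)[2]) + o[1]
      img[rr, cc, ] <- chart$image
    }
    flat <- matrix(clip255(img), h * w, 3) %*% params$cast
    if (params$noise_sd > 0)
      flat <- flat + rnorm(length(flat), 0, params$noise_sd)
    img <- array(round(clip255(flat)), dim = c(h, w, 3))
    counts <- c(background = sum(labels == 0L), epithelial = sum(labels == 1L),
                granulation = sum(labels == 2L), necrotic = sum(labels == 3L),
                wound = sum(wound_mask))
    truth <- list(params = params, mm_per_px = 1 / params$px_per_mm,
                  cast = params$cast, pixel_counts = counts,
                  chart_origin_px = if (!is.null(chart)) params$chart_origin_px,
                  chart_truth = if (!is.null(chart)) chart$truth)
    structure(list(image = img, wound_mask = wound_mask,
                   tissue_labels = labels, truth = truth),
              class = "wound_scene")
  })
}

#' @export
print.wound_scene <- function(x, ...) {
  pc <- x$truth$pixel_counts
  cat(sprintf("wound scene %dx%d px (%.3g mm/px): wound %d px (epi %d, gran %d, necr %d)\n",
              dim(x$image)[2], dim(x$image)[1], x$truth$mm_per_px,
              pc["wound"], pc["epithelial"], pc["granulation"], pc["necrotic"]))
  invisible(x)
}

#' Generate a longitudinal synthetic cohort
#'
#' Simulates repeat clinic visits for several subjects. Per subject the
#' wound radius shrinks by a fixed per-visit factor (so the true wound
#' area is strictly decreasing across visits) and the tissue mixture
#' drifts toward healing: the necrotic share decays while the epithelial
#' share grows. Each record carries its subject ID so evaluation splits
#' can be grouped by subject.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject either a single count applied to all
#'   subjects or a vector of per-subject visit counts.
#' @param params base [scene_params()] shared by every scene; per-scene
#'   seeds and casts are derived from `seed`.
#' @param seed cohort-level RNG seed.
#' @param cast_strength when positive, each scene receives its own
#'   [random_cast()] of this strength (emulating different phones and
#'   lighting per visit); when zero, all scenes share `params$cast`.
#' @return An object of class `wound_cohort`: a list of records, each
#'   with `subject_id`, `visit`, and `scene` (a `wound_scene`).
#' @export
generate_cohort <- function(n_subjects = 20, visits_per_subject = NULL,
                            params = scene_params(), seed = 1L,
                            cast_strength = 0) {
  stopifnot(n_subjects >= 1)
  if (is.null(visits_per_subject)) {
    # default emulates a small clinical collection: ~1.5 images per
    # subject with a few repeat attenders
    visits_per_subject <- rep(1L, n_subjects)
    extra <- round(n_subjects * 0.55)
    if (extra > 0) visits_per_subject[seq_len(min(extra, n_subjects))] <-
      visits_per_subject[seq_len(min(extra, n_subjects))] + 1L
  }
  if (length(visits_per_subject) == 1L)
    visits_per_subject <- rep(as.integer(visits_per_subject), n_subjects)
  stopifnot(length(visits_per_subject) == n_subjects,
            all(visits_per_subject >= 1))
  n_total <- sum(visits_per_subject)
  recs <- vector("list", n_total)
  with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    base_r <- params$wound_radius_px
    if (is.null(base_r)) base_r <- 0.22 * min(params$width_px, params$height_px)
    r0 <- runif(n_subjects, 0.85, 1.1) * base_r
    shrink <- runif(n_subjects, 0.80, 0.88)     # per-visit radius factor
    k <- 0L
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      tw0 <- params$tissue_weights
      for (v in seq_len(visits_per_subject[s])) {
        k <- k + 1L
        p <- params
        p$seed <- scene_seeds[k]
        p$wound_radius_px <- r0[s] * shrink[s]^(v - 1)
        heal <- (v - 1) / max(1, visits_per_subject[s] - 1)
        tw <- c(epithelial = tw0[[1]] * (1 + 1.5 * heal),
                granulation = tw0[[2]],
                necrotic = tw0[[3]] * (1 - 0.8 * heal))
        p$tissue_weights <- tw / sum(tw)
        if (cast_strength > 0)
          p$cast <- random_cast(cast_strength,
                                seed = scene_seeds[k] %% 1000003L)
        recs[[k]] <- list(subject_id = sid, visit = v,
                          scene = generate_scene(p))
      }
    }
  })
  structure(recs, class = "wound_cohort")
}

#' @export
print.wound_cohort <- function(x, ...) {
  sid <- vapply(x, `[[`, character(1), "subject_id")
  cat(sprintf("synthetic wound cohort: %d scenes from %d subjects\n",
              length(x), length(unique(sid))))
  invisible(x)
}

#' Subject IDs of a cohort
#' @param cohort a `wound_cohort`.
#' @return character vector, one ID per scene.
#' @export
cohort_subjects <- function(cohort) {
  vapply(cohort, `[[`, character(1), "subject_id")
}
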