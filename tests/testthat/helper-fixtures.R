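# Shared fixtures, memoized so expensive renders happen once per run.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

chart_at <- function(ppm) {
  memo(paste0("chart", ppm), render_chart(chart_spec(), px_per_mm = ppm))
}

# small chartless wound scenes for network tests
tiny_scene <- function(seed, side = 32) {
  generate_scene(scene_params(width_px = side, height_px = side,
                              include_chart = FALSE, seed = seed,
                              wound_center_px = c(side / 2, side / 2),
                              wound_radius_px = side * 0.3))
}

tiny_cohort <- function(n = 4, side = 32, seed = 5) {
  memo(sprintf("cohort_%d_%d_%d", n, side, seed),
       generate_cohort(n, 1,
                       scene_params(width_px = side, height_px = side,
                                    include_chart = FALSE,
                                    wound_center_px = c(side / 2, side / 2),
                                    wound_radius_px = side * 0.3),
                       seed = seed))
}

# brute-force per-pixel confusion tally, kept deliberately naive so it is
# independent of confusion_counts()
brute_confusion <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] != 0; t <- truth[i, j] != 0
    if (p && t) tp <- tp + 1
    else if (!p && !t) tn <- tn + 1
    else if (p && !t) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}
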