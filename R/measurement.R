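# Metric wound measurement: convert segmentation masks to physical areas
# using the chart-derived scale, and assemble per-subject longitudinal
# series of wound and tissue areas across clinic visits.

#' Physical area of a binary mask
#'
#' `pixel count x mm_per_px^2`: the planar area in the chart plane, in
#' square millimetres. No curvature correction is applied — the wound is
#' treated as lying in the plane of the chart.
#'
#' @param mask binary matrix (values 0/1 or logical).
#' @param mm_per_px scale from [estimate_scale()] or a
#'   `calibration_result`.
#' @return area in mm^2.
#' @examples
#' mask_area_mm2(matrix(c(1, 1, 0, 0), 2), mm_per_px = 0.5)
#' @export
mask_area_mm2 <- function(mask, mm_per_px) {
  stopifnot(mm_per_px > 0)
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1)))
    stop("mask must be binary (0/1)", call. = FALSE)
  sum(v) * mm_per_px^2
}

#' Per-visit tissue areas of one scene or prediction
#'
#' @param x a `wound_scene` or `wound_prediction` (anything with
#'   `wound_mask` and `tissue_labels`).
#' @param mm_per_px metric scale.
#' @return named numeric vector of areas in mm^2: wound, epithelial,
#'   granulation, necrotic.
#' @export
tissue_areas_mm2 <- function(x, mm_per_px) {
  c(wound = mask_area_mm2((x$wound_mask == 1) * 1, mm_per_px),
    epithelial = mask_area_mm2((x$tissue_labels == 1) * 1, mm_per_px),
    granulation = mask_area_mm2((x$tissue_labels == 2) * 1, mm_per_px),
    necrotic = mask_area_mm2((x$tissue_labels == 3) * 1, mm_per_px))
}

#' Visit record for longitudinal tracking
#'
#' @param subject_id subject identifier.
#' @param visit visit index (1, 2, ...).
#' @param areas_mm2 named vector from [tissue_areas_mm2()].
#' @param mm_per_px the scale the areas were computed with.
#' @param source optional path of the source image.
#' @return one-row data frame.
#' @export
visit_record <- function(subject_id, visit, areas_mm2, mm_per_px,
                         source = NA_character_) {
  stopifnot(all(areas_mm2 >= 0), mm_per_px > 0)
  data.frame(subject_id = subject_id, visit = as.integer(visit),
             wound_mm2 = areas_mm2[["wound"]],
             epithelial_mm2 = areas_mm2[["epithelial"]],
             granulation_mm2 = areas_mm2[["granulation"]],
             necrotic_mm2 = areas_mm2[["necrotic"]],
             mm_per_px = mm_per_px, source = source)
}

#' Longitudinal per-subject area series
#'
#' Orders one subject's visit records by visit index and derives the
#' per-class first differences and overall direction flags (is the wound
#' area shrinking?), the quantities a clinician tracks over the course
#' of treatment.
#'
#' @param records data frame of [visit_record()] rows for one subject.
#' @return list with `series` (records sorted by visit), `deltas`
#'   (first differences per area column; zero rows for a single visit)
#'   and `direction` (named: "decreasing", "increasing" or "mixed" per
#'   class).
#' @export
longitudinal_series <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$subject_id)) != 1)
    stop("records must belong to a single subject", call. = FALSE)
  if (anyDuplicated(records$visit))
    stop("duplicate visit index", call. = FALSE)
  series <- records[order(records$visit), ]
  area_cols <- c("wound_mm2", "epithelial_mm2", "granulation_mm2",
                 "necrotic_mm2")
  if (nrow(series) > 1) {
    deltas <- as.data.frame(lapply(series[area_cols], diff))
    deltas$visit_from <- series$visit[-nrow(series)]
    deltas$visit_to <- series$visit[-1]
  } else {
    deltas <- series[0, area_cols]
  }
  direction <- vapply(area_cols, function(cl) {
    d <- if (nrow(series) > 1) diff(series[[cl]]) else numeric(0)
    if (!length(d)) "single-visit"
    else if (all(d < 0)) "decreasing"
    else if (all(d > 0)) "increasing"
    else "mixed"
  }, character(1))
  names(direction) <- sub("_mm2$", "", area_cols)
  list(series = series, deltas = deltas, direction = direction)
}
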