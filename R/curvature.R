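#' Measure lateral spinal curvature from a midline
#'
#' Computes the tangent-range angle, a supine Cobb analogue: the tangent
#' direction `theta(row) = atan(d column / d row)` is evaluated along the
#' smoothed midline and the curvature angle is `max(theta) - min(theta)` in
#' degrees. A straight midline gives 0. The number of curves is the number
#' of sign-alternating arcs of lateral deviation from the end-to-end chord
#' (one for a C shape, two for an S); apex rows are the
#' local extrema of that deviation. A small
#' fraction of rows (`midline.trim_frac`) is trimmed at each end before
#' taking the tangent range, so single-row segmentation artefacts at the
#' spine ends cannot dominate the angle.
#'
#' @param midline a [extract_midline()] result, or any data frame with
#'   numeric `row` and `column` columns (e.g. a phantom's true midline).
#' @param config a [dsm_config()].
#' @return Object of class `curve_measurement`: list with `angle_deg`,
#'   `n_curves`, `apex_rows`, `grade` and the tangent series `theta_deg`.
#' @examples
#' ml <- data.frame(row = 1:200, column = 50 + 10 * sin(pi * (1:200) / 200))
#' measure_curvature(ml)$angle_deg
#' @export
measure_curvature <- function(midline, config = dsm_config()) {
  if (!is.data.frame(midline) || !all(c("row", "column") %in% names(midline)))
    stop_dxascol("invalid_input", "midline must have `row` and `column` columns")
  if (nrow(midline) < 10)
    stop_dxascol("insufficient_spine",
                 "need >= 10 midline points to measure curvature (got %d)",
                 nrow(midline))
  fit <- attr(midline, "spline")
  if (is.null(fit))
    fit <- stats::smooth.spline(midline$row, midline$column,
                                df = min(config$midline$df, nrow(midline) - 1L))
  trim <- ceiling(config$midline$trim_frac * nrow(midline))
  rows <- midline$row[(1 + trim):(nrow(midline) - trim)]
  slope <- stats::predict(fit, rows, deriv = 1)$y
  theta <- atan(slope) * 180 / pi
  angle <- diff(range(theta))
  # curves are counted as sign-alternating arcs of lateral deviation from
  # the end-to-end chord: a C gives one arc, an S two
  colfit <- stats::predict(fit, rows)$y
  chord <- seq(colfit[1], colfit[length(colfit)], length.out = length(rows))
  dev <- colfit - chord
  sgn <- sign(dev[abs(dev) > 0.5])
  n_curves <- if (length(sgn)) sum(diff(sgn) != 0) + 1L else 1L
  inner <- 2:(length(dev) - 1L)
  is_ext <- (dev[inner] - dev[inner - 1L]) * (dev[inner + 1L] - dev[inner]) <= 0 &
    abs(dev[inner]) > 0.5
  apex_rows <- rows[inner][is_ext]
  structure(list(angle_deg = angle, n_curves = as.integer(round(n_curves)),
                 apex_rows = apex_rows, grade = grade_curve(angle),
                 theta_deg = stats::setNames(theta, rows)),
            class = "curve_measurement")
}

#' @export
print.curve_measurement <- function(x, ...) {
  cat(sprintf("<curve_measurement> %.2f deg, %d curve(s), grade %s\n",
              x$angle_deg, x$n_curves, x$grade))
  invisible(x)
}

#' Three-class curvature grade
#'
#' Grades a curvature angle into the scheme used for training the automated
#' classifier: `none` below 6 degrees, `mild_6_10` from 6 to 10 degrees
#' inclusive, `major_gt_10` above 10 degrees.
#'
#' @param angle_deg non-negative angle(s) in degrees; vectorised.
#' @return Factor with levels `none`, `mild_6_10`, `major_gt_10`.
#' @examples
#' grade_curve(c(0, 5.9, 6, 10, 10.1))
#' @export
grade_curve <- function(angle_deg) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0))
    stop_dxascol("invalid_input", "angle_deg must be finite and non-negative")
  factor(ifelse(angle_deg < 6, "none",
         ifelse(angle_deg <= 10, "mild_6_10", "major_gt_10")),
         levels = c("none", "mild_6_10", "major_gt_10"))
}

#' Scoliosis suspiciousness score
#'
#' Collapses a curvature measurement to a continuous score in (0, 1): 0
#' means low suspicion of scoliosis, 1 high suspicion. The score is a
#' logistic function of the angle,
#' `1 / (1 + exp(-steepness * (angle - midpoint)))`, strictly increasing in
#' the angle with value 0.5 at the midpoint. The defaults (midpoint 6
#' degrees, steepness 1.5 per degree) place the operating cut-offs used for
#' binary screening (0.95-0.9995) at clinically sensible angle thresholds:
#' e.g. a score of 0.999 corresponds to about 10.6 degrees.
#'
#' @param x a `curve_measurement` or numeric angle(s) in degrees.
#' @param midpoint_deg angle mapped to score 0.5 (> 0).
#' @param steepness_per_deg logistic slope (> 0).
#' @return Score(s) in (0, 1).
#' @examples
#' suspiciousness(10)  # ~0.9975 at the default calibration
#' @export
suspiciousness <- function(x, midpoint_deg = dsm_config()$suspiciousness$midpoint_deg,
                           steepness_per_deg = dsm_config()$suspiciousness$steepness_per_deg) {
  if (midpoint_deg <= 0 || steepness_per_deg <= 0)
    stop_dxascol("invalid_input", "calibration parameters must be positive")
  angle <- if (inherits(x, "curve_measurement")) x$angle_deg else x
  stats::plogis(steepness_per_deg * (angle - midpoint_deg))
}

#' Positioning-error score from raw components
#'
#' Closed-form component arithmetic behind [positioning_error_score()]:
#' each component is normalised by its saturation value and the score is the
#' maximum, clipped to `[0, 1]`.
#'
#' @param tilt_deg signed body-axis tilt, degrees.
#' @param offset_px signed lateral centroid offset, pixels.
#' @param leg_asymmetry leg-length asymmetry fraction.
#' @param width_px image width, used to normalise the offset.
#' @param tilt_max_deg,offset_max_frac,asym_max saturation values.
#' @return Score(s) in `[0, 1]`; vectorised.
#' @export
positioning_component_score <- function(tilt_deg, offset_px, leg_asymmetry,
                                        width_px,
                                        tilt_max_deg = 10,
                                        offset_max_frac = 0.15,
                                        asym_max = 0.2) {
  pmin(pmax(pmax(abs(tilt_deg) / tilt_max_deg,
                 abs(offset_px) / (offset_max_frac * width_px),
                 leg_asymmetry / asym_max), 0), 1)
}

#' Positioning-error score of a segmented scan
#'
#' Scores deviation from the standard supine pose in `[0, 1]`; scans scoring
#' above the exclusion threshold (default 0.5) are excluded from diagnostic
#' evaluation. Components measured from the segmentation: body-axis tilt
#' (principal axis of all body pixels relative to vertical), lateral
#' centroid offset from the image centre, and leg-length asymmetry (relative
#' difference of the leg bounding-box heights). Each is normalised by its
#' configured saturation value (`positioning.*` config keys) and the score
#' is their clipped maximum; a perfectly posed phantom scores 0.
#'
#' @param seg a [segment_body()] result.
#' @param config a [dsm_config()].
#' @return List of class `positioning_score`: `score`, `components`
#'   (measured `tilt_deg`, `offset_px`, `leg_asymmetry`) and `excluded`.
#' @export
positioning_error_score <- function(seg, config = dsm_config()) {
  idx <- which(seg$labels > 0L, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  tilt <- atan2(ev[2], ev[1]) * 180 / pi       # angle from the row axis
  if (tilt > 90) tilt <- tilt - 180
  if (tilt < -90) tilt <- tilt + 180
  offset <- ctr[2] - (seg$dims[2] + 1) / 2
  len_l <- diff(seg$region_stats$left_leg$bbox[1:2])
  len_r <- diff(seg$region_stats$right_leg$bbox[1:2])
  asym <- abs(len_l - len_r) / max(len_l, len_r, 1)
  p <- config$positioning
  score <- positioning_component_score(tilt, offset, asym, seg$dims[2],
                                       p$tilt_max_deg, p$offset_max_frac,
                                       p$asym_max)
  structure(list(score = unname(score),
                 components = list(tilt_deg = unname(tilt),
                                   offset_px = unname(offset),
                                   leg_asymmetry = unname(asym)),
                 excluded = unname(score) > p$exclusion_threshold),
            class = "positioning_score")
}

#' @export
print.positioning_score <- function(x, ...) {
  cat(sprintf("<positioning_score> %.3f (tilt %.2f deg, offset %.1f px, asym %.3f)%s\n",
              x$score, x$components$tilt_deg, x$components$offset_px,
              x$components$leg_asymmetry, if (x$excluded) " -- EXCLUDED" else ""))
  invisible(x)
}

#' Binary scoliosis call from a suspiciousness score
#'
#' Strict comparison: positive iff `score > cutoff`, so a score exactly at
#' the cut-off is negative.
#'
#' @param score,cutoff values in `[0, 1]`; `score` may be a vector.
#' @return Logical.
#' @export
binarize <- function(score, cutoff) {
  if (any(!is.finite(score)) || any(score < 0 | score > 1))
    stop_dxascol("invalid_input", "scores must be in [0, 1]")
  if (!is_scalar_num(cutoff) || cutoff < 0 || cutoff > 1)
    stop_dxascol("invalid_input", "cutoff must be in [0, 1]")
  score > cutoff
}

#' Midline-deviation explanation map
#'
#' A per-pixel explanation of the curvature decision: the mid-spine
#' likelihood weighted, row by row, by the midline's absolute lateral
#' deviation from its end-to-end chord (normalised to max 1). Bright rows
#' are the spine regions that drive the suspiciousness score, analogous to a
#' saliency heatmap over the scan.
#'
#' @param map a [compute_midspine_map()] result.
#' @param midline the matching [extract_midline()] result.
#' @return A matrix in `[0, 1]` of the image shape.
#' @export
explanation_map <- function(map, midline) {
  chord <- seq(midline$column[1], midline$column[nrow(midline)],
               length.out = nrow(midline))
  dev <- abs(midline$column - chord)
  if (max(dev) > 0) dev <- dev / max(dev)
  w <- stats::setNames(dev, midline$row)
  out <- map$likelihood * 0
  for (i in seq_len(nrow(midline)))
    out[midline$row[i], ] <- map$likelihood[midline$row[i], ] * dev[i]
  out
}
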