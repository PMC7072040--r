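#' Heuristic whole-body segmentation
#'
#' Segments a standardised supine whole-body scan into the five expected
#' structures — head, spine, pelvis, left leg, right leg — using simple,
#' deterministic heuristics:
#' \enumerate{
#'   \item Otsu threshold, then the largest connected foreground component.
#'   \item Row-wise width profile: the head is the component above the
#'     shoulder/neck width minimum; the pelvis is the widest band below the
#'     mid-torso (first row whose width exceeds the torso median by a
#'     configured ratio, down to the crotch).
#'   \item The crotch is the first row below the torso where the foreground
#'     splits around the body midline; everything below it forms the two leg
#'     components.
#'   \item The spine is the per-row maximal-intensity ridge within the
#'     central portion of the torso between neck and pelvis, grown to the
#'     contiguous high-intensity run around the ridge.
#' }
#' Violated anatomical expectations (no head candidate, fewer than two leg
#' components, empty spine) raise an anatomy-violation error naming the
#' failed expectation.
#'
#' @param image a standardised [dxa_image()].
#' @param config a [dsm_config()].
#' @return Object of class `body_segmentation`: list with `labels` (integer
#'   matrix; 0 background, 1 head, 2 spine, 3 pelvis, 4 left leg, 5 right
#'   leg), `region_stats` (per-label pixel count and bounding box),
#'   `neck_row`, `pelvis_top`, `crotch_row`, and `dims`.
#' @export
segment_body <- function(image, config = dsm_config()) {
  if (!is_dxa_image(image)) image <- dxa_image(image)
  v <- unclass(image)
  H <- nrow(v); W <- ncol(v)
  th <- EBImage::otsu(EBImage::Image(v))
  fg <- v > th
  comp <- EBImage::bwlabel(EBImage::Image(fg))
  cd <- EBImage::imageData(comp)
  if (max(cd) < 1) stop_dxascol("anatomy_violation", "no foreground found")
  main_id <- which.max(tabulate(cd[cd > 0]))
  fg <- cd == main_id

  body_rows <- which(rowSums(fg) > 0)
  rtop <- min(body_rows); rbot <- max(body_rows)
  hb <- rbot - rtop + 1
  wd <- rowSums(fg)

  # neck: width minimum in the upper body window
  win <- rtop + round(config$segmentation$neck_search_frac * hb)
  win_rows <- seq(max(win[1], rtop + 1L), min(win[2], rbot))
  neck_row <- win_rows[which.min(wd[win_rows])]
  head_mask <- fg
  head_mask[neck_row:H, ] <- FALSE
  if (!any(head_mask))
    stop_dxascol("anatomy_violation", "expected a head above the neck minimum")

  # crotch: first row below mid-body where the foreground splits around the
  # body centre column, persisting for >= 5 rows
  ccol <- mean(which(colSums(fg) > 0))
  split_row <- function(r) {
    runs <- true_runs(fg[r, ])
    nrow(runs) >= 2 && any(runs[-nrow(runs), "end"] < ccol & runs[-1, "start"] > ccol)
  }
  mid_body <- rtop + round(0.45 * hb)
  crotch_row <- NA_integer_
  r <- mid_body
  while (r <= rbot - 5L) {
    if (split_row(r) && all(vapply(r:(r + 4L), split_row, logical(1)))) {
      crotch_row <- r; break
    }
    r <- r + 1L
  }
  if (is.na(crotch_row))
    stop_dxascol("anatomy_violation", "expected two legs below the pelvis (no crotch split found)")
  legs_mask <- fg
  legs_mask[1:(crotch_row - 1L), ] <- FALSE
  lc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(legs_mask)))
  sizes <- tabulate(lc[lc > 0])
  big <- which(sizes >= config$segmentation$min_leg_px)
  if (length(big) < 2)
    stop_dxascol("anatomy_violation", "expected two legs below the pelvis (found %d)",
                 length(big))
  big <- big[order(sizes[big], decreasing = TRUE)][1:2]
  cols_mean <- vapply(big, function(id) mean(col(lc)[lc == id]), numeric(1))
  left_id <- big[which.min(cols_mean)]; right_id <- big[which.max(cols_mean)]

  # pelvis: rows between the lower-torso width step and the crotch
  torso_rows <- seq(neck_row, crotch_row - 1L)
  med_wd <- stats::median(wd[seq(neck_row, rtop + round(0.45 * hb))])
  lower <- torso_rows[torso_rows > rtop + round(0.45 * hb)]
  step <- lower[wd[lower] >= config$segmentation$pelvis_width_ratio * med_wd]
  pelvis_top <- if (length(step)) min(step)
                else crotch_row - round(config$segmentation$pelvis_fallback_frac * hb)
  pelvis_top <- max(pelvis_top, neck_row + 10L)

  # spine: per-row intensity ridge in the central part of the torso
  spine_mask <- matrix(FALSE, H, W)
  for (rr in seq(neck_row, pelvis_top - 1L)) {
    cols <- which(fg[rr, ])
    if (length(cols) < 5) next
    span <- range(cols)
    half <- config$segmentation$spine_central_frac / 2 * diff(span)
    centre <- mean(span)
    cand <- cols[cols >= centre - half & cols <= centre + half]
    if (!length(cand)) next
    ridge <- cand[which.max(v[rr, cand])]
    # require a prominent ridge: rows without true spine signal (neck,
    # pelvis) have no bright medial band and are skipped
    if (v[rr, ridge] - stats::median(v[rr, cols]) <
        config$segmentation$ridge_prominence) next
    thr <- (v[rr, ridge] + stats::median(v[rr, cols])) / 2
    lo <- ridge; while (lo > span[1] && v[rr, lo - 1L] >= thr) lo <- lo - 1L
    hi <- ridge; while (hi < span[2] && v[rr, hi + 1L] >= thr) hi <- hi + 1L
    spine_mask[rr, lo:hi] <- TRUE
  }
  if (sum(rowSums(spine_mask) > 0) < 10)
    stop_dxascol("anatomy_violation", "expected a spine between head and pelvis")

  labels <- matrix(0L, H, W)
  labels[fg & row(fg) >= pelvis_top & row(fg) < crotch_row] <- 3L
  labels[lc == left_id] <- 4L
  labels[lc == right_id] <- 5L
  labels[head_mask] <- 1L
  labels[spine_mask] <- 2L

  stats_tab <- lapply(stats::setNames(1:5, dsm_labels()[-1]), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    list(n = nrow(idx),
         bbox = if (nrow(idx)) c(range(idx[, 1]), range(idx[, 2])) else rep(NA, 4))
  })
  seg <- structure(list(labels = labels, region_stats = stats_tab,
                        neck_row = neck_row, pelvis_top = pelvis_top,
                        crotch_row = crotch_row, dims = c(H, W),
                        image_id = attr(image, "image_id")),
                   class = "body_segmentation")
  validate_segmentation(seg)
  seg
}

dsm_labels <- function() {
  c("background", "head", "spine", "pelvis", "left_leg", "right_leg")
}

validate_segmentation <- function(seg) {
  s <- seg$region_stats
  if (s$head$bbox[2] >= s$pelvis$bbox[1])
    stop_dxascol("anatomy_violation", "head must lie above the pelvis")
  if (s$spine$bbox[1] <= s$head$bbox[1] || s$spine$bbox[2] > s$pelvis$bbox[2])
    stop_dxascol("anatomy_violation", "spine must lie between head and pelvis")
  if (s$left_leg$bbox[1] < s$pelvis$bbox[1] || s$right_leg$bbox[1] < s$pelvis$bbox[1])
    stop_dxascol("anatomy_violation", "legs must lie below the pelvis")
  invisible(seg)
}

#' @export
print.body_segmentation <- function(x, ...) {
  cat(sprintf("<body_segmentation> %s (%d x %d)\n", x$image_id,
              x$dims[1], x$dims[2]))
  for (nm in names(x$region_stats))
    cat(sprintf("  %-9s %6d px, rows %s-%s\n", nm, x$region_stats[[nm]]$n,
                x$region_stats[[nm]]$bbox[1], x$region_stats[[nm]]$bbox[2]))
  invisible(x)
}

#' Mid-spine likelihood map
#'
#' For every segmented spine row, places a unimodal Gaussian bump (SD
#' `midspine.sigma_px`) centred at the intensity-weighted centroid column of
#' that row's spine pixels; the map is zeroed outside a disc dilation of the
#' spine mask and renormalised so each supported row attains maximum 1.
#' The map's row-wise trace is the working definition of "the middle of the
#' spine".
#'
#' @param image the [dxa_image()] the segmentation came from.
#' @param seg a [segment_body()] result.
#' @param config a [dsm_config()].
#' @return Object of class `midspine_map`: list with `likelihood` (matrix in
#'   `[0,1]`, same shape as the image) and `support_rows`.
#' @export
compute_midspine_map <- function(image, seg, config = dsm_config()) {
  if (!is_dxa_image(image)) image <- dxa_image(image)
  v <- unclass(image)
  spine <- seg$labels == 2L
  rows <- which(rowSums(spine) > 0)
  if (!length(rows))
    stop_dxascol("anatomy_violation", "segmentation has an empty spine region")
  sigma <- config$midspine$sigma_px
  brush_size <- 2L * as.integer(config$midspine$dilate_px) + 1L
  support <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(spine), EBImage::makeBrush(brush_size, shape = "disc"))) > 0
  lik <- matrix(0, nrow(v), ncol(v))
  cols_all <- seq_len(ncol(v))
  for (r in rows) {
    sc <- which(spine[r, ])
    centroid <- sum(sc * v[r, sc]) / sum(v[r, sc])
    bump <- exp(-(cols_all - centroid)^2 / (2 * sigma^2))
    bump[!support[r, ]] <- 0
    if (max(bump) > 0) lik[r, ] <- bump / max(bump)
  }
  structure(list(likelihood = lik, support_rows = rows,
                 image_id = seg$image_id),
            class = "midspine_map")
}

#' @export
plot.midspine_map <- function(x, ...) {
  plot(dxa_image(x$likelihood, image_id = paste0(x$image_id, " mid-spine map")),
       ...)
}

#' Extract the spine midline from a mid-spine map
#'
#' Takes the centre of mass of each supported row's likelihood as the
#' sub-pixel spine-centre column, then smooths the columns with a cubic
#' smoothing spline (`midline.df` degrees of freedom) so downstream tangent
#' angles are differentiable. Rows are strictly increasing, head to pelvis.
#'
#' @param map a [compute_midspine_map()] result.
#' @param config a [dsm_config()].
#' @return Object of class `midline`: data frame with columns `row` and
#'   `column` (smoothed); the raw centre-of-mass columns are kept in
#'   attribute `raw_column`, and the fitted spline in attribute `spline`.
#' @export
extract_midline <- function(map, config = dsm_config()) {
  rows <- map$support_rows[rowSums(map$likelihood[map$support_rows, ,
                                                  drop = FALSE]) > 0]
  if (length(rows) < 10)
    stop_dxascol("insufficient_spine",
                 "need >= 10 supported rows to extract a midline (got %d)",
                 length(rows))
  cols_all <- seq_len(ncol(map$likelihood))
  raw <- vapply(rows, function(r) {
    w <- map$likelihood[r, ]
    sum(cols_all * w) / sum(w)
  }, numeric(1))
  # robust two-pass fit: residual outliers (segmentation slips onto bright
  # non-spine pixels) are dropped before the final spline
  fit <- stats::smooth.spline(rows, raw,
                              df = min(config$midline$df, length(rows) - 1L))
  res <- raw - stats::predict(fit, rows)$y
  keep <- abs(res) <= max(4 * stats::mad(res), 2)
  if (sum(keep) >= 10 && any(!keep))
    fit <- stats::smooth.spline(rows[keep], raw[keep],
                                df = min(config$midline$df, sum(keep) - 1L))
  ml <- data.frame(row = rows, column = stats::predict(fit, rows)$y)
  structure(ml, raw_column = raw, spline = fit,
            image_id = map$image_id, class = c("midline", "data.frame"))
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> %s: %d rows (%d-%d), columns %.1f-%.1f\n",
              attr(x, "image_id"), nrow(x), min(x$row), max(x$row),
              min(x$column), max(x$column)))
  invisible(x)
}

# Dice overlap of two logical masks; used to validate segmentations against
# generator truth masks.
#' Dice overlap coefficient between two masks
#' @param a,b logical matrices of the same shape.
#' @return `2|a & b| / (|a| + |b|)`.
#' @export
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
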