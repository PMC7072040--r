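#' Specification of a synthetic whole-body DXA phantom
#'
#' A phantom emulates a supine total-body DXA scan: a silhouette with a head,
#' a torso, a pelvis and two legs, and a bright spine band whose midline
#' carries a controllable lateral curve. The curve magnitude is the
#' tangent-range angle (a supine Cobb analogue): the range of midline tangent
#' angles along the spine, in degrees. Positioning perturbations (whole-body
#' tilt, lateral offset, leg-length asymmetry) and Poisson-scaled Gaussian
#' noise emulate scan-to-scan variation.
#'
#' @param image_height_px,image_width_px image dimensions in pixels
#'   (default 800 x 300, a typical whole-body aspect ratio).
#' @param curve_angle_deg non-negative ground-truth tangent-range angle in
#'   degrees; must be 0 exactly when `curve_pattern` is `"straight"`.
#' @param curve_pattern `"straight"`, `"single_C"` (one lateral bump) or
#'   `"double_S"` (one sign change, two apices).
#' @param apex_row_fraction apex position along the spine, strictly in (0,1);
#'   used by `single_C`.
#' @param noise_sigma base standard deviation of the additive noise
#'   (intensity units on the `[0,1]` scale); the per-pixel SD scales with
#'   `sqrt(0.25 + intensity)` so brighter tissue is noisier.
#' @param tilt_deg signed whole-body axis rotation in degrees.
#' @param lateral_offset_px signed lateral shift of the body in pixels.
#' @param leg_asymmetry fraction in `[0,1]` by which the right leg is
#'   shortened relative to the left.
#' @param seed integer seed controlling the noise (and any jitter drawn from
#'   this spec).
#' @return A validated list of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_repeat_pair()], [generate_cohort()]
#' @export
phantom_spec <- function(image_height_px = 800L, image_width_px = 300L,
                         curve_angle_deg = 0,
                         curve_pattern = c("straight", "single_C", "double_S"),
                         apex_row_fraction = 0.5, noise_sigma = 0.05,
                         tilt_deg = 0, lateral_offset_px = 0,
                         leg_asymmetry = 0, seed = 1L) {
  curve_pattern <- match.arg(curve_pattern)
  spec <- list(image_height_px = as.integer(image_height_px),
               image_width_px = as.integer(image_width_px),
               curve_angle_deg = curve_angle_deg,
               curve_pattern = curve_pattern,
               apex_row_fraction = apex_row_fraction,
               noise_sigma = noise_sigma, tilt_deg = tilt_deg,
               lateral_offset_px = lateral_offset_px,
               leg_asymmetry = leg_asymmetry, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = c("phantom_spec", "list"))
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (curve_angle_deg < 0 || curve_angle_deg >= 90)
      stop_dxascol("invalid_input", "curve_angle_deg must be in [0, 90)")
    if ((curve_angle_deg == 0) != (curve_pattern == "straight"))
      stop_dxascol("invalid_input",
                   "curve_angle_deg must be 0 iff curve_pattern is 'straight'")
    if (apex_row_fraction <= 0 || apex_row_fraction >= 1)
      stop_dxascol("invalid_input", "apex_row_fraction must be in (0, 1)")
    if (noise_sigma < 0) stop_dxascol("invalid_input", "noise_sigma must be >= 0")
    if (leg_asymmetry < 0 || leg_asymmetry > 1)
      stop_dxascol("invalid_input", "leg_asymmetry must be in [0, 1]")
  })
  invisible(spec)
}

# Anatomy layout as fractions of image height (H) / width (W); shared by the
# renderer and the ground-truth masks.
phantom_geometry <- function(H, W) {
  cc <- (W + 1) / 2
  list(
    cc = cc,
    head_r = 0.08 * H, head_rad = 0.13 * W,
    neck = c(0.115, 0.145) * H, neck_hw = 0.07 * W,
    torso = c(0.135, 0.53) * H, torso_hw = 0.28 * W,
    pelvis = c(0.53, 0.63) * H, pelvis_hw = 0.40 * W,
    hip_row = 0.61 * H, foot_row = 0.97 * H,
    hip_dx = 0.165 * W, foot_dx = 0.19 * W, leg_rad = 0.085 * W,
    spine = c(0.145, 0.53) * H, spine_hw = 0.025 * W
  )
}

# Unit-amplitude midline shapes on t in [0,1] and their derivatives d/dt.
# Both have zero tangent at the spine ends so the tangent-angle extremes lie
# strictly inside the spine, robust to end-row trimming downstream.
curve_shape <- function(pattern, apex = 0.5) {
  switch(pattern,
    straight = list(f = function(t) rep(0, length(t)),
                    d = function(t) rep(0, length(t))),
    single_C = list(
      f = function(t) ifelse(t <= apex,
                             (1 - cos(pi * t / apex)) / 2,
                             (1 + cos(pi * (t - apex) / (1 - apex))) / 2),
      d = function(t) ifelse(t <= apex,
                             pi / (2 * apex) * sin(pi * t / apex),
                             -pi / (2 * (1 - apex)) * sin(pi * (t - apex) / (1 - apex)))),
    double_S = {
      nrm <- 4 / (3 * sqrt(3))  # max of 2 sin^2(x) cos(x)
      list(
        f = function(t) 2 * sin(pi * t)^2 * cos(pi * t) / nrm,
        d = function(t) 2 * pi * sin(pi * t) * (3 * cos(pi * t)^2 - 1) / nrm)
    })
}

# Tangent-range angle (degrees) of midline column offset a * shape over a
# spine of `len` rows.
tangent_range_deg <- function(a, shape, len, n_grid = 2001L) {
  t <- seq(0, 1, length.out = n_grid)
  theta <- atan(a * shape$d(t) / len) * 180 / pi
  diff(range(theta))
}

# Amplitude (px) whose tangent range equals the target angle; monotone in a,
# solved with uniroot to 1e-6 degrees.
solve_amplitude <- function(angle_deg, shape, len) {
  if (angle_deg == 0) return(0)
  hi <- len
  while (tangent_range_deg(hi, shape, len) < angle_deg) hi <- hi * 2
  stats::uniroot(function(a) tangent_range_deg(a, shape, len) - angle_deg,
                 c(0, hi), tol = 1e-9)$root
}

# Distance from points (r, c) to segment (r1,c1)-(r2,c2), vectorised.
seg_dist <- function(r, c, r1, c1, r2, c2) {
  vr <- r2 - r1; vc <- c2 - c1
  tt <- pmin(pmax(((r - r1) * vr + (c - c1) * vc) / (vr^2 + vc^2), 0), 1)
  sqrt((r - (r1 + tt * vr))^2 + (c - (c1 + tt * vc))^2)
}

#' Generate a synthetic DXA phantom with ground truth
#'
#' Renders the five anatomical structures (head, spine, pelvis, two legs) on
#' a soft-tissue silhouette, applies the positioning transform (tilt about the
#' image centre, then lateral offset) and additive signal-dependent noise,
#' and returns the image together with its analytic ground truth: the spine
#' midline (one sub-pixel column per image row), the injected tangent-range
#' angle, the three-class grade (`none` < 6, `mild_6_10` in [6,10],
#' `major_gt_10` > 10 degrees) and a positioning-error flag.
#'
#' Deterministic: the same spec (including its seed) yields a bit-identical
#' image.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `dxa_phantom` with elements `image`
#'   ([dxa_image()]), `truth` (list: `true_midline` data frame with columns
#'   `row`, `column`; `true_angle_deg`; `true_class`; `true_positioning_error`;
#'   `spec`) and `masks` (logical matrices `head`, `spine`, `pelvis`,
#'   `left_leg`, `right_leg`).
#' @examples
#' ph <- generate_phantom(phantom_spec(curve_angle_deg = 15,
#'                                     curve_pattern = "single_C", seed = 3))
#' ph$truth$true_class
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$image_height_px; W <- spec$image_width_px
  if (H < 120 || W < 60)
    stop_dxascol("sizing",
                 "image too small to contain all structures (need >= 120 x 60 px)")
  g <- phantom_geometry(H, W)
  shape <- curve_shape(spec$curve_pattern, spec$apex_row_fraction)
  s0 <- g$spine[1]; s1 <- g$spine[2]; len <- s1 - s0
  amp <- solve_amplitude(spec$curve_angle_deg, shape, len)

  # body-frame coordinates of every pixel (inverse positioning transform)
  ctr_r <- (H + 1) / 2; ctr_c <- (W + 1) / 2
  th <- spec$tilt_deg * pi / 180
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- r - ctr_r; dc <- c_ - ctr_c - spec$lateral_offset_px
  rb <- cos(th) * dr + sin(th) * dc + ctr_r
  cb <- -sin(th) * dr + cos(th) * dc + ctr_c

  cc <- g$cc
  headM <- (rb - g$head_r)^2 + (cb - cc)^2 <= g$head_rad^2
  neckM <- rb >= g$neck[1] & rb <= g$neck[2] & abs(cb - cc) <= g$neck_hw
  se6 <- function(rr, band, hw) {
    rm <- mean(band); rh <- diff(band) / 2
    (abs((rb - rm) / rh))^6 + (abs((cb - cc) / hw))^6 <= 1
  }
  torsoM <- se6(rb, g$torso, g$torso_hw)
  pelvisM <- se6(rb, g$pelvis, g$pelvis_hw)
  foot_l <- g$foot_row
  foot_r <- g$hip_row + (1 - spec$leg_asymmetry) * (g$foot_row - g$hip_row)
  legL <- seg_dist(rb, cb, g$hip_row, cc - g$hip_dx, foot_l, cc - g$foot_dx) <= g$leg_rad
  legR <- seg_dist(rb, cb, g$hip_row, cc + g$hip_dx, foot_r, cc + g$foot_dx) <= g$leg_rad
  tt <- pmin(pmax((rb - s0) / len, 0), 1)
  spine_dist <- abs(cb - (cc + amp * shape$f(tt)))
  in_span <- rb >= s0 & rb <= s1
  spineM <- in_span & spine_dist <= g$spine_hw
  # partial-volume edge coverage so the band's centre of mass is sub-pixel
  # accurate (emulates the soft bone/soft-tissue boundary of real scans)
  spine_cov <- ifelse(in_span,
                      pmin(pmax(g$spine_hw + 0.5 - spine_dist, 0), 1), 0)

  img <- matrix(0.02, H, W)
  img[torsoM | neckM] <- 0.35
  img[legL | legR] <- 0.45
  img[pelvisM] <- 0.50
  img[headM] <- 0.55
  img <- img * (1 - spine_cov) + 0.92 * spine_cov

  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      img + stats::rnorm(length(img), 0, spec$noise_sigma * sqrt(0.25 + img))
    })
    img <- matrix(pmin(pmax(img, 0), 1), H, W)
  }

  # ground-truth midline in image coordinates (forward transform, then
  # resampled at integer image rows)
  rb_mid <- seq(s0, s1, by = 0.5)
  cb_mid <- cc + amp * shape$f((rb_mid - s0) / len)
  r_img <- cos(th) * (rb_mid - ctr_r) - sin(th) * (cb_mid - ctr_c) + ctr_r
  c_img <- sin(th) * (rb_mid - ctr_r) + cos(th) * (cb_mid - ctr_c) +
    ctr_c + spec$lateral_offset_px
  rows <- seq(ceiling(min(r_img)), floor(max(r_img)))
  midline <- data.frame(row = rows,
                        column = stats::approx(r_img, c_img, xout = rows)$y)

  pos_score <- positioning_component_score(
    tilt_deg = spec$tilt_deg, offset_px = spec$lateral_offset_px,
    leg_asymmetry = spec$leg_asymmetry, width_px = W)
  truth <- list(
    true_midline = midline,
    true_angle_deg = spec$curve_angle_deg,
    true_class = grade_curve(spec$curve_angle_deg),
    true_positioning_error = pos_score > 0.5,
    body_midline = data.frame(row = rb_mid, column = cb_mid),
    spec = spec)
  masks <- list(head = headM & !spineM,
                spine = spineM,
                pelvis = pelvisM & !spineM,
                left_leg = legL & !pelvisM,
                right_leg = legR & !pelvisM)
  structure(list(
    image = dxa_image(img, image_id = sprintf("phantom_s%d", spec$seed)),
    truth = truth, masks = masks),
    class = "dxa_phantom")
}

#' @export
print.dxa_phantom <- function(x, ...) {
  cat(sprintf("<dxa_phantom> %s: %.1f deg (%s), class %s%s\n",
              attr(x$image, "image_id"), x$truth$true_angle_deg,
              x$truth$spec$curve_pattern, x$truth$true_class,
              if (x$truth$true_positioning_error) ", positioning error" else ""))
  invisible(x)
}

#' @export
plot.dxa_phantom <- function(x, midline = TRUE, ...) {
  plot(x$image, ...)
  if (midline) {
    H <- nrow(x$image); W <- ncol(x$image)
    ml <- x$truth$true_midline
    graphics::lines((ml$column - 1) / (W - 1), 1 - (ml$row - 1) / (H - 1),
                    col = "red", lwd = 2)
  }
  invisible(x)
}

#' Generate a repeat-scan phantom pair with repositioning jitter
#'
#' Emulates two scans of the same subject taken weeks apart with
#' repositioning in between: both images share the same spine (identical
#' curve pattern and angle); the second differs only by re-sampled tilt,
#' lateral offset, leg asymmetry and noise. With all jitter SDs zero and
#' `noise_sigma = 0` the two images are identical.
#'
#' @param spec a [phantom_spec()] for the first scan.
#' @param jitter list with non-negative elements `tilt_sd_deg`,
#'   `offset_sd_px`, `asym_sd`: SDs of the repositioning perturbations added
#'   for the second scan.
#' @return List of class `dxa_repeat_pair`: `scan1`, `scan2` (both
#'   `dxa_phantom`) and `truth` (the shared ground truth of scan 1).
#' @export
generate_repeat_pair <- function(spec,
                                 jitter = list(tilt_sd_deg = 2,
                                               offset_sd_px = 4,
                                               asym_sd = 0.02)) {
  jitter <- modifyList(list(tilt_sd_deg = 0, offset_sd_px = 0, asym_sd = 0),
                       jitter)
  if (any(unlist(jitter) < 0))
    stop_dxascol("invalid_input", "jitter magnitudes must be non-negative")
  p1 <- generate_phantom(spec)
  delta <- with_seed(spec$seed + 7919L,
                     stats::rnorm(3) * c(jitter$tilt_sd_deg,
                                         jitter$offset_sd_px, jitter$asym_sd))
  spec2 <- spec
  spec2$tilt_deg <- spec$tilt_deg + delta[1]
  spec2$lateral_offset_px <- spec$lateral_offset_px + delta[2]
  spec2$leg_asymmetry <- min(max(spec$leg_asymmetry + delta[3], 0), 1)
  spec2$seed <- (spec$seed + 1000003L) %% .Machine$integer.max
  p2 <- generate_phantom(spec2)
  attr(p2$image, "image_id") <- paste0(attr(p1$image, "image_id"), "_repeat")
  structure(list(scan1 = p1, scan2 = p2, truth = p1$truth),
            class = "dxa_repeat_pair")
}

#' Generate a synthetic screening cohort
#'
#' Draws `n` subjects with scoliosis prevalence `prevalence`; scoliotic
#' subjects are split between the mild (6-10 degrees) and major (> 10
#' degrees) classes, with angles drawn uniformly from the per-class ranges.
#' Positioning perturbations are drawn per subject; a fraction `p_error`
#' receives a gross tilt that flags the scan as a positioning error.
#'
#' @param n cohort size (>= 1).
#' @param prevalence scoliosis prevalence, strictly in (0,1), or 0 for an
#'   all-normal cohort (default 0.059, the adolescent prevalence used for
#'   population projections).
#' @param angles list: `none`, `mild`, `major` angle ranges (degrees) and
#'   `p_mild`, the mild share among scoliotic subjects.
#' @param positioning list: `tilt_sd_deg`, `offset_sd_px`, `asym_sd` for
#'   routine variation and `p_error` for gross positioning errors.
#' @param height_px,width_px,noise_sigma forwarded to [phantom_spec()].
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @param render if `FALSE`, skip image rendering and return the truth table
#'   only (fast statistical checks).
#' @return List of class `dxa_cohort`: `phantoms` (list of `dxa_phantom`, or
#'   `NULL`s when `render = FALSE`) and `truth` (data frame with one row per
#'   subject: `image_id`, `true_angle_deg`, `true_class`, `tilt_deg`,
#'   `offset_px`, `leg_asymmetry`, `positioning_error`, `seed`).
#' @export
generate_cohort <- function(n, prevalence = 0.059,
                            angles = list(none = c(0, 5), mild = c(6, 10),
                                          major = c(11, 28), p_mild = 0.5),
                            positioning = list(tilt_sd_deg = 1.5,
                                               offset_sd_px = 3,
                                               asym_sd = 0.02, p_error = 0),
                            height_px = 800L, width_px = 300L,
                            noise_sigma = 0.05, seed = 1L, render = TRUE) {
  if (n < 1) stop_dxascol("empty_cohort", "cohort size n must be >= 1")
  if (prevalence < 0 || prevalence >= 1)
    stop_dxascol("invalid_input", "prevalence must be in [0, 1)")
  draws <- with_seed(seed, {
    scol <- stats::runif(n) < prevalence
    mild <- stats::runif(n) < angles$p_mild
    ang <- ifelse(!scol, stats::runif(n, angles$none[1], angles$none[2]),
           ifelse(mild, stats::runif(n, angles$mild[1], angles$mild[2]),
                        stats::runif(n, angles$major[1], angles$major[2])))
    pattern <- ifelse(ang == 0, "straight",
               ifelse(scol & stats::runif(n) < 0.3, "double_S", "single_C"))
    err <- stats::runif(n) < positioning$p_error
    tilt <- stats::rnorm(n, 0, positioning$tilt_sd_deg) +
      err * sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 6, 9)
    data.frame(
      true_angle_deg = ang, pattern = pattern,
      apex = stats::runif(n, 0.35, 0.65),
      tilt_deg = tilt,
      offset_px = stats::rnorm(n, 0, positioning$offset_sd_px),
      leg_asymmetry = pmin(abs(stats::rnorm(n, 0, positioning$asym_sd)), 1),
      seed = (seed + 104729L * seq_len(n)) %% 2147483647L)
  })
  phantoms <- vector("list", n)
  truth <- draws
  truth$image_id <- sprintf("subj%04d", seq_len(n))
  truth$true_class <- grade_curve(truth$true_angle_deg)
  truth$positioning_error <- positioning_component_score(
    truth$tilt_deg, truth$offset_px, truth$leg_asymmetry, width_px) > 0.5
  for (i in seq_len(n)) {
    sp <- phantom_spec(height_px, width_px,
                       curve_angle_deg = draws$true_angle_deg[i],
                       curve_pattern = draws$pattern[i],
                       apex_row_fraction = draws$apex[i],
                       noise_sigma = noise_sigma,
                       tilt_deg = draws$tilt_deg[i],
                       lateral_offset_px = draws$offset_px[i],
                       leg_asymmetry = draws$leg_asymmetry[i],
                       seed = draws$seed[i])
    if (render) {
      phantoms[[i]] <- generate_phantom(sp)
      attr(phantoms[[i]]$image, "image_id") <- truth$image_id[i]
    } else {
      phantoms[i] <- list(NULL)
    }
  }
  truth <- truth[, c("image_id", "true_angle_deg", "true_class", "tilt_deg",
                     "offset_px", "leg_asymmetry", "positioning_error", "seed")]
  structure(list(phantoms = phantoms, truth = truth), class = "dxa_cohort")
}

#' Write a cohort to disk
#'
#' Writes each phantom as 16-bit grayscale TIFF plus a `truth.csv` table
#' (columns `image_id`, `true_angle_deg`, `true_class`, `tilt_deg`,
#' `offset_px`, `leg_asymmetry`, `positioning_error`, `seed`).
#'
#' @param cohort a rendered [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in cohort$phantoms) {
    if (is.null(ph)) stop_dxascol("invalid_input", "cohort was not rendered")
    write_dxa(ph$image, file.path(dir, paste0(attr(ph$image, "image_id"), ".tif")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
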