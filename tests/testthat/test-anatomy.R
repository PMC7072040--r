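test_that("segmentation finds all five structures with a valid layout", {
  seg <- fix_chain(0)$seg
  counts <- vapply(seg$region_stats, `[[`, numeric(1), "n")
  expect_true(all(counts > 0))
  s <- seg$region_stats
  expect_lt(s$head$bbox[2], s$pelvis$bbox[1])
  expect_gt(s$spine$bbox[1], s$head$bbox[1])
  expect_lte(s$spine$bbox[2], s$pelvis$bbox[2])
  expect_gte(s$left_leg$bbox[1], s$pelvis$bbox[1])
  expect_gte(s$right_leg$bbox[1], s$pelvis$bbox[1])
  # left leg is left of right leg
  expect_lt(mean(s$left_leg$bbox[3:4]), mean(s$right_leg$bbox[3:4]))
})

test_that("erasing one leg raises an anatomy violation naming the legs", {
  ph <- fix_phantom(0)
  img <- unclass(ph$image)
  img[500:800, 151:300] <- 0.02   # wipe everything right of midline below crotch
  err <- expect_error(segment_body(standardize_height(dxa_image(img))),
                      class = "dxascol_anatomy_violation")
  expect_match(conditionMessage(err), "leg")
})

test_that("segmentation overlaps generator truth masks (Dice >= 0.8)", {
  # segment at native height so masks align; noise at the documented level
  cfg <- dsm_config(preprocessing = list(target_height_px = 800))
  ph <- fix_phantom(15, noise = 0.05, seed = 4)
  seg <- segment_body(ph$image, cfg)
  for (k in seq_along(ph$masks)) {
    expect_gt(dice(seg$labels == k, ph$masks[[names(ph$masks)[k]]]), 0.8)
  }
})

test_that("mid-spine map is unimodal, normalised and supported on the spine", {
  ch <- fix_chain(0)
  lik <- ch$map$likelihood
  expect_true(all(lik >= 0 & lik <= 1))
  rows <- ch$map$support_rows
  # straight phantom: per-row argmax constant
  am <- apply(lik[rows, ], 1, which.max)
  expect_lt(diff(range(am)), 1e-9)
  # every supported row attains maximum 1
  expect_true(all(abs(apply(lik[rows, ], 1, max) - 1) < 1e-12))
  # zero outside the dilated spine mask
  spine <- ch$seg$labels == 2L
  brush <- EBImage::makeBrush(2L * ch$cfg$midspine$dilate_px + 1L, "disc")
  support <- EBImage::imageData(EBImage::dilate(EBImage::Image(spine), brush)) > 0
  expect_true(all(lik[!support] == 0))
})

test_that("map argmax trace follows the true midline on a curved phantom", {
  ch <- fix_chain(15, noise = 0.05, seed = 4)
  rows <- ch$map$support_rows
  am <- apply(ch$map$likelihood[rows, ], 1, which.max)
  tc <- truth_at(ch$phantom, rows)
  ok <- !is.na(tc)
  expect_lt(sqrt(mean((am[ok] - tc[ok])^2)), 2)
})

test_that("midline extraction is sub-pixel accurate and mirror-equivariant", {
  ch <- fix_chain(20)
  tc <- truth_at(ch$phantom, ch$midline$row)
  ok <- !is.na(tc)
  expect_lt(max(abs(ch$midline$column[ok] - tc[ok])), 2)
  expect_false(is.unsorted(ch$midline$row, strictly = TRUE))
  # support equals the spine row extent of the segmentation
  spine_rows <- which(rowSums(ch$seg$labels == 2L) > 0)
  expect_equal(range(ch$midline$row), range(spine_rows))
  # left-right flip mirrors the midline and swaps the leg labels
  W <- ncol(ch$std)
  flip <- dxa_image(unclass(ch$std)[, W:1], image_id = "flip")
  segf <- segment_body(flip, ch$cfg)
  expect_equal(unname((segf$labels == 4L)[, W:1]),
               unname(ch$seg$labels == 5L))
  mlf <- extract_midline(compute_midspine_map(flip, segf, ch$cfg), ch$cfg)
  expect_lt(max(abs((W + 1 - mlf$column) - ch$midline$column)), 1e-6)
})

test_that("a symmetric single-bump row centres its midline column", {
  lik <- matrix(0, 30, 21)
  for (r in 6:25) lik[r, ] <- exp(-((1:21) - 11)^2 / 8)
  ml <- extract_midline(structure(list(likelihood = lik, support_rows = 6:25,
                                       image_id = "toy"),
                                  class = "midspine_map"))
  expect_true(all(abs(ml$column - 11) < 1e-9))
})

test_that("too little spine support raises an insufficient-spine error", {
  lik <- matrix(0, 30, 21)
  for (r in 6:10) lik[r, ] <- exp(-((1:21) - 11)^2 / 8)
  expect_error(extract_midline(structure(list(likelihood = lik,
                                              support_rows = 6:10,
                                              image_id = "toy"),
                                         class = "midspine_map")),
               class = "dxascol_insufficient_spine")
})
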