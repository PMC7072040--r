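# Shared seeded fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fix_phantom <- function(angle, pattern = if (angle == 0) "straight" else "single_C",
                        noise = 0, tilt = 0, seed = 11, ...) {
  key <- paste("ph", angle, pattern, noise, tilt, seed, ..., sep = "_")
  cached(key, generate_phantom(
    phantom_spec(curve_angle_deg = angle, curve_pattern = pattern,
                 noise_sigma = noise, tilt_deg = tilt, seed = seed, ...)))
}

fix_processed <- function(angle, pattern = if (angle == 0) "straight" else "single_C",
                          noise = 0, tilt = 0, seed = 11, ...) {
  key <- paste("rec", angle, pattern, noise, tilt, seed, ..., sep = "_")
  cached(key, process_scan(fix_phantom(angle, pattern, noise, tilt, seed, ...)))
}

# Standardised image -> segmentation -> map -> midline chain, cached.
fix_chain <- function(angle, pattern = if (angle == 0) "straight" else "single_C",
                      noise = 0, tilt = 0, seed = 11) {
  key <- paste("chain", angle, pattern, noise, tilt, seed, sep = "_")
  cached(key, {
    cfg <- dsm_config()
    ph <- fix_phantom(angle, pattern, noise, tilt, seed)
    std <- standardize_height(ph$image)
    seg <- segment_body(std, cfg)
    map <- compute_midspine_map(std, seg, cfg)
    ml <- extract_midline(map, cfg)
    list(phantom = ph, std = std, seg = seg, map = map, midline = ml,
         cfg = cfg)
  })
}

# Truth midline rescaled to the standardised height, sampled at given rows.
truth_at <- function(phantom, rows, target_height = 512) {
  s <- target_height / nrow(phantom$image)
  tm <- phantom$truth$true_midline
  stats::approx(tm$row * s, tm$column * s, xout = rows)$y
}
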