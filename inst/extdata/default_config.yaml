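# dxascol default pipeline profile.
# Every operating constant of the pipeline is a named key here; nothing is
# hard-coded in the processing functions.
preprocessing:
  target_height_px: 512        # common height images are standardised to
segmentation:
  neck_search_frac: [0.03, 0.35]  # body-extent window searched for the neck minimum
  pelvis_width_ratio: 1.12        # row counts as pelvic once width exceeds ratio x torso median
  pelvis_fallback_frac: 0.10      # pelvis band height if no width step is found
  spine_central_frac: 0.60        # fraction of each row's body span searched for the spine ridge
  ridge_prominence: 0.20          # min ridge intensity above the row median for a spine row
  min_leg_px: 30                  # minimum pixels for a leg component
midspine:
  sigma_px: 3                  # Gaussian bump width at the standard height
  dilate_px: 7                 # support = spine mask dilated by this disc radius
midline:
  df: 12                       # smoothing-spline degrees of freedom
  trim_frac: 0.02              # rows trimmed at each end before tangent angles
suspiciousness:
  midpoint_deg: 6              # angle mapped to score 0.5
  steepness_per_deg: 1.5       # logistic slope
positioning:
  tilt_max_deg: 10             # tilt saturating its component at 1
  offset_max_frac: 0.15        # lateral offset saturating at 1, as fraction of width
  asym_max: 0.2                # leg-length asymmetry saturating at 1
  exclusion_threshold: 0.5     # scans scoring above this are excluded
classification:
  cutoff: 0.999                # final binary cut-off on the suspiciousness score
  cutoff_sweep: [0.95, 0.98, 0.99, 0.995, 0.999, 0.9995]
projection:
  prevalence: 0.059            # population prevalence used for projections
  n_population: 10000          # hypothetical population size
seed: 1
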