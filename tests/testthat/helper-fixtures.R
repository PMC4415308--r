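# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# flat-plane wound: plane base, elliptical wound, no noise
flat_wound <- function() fixture("flat_wound", function() {
  synth_generate(synthetic_wound_spec(
    footprint_mm = c(50, 50), pitch_mm = 0.5, cyl_radius_mm = 1e9,
    undulation_amp_mm = 0, noise_sd_mm = 0,
    a_mm = 10, b_mm = 8, phi_deg = 30, depth_mm = 2, taper_mm = 3, seed = 11))
})

# curved noisy wound at device-scale pitch (used for metrology checks)
curved_wound <- function() fixture("curved_wound", function() {
  synth_generate(synthetic_wound_spec(
    footprint_mm = c(52, 48), pitch_mm = 0.25, cyl_radius_mm = 60,
    a_mm = 11, b_mm = 8.5, phi_deg = 40, depth_mm = 3, taper_mm = 3,
    seed = 12))
})

# small high-contrast fixture for segmentation back-ends
seg_fixture <- function() fixture("seg_fixture", function() {
  g <- synth_generate(synthetic_wound_spec(
    footprint_mm = c(40, 40), pitch_mm = 0.4,
    a_mm = 9, b_mm = 7, phi_deg = 25, depth_mm = 3, taper_mm = 3, seed = 7))
  list(g = g, img = extract_color_image(g$wounded),
       seeds = make_seeds(g$true_mask, erode_px = 5, dilate_px = 9))
})

# six-wound bias experiment (used by several acceptance checks)
bias_report <- function() fixture("bias_report", function() {
  suppressWarnings(cmd_bias(master_seed = 1L))
})
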