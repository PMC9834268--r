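# Shared fixtures: a small chip whose renders take milliseconds, with growth
# scaled so spheroids stay inside the 125 um anchors; the full 154-anchor
# chip is exercised in test-acceptance.R.

tiny_layout <- function(n = 12, pixel = 10) {
  build_hexagonal_layout(n, chamber_area_mm2 = 8, pitch_um = 500,
                         pixel_size_um = pixel)
}

tiny_growth <- function() growth_spec(d0_um = 80, dmax_um = 150)

noiseless_optics <- function(...) optics_model(noise_sd = 0, ...)

# render a single anchor carrying one codebook condition, reusable truth row
truth_row <- function(layout, cb, condition, timepoint_h = 72,
                      diameter_um = 120, dead_fraction = 0,
                      anchor_id = 1L) {
  conc <- code_concentrations(cb)
  i <- match(condition, conc$condition_label)
  stopifnot(!is.na(i))
  data.frame(anchor_id = anchor_id, condition_label = condition,
             drug = cb$codes$drug[i], dose_umol = cb$codes$dose_umol[i],
             timepoint_h = timepoint_h, true_diameter_um = diameter_um,
             true_dead_fraction = dead_fraction,
             red_umol = conc$red_umol[i] / cb$dilution_factor,
             green_umol = conc$green_umol[i] / cb$dilution_factor,
             blue_umol = conc$blue_umol[i] / cb$dilution_factor,
             n_immune_cells = 0L, empty = FALSE)
}

# measurements table derived directly from ground truth (bypasses imaging),
# for unit-testing the aggregation layer in isolation
measurements_from_truth <- function(truth, pi_level = 3000, background = 100) {
  data.frame(anchor_id = truth$anchor_id,
             timepoint_h = truth$timepoint_h,
             area_px = 300,
             diameter_um = truth$true_diameter_um,
             dead_pixel_count = round(truth$true_dead_fraction * 300),
             dead_fraction = truth$true_dead_fraction,
             viability = 1 - truth$true_dead_fraction,
             mean_dead_intensity = background +
               truth$true_dead_fraction * pi_level,
             local_threshold_used = background + 20,
             circularity = 1, qc_flags = "")
}

# assignments table equal to the ground-truth allocation
assignments_from_truth <- function(truth) {
  t0 <- truth[truth$timepoint_h == min(truth$timepoint_h), ]
  data.frame(anchor_id = t0$anchor_id, condition_label = t0$condition_label,
             unassigned_reason = NA_character_, log_margin = 1)
}
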