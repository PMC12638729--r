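# shared builders for synthetic test vessels

tube_profile <- function(r_mm = 1.5, length_mm = 30, n = 200) {
  resample_profile(
    centreline_profile(c(0, length_mm), c(r_mm, r_mm), case_id = "tube"), n)
}

taper_profile <- function(r_in = 1.35, r_out = 0.95, length_mm = 30, n = 200) {
  resample_profile(generate_vessel(
    vessel_spec(length_mm = length_mm, r_in_mm = r_in, r_out_mm = r_out)), n)
}

stenosed_spec <- function(ds, width_mm = 2, centre = 0.5,
                          r_in = 1.35, r_out = 0.95) {
  vessel_spec(r_in_mm = r_in, r_out_mm = r_out,
              stenoses = data.frame(centre = centre, ds = ds,
                                    width_mm = width_mm))
}

# linear taper baseline matching vessel_spec smooth mode, in metres
taper_baseline <- function(profile, r_in = 1.35, r_out = 0.95) {
  (r_in + (r_out - r_in) * profile$s / profile$s[profile$n_points]) * 1e-3
}

# segmentation with a known healthy radius, bypassing the envelope fit so
# numerical tests are free of its data-dependent wiggle
manual_segmentation <- function(profile, r_healthy = profile$r,
                                mask = rep(FALSE, profile$n_points)) {
  structure(
    list(r_healthy = r_healthy, area_ratio = (profile$r / r_healthy)^2,
         stenosed_mask = mask,
         stenosis_intervals = vffr1d:::mask_to_intervals(mask)),
    class = "healthy_segmentation"
  )
}
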