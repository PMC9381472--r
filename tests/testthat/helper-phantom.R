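# Small desk-scale phantom used across the image-level tests: 32 x 32 x 16
# voxels at 2 mm keeps per-subject simulation in the tens of milliseconds.
test_phantom_config <- function(noise = 0.02, ...) {
  phantom_config(
    grid_shape = c(32, 32, 16), voxel_size = c(2, 2, 2),
    noise_sd_relative = noise,
    brain_center = c(16.5, 16.5, 8.5), brain_radii = c(14, 14, 7),
    left_center = c(10, 16, 8), left_radii = c(4, 3, 2.5),
    right_center = c(23, 16, 8), right_radii = c(4, 3, 2.5),
    csf_center = c(16.5, 16, 8), csf_radii = c(2, 2, 2),
    ...
  )
}

hc_row <- function() dplyr::filter(default_group_params(), group == "HC")

mrneg_rows <- function() {
  dplyr::filter(default_group_params(), grepl("^MRneg", group))
}
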