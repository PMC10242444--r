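#' Matched generator and quantification settings for cohort simulation
#'
#' The synthetic-cohort studies in this package run at a reduced
#' resolution (default 0.5 um/pixel, a 492 x 492 grid for the 246 um
#' field) so that hundreds of areas can be rendered and quantified on one
#' CPU. The DoG band-pass must track the pixel size: the small sigma sits
#' just under the rendered focus width and the large sigma well above it,
#' so that the band-pass leaves focus peaks intact while spreading the
#' compensating negative lobe thinly across the nucleus (a concentrated
#' negative lobe inflates the per-nucleus scale estimate and with it the
#' adaptive threshold). This helper returns an [image_sim_params()]
#' template and a matched [foci_params()] object.
#'
#' @param pixel_size_um Pixel pitch of the rendered cohort images.
#' @param n_z Number of z-slices per stack.
#' @param seed Optional seed stored in the image template.
#' @return List with `image_params` and `foci_params`.
#' @export
pipeline_defaults <- function(pixel_size_um = 0.5, n_z = 3, seed = NULL) {
  image_params <- image_sim_params(
    field_size_um = 246,
    pixel_size_um = pixel_size_um,
    n_z = n_z,
    nucleus_radius_um = c(5.5, 6.5),
    touching_pair_fraction = 0.08,
    stromal_fraction = 0.08,
    focus_sigma_um = c(0.35, 0.45),
    focus_min_spacing_um = 2.6,
    focus_amplitude = c(40000, 50000),
    seed = seed
  )
  fparams <- foci_params(
    median_radius_px = 2,
    dog_sigma_small_px = max(0.25 / pixel_size_um, 0.5),
    dog_sigma_large_px = 6 / pixel_size_um,
    min_focus_area_px = 1,
    max_focus_area_px = ceiling(500 * (0.24 / pixel_size_um)^2)
  )
  list(image_params = image_params, foci_params = fparams)
}
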