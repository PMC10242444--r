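# Shared synthetic-field builders for the image tests.

# Small full-resolution field: a handful of well-separated nuclei, most of
# them focus-free, with fixed planted counts. Used for exact-recovery
# checks (noiseless -> classical scale; noisy -> robust default).
recovery_field_params <- function(counts = c(0, 0, 0, 0, 0, 0, 1, 2, 3, 5),
                                  gaussian_sd = 0, seed = 42) {
  image_sim_params(
    field_size_um = 72, pixel_size_um = 0.24, n_z = 4,
    n_nuclei = length(counts), nucleus_radius_um = c(5, 6),
    touching_pair_fraction = 0, stromal_fraction = 0,
    foci_per_nucleus = list(kind = "fixed", counts = counts),
    focus_sigma_um = c(0.35, 0.45),
    focus_min_spacing_um = 3.0,
    focus_amplitude = c(24000, 30000),
    noise = list(gaussian_sd = gaussian_sd, poisson = FALSE),
    seed = seed
  )
}

# Match planted nuclei to retained segmentation labels by nearest
# centroid; returns the detected focus count per planted nucleus (NA when
# unmatched within max_dist pixels).
match_planted_counts <- function(ground_truth, quant, max_dist = 7) {
  info <- quant$mask$info[quant$mask$info$retained, ]
  vapply(seq_len(nrow(ground_truth)), function(i) {
    d <- sqrt((info$centroid_y - ground_truth$centroid_y_px[i])^2 +
                (info$centroid_x - ground_truth$centroid_x_px[i])^2)
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= max_dist) {
      quant$cells$foci_count[quant$cells$nucleus == info$label[j]]
    } else {
      NA_integer_
    }
  }, numeric(1))
}

# Minimal in-memory stack from explicit channel arrays.
manual_stack <- function(dapi, foci = NULL, pixel_size_um = 0.24) {
  if (is.null(foci)) foci <- array(0, dim = dim(dapi))
  structure(list(dapi = dapi, foci = foci, pixel_size_um = pixel_size_um),
            class = "irif_stack")
}
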