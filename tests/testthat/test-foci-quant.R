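# Nucleus segmentation, projection, DoG, adaptive detection, filtering,
# positivity.

test_that("blank DAPI yields an empty mask, not an error", {
  st <- manual_stack(array(0, dim = c(40, 40, 2)))
  m <- segment_nuclei(st)
  expect_equal(nrow(m$info), 0)
  expect_true(all(m$labels == 0))
})

test_that("a single synthetic disk segments to one label of the right area", {
  ny <- 101
  dapi <- array(0, dim = c(ny, ny, 2))
  yy <- row(matrix(0, ny, ny)); xx <- col(matrix(0, ny, ny))
  disk <- sqrt((yy - 51)^2 + (xx - 51)^2) <= 20
  for (z in 1:2) dapi[, , z][disk] <- 20000
  m <- segment_nuclei(manual_stack(dapi))
  expect_equal(sum(m$info$retained), 1)
  expect_lt(abs(m$info$area_px[1] - pi * 400) / (pi * 400), 0.05)
})

test_that("touching nuclei are split so label count matches planted count", {
  p <- image_sim_params(field_size_um = 60, pixel_size_um = 0.4, n_z = 2,
                        n_nuclei = 8, nucleus_radius_um = c(3.5, 4.5),
                        touching_pair_fraction = 0.25, stromal_fraction = 0,
                        foci_per_nucleus = list(kind = "fixed", counts = 0),
                        seed = 17)
  g <- generate_area_image(p)
  m <- segment_nuclei(g$stack)
  expect_equal(nrow(m$info), nrow(g$ground_truth))
})

test_that("foci projection is the per-pixel maximum across z", {
  a <- array(0, dim = c(5, 6, 3)); a[2, 3, 2] <- 7
  expect_equal(project_foci(list(foci = a))[2, 3], 7)
  expect_equal(sum(project_foci(list(foci = a)) != 0), 1)

  cst <- array(4.2, dim = c(4, 4, 5))
  expect_true(all(project_foci(list(foci = cst)) == 4.2))

  set.seed(2)
  r <- array(runif(6 * 7 * 4), dim = c(6, 7, 4))
  loopmax <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) loopmax[i, j] <- max(r[i, j, ])
  expect_equal(project_foci(list(foci = r)), loopmax)
})

test_that("DoG background subtraction behaves like a band-pass", {
  fp <- foci_params()
  cst <- matrix(500, 64, 64)
  expect_lt(max(abs(subtract_background(cst, fp))), 1e-6)

  imp <- matrix(0, 64, 64); imp[32, 32] <- 1000
  expect_gt(subtract_background(imp, fp)[32, 32], 0)

  # narrow blob responds more than a broad blob of equal height
  yy <- row(matrix(0, 64, 64)); xx <- col(matrix(0, 64, 64))
  narrow <- 1000 * exp(-((yy - 32)^2 + (xx - 32)^2) /
                         (2 * fp$dog_sigma_small_px^2))
  broad <- 1000 * exp(-((yy - 32)^2 + (xx - 32)^2) /
                        (2 * (3 * fp$dog_sigma_large_px)^2))
  expect_gt(max(subtract_background(narrow, fp)),
            max(subtract_background(broad, fp)))

  expect_error(foci_params(dog_sigma_small_px = 6, dog_sigma_large_px = 2),
               "dog_sigma")
})

test_that("uniform signal inside nuclei is degenerate: zero foci, warning", {
  lab <- matrix(0L, 30, 30)
  lab[5:12, 5:12] <- 1L; lab[18:25, 18:25] <- 2L
  mask <- structure(list(labels = lab,
                         info = data.frame(label = 1:2, area_px = 64,
                                           centroid_y = c(8.5, 21.5),
                                           centroid_x = c(8.5, 21.5),
                                           on_border = FALSE,
                                           retained = TRUE)),
                    class = "nucleus_mask")
  bg <- matrix(5, 30, 30)
  for (sdm in c("robust", "classical", "pooled")) {
    expect_warning(calls <- detect_foci(bg, mask, foci_params(sd_method = sdm)),
                   "degenerate")
    expect_equal(nrow(calls), 0)
  }
})

test_that("an absurdly large detection factor suppresses all foci", {
  g <- generate_area_image(recovery_field_params(gaussian_sd = 60, seed = 3))
  q <- quantify_stack(g$stack, foci_params(detection_factor = 1e6))
  expect_true(all(q$cells$foci_count == 0))
})

test_that("noiseless fields are recovered exactly (classical scale)", {
  counts <- c(0, 0, 0, 0, 0, 0, 1, 2, 3, 5)
  g <- generate_area_image(recovery_field_params(counts, gaussian_sd = 0))
  q <- quantify_stack(g$stack, foci_params(sd_method = "classical",
                                           min_focus_area_px = 4))
  det <- match_planted_counts(g$ground_truth, q)
  expect_equal(det, counts)
})

test_that("noisy fields are recovered exactly with the robust default", {
  counts <- c(0, 0, 0, 0, 0, 0, 1, 2, 3, 5)
  g <- generate_area_image(recovery_field_params(counts, gaussian_sd = 60))
  q <- quantify_stack(g$stack, foci_params())
  det <- match_planted_counts(g$ground_truth, q)
  expect_equal(det, counts)
})

test_that("call filtering keeps inclusive bounds and drops dim calls", {
  fp <- foci_params(min_focus_area_px = 3, max_focus_area_px = 10,
                    min_peak_intensity = 100)
  empty <- data.frame(focus_id = integer(0), nucleus = integer(0),
                      area_px = integer(0), peak = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0))
  expect_equal(nrow(filter_calls(empty, fp)), 0)

  calls <- data.frame(focus_id = 1:4, nucleus = 1L,
                      area_px = c(3, 10, 2, 5),
                      peak = c(100, 500, 500, 50),
                      centroid_y = 1, centroid_x = 1)
  kept <- filter_calls(calls, fp)
  # area bounds inclusive; undersized and dim calls removed
  expect_equal(kept$focus_id, c(1L, 2L))
})

test_that("positivity is inclusive at the cutoff", {
  mask <- structure(list(labels = matrix(0L, 2, 2),
                         info = data.frame(label = 1:3, area_px = 50,
                                           centroid_y = 1, centroid_x = 1,
                                           on_border = FALSE,
                                           retained = TRUE)),
                    class = "nucleus_mask")
  calls <- data.frame(nucleus = c(rep(2L, 5), rep(3L, 6)))
  rec <- count_and_classify(calls, mask, foci_params())
  expect_equal(rec$foci_count, c(0L, 5L, 6L))
  expect_equal(rec$positive, c(FALSE, TRUE, TRUE))

  rec4 <- count_and_classify(data.frame(nucleus = rep(1:3, each = 4)),
                             mask, foci_params())
  expect_equal(mean(rec4$positive), 0)

  none <- structure(list(labels = matrix(0L, 2, 2),
                         info = data.frame(label = integer(0),
                                           area_px = numeric(0),
                                           centroid_y = numeric(0),
                                           centroid_x = numeric(0),
                                           on_border = logical(0),
                                           retained = logical(0))),
                    class = "nucleus_mask")
  expect_equal(nrow(count_and_classify(calls, none, foci_params())), 0)
})

test_that("detected foci are monotone in threshold-tightening parameters", {
  g <- generate_area_image(recovery_field_params(
    counts = c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5), gaussian_sd = 60, seed = 9))
  mask <- segment_nuclei(g$stack)
  raw <- subtract_background(project_foci(g$stack), foci_params(),
                             clamp = FALSE)
  bg <- pmax(raw, 0)
  n_at <- function(k) nrow(detect_foci(bg, mask,
                                       foci_params(detection_factor = k),
                                       bg_raw = raw))
  ks <- c(5, 15, 25, 60, 200)
  expect_true(all(diff(sapply(ks, n_at)) <= 0))

  calls <- detect_foci(bg, mask, foci_params(), bg_raw = raw)
  n_filtered <- function(min_area, min_peak) {
    nrow(filter_calls(calls, foci_params(min_focus_area_px = min_area,
                                         min_peak_intensity = min_peak)))
  }
  expect_true(all(diff(sapply(c(1, 3, 6, 12), n_filtered,
                              min_peak = 0)) <= 0))
  expect_true(all(diff(sapply(c(0, 500, 2000, 1e5), n_filtered,
                              min_area = 1)) <= 0))
})

test_that("every focus belongs to exactly one nucleus, never background", {
  g <- generate_area_image(recovery_field_params(
    counts = c(1, 2, 3, 0, 0, 0, 4, 5, 2, 3), gaussian_sd = 60, seed = 10))
  q <- quantify_stack(g$stack)
  for (i in seq_len(nrow(q$calls))) {
    labs <- q$mask$labels[q$calls$pixels[[i]]]
    expect_true(all(labs == q$calls$nucleus[i]))
  }
})

test_that("quantification is deterministic for identical inputs", {
  g <- generate_area_image(recovery_field_params(gaussian_sd = 60, seed = 12))
  q1 <- quantify_stack(g$stack)
  q2 <- quantify_stack(g$stack)
  expect_identical(q1$cells, q2$cells)
})

test_that("stacks written to TIFF round-trip exactly through quantification", {
  g <- generate_area_image(recovery_field_params(gaussian_sd = 60, seed = 13))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_area_stack(g$stack, tif)
  st <- read_area_stack(tif)
  # intensities are integer-valued a.u. on a 16-bit range: exact round trip
  expect_equal(st$dapi, round(g$stack$dapi))
  expect_identical(quantify_stack(st)$cells,
                   quantify_stack(manual_stack(round(g$stack$dapi),
                                               round(g$stack$foci)))$cells)
})
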