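#' Parameters of the foci-quantification pipeline
#'
#' Controls nucleus segmentation, difference-of-Gaussians (DoG) background
#' subtraction, the adaptive detection threshold, the size/brightness
#' filters and the per-cell positivity cutoff.
#'
#' The detection threshold is adaptive: foci candidates are pixels of the
#' background-subtracted projection exceeding `detection_factor` times the
#' median over nuclei of the per-nucleus standard deviation of that image
#' (the factor is typically 25). Nucleus-area gates default to an adaptive
#' rule (`NULL`): minimum 50% and maximum 300% of the median nucleus area
#' in the image, which removes small stromal nuclei and large fusions
#' without a resolution-dependent constant.
#'
#' @param median_radius_px Radius of the median filter applied to the DAPI
#'   projection before thresholding.
#' @param dog_sigma_small_px,dog_sigma_large_px Gaussian widths of the DoG
#'   band-pass (small < large).
#' @param detection_factor Multiplier `k` of the median per-nucleus SD
#'   defining the foci threshold (default 25).
#' @param min_focus_area_px,max_focus_area_px Inclusive focus-size gate in
#'   pixels.
#' @param min_nucleus_area_px,max_nucleus_area_px Inclusive nucleus-area
#'   gate in pixels; `NULL` means adaptive (see Details).
#' @param min_peak_intensity Absolute-brightness filter on the focus peak
#'   in the background-subtracted image (0 disables it).
#' @param positivity_cutoff A cell is IRIF-positive when its filtered focus
#'   count is `>= positivity_cutoff` (default 5, inclusive).
#' @param sd_method How the per-nucleus scale entering the adaptive
#'   threshold is estimated: `"robust"` (default; 1.4826 x median absolute
#'   deviation, which tracks the background fluctuation inside a nucleus
#'   even when a large pixel fraction belongs to foci), `"classical"`
#'   (plain standard deviation of all pixels in the nucleus; inflated by
#'   bright foci, appropriate for sparse fields), or `"pooled"` (single SD
#'   of the pooled pixels of all retained nuclei).
#' @param watershed_tolerance Minimum object-height separation in the
#'   distance-transform watershed used to split touching nuclei.
#'
#' @return An object of class `foci_params`.
#' @export
foci_params <- function(median_radius_px = 2,
                        dog_sigma_small_px = 1.5,
                        dog_sigma_large_px = 6,
                        detection_factor = 25,
                        min_focus_area_px = 1,
                        max_focus_area_px = 500,
                        min_nucleus_area_px = NULL,
                        max_nucleus_area_px = NULL,
                        min_peak_intensity = 0,
                        positivity_cutoff = 5,
                        sd_method = c("robust", "classical", "pooled"),
                        watershed_tolerance = 1) {
  sd_method <- match.arg(sd_method)
  if (dog_sigma_small_px >= dog_sigma_large_px) {
    stop("dog_sigma_small_px must be < dog_sigma_large_px", call. = FALSE)
  }
  stopifnot_scalar_number(detection_factor, "detection_factor", min = 1e-12)
  if (min_focus_area_px > max_focus_area_px) {
    stop("min_focus_area_px must be <= max_focus_area_px", call. = FALSE)
  }
  if (!is.null(min_nucleus_area_px) && !is.null(max_nucleus_area_px) &&
      min_nucleus_area_px > max_nucleus_area_px) {
    stop("min_nucleus_area_px must be <= max_nucleus_area_px", call. = FALSE)
  }
  stopifnot_scalar_number(positivity_cutoff, "positivity_cutoff", min = 1)
  structure(list(median_radius_px = median_radius_px,
                 dog_sigma_small_px = dog_sigma_small_px,
                 dog_sigma_large_px = dog_sigma_large_px,
                 detection_factor = detection_factor,
                 min_focus_area_px = min_focus_area_px,
                 max_focus_area_px = max_focus_area_px,
                 min_nucleus_area_px = min_nucleus_area_px,
                 max_nucleus_area_px = max_nucleus_area_px,
                 min_peak_intensity = min_peak_intensity,
                 positivity_cutoff = positivity_cutoff,
                 sd_method = sd_method,
                 watershed_tolerance = watershed_tolerance),
            class = "foci_params")
}

#' Segment nuclei from the DAPI channel
#'
#' Computes the maximum-intensity projection of the DAPI channel, median-
#' filters it, thresholds it (Otsu), and splits touching nuclei by a
#' watershed on the distance transform. Labels whose area falls outside
#' the nucleus-area gate or that touch the image border are flagged and
#' excluded from downstream counting (but kept in the label image).
#'
#' @param stack An `irif_stack` (see [generate_area_image()]) or a list
#'   with a `dapi` ny x nx x nz array.
#' @param params A [foci_params()] object.
#'
#' @return An object of class `nucleus_mask`: list with `labels` (integer
#'   matrix, 0 background, 1..N nuclei, labels contiguous) and `info`
#'   (data.frame: `label`, `area_px`, `centroid_y`, `centroid_x`,
#'   `on_border`, `retained`).
#' @export
segment_nuclei <- function(stack, params = foci_params()) {
  dapi <- stack$dapi
  if (is.null(dapi) || length(dim(dapi)) != 3L) {
    stop("stack$dapi must be an ny x nx x nz array", call. = FALSE)
  }
  proj <- max_project(dapi)
  ny <- nrow(proj); nx <- ncol(proj)
  empty <- structure(list(labels = matrix(0L, ny, nx),
                          info = data.frame(label = integer(0),
                                            area_px = numeric(0),
                                            centroid_y = numeric(0),
                                            centroid_x = numeric(0),
                                            on_border = logical(0),
                                            retained = logical(0))),
                     class = "nucleus_mask")
  mx <- max(proj)
  if (mx <= 0) return(empty)
  nproj <- proj / mx
  if (params$median_radius_px >= 1) {
    nproj <- EBImage::medianFilter(nproj, round(params$median_radius_px))
  }
  th <- EBImage::otsu(EBImage::Image(nproj))
  bin <- nproj > th
  if (!any(bin)) return(empty)
  bin <- EBImage::fillHull(bin)
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = 1)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L) return(empty)

  area <- tabulate(lab[lab > 0L], nbins = n)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  yy <- ((idx - 1L) %% ny) + 1L
  xx <- ((idx - 1L) %/% ny) + 1L
  cy <- rowsum(as.numeric(yy), lv)[, 1] / area
  cx <- rowsum(as.numeric(xx), lv)[, 1] / area
  border <- yy == 1L | yy == ny | xx == 1L | xx == nx
  on_border <- as.logical(rowsum(as.numeric(border), lv)[, 1] > 0)

  min_a <- params$min_nucleus_area_px
  max_a <- params$max_nucleus_area_px
  med_a <- median(area)
  if (is.null(min_a)) min_a <- 0.5 * med_a
  if (is.null(max_a)) max_a <- 3.0 * med_a
  retained <- area >= min_a & area <= max_a & !on_border

  structure(list(labels = lab,
                 info = data.frame(label = seq_len(n), area_px = area,
                                   centroid_y = cy, centroid_x = cx,
                                   on_border = on_border,
                                   retained = retained)),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d label(s), %d retained\n",
              nrow(x$info), sum(x$info$retained)))
  invisible(x)
}

#' Maximum-intensity projection of the foci channel
#'
#' @param stack An `irif_stack` or a list with a `foci` ny x nx x nz array.
#' @return A 2-D matrix: element-wise maximum across z.
#' @export
project_foci <- function(stack) {
  f <- stack$foci
  if (is.null(f) || length(dim(f)) != 3L || dim(f)[3] < 1L) {
    stop("stack$foci must be an ny x nx x nz array with nz >= 1",
         call. = FALSE)
  }
  max_project(f)
}

#' Difference-of-Gaussians background subtraction
#'
#' Band-pass filters a projected foci image: `G(sigma_small) * img -
#' G(sigma_large) * img`, with negative values clamped to 0 (the detection
#' statistic is one-sided: foci exceed the local background).
#'
#' @param img 2-D intensity matrix.
#' @param params A [foci_params()] object (uses the two DoG sigmas).
#' @param clamp Clamp negative band-pass values to 0 (default TRUE; the
#'   unclamped image is useful for noise-scale estimation).
#' @return A 2-D matrix of the same shape (non-negative when clamped).
#' @export
subtract_background <- function(img, params = foci_params(), clamp = TRUE) {
  stopifnot(is.matrix(img))
  small <- EBImage::gblur(img, sigma = params$dog_sigma_small_px,
                          boundary = "replicate")
  large <- EBImage::gblur(img, sigma = params$dog_sigma_large_px,
                          boundary = "replicate")
  out <- small - large
  if (clamp) out[out < 0] <- 0
  out
}

#' Detect foci candidates with an adaptive per-image threshold
#'
#' For every retained nucleus the standard deviation of the background-
#' subtracted pixel values within that nucleus is computed; the detection
#' threshold is `detection_factor` times the median of these per-nucleus
#' SDs. Foci candidates are the 8-connected components of above-threshold
#' pixels within each nucleus.
#'
#' @param bg Background-subtracted 2-D image (see [subtract_background()]).
#' @param mask A `nucleus_mask` from [segment_nuclei()].
#' @param params A [foci_params()] object.
#' @param bg_raw Optional unclamped band-pass image
#'   (`subtract_background(..., clamp = FALSE)`); when supplied, the
#'   robust scale estimate uses it (the zero-clamped image degrades the
#'   MAD because half the background mass sits at exactly 0). Ignored by
#'   the classical and pooled estimators.
#'
#' @return A data.frame of focus calls: `focus_id`, `nucleus`, `area_px`,
#'   `peak`, `centroid_y`, `centroid_x`, and a `pixels` list-column of
#'   linear pixel indices. Zero rows when no nucleus is retained or the
#'   image is degenerate (all-flat: median SD of 0 raises a warning).
#' @export
detect_foci <- function(bg, mask, params = foci_params(), bg_raw = NULL) {
  stopifnot(is.matrix(bg))
  lab <- mask$labels
  if (!all(dim(lab) == dim(bg))) {
    stop("mask and bg must share shape", call. = FALSE)
  }
  empty <- data.frame(focus_id = integer(0), nucleus = integer(0),
                      area_px = integer(0), peak = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0))
  empty$pixels <- list()
  retained <- mask$info$label[mask$info$retained]
  if (length(retained) == 0L) return(empty)

  inside <- lab > 0L & matrix(lab %in% retained, nrow(lab), ncol(lab))
  idx_in <- which(inside)
  lv <- lab[idx_in]
  v <- bg[idx_in]
  if (params$sd_method == "pooled") {
    sigma_med <- sd(v)
  } else if (params$sd_method == "classical") {
    n_i <- tabulate(lv)
    s_i <- rowsum(v, lv)
    s2_i <- rowsum(v^2, lv)
    labs_present <- sort(unique(lv))
    n_l <- n_i[labs_present]
    var_l <- (s2_i[, 1] - s_i[, 1]^2 / n_l) / pmax(n_l - 1, 1)
    sigma_med <- median(sqrt(pmax(var_l, 0)))
  } else {
    if (!is.null(bg_raw)) {
      vr <- bg_raw[idx_in]
      sds <- vapply(split(vr, lv), function(px) stats::mad(px), numeric(1))
    } else {
      # clamped image: half the background mass sits at exactly 0, so a
      # spread-based quantile estimate replaces the MAD (for N(0, s)
      # clamped at 0, q75 - q25 = 0.6745 s; a constant image gives 0)
      sds <- vapply(split(v, lv), function(px) {
        q <- quantile(px, c(0.25, 0.75), names = FALSE)
        (q[2] - q[1]) / 0.6745
      }, numeric(1))
    }
    sigma_med <- median(sds)
  }
  if (!is.finite(sigma_med) || sigma_med <= 0) {
    warning("degenerate image: median per-nucleus SD is 0; no foci called")
    return(empty)
  }
  threshold <- params$detection_factor * sigma_med

  cand <- idx_in[v > threshold]
  if (length(cand) == 0L) return(empty)
  grp <- lab[cand]
  comp <- label_components_8(cand, grp, nrow(bg), ncol(bg))
  key <- comp  # components already nucleus-exclusive (grouped labeling)
  ny <- nrow(bg)
  vals <- bg[cand]
  yy <- ((cand - 1L) %% ny) + 1L
  xx <- ((cand - 1L) %/% ny) + 1L
  o <- order(key)
  splits <- split(seq_along(cand)[o], key[o])
  out <- data.frame(
    focus_id = seq_along(splits),
    nucleus = vapply(splits, function(s) grp[s[1]], integer(1)),
    area_px = vapply(splits, length, integer(1)),
    peak = vapply(splits, function(s) max(vals[s]), numeric(1)),
    centroid_y = vapply(splits, function(s) mean(yy[s]), numeric(1)),
    centroid_x = vapply(splits, function(s) mean(xx[s]), numeric(1))
  )
  out$pixels <- lapply(splits, function(s) cand[s])
  rownames(out) <- NULL
  out
}

#' Filter focus calls by size and absolute brightness
#'
#' Keeps calls with `min_focus_area_px <= area_px <= max_focus_area_px`
#' (inclusive bounds) and `peak >= min_peak_intensity`. Nuclei outside the
#' nucleus-area gate were already excluded in [segment_nuclei()].
#'
#' @param calls Focus-call data.frame from [detect_foci()].
#' @param params A [foci_params()] object.
#' @return The filtered data.frame.
#' @export
filter_calls <- function(calls, params = foci_params()) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$area_px >= params$min_focus_area_px &
    calls$area_px <= params$max_focus_area_px &
    calls$peak >= params$min_peak_intensity
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count foci per nucleus and call per-cell positivity
#'
#' One record per retained nucleus; a cell is positive when its filtered
#' focus count reaches the positivity cutoff (default >= 5 foci/nucleus,
#' inclusive).
#'
#' @param calls Filtered focus calls (see [filter_calls()]).
#' @param mask A `nucleus_mask` from [segment_nuclei()].
#' @param params A [foci_params()] object.
#' @return A data.frame of cell records: `nucleus`, `area_px`,
#'   `foci_count`, `positive`.
#' @export
count_and_classify <- function(calls, mask, params = foci_params()) {
  info <- mask$info[mask$info$retained, , drop = FALSE]
  if (nrow(info) == 0L) {
    return(data.frame(nucleus = integer(0), area_px = numeric(0),
                      foci_count = integer(0), positive = logical(0)))
  }
  cnt <- if (nrow(calls) > 0L) {
    tab <- table(factor(calls$nucleus, levels = info$label))
    as.integer(tab)
  } else {
    integer(nrow(info))
  }
  data.frame(nucleus = info$label, area_px = info$area_px,
             foci_count = cnt,
             positive = cnt >= params$positivity_cutoff)
}

#' Quantify one image stack end to end
#'
#' Runs segmentation, projection, background subtraction, detection,
#' filtering and positivity calling on a two-channel stack.
#'
#' @param stack An `irif_stack`.
#' @param params A [foci_params()] object.
#' @return A list with `mask` (nucleus_mask), `calls` (filtered focus
#'   calls) and `cells` (cell records).
#' @export
quantify_stack <- function(stack, params = foci_params()) {
  mask <- segment_nuclei(stack, params)
  raw <- subtract_background(project_foci(stack), params, clamp = FALSE)
  bg <- pmax(raw, 0)
  calls <- filter_calls(detect_foci(bg, mask, params, bg_raw = raw), params)
  cells <- count_and_classify(calls, mask, params)
  list(mask = mask, calls = calls, cells = cells)
}
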