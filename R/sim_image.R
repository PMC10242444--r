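#' Parameters for the synthetic microscopy-field generator
#'
#' Bundles all tunables of [generate_area_image()]. Defaults emulate the
#' in situ IRIF assay geometry: square fields of 246 x 246 um imaged as
#' short confocal stacks (~6 z-slices) containing on the order of
#' 100-200 nuclei per area. Intensities are arbitrary units on a 16-bit
#' range; there is no camera model because the downstream pipeline is
#' ratio/threshold based.
#'
#' @param field_size_um Side length of the square field in micrometers.
#' @param pixel_size_um Pixel pitch in micrometers; `field_size_um /
#'   pixel_size_um` must be an integer.
#' @param n_z Number of z-slices (>= 1).
#' @param n_nuclei Number of nuclei to plant: a scalar, or a length-2 range
#'   from which a count is drawn uniformly.
#' @param nucleus_radius_um Range of tumor-nucleus radii (um).
#' @param touching_pair_fraction Fraction of nuclei planted as touching
#'   pairs (overlapping ellipses), to exercise watershed splitting.
#' @param stromal_fraction Fraction of nuclei planted as small stromal
#'   nuclei, at under 50% of the median tumor-nucleus area so that the
#'   nucleus-size filter has a separable target.
#' @param foci_per_nucleus Distribution of planted foci counts per
#'   non-stromal nucleus. One of `list(kind = "fixed", counts = ...)`
#'   (a scalar or one count per non-stromal nucleus),
#'   `list(kind = "poisson", lambda = ...)`, or a two-component mixture
#'   `list(kind = "mixture", lambda = c(l1, l2), prob = p)` where `prob`
#'   is the probability of the first (e.g. HR-restored) component.
#' @param focus_sigma_um Range of focus Gaussian widths (um).
#' @param focus_amplitude Range of focus peak amplitudes (a.u.).
#' @param focus_min_spacing_um Minimum center-to-center spacing imposed
#'   (best effort) between planted foci inside a nucleus.
#' @param dapi_amplitude Range of per-nucleus DAPI plateau intensities.
#' @param background List with `offset` (additive floor, a.u.) and
#'   `gradient` (peak-to-peak amplitude of a linear gradient across the
#'   field in a random direction, a.u.).
#' @param noise List with `gaussian_sd` (additive Gaussian noise, a.u.)
#'   and `poisson` (logical; apply Poisson resampling of intensities).
#' @param touch_margin Fractional center-distance deficit for touching
#'   pairs: centers are planted at `(r1 + r2) * (1 - touch_margin)`.
#' @param seed Integer seed; identical seeds give bit-identical fields.
#'
#' @return An object of class `image_sim_params` (a validated list).
#' @seealso [generate_area_image()]
#' @export
image_sim_params <- function(field_size_um = 246,
                             pixel_size_um = 0.24,
                             n_z = 6,
                             n_nuclei = c(100, 200),
                             nucleus_radius_um = c(3.5, 5.5),
                             touching_pair_fraction = 0.1,
                             stromal_fraction = 0.1,
                             foci_per_nucleus = list(kind = "poisson",
                                                     lambda = 1),
                             focus_sigma_um = c(0.25, 0.35),
                             focus_amplitude = c(15000, 30000),
                             focus_min_spacing_um = 1.0,
                             dapi_amplitude = c(12000, 25000),
                             background = list(offset = 300, gradient = 200),
                             noise = list(gaussian_sd = 60, poisson = FALSE),
                             touch_margin = 0.15,
                             seed = NULL) {
  stopifnot_scalar_number(field_size_um, "field_size_um", min = 1e-6)
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  stopifnot_scalar_number(n_z, "n_z", min = 1)
  stopifnot_fraction(touching_pair_fraction, "touching_pair_fraction")
  stopifnot_fraction(stromal_fraction, "stromal_fraction")
  stopifnot_fraction(touch_margin, "touch_margin")
  n_px <- field_size_um / pixel_size_um
  if (abs(n_px - round(n_px)) > 1e-8) {
    stop("field_size_um / pixel_size_um must yield an integer pixel grid",
         call. = FALSE)
  }
  if (any(n_nuclei < 0)) stop("n_nuclei must be >= 0", call. = FALSE)
  if (!is.list(foci_per_nucleus) || is.null(foci_per_nucleus$kind) ||
      !foci_per_nucleus$kind %in% c("fixed", "poisson", "mixture")) {
    stop("foci_per_nucleus must be a list with kind 'fixed', 'poisson' or ",
         "'mixture'", call. = FALSE)
  }
  max_r_px <- max(nucleus_radius_um) / pixel_size_um
  if (2 * max_r_px + 4 > round(n_px)) {
    stop("nucleus larger than field", call. = FALSE)
  }
  structure(list(field_size_um = field_size_um,
                 pixel_size_um = pixel_size_um,
                 n_z = as.integer(round(n_z)),
                 n_nuclei = n_nuclei,
                 nucleus_radius_um = nucleus_radius_um,
                 touching_pair_fraction = touching_pair_fraction,
                 stromal_fraction = stromal_fraction,
                 foci_per_nucleus = foci_per_nucleus,
                 focus_sigma_um = focus_sigma_um,
                 focus_amplitude = focus_amplitude,
                 focus_min_spacing_um = focus_min_spacing_um,
                 dapi_amplitude = dapi_amplitude,
                 background = background,
                 noise = noise,
                 touch_margin = touch_margin,
                 seed = seed),
            class = "image_sim_params")
}

#' Generate one synthetic two-channel image stack with ground truth
#'
#' Plants elliptical nuclei (including touching pairs and undersized
#' stromal nuclei) in the DAPI channel and, inside each non-stromal
#' nucleus, exactly the planted number of Gaussian foci in the foci
#' channel, distributed across z. Adds a linear background gradient and
#' noise. Deterministic given `params$seed`.
#'
#' @param params An [image_sim_params()] object.
#'
#' @return A list with components
#'   \describe{
#'     \item{stack}{an `irif_stack`: list with `dapi` and `foci`
#'       (ny x nx x nz arrays, a.u. on a 16-bit range) and
#'       `pixel_size_um`.}
#'     \item{ground_truth}{a data.frame with one row per planted nucleus
#'       (`nucleus_id`, `centroid_y_px`, `centroid_x_px`, `area_px`,
#'       `is_stromal`, `true_foci_count`), with the planted focus
#'       positions in `attr(, "foci")` and the label image of planted
#'       nuclei in `attr(, "labels")`.}
#'   }
#' @examples
#' p <- image_sim_params(field_size_um = 24, pixel_size_um = 0.5, n_z = 2,
#'                       n_nuclei = 3, nucleus_radius_um = c(2, 3),
#'                       touching_pair_fraction = 0, stromal_fraction = 0,
#'                       foci_per_nucleus = list(kind = "fixed",
#'                                               counts = c(0, 3, 7)),
#'                       seed = 1)
#' g <- generate_area_image(p)
#' g$ground_truth$true_foci_count
#' @export
generate_area_image <- function(params) {
  if (!inherits(params, "image_sim_params")) {
    stop("params must be created with image_sim_params()", call. = FALSE)
  }
  with_seed(params$seed, generate_area_image_impl(params))
}

generate_area_image_impl <- function(p) {
  n_px <- as.integer(round(p$field_size_um / p$pixel_size_um))
  nz <- p$n_z
  dapi <- array(0, dim = c(n_px, n_px, nz))
  foci <- array(0, dim = c(n_px, n_px, nz))
  labels <- matrix(0L, n_px, n_px)

  n_total <- if (length(p$n_nuclei) == 1L) {
    as.integer(round(p$n_nuclei))
  } else {
    as.integer(round(runif(1, min(p$n_nuclei), max(p$n_nuclei))))
  }

  gt <- data.frame(nucleus_id = integer(0), centroid_y_px = numeric(0),
                   centroid_x_px = numeric(0), area_px = numeric(0),
                   is_stromal = logical(0), true_foci_count = integer(0))
  foci_tab <- data.frame(nucleus_id = integer(0), y_px = numeric(0),
                         x_px = numeric(0), z = integer(0))

  if (n_total > 0L) {
    n_strom <- as.integer(round(p$stromal_fraction * n_total))
    n_tumor <- n_total - n_strom
    r_tumor <- draw_range(p$nucleus_radius_um, n_tumor) / p$pixel_size_um
    r_med <- if (n_tumor > 0) median(r_tumor) else
      mean(p$nucleus_radius_um) / p$pixel_size_um
    # stromal area < 50% of median tumor area by construction
    r_strom <- runif(n_strom, 0.40, 0.65) * r_med
    radii <- c(r_tumor, r_strom)
    is_stromal <- c(rep(FALSE, n_tumor), rep(TRUE, n_strom))
    ord <- sample.int(n_total)
    radii <- radii[ord]
    is_stromal <- is_stromal[ord]

    ecc <- runif(n_total, 0, 0.25)
    ax_a <- radii * (1 + ecc)
    ax_b <- radii * (1 - ecc)
    theta <- runif(n_total, 0, pi)

    n_pairs <- as.integer(round(p$touching_pair_fraction * n_total / 2))
    partner_of <- rep(NA_integer_, n_total)
    if (n_pairs > 0) {
      for (k in seq_len(n_pairs)) partner_of[2 * k] <- 2 * k - 1
    }

    cy <- numeric(n_total)
    cx <- numeric(n_total)
    for (i in seq_len(n_total)) {
      rmax_i <- max(ax_a[i], ax_b[i])
      placed <- FALSE
      for (attempt in seq_len(2000L)) {
        if (!is.na(partner_of[i])) {
          j <- partner_of[i]
          d <- (radii[i] + radii[j]) * (1 - p$touch_margin)
          ang <- runif(1, 0, 2 * pi)
          yy <- cy[j] + d * sin(ang)
          xx <- cx[j] + d * cos(ang)
        } else {
          yy <- runif(1, rmax_i + 2, n_px - rmax_i - 1)
          xx <- runif(1, rmax_i + 2, n_px - rmax_i - 1)
        }
        if (yy < rmax_i + 2 || yy > n_px - rmax_i - 1 ||
            xx < rmax_i + 2 || xx > n_px - rmax_i - 1) next
        prev <- seq_len(i - 1L)
        if (!is.na(partner_of[i])) prev <- setdiff(prev, partner_of[i])
        if (length(prev) > 0) {
          dd <- sqrt((cy[prev] - yy)^2 + (cx[prev] - xx)^2)
          lim <- radii[prev] + radii[i] + 1
          if (any(dd < lim)) next
        }
        cy[i] <- yy; cx[i] <- xx
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place nucleus ", i, ": field too crowded; reduce ",
             "n_nuclei or nucleus_radius_um", call. = FALSE)
      }
    }

    # foci counts per nucleus (stromal nuclei carry none)
    counts <- integer(n_total)
    non_strom <- which(!is_stromal)
    fp <- p$foci_per_nucleus
    if (fp$kind == "fixed") {
      cnt <- fp$counts
      if (length(cnt) == 1L) cnt <- rep(cnt, length(non_strom))
      if (length(cnt) != length(non_strom)) {
        stop("foci_per_nucleus$counts must have length 1 or one entry per ",
             "non-stromal nucleus (", length(non_strom), ")", call. = FALSE)
      }
      counts[non_strom] <- as.integer(cnt)
    } else if (fp$kind == "poisson") {
      counts[non_strom] <- rpois(length(non_strom), fp$lambda)
    } else {
      comp1 <- runif(length(non_strom)) < fp$prob
      lam <- ifelse(comp1, fp$lambda[1], fp$lambda[2])
      counts[non_strom] <- rpois(length(non_strom), lam)
    }
    if (any(counts < 0)) stop("true foci counts must be >= 0", call. = FALSE)

    # render nuclei (DAPI) and collect label image / areas
    area_px <- numeric(n_total)
    z0 <- runif(n_total, 1, nz)
    sz <- max(nz / 2.5, 0.8)
    zw <- outer(seq_len(nz), z0, function(z, z0) exp(-0.5 * ((z - z0) / sz)^2))
    zw <- sweep(zw, 2, apply(zw, 2, max), "/")  # per-nucleus max weight 1
    base <- draw_range(p$dapi_amplitude, n_total)
    for (i in seq_len(n_total)) {
      rmax_i <- max(ax_a[i], ax_b[i])
      y0 <- max(1L, floor(cy[i] - rmax_i - 1))
      y1 <- min(n_px, ceiling(cy[i] + rmax_i + 1))
      x0 <- max(1L, floor(cx[i] - rmax_i - 1))
      x1 <- min(n_px, ceiling(cx[i] + rmax_i + 1))
      ys <- y0:y1; xs <- x0:x1
      dy <- outer(ys - cy[i], rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx[i])
      u <- dy * cos(theta[i]) + dx * sin(theta[i])
      v <- -dy * sin(theta[i]) + dx * cos(theta[i])
      inside <- (u / ax_a[i])^2 + (v / ax_b[i])^2 <= 1
      area_px[i] <- sum(inside)
      sub <- labels[ys, xs]
      sub[inside] <- i
      labels[ys, xs] <- sub
      for (z in seq_len(nz)) {
        sl <- dapi[ys, xs, z]
        val <- base[i] * zw[z, i]
        sl[inside] <- pmax(sl[inside], val)
        dapi[ys, xs, z] <- sl
      }
    }

    # render foci inside their nucleus, spaced best-effort
    sig_px_range <- p$focus_sigma_um / p$pixel_size_um
    spacing_px <- p$focus_min_spacing_um / p$pixel_size_um
    for (i in seq_len(n_total)) {
      k <- counts[i]
      if (k == 0L) next
      sig <- draw_range(sig_px_range, k)
      amp <- draw_range(p$focus_amplitude, k)
      margin <- 2 * max(sig) + 1
      fy <- numeric(k); fx <- numeric(k)
      for (f in seq_len(k)) {
        ok <- FALSE
        for (attempt in seq_len(200L)) {
          # uniform in the inner ellipse (margin inset from the rim)
          rr <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
          u <- rr * max(ax_a[i] - margin, 0.3) * cos(ang)
          v <- rr * max(ax_b[i] - margin, 0.3) * sin(ang)
          yy <- cy[i] + u * cos(theta[i]) - v * sin(theta[i])
          xx <- cx[i] + u * sin(theta[i]) + v * cos(theta[i])
          if (f > 1L) {
            dd <- sqrt((fy[seq_len(f - 1L)] - yy)^2 +
                       (fx[seq_len(f - 1L)] - xx)^2)
            if (min(dd) < spacing_px && attempt < 200L) next
          }
          ok <- TRUE
          break
        }
        fy[f] <- yy; fx[f] <- xx
      }
      # each focus lives in one discrete slice (foci are small relative to
      # the slice spacing), so the max projection recovers its amplitude
      fz0 <- sample.int(nz, k, replace = TRUE)
      for (f in seq_len(k)) {
        ext <- ceiling(4 * sig[f])
        y0 <- max(1L, floor(fy[f] - ext)); y1 <- min(n_px, ceiling(fy[f] + ext))
        x0 <- max(1L, floor(fx[f] - ext)); x1 <- min(n_px, ceiling(fx[f] + ext))
        ys <- y0:y1; xs <- x0:x1
        g2 <- exp(-0.5 * (outer((ys - fy[f])^2, (xs - fx[f])^2, "+")) /
                    sig[f]^2)
        for (z in seq_len(nz)) {
          w <- exp(-0.5 * ((z - fz0[f]) / 0.7)^2)
          if (w < 0.01) next
          foci[ys, xs, z] <- foci[ys, xs, z] + amp[f] * w * g2
        }
      }
      foci_tab <- rbind(foci_tab,
                        data.frame(nucleus_id = i, y_px = fy, x_px = fx,
                                   z = as.integer(round(fz0))))
    }

    gt <- data.frame(nucleus_id = seq_len(n_total),
                     centroid_y_px = cy, centroid_x_px = cx,
                     area_px = area_px, is_stromal = is_stromal,
                     true_foci_count = counts)
  }

  # background gradient (random direction) + offset, both channels' floor
  ang <- runif(1, 0, 2 * pi)
  gy <- sin(ang); gx <- cos(ang)
  ramp <- outer(seq_len(n_px) / n_px * gy, rep(1, n_px)) +
    outer(rep(1, n_px), seq_len(n_px) / n_px * gx)
  ramp <- (ramp - min(ramp)) / max(diff(range(ramp)), 1e-12)
  bgimg <- p$background$offset + p$background$gradient * ramp
  for (z in seq_len(nz)) {
    foci[, , z] <- foci[, , z] + bgimg
    dapi[, , z] <- dapi[, , z] + 0.5 * bgimg
  }

  if (isTRUE(p$noise$poisson)) {
    dapi[] <- rpois(length(dapi), pmax(dapi, 0))
    foci[] <- rpois(length(foci), pmax(foci, 0))
  }
  if (p$noise$gaussian_sd > 0) {
    dapi <- dapi + rnorm(length(dapi), 0, p$noise$gaussian_sd)
    foci <- foci + rnorm(length(foci), 0, p$noise$gaussian_sd)
  }
  dapi <- pmin(pmax(dapi, 0), 65535)
  foci <- pmin(pmax(foci, 0), 65535)

  stack <- structure(list(dapi = dapi, foci = foci,
                          pixel_size_um = p$pixel_size_um),
                     class = "irif_stack")
  attr(gt, "foci") <- foci_tab
  attr(gt, "labels") <- labels
  list(stack = stack, ground_truth = gt)
}

#' True percent of IRIF-positive cells in a ground-truth table
#'
#' @param ground_truth Ground-truth table from [generate_area_image()].
#' @param cutoff Positivity cutoff on the true foci count (inclusive).
#' @param include_stromal Count stromal nuclei in the denominator?
#' @return Percentage in \[0, 100\] (NA if no eligible nuclei).
#' @export
true_percent_positive <- function(ground_truth, cutoff = 5,
                                  include_stromal = FALSE) {
  g <- ground_truth
  if (!include_stromal) g <- g[!g$is_stromal, , drop = FALSE]
  if (nrow(g) == 0) return(NA_real_)
  100 * mean(g$true_foci_count >= cutoff)
}

#' @export
print.irif_stack <- function(x, ...) {
  d <- dim(x$dapi)
  cat(sprintf("<irif_stack> %d x %d px, %d z-slice(s), pixel %.3g um\n",
              d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}
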