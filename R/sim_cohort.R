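#' Design of a synthetic IRIF cohort
#'
#' Describes a cohort of tumors from the mouse mammary tumor models used
#' in PARP-inhibitor resistance studies (KB1P = Brca1;p53-null, KB1PM =
#' additionally Mdr1a/b-null, KB2P = Brca2;p53-null, KP = p53-null
#' control), each imaged over several areas in an irradiated (IR) and a
#' non-irradiated (NIR) arm.
#'
#' Which tumors are planted as HR-restored is deterministic:
#' `round(restored_fraction * n_tumors)` tumors per group (the first ones
#' by index), so recovery tests are exact; set `bernoulli = TRUE` for
#' random assignment instead. Within a restored tumor a fraction
#' `restored_cell_fraction` of cells (default 0.6) draws its focus count
#' from the restored distribution; all other cells, and all cells of
#' deficient tumors, draw from the deficient distribution. NIR arms get
#' background-level foci.
#'
#' @param groups Data.frame with columns `model` (one of KB1P, KB1PM,
#'   KB2P, KP), `treatment` (`naive` or `resistant`), `n_tumors`, and
#'   `restored_fraction` (fraction of tumors planted HR-restored).
#' @param areas_per_tumor Imaged areas per tumor and arm (default 5).
#' @param arms Treatment arms to simulate (default IR and NIR).
#' @param cells_per_area Range (or scalar) of cells per area
#'   (default 100-200).
#' @param restored_cell_fraction Fraction of HR-restored cells within a
#'   restored tumor (default 0.6).
#' @param lambda_restored,lambda_deficient,lambda_nir Poisson means of the
#'   per-cell focus count for restored cells after IR, deficient cells
#'   after IR, and any cell without irradiation.
#' @param bernoulli Assign restored tumors by Bernoulli draws instead of
#'   deterministic counts (default FALSE).
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups,
                          areas_per_tumor = 5,
                          arms = c("IR", "NIR"),
                          cells_per_area = c(100, 200),
                          restored_cell_fraction = 0.6,
                          lambda_restored = 12,
                          lambda_deficient = 0.8,
                          lambda_nir = 0.3,
                          bernoulli = FALSE,
                          seed = NULL) {
  if (!is.data.frame(groups) || nrow(groups) == 0L) {
    stop("groups must be a non-empty data.frame", call. = FALSE)
  }
  req <- c("model", "treatment", "n_tumors", "restored_fraction")
  if (!all(req %in% names(groups))) {
    stop("groups needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(groups$model %in% c("KB1P", "KB1PM", "KB2P", "KP"))) {
    stop("model must be one of KB1P, KB1PM, KB2P, KP", call. = FALSE)
  }
  if (!all(groups$treatment %in% c("naive", "resistant"))) {
    stop("treatment must be 'naive' or 'resistant'", call. = FALSE)
  }
  if (any(groups$n_tumors < 1)) stop("n_tumors must be >= 1", call. = FALSE)
  if (any(groups$restored_fraction < 0 | groups$restored_fraction > 1)) {
    stop("restored_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(areas_per_tumor, "areas_per_tumor", min = 1)
  if (!all(arms %in% c("IR", "NIR")) || length(arms) < 1L) {
    stop("arms must be a subset of c('IR', 'NIR')", call. = FALSE)
  }
  stopifnot_fraction(restored_cell_fraction, "restored_cell_fraction")
  structure(list(groups = groups,
                 areas_per_tumor = as.integer(areas_per_tumor),
                 arms = arms,
                 cells_per_area = cells_per_area,
                 restored_cell_fraction = restored_cell_fraction,
                 lambda_restored = lambda_restored,
                 lambda_deficient = lambda_deficient,
                 lambda_nir = lambda_nir,
                 bernoulli = isTRUE(bernoulli),
                 seed = seed),
            class = "cohort_design")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-cell true focus counts for every tumor, arm and area of the
#' design. In `"counts"` mode this is the output; in `"images"` mode each
#' area is additionally rendered as a two-channel stack (see
#' [generate_area_image()]) and written to `out_dir` as multi-page TIFF
#' plus a YAML sidecar, or returned in memory when `out_dir` is NULL
#' (memory grows with cohort size; prefer [run_irif_pipeline()], which
#' renders and quantifies one area at a time).
#'
#' @param design A [cohort_design()].
#' @param mode `"counts"` (tables only) or `"images"`.
#' @param image_params An [image_sim_params()] template used for rendering
#'   (its `n_nuclei`, `foci_per_nucleus` and `seed` are overridden per
#'   area).
#' @param out_dir Directory for TIFF output in images mode (optional).
#' @return A list of class `irif_cohort_data`:
#'   \describe{
#'     \item{tumors}{data.frame `tumor`, `group`, `model`, `treatment`,
#'       `hr_truth` ("positive"/"negative").}
#'     \item{cells}{data.frame with one row per planted cell: `tumor`,
#'       `arm`, `area`, `nucleus`, `restored_cell`, `true_foci_count`.}
#'     \item{areas}{data.frame per area: `tumor`, `arm`, `area`,
#'       `n_cells`, `true_percent_positive` (at cutoff 5) and `area_seed`
#'       (the seed used to render that area).}
#'     \item{images}{images-mode only: list of per-area results or, with
#'       `out_dir`, a data.frame of file paths.}
#'   }
#' @export
generate_cohort <- function(design, mode = c("counts", "images"),
                            image_params = image_sim_params(),
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (!inherits(design, "cohort_design")) {
    stop("design must be created with cohort_design()", call. = FALSE)
  }
  out <- with_seed(design$seed, generate_cohort_tables(design))
  if (mode == "images") {
    imgs <- list()
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- data.frame(tumor = character(0), arm = character(0),
                          area = integer(0), tiff = character(0),
                          yaml = character(0))
    }
    for (i in seq_len(nrow(out$areas))) {
      a <- out$areas[i, ]
      g <- render_cohort_area(out$cells, a, image_params)
      if (is.null(out_dir)) {
        imgs[[paste(a$tumor, a$arm, a$area, sep = "_")]] <- g
      } else {
        base <- file.path(out_dir,
                          sprintf("%s_%s_area%02d", a$tumor, a$arm, a$area))
        write_area_stack(g$stack, paste0(base, ".tif"),
                         paste0(base, ".yml"))
        write_records(g$ground_truth, paste0(base, "_truth.tsv"))
        paths <- rbind(paths, data.frame(tumor = a$tumor, arm = a$arm,
                                         area = a$area,
                                         tiff = paste0(base, ".tif"),
                                         yaml = paste0(base, ".yml")))
      }
    }
    out$images <- if (is.null(out_dir)) imgs else paths
  }
  class(out) <- "irif_cohort_data"
  out
}

generate_cohort_tables <- function(d) {
  g <- d$groups
  tumors <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    n <- g$n_tumors[i]
    n_restored <- if (d$bernoulli) {
      sum(runif(n) < g$restored_fraction[i])
    } else {
      round(g$restored_fraction[i] * n)
    }
    data.frame(
      tumor = sprintf("%s_%s_%02d", g$model[i], g$treatment[i], seq_len(n)),
      group = paste(g$model[i], g$treatment[i], sep = "_"),
      model = g$model[i], treatment = g$treatment[i],
      hr_truth = c(rep("positive", n_restored),
                   rep("negative", n - n_restored))
    )
  }))
  rownames(tumors) <- NULL

  grid <- expand.grid(area = seq_len(d$areas_per_tumor), arm = d$arms,
                      tumor = tumors$tumor, stringsAsFactors = FALSE)
  grid <- grid[, c("tumor", "arm", "area")]
  grid <- grid[order(match(grid$tumor, tumors$tumor), grid$arm, grid$area), ]
  rownames(grid) <- NULL
  restored_tumor <- tumors$hr_truth[match(grid$tumor, tumors$tumor)] ==
    "positive"

  cells_list <- vector("list", nrow(grid))
  n_cells <- integer(nrow(grid))
  tpp <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nc <- as.integer(round(draw_range(d$cells_per_area)))
    n_cells[i] <- nc
    if (grid$arm[i] == "NIR") {
      restored_cell <- rep(FALSE, nc)
      lam <- rep(d$lambda_nir, nc)
    } else if (restored_tumor[i]) {
      restored_cell <- runif(nc) < d$restored_cell_fraction
      lam <- ifelse(restored_cell, d$lambda_restored, d$lambda_deficient)
    } else {
      restored_cell <- rep(FALSE, nc)
      lam <- rep(d$lambda_deficient, nc)
    }
    cnt <- rpois(nc, lam)
    tpp[i] <- 100 * mean(cnt >= 5)
    cells_list[[i]] <- data.frame(tumor = grid$tumor[i], arm = grid$arm[i],
                                  area = grid$area[i], nucleus = seq_len(nc),
                                  restored_cell = restored_cell,
                                  true_foci_count = cnt)
  }
  areas <- cbind(grid, n_cells = n_cells, true_percent_positive = tpp,
                 area_seed = sample.int(.Machine$integer.max - 1,
                                        nrow(grid)))
  list(tumors = tumors, cells = do.call(rbind, cells_list), areas = areas)
}

# Render one cohort area as an image stack: the planted per-cell counts of
# that area become the fixed foci_per_nucleus list; the total nucleus count
# is inflated so that the generator's stromal fraction yields exactly the
# planted number of non-stromal (tumor) cells.
render_cohort_area <- function(cells, area_row, template) {
  cc <- cells[cells$tumor == area_row$tumor & cells$arm == area_row$arm &
                cells$area == area_row$area, ]
  nc <- nrow(cc)
  sf <- template$stromal_fraction
  n_total <- nc
  repeat {
    if (n_total - round(sf * n_total) >= nc) break
    n_total <- n_total + 1L
  }
  p <- template
  p$n_nuclei <- n_total
  p$foci_per_nucleus <- list(kind = "fixed", counts = cc$true_foci_count)
  p$seed <- area_row$area_seed
  class(p) <- "image_sim_params"
  generate_area_image(p)
}

#' Run the full IRIF pipeline on a synthetic cohort
#'
#' Simulate -> quantify -> classify -> cohort table, one area at a time
#' (images are rendered, quantified and discarded, so memory stays flat).
#' With `quantify = FALSE` the per-area percent positive is computed
#' directly from the planted true counts (no imaging), which isolates the
#' classification stage.
#'
#' @param design A [cohort_design()].
#' @param image_params An [image_sim_params()] template for rendering.
#' @param fparams A [foci_params()] object for quantification.
#' @param rule A [classification_rule()].
#' @param quantify Render and quantify images (TRUE) or use true counts
#'   (FALSE).
#' @param verbose Print one progress line per tumor.
#' @return An object of class `irif_cohort`: list with `areas` (per-area
#'   summaries incl. ground truth), `tumors` (per-tumor status calls and
#'   truth), `table` (see [build_cohort_table()]), `fisher` (two-sided
#'   Fisher test across the first two groups, when >= 2 groups),
#'   `status_recovery_pct` (percent of tumors whose call matches the
#'   planted truth, mixed pooled with positive) and the `rule` used.
#' @export
run_irif_pipeline <- function(design,
                              image_params = image_sim_params(),
                              fparams = foci_params(),
                              rule = classification_rule(),
                              quantify = TRUE,
                              verbose = FALSE) {
  cohort <- generate_cohort(design, mode = "counts")
  areas <- cohort$areas
  res <- vector("list", nrow(areas))
  for (i in seq_len(nrow(areas))) {
    a <- areas[i, ]
    if (quantify) {
      g <- render_cohort_area(cohort$cells, a, image_params)
      q <- quantify_stack(g$stack, fparams)
      s <- summarize_area(q$cells, a$tumor, a$arm, a$area)
    } else {
      cc <- cohort$cells[cohort$cells$tumor == a$tumor &
                           cohort$cells$arm == a$arm &
                           cohort$cells$area == a$area, ]
      cells <- data.frame(positive =
                            cc$true_foci_count >= fparams$positivity_cutoff)
      s <- summarize_area(cells, a$tumor, a$arm, a$area)
    }
    s$true_percent_positive <- a$true_percent_positive
    res[[i]] <- s
    if (verbose && a$arm == tail(design$arms, 1) &&
        a$area == design$areas_per_tumor) {
      message(sprintf("quantified %s (%d/%d tumors)", a$tumor,
                      match(a$tumor, cohort$tumors$tumor),
                      nrow(cohort$tumors)))
    }
  }
  summaries <- do.call(rbind, res)

  tumors <- cohort$tumors
  tumors$status <- vapply(tumors$tumor, function(t) {
    s <- summaries[summaries$tumor == t, ]
    classify_tumor(s[s$arm == "IR", ],
                   s[s$arm == "NIR", ],
                   rule)
  }, character(1))
  tab <- build_cohort_table(tumors)

  called_pos <- tumors$status %in% c("positive", "mixed")
  truth_pos <- tumors$hr_truth == "positive"
  recovery <- 100 * mean(called_pos == truth_pos)

  fisher <- NULL
  if (nrow(tab$two_by_two) >= 2L) {
    fisher <- fisher_exact_2x2(tab$two_by_two[1:2, , drop = FALSE])
  }
  structure(list(areas = summaries, tumors = tumors, table = tab,
                 fisher = fisher, status_recovery_pct = recovery,
                 rule = rule, design = design),
            class = "irif_cohort")
}

#' @export
print.irif_cohort <- function(x, ...) {
  cat("<irif_cohort>", nrow(x$tumors), "tumors,",
      nrow(x$areas), "imaged areas\n")
  print(x$table$counts)
  if (!is.null(x$fisher)) {
    cat(sprintf("Fisher exact (two-sided), first two groups: p = %.3g\n",
                x$fisher$p_value))
  }
  cat(sprintf("planted-status recovery: %.1f%%\n", x$status_recovery_pct))
  invisible(x)
}

#' @export
summary.irif_cohort <- function(object, ...) {
  cat("HR-status calls by group:\n")
  print(object$table$counts)
  cat("\n2x2 (mixed pooled with positive):\n")
  print(object$table$two_by_two)
  if (!is.null(object$fisher)) print(object$fisher)
  cat(sprintf("\nplanted-status recovery: %.1f%%\n",
              object$status_recovery_pct))
  agg <- stats::aggregate(percent_positive ~ arm,
                          data = object$areas, FUN = mean)
  cat("mean percent positive by arm:\n")
  print(agg)
  invisible(object)
}
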