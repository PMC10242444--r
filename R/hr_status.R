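#' Tumor HR-status classification rule
#'
#' The per-tumor call (RAD51-IRIF positive / negative / mixed) is a
#' judgment call in routine practice; this rule makes it explicit and
#' reproducible. An irradiated (IR) area is "positive" when its percent of
#' IRIF-positive cells reaches `area_positive_cutoff_pct` and "negative"
#' when it is below `area_negative_cutoff_pct`; the dead zone between the
#' two cutoffs prevents flip-flopping. A tumor is:
#' \itemize{
#'   \item \strong{mixed} when at least one positive and one negative IR
#'     area coexist;
#'   \item \strong{positive} when at least `min_positive_areas` IR areas
#'     are positive and (when `require_ir_gt_nir`) the two-tailed
#'     Mann-Whitney U test of IR vs non-irradiated (NIR) area percentages
#'     has p < `alpha`;
#'   \item \strong{negative} otherwise;
#'   \item \strong{not_determined} when there are no usable IR areas.
#' }
#'
#' @param area_positive_cutoff_pct Percent-positive cutoff above which an
#'   area counts as positive (default 10).
#' @param area_negative_cutoff_pct Cutoff below which an area counts as
#'   negative (default 5; must be <= the positive cutoff).
#' @param min_positive_areas Minimum number of positive IR areas (default 1).
#' @param alpha Significance level of the IR-vs-NIR test (default 0.05).
#' @param require_ir_gt_nir Require the IR-vs-NIR Mann-Whitney test for a
#'   positive call (default TRUE); the irradiation contrast guards against
#'   constitutive foci.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(area_positive_cutoff_pct = 10,
                                area_negative_cutoff_pct = 5,
                                min_positive_areas = 1,
                                alpha = 0.05,
                                require_ir_gt_nir = TRUE) {
  if (area_negative_cutoff_pct > area_positive_cutoff_pct) {
    stop("area_negative_cutoff_pct must be <= area_positive_cutoff_pct",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(area_positive_cutoff_pct = area_positive_cutoff_pct,
                 area_negative_cutoff_pct = area_negative_cutoff_pct,
                 min_positive_areas = min_positive_areas,
                 alpha = alpha,
                 require_ir_gt_nir = isTRUE(require_ir_gt_nir)),
            class = "classification_rule")
}

#' Summarize one imaged area
#'
#' Aggregates cell records of a single imaged area into the per-area data
#' point used throughout the assay: the percentage of IRIF-positive cells
#' (typically 100-200 cells per area).
#'
#' @param cells Cell-record data.frame (needs a logical `positive` column;
#'   see [count_and_classify()]).
#' @param tumor,arm,area Identifiers carried into the summary; `arm` is
#'   `"IR"` or `"NIR"`.
#' @return A one-row data.frame: `tumor`, `arm`, `area`, `n_cells`,
#'   `percent_positive` (NA with a warning when there are no cells).
#' @export
summarize_area <- function(cells, tumor, arm = c("IR", "NIR"), area = 1L) {
  arm <- match.arg(arm)
  n <- nrow(cells)
  if (n == 0L) {
    warning(sprintf("tumor %s area %s (%s): no cells; area not determined",
                    tumor, area, arm))
    return(data.frame(tumor = tumor, arm = arm, area = area, n_cells = 0L,
                      percent_positive = NA_real_))
  }
  data.frame(tumor = tumor, arm = arm, area = area, n_cells = n,
             percent_positive = 100 * mean(cells$positive))
}

#' Classify one tumor's HR status from its area summaries
#'
#' @param ir,nir Area-summary data.frames (see [summarize_area()]) for the
#'   irradiated and non-irradiated arm of this tumor; `nir` may have zero
#'   rows only when the rule does not require the IR-vs-NIR contrast.
#' @param rule A [classification_rule()].
#' @return One of `"positive"`, `"negative"`, `"mixed"`,
#'   `"not_determined"`.
#' @export
classify_tumor <- function(ir, nir = NULL, rule = classification_rule()) {
  pct <- ir$percent_positive[!is.na(ir$percent_positive)]
  if (length(pct) == 0L) return("not_determined")
  n_pos <- sum(pct >= rule$area_positive_cutoff_pct)
  n_neg <- sum(pct < rule$area_negative_cutoff_pct)
  if (n_pos >= 1L && n_neg >= 1L) return("mixed")
  if (n_pos >= rule$min_positive_areas) {
    if (rule$require_ir_gt_nir) {
      nir_pct <- nir$percent_positive[!is.na(nir$percent_positive)]
      if (length(nir_pct) == 0L) {
        stop("NIR areas required when require_ir_gt_nir = TRUE",
             call. = FALSE)
      }
      if (mann_whitney_u(pct, nir_pct)$p_value < rule$alpha) {
        return("positive")
      }
      return("negative")
    }
    return("positive")
  }
  "negative"
}

#' Cohort contingency table of HR-status calls
#'
#' Counts each HR status per model group and derives the 2-column table
#' used for the cohort comparison, pooling mixed tumors with positive ones
#' (a tumor with any IRIF-positive area has demonstrated restored focus
#' formation). Tumors with undetermined status are excluded from the
#' 2-column table.
#'
#' @param tumors Data.frame with columns `tumor`, `group`, `status`.
#' @return A list with `counts` (group x status table over the statuses
#'   positive/negative/mixed/not_determined) and `two_by_two` (group x
#'   c(positive, negative) matrix with mixed pooled into positive).
#' @export
build_cohort_table <- function(tumors) {
  stopifnot(all(c("tumor", "group", "status") %in% names(tumors)))
  if (nrow(tumors) == 0L) stop("at least one tumor required", call. = FALSE)
  lev <- c("positive", "negative", "mixed", "not_determined")
  if (!all(tumors$status %in% lev)) {
    stop("unknown status value(s): ",
         paste(setdiff(tumors$status, lev), collapse = ", "), call. = FALSE)
  }
  counts <- table(group = tumors$group,
                  status = factor(tumors$status, levels = lev))
  two <- cbind(positive = counts[, "positive"] + counts[, "mixed"],
               negative = counts[, "negative"])
  rownames(two) <- rownames(counts)
  list(counts = counts, two_by_two = two)
}
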