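#' Design of a synthetic matched naive/resistant omics cohort
#'
#' Emulates the input structure of a multi-omics PARP-inhibitor resistance
#' screen: per-donor matched naive/resistant tumor samples, a known-factor
#' panel with driver directions, and planted genomic and transcriptional
#' alterations at configurable per-group frequencies.
#'
#' Planting is deterministic by default (`round(frequency * n)` affected
#' samples, the first of each group) so that recovery tests are exact; set
#' `bernoulli = TRUE` for Bernoulli draws. Log2 expression is baseline +
#' donor effect + Gaussian noise, with planted shifts added to the
#' designated resistant samples; counts are Poisson draws around the
#' linear-scale expression.
#'
#' @param groups Data.frame with columns `group` (resistant-group label,
#'   e.g. `RAD51pos_KB1PM`) and `n_donors` (matched pairs per group).
#' @param genes Character vector of gene symbols in the expression matrix.
#' @param planted_genomic Data.frame `gene`, `group`, `class` (one of
#'   `copy_number_deletion`, `stop_gained_SNV`, `frameshift_SNV`,
#'   `loss_of_function_SV`, `focal_amplification`), `frequency`; optional
#'   `impact` (default `high`). May have zero rows.
#' @param planted_expression Data.frame `gene`, `group`, `log2_shift`,
#'   `subset_fraction`. May have zero rows.
#' @param germline Data.frame `gene`, `variant_id`; these variants are
#'   planted in both members of every donor pair. May have zero rows.
#' @param baseline_log2_mean Range of per-gene baseline log2 expression.
#' @param noise_sd SD of Gaussian noise on log2 expression (default 0.2).
#' @param donor_effect_sd SD of the per-donor random effect.
#' @param bernoulli Use Bernoulli draws for planting (default FALSE).
#' @param seed Integer seed.
#' @return An object of class `omics_design`.
#' @export
omics_design <- function(groups,
                         genes,
                         planted_genomic = NULL,
                         planted_expression = NULL,
                         germline = NULL,
                         baseline_log2_mean = c(3, 9),
                         noise_sd = 0.2,
                         donor_effect_sd = 0.3,
                         bernoulli = FALSE,
                         seed = NULL) {
  if (!is.data.frame(groups) || nrow(groups) == 0L ||
      !all(c("group", "n_donors") %in% names(groups))) {
    stop("groups must be a data.frame with columns group, n_donors",
         call. = FALSE)
  }
  if (any(groups$n_donors < 1)) stop("n_donors must be >= 1", call. = FALSE)
  if (length(genes) == 0L || anyDuplicated(genes)) {
    stop("genes must be non-empty and unique", call. = FALSE)
  }
  empty_gen <- data.frame(gene = character(0), group = character(0),
                          class = character(0), frequency = numeric(0))
  empty_exp <- data.frame(gene = character(0), group = character(0),
                          log2_shift = numeric(0),
                          subset_fraction = numeric(0))
  if (is.null(planted_genomic)) planted_genomic <- empty_gen
  if (is.null(planted_expression)) planted_expression <- empty_exp
  if (is.null(germline)) {
    germline <- data.frame(gene = character(0), variant_id = character(0))
  }
  classes <- c("copy_number_deletion", "stop_gained_SNV", "frameshift_SNV",
               "loss_of_function_SV", "focal_amplification")
  if (nrow(planted_genomic) > 0) {
    if (!all(planted_genomic$class %in% classes)) {
      stop("unknown variant class in planted_genomic", call. = FALSE)
    }
    if (is.null(planted_genomic$impact)) planted_genomic$impact <- "high"
  }
  bad <- setdiff(c(planted_genomic$gene, planted_expression$gene,
                   germline$gene), genes)
  if (length(bad) > 0) {
    stop("planted alteration table references unknown gene(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  freqs <- c(planted_genomic$frequency, planted_expression$subset_fraction)
  if (any(freqs < 0 | freqs > 1)) {
    stop("planted frequencies must be in [0, 1]", call. = FALSE)
  }
  bad_grp <- setdiff(c(planted_genomic$group, planted_expression$group),
                     groups$group)
  if (length(bad_grp) > 0) {
    stop("planted alteration table references unknown group(s): ",
         paste(unique(bad_grp), collapse = ", "), call. = FALSE)
  }
  structure(list(groups = groups, genes = genes,
                 planted_genomic = planted_genomic,
                 planted_expression = planted_expression,
                 germline = germline,
                 baseline_log2_mean = baseline_log2_mean,
                 noise_sd = noise_sd, donor_effect_sd = donor_effect_sd,
                 bernoulli = isTRUE(bernoulli), seed = seed),
            class = "omics_design")
}

#' Generate matched naive/resistant omics tables with ground truth
#'
#' @param design An [omics_design()].
#' @return A list of class `irif_omics`:
#'   \describe{
#'     \item{samples}{sample sheet: `sample`, `donor`, `group`,
#'       `treatment` (naive samples carry group `naive_<group>`).}
#'     \item{pairing}{data.frame `resistant`, `naive` (matched samples).}
#'     \item{expression}{genes x samples matrix of log2 expression.}
#'     \item{counts}{genes x samples matrix of Poisson counts around the
#'       linear-scale expression (for the CPM filter).}
#'     \item{variants}{variant records: `gene`, `sample`, `class`,
#'       `impact`, `variant_id` (includes germline records present in both
#'       members of each pair).}
#'     \item{cnv}{the focal copy-number subset of `variants`.}
#'     \item{ground_truth}{planted alteration table: `gene`, `sample`,
#'       `type` ("genomic"/"transcriptional"), `detail`.}
#'   }
#' @export
generate_omics <- function(design) {
  if (!inherits(design, "omics_design")) {
    stop("design must be created with omics_design()", call. = FALSE)
  }
  with_seed(design$seed, generate_omics_impl(design))
}

generate_omics_impl <- function(d) {
  grp <- d$groups
  samples <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    n <- grp$n_donors[i]
    donor <- sprintf("%s_d%02d", grp$group[i], seq_len(n))
    rbind(data.frame(sample = paste0(donor, "_naive"), donor = donor,
                     group = paste0("naive_", grp$group[i]),
                     treatment = "naive"),
          data.frame(sample = paste0(donor, "_res"), donor = donor,
                     group = grp$group[i], treatment = "resistant"))
  }))
  rownames(samples) <- NULL
  res_samples <- samples[samples$treatment == "resistant", ]
  pairing <- data.frame(
    resistant = res_samples$sample,
    naive = samples$sample[match(res_samples$donor, samples$donor)]
  )

  ng <- length(d$genes)
  ns <- nrow(samples)
  baseline <- runif(ng, min(d$baseline_log2_mean), max(d$baseline_log2_mean))
  donor_eff <- rnorm(length(unique(samples$donor)), 0, d$donor_effect_sd)
  names(donor_eff) <- unique(samples$donor)
  expr <- matrix(baseline, ng, ns) +
    matrix(donor_eff[samples$donor], ng, ns, byrow = TRUE) +
    matrix(rnorm(ng * ns, 0, d$noise_sd), ng, ns)
  dimnames(expr) <- list(d$genes, samples$sample)

  gt <- data.frame(gene = character(0), sample = character(0),
                   type = character(0), detail = character(0))

  n_affected <- function(frac, n) {
    if (d$bernoulli) sum(runif(n) < frac) else round(frac * n)
  }
  group_res_samples <- function(g) {
    res_samples$sample[res_samples$group == g]
  }

  pe <- d$planted_expression
  for (i in seq_len(nrow(pe))) {
    sset <- group_res_samples(pe$group[i])
    k <- n_affected(pe$subset_fraction[i], length(sset))
    if (k == 0) next
    hit <- sset[seq_len(k)]
    expr[pe$gene[i], hit] <- expr[pe$gene[i], hit] + pe$log2_shift[i]
    gt <- rbind(gt, data.frame(gene = pe$gene[i], sample = hit,
                               type = "transcriptional",
                               detail = sprintf("log2_shift=%g",
                                                pe$log2_shift[i])))
  }

  variants <- data.frame(gene = character(0), sample = character(0),
                         class = character(0), impact = character(0),
                         variant_id = character(0))
  pg <- d$planted_genomic
  for (i in seq_len(nrow(pg))) {
    sset <- group_res_samples(pg$group[i])
    k <- n_affected(pg$frequency[i], length(sset))
    if (k == 0) next
    hit <- sset[seq_len(k)]
    vid <- sprintf("%s_%s_%s", pg$gene[i], pg$group[i], pg$class[i])
    variants <- rbind(variants,
                      data.frame(gene = pg$gene[i], sample = hit,
                                 class = pg$class[i],
                                 impact = pg$impact[i], variant_id = vid))
    gt <- rbind(gt, data.frame(gene = pg$gene[i], sample = hit,
                               type = "genomic", detail = pg$class[i]))
  }

  gl <- d$germline
  for (i in seq_len(nrow(gl))) {
    variants <- rbind(variants,
                      data.frame(gene = gl$gene[i],
                                 sample = samples$sample,
                                 class = "stop_gained_SNV",
                                 impact = "high",
                                 variant_id = gl$variant_id[i]))
  }
  rownames(variants) <- NULL
  rownames(gt) <- NULL

  counts <- matrix(rpois(ng * ns, lambda = 2^expr), ng, ns,
                   dimnames = dimnames(expr))

  structure(list(samples = samples, pairing = pairing, expression = expr,
                 counts = counts, variants = variants,
                 cnv = variants[variants$class %in%
                                  c("copy_number_deletion",
                                    "focal_amplification"), ],
                 ground_truth = gt),
            class = "irif_omics")
}

#' @export
print.irif_omics <- function(x, ...) {
  cat(sprintf("<irif_omics> %d genes x %d samples (%d matched pairs), %d variant records, %d planted alterations\n",
              nrow(x$expression), ncol(x$expression), nrow(x$pairing),
              nrow(x$variants), nrow(x$ground_truth)))
  invisible(x)
}
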