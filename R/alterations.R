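# Resistance-alteration calling on tabular omics inputs.

#' Known PARP-inhibitor resistance factor panel
#'
#' A curated default panel of 25 mouse genes reported to drive PARPi
#' resistance, each annotated with its driver direction (loss or gain of
#' function decides the direction of the two-fold transcriptional rule)
#' and the resistance mechanism class (HR restoration, replication-fork
#' stability, PARP signaling). Ships as a plain TSV under `extdata`; pass
#' your own table with the same columns to override.
#'
#' @return Data.frame with columns `gene`, `driver_direction`
#'   (`loss_of_function`/`gain_of_function`), `mechanism`
#'   (`HR_restoration`/`fork_stability`/`PARP_signaling`).
#' @export
known_factor_panel <- function() {
  path <- system.file("extdata", "known_factor_panel.tsv", package = "irifq",
                      mustWork = TRUE)
  read_records(path)
}

#' Filter genes by counts-per-million expression
#'
#' Keeps genes with CPM > 1 in at least 10% of samples (boundary
#' inclusive), the standard pre-filter before differential expression.
#'
#' @param counts Non-negative genes x samples count matrix.
#' @param min_cpm CPM threshold (strictly greater; default 1).
#' @param min_fraction Minimum fraction of samples (default 0.10,
#'   inclusive).
#' @return The filtered count matrix (possibly zero rows).
#' @export
filter_expressed_genes <- function(counts, min_cpm = 1,
                                   min_fraction = 0.10) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(counts) == 0L) return(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(counts, 2, tot, "/") * 1e6
  frac <- rowMeans(cpm > min_cpm)
  counts[frac >= min_fraction - 1e-12, , drop = FALSE]
}

#' Call resistance-specific genomic alterations
#'
#' A genomic call is emitted for a (gene, resistant tumor) pair when a
#' high-impact variant (or a focal copy-number deletion/amplification) is
#' present in the resistant tumor, absent from its matched naive tumor(s),
#' and not in the germline list. Variant identity is matched by
#' `variant_id` (by gene and class for copy-number events, which carry no
#' positional identity).
#'
#' @param variants Data.frame `gene`, `sample`, `class`, `impact`,
#'   `variant_id` (see [generate_omics()] for the vocabularies).
#' @param germline Character vector of germline `variant_id`s (or a
#'   data.frame with a `variant_id` column).
#' @param pairing Data.frame `resistant`, `naive`; must cover every
#'   resistant sample that carries variants.
#' @return Data.frame of calls: `gene`, `tumor`, `class`.
#' @export
call_genomic_alterations <- function(variants, germline, pairing) {
  stopifnot(all(c("gene", "sample", "class", "impact", "variant_id") %in%
                  names(variants)),
            all(c("resistant", "naive") %in% names(pairing)))
  if (is.data.frame(germline)) germline <- germline$variant_id
  empty <- data.frame(gene = character(0), tumor = character(0),
                      class = character(0))
  if (nrow(variants) == 0L) return(empty)
  known <- unique(c(pairing$resistant, pairing$naive))
  bad <- setdiff(variants$sample, known)
  if (length(bad) > 0) {
    stop("variant(s) reference unknown sample(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  cnv_classes <- c("copy_number_deletion", "focal_amplification")
  key <- ifelse(variants$class %in% cnv_classes,
                paste(variants$gene, variants$class, sep = "|"),
                paste(variants$gene, variants$variant_id, sep = "|"))

  in_res <- variants$sample %in% pairing$resistant
  eligible <- in_res &
    (variants$impact == "high" | variants$class %in% cnv_classes) &
    !(variants$variant_id %in% germline)
  if (!any(eligible)) return(empty)

  # key set seen in each naive sample
  naive_keys <- split(key[!in_res], variants$sample[!in_res])
  matched_naive <- split(pairing$naive, pairing$resistant)

  v <- variants[eligible, , drop = FALSE]
  k <- key[eligible]
  keep <- vapply(seq_len(nrow(v)), function(i) {
    nv <- matched_naive[[v$sample[i]]]
    !any(k[i] %in% unlist(naive_keys[nv]))
  }, logical(1))
  v <- v[keep, , drop = FALSE]
  k <- k[keep]
  out <- unique(data.frame(gene = v$gene, tumor = v$sample, class = v$class))
  rownames(out) <- NULL
  out
}

#' Call transcriptional alterations by the matched-pair two-fold rule
#'
#' For each resistant tumor and panel gene, the expression change is
#' `delta = log2(resistant) - mean(log2(matched naive))`. A call is made
#' when `delta < -1` for loss-of-function drivers or `delta > +1` for
#' gain-of-function drivers (strictly more than two-fold; the boundary
#' itself does not call).
#'
#' @param expr Genes x samples matrix of log2 expression.
#' @param panel Known-factor data.frame (`gene`, `driver_direction`; see
#'   [known_factor_panel()]). Panel genes missing from `expr` are reported
#'   and skipped.
#' @param pairing Data.frame `resistant`, `naive`.
#' @param log2_cutoff Absolute log2 fold-change bound (default 1 = two-fold).
#' @return Data.frame of calls: `gene`, `tumor`, `delta`, `direction`
#'   (`down`/`up`).
#' @export
call_expression_alterations <- function(expr, panel, pairing,
                                        log2_cutoff = 1) {
  stopifnot(is.matrix(expr),
            all(c("gene", "driver_direction") %in% names(panel)))
  missing_genes <- setdiff(panel$gene, rownames(expr))
  if (length(missing_genes) > 0) {
    warning("panel gene(s) not in expression matrix, skipped: ",
            paste(missing_genes, collapse = ", "))
    panel <- panel[panel$gene %in% rownames(expr), , drop = FALSE]
  }
  res <- unique(pairing$resistant)
  res_in <- character(0)
  for (tumor in res[res %in% colnames(expr)]) {
    nv <- pairing$naive[pairing$resistant == tumor]
    if (any(nv %in% colnames(expr))) {
      res_in <- c(res_in, tumor)
    } else {
      warning("no matched naive sample for ", tumor, "; tumor excluded")
    }
  }
  if (length(res_in) == 0L || nrow(panel) == 0L) {
    return(data.frame(gene = character(0), tumor = character(0),
                      delta = numeric(0), direction = character(0)))
  }
  sub <- expr[panel$gene, , drop = FALSE]
  naive_mean <- vapply(res_in, function(tumor) {
    nv <- pairing$naive[pairing$resistant == tumor]
    nv <- nv[nv %in% colnames(expr)]
    rowMeans(sub[, nv, drop = FALSE])
  }, numeric(nrow(panel)))
  delta <- sub[, res_in, drop = FALSE] - naive_mean
  lof <- panel$driver_direction == "loss_of_function"
  hit <- which((lof & delta < -log2_cutoff) |
                 (!lof & delta > log2_cutoff), arr.ind = TRUE)
  out <- data.frame(gene = panel$gene[hit[, 1]],
                    tumor = res_in[hit[, 2]],
                    delta = delta[hit],
                    direction = ifelse(lof[hit[, 1]], "down", "up"))
  out <- out[order(out$tumor, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Combine genomic and transcriptional calls per (gene, tumor)
#'
#' @param genomic Calls from [call_genomic_alterations()].
#' @param transcriptional Calls from [call_expression_alterations()].
#' @param panel Known-factor panel (used for direction consistency: loss-
#'   type genomic classes and downregulation match loss-of-function
#'   drivers; amplification and upregulation match gain-of-function).
#' @return Data.frame `gene`, `tumor`, `genomic`, `transcriptional`,
#'   `direction_consistent` (one row per altered pair; at least one flag
#'   is TRUE on every row).
#' @export
combine_alteration_calls <- function(genomic, transcriptional, panel) {
  gkey <- if (nrow(genomic)) paste(genomic$gene, genomic$tumor) else
    character(0)
  tkey <- if (nrow(transcriptional))
    paste(transcriptional$gene, transcriptional$tumor) else character(0)
  all_keys <- union(gkey, tkey)
  if (length(all_keys) == 0L) {
    return(data.frame(gene = character(0), tumor = character(0),
                      genomic = logical(0), transcriptional = logical(0),
                      direction_consistent = logical(0)))
  }
  parts <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  out <- data.frame(gene = parts[, 1], tumor = parts[, 2],
                    genomic = all_keys %in% gkey,
                    transcriptional = all_keys %in% tkey)
  dir <- panel$driver_direction[match(out$gene, panel$gene)]
  loss_classes <- c("copy_number_deletion", "stop_gained_SNV",
                    "frameshift_SNV", "loss_of_function_SV")
  consistent <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (is.na(dir[i])) { consistent[i] <- NA; next }
    want_loss <- dir[i] == "loss_of_function"
    ok <- TRUE
    if (out$genomic[i]) {
      cls <- genomic$class[gkey == all_keys[i]]
      ok <- ok && all((cls %in% loss_classes) == want_loss)
    }
    if (out$transcriptional[i]) {
      drn <- transcriptional$direction[tkey == all_keys[i]]
      ok <- ok && all((drn == "down") == want_loss)
    }
    consistent[i] <- ok
  }
  out$direction_consistent <- consistent
  rownames(out) <- NULL
  out
}

#' Per-gene alteration frequencies by group with pairwise Fisher tests
#'
#' Frequency = altered tumors / group size, per gene and group. For each
#' gene and each pair of groups a two-sided Fisher exact test on the
#' altered/not-altered counts flags preferential alteration (p < 0.05).
#'
#' @param calls Data.frame with `gene` and `tumor` columns (any caller
#'   output; rows are altered pairs).
#' @param groups Named character vector mapping tumor -> group (every
#'   called tumor must be covered), or a data.frame `tumor`, `group`.
#' @return List with `frequencies` (`gene`, `group`, `n_altered`,
#'   `group_size`, `frequency`) and `tests` (`gene`, `group1`, `group2`,
#'   `p_value`, `significant`).
#' @export
summarize_factor_frequencies <- function(calls, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$tumor)
  }
  if (length(groups) == 0L) stop("empty group map", call. = FALSE)
  glev <- unique(unname(groups))
  gsize <- table(factor(unname(groups), levels = glev))
  if (any(gsize == 0)) stop("empty group", call. = FALSE)
  bad <- setdiff(calls$tumor, names(groups))
  if (length(bad) > 0) {
    stop("called tumor(s) without group assignment: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  genes <- unique(calls$gene)
  if (length(genes) == 0L) {
    return(list(frequencies = data.frame(gene = character(0),
                                         group = character(0),
                                         n_altered = integer(0),
                                         group_size = integer(0),
                                         frequency = numeric(0)),
                tests = data.frame(gene = character(0),
                                   group1 = character(0),
                                   group2 = character(0),
                                   p_value = numeric(0),
                                   significant = logical(0))))
  }
  freq <- do.call(rbind, lapply(genes, function(g) {
    tum <- unique(calls$tumor[calls$gene == g])
    n_alt <- table(factor(groups[tum], levels = glev))
    data.frame(gene = g, group = glev, n_altered = as.integer(n_alt),
               group_size = as.integer(gsize),
               frequency = as.numeric(n_alt / gsize))
  }))
  tests <- NULL
  if (length(glev) >= 2L) {
    prs <- combn(glev, 2)
    tests <- do.call(rbind, lapply(genes, function(g) {
      fg <- freq[freq$gene == g, ]
      do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        g1 <- prs[1, j]; g2 <- prs[2, j]
        a <- fg$n_altered[fg$group == g1]; n1 <- fg$group_size[fg$group == g1]
        b <- fg$n_altered[fg$group == g2]; n2 <- fg$group_size[fg$group == g2]
        p <- fisher_exact_2x2(matrix(c(a, n1 - a, b, n2 - b), 2,
                                     byrow = TRUE))$p_value
        data.frame(gene = g, group1 = g1, group2 = g2, p_value = p,
                   significant = p < 0.05)
      }))
    }))
  }
  rownames(freq) <- NULL
  if (!is.null(tests)) rownames(tests) <- NULL
  list(frequencies = freq, tests = tests)
}

#' Fraction of resistant tumors with any known-factor alteration
#'
#' @param calls Data.frame with `gene` and `tumor` columns.
#' @param panel Known-factor panel (or character vector of gene symbols).
#' @param tumors Character vector of all resistant tumors (the
#'   denominator).
#' @return Fraction in \[0, 1\].
#' @export
fraction_with_any_known_factor <- function(calls, panel, tumors) {
  genes <- if (is.data.frame(panel)) panel$gene else panel
  if (length(tumors) == 0L) return(0)
  hit <- unique(calls$tumor[calls$gene %in% genes])
  length(intersect(hit, tumors)) / length(tumors)
}

#' Subgroup-outlier score with permutation test
#'
#' Detects genes whose expression is shifted in only a subset of resistant
#' tumors relative to the whole naive range (the heterogeneous-resistance
#' signal that a homogeneous-shift test dilutes). The statistic is a
#' range-exceedance sum: with `lo = min(naive)` and `hi = max(naive)`,
#' `S_down = sum over resistant values v < lo of (lo - v)^exponent` and
#' `S_up` symmetrically above `hi`; the signed score is `S_up` when
#' `S_up >= S_down`, else `-S_down`. Significance is a permutation test of
#' the arm labels: full enumeration when `choose(n + m, m) <= 1e5`, else
#' Monte-Carlo with `n_perm` draws (add-one corrected), counting
#' permutations with `|score| >=` the observed.
#'
#' @param naive,resistant Numeric expression values (>= 3 per arm).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible
#'   (default 10000).
#' @param seed Optional seed for the Monte-Carlo branch.
#' @param exponent Exponent on the exceedance distance (default 1).
#' @return A list of class `outlier_score`: `score` (signed), `s_up`,
#'   `s_down`, `p_value`, `exact` (TRUE for full enumeration).
#' @export
subgroup_outlier_score <- function(naive, resistant, n_perm = 10000,
                                   seed = NULL, exponent = 1) {
  if (length(naive) < 3L || length(resistant) < 3L) {
    stop("at least 3 samples per arm required", call. = FALSE)
  }
  v <- c(naive, resistant)
  n <- length(naive); m <- length(resistant); N <- n + m

  stat <- function(nv, rv) {
    lo <- min(nv); hi <- max(nv)
    s_dn <- sum(pmax(lo - rv, 0)^exponent)
    s_up <- sum(pmax(rv - hi, 0)^exponent)
    if (s_up >= s_dn) s_up else -s_dn
  }
  s_obs <- stat(naive, resistant)
  lo <- min(naive); hi <- max(naive)
  s_up <- sum(pmax(resistant - hi, 0)^exponent)
  s_dn <- sum(pmax(lo - resistant, 0)^exponent)

  n_assign <- choose(N, m)
  if (n_assign <= 1e5) {
    cmb <- combn(N, m)   # columns: indices assigned to the resistant arm
    scores <- vapply(seq_len(ncol(cmb)), function(j) {
      idx <- cmb[, j]
      stat(v[-idx], v[idx])
    }, numeric(1))
    p <- mean(abs(scores) >= abs(s_obs) - 1e-12)
    exact <- TRUE
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(j) {
        idx <- sample.int(N, m)
        abs(stat(v[-idx], v[idx])) >= abs(s_obs) - 1e-12
      }, logical(1)))
    })
    p <- (count + 1) / (n_perm + 1)
    exact <- FALSE
  }
  structure(list(score = s_obs, s_up = s_up, s_down = s_dn,
                 p_value = p, exact = exact),
            class = "outlier_score")
}

#' @export
print.outlier_score <- function(x, ...) {
  cat(sprintf("subgroup outlier score = %.4g (S_up %.4g, S_down %.4g), p = %.4g%s\n",
              x$score, x$s_up, x$s_down, x$p_value,
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Overlap (Venn) summary of two gene sets
#'
#' @param genomic,transcriptional Character vectors of gene symbols.
#' @return Named integer vector: `genomic_only`, `transcriptional_only`,
#'   `shared`.
#' @export
overlap_summary <- function(genomic, transcriptional) {
  g <- unique(genomic); t <- unique(transcriptional)
  shared <- intersect(g, t)
  c(genomic_only = length(setdiff(g, t)),
    transcriptional_only = length(setdiff(t, g)),
    shared = length(shared))
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact test (enrichment direction) of the query against
#' each gene set (intersected with the universe), followed by
#' Benjamini-Hochberg adjustment across sets; sets with adjusted p below
#' `fdr_cutoff` are flagged as enriched.
#'
#' @param query Character vector of hit genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of all testable genes.
#' @param gene_sets Named list of character vectors.
#' @param fdr_cutoff Adjusted-p cutoff for the `enriched` flag
#'   (default 0.25).
#' @return Data.frame: `set`, `set_size`, `overlap`, `p_value`,
#'   `adjusted_p`, `enriched`, ordered by p-value.
#' @export
gene_set_overrepresentation <- function(query, universe, gene_sets,
                                        fdr_cutoff = 0.25) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  if (length(gene_sets) == 0L) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), enriched = logical(0)))
  }
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, s))
    tab <- matrix(c(k, length(query) - k,
                    length(s) - k,
                    length(universe) - length(s) - length(query) + k),
                  2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p)
  }))
  res$adjusted_p <- bh_adjust(res$p_value)
  res$enriched <- res$adjusted_p < fdr_cutoff
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  res
}
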