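#' Two-tailed Mann-Whitney U test with exact small-sample p-values
#'
#' Computes the Mann-Whitney U statistic for `x` (midranks for ties). The
#' two-tailed p-value is exact for small samples: without ties it uses the
#' exact null distribution of U; with ties it enumerates all
#' `choose(n + m, n)` group assignments of the pooled midranks and counts
#' those at least as extreme (|U - nm/2|) as observed. Beyond
#' `exact_bound` assignments it falls back to the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_bound Maximum number of assignments for the exact branch
#'   (default 200000).
#' @return An `irif_test` list: `statistic` (U for `x`), `p_value`,
#'   `method`, `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
mann_whitney_u <- function(x, y, exact_bound = 200000) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stop("samples must be numeric without NAs", call. = FALSE)
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- anyDuplicated(pooled) > 0L
  n_assign <- choose(N, n)

  if (n_assign <= exact_bound) {
    if (!ties) {
      # exact null distribution of U (no ties)
      p <- if (U > mu) {
        2 * (1 - pwilcox(U - 1, n, m))
      } else if (U < mu) {
        2 * pwilcox(U, n, m)
      } else {
        1
      }
      p <- min(1, p)
      exact <- TRUE
      method <- "Mann-Whitney U (exact)"
    } else {
      cmb <- combn(N, n)
      Us <- colSums(matrix(r[cmb], nrow = n)) - n * (n + 1) / 2
      d_obs <- abs(U - mu)
      p <- mean(abs(Us - mu) >= d_obs - 1e-9)
      exact <- TRUE
      method <- "Mann-Whitney U (exact, enumeration with midranks)"
    }
  } else {
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    exact <- FALSE
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_irif_test(statistic = U, p_value = p, method = method, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' monotone, clipped at 1 and returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability convention: the sum of
#' hypergeometric probabilities (margins fixed) of all tables whose point
#' probability does not exceed that of the observed table (within a small
#' relative tolerance).
#'
#' @param tab A 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no), or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @return An `irif_test` with the odds-ratio estimate as `statistic`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p_value
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(tab) || !all(dim(tab) == 2L)) {
    stop("tab must be a 2x2 matrix", call. = FALSE)
  }
  if (any(tab < 0) || anyNA(tab)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(tab) == 0) stop("table total must be > 0", call. = FALSE)
  ft <- fisher.test(tab)
  new_irif_test(statistic = unname(ft$estimate), p_value = ft$p.value,
                method = "Fisher exact (two-sided)", exact = TRUE)
}

#' Fisher test on dichotomized IHC staining percentages
#'
#' Dichotomizes per-sample staining percentages at a cutoff (inclusive:
#' `>= cutoff` counts as "above"), builds the 2x2 group-by-side table and
#' applies [fisher_exact_2x2()]. Typical cutoffs are 5% and 10%; run once
#' per cutoff and report both.
#'
#' @param values Numeric staining percentages, one per sample.
#' @param groups Group label per sample (exactly two distinct groups).
#' @param cutoff_pct Dichotomization cutoff in percent.
#' @return An `irif_test`, with the 2x2 table attached as `table`.
#' @export
ihc_group_test <- function(values, groups, cutoff_pct) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  above <- values >= cutoff_pct
  tab <- matrix(c(sum(above[groups == lev[1]]), sum(!above[groups == lev[1]]),
                  sum(above[groups == lev[2]]), sum(!above[groups == lev[2]])),
                2, 2, byrow = TRUE,
                dimnames = list(lev, c("above", "below")))
  if (all(above) || all(!above)) {
    warning("all samples on one side of the cutoff in both groups; p = 1")
  }
  res <- fisher_exact_2x2(tab)
  res$table <- tab
  res$method <- sprintf("IHC dichotomized at %g%% (Fisher exact, two-sided)",
                        cutoff_pct)
  res
}

#' Ellipsoid tumor-volume formula
#'
#' Volume in mm^3 from caliper measurements: `0.5 * length * width^2`.
#'
#' @param length_mm,width_mm Non-negative measurements in mm (vectorized).
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 10)  # 500
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stop("measurements must be >= 0", call. = FALSE)
  }
  0.5 * length_mm * width_mm^2
}

new_irif_test <- function(statistic, p_value, method, exact) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact),
            class = "irif_test")
}

#' @export
print.irif_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}
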