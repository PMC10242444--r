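# Resistance-alteration calling: expression filter, genomic and
# transcriptional rules, frequencies, outlier score, overlaps, ORA.

toy_pairing <- data.frame(resistant = c("r1", "r2"), naive = c("n1", "n2"))

test_that("CPM filter keeps 'at least 10% of samples' inclusively", {
  # 10 samples with equal library size 1e6: count == CPM
  counts <- matrix(10, nrow = 3, ncol = 10,
                   dimnames = list(c("low", "boundary", "high"), NULL))
  counts["low", ] <- 1                       # CPM ~ 1, never > 1
  counts["boundary", ] <- 0                  # CPM 2 in exactly 1/10 samples
  counts["boundary", 1] <- 2
  colsums_target <- 1e6
  counts <- rbind(counts,
                  filler = colsums_target - colSums(counts))
  kept <- filter_expressed_genes(counts)
  expect_false("low" %in% rownames(kept))
  expect_true("boundary" %in% rownames(kept))
  expect_true("high" %in% rownames(kept))

  expect_equal(nrow(filter_expressed_genes(counts[0, , drop = FALSE])), 0)
  bad <- counts; bad[, 3] <- 0; colnames(bad) <- paste0("s", 1:10)
  expect_error(filter_expressed_genes(bad), "s3")
})

test_that("genomic calls are resistance-specific and germline-free", {
  v <- data.frame(
    gene = c("Trp53bp1", "Trp53bp1", "Parg", "Rif1", "Mad2l2"),
    sample = c("r1", "n1", "r1", "r2", "r2"),
    class = c("stop_gained_SNV", "stop_gained_SNV", "stop_gained_SNV",
              "frameshift_SNV", "stop_gained_SNV"),
    impact = "high",
    variant_id = c("v_shared", "v_shared", "v_parg", "v_rif1", "v_gl")
  )
  calls <- call_genomic_alterations(v, germline = "v_gl", toy_pairing)
  # shared with matched naive -> dropped; germline -> dropped
  expect_equal(sort(calls$gene), c("Parg", "Rif1"))
  expect_equal(calls$class[calls$gene == "Rif1"], "frameshift_SNV")

  # moderate-impact SNVs never call; focal CNVs call regardless of impact
  v2 <- data.frame(gene = c("A", "B"), sample = "r1",
                   class = c("stop_gained_SNV", "copy_number_deletion"),
                   impact = c("moderate", "moderate"),
                   variant_id = c("m1", "cnv1"))
  calls2 <- call_genomic_alterations(v2, character(0), toy_pairing)
  expect_equal(calls2$gene, "B")

  v3 <- v[1, ]; v3$sample <- "mystery"
  expect_error(call_genomic_alterations(v3, character(0), toy_pairing),
               "unknown sample")
})

test_that("the two-fold transcriptional rule uses strict boundaries", {
  panel <- data.frame(gene = c("LoF1", "GoF1"),
                      driver_direction = c("loss_of_function",
                                           "gain_of_function"))
  expr <- matrix(10, nrow = 2, ncol = 4,
                 dimnames = list(c("LoF1", "GoF1"),
                                 c("r1", "r2", "n1", "n2")))
  expr["LoF1", "r1"] <- 10 - 1.1   # delta -1.1 -> call
  expr["LoF1", "r2"] <- 10 - 0.9   # delta -0.9 -> no call
  expr["GoF1", "r1"] <- 10 + 1.0   # delta exactly +1 -> no call (strict)
  expr["GoF1", "r2"] <- 10 + 1.01  # -> call
  calls <- call_expression_alterations(expr, panel, toy_pairing)
  expect_equal(calls[order(calls$gene), c("gene", "tumor", "direction")],
               data.frame(gene = c("GoF1", "LoF1"), tumor = c("r2", "r1"),
                          direction = c("up", "down")),
               ignore_attr = TRUE)

  panel2 <- rbind(panel, data.frame(gene = "Ghost",
                                    driver_direction = "loss_of_function"))
  expect_warning(call_expression_alterations(expr, panel2, toy_pairing),
                 "Ghost")
})

test_that("matched-naive aggregation averages multiple naive samples", {
  panel <- data.frame(gene = "G", driver_direction = "loss_of_function")
  expr <- matrix(c(10 - 1.2, 10.5, 9.5), nrow = 1,
                 dimnames = list("G", c("r1", "n1a", "n1b")))
  pairing <- data.frame(resistant = c("r1", "r1"), naive = c("n1a", "n1b"))
  calls <- call_expression_alterations(expr, panel, pairing)
  expect_equal(calls$delta, -1.2)

  expect_warning(
    none <- call_expression_alterations(
      expr, panel, data.frame(resistant = "r1", naive = "missing")),
    "excluded")
  expect_equal(nrow(none), 0)
})

test_that("factor frequencies and pairwise Fisher tests match the oracle", {
  groups <- setNames(rep(c("g1", "g2"), c(29, 15)),
                     c(paste0("a", 1:29), paste0("b", 1:15)))
  calls <- data.frame(gene = "Trp53bp1",
                      tumor = c(paste0("a", 1:12), "b1"))
  res <- summarize_factor_frequencies(calls, groups)
  f <- res$frequencies
  expect_equal(f$frequency[f$group == "g1"], 12 / 29, tolerance = 1e-12)
  expect_equal(f$frequency[f$group == "g2"], 1 / 15, tolerance = 1e-12)
  expect_equal(res$tests$p_value,
               oracle_fisher_p(12, 17, 1, 14), tolerance = 1e-7)
  expect_true(res$tests$significant)

  # unaltered gene: p = 1 in every pair
  res0 <- summarize_factor_frequencies(
    data.frame(gene = character(0), tumor = character(0)), groups)
  expect_equal(nrow(res0$frequencies), 0)

  expect_error(summarize_factor_frequencies(
    data.frame(gene = "X", tumor = "zz"), groups), "without group")
})

test_that("fraction of tumors with any known-factor alteration", {
  tumors <- paste0("t", 1:71)
  calls <- data.frame(gene = "Trp53bp1", tumor = paste0("t", 1:55))
  expect_equal(fraction_with_any_known_factor(calls, known_factor_panel(),
                                              tumors), 55 / 71)
  expect_equal(fraction_with_any_known_factor(calls[0, ], "Trp53bp1",
                                              tumors), 0)
  expect_equal(fraction_with_any_known_factor(
    data.frame(gene = "Parg", tumor = tumors), "Parg", tumors), 1)
})

test_that("subgroup outlier score: signs, degenerate cases, oracle equality", {
  r <- subgroup_outlier_score(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_equal(r$score, 0)
  expect_equal(r$p_value, 1)

  r2 <- subgroup_outlier_score(c(0, 0, 0, 0), c(0, 0, -3, -4))
  expect_lt(r2$score, 0)
  expect_equal(r2$s_down, 7)

  set.seed(41)
  for (i in 1:15) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    nv <- rnorm(n); rv <- rnorm(m, sample(c(0, 2), 1))
    got <- subgroup_outlier_score(nv, rv)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_outlier_p(nv, rv), tolerance = 1e-12)
  }

  expect_error(subgroup_outlier_score(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("Monte-Carlo permutation branch is seed-reproducible", {
  set.seed(88)
  nv <- rnorm(12); rv <- c(rnorm(5), 6, 7, 8, 9)  # choose(21, 9) > 1e5 -> MC
  r1 <- subgroup_outlier_score(nv, rv, n_perm = 2000, seed = 5)
  r2 <- subgroup_outlier_score(nv, rv, n_perm = 2000, seed = 5)
  expect_false(r1$exact)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
})

test_that("overlap summaries follow set algebra", {
  expect_equal(unname(overlap_summary(c("a", "b", "c"),
                                      c("d", "e", "f", "g"))),
               c(3, 4, 0))
  expect_equal(unname(overlap_summary(c("a", "b"), c("b", "a"))), c(0, 0, 2))
  set.seed(4)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    got <- overlap_summary(a, b)
    expect_equal(unname(got), oracle_overlap(a, b))
    expect_equal(sum(got), length(union(a, b)))
  }
})

test_that("over-representation matches the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:10), cold = paste0("g", 51:60))
  query <- c(paste0("g", 1:5), paste0("g", 96:100))
  res <- gene_set_overrepresentation(query, universe, sets)
  expect_equal(res$p_value[res$set == "hit"],
               oracle_ora_p(5, 10, 10, 100), tolerance = 1e-9)
  expect_true(res$enriched[res$set == "hit"])

  # empty query enriches nothing; full query cannot be enriched
  r0 <- gene_set_overrepresentation(character(0), universe, sets)
  expect_false(any(r0$enriched))
  r1 <- gene_set_overrepresentation(universe, universe, sets)
  expect_true(all(r1$p_value == 1))

  expect_error(gene_set_overrepresentation("x", character(0), sets),
               "universe")
  expect_error(gene_set_overrepresentation("zz", universe, sets), "subset")
})

test_that("planted transcriptional alterations are recovered on noisy omics", {
  panel <- known_factor_panel()
  lof <- panel$gene[panel$driver_direction == "loss_of_function"]
  d <- omics_design(
    groups = data.frame(group = "RAD51pos_KB1PM", n_donors = 250),
    genes = c(panel$gene, paste0("bg", 1:30)),
    planted_expression = data.frame(gene = lof, group = "RAD51pos_KB1PM",
                                    log2_shift = -1.5,
                                    subset_fraction = 0.4),
    noise_sd = 0.2, seed = 55)
  om <- generate_omics(d)
  calls <- call_expression_alterations(om$expression, panel, om$pairing)
  truth_keys <- paste(om$ground_truth$gene, om$ground_truth$sample)
  call_keys <- paste(calls$gene, calls$tumor)
  expect_gte(mean(truth_keys %in% call_keys), 0.95)
  # false calls across all unplanted (panel gene, tumor) pairs
  all_keys <- as.vector(outer(panel$gene, om$pairing$resistant, paste))
  unplanted <- setdiff(all_keys, truth_keys)
  expect_lte(mean(unplanted %in% call_keys), 0.05)
})

test_that("combined calls keep direction consistency per driver class", {
  panel <- data.frame(gene = c("L", "G"),
                      driver_direction = c("loss_of_function",
                                           "gain_of_function"))
  genomic <- data.frame(gene = c("L", "G"), tumor = "t1",
                        class = c("stop_gained_SNV", "focal_amplification"))
  transcr <- data.frame(gene = "L", tumor = c("t1", "t2"),
                        delta = c(-1.4, -1.2), direction = "down")
  comb <- combine_alteration_calls(genomic, transcr, panel)
  expect_equal(nrow(comb), 3)
  expect_true(all(comb$genomic | comb$transcriptional))
  expect_true(all(comb$direction_consistent))
  # an upregulated loss-of-function driver is inconsistent
  transcr_bad <- data.frame(gene = "L", tumor = "t3", delta = 1.5,
                            direction = "up")
  comb2 <- combine_alteration_calls(genomic[0, ], transcr_bad, panel)
  expect_false(comb2$direction_consistent)
})

test_that("the shipped known-factor panel has the documented structure", {
  panel <- known_factor_panel()
  expect_equal(nrow(panel), 25)
  expect_equal(sum(panel$driver_direction == "loss_of_function"), 23)
  expect_equal(sum(panel$driver_direction == "gain_of_function"), 2)
  expect_setequal(unique(panel$mechanism),
                  c("HR_restoration", "fork_stability", "PARP_signaling"))
  expect_false(anyDuplicated(panel$gene) > 0)
})
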