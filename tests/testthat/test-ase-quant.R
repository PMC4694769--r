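test_that("load_allele_counts reads a long TSV and enforces the schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(make_counts_df(c("gA", "gB", "gC"), c(10, 20, 30),
                             c(5, 25, 35), condition = "c1"),
              make_counts_df(c("gA", "gB", "gC"), c(11, 21, 31),
                             c(6, 26, 36), condition = "c2"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- load_allele_counts(path)
  expect_s3_class(tab, "allele_count_table")
  expect_equal(nrow(tab$counts), 12L)
  expect_setequal(table_genes(tab), c("gA", "gB", "gC"))

  # duplicated cell names the gene
  dup <- rbind(df, df[1L, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_allele_counts(path), "gA")

  # negative count names the line
  bad <- df
  bad$count[3L] <- -4
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_allele_counts(path), "line 4")

  # non-integer count rejected too
  bad$count[3L] <- 2.5
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_allele_counts(path), "2.5")
})

test_that("exclude_genes drops exactly the blacklist and warns on absences", {
  tab <- allele_count_table(make_counts_df(sprintf("g%d", 1:6),
                                           21:26, 31:36))
  out <- exclude_genes(tab, c("g2", "g5"))
  expect_setequal(table_genes(out), c("g1", "g3", "g4", "g6"))
  expect_equal(attr(out, "n_removed"), 2L)

  expect_identical(exclude_genes(tab, character(0))$counts, tab$counts)
  expect_warning(res <- exclude_genes(tab, "nope"), "nope")
  expect_identical(res$counts, tab$counts)
})

test_that("coverage filter keeps genes with >= min_reads on both alleles", {
  tab <- allele_count_table(make_counts_df(
    c("low_a", "boundary", "high"), c(19, 20, 3000), c(3000, 20, 3000)))
  kept <- table_genes(filter_min_coverage(tab, 20, "cond1"))
  expect_setequal(kept, c("boundary", "high"))  # 19 fails, 20 passes

  # replicates pooled by summation before the threshold
  two_rep <- rbind(
    make_counts_df("gX", 12, 30, replicate = "rep1"),
    make_counts_df("gX", 11, 30, replicate = "rep2"))
  expect_equal(table_genes(filter_min_coverage(
    allele_count_table(two_rep), 20, "cond1")), "gX")

  expect_identical(
    table_genes(filter_min_coverage(tab, 1, "cond1")), table_genes(tab))
  expect_error(filter_min_coverage(tab, 20, "absent"), "absent")
  expect_error(filter_min_coverage(tab, 0, "cond1"), "min_reads")
})

test_that("ase_ratios pools replicates, forms ratios and tests bias", {
  df <- rbind(
    make_counts_df(c("even", "fourfold"), c(25, 40), c(25, 10),
                   replicate = "rep1"),
    make_counts_df(c("even", "fourfold"), c(25, 40), c(25, 10),
                   replicate = "rep2"))
  rec <- ase_ratios(allele_count_table(df), "cond1")
  even <- rec[rec$gene == "even", ]
  expect_equal(even$ratio, 1.0)
  expect_equal(even$log2_ratio, 0.0)
  expect_equal(even$count_A, 50)  # pooled by summation
  four <- rec[rec$gene == "fourfold", ]
  expect_equal(four$ratio, 4.0)
  expect_equal(four$log2_ratio, 2.0)
  expect_true(all(rec$q_value >= rec$p_value))

  zero <- allele_count_table(make_counts_df("gZ", 20, 0))
  expect_error(ase_ratios(zero, "cond1"), "filter")
})

test_that("exact binomial allele test matches enumeration and is symmetric", {
  expect_equal(binom_allele_test(10, 10), 1.0)
  # (20, 0): p = 2 * 0.5^20
  expect_equal(binom_allele_test(20, 0), 2 * 0.5^20, tolerance = 1e-12)
  # (7, 3): full enumeration over the 11 outcomes
  expect_equal(binom_allele_test(7, 3), oracle_binom_two_sided(7, 10),
               tolerance = 1e-12)

  # symmetry at p0 = 0.5 over a grid of counts
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:200, 1)
    b <- sample(0:200, 1)
    if (a + b == 0) next
    expect_identical(binom_allele_test(a, b), binom_allele_test(b, a))
  }

  # oracle agreement to 1e-12 for all totals n <= 60
  for (n in c(1, 2, 7, 13, 24, 41, 60)) {
    for (x in unique(c(0, 1, n %/% 3, n %/% 2, n))) {
      expect_equal(binom_allele_test(x, n - x),
                   oracle_binom_two_sided(x, n), tolerance = 1e-12)
    }
  }
  expect_error(binom_allele_test(0, 0), ">= 1")
  expect_error(binom_allele_test(5, 5, p0 = 1), "p0")
})

test_that("response test uses the library-size null and matches enumeration", {
  expect_equal(binom_response_test(30, 30, 1e6, 1e6), 1.0)
  expect_equal(binom_response_test(40, 10, 1e6, 1e6),
               oracle_binom_two_sided(40, 50), tolerance = 1e-12)
  # unequal libraries shift the null to 2/3
  expect_equal(binom_response_test(10, 10, 2e6, 1e6),
               oracle_binom_two_sided(10, 20, p0 = 2 / 3),
               tolerance = 1e-12)
  expect_error(binom_response_test(10, 10, 0, 1e6), "positive")
  expect_error(binom_response_test(20, 10, 15, 1e6), "exceeds")
})

test_that("response fold change normalises by library size", {
  expect_equal(response_fold_change(100, 100, 1e6, 1e6), 1.0)
  expect_equal(response_fold_change(400, 100, 1e6, 1e6), 4.0)
  expect_equal(response_fold_change(400, 100, 2e6, 1e6), 2.0)
  expect_error(response_fold_change(0, 100, 1e6, 1e6), "zero count")
  expect_equal(response_fold_change(0, 100, 1e6, 1e6, pseudocount = 0.5),
               (0.5 / 1e6) / (100.5 / 1e6))
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  # hand computation: p(i) * m / i with the step-up monotone envelope
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.04, 0.04))
  p2 <- c(0.001, 0.02, 0.9, 0.04)
  expect_equal(bh_fdr(p2), c(0.004, 0.04, 0.9, 0.0533333333333333),
               tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")

  # permutation equivariance
  set.seed(7)
  p3 <- runif(40)
  perm <- sample(40)
  expect_equal(bh_fdr(p3)[perm], bh_fdr(p3[perm]))
})

test_that("filtered ASE ratios never produce non-finite log2 values", {
  sim <- gen_ase_counts(n_genes = 400, set_size = 5, depth_mean = 60,
                        dispersion = 0.4, seed = 91)
  tab <- filter_min_coverage(sim$table, 20, "cond1")
  rec <- ase_ratios(tab, "cond1", tests = FALSE)
  expect_true(all(is.finite(rec$log2_ratio)))
  expect_true(all(rec$ratio > 0))
})

test_that("allele test is calibrated on null synthetic data", {
  # zero true ASE everywhere: background SD 0 and no set effect
  sim <- gen_ase_counts(n_genes = 4394, set_size = 11,
                        set_effect_log2 = 0, ase_sd = 0,
                        conditions = 1, replicates = 2, seed = 301)
  tab <- filter_min_coverage(sim$table, 20, "cond1")
  rec <- ase_ratios(tab, "cond1")
  m <- nrow(rec)
  for (alpha in c(0.05, 0.01)) {
    rate <- mean(rec$p_value < alpha)
    upper <- alpha + 2.576 * sqrt(alpha * (1 - alpha) / m)
    # exact tests are super-uniform: never anti-conservative beyond noise
    expect_lte(rate, upper)
    # and not degenerate: some rejections do occur near the nominal level
    expect_gte(rate, alpha / 4)
  }
})

test_that("per-replicate response records match scalar operations", {
  genes <- c("flat", "induced")
  df <- rbind(
    make_counts_df(genes, c(100, 50), c(100, 60),
                   condition = "untreated", replicate = "rep1"),
    make_counts_df(genes, c(100, 400), c(100, 480),
                   condition = "treated", replicate = "rep1"),
    make_counts_df(genes, c(110, 55), c(105, 66),
                   condition = "untreated", replicate = "rep2"),
    make_counts_df(genes, c(110, 440), c(105, 528),
                   condition = "treated", replicate = "rep2"))
  tab <- allele_count_table(df)
  resp <- response_records(tab, treated = "treated",
                           untreated = "untreated")
  expect_equal(nrow(resp), 8L)  # 2 genes x 2 alleles x 2 replicates
  row <- resp[resp$gene == "induced" & resp$allele == "A" &
                resp$replicate == "rep1", ]
  libs <- tab$library_sizes
  lt <- libs$lib_size[libs$allele == "A" & libs$condition == "treated" &
                        libs$replicate == "rep1"]
  lu <- libs$lib_size[libs$allele == "A" & libs$condition == "untreated" &
                        libs$replicate == "rep1"]
  expect_equal(row$fold_change, response_fold_change(400, 50, lt, lu))
  expect_equal(row$p_value, binom_response_test(400, 50, lt, lu))
})
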