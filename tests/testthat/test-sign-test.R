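test_that("top_stratum rounds half-up and breaks ties lexicographically", {
  rec <- make_ranked_records(4394, integer(0))
  expect_length(top_stratum(rec, 0.01), 44L)   # round(43.94) = 44
  expect_length(top_stratum(rec, 0.05), 220L)
  expect_length(top_stratum(rec, 1), 4394L)
  # direction B takes the other end of the ranking
  expect_equal(top_stratum(rec, 0.01, "B")[1L], rec$gene[4394L])

  tied <- data.frame(gene = c("gB", "gA", "gC"),
                     log2_ratio = c(1, 1, 2), ratio = c(2, 2, 4))
  # K = 2: gC first, then the lexicographically smaller of the tied pair
  expect_equal(sort(top_stratum(tied, 2 / 3)), c("gA", "gC"))
  expect_error(top_stratum(rec, 1e-5), "rounding")
  expect_error(top_stratum(rec, 0), "fraction")
})

test_that("hypergeometric tail reproduces published configurations", {
  # 4 of 11 tested genes inside the top-1% stratum of 4394
  expect_equal(hypergeom_tail(4394, 44, 11, 4), 2.7e-6,
               tolerance = 0.02)
  # 10 of 11 inside the top 25%
  expect_equal(hypergeom_tail(4394, 1098, 11, 10), 7.8e-6,
               tolerance = 0.02)
  expect_equal(hypergeom_tail(4394, 1099, 11, 10), 7.8e-6,
               tolerance = 0.02)
})

test_that("hypergeometric tail matches enumeration and is monotone", {
  expect_equal(hypergeom_tail(10, 4, 3, 0), 1.0)
  # every C(10,3) sample enumerated
  expect_equal(hypergeom_tail(10, 4, 3, 2), oracle_hyper_enum(10, 4, 3, 2),
               tolerance = 1e-12)
  for (N in c(8, 17, 30)) {
    K <- N %/% 3
    n <- N %/% 2
    prev <- 1
    for (k in 0:min(K, n)) {
      p <- hypergeom_tail(N, K, n, k)
      expect_equal(p, oracle_hyper_sum(N, K, n, k), tolerance = 1e-12)
      expect_lte(p, prev + 1e-15)  # nonincreasing in k
      prev <- p
    }
  }
  expect_error(hypergeom_tail(10, 11, 3, 2), "inconsistent")
  expect_error(hypergeom_tail(10, 4, 3, 4), "inconsistent")
})

test_that("directionality test is the upper binomial tail", {
  expect_equal(direction_bias_test(11, 11), 0.5^11, tolerance = 1e-12)
  expect_equal(direction_bias_test(0, 7), 1.0)
  expect_equal(direction_bias_test(5, 10), oracle_binom_upper(5, 10),
               tolerance = 1e-12)
  expect_error(direction_bias_test(5, 0), "n must")
  expect_error(direction_bias_test(6, 5), "n_up")
})

test_that("evaluate_set reproduces a ranked configuration from its ranks", {
  # 11-member set: 4 inside the top 44, 10 inside the top 25%, all with
  # direction-consistent ASE
  member_ranks <- c(1, 3, 10, 20, 200, 350, 500, 650, 800, 950, 2100)
  members <- sprintf("set%02d", seq_along(member_ranks))
  rec <- make_ranked_records(4394, member_ranks, members)
  res <- evaluate_set(rec, members, set_name = "citrinin_induced")
  r1 <- res[res$fraction == 0.01 & res$direction == "A", ]
  expect_equal(r1$k, 4L)
  expect_equal(r1$n, 11L)
  expect_equal(r1$p_hyper, 2.7e-6, tolerance = 0.02)
  r25 <- res[res$fraction == 0.25 & res$direction == "A", ]
  expect_equal(r25$k, 10L)
  expect_equal(r25$p_hyper, 7.8e-6, tolerance = 0.02)
  expect_equal(r1$n_up, 11L)
  expect_equal(r1$p_binom, 0.5^11, tolerance = 1e-12)

  # fully embedded set: k = n and minimal p
  rec2 <- make_ranked_records(1000, 1:5, sprintf("m%d", 1:5))
  res2 <- evaluate_set(rec2, sprintf("m%d", 1:5), fractions = 0.01,
                       directions = "A")
  expect_equal(res2$k, res2$n)
  expect_equal(res2$p_hyper, oracle_hyper_sum(1000, 10, 5, 5),
               tolerance = 1e-9)

  # f = 1 stratum contains everything: p must be exactly 1 when k = n
  res3 <- evaluate_set(rec2, sprintf("m%d", 1:5), fractions = 1)
  expect_true(all(res3$p_hyper == 1))

  # n counts only members present in the universe
  res4 <- evaluate_set(rec2, c("m1", "m2", "not_measured"),
                       fractions = 0.25, directions = "A")
  expect_equal(res4$n, 2L)
  expect_error(evaluate_set(rec2, c("x", "y")), "no member")
})

test_that("genomically adjacent set members trigger a warning", {
  rec <- make_ranked_records(100, integer(0))
  members <- rec$gene[c(1, 5, 9)]
  pos <- data.frame(gene = rec$gene,
                    chrom = rep("chrI", 100),
                    index = seq_len(100))
  pos$index[match(members[2:3], pos$gene)] <- c(50, 51)  # neighbours
  expect_warning(evaluate_set(rec, members, fractions = 0.25,
                              gene_positions = pos), "adjacent")
  pos$index <- seq_len(100) * 10  # spread out again
  expect_silent(evaluate_set(rec, members, fractions = 0.25,
                             gene_positions = pos))
})

test_that("scan_collection applies the full Bonferroni factor", {
  rec <- make_ranked_records(1000, 1:6, sprintf("hit%d", 1:6))
  one <- scan_collection(rec, list(only = sprintf("hit%d", 1:6)),
                         fractions = 0.01, directions = "A")
  expect_equal(one$p_adjusted, one$p_hyper)  # single test

  set.seed(5)
  coll <- c(list(shifted = sprintf("hit%d", 1:6)),
            stats::setNames(lapply(1:20, function(i) {
              sample(rec$gene[100:1000], 8)
            }), paste0("rand", 1:20)))
  res <- scan_collection(rec, coll)
  expect_equal(res$set_name[1L], "shifted")  # truly shifted set ranks first
  factor_expected <- length(coll) * 3 * 2
  expect_equal(res$p_adjusted,
               pmin(1, res$p_hyper * factor_expected))
})

test_that("random sets on permuted ranks are not called significant", {
  set.seed(23)
  rec <- make_ranked_records(2000, integer(0))
  rec$log2_ratio <- sample(rec$log2_ratio)  # destroy any structure
  coll <- stats::setNames(lapply(1:100, function(i) sample(rec$gene, 11)),
                          paste0("s", 1:100))
  res <- scan_collection(rec, coll, alpha = 0.01)
  expect_lte(sum(res$significant), 1L)  # expected ~0 after Bonferroni
})

test_that("calibrate_null is reproducible and super-uniform", {
  rec <- make_ranked_records(2000, integer(0))
  a <- calibrate_null(rec, set_size = 11, n_perm = 300, seed = 17)
  b <- calibrate_null(rec, set_size = 11, n_perm = 300, seed = 17)
  expect_identical(a, b)

  # discrete exact tests: null p-values stochastically >= uniform, so the
  # rejection rate cannot exceed the nominal level beyond sampling noise
  n_perm <- 1000
  cal <- calibrate_null(rec, set_size = 11, n_perm = n_perm, seed = 99)
  for (i in seq_len(nrow(cal$type1))) {
    a <- cal$type1$level[i]
    upper <- a + 2.576 * sqrt(a * (1 - a) / n_perm)
    expect_lte(cal$type1$rate_hyper[i], upper)
    expect_lte(cal$type1$rate_binom[i], upper)
  }
  # p_binom stochastically dominates uniform at every grid point
  for (q in c(0.05, 0.1, 0.25, 0.5, 0.75)) {
    expect_lte(mean(cal$p_binom <= q),
               q + 2.576 * sqrt(q * (1 - q) / n_perm))
  }
  expect_error(calibrate_null(rec, 11, n_perm = 10, seed = 1), "100")
  expect_error(calibrate_null(rec, 3000, n_perm = 100, seed = 1),
               "universe")
})
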