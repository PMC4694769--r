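test_that("newick parsing validates structure and labels", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("((A,B),(C,D);"), "unbalanced")
  expect_error(parse_newick("(A,B)),C;"), "position")
  # polytomies are allowed
  poly <- parse_newick("(A,B,C);")
  expect_equal(poly$Nnode, 1L)
  # round-trips through the writer
  expect_equal(ape::Ntip(parse_newick(ape::write.tree(tr))), 4L)
})

test_that("auto threshold splits at the largest gap", {
  v <- c(s1 = -2.1, s2 = -1.9, s3 = 0.1, s4 = 0.2)
  st <- binarize_resistance(v)
  expect_equal(unname(st[c("s1", "s2")]), rep("resistant", 2))
  expect_equal(unname(st[c("s3", "s4")]), rep("sensitive", 2))

  st2 <- binarize_resistance(c(a = -1, b = 1), threshold = 0)
  expect_setequal(unname(st2), c("resistant", "sensitive"))
  expect_error(binarize_resistance(c(a = 1, b = 1, c = 1)), "no gap")
  expect_error(binarize_resistance(c(a = -1, b = 1)), "3 strains")
  st3 <- binarize_resistance(v, resistant = "higher")
  expect_equal(unname(st3[c("s3", "s4")]), rep("resistant", 2))
})

test_that("small parsimony handles the canonical cases", {
  tr <- parse_newick("((A,B),(C,D));")
  same <- c(A = "resistant", B = "resistant", C = "resistant",
            D = "resistant")
  expect_equal(fitch_min_changes(tr, same)$min_changes, 0)

  two <- parse_newick("(A,B);")
  expect_equal(fitch_min_changes(two, c(A = "resistant",
                                        B = "sensitive"))$min_changes, 1)

  # clade-structured case: outgroup and one clade sensitive, a second
  # clade resistant, a third mostly resistant with one reversal
  tr8 <- parse_newick("(out,((haw,am),(ea,(eu1,(eu2,eu3)))));")
  st8 <- c(out = "sensitive", haw = "sensitive", am = "sensitive",
           ea = "resistant", eu1 = "resistant", eu2 = "resistant",
           eu3 = "sensitive")
  f <- fitch_min_changes(tr8, st8)
  expect_equal(f$min_changes, oracle_parsimony(tr8, st8))
  expect_error(fitch_min_changes(tr8, st8[-2L]), "haw")
})

test_that("parsimony equals brute force on random trees", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    g <- gen_trait_tree(n, seed = 5000 + i)
    states <- stats::setNames(
      sample(c("resistant", "sensitive"), n, replace = TRUE),
      g$tree$tip.label)
    if (length(unique(states)) == 1L) states[1L] <- "resistant"
    expect_equal(fitch_min_changes(g$tree, states)$min_changes,
                 oracle_parsimony(g$tree, states))
  }
})

test_that("change count is invariant to child order and state relabeling", {
  set.seed(31)
  for (i in 1:20) {
    g <- gen_trait_tree(7, seed = 6000 + i)
    states <- stats::setNames(
      sample(c("resistant", "sensitive"), 7, replace = TRUE),
      g$tree$tip.label)
    base <- fitch_min_changes(g$tree, states)$min_changes
    rot <- ape::rotate(g$tree, node = ape::Ntip(g$tree) + 1L)
    expect_equal(fitch_min_changes(rot, states)$min_changes, base)
    flipped <- stats::setNames(
      ifelse(states == "resistant", "sensitive", "resistant"),
      names(states))
    expect_equal(fitch_min_changes(g$tree, flipped)$min_changes, base)
  }
})

test_that("parsimony count agrees with an established implementation", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(
      sample(c("r", "s"), n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) states[1L] <- "r"
    pd <- phangorn::phyDat(as.matrix(states), type = "USER",
                           levels = c("r", "s"))
    expect_equal(fitch_min_changes(tr, states)$min_changes,
                 phangorn::parsimony(tr, pd))
  }
})

test_that("MPR enumeration finds every minimal reconstruction", {
  # unambiguous star case: one deviant leaf, a single reconstruction
  star <- parse_newick("(A,B,C,D);")
  st <- c(A = "resistant", B = "sensitive", C = "sensitive",
          D = "sensitive")
  m <- enumerate_mprs(star, st)
  expect_equal(m$min_changes, 1)
  expect_length(m$reconstructions, 1L)
  expect_equal(nrow(m$reconstructions[[1L]]$events), 1L)

  # symmetric balanced case: gain vs loss at the root split
  tr <- parse_newick("((A,B),(C,D));")
  st2 <- c(A = "resistant", B = "resistant", C = "sensitive",
           D = "sensitive")
  m2 <- enumerate_mprs(tr, st2)
  expect_length(m2$reconstructions, 2L)
  types <- sort(vapply(m2$reconstructions,
                       function(r) r$events$type[1L], character(1)))
  expect_equal(types, c("gain", "loss"))

  # every reconstruction's event cost equals the minimum
  tr8 <- parse_newick("(out,((haw,am),(ea,(eu1,(eu2,eu3)))));")
  st8 <- c(out = "sensitive", haw = "sensitive", am = "sensitive",
           ea = "resistant", eu1 = "resistant", eu2 = "resistant",
           eu3 = "sensitive")
  m3 <- enumerate_mprs(tr8, st8)
  fit <- fitch_min_changes(tr8, st8)
  for (r in m3$reconstructions) {
    expect_equal(nrow(r$events), fit$min_changes)
  }
  # node_states from the two-pass DP match the union over the MPRs
  ntot <- ape::Ntip(tr8) + tr8$Nnode
  for (v in seq_len(ntot)) {
    in_mprs <- sort(unique(vapply(m3$reconstructions,
                                  function(r) r$node_states[v],
                                  character(1))))
    expect_equal(sort(fit$node_states[[v]]), in_mprs)
  }

  expect_error(enumerate_mprs(tr, st2, cap = 1), "cap")
})

test_that("asymmetric gain/loss weights shift the optimum", {
  # resistant clade with one reversal: equal weights allow loss-based
  # histories, but costly losses force independent gains
  tr <- parse_newick("((A,(B,C)),(D,E));")
  st <- c(A = "sensitive", B = "resistant", C = "resistant",
          D = "resistant", E = "resistant")
  eq <- fitch_min_changes(tr, st, levels = c("sensitive", "resistant"))
  expect_equal(eq$min_changes,
               oracle_parsimony(tr, st, levels = c("sensitive",
                                                   "resistant")))
  heavy_loss <- fitch_min_changes(tr, st,
                                  levels = c("sensitive", "resistant"),
                                  gain_weight = 1, loss_weight = 10)
  expect_equal(heavy_loss$min_changes,
               oracle_parsimony(tr, st,
                                levels = c("sensitive", "resistant"),
                                gain_weight = 1, loss_weight = 10))
  expect_gte(heavy_loss$min_changes, eq$min_changes)
})
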