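# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, full enumeration) and never share code with
# the package paths they check.

# Two-sided exact binomial p by full pmf enumeration, minimum-likelihood
# convention (sum of all outcomes no more probable than the observed one).
oracle_binom_two_sided <- function(x, n, p0 = 0.5) {
  d_obs <- dbinom(x, n, p0)
  total <- 0
  for (k in 0:n) {
    dk <- dbinom(k, n, p0)
    if (dk <= d_obs * (1 + 1e-7)) total <- total + dk
  }
  min(1, total)
}

# One-sided upper binomial tail by summation.
oracle_binom_upper <- function(x, n, p0 = 0.5) {
  total <- 0
  for (k in x:n) total <- total + dbinom(k, n, p0)
  min(1, total)
}

# Upper-tail hypergeometric by enumerating every possible sample of n
# genes out of N (feasible for small N).
oracle_hyper_enum <- function(N, K, n, k) {
  marked <- seq_len(K)
  samples <- utils::combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(samples))) {
    if (sum(samples[, j] %in% marked) >= k) hits <- hits + 1L
  }
  hits / ncol(samples)
}

# Upper-tail hypergeometric by direct summation of the pmf formula.
oracle_hyper_sum <- function(N, K, n, k) {
  total <- 0
  for (i in k:min(K, n)) {
    total <- total + choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }
  total
}

# Maximum window slope by fitting lm() to every window.
oracle_max_window_slope <- function(times, od, window = 20) {
  m <- length(od)
  best <- -Inf
  best_start <- NA_real_
  for (i in seq_len(m - window + 1L)) {
    j <- i:(i + window - 1L)
    sl <- unname(stats::coef(stats::lm(log10(od[j]) ~ I(times[j] / 60)))[2L])
    if (sl > best) {
      best <- sl
      best_start <- times[i]
    }
  }
  list(slope = best, start = best_start)
}

# Minimal weighted change count by exhaustive enumeration of all internal
# state assignments (2^Nnode), counting changes over every edge.
oracle_parsimony <- function(tree, states, levels = NULL,
                             gain_weight = 1, loss_weight = 1) {
  if (is.null(levels)) levels <- sort(unique(as.character(states)))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  leaf_state <- match(states[tree$tip.label], levels)
  best <- Inf
  for (mask in 0:(2^nnode - 1L)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)] + 1L
    full <- c(leaf_state, internal)
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- full[tree$edge[e, 1L]]
      c_ <- full[tree$edge[e, 2L]]
      if (p == 1L && c_ == 2L) cost <- cost + gain_weight
      if (p == 2L && c_ == 1L) cost <- cost + loss_weight
    }
    if (cost < best) best <- cost
  }
  best
}

# A ranked ASE-record table with chosen genes placed at chosen ranks
# (rank 1 = most allele-A-biased). Used to rebuild published sign-test
# configurations from stated ranks.
make_ranked_records <- function(n_genes, member_ranks,
                                member_names = NULL) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  # strictly decreasing log2 ratios, all positive in the top half
  log2r <- seq(4, -4, length.out = n_genes)
  if (!is.null(member_names)) {
    genes[member_ranks] <- member_names
  }
  data.frame(gene = genes, log2_ratio = log2r,
             ratio = 2^log2r, stringsAsFactors = FALSE)
}

# A small allele-count data frame in long format.
make_counts_df <- function(genes, counts_A, counts_B,
                           condition = "cond1", replicate = "rep1") {
  data.frame(gene = rep(genes, 2L),
             allele = rep(c("A", "B"), each = length(genes)),
             condition = condition, replicate = replicate,
             count = c(counts_A, counts_B), stringsAsFactors = FALSE)
}
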