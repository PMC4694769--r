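#' Directional sign test for selection on cis-regulation
#'
#' Under neutral evolution of gene expression, the direction of
#' cis-regulatory divergence (which parental allele is more highly
#' expressed) is random across genes, so a functionally related gene set
#' should not be concentrated among the most allele-A-biased genes, nor
#' show concordant directionality. Two statistics probe this null for a
#' gene set against a ranked ASE universe:
#' \describe{
#'   \item{stratum enrichment}{the set's overlap with the top fraction
#'     `f` of genes most biased in one direction, assessed with the
#'     upper-tail hypergeometric probability ([hypergeom_tail()]);}
#'   \item{directionality bias}{the number of set members whose ASE points
#'     in the given direction at all, assessed with a one-sided binomial
#'     test ([direction_bias_test()]).}
#' }
#' [evaluate_set()] computes both over a grid of strata;
#' [scan_collection()] scans a gene-set collection with Bonferroni
#' correction; [calibrate_null()] checks calibration by drawing random
#' sets.
#'
#' @name sign_test
NULL

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the overlap between a random sample of `n`
#' genes (the tested set) and a fixed stratum of `K` marked genes, drawn
#' without replacement from a universe of `N`. Computed in log space via
#' the hypergeometric distribution function for numerical stability at
#' extreme tails.
#'
#' @param N universe size.
#' @param K stratum (marked) size, `0 <= K <= N`.
#' @param n tested set size, `0 <= n <= N`.
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_tail(N = 4394, K = 44, n = 11, k = 4)  # ~2.7e-6
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' One-sided binomial directionality test
#'
#' `P(X >= n_up)` for `X ~ Binomial(n, p0)`: the probability that at least
#' `n_up` of `n` independent genes have direction-consistent ASE when each
#' gene's direction is a coin flip under the neutral null.
#'
#' @param n_up number of direction-consistent genes.
#' @param n number of genes tested, `n >= 1`.
#' @param p0 null per-gene probability of the direction (default 0.5).
#' @return One-sided p-value.
#' @export
direction_bias_test <- function(n_up, n, p0 = 0.5) {
  if (n < 1) stop("n must be >= 1")
  if (n_up > n || n_up < 0) stop("n_up must be in [0, n]")
  if (n_up == 0) return(1)
  exp(stats::pbinom(n_up - 1, n, p0, lower.tail = FALSE, log.p = TRUE))
}

#' Top ASE stratum of a ranked universe
#'
#' The `K = round(f * N)` genes (half-up rounding) with the most extreme
#' pooled log2 ASE ratio in the given direction. Ties at the stratum
#' boundary are broken lexicographically by gene identifier, so the stratum
#' is deterministic.
#'
#' @param records an `ase_records` data frame ([ase_ratios()]).
#' @param fraction stratum fraction `f`, `0 < f <= 1`.
#' @param direction `"A"` for allele-A-biased (largest `log2_ratio` first)
#'   or `"B"` for allele-B-biased.
#' @return Character vector of the stratum's gene identifiers.
#' @export
top_stratum <- function(records, fraction, direction = c("A", "B")) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  N <- nrow(records)
  if (N == 0L) stop("no ASE records")
  K <- floor(fraction * N + 0.5)  # half-up, not banker's rounding
  if (K == 0L) stop("stratum empty after rounding; increase fraction")
  signed <- if (direction == "A") -records$log2_ratio else records$log2_ratio
  ord <- order(signed, records$gene)
  records$gene[ord[seq_len(K)]]
}

#' Parse a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are dropped.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (members), names are set names.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("empty gene set: ", f[1L])
    if (f[1L] %in% names(sets)) stop("duplicate set name: ", f[1L])
    sets[[f[1L]]] <- members
  }
  sets
}

#' Sign test for one gene set
#'
#' Evaluates a gene set against a ranked ASE universe at each combination
#' of stratum fraction and direction, returning the hypergeometric
#' enrichment p-value and the binomial directionality p-value.
#'
#' Only set members present in the ASE universe count towards `n`. If gene
#' positions are supplied, set members adjacent in the genome (same
#' chromosome, consecutive gene indices) trigger a warning, since the sign
#' test assumes independent cis-regulatory changes; they are not excluded.
#'
#' @param records an `ase_records` data frame.
#' @param gene_set character vector of member gene identifiers.
#' @param fractions stratum fractions to evaluate (default 1%, 5%, 25%).
#' @param directions directions to evaluate (default both).
#' @param set_name label carried into the result.
#' @param gene_positions optional data frame `gene`, `chrom`, `index` used
#'   for the adjacency warning.
#' @return Data frame of class `sign_test_result` with one row per
#'   (fraction, direction): columns `set_name`, `fraction`, `direction`,
#'   `N`, `K`, `n`, `k`, `p_hyper`, `n_up`, `p_binom`.
#' @export
evaluate_set <- function(records, gene_set,
                         fractions = c(0.01, 0.05, 0.25),
                         directions = c("A", "B"),
                         set_name = "set",
                         gene_positions = NULL) {
  gene_set <- unique(as.character(gene_set))
  universe <- records$gene
  members <- intersect(gene_set, universe)
  if (length(members) == 0L) {
    stop("gene set '", set_name, "' has no member in the ASE universe")
  }
  if (!is.null(gene_positions)) {
    gp <- gene_positions[gene_positions$gene %in% members, , drop = FALSE]
    gp <- gp[order(gp$chrom, gp$index), , drop = FALSE]
    if (nrow(gp) >= 2L) {
      adj <- gp$chrom[-1L] == gp$chrom[-nrow(gp)] &
        diff(gp$index) == 1L
      if (any(adj)) {
        warning("set '", set_name, "' contains genomically adjacent ",
                "members: ", paste(gp$gene[which(adj)], collapse = ", "),
                " (and neighbours); the sign test assumes independent ",
                "cis-regulatory changes")
      }
    }
  }
  N <- nrow(records)
  n <- length(members)
  mem_log2 <- records$log2_ratio[match(members, records$gene)]
  out <- list()
  for (dir in directions) {
    n_up <- if (dir == "A") sum(mem_log2 > 0) else sum(mem_log2 < 0)
    for (f in fractions) {
      stratum <- top_stratum(records, f, dir)
      k <- length(intersect(members, stratum))
      out[[length(out) + 1L]] <- data.frame(
        set_name = set_name, fraction = f, direction = dir,
        N = N, K = length(stratum), n = n, k = k,
        p_hyper = hypergeom_tail(N, length(stratum), n, k),
        n_up = n_up,
        p_binom = direction_bias_test(n_up, n),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sign_test_result", "data.frame")
  res
}

#' Scan a gene-set collection with the sign test
#'
#' Applies [evaluate_set()] to every set of a collection and Bonferroni
#' corrects the hypergeometric p-values over all tests performed: the
#' correction factor is (number of sets) x (number of fractions) x
#' (number of directions), the most conservative accounting.
#'
#' @param records an `ase_records` data frame.
#' @param collection named list of character vectors ([read_gmt()]).
#' @param fractions,directions as in [evaluate_set()].
#' @param alpha significance level applied to the adjusted p (default
#'   0.01).
#' @param gene_positions optional, see [evaluate_set()].
#' @return `sign_test_result` data frame over all sets, sorted by
#'   `p_adjusted`, with extra columns `p_adjusted` and `significant`. Sets
#'   with no member in the universe are skipped with a warning.
#' @export
scan_collection <- function(records, collection,
                            fractions = c(0.01, 0.05, 0.25),
                            directions = c("A", "B"),
                            alpha = 0.01,
                            gene_positions = NULL) {
  if (length(collection) == 0L) stop("empty collection")
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    stop("collection must be a named list")
  }
  res <- list()
  for (nm in names(collection)) {
    r <- tryCatch(
      evaluate_set(records, collection[[nm]], fractions, directions,
                   set_name = nm, gene_positions = gene_positions),
      error = function(e) {
        warning("skipping set '", nm, "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(r)) res[[nm]] <- r
  }
  if (length(res) == 0L) stop("no testable set in collection")
  tab <- do.call(rbind, res)
  n_tests <- length(res) * length(fractions) * length(directions)
  tab$p_adjusted <- pmin(1, tab$p_hyper * n_tests)
  tab$significant <- tab$p_adjusted < alpha
  tab <- tab[order(tab$p_adjusted, tab$p_hyper, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("sign_test_result", "data.frame")
  tab
}

#' Permutation calibration of the sign test null
#'
#' Draws `n_perm` random gene sets of size `set_size` from the ASE universe
#' and records both sign-test p-values for each, giving the empirical null
#' distribution under random set membership (equivalently, random
#' directionality of ASE relative to the set). Because both tests are exact
#' and discrete, their null p-values are super-uniform: the empirical
#' type-I error at a nominal level must not exceed it beyond sampling
#' noise, and is typically below it.
#'
#' @param records an `ase_records` data frame.
#' @param set_size size of each random set.
#' @param n_perm number of random sets, at least 100.
#' @param seed integer seed; the draw is reproducible.
#' @param fraction stratum fraction used for `p_hyper` (default 0.01).
#' @param direction direction used (default `"A"`).
#' @param levels nominal levels at which type-I error is reported.
#' @return List with `p_hyper`, `p_binom` (numeric vectors, length
#'   `n_perm`) and `type1`, a data frame of empirical rejection rates per
#'   nominal level for both statistics.
#' @export
calibrate_null <- function(records, set_size, n_perm, seed,
                           fraction = 0.01, direction = "A",
                           levels = c(0.05, 0.01)) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- nrow(records)
  if (set_size > N) stop("set_size exceeds universe size")
  set.seed(as.integer(seed))
  stratum <- top_stratum(records, fraction, direction)
  K <- length(stratum)
  in_stratum <- records$gene %in% stratum
  up <- if (direction == "A") records$log2_ratio > 0 else
    records$log2_ratio < 0
  p_hyper <- numeric(n_perm)
  p_binom <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(N, set_size)
    k <- sum(in_stratum[idx])
    p_hyper[i] <- hypergeom_tail(N, K, set_size, k)
    p_binom[i] <- direction_bias_test(sum(up[idx]), set_size)
  }
  type1 <- do.call(rbind, lapply(levels, function(a) {
    data.frame(level = a,
               rate_hyper = mean(p_hyper < a),
               rate_binom = mean(p_binom < a))
  }))
  list(p_hyper = p_hyper, p_binom = p_binom, type1 = type1)
}
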