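#' Synthetic data generators
#'
#' Every generator draws from a seeded RNG and returns, alongside the
#' dataset, a `truth` element recording the simulation's ground truth so
#' that recovery and calibration can be tested without any external data.
#' Identical seeds give identical output.
#'
#' @name synthetic_data
NULL

#' Simulate an allele-specific count table with an embedded selected set
#'
#' Emulates the structure of a hybrid ASE experiment: a genome-scale gene
#' universe whose background cis-regulatory divergence is symmetric about
#' zero, with one embedded gene set shifted towards allele A — the
#' signature the directional sign test is designed to detect. Gene totals
#' are gamma-Poisson (negative binomial) distributed, with the allele
#' split strictly binomial given the total, matching the assumptions of
#' the exact binomial allele test so calibration checks are fair.
#'
#' Defaults mirror the scale of the motivating study: a 4394-gene universe
#' and an 11-member set shifted by 2 on the log2 scale. The background
#' log2-ASE SD of 0.3 is a tunable realism choice (top ~1% of genes at
#' roughly |log2| 0.9), not an estimate from data.
#'
#' @param n_genes number of genes (default 4394).
#' @param set_size size of the embedded set (default 11).
#' @param set_effect_log2 log2 shift of the set towards allele A
#'   (default 2; 0 gives a fully null table).
#' @param depth_mean mean read total per gene per (condition, replicate)
#'   (default 500).
#' @param dispersion gamma-Poisson overdispersion; 0 means Poisson
#'   (default 0.1).
#' @param conditions,replicates numbers of conditions and replicates
#'   (defaults 2 and 2).
#' @param ase_sd SD of the background true log2 ASE (default 0.3).
#' @param induced_fold if > 1, genes of the embedded set have their
#'   expected totals multiplied by this fold in the last condition,
#'   emulating a treatment response of the set (default 1 = off).
#' @param seed integer seed.
#' @return List with `table` (an [allele_count_table()]) and `truth`
#'   (per-gene `true_log2_ase`, the member `set`, and the parameters).
#' @export
gen_ase_counts <- function(n_genes = 4394, set_size = 11,
                           set_effect_log2 = 2.0, depth_mean = 500,
                           dispersion = 0.1, conditions = 2,
                           replicates = 2, ase_sd = 0.3,
                           induced_fold = 1, seed) {
  if (set_size > n_genes) stop("set_size exceeds n_genes")
  if (depth_mean <= 0 || dispersion < 0) stop("invalid depth parameters")
  set.seed(as.integer(seed))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  true_log2 <- stats::rnorm(n_genes, 0, ase_sd)
  members <- sample(genes, set_size)
  idx <- match(members, genes)
  true_log2[idx] <- true_log2[idx] + set_effect_log2
  pA <- 2^true_log2 / (1 + 2^true_log2)

  cond_ids <- paste0("cond", seq_len(conditions))
  rep_ids <- paste0("rep", seq_len(replicates))
  rows <- vector("list", conditions * replicates)
  i <- 0L
  for (cond in cond_ids) {
    fold <- rep(1, n_genes)
    if (induced_fold != 1 && cond == cond_ids[conditions]) {
      fold[idx] <- induced_fold
    }
    for (rp in rep_ids) {
      i <- i + 1L
      mu <- depth_mean * fold
      total <- if (dispersion > 0) {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(n_genes, mu)
      }
      a <- stats::rbinom(n_genes, total, pA)
      rows[[i]] <- data.frame(
        gene = rep(genes, 2L),
        allele = rep(c("A", "B"), each = n_genes),
        condition = cond, replicate = rp,
        count = c(a, total - a), stringsAsFactors = FALSE)
    }
  }
  tab <- allele_count_table(do.call(rbind, rows))
  list(table = tab,
       truth = list(true_log2_ase = stats::setNames(true_log2, genes),
                    set = members, set_effect_log2 = set_effect_log2,
                    induced_fold = induced_fold, seed = seed))
}

#' Simulate plate-reader growth curves
#'
#' Logistic growth with a lag phase, sampled at a fixed reading interval
#' with additive Gaussian measurement noise floored at 0.001 OD.
#' Parameters default to a realistic yeast plate-reader run: carrying
#' capacity 1.5 OD, intrinsic rate 0.006 per minute, 120-minute lag,
#' inoculum 0.025 OD, 12-minute readings over 48 hours.
#'
#' @param K carrying capacity (OD600).
#' @param r intrinsic growth rate (per minute).
#' @param lag lag time (minutes).
#' @param od0 inoculum density (OD600).
#' @param interval reading interval (minutes).
#' @param duration run length (minutes).
#' @param noise_sd SD of additive Gaussian OD noise (default 0.005).
#' @param n_wells number of replicate wells (default 1).
#' @param seed integer seed.
#' @return List with `curves` (list of [growth_curve()], wells named
#'   `"W1"`, ...) and `truth` (the parameters, including the analytic
#'   early-phase slope `r * log10(e) * 60` in log10 OD per hour).
#' @export
gen_growth_curves <- function(K = 1.5, r = 0.006, lag = 120, od0 = 0.025,
                              interval = 12, duration = 2880,
                              noise_sd = 0.005, n_wells = 1, seed) {
  if (any(c(K, r, od0, interval, duration) <= 0)) {
    stop("parameters must be positive")
  }
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = interval)
  t_eff <- pmax(times - lag, 0)
  det <- K * od0 * exp(r * t_eff) / (K + od0 * (exp(r * t_eff) - 1))
  curves <- list()
  for (w in seq_len(n_wells)) {
    od <- det + stats::rnorm(length(times), 0, noise_sd)
    od <- pmax(od, 0.001)
    curves[[paste0("W", w)]] <- growth_curve(times, od,
                                             well = paste0("W", w))
  }
  list(curves = curves,
       truth = list(K = K, r = r, lag = lag, od0 = od0,
                    max_slope_log10_per_hr = r * log10(exp(1)) * 60,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a pooled barcode competition
#'
#' Strains start at equal frequencies (the even-mixture pooling of the
#' assay), then change deterministically over `generations` doublings as
#' `f_i proportional to f_i * exp(s_i * T)`. Barcode counts at both
#' timepoints are multinomial draws at the given sequencing depth, with
#' each strain's frequency split evenly among its barcodes. Optionally
#' emits synthetic reads embedding each barcode between its flanks for
#' testing the exact-matching counter.
#'
#' @param s named numeric vector of true per-generation selection
#'   coefficients, one per strain; must include a strain named
#'   `"control"` or a `control` argument naming one.
#' @param generations doublings elapsed (default 40).
#' @param depth sequencing depth per sample (default 1e5).
#' @param barcodes_per_strain barcodes per strain (default 3).
#' @param replicates number of replicate competitions (default 12).
#' @param seed integer seed.
#' @param emit_reads if `TRUE`, also return character vectors of reads
#'   (flank5+barcode+flank3 embedded in filler sequence) per sample.
#' @return List with `map` (a [barcode_map()]), `samples` (per replicate:
#'   `initial` and `final` named barcode-count vectors, plus reads if
#'   requested) and `truth` (the `s` vector and parameters).
#' @export
gen_competition <- function(s, generations = 40, depth = 1e5,
                            barcodes_per_strain = 3, replicates = 12,
                            seed, emit_reads = FALSE) {
  if (any(!is.finite(s))) stop("s must be finite")
  if (is.null(names(s))) stop("s must be named by strain")
  set.seed(as.integer(seed))
  n_strains <- length(s)
  # barcodes: enumerate 6-mers over a 3-letter alphabet spaced >= 2 apart
  # by construction (differ in >= 2 positions via a parity digit)
  alphabet <- c("A", "C", "G")
  pool <- character(0)
  i <- 0L
  while (length(pool) < n_strains * barcodes_per_strain) {
    digits <- integer(5)
    x <- i
    for (d in 1:5) { digits[d] <- x %% 3L; x <- x %/% 3L }
    parity <- sum(digits) %% 3L
    pool <- c(pool, paste(alphabet[c(digits, parity) + 1L], collapse = ""))
    i <- i + 1L
  }
  map <- barcode_map(pool,
                     strain = rep(names(s), each = barcodes_per_strain),
                     flank_5 = "TTGACC", flank_3 = "GGTCAA")
  f0_strain <- rep(1 / n_strains, n_strains)
  fT_strain <- f0_strain * exp(s * generations)
  fT_strain <- fT_strain / sum(fT_strain)
  per_bc <- function(fs) rep(fs / barcodes_per_strain,
                             each = barcodes_per_strain)
  p0 <- per_bc(f0_strain)
  pT <- per_bc(fT_strain)

  make_reads <- function(counts) {
    pats <- paste0(map$flank_5, map$barcode, map$flank_3)
    unlist(mapply(function(pat, k) {
      if (k == 0) return(character(0))
      pre <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                   collapse = "")
      rep(paste0(pre, pat, "ACGT"), k)
    }, pats, counts, SIMPLIFY = FALSE), use.names = FALSE)
  }

  samples <- lapply(seq_len(replicates), function(rp) {
    ci <- stats::rmultinom(1, depth, p0)[, 1L]
    cf <- stats::rmultinom(1, depth, pT)[, 1L]
    names(ci) <- names(cf) <- map$barcode
    out <- list(initial = ci, final = cf)
    if (emit_reads) {
      out$initial_reads <- make_reads(ci)
      out$final_reads <- make_reads(cf)
    }
    out
  })
  list(map = map, samples = samples,
       truth = list(s = s, generations = generations, depth = depth,
                    barcodes_per_strain = barcodes_per_strain,
                    replicates = replicates, seed = seed))
}

#' Simulate a binary trait history on a random tree
#'
#' Draws a random rooted topology, then propagates a binary trait from the
#' root (state `"sensitive"`), applying the requested gain and loss events
#' on the branches leading to named internal nodes or leaves. The truth
#' records exactly which branches carry events, so parsimony recovery can
#' be checked against a known history.
#'
#' @param n_leaves number of leaves.
#' @param events data frame with columns `node` (a leaf label such as
#'   `"t3"`, or an internal node label `"n<k>"` where `k` is the phylo
#'   node number) and `type` (`"gain"` or `"loss"`). Events apply to the
#'   branch above the node. A loss on a lineage that has not gained the
#'   trait (or a second gain) is an inconsistency error.
#' @param seed integer seed (controls the topology).
#' @return List with `tree` (phylo, internal nodes labelled), `states`
#'   (named leaf vector, `"resistant"`/`"sensitive"`) and `truth` (the
#'   event table and seed).
#' @export
gen_trait_tree <- function(n_leaves, events = NULL, seed) {
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  ntip <- ape::Ntip(tree)
  tree$node.label <- paste0("n", (ntip + 1L):(ntip + tree$Nnode))
  label_to_node <- c(stats::setNames(seq_len(ntip), tree$tip.label),
                     stats::setNames((ntip + 1L):(ntip + tree$Nnode),
                                     tree$node.label))
  ev_node <- integer(0)
  ev_type <- character(0)
  if (!is.null(events) && nrow(events) > 0L) {
    if (!all(events$node %in% names(label_to_node))) {
      stop("unknown node label in events")
    }
    ev_node <- unname(label_to_node[events$node])
    ev_type <- events$type
    if (anyDuplicated(ev_node)) stop("multiple events on one branch")
  }
  kids <- .children_of(tree)
  state <- rep(NA_integer_, ntip + tree$Nnode)  # 0 sensitive, 1 resistant
  root <- ntip + 1L
  state[root] <- 0L
  walk <- function(v) {
    for (c_ in kids[[v]]) {
      st <- state[v]
      hit <- which(ev_node == c_)
      if (length(hit) == 1L) {
        if (ev_type[hit] == "gain") {
          if (st == 1L) stop("gain on an already-resistant lineage")
          st <- 1L
        } else {
          if (st == 0L) stop("loss before any gain on this lineage")
          st <- 0L
        }
      }
      state[c_] <<- st
      walk(c_)
    }
  }
  walk(root)
  states <- ifelse(state[seq_len(ntip)] == 1L, "resistant", "sensitive")
  names(states) <- tree$tip.label
  list(tree = tree, states = states,
       truth = list(events = if (length(ev_node) > 0L) {
       data.frame(node = ev_node, type = ev_type,
                  stringsAsFactors = FALSE)
     } else {
       data.frame(node = integer(0), type = character(0))
     }, seed = seed))
}
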