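#' Barcode-to-strain map
#'
#' Strains in a pooled competition are tagged by short plasmid barcodes
#' (several per strain, to average out barcode-specific biases) read out by
#' amplicon sequencing. The map records each barcode with its strain and
#' the fixed flanking sequences used for exact matching.
#'
#' @param barcode character vector of barcode sequences, all the same
#'   length (`barcode_length`), unique, pairwise Hamming distance >= 2.
#' @param strain strain label per barcode.
#' @param flank_5,flank_3 fixed flanking sequences (recycled if scalar).
#' @param barcode_length expected barcode length (default 6).
#' @return Data frame of class `barcode_map`.
#' @export
barcode_map <- function(barcode, strain, flank_5, flank_3,
                        barcode_length = 6) {
  barcode <- toupper(as.character(barcode))
  if (anyDuplicated(barcode)) stop("duplicate barcode(s)")
  if (any(nchar(barcode) != barcode_length)) {
    stop("all barcodes must be ", barcode_length, " bases")
  }
  n <- length(barcode)
  flank_5 <- rep_len(toupper(flank_5), n)
  flank_3 <- rep_len(toupper(flank_3), n)
  # pairwise Hamming distance >= 2 so one sequencing error cannot convert
  # one barcode into another
  if (n > 1L) {
    mat <- do.call(rbind, strsplit(barcode, ""))
    for (i in seq_len(n - 1L)) {
      d <- rowSums(mat[(i + 1L):n, , drop = FALSE] !=
                     matrix(mat[i, ], n - i, barcode_length, byrow = TRUE))
      if (any(d < 2)) {
        stop("barcodes '", barcode[i], "' and '",
             barcode[i + which(d < 2)[1L]], "' are fewer than 2 ",
             "substitutions apart")
      }
    }
  }
  pattern <- paste0(flank_5, barcode, flank_3)
  if (anyDuplicated(pattern)) {
    stop("barcode collision after flank concatenation")
  }
  structure(data.frame(barcode = barcode, strain = as.character(strain),
                       flank_5 = flank_5, flank_3 = flank_3,
                       stringsAsFactors = FALSE),
            class = c("barcode_map", "data.frame"))
}

#' Read a barcode map from TSV
#'
#' Expects columns `barcode,strain,flank5,flank3`.
#'
#' @param path TSV file path.
#' @param barcode_length expected barcode length (default 6).
#' @return A [barcode_map()].
#' @export
read_barcode_map <- function(path, barcode_length = 6) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "strain", "flank5", "flank3")
  if (!all(need %in% names(df))) {
    stop("barcode map needs columns: ", paste(need, collapse = ", "))
  }
  barcode_map(df$barcode, df$strain, df$flank5, df$flank3,
              barcode_length = barcode_length)
}

#' Count barcodes in sequencing reads by exact matching
#'
#' A read is assigned to a barcode only if it contains, anywhere, a perfect
#' match to that barcode's full `flank_5 + barcode + flank_3` pattern. Each
#' read contributes at most one count; reads matching no pattern — or,
#' degenerately, more than one — are tallied as unmatched.
#'
#' @param reads either a character vector of read sequences or the path to
#'   a FASTQ file (read with Biostrings).
#' @param map a [barcode_map()].
#' @return List with `counts` (named integer vector, one entry per barcode
#'   in map order) and `unmatched` (integer).
#' @export
match_barcodes <- function(reads, map) {
  stopifnot(inherits(map, "barcode_map"))
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  }
  reads <- toupper(as.character(reads))
  patterns <- paste0(map$flank_5, map$barcode, map$flank_3)
  counts <- integer(nrow(map))
  names(counts) <- map$barcode
  if (length(reads) == 0L) return(list(counts = counts, unmatched = 0L))
  hit <- matrix(FALSE, length(reads), nrow(map))
  for (j in seq_along(patterns)) {
    hit[, j] <- grepl(patterns[j], reads, fixed = TRUE)
  }
  n_hits <- rowSums(hit)
  for (j in seq_along(patterns)) {
    counts[j] <- sum(hit[, j] & n_hits == 1L)
  }
  list(counts = counts, unmatched = sum(n_hits != 1L))
}

#' Strain relative abundances from barcode counts
#'
#' Sums each strain's barcode counts and divides by the total matched
#' reads; frequencies sum to 1.
#'
#' @param counts named numeric vector of barcode counts (names are
#'   barcodes present in `map`).
#' @param map a [barcode_map()].
#' @return Named numeric vector of per-strain frequencies.
#' @export
strain_frequencies <- function(counts, map) {
  stopifnot(inherits(map, "barcode_map"))
  unknown <- setdiff(names(counts), map$barcode)
  if (length(unknown) > 0L) {
    stop("counts keyed by unknown barcode(s): ",
         paste(unknown, collapse = ", "))
  }
  total <- sum(counts)
  if (total <= 0) stop("zero total matched reads")
  strains <- unique(map$strain)
  freq <- vapply(strains, function(s) {
    sum(counts[names(counts) %in% map$barcode[map$strain == s]]) / total
  }, numeric(1))
  names(freq) <- strains
  freq
}

#' Per-generation selection coefficient from frequency ratios
#'
#' With `R = f_strain / f_control` the relative abundance of a strain
#' against the control, the selection coefficient per generation (natural
#' log scale per doubling) is `s = ln(R_final / R_initial) / T` over `T`
#' doublings. A strain ending 20% less abundant than the control after 40
#' generations has s = ln(0.80)/40 ~ -0.56% per generation.
#'
#' @param freq_ratio_initial,freq_ratio_final strain/control frequency
#'   ratios at the start and end of the competition; must be positive.
#' @param generations number of culture doublings `T` (> 0).
#' @return The selection coefficient `s` (dimensionless, per generation).
#' @export
fitness_per_generation <- function(freq_ratio_initial, freq_ratio_final,
                                   generations) {
  if (any(c(freq_ratio_initial, freq_ratio_final) <= 0)) {
    stop("frequency ratios must be positive")
  }
  if (generations <= 0) stop("generations must be positive")
  log(freq_ratio_final / freq_ratio_initial) / generations
}

#' Culture doublings under a serial-dilution scheme
#'
#' Cultures grown from `od_start` to `od_trigger`, with `n_dilutions`
#' transfers of `v_transfer` microlitres into `v_well` microlitres of fresh
#' medium, each followed by regrowth to the trigger OD. Total doublings:
#' `log2(od_trigger/od_start) + n_dilutions * log2((v_transfer+v_well)/v_transfer)`.
#' The study's scheme (0.025 to 0.76, 23 ul into 700 ul, 7 dilutions)
#' gives ~39.7, i.e. approximately 40 doublings.
#'
#' @param od_start initial OD after the first dilution.
#' @param od_trigger OD at which a transfer is made.
#' @param v_transfer,v_well transfer and well volumes (microlitres).
#' @param n_dilutions number of dilutions performed.
#' @return Estimated number of doublings.
#' @export
estimate_generations <- function(od_start, od_trigger, v_transfer, v_well,
                                 n_dilutions) {
  if (v_transfer <= 0 || v_well <= 0) stop("volumes must be positive")
  if (od_start <= 0 || od_trigger <= 0) stop("ODs must be positive")
  dilution_factor <- (v_transfer + v_well) / v_transfer
  if (od_trigger <= od_start / dilution_factor) {
    stop("od_trigger must exceed the post-dilution OD")
  }
  log2(od_trigger / od_start) + n_dilutions * log2(dilution_factor)
}

#' Aggregate barcode-level fitness into a strain estimate
#'
#' Within each replicate, the barcode-level selection coefficients of one
#' strain are averaged (unweighted mean across its barcodes); across
#' replicates, the mean and its standard error are reported.
#'
#' @param per_barcode_s list with one numeric vector per replicate, each
#'   holding that replicate's barcode-level `s` values for the strain.
#' @param strain,condition labels carried into the estimate.
#' @return List of class `fitness_estimate`: `strain`, `condition`, `s`,
#'   `se`, `n_replicates`, `replicate_s`.
#' @export
aggregate_fitness <- function(per_barcode_s, strain = NA_character_,
                              condition = NA_character_) {
  if (length(per_barcode_s) < 1L) stop("at least one replicate required")
  rep_s <- vapply(per_barcode_s, mean, numeric(1))
  n <- length(rep_s)
  se <- if (n > 1L) stats::sd(rep_s) / sqrt(n) else 0
  structure(list(strain = strain, condition = condition,
                 s = mean(rep_s), se = se, n_replicates = n,
                 replicate_s = rep_s),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("fitness_estimate: strain %s, condition %s: s = %+0.4f%% ",
              x$strain, x$condition, 100 * x$s),
      sprintf("per generation (SE %0.4f%%, %d replicates)\n",
              100 * x$se, x$n_replicates))
  invisible(x)
}

#' Replicate-level selection coefficients from a pair of count samples
#'
#' Convenience route from barcode counts to barcode-level `s`: for each
#' barcode of `strain`, its frequency relative to the summed frequency of
#' the control strain is formed at both timepoints and passed through
#' [fitness_per_generation()]. Zero final barcode counts are replaced by
#' 0.5 (continuity correction) with a warning.
#'
#' @param initial_counts,final_counts named numeric vectors of barcode
#'   counts at the two timepoints.
#' @param map a [barcode_map()].
#' @param strain strain whose fitness is estimated.
#' @param control control strain name.
#' @param generations doublings elapsed between the samples.
#' @return Numeric vector of barcode-level `s` for the strain's barcodes.
#' @export
barcode_fitness <- function(initial_counts, final_counts, map, strain,
                            control, generations) {
  stopifnot(inherits(map, "barcode_map"))
  for (s in c(strain, control)) {
    if (!s %in% map$strain) stop("strain '", s, "' not in map")
  }
  fix_zero <- function(x) {
    if (any(x == 0)) {
      warning("zero barcode count(s) replaced by 0.5")
      x[x == 0] <- 0.5
    }
    x
  }
  bc <- map$barcode[map$strain == strain]
  ctrl_bc <- map$barcode[map$strain == control]
  ci <- fix_zero(initial_counts[bc]); cf <- fix_zero(final_counts[bc])
  ctrl_i <- sum(fix_zero(initial_counts[ctrl_bc]))
  ctrl_f <- sum(fix_zero(final_counts[ctrl_bc]))
  tot_i <- sum(initial_counts); tot_f <- sum(final_counts)
  r0 <- (ci / tot_i) / (ctrl_i / tot_i)
  rT <- (cf / tot_f) / (ctrl_f / tot_f)
  vapply(seq_along(bc), function(j) {
    fitness_per_generation(r0[j], rT[j], generations)
  }, numeric(1))
}

#' Compare replicate-level fitness between two conditions
#'
#' Welch's two-sample t-test on replicate-level selection coefficients;
#' used to ask whether a strain's fitness differs between, e.g., toxin and
#' no-toxin conditions.
#'
#' @param estimates_condA,estimates_condB numeric vectors of
#'   replicate-level `s` (at least 2 each).
#' @return List with `t`, `df`, `p_value`, `mean_A`, `mean_B`.
#' @export
condition_contrast <- function(estimates_condA, estimates_condB) {
  if (length(estimates_condA) < 2L || length(estimates_condB) < 2L) {
    stop("at least 2 replicates per condition required")
  }
  tt <- stats::t.test(estimates_condA, estimates_condB,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_A = mean(estimates_condA), mean_B = mean(estimates_condB))
}
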