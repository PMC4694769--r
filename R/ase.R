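#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests whether reads from the two alleles of a gene deviate from a null
#' proportion `p0` (0.5 for no allelic imbalance). The two-sided p-value is
#' the minimum-likelihood convention: the sum of the probabilities of all
#' outcomes whose point probability does not exceed that of the observed
#' outcome. At `p0 = 0.5` this is symmetric in the two counts.
#'
#' @param count_A,count_B read counts for the two alleles (A is the allele
#'   of the lineage under test, e.g. the S. paradoxus allele of a hybrid).
#' @param p0 null proportion of allele-A reads, strictly inside (0, 1).
#' @return Two-sided p-value.
#' @export
binom_allele_test <- function(count_A, count_B, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be inside (0, 1)")
  n <- count_A + count_B
  if (n < 1) stop("count_A + count_B must be >= 1")
  stats::binom.test(count_A, n, p = p0)$p.value
}

#' Exact binomial test for a treatment response
#'
#' Tests whether a gene's (or allele's) read count changed between a treated
#' and an untreated library, against the null that the treated fraction of
#' its reads equals the treated fraction of the total library:
#' `p0 = lib_treated / (lib_treated + lib_untreated)`. This is the exact
#' analogue of a library-size-normalised fold-change test and is applied
#' per biological replicate.
#'
#' @param count_treated,count_untreated the gene's read counts in each
#'   library.
#' @param lib_treated,lib_untreated total mapped reads of each library.
#' @return Two-sided p-value (minimum-likelihood convention).
#' @export
binom_response_test <- function(count_treated, count_untreated,
                                lib_treated, lib_untreated) {
  if (lib_treated <= 0 || lib_untreated <= 0) {
    stop("library sizes must be positive")
  }
  if (count_treated > lib_treated || count_untreated > lib_untreated) {
    stop("count exceeds its library size")
  }
  n <- count_treated + count_untreated
  if (n < 1) stop("count sum must be >= 1")
  p0 <- lib_treated / (lib_treated + lib_untreated)
  stats::binom.test(count_treated, n, p = p0)$p.value
}

#' Library-size-normalised response fold change
#'
#' `(count_treated/lib_treated) / (count_untreated/lib_untreated)`; the
#' expression ratio of a gene (or allele) between a treated and an untreated
#' library after normalising both counts by their library sizes.
#'
#' No pseudocount is applied: zero counts are an error, matching the
#' coverage-filter-first policy of the pipeline. A pseudocount can be opted
#' into explicitly.
#'
#' @inheritParams binom_response_test
#' @param pseudocount value added to both counts before the ratio
#'   (default 0, i.e. off).
#' @return Fold change (dimensionless, > 0).
#' @export
response_fold_change <- function(count_treated, count_untreated,
                                 lib_treated, lib_untreated,
                                 pseudocount = 0) {
  if (lib_treated <= 0 || lib_untreated <= 0) {
    stop("library sizes must be positive")
  }
  ct <- count_treated + pseudocount
  cu <- count_untreated + pseudocount
  if (ct <= 0 || cu <= 0) {
    stop("zero count; filter first or set a pseudocount explicitly")
  }
  (ct / lib_treated) / (cu / lib_untreated)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment over the supplied p-values. The q-values
#' are computed over exactly the vector given, so callers must pass the full
#' filtered gene universe, not a subset.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; `NaN`/`NA` is an
#'   error (filter first).
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values))) stop("NA/NaN p-values not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Allele-specific expression ratios with allele-bias tests
#'
#' Computes, for every gene of a coverage-filtered table, the ASE ratio for
#' one condition: reads mapping to allele A divided by reads mapping to
#' allele B, with replicates pooled by summation before the ratio. Each gene
#' also gets an exact binomial allele-bias p-value ([binom_allele_test()])
#' and a BH q-value computed over the filtered universe.
#'
#' @param table an [allele_count_table()] that has already been through
#'   [filter_min_coverage()]; any zero pooled allele count is an error.
#' @param condition condition identifier.
#' @param allele_A,allele_B the allele codes taking the numerator and
#'   denominator roles (defaults `"A"` and `"B"`).
#' @param tests compute the binomial p and BH q columns (default `TRUE`);
#'   set `FALSE` when only the ratios and ranks are needed, e.g. in large
#'   simulation loops.
#' @return A data frame of class `ase_records` with columns `gene`,
#'   `count_A`, `count_B`, `ratio`, `log2_ratio`, `p_value`, `q_value`, one
#'   row per gene.
#' @export
ase_ratios <- function(table, condition, allele_A = "A", allele_B = "B",
                       tests = TRUE) {
  stopifnot(inherits(table, "allele_count_table"))
  cc <- table$counts[table$counts$condition == condition, , drop = FALSE]
  if (nrow(cc) == 0L) stop("condition '", condition, "' not present")
  pooled <- stats::aggregate(count ~ gene + allele, data = cc, FUN = sum,
                             na.rm = TRUE)
  a <- pooled[pooled$allele == allele_A, c("gene", "count")]
  b <- pooled[pooled$allele == allele_B, c("gene", "count")]
  names(a)[2L] <- "count_A"
  names(b)[2L] <- "count_B"
  rec <- merge(a, b, by = "gene")
  if (any(rec$count_A == 0 | rec$count_B == 0)) {
    stop("zero pooled allele count for gene '",
         rec$gene[rec$count_A == 0 | rec$count_B == 0][1L],
         "'; run filter_min_coverage() first")
  }
  rec <- rec[order(rec$gene), , drop = FALSE]
  rec$ratio <- rec$count_A / rec$count_B
  rec$log2_ratio <- log2(rec$count_A) - log2(rec$count_B)
  if (tests) {
    rec$p_value <- mapply(binom_allele_test, rec$count_A, rec$count_B)
    rec$q_value <- bh_fdr(rec$p_value)
  } else {
    rec$p_value <- NA_real_
    rec$q_value <- NA_real_
  }
  rownames(rec) <- NULL
  class(rec) <- c("ase_records", "data.frame")
  rec
}

#' Per-replicate, per-allele treatment response records
#'
#' For each gene, allele and biological replicate, computes the
#' library-size-normalised fold change of expression between a treated and
#' an untreated condition, and an exact binomial response p-value
#' ([binom_response_test()]). Responses are deliberately kept per replicate
#' (not pooled): downstream candidate selection requires the response to be
#' significant in each biological replicate of each allele.
#'
#' @param table an [allele_count_table()] covering both conditions.
#' @param treated,untreated condition identifiers.
#' @return Data frame of class `response_records` with columns `gene`,
#'   `allele`, `replicate`, `fold_change`, `p_value`. Genes with a zero
#'   count in either condition of a replicate get `NA` fold change and
#'   p-value for that replicate.
#' @export
response_records <- function(table, treated, untreated) {
  stopifnot(inherits(table, "allele_count_table"))
  for (cond in c(treated, untreated)) {
    if (!cond %in% table$counts$condition) {
      stop("condition '", cond, "' not present")
    }
  }
  libs <- table$library_sizes
  lib_of <- function(allele, condition, replicate) {
    v <- libs$lib_size[libs$allele == allele & libs$condition == condition &
                         libs$replicate == replicate]
    if (length(v) != 1L) stop("no library size for (", allele, ", ",
                              condition, ", ", replicate, ")")
    v
  }
  tr <- table$counts[table$counts$condition == treated, , drop = FALSE]
  un <- table$counts[table$counts$condition == untreated, , drop = FALSE]
  m <- merge(tr[, c("gene", "allele", "replicate", "count")],
             un[, c("gene", "allele", "replicate", "count")],
             by = c("gene", "allele", "replicate"),
             suffixes = c("_t", "_u"))
  m <- m[order(m$gene, m$allele, m$replicate), , drop = FALSE]
  n <- nrow(m)
  fc <- rep(NA_real_, n)
  pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lt <- lib_of(m$allele[i], treated, m$replicate[i])
    lu <- lib_of(m$allele[i], untreated, m$replicate[i])
    ct <- m$count_t[i]
    cu <- m$count_u[i]
    if (is.na(ct) || is.na(cu) || ct == 0 || cu == 0) next
    fc[i] <- response_fold_change(ct, cu, lt, lu)
    pv[i] <- binom_response_test(ct, cu, lt, lu)
  }
  out <- data.frame(gene = m$gene, allele = m$allele,
                    replicate = m$replicate,
                    fold_change = fc, p_value = pv,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_records", "data.frame")
  out
}

#' Write ASE or response records to TSV
#'
#' @param records a data frame (`ase_records` or `response_records`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  df <- as.data.frame(records)
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
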