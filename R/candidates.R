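#' Candidate selection criteria
#'
#' Thresholds for calling a gene a candidate adaptation gene: strong
#' allele-A-biased ASE combined with strong, statistically solid induction
#' of both alleles by the treatment. Defaults are 4-fold on both axes and a
#' per-replicate response p of 1e-5, with both alleles required.
#'
#' @param min_ase_fold minimum pooled ASE ratio (allele A over B), > 1.
#' @param min_induction_fold minimum allele-minimum induction fold, > 1.
#' @param require_both_alleles must every replicate of both alleles pass
#'   the response p threshold? (If `FALSE`, only allele A is required.)
#' @param max_response_p per-replicate response p-value ceiling, in (0, 1].
#' @return List of class `candidate_criteria`.
#' @export
candidate_criteria <- function(min_ase_fold = 4, min_induction_fold = 4,
                               require_both_alleles = TRUE,
                               max_response_p = 1e-5) {
  if (min_ase_fold <= 1 || min_induction_fold <= 1) {
    stop("fold thresholds must exceed 1")
  }
  if (max_response_p <= 0 || max_response_p > 1) {
    stop("max_response_p must be in (0, 1]")
  }
  structure(list(min_ase_fold = min_ase_fold,
                 min_induction_fold = min_induction_fold,
                 require_both_alleles = isTRUE(require_both_alleles),
                 max_response_p = max_response_p),
            class = "candidate_criteria")
}

#' Conservative per-gene response fold
#'
#' The smaller of the two alleles' response fold changes; using the minimum
#' means a gene only counts as induced if both alleles are induced at least
#' that much.
#'
#' @param response_A,response_B fold changes of the two alleles (> 0).
#' @return The smaller fold.
#' @export
allele_min_response <- function(response_A, response_B) {
  if (any(c(response_A, response_B) <= 0)) stop("folds must be positive")
  pmin(response_A, response_B)
}

#' Select candidate adaptation genes
#'
#' Joint thresholding on ASE bias and treatment response (the
#' two-dimensional quadrant logic): a gene is selected when its pooled ASE
#' ratio is at least `min_ase_fold` allele-A-biased, its allele-minimum
#' response fold ([allele_min_response()], computed from replicate-pooled
#' per-allele folds) is at least `min_induction_fold`, and every
#' per-replicate response p-value of every required allele is at most
#' `max_response_p`. All fold thresholds are inclusive.
#'
#' Alongside the selection, a census of the four quadrants of the
#' (log2 ASE, log2 min-response) plane is returned at the same fold
#' thresholds (A-biased/induced, B-biased/induced, A-biased/repressed,
#' B-biased/repressed), with the p criterion applied throughout;
#' repression is judged on the allele-maximum fold (both alleles down).
#'
#' @param ase an `ase_records` data frame ([ase_ratios()]).
#' @param responses a `response_records` data frame ([response_records()]).
#' @param criteria a [candidate_criteria()] list.
#' @param near_miss_margin report genes failing exactly one fold criterion
#'   by at most this relative margin (default 0.10). Near misses are
#'   reported, never auto-selected.
#' @return List with `candidates` (character vector), `table` (per-gene
#'   data frame: `gene`, `ase_fold`, `min_response_fold`, `worst_p`,
#'   `selected`, `quadrant`), `census` (named integer vector over the four
#'   quadrants) and `near_misses` (character vector).
#' @export
select_candidates <- function(ase, responses, criteria = candidate_criteria(),
                              near_miss_margin = 0.10) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  shared <- intersect(ase$gene, responses$gene)
  if (length(shared) == 0L) stop("ase and responses share no genes")

  alleles <- unique(responses$allele)
  need_alleles <- if (criteria$require_both_alleles) alleles else "A"

  per_gene <- lapply(shared, function(g) {
    r <- responses[responses$gene == g, , drop = FALSE]
    # replicate-pooled fold per allele: geometric mean across replicates
    folds <- tapply(r$fold_change, r$allele, function(x) {
      if (any(is.na(x))) NA_real_ else exp(mean(log(x)))
    })
    ps <- r$p_value[r$allele %in% need_alleles]
    worst_p <- if (any(is.na(ps))) NA_real_ else max(ps)
    fa <- folds[["A"]]
    fb <- if ("B" %in% names(folds)) folds[["B"]] else folds[["A"]]
    min_fold <- if (is.na(fa) || is.na(fb)) NA_real_ else
      allele_min_response(fa, fb)
    max_fold <- if (is.na(fa) || is.na(fb)) NA_real_ else max(fa, fb)
    data.frame(gene = g, min_response_fold = min_fold,
               max_response_fold = max_fold, worst_p = worst_p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_gene)
  tab$ase_fold <- ase$ratio[match(tab$gene, ase$gene)]

  p_ok <- !is.na(tab$worst_p) & tab$worst_p <= criteria$max_response_p
  ase_A <- tab$ase_fold >= criteria$min_ase_fold
  ase_B <- tab$ase_fold <= 1 / criteria$min_ase_fold
  ind <- !is.na(tab$min_response_fold) &
    tab$min_response_fold >= criteria$min_induction_fold
  rep_ <- !is.na(tab$max_response_fold) &
    tab$max_response_fold <= 1 / criteria$min_induction_fold

  quadrant <- rep(NA_character_, nrow(tab))
  quadrant[ase_A & ind & p_ok] <- "A_biased_induced"
  quadrant[ase_B & ind & p_ok] <- "B_biased_induced"
  quadrant[ase_A & rep_ & p_ok] <- "A_biased_repressed"
  quadrant[ase_B & rep_ & p_ok] <- "B_biased_repressed"
  tab$quadrant <- quadrant
  tab$selected <- !is.na(quadrant) & quadrant == "A_biased_induced"

  census <- vapply(c("A_biased_induced", "B_biased_induced",
                     "A_biased_repressed", "B_biased_repressed"),
                   function(q) sum(quadrant == q, na.rm = TRUE),
                   integer(1))

  # near miss: passes all but one fold criterion, misses it by <= margin
  ase_near <- !ase_A & tab$ase_fold >=
    criteria$min_ase_fold * (1 - near_miss_margin)
  ind_near <- !ind & !is.na(tab$min_response_fold) &
    tab$min_response_fold >=
      criteria$min_induction_fold * (1 - near_miss_margin)
  near <- p_ok & ((ase_near & ind) | (ase_A & ind_near))
  tab <- tab[, c("gene", "ase_fold", "min_response_fold", "worst_p",
                 "selected", "quadrant")]
  rownames(tab) <- NULL
  list(candidates = tab$gene[tab$selected],
       table = tab,
       census = census,
       near_misses = tab$gene[near])
}
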