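#' Allele-specific count tables
#'
#' An `allele_count_table` holds per-gene read counts from a hybrid RNA-seq
#' experiment, indexed by allele (the two parental alleles, coded `"A"` and
#' `"B"`), condition and replicate, together with per-library total mapped
#' read counts. It is the entry point of the ASE pipeline: downstream
#' operations ([exclude_genes()], [filter_min_coverage()], [ase_ratios()])
#' consume and return this class.
#'
#' @param counts data frame with columns `gene`, `allele`, `condition`,
#'   `replicate`, `count`. Counts must be non-negative integers; a missing
#'   cell is represented by an absent row (or `NA` count), never by a silent
#'   zero.
#' @param library_sizes optional data frame with columns `allele`,
#'   `condition`, `replicate`, `lib_size` giving total mapped reads per
#'   library. Defaults to the column sums of `counts`. Each `lib_size` must
#'   be at least the corresponding column sum.
#'
#' @return An object of class `allele_count_table`: a list with elements
#'   `counts` and `library_sizes`.
#' @seealso [load_allele_counts()] to read one from a TSV file.
#' @export
allele_count_table <- function(counts, library_sizes = NULL) {
  required <- c("gene", "allele", "condition", "replicate", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0L) {
    stop("counts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- as.data.frame(counts)[required]
  counts$gene <- as.character(counts$gene)
  counts$allele <- as.character(counts$allele)
  counts$condition <- as.character(counts$condition)
  counts$replicate <- as.character(counts$replicate)

  bad <- which(!is.na(counts$count) &
                 (counts$count < 0 | counts$count != floor(counts$count)))
  if (length(bad) > 0L) {
    stop("negative or non-integer count in row ", bad[1L],
         " (gene ", counts$gene[bad[1L]], ")")
  }
  counts$count <- as.integer(counts$count)

  key <- paste(counts$gene, counts$allele, counts$condition, counts$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup_gene <- counts$gene[duplicated(key)][1L]
    stop("duplicate rows for gene '", dup_gene, "'")
  }

  col_sums <- stats::aggregate(count ~ allele + condition + replicate,
                               data = counts, FUN = sum, na.rm = TRUE)
  names(col_sums)[names(col_sums) == "count"] <- "lib_size"
  if (is.null(library_sizes)) {
    library_sizes <- col_sums
  } else {
    library_sizes <- as.data.frame(library_sizes)
    need <- c("allele", "condition", "replicate", "lib_size")
    if (!all(need %in% names(library_sizes))) {
      stop("library_sizes needs columns: ", paste(need, collapse = ", "))
    }
    library_sizes <- library_sizes[need]
    m <- merge(col_sums, library_sizes,
               by = c("allele", "condition", "replicate"),
               suffixes = c(".sum", ""))
    if (any(m$lib_size < m$lib_size.sum)) {
      stop("library_sizes smaller than the column sums of counts")
    }
  }

  structure(list(counts = counts, library_sizes = library_sizes),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat("allele_count_table:", length(unique(x$counts$gene)), "genes,",
      length(unique(x$counts$allele)), "alleles,",
      length(unique(x$counts$condition)), "condition(s),",
      length(unique(x$counts$replicate)), "replicate(s)\n")
  invisible(x)
}

#' Genes present in an allele count table
#'
#' @param table an [allele_count_table()].
#' @return Character vector of unique gene identifiers, in first-seen order.
#' @export
table_genes <- function(table) {
  stopifnot(inherits(table, "allele_count_table"))
  unique(table$counts$gene)
}

#' Read an allele-specific count table from TSV
#'
#' Reads a long-format tab-separated file with one row per
#' (gene, allele, condition, replicate) cell, or a wide-format variant via a
#' schema map. Validation is strict: duplicated cells are an error naming
#' the gene, and negative or non-integer counts are an error naming the
#' offending line. Missing cells stay missing; they are never zero-filled.
#'
#' @param path path to a TSV file with a header.
#' @param schema named character vector mapping the roles `gene`, `allele`,
#'   `condition`, `replicate`, `count` to the file's column names. Defaults
#'   to identity (the file uses the role names themselves as headers).
#' @param library_sizes optional library-size data frame, see
#'   [allele_count_table()].
#' @return An [allele_count_table()].
#' @export
load_allele_counts <- function(path,
                               schema = c(gene = "gene", allele = "allele",
                                          condition = "condition",
                                          replicate = "replicate",
                                          count = "count"),
                               library_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("gene", "allele", "condition", "replicate", "count")
  if (!all(roles %in% names(schema))) {
    stop("schema must map all of: ", paste(roles, collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[roles]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(gene = raw[[schema[["gene"]]]],
                   allele = raw[[schema[["allele"]]]],
                   condition = raw[[schema[["condition"]]]],
                   replicate = raw[[schema[["replicate"]]]],
                   count_chr = raw[[schema[["count"]]]],
                   stringsAsFactors = FALSE)
  num <- suppressWarnings(as.numeric(df$count_chr))
  bad <- which(!is.na(df$count_chr) & df$count_chr != "" &
                 (is.na(num) | num < 0 | num != floor(num)))
  if (length(bad) > 0L) {
    # +1 for the header line
    stop("invalid count '", df$count_chr[bad[1L]], "' at line ", bad[1L] + 1L,
         " of ", path)
  }
  df$count <- num
  df$count_chr <- NULL

  key <- paste(df$gene, df$allele, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate rows for gene '", df$gene[duplicated(key)][1L],
         "' in ", path)
  }
  allele_count_table(df, library_sizes = library_sizes)
}

#' Remove blacklisted genes from a count table
#'
#' Marker genes whose allelic balance is an artifact of strain construction
#' (auxotrophic markers such as URA3 or MET17 deleted in one parent) must be
#' removed before any ASE analysis.
#'
#' @param table an [allele_count_table()].
#' @param blacklist character vector of gene identifiers to drop. Entries
#'   absent from the table produce a warning, not an error.
#' @return The filtered [allele_count_table()], with attribute `"n_removed"`
#'   giving the number of genes actually removed.
#' @export
exclude_genes <- function(table, blacklist) {
  stopifnot(inherits(table, "allele_count_table"))
  blacklist <- as.character(blacklist)
  present <- table_genes(table)
  absent <- setdiff(blacklist, present)
  if (length(absent) > 0L) {
    warning("blacklisted gene(s) not in table: ",
            paste(absent, collapse = ", "))
  }
  removed <- intersect(blacklist, present)
  keep <- !(table$counts$gene %in% removed)
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  rownames(out$counts) <- NULL
  attr(out, "n_removed") <- length(removed)
  out
}

#' Coverage-filter a count table
#'
#' Retains only genes with at least `min_reads` reads mapping to each of the
#' two alleles in the given condition, with replicates pooled by summation
#' (one ASE value is computed per gene per condition, so the filter applies
#' to the replicate-summed counts). Genes with a missing allele cell are
#' treated as zero-coverage for that allele and removed.
#'
#' @param table an [allele_count_table()].
#' @param min_reads minimum replicate-summed reads per allele (default 20).
#' @param condition condition identifier the filter applies to.
#' @return The filtered [allele_count_table()] (all conditions retained, but
#'   only for genes passing the filter in `condition`).
#' @export
filter_min_coverage <- function(table, min_reads = 20, condition) {
  stopifnot(inherits(table, "allele_count_table"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  if (missing(condition)) stop("condition must be given")
  if (!condition %in% table$counts$condition) {
    stop("condition '", condition, "' not present in table")
  }
  cc <- table$counts[table$counts$condition == condition, , drop = FALSE]
  pooled <- stats::aggregate(count ~ gene + allele, data = cc, FUN = sum,
                             na.rm = TRUE)
  alleles <- sort(unique(table$counts$allele))
  ok_by_gene <- tapply(pooled$count >= min_reads, pooled$gene, all)
  n_alleles <- tapply(pooled$allele, pooled$gene, function(a) {
    length(unique(a))
  })
  keep_genes <- names(ok_by_gene)[ok_by_gene & n_alleles == length(alleles)]
  out <- table
  out$counts <- table$counts[table$counts$gene %in% keep_genes, ,
                             drop = FALSE]
  rownames(out$counts) <- NULL
  out
}
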