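#' Pipeline configuration
#'
#' A single configuration list drives all pipeline stages; it round-trips
#' losslessly through YAML ([load_config()] / [save_config()]). Thresholds
#' default to the analysis' standard settings: minimum coverage 20 reads
#' per allele, stratum fractions 1/5/25%, candidate folds 4 and 4,
#' per-replicate response p ceiling 1e-5, scan alpha 0.01.
#'
#' @param seed integer seed stamped on every run (used by stages that
#'   draw random numbers; recorded in provenance either way).
#' @param out_dir output directory.
#' @param ... named overrides merged over the defaults (nested lists are
#'   replaced wholesale, not merged).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = "polycis_out", ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    min_reads = 20,
    fractions = c(0.01, 0.05, 0.25),
    alpha = 0.01,
    blacklist = character(0),
    conditions = list(ase = "cond1", treated = "cond2",
                      untreated = "cond1"),
    candidate = list(min_ase_fold = 4, min_induction_fold = 4,
                     max_response_p = 1e-5),
    simulate = list(n_genes = 4394, set_size = 11, set_effect_log2 = 2.0,
                    depth_mean = 500, dispersion = 0.1, conditions = 2,
                    replicates = 2, induced_fold = 1),
    inputs = list(),
    fitness = list(control = "control", generations = 40),
    parsimony = list())
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Atomic write: write to a temp file in the target directory, then rename.
.write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

.provenance <- function(stage, config, inputs, outputs) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  list(stage = stage,
       package_version = as.character(utils::packageVersion("polycis")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(cfg_file)),
       input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
       outputs = outputs,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic allele-count table, embedded
#' gene set and truth), `ase` (counts to filtered ASE records),
#' `signtest` (scan a gene-set collection), `candidates` (joint
#' ASE/response selection), `growth` (plate summaries), `fitness`
#' (barcode competition estimates and condition contrast), `parsimony`
#' (minimal trait history) and `report` (collect stage outputs into one
#' JSON). Inputs are validated before any output is written, outputs are
#' written atomically, and each stage writes a provenance JSON recording
#' the config hash, seed, input checksums and package version.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return Named list of output file paths, invisibly; the provenance
#'   path is always included.
#' @export
run_stage <- function(name, config) {
  stages <- c("simulate", "ase", "signtest", "candidates", "growth",
              "fitness", "parsimony", "report")
  if (!name %in% stages) {
    stop("unknown stage '", name, "'; available: ",
         paste(stages, collapse = ", "))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir, paste0(name, "_"))
  need <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop("stage '", name, "' requires input '", key,
           "' (missing or not a file)")
    }
    p
  }
  inputs <- character(0)
  outputs <- list()

  if (name == "simulate") {
    sim <- do.call(gen_ase_counts, c(config$simulate,
                                     list(seed = config$seed)))
    counts_path <- paste0(out, "counts.tsv")
    .write_atomic(function(p) {
      utils::write.table(sim$table$counts, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, counts_path)
    gmt_path <- paste0(out, "sets.gmt")
    .write_atomic(function(p) {
      writeLines(paste(c("embedded_set", "simulated truth set",
                         sim$truth$set), collapse = "\t"), p)
    }, gmt_path)
    truth_path <- paste0(out, "truth.json")
    .write_atomic(function(p) {
      jsonlite::write_json(list(set = sim$truth$set,
                                set_effect_log2 = sim$truth$set_effect_log2,
                                seed = sim$truth$seed),
                           p, auto_unbox = TRUE, digits = NA)
    }, truth_path)
    outputs <- list(counts = counts_path, sets = gmt_path,
                    truth = truth_path)
  } else if (name == "ase") {
    counts_path <- need("counts")
    inputs <- counts_path
    tab <- load_allele_counts(counts_path)
    if (length(config$blacklist) > 0L) {
      tab <- exclude_genes(tab, config$blacklist)
    }
    tab <- filter_min_coverage(tab, config$min_reads,
                               config$conditions$ase)
    rec <- ase_ratios(tab, config$conditions$ase)
    ase_path <- paste0(out, "records.tsv")
    .write_atomic(function(p) write_records_tsv(rec, p), ase_path)
    outputs <- list(ase = ase_path)
  } else if (name == "signtest") {
    ase_path <- need("ase")
    gmt_path <- need("gene_sets")
    inputs <- c(ase_path, gmt_path)
    rec <- utils::read.delim(ase_path, stringsAsFactors = FALSE)
    collection <- read_gmt(gmt_path)
    res <- scan_collection(rec, collection, fractions = config$fractions,
                           alpha = config$alpha)
    res_path <- paste0(out, "results.tsv")
    .write_atomic(function(p) write_records_tsv(res, p), res_path)
    json_path <- paste0(out, "summary.json")
    top <- res[1L, ]
    .write_atomic(function(p) {
      jsonlite::write_json(list(n_tests = nrow(res),
                                n_significant = sum(res$significant),
                                top_set = top$set_name,
                                top_p_hyper = top$p_hyper,
                                top_p_adjusted = top$p_adjusted),
                           p, auto_unbox = TRUE, digits = NA)
    }, json_path)
    outputs <- list(results = res_path, summary = json_path)
  } else if (name == "candidates") {
    counts_path <- need("counts")
    inputs <- counts_path
    tab <- load_allele_counts(counts_path)
    if (length(config$blacklist) > 0L) {
      tab <- exclude_genes(tab, config$blacklist)
    }
    tab <- filter_min_coverage(tab, config$min_reads,
                               config$conditions$ase)
    rec <- ase_ratios(tab, config$conditions$ase)
    resp <- response_records(tab, config$conditions$treated,
                             config$conditions$untreated)
    crit <- candidate_criteria(
      min_ase_fold = config$candidate$min_ase_fold,
      min_induction_fold = config$candidate$min_induction_fold,
      max_response_p = config$candidate$max_response_p)
    sel <- select_candidates(rec, resp, crit)
    cand_path <- paste0(out, "table.tsv")
    .write_atomic(function(p) write_records_tsv(sel$table, p), cand_path)
    json_path <- paste0(out, "summary.json")
    .write_atomic(function(p) {
      jsonlite::write_json(list(candidates = sel$candidates,
                                census = as.list(sel$census),
                                near_misses = sel$near_misses),
                           p, auto_unbox = TRUE, digits = NA)
    }, json_path)
    outputs <- list(table = cand_path, summary = json_path)
  } else if (name == "growth") {
    curves_path <- need("growth_curves")
    layout_path <- need("layout")
    inputs <- c(curves_path, layout_path)
    layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
    curves <- read_growth_curves(curves_path, format = "long",
                                 layout = layout)
    summ <- summarize_plate(layout, curves)
    summ_path <- paste0(out, "summary.tsv")
    .write_atomic(function(p) write_records_tsv(summ, p), summ_path)
    outputs <- list(summary = summ_path)
  } else if (name == "fitness") {
    sheet_path <- need("sample_sheet")
    map_path <- need("barcode_map")
    inputs <- c(sheet_path, map_path)
    sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
    map <- read_barcode_map(map_path)
    est <- .fitness_from_sheet(sheet, map, config)
    est_path <- paste0(out, "estimates.tsv")
    .write_atomic(function(p) write_records_tsv(est$estimates, p),
                  est_path)
    json_path <- paste0(out, "contrasts.json")
    .write_atomic(function(p) {
      jsonlite::write_json(est$contrasts, p, auto_unbox = TRUE,
                           digits = NA)
    }, json_path)
    outputs <- list(estimates = est_path, contrasts = json_path)
  } else if (name == "parsimony") {
    tree_path <- need("tree")
    states_path <- need("states")
    inputs <- c(tree_path, states_path)
    tree <- parse_newick(paste(readLines(tree_path, warn = FALSE),
                               collapse = ""))
    st_df <- utils::read.delim(states_path, stringsAsFactors = FALSE)
    states <- stats::setNames(st_df$state, st_df$strain)
    fit <- fitch_min_changes(tree, states)
    mprs <- enumerate_mprs(tree, states)
    json_path <- paste0(out, "result.json")
    .write_atomic(function(p) {
      jsonlite::write_json(
        list(min_changes = fit$min_changes,
             n_reconstructions = length(mprs$reconstructions),
             reconstructions = lapply(mprs$reconstructions, function(r) {
               list(node_states = r$node_states, events = r$events)
             })),
        p, auto_unbox = TRUE, digits = NA)
    }, json_path)
    outputs <- list(result = json_path)
  } else if (name == "report") {
    files <- list.files(config$out_dir, pattern = "\\.(json|tsv)$",
                        full.names = TRUE)
    files <- files[!grepl("(report_|_provenance)", basename(files))]
    report_path <- paste0(out, "summary.json")
    .write_atomic(function(p) {
      jsonlite::write_json(
        list(files = basename(files),
             md5 = as.list(tools::md5sum(files))),
        p, auto_unbox = TRUE, digits = NA)
    }, report_path)
    outputs <- list(report = report_path)
  }

  prov_path <- paste0(out, "provenance.json")
  .write_atomic(function(p) {
    jsonlite::write_json(.provenance(name, config, inputs, outputs), p,
                         auto_unbox = TRUE, digits = NA)
  }, prov_path)
  outputs$provenance <- prov_path
  invisible(outputs)
}

# Replicate-level fitness estimates and condition contrasts from a sample
# sheet with columns: sample, file, timepoint (initial/final), condition,
# replicate, generations. Count files are TSV `barcode<TAB>count`.
.fitness_from_sheet <- function(sheet, map, config) {
  need_cols <- c("sample", "file", "timepoint", "condition", "replicate",
                 "generations")
  if (!all(need_cols %in% names(sheet))) {
    stop("sample sheet needs columns: ", paste(need_cols, collapse = ", "))
  }
  control <- config$fitness$control
  strains <- setdiff(unique(map$strain), control)
  read_counts <- function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    stats::setNames(df$count, df$barcode)
  }
  rows <- list()
  contrasts <- list()
  rep_s_store <- list()
  for (cond in unique(sheet$condition)) {
    sub <- sheet[sheet$condition == cond, , drop = FALSE]
    for (strain in strains) {
      per_rep <- list()
      for (rp in unique(sub$replicate)) {
        ini <- sub[sub$replicate == rp & sub$timepoint == "initial", ]
        fin <- sub[sub$replicate == rp & sub$timepoint == "final", ]
        if (nrow(ini) != 1L || nrow(fin) != 1L) {
          stop("replicate ", rp, " of condition ", cond,
               " lacks an initial/final pair")
        }
        per_rep[[as.character(rp)]] <- barcode_fitness(
          read_counts(ini$file), read_counts(fin$file), map, strain,
          control, fin$generations)
      }
      est <- aggregate_fitness(per_rep, strain = strain, condition = cond)
      rep_s_store[[paste(strain, cond, sep = "\r")]] <- est$replicate_s
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, condition = cond, s = est$s, se = est$se,
        n_replicates = est$n_replicates, stringsAsFactors = FALSE)
    }
  }
  conds <- unique(sheet$condition)
  if (length(conds) == 2L) {
    for (strain in strains) {
      a <- rep_s_store[[paste(strain, conds[1L], sep = "\r")]]
      b <- rep_s_store[[paste(strain, conds[2L], sep = "\r")]]
      if (length(a) >= 2L && length(b) >= 2L) {
        ct <- condition_contrast(a, b)
        contrasts[[strain]] <- c(list(condition_A = conds[1L],
                                      condition_B = conds[2L]), ct)
      }
    }
  }
  list(estimates = do.call(rbind, rows), contrasts = contrasts)
}
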