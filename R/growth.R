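#' Growth curve container
#'
#' One well's OD600 time course. Readings at or below `blank_floor` are
#' dropped at construction (plate readers produce near-blank noise and the
#' rate estimate needs log-positive values); set `blank_floor = 0` to keep
#' everything positive.
#'
#' @param times reading times in minutes, strictly increasing.
#' @param od OD600 readings, same length as `times`.
#' @param strain,condition,well metadata labels.
#' @param blank_floor OD below or at which a reading is discarded
#'   (default 0.01).
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, strain = NA_character_,
                         condition = NA_character_, well = NA_character_,
                         blank_floor = 0.01) {
  if (length(times) != length(od)) stop("times and od differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  keep <- !is.na(od) & od > blank_floor & od > 0
  structure(list(times = as.numeric(times[keep]),
                 od = as.numeric(od[keep]),
                 strain = strain, condition = condition, well = well),
            class = "growth_curve")
}

#' Maximum growth rate by sliding-window regression
#'
#' Fits an ordinary least-squares line to log10(OD) against time for every
#' set of `window` consecutive time points (20 points = 4 hours at the
#' nominal 12-minute reading interval) and records the highest slope. The
#' regression always uses the actual reading times, so irregular sampling
#' is handled; the window is defined by point count, not elapsed time.
#'
#' @param curve a [growth_curve()].
#' @param window number of consecutive points per regression (default 20).
#' @return List of class `growth_summary`: `max_rate` (slope of log10(OD)
#'   per hour), `max_od` (maximum cleaned OD), `window_start` (minutes,
#'   start of the winning window), plus the curve's metadata.
#' @export
max_growth_rate <- function(curve, window = 20) {
  stopifnot(inherits(curve, "growth_curve"))
  m <- length(curve$od)
  if (m < window) {
    stop("well '", curve$well, "' has ", m,
         " usable points, fewer than the window of ", window)
  }
  x <- curve$times / 60  # hours
  y <- log10(curve$od)
  # rolling sums via cumulative sums: closed-form OLS slope per window
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, x * x)); cxy <- cumsum(c(0, x * y))
  i <- seq_len(m - window + 1L)
  Sx <- cx[i + window] - cx[i]
  Sy <- cy[i + window] - cy[i]
  Sxx <- cxx[i + window] - cxx[i]
  Sxy <- cxy[i + window] - cxy[i]
  slopes <- (window * Sxy - Sx * Sy) / (window * Sxx - Sx * Sx)
  best <- which.max(slopes)
  structure(list(max_rate = slopes[best],
                 max_od = max(curve$od),
                 window_start = curve$times[best],
                 strain = curve$strain, condition = curve$condition,
                 well = curve$well),
            class = "growth_summary")
}

#' Maximum OD across all time points
#'
#' @param curve a [growth_curve()].
#' @return The maximum cleaned OD600 reading.
#' @export
max_od <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$od) == 0L) stop("empty curve")
  max(curve$od)
}

#' Treatment effect as a log-ratio relative to a reference strain
#'
#' Expresses how much more (or less) a treatment reduces a strain's growth
#' metric than it reduces a reference strain's. With fold-reductions
#' `reduction = metric_untreated / metric_treated` for strain and
#' reference, the effect is `log2(reduction_strain / reduction_ref)`: a
#' strain whose rate is reduced 2-fold more than the reference scores 1; a
#' 4-fold smaller reduction scores -2; the reference against itself
#' scores 0.
#'
#' @param metric_untreated,metric_treated the strain's metric (max growth
#'   rate or max OD) without and with treatment; all metrics must be > 0.
#' @param ref_untreated,ref_treated the reference strain's metrics.
#' @return The log2 relative effect.
#' @export
effect_logratio <- function(metric_untreated, metric_treated,
                            ref_untreated, ref_treated) {
  vals <- c(metric_untreated, metric_treated, ref_untreated, ref_treated)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all metrics must be positive and finite; ",
         "a zero treated metric means the strain failed to grow")
  }
  log2((metric_untreated / metric_treated) /
         (ref_untreated / ref_treated))
}

#' Read growth curves from CSV
#'
#' Long format has columns `well,time_min,od`; wide format has a `time_min`
#' column plus one OD column per well.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param layout optional data frame `well,strain,condition` used to attach
#'   metadata to each curve.
#' @param blank_floor passed to [growth_curve()].
#' @return Named list of [growth_curve()] objects, one per well.
#' @export
read_growth_curves <- function(path, format = c("long", "wide"),
                               layout = NULL, blank_floor = 0.01) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  curves <- list()
  if (format == "long") {
    if (!all(c("well", "time_min", "od") %in% names(df))) {
      stop("long format needs columns well,time_min,od")
    }
    for (w in unique(df$well)) {
      sub <- df[df$well == w, , drop = FALSE]
      sub <- sub[order(sub$time_min), , drop = FALSE]
      curves[[w]] <- growth_curve(sub$time_min, sub$od, well = w,
                                  blank_floor = blank_floor)
    }
  } else {
    if (!"time_min" %in% names(df)) stop("wide format needs a time_min column")
    for (w in setdiff(names(df), "time_min")) {
      curves[[w]] <- growth_curve(df$time_min, df[[w]], well = w,
                                  blank_floor = blank_floor)
    }
  }
  if (!is.null(layout)) {
    for (w in names(curves)) {
      row <- layout[layout$well == w, , drop = FALSE]
      if (nrow(row) == 1L) {
        curves[[w]]$strain <- row$strain
        curves[[w]]$condition <- row$condition
      }
    }
  }
  curves
}

#' Summarise a plate of growth curves per strain and condition
#'
#' Computes [max_growth_rate()] and [max_od()] for every well, then groups
#' replicate wells by (strain, condition) and reports the mean and standard
#' error (sample SD / sqrt(replicates)) of both metrics.
#'
#' @param layout data frame `well,strain,condition`; every curve's well
#'   must appear exactly once.
#' @param curves named list of [growth_curve()] objects (names are wells).
#' @param window passed to [max_growth_rate()].
#' @return Data frame with one row per (strain, condition): `n_wells`,
#'   `mean_rate`, `se_rate`, `mean_max_od`, `se_max_od`.
#' @export
summarize_plate <- function(layout, curves, window = 20) {
  wells <- names(curves)
  missing_wells <- setdiff(wells, layout$well)
  if (length(missing_wells) > 0L) {
    stop("well(s) missing from layout: ",
         paste(missing_wells, collapse = ", "))
  }
  per_well <- do.call(rbind, lapply(wells, function(w) {
    s <- max_growth_rate(curves[[w]], window = window)
    row <- layout[layout$well == w, , drop = FALSE]
    data.frame(well = w, strain = row$strain, condition = row$condition,
               max_rate = s$max_rate, max_od = s$max_od,
               stringsAsFactors = FALSE)
  }))
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  groups <- unique(per_well[, c("strain", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- per_well[per_well$strain == groups$strain[i] &
                    per_well$condition == groups$condition[i], ]
    data.frame(strain = groups$strain[i], condition = groups$condition[i],
               n_wells = nrow(g),
               mean_rate = mean(g$max_rate), se_rate = se(g$max_rate),
               mean_max_od = mean(g$max_od), se_max_od = se(g$max_od),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
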