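STATUS_LEVELS <- c("zero", "very_low", "low_moderate", "high")

#' Transcriptional-status thresholds relative to a housekeeping reference
#'
#' The yardstick is the Pol II occupancy R of an abundantly expressed
#' housekeeping gene (beta-actin, Actb, by default).  Genes are classified:
#' \describe{
#'   \item{zero}{RPKM = 0 — no detectable Pol II binding}
#'   \item{very_low}{0 < RPKM < R * low_fraction (default R/10)}
#'   \item{low_moderate}{R * low_fraction <= RPKM <= R * high_fraction
#'     (default R/10 .. R/2); the boundaries close this middle tier, matching
#'     the strict inequalities that delimit the outer tiers}
#'   \item{high}{RPKM > R * high_fraction (default R/2)}
#' }
#'
#' @param reference_rpkm occupancy R of the reference gene (positive).
#' @param reference_symbol reference gene symbol (default "Actb").
#' @param low_fraction,high_fraction tier cut fractions of R; defaults 0.1
#'   and 0.5.
#' @return an object of class `status_thresholds`.
#' @export
status_thresholds <- function(reference_rpkm, reference_symbol = "Actb",
                              low_fraction = 0.1, high_fraction = 0.5) {
  stopifnot(is.numeric(reference_rpkm), length(reference_rpkm) == 1,
            reference_rpkm > 0,
            low_fraction > 0, low_fraction < high_fraction,
            high_fraction <= 1)
  structure(list(reference_rpkm = reference_rpkm,
                 reference_symbol = reference_symbol,
                 low_fraction = low_fraction,
                 high_fraction = high_fraction),
            class = "status_thresholds")
}

#' Classify genes into transcriptional-status tiers
#'
#' @param rpkm numeric vector of non-negative RPKM values.
#' @param thresholds a [status_thresholds()] object.
#' @return factor over the tiers zero / very_low / low_moderate / high.
#' @export
classify_status <- function(rpkm, thresholds) {
  stopifnot(inherits(thresholds, "status_thresholds"))
  if (any(!is.finite(rpkm) | rpkm < 0)) {
    stop("rpkm values must be finite and non-negative", call. = FALSE)
  }
  lo <- thresholds$reference_rpkm * thresholds$low_fraction
  hi <- thresholds$reference_rpkm * thresholds$high_fraction
  out <- ifelse(rpkm == 0, "zero",
                ifelse(rpkm < lo, "very_low",
                       ifelse(rpkm <= hi, "low_moderate", "high")))
  factor(out, levels = STATUS_LEVELS)
}

#' Status summary over a gene cohort
#'
#' Counts and percentages per tier, plus the combined "transcriptionally
#' inactive or very low" percentage (zero + very_low).  Reported percentages
#' are computed from the raw counts and then rounded to the nearest integer;
#' in particular the combined percentage is the rounded percentage of the
#' summed counts, not the sum of rounded per-tier percentages.
#'
#' @param occupancy either an occupancy data frame from [polii_occupancy()]
#'   (columns symbol and rpkm) or a named numeric vector of RPKMs.
#' @param thresholds a [status_thresholds()] object, or `NULL` to look the
#'   reference occupancy up from `occupancy` by `reference_symbol` (an error
#'   if the reference gene is absent).
#' @param reference_symbol used for the lookup when `thresholds` is `NULL`,
#'   and to exclude the yardstick gene itself from the cohort.
#' @param low_fraction,high_fraction passed to [status_thresholds()] when
#'   looking the reference up.
#' @return an object of class `status_table`: list with `table` (per-gene
#'   symbol, rpkm, category), `counts`, `percent` (raw), `percent_rounded`,
#'   `combined_inactive_percent` (rounded), `n`, and `thresholds`.
#' @export
status_summary <- function(occupancy, thresholds = NULL,
                           reference_symbol = "Actb",
                           low_fraction = 0.1, high_fraction = 0.5) {
  if (is.data.frame(occupancy)) {
    assert_cols(occupancy, c("symbol", "rpkm"), "occupancy")
    rpkm <- stats::setNames(occupancy$rpkm, occupancy$symbol)
  } else {
    rpkm <- occupancy
    if (is.null(names(rpkm))) {
      names(rpkm) <- sprintf("gene_%d", seq_along(rpkm))
    }
  }
  if (is.null(thresholds)) {
    hit <- which(names(rpkm) == reference_symbol)
    if (length(hit) == 0) {
      stop("reference gene '", reference_symbol,
           "' not found in the occupancy table", call. = FALSE)
    }
    thresholds <- status_thresholds(unname(rpkm[hit[1]]),
                                    reference_symbol = reference_symbol,
                                    low_fraction = low_fraction,
                                    high_fraction = high_fraction)
  }
  stopifnot(inherits(thresholds, "status_thresholds"))
  # the yardstick gene is not a member of the cohort it calibrates
  rpkm <- rpkm[names(rpkm) != thresholds$reference_symbol]
  if (length(rpkm) == 0) {
    stop("status_summary: empty gene cohort", call. = FALSE)
  }
  category <- classify_status(unname(rpkm), thresholds)
  counts <- table(category)
  n <- length(rpkm)
  percent <- 100 * as.integer(counts) / n
  combined <- round(100 * sum(counts[c("zero", "very_low")]) / n)
  structure(list(
    table = data.frame(symbol = names(rpkm), rpkm = unname(rpkm),
                       category = category, stringsAsFactors = FALSE),
    counts = stats::setNames(as.integer(counts), STATUS_LEVELS),
    percent = stats::setNames(percent, STATUS_LEVELS),
    percent_rounded = stats::setNames(as.integer(round(percent)),
                                      STATUS_LEVELS),
    combined_inactive_percent = as.integer(combined),
    n = n,
    thresholds = thresholds), class = "status_table")
}

#' @export
print.status_table <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Transcriptional status of %d genes (reference %s = %.2f RPKM)\n",
              x$n, th$reference_symbol, th$reference_rpkm))
  cat(sprintf("  cuts: very_low < %.2f, high > %.2f RPKM\n",
              th$reference_rpkm * th$low_fraction,
              th$reference_rpkm * th$high_fraction))
  for (lev in STATUS_LEVELS) {
    cat(sprintf("  %-13s %5d  (%d%%)\n", lev, x$counts[lev],
                x$percent_rounded[lev]))
  }
  cat(sprintf("  combined inactive/very-low: %d%%\n",
              x$combined_inactive_percent))
  invisible(x)
}

#' Paired fold-enrichment / occupancy export
#'
#' One row per gene: the representative fold enrichment of its best peak
#' (from [best_peak_per_gene()]) next to its Pol II occupancy, sorted by
#' decreasing RPKM.
#'
#' @param best_peaks output of [best_peak_per_gene()].
#' @param occupancy output of [polii_occupancy()].
#' @return data frame with columns symbol, representative_fe, rpkm.
#' @export
peak_occupancy_table <- function(best_peaks, occupancy) {
  assert_cols(best_peaks, c("gene_symbol", "representative_fe"), "best_peaks")
  assert_cols(occupancy, c("symbol", "rpkm"), "occupancy")
  idx <- match(best_peaks$gene_symbol, occupancy$symbol)
  out <- data.frame(symbol = best_peaks$gene_symbol,
                    representative_fe = best_peaks$representative_fe,
                    rpkm = occupancy$rpkm[idx],
                    stringsAsFactors = FALSE)
  out[order(-out$rpkm, out$symbol, method = "radix"), , drop = FALSE]
}
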