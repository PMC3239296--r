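#' Derive consensus peaks shared between two replicate peak sets
#'
#' Two peaks correspond when their intervals overlap or are separated by at
#' most `max_gap` intervening bases (the gap between nearest edges; an
#' overlap counts as gap 0).  Matching is one-to-one and greedy by increasing
#' gap, with ties broken by the leftmost coordinate of the candidate pair, so
#' the result is deterministic and symmetric in the two replicates.
#' Unmatched peaks are dropped.
#'
#' The consensus interval is the union of the matched pair — a conservative
#' footprint for downstream sequence scanning.  The representative fold
#' enrichment of a consensus peak is taken from replicate 1 (`set_a`), which
#' by convention is the deeper data set.
#'
#' @param set_a,set_b replicate peak data frames (columns chrom, start, end,
#'   fold_enrichment; optional name).  `set_a` is replicate 1.
#' @param max_gap maximum number of intervening bases between corresponding
#'   peaks (default 50).
#' @param known_chroms optional character vector of valid chromosome names;
#'   peaks on other chromosomes raise an error listing the offending records.
#' @return data frame of consensus peaks with columns chrom, start, end,
#'   name, fe_rep1, fe_rep2, representative_fe, gap, name_rep1, name_rep2.
#' @export
match_peak_sets <- function(set_a, set_b, max_gap = 50, known_chroms = NULL) {
  validate_peaks(set_a)
  validate_peaks(set_b)
  stopifnot(max_gap >= 0)
  if (!is.null(known_chroms)) {
    bad_a <- which(!set_a$chrom %in% known_chroms)
    bad_b <- which(!set_b$chrom %in% known_chroms)
    if (length(bad_a) + length(bad_b) > 0) {
      desc <- c(sprintf("set_a[%d]=%s", bad_a, set_a$chrom[bad_a]),
                sprintf("set_b[%d]=%s", bad_b, set_b$chrom[bad_b]))
      stop("peaks on unknown chromosomes: ",
           paste(utils::head(desc, 10), collapse = ", "), call. = FALSE)
    }
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), fe_rep1 = numeric(),
                      fe_rep2 = numeric(), representative_fe = numeric(),
                      gap = integer(), name_rep1 = character(),
                      name_rep2 = character(), stringsAsFactors = FALSE)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  name_a <- set_a$name %||% paste0("a_", seq_len(nrow(set_a)))
  name_b <- set_b$name %||% paste0("b_", seq_len(nrow(set_b)))
  out <- list()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ia <- which(set_a$chrom == ch)
    ib <- which(set_b$chrom == ch)
    ra <- IRanges::IRanges(set_a$start[ia] + 1L, set_a$end[ia])
    rb <- IRanges::IRanges(set_b$start[ib] + 1L, set_b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, maxgap = max_gap)
    if (length(hits) == 0) next
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    gap <- pmax(0L, pmax(set_a$start[qa], set_b$start[qb]) -
                  pmin(set_a$end[qa], set_b$end[qb]))
    # greedy one-to-one: smallest gap first; symmetric tie-break keys
    ord <- order(gap,
                 pmin(set_a$start[qa], set_b$start[qb]),
                 pmax(set_a$start[qa], set_b$start[qb]),
                 pmin(set_a$end[qa], set_b$end[qb]),
                 pmax(set_a$end[qa], set_b$end[qb]),
                 method = "radix")
    used_a <- logical(nrow(set_a))
    used_b <- logical(nrow(set_b))
    keep <- integer(0)
    for (k in ord) {
      if (!used_a[qa[k]] && !used_b[qb[k]]) {
        used_a[qa[k]] <- TRUE
        used_b[qb[k]] <- TRUE
        keep <- c(keep, k)
      }
    }
    qa <- qa[keep]; qb <- qb[keep]
    out[[ch]] <- data.frame(
      chrom = ch,
      start = pmin(set_a$start[qa], set_b$start[qb]),
      end = pmax(set_a$end[qa], set_b$end[qb]),
      name = NA_character_,
      fe_rep1 = set_a$fold_enrichment[qa],
      fe_rep2 = set_b$fold_enrichment[qb],
      representative_fe = set_a$fold_enrichment[qa],
      gap = gap[keep],
      name_rep1 = name_a[qa],
      name_rep2 = name_b[qb],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end, method = "radix"), ,
             drop = FALSE]
  res$name <- sprintf("consensus_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Best peak per gene by fold enrichment
#'
#' When several peaks annotate to the same gene, only the peak with the
#' highest representative fold enrichment is retained (ties broken by the
#' leftmost interval).  Peaks without an assigned gene are dropped.
#'
#' @param annotated annotated-peak data frame from [annotate_peaks()] (needs
#'   columns gene_symbol and representative_fe).
#' @return data frame with one row per gene symbol, ordered by symbol.
#' @export
best_peak_per_gene <- function(annotated) {
  assert_cols(annotated, c("gene_symbol", "representative_fe",
                           "chrom", "start", "end"), "annotated")
  keep <- !is.na(annotated$gene_symbol)
  ann <- annotated[keep, , drop = FALSE]
  if (nrow(ann) == 0) return(ann)
  ord <- order(ann$gene_symbol, -ann$representative_fe, ann$chrom,
               ann$start, ann$end, method = "radix")
  ann <- ann[ord, , drop = FALSE]
  out <- ann[!duplicated(ann$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
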