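#' Effective gene region length under Pol II peaks
#'
#' The quantification region for a gene is its transcript body; when Pol II
#' peaks overlapping the body protrude beyond it, the protruding footprint is
#' added to the region length.  Protrusions from several peaks are merged
#' before summing, so overlapping extensions are never double counted (all
#' left protrusions share the body start as their right edge, so the merged
#' left extension is simply the farthest reach, and likewise on the right).
#'
#' @param gene a single gene model (one-row gene-model data frame).
#' @param polii_peaks Pol II peak data frame (chrom, start, end, and
#'   tag_count when used for quantification).
#' @return list with `effective_length` (bp) and `overlapping` (the rows of
#'   `polii_peaks` with at least 1 bp overlap with the gene body).
#' @export
effective_gene_region <- function(gene, polii_peaks) {
  validate_gene_models(gene)
  stopifnot(nrow(gene) == 1)
  validate_peaks(polii_peaks)
  body_len <- gene$end - gene$start
  ov <- polii_peaks$chrom == gene$chrom &
    polii_peaks$start < gene$end & polii_peaks$end > gene$start
  overlapping <- polii_peaks[ov, , drop = FALSE]
  ext <- 0L
  if (nrow(overlapping) > 0) {
    left <- max(0L, gene$start - min(overlapping$start))
    right <- max(0L, max(overlapping$end) - gene$end)
    ext <- left + right
  }
  list(effective_length = as.integer(body_len + ext),
       overlapping = overlapping)
}

#' Pol II occupancy of one gene in RPKM
#'
#' RPKM = (C / (L / 1000)) / (N / 1e6), where C is the total tag count of
#' Pol II peaks overlapping the gene body, L the effective region length
#' from [effective_gene_region()], and N the library size (total uniquely
#' mapped reads, supplied by the caller — it cannot be inferred from peak
#' calls).  A gene without overlapping peaks has C = 0 and RPKM 0.  A peak
#' overlapping two genes contributes its full tag count to both.
#'
#' @param gene a single gene model (one-row gene-model data frame).
#' @param polii_peaks Pol II peaks with a `tag_count` column.
#' @param library_size total uniquely mapped reads (positive scalar).
#' @return one-row data frame: symbol, tag_count, effective_length,
#'   library_size, rpkm.
#' @export
compute_rpkm <- function(gene, polii_peaks, library_size) {
  stopifnot(length(library_size) == 1, library_size > 0)
  reg <- effective_gene_region(gene, polii_peaks)
  validate_peaks(reg$overlapping, need_tags = nrow(reg$overlapping) > 0)
  C <- if (nrow(reg$overlapping) > 0) sum(reg$overlapping$tag_count) else 0L
  L <- reg$effective_length
  rpkm <- (C / (L / 1000)) / (library_size / 1e6)
  data.frame(symbol = gene$symbol, tag_count = as.integer(C),
             effective_length = L, library_size = library_size,
             rpkm = rpkm, stringsAsFactors = FALSE)
}

#' Pol II occupancy table over a gene cohort
#'
#' Applies the longest-model-per-symbol rule, then computes
#' [compute_rpkm()] per gene.
#'
#' @param models gene-model data frame (all transcripts; collapsed
#'   internally).
#' @param polii_peaks Pol II peaks with tag counts.
#' @param library_size total uniquely mapped reads.
#' @param symbols optional character vector restricting the cohort.
#' @return data frame with one row per gene symbol.
#' @export
polii_occupancy <- function(models, polii_peaks, library_size,
                            symbols = NULL) {
  longest <- longest_model_per_symbol(models)
  if (!is.null(symbols)) {
    miss <- setdiff(symbols, longest$symbol)
    if (length(miss) > 0) {
      stop("no gene model for symbol(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    longest <- longest[longest$symbol %in% symbols, , drop = FALSE]
  }
  validate_peaks(polii_peaks, need_tags = nrow(polii_peaks) > 0)
  rows <- lapply(seq_len(nrow(longest)), function(i) {
    compute_rpkm(longest[i, , drop = FALSE], polii_peaks, library_size)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
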