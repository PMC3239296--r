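#' Gene models and genomic coordinate conventions
#'
#' All coordinates in this package are 0-based half-open (BED native): an
#' interval `[start, end)` covers bases `start .. end - 1` and has length
#' `end - start`.  refFlat files already use this convention for txStart/txEnd
#' and exon bounds, so both supported dialects parse without coordinate
#' shifts.  The transcription start site (TSS) of a model is `start` on the
#' plus strand and `end - 1` on the minus strand.
#'
#' Gene models are plain data frames with one row per transcript and columns:
#' \describe{
#'   \item{accession}{transcript identifier (e.g. NM_ accession)}
#'   \item{symbol}{gene symbol}
#'   \item{chrom, start, end, strand}{transcript body; strand is "+" or "-"}
#'   \item{exon_starts, exon_ends}{list columns of integer vectors, sorted,
#'     pairwise non-overlapping, contained in the body}
#' }
#'
#' @name gene_models
NULL

new_gene_models <- function(accession, symbol, chrom, strand, start, end,
                            exon_starts, exon_ends) {
  df <- data.frame(accession = as.character(accession),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$exon_starts <- lapply(exon_starts, as.integer)
  df$exon_ends <- lapply(exon_ends, as.integer)
  validate_gene_models(df)
  df
}

validate_gene_models <- function(models) {
  assert_cols(models, c("accession", "symbol", "chrom", "strand",
                        "start", "end", "exon_starts", "exon_ends"),
              "models")
  if (nrow(models) == 0) return(invisible(models))
  if (any(models$start < 0) || any(models$start >= models$end)) {
    stop("gene model bodies must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop("gene models require an explicit strand ('+' or '-')", call. = FALSE)
  }
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]
    ee <- models$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0) {
      stop(sprintf("model '%s': exon start/end vectors must be non-empty and equal length",
                   models$accession[i]), call. = FALSE)
    }
    if (any(es >= ee)) {
      stop(sprintf("model '%s': empty or inverted exon", models$accession[i]),
           call. = FALSE)
    }
    if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)])) {
      stop(sprintf("model '%s': exons must be sorted and non-overlapping",
                   models$accession[i]), call. = FALSE)
    }
    if (es[1] < models$start[i] || ee[length(ee)] > models$end[i]) {
      stop(sprintf("model '%s': exons extend beyond the transcript body",
                   models$accession[i]), call. = FALSE)
    }
  }
  invisible(models)
}

# Strand-aware transcription start site (single genomic position).
gene_tss <- function(models) {
  ifelse(models$strand == "+", models$start, models$end - 1L)
}

#' Read gene models from a refFlat or BED12 file
#'
#' refFlat is the UCSC tab-separated dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; exon
#' coordinate lists comma-terminated).  BED12 reconstructs exons from the
#' block fields; its single `name` field serves as both accession and symbol.
#' Both dialects are 0-based half-open and parse without coordinate shifts.
#'
#' @param path file path.
#' @param format `"refFlat"` (default) or `"BED12"`.
#' @return a gene-model data frame (see [gene_models]).
#' @export
parse_gene_models <- function(path, format = c("refFlat", "BED12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, refFlat = read_refflat(path), BED12 = read_bed12(path))
}

split_coord_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}

#' @rdname parse_gene_models
#' @export
read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_gene_models(character(), character(), character(), character(),
                           integer(), integer(), list(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 11L)
  if (length(bad) > 0) {
    stop(sprintf("refFlat parse error at line %d: expected 11 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  exon_starts <- split_coord_list(m[, 10])
  exon_ends <- split_coord_list(m[, 11])
  n_exons <- suppressWarnings(as.integer(m[, 9]))
  bad <- which(is.na(n_exons) |
                 vapply(exon_starts, length, 1L) != n_exons |
                 vapply(exon_ends, length, 1L) != n_exons)
  if (length(bad) > 0) {
    stop(sprintf("refFlat parse error at line %d: exon count does not match exon coordinate lists",
                 bad[1]), call. = FALSE)
  }
  new_gene_models(accession = m[, 2], symbol = m[, 1], chrom = m[, 3],
                  strand = m[, 4], start = as.integer(m[, 5]),
                  end = as.integer(m[, 6]),
                  exon_starts = exon_starts, exon_ends = exon_ends)
}

#' @rdname parse_gene_models
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_gene_models(character(), character(), character(), character(),
                           integer(), integer(), list(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0) {
    stop(sprintf("BED12 parse error at line %d: expected 12 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  start <- as.integer(m[, 2])
  sizes <- split_coord_list(m[, 11])
  offsets <- split_coord_list(m[, 12])
  n_blocks <- suppressWarnings(as.integer(m[, 10]))
  bad <- which(is.na(n_blocks) |
                 vapply(sizes, length, 1L) != n_blocks |
                 vapply(offsets, length, 1L) != n_blocks)
  if (length(bad) > 0) {
    stop(sprintf("BED12 parse error at line %d: blockCount does not match block lists",
                 bad[1]), call. = FALSE)
  }
  exon_starts <- mapply(function(s, off) s + off, start, offsets,
                        SIMPLIFY = FALSE)
  exon_ends <- mapply(function(es, sz) es + sz, exon_starts, sizes,
                      SIMPLIFY = FALSE)
  new_gene_models(accession = m[, 4], symbol = m[, 4], chrom = m[, 1],
                  strand = m[, 6], start = start, end = as.integer(m[, 3]),
                  exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Write gene models as refFlat
#'
#' Round-trips bit-exactly with [read_refflat()]. cdsStart/cdsEnd are written
#' as the transcript bounds (CDS structure is not modelled).
#'
#' @param models gene-model data frame.
#' @param path output path.
#' @export
write_refflat <- function(models, path) {
  validate_gene_models(models)
  fmt_list <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(models)), function(i) {
    paste(models$symbol[i], models$accession[i], models$chrom[i],
          models$strand[i], models$start[i], models$end[i],
          models$start[i], models$end[i],
          length(models$exon_starts[[i]]),
          fmt_list(models$exon_starts[[i]]),
          fmt_list(models$exon_ends[[i]]), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$size, df$chrom)
}

#' Keep the longest transcript model per gene symbol
#'
#' "Length" is the transcript body span (`end - start`), the same span that
#' forms the RPKM denominator; summed exon length is not used.  Ties on equal
#' span are broken by lexicographically smallest accession, so the result is
#' deterministic.
#'
#' @param models gene-model data frame.
#' @return gene-model data frame with exactly one row per symbol, ordered by
#'   symbol.
#' @export
longest_model_per_symbol <- function(models) {
  validate_gene_models(models)
  if (nrow(models) == 0) return(models)
  len <- models$end - models$start
  ord <- order(models$symbol, -len, models$accession, method = "radix")
  models <- models[ord, , drop = FALSE]
  keep <- !duplicated(models$symbol)
  out <- models[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
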