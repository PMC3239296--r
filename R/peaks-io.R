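#' Read replicate peak calls from a BED6+ file
#'
#' Columns: chrom, start, end, name, fold_enrichment (BED score slot),
#' strand, and optionally tag_count as a seventh column.  Coordinates are
#' 0-based half-open.  Fold enrichment must be positive for every peak.
#'
#' @param path file path.
#' @return data frame with columns chrom, start, end, name, fold_enrichment,
#'   strand and (if present in the file) tag_count.
#' @export
read_peak_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      fold_enrichment = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 6L)) {
    stop(sprintf("peak BED parse error at line %d: expected at least 6 fields",
                 which(nf < 6L)[1]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  out <- data.frame(chrom = m[, 1],
                    start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]),
                    name = m[, 4],
                    fold_enrichment = as.numeric(m[, 5]),
                    strand = m[, 6],
                    stringsAsFactors = FALSE)
  if (all(nf >= 7L)) {
    out$tag_count <- as.integer(vapply(fields, `[`, character(1), 7L))
  }
  validate_peaks(out)
  out
}

validate_peaks <- function(peaks, need_tags = FALSE) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  if (nrow(peaks) == 0) return(invisible(peaks))
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(peaks$fold_enrichment) &&
      any(!is.finite(peaks$fold_enrichment) | peaks$fold_enrichment <= 0)) {
    stop("fold_enrichment must be positive and finite", call. = FALSE)
  }
  if (need_tags) {
    if (is.null(peaks$tag_count) || anyNA(peaks$tag_count)) {
      bad <- if (is.null(peaks$tag_count)) peaks$name else
        peaks$name[is.na(peaks$tag_count)]
      stop("peak(s) lacking tag_count: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (any(peaks$tag_count < 0)) {
      stop("tag_count must be non-negative", call. = FALSE)
    }
  }
  invisible(peaks)
}

#' Write peaks as BED6+
#'
#' @param peaks peak data frame (see [read_peak_bed()]); extra numeric
#'   columns named in `extra` are appended after the strand.
#' @param path output path.
#' @param extra character vector of additional column names to write.
#' @export
write_peak_bed <- function(peaks, path, extra = intersect("tag_count", names(peaks))) {
  validate_peaks(peaks)
  name <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
  strand <- peaks$strand %||% rep(".", nrow(peaks))
  score <- peaks$fold_enrichment %||% rep(0, nrow(peaks))
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, name, score, strand,
                   stringsAsFactors = FALSE)
  for (col in extra) df[[col]] <- peaks[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
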