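LOCATION_LEVELS <- c("five_prime_upstream", "exonic", "intronic",
                     "three_prime_downstream", "intergenic")

#' Annotate peaks with their nearest gene and a location category
#'
#' Each peak is reduced to its midpoint, `floor((start + end) / 2)`, and
#' classified against the gene models:
#' \itemize{
#'   \item midpoint inside a transcript body: \code{exonic} if it falls in an
#'     exon of the assigned model, else \code{intronic};
#'   \item otherwise within `window` bp upstream of a TSS (strand-aware):
#'     \code{five_prime_upstream};
#'   \item otherwise within `window` bp past a transcript end:
#'     \code{three_prime_downstream};
#'   \item otherwise \code{intergenic}.
#' }
#' When several genes qualify, genic placement takes precedence over another
#' gene's promoter window, which takes precedence over a downstream window;
#' remaining ties go to the smaller distance, then the lexicographically
#' smaller symbol, then accession.  Intergenic peaks still record the nearest
#' gene (minimal unsigned midpoint-to-body distance) when the chromosome has
#' one; `gene_symbol` is `NA` only when no model shares the chromosome.
#'
#' @param peaks peak data frame (consensus peaks from [match_peak_sets()] or
#'   any data frame with chrom/start/end).
#' @param models gene-model data frame.
#' @param window promoter/downstream window in bp (default 20000, i.e. the
#'   20 kb rule; positions farther than this from every TSS and transcript
#'   end are intergenic).
#' @return the input data frame with added columns `midpoint`, `gene_symbol`,
#'   `gene_accession`, `category` (factor over the five location levels) and
#'   `distance` (signed bp from midpoint to the TSS of the assigned gene,
#'   negative upstream of the TSS, strand-aware).
#' @export
annotate_peaks <- function(peaks, models, window = 20000) {
  validate_peaks(peaks)
  validate_gene_models(models)
  stopifnot(window >= 0)
  n <- nrow(peaks)
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  gene_symbol <- rep(NA_character_, n)
  gene_accession <- rep(NA_character_, n)
  category <- rep("intergenic", n)
  distance <- rep(NA_integer_, n)
  for (ch in unique(peaks$chrom)) {
    pidx <- which(peaks$chrom == ch)
    ms <- models[models$chrom == ch, , drop = FALSE]
    if (nrow(ms) == 0) next
    tss <- gene_tss(ms)
    last_base <- ifelse(ms$strand == "+", ms$end - 1L, ms$start)
    for (i in pidx) {
      m <- mid[i]
      inside <- m >= ms$start & m < ms$end
      # signed distance to TSS; negative = upstream of the TSS
      dsign <- ifelse(ms$strand == "+", m - tss, tss - m)
      ddown <- ifelse(ms$strand == "+", m - last_base, last_base - m)
      upstream <- !inside & dsign < 0 & -dsign <= window
      downstream <- !inside & ddown > 0 & ddown <= window
      priority <- ifelse(inside, 1L, ifelse(upstream, 2L,
                         ifelse(downstream, 3L, 4L)))
      dist_rank <- ifelse(inside, 0L, ifelse(upstream, -dsign,
                          ifelse(downstream, ddown, NA_integer_)))
      cand <- which(priority < 4L)
      if (length(cand) > 0) {
        j <- cand[order(priority[cand], dist_rank[cand], ms$symbol[cand],
                        ms$accession[cand], method = "radix")[1]]
        if (inside[j]) {
          es <- ms$exon_starts[[j]]
          ee <- ms$exon_ends[[j]]
          category[i] <- if (any(m >= es & m < ee)) "exonic" else "intronic"
        } else {
          category[i] <- if (upstream[j]) "five_prime_upstream" else
            "three_prime_downstream"
        }
      } else {
        # intergenic: still record the nearest gene by body distance
        dbody <- pmax(ms$start - m, m - (ms$end - 1L), 0L)
        j <- order(dbody, ms$symbol, ms$accession, method = "radix")[1]
        category[i] <- "intergenic"
      }
      gene_symbol[i] <- ms$symbol[j]
      gene_accession[i] <- ms$accession[j]
      distance[i] <- dsign[j]
    }
  }
  out <- peaks
  out$midpoint <- mid
  out$gene_symbol <- gene_symbol
  out$gene_accession <- gene_accession
  out$category <- factor(category, levels = LOCATION_LEVELS)
  out$distance <- distance
  out
}

#' Summarize peak location categories
#'
#' @param annotated annotated-peak data frame from [annotate_peaks()].
#' @return data frame with one row per location category: count and percent
#'   of all peaks (percent rounded to one decimal).
#' @export
location_summary <- function(annotated) {
  assert_cols(annotated, "category", "annotated")
  if (nrow(annotated) == 0) {
    stop("location_summary: empty input", call. = FALSE)
  }
  cat <- factor(as.character(annotated$category), levels = LOCATION_LEVELS)
  counts <- table(cat)
  data.frame(category = factor(LOCATION_LEVELS, levels = LOCATION_LEVELS),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / nrow(annotated), 1),
             stringsAsFactors = FALSE)
}
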