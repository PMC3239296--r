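#' Run the full ChIP-seq target-analysis pipeline
#'
#' Orchestrates the stages end to end: replicate consensus matching,
#' peak-to-gene annotation, Pol II occupancy quantification,
#' transcriptional-status classification, and (when the respective inputs
#' are provided) consensus-motif scanning and qPCR fold-change analysis.
#' All inputs are validated before any stage runs; per-stage record counts
#' are logged as messages.
#'
#' The configuration is a list (or the path of a YAML file holding one):
#' \describe{
#'   \item{rep1, rep2}{replicate peak BED paths (or peak data frames);
#'     rep1 is the deeper set and supplies representative fold enrichments}
#'   \item{gene_models}{refFlat/BED12 path (or gene-model data frame)}
#'   \item{gene_format}{"refFlat" (default) or "BED12"}
#'   \item{polii}{Pol II peak BED path with tag counts (or data frame)}
#'   \item{library_size}{total uniquely mapped Pol II reads}
#'   \item{fasta}{optional peak-sequence FASTA for the motif scan}
#'   \item{ct}{optional Ct table TSV (or data frame) for the qPCR stage}
#'   \item{max_gap, window}{consensus gap (50) and annotation window (20000)}
#'   \item{reference_symbol, reference_rpkm}{status yardstick; when
#'     `reference_rpkm` is absent it is looked up from the computed
#'     occupancy of `reference_symbol` (default "Actb")}
#'   \item{low_fraction, high_fraction}{status tier cuts (0.1, 0.5)}
#'   \item{motifs}{optional named character vector of IUPAC strings
#'     replacing [default_motifs()]}
#' }
#'
#' @param config list or YAML path (see details).
#' @param outdir optional output directory; when given, per-stage TSV/BED
#'   tables, a JSON summary and a run manifest with file checksums are
#'   written there.
#' @return an object of class `tf_target_run` with components `consensus`,
#'   `annotated`, `location`, `occupancy`, `status`, `best_peaks`,
#'   `peak_occupancy`, `motifs` (or NULL), `qpcr` (or NULL), `counts` and
#'   `config`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (key in c("rep1", "rep2", "gene_models", "polii", "library_size")) {
    if (is.null(config[[key]])) {
      stop("pipeline config is missing required entry '", key, "'",
           call. = FALSE)
    }
  }
  as_path <- function(x) is.character(x) && length(x) == 1
  for (key in c("rep1", "rep2", "gene_models", "polii", "fasta", "ct")) {
    v <- config[[key]]
    if (!is.null(v) && as_path(v) && !file.exists(v)) {
      stop("input file for '", key, "' not found: ", v, call. = FALSE)
    }
  }
  max_gap <- config$max_gap %||% 50
  window <- config$window %||% 20000
  ref_sym <- config$reference_symbol %||% "Actb"
  low_frac <- config$low_fraction %||% 0.1
  high_frac <- config$high_fraction %||% 0.5

  load_peaks <- function(x) if (is.data.frame(x)) x else read_peak_bed(x)
  rep1 <- load_peaks(config$rep1)
  rep2 <- load_peaks(config$rep2)
  models <- if (is.data.frame(config$gene_models)) config$gene_models else
    parse_gene_models(config$gene_models,
                      format = config$gene_format %||% "refFlat")
  polii <- load_peaks(config$polii)
  validate_peaks(polii, need_tags = TRUE)

  message(sprintf("consensus: %d + %d replicate peaks, max gap %d bp",
                  nrow(rep1), nrow(rep2), max_gap))
  consensus <- match_peak_sets(rep1, rep2, max_gap = max_gap)
  message(sprintf("consensus: %d matched peak pairs", nrow(consensus)))

  annotated <- annotate_peaks(consensus, models, window = window)
  location <- location_summary(annotated)
  assoc <- unique(annotated$gene_symbol[!is.na(annotated$gene_symbol)])
  message(sprintf("annotation: %d peaks assigned to %d genes",
                  sum(!is.na(annotated$gene_symbol)), length(assoc)))

  need_ref <- is.null(config$reference_rpkm)
  cohort <- if (need_ref) union(assoc, ref_sym) else assoc
  longest <- longest_model_per_symbol(models)
  cohort <- intersect(cohort, longest$symbol)
  if (need_ref && !ref_sym %in% cohort) {
    stop("reference gene '", ref_sym, "' has no gene model; supply ",
         "'reference_rpkm' directly", call. = FALSE)
  }
  occupancy <- polii_occupancy(models, polii, config$library_size,
                               symbols = cohort)
  message(sprintf("quantification: %d genes, library size %g",
                  nrow(occupancy), config$library_size))

  thresholds <- if (need_ref) NULL else
    status_thresholds(config$reference_rpkm, reference_symbol = ref_sym,
                      low_fraction = low_frac, high_fraction = high_frac)
  status <- status_summary(occupancy, thresholds = thresholds,
                           reference_symbol = ref_sym,
                           low_fraction = low_frac,
                           high_fraction = high_frac)
  message(sprintf("classification: %d genes, combined inactive %d%%",
                  status$n, status$combined_inactive_percent))

  best <- best_peak_per_gene(annotated)
  pk_occ <- peak_occupancy_table(best, occupancy)

  motifs_res <- NULL
  if (!is.null(config$fasta)) {
    seqs <- if (as_path(config$fasta)) read_peak_sequences(config$fasta)
            else config$fasta
    motif_set <- if (!is.null(config$motifs)) {
      mapply(motif_definition, names(config$motifs), config$motifs,
             SIMPLIFY = FALSE)
    } else default_motifs()
    motifs_res <- motif_summary(seqs, motif_set)
    message(sprintf("motif scan: %d peak sequences x %d motifs",
                    length(seqs), length(motif_set)))
  }

  qpcr_res <- NULL
  if (!is.null(config$ct)) {
    ct <- if (is.data.frame(config$ct)) config$ct else
      read_ct_table(config$ct)
    qpcr_res <- fold_change_table(ct)
    message(sprintf("qPCR: %d targets", nrow(qpcr_res)))
  }

  run <- structure(list(
    consensus = consensus, annotated = annotated, location = location,
    occupancy = occupancy, status = status, best_peaks = best,
    peak_occupancy = pk_occ, motifs = motifs_res, qpcr = qpcr_res,
    counts = c(rep1 = nrow(rep1), rep2 = nrow(rep2),
               consensus = nrow(consensus),
               genes = length(assoc), quantified = nrow(occupancy)),
    config = config), class = "tf_target_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Serialize every stage table plus a JSON summary and checksum manifest.
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(consensus = file.path(outdir, "consensus_peaks.bed"),
             annotated = file.path(outdir, "annotated_peaks.tsv"),
             location = file.path(outdir, "location_summary.tsv"),
             occupancy = file.path(outdir, "occupancy.tsv"),
             status = file.path(outdir, "status_table.tsv"),
             peak_occupancy = file.path(outdir, "peak_occupancy.tsv"),
             summary = file.path(outdir, "summary.json"))
  cons <- run$consensus
  cons_bed <- data.frame(cons$chrom, cons$start, cons$end, cons$name,
                         cons$representative_fe, ".", cons$fe_rep1,
                         cons$fe_rep2)
  utils::write.table(cons_bed, paths["consensus"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ann <- run$annotated
  write_tsv(ann[, c("chrom", "start", "end", "name", "representative_fe",
                    "midpoint", "gene_symbol", "gene_accession",
                    "category", "distance")], paths["annotated"])
  write_tsv(run$location, paths["location"])
  write_tsv(run$occupancy, paths["occupancy"])
  write_tsv(run$status$table, paths["status"])
  write_tsv(run$peak_occupancy, paths["peak_occupancy"])
  if (!is.null(run$motifs)) {
    paths["motifs"] <- file.path(outdir, "motif_summary.tsv")
    write_tsv(run$motifs, paths["motifs"])
  }
  if (!is.null(run$qpcr)) {
    paths["qpcr"] <- file.path(outdir, "qpcr_fold_changes.tsv")
    write_tsv(run$qpcr, paths["qpcr"])
  }
  summary_json <- list(
    counts = as.list(run$counts),
    location = stats::setNames(as.list(run$location$percent),
                               as.character(run$location$category)),
    status = list(
      percent = as.list(run$status$percent_rounded),
      combined_inactive_percent = run$status$combined_inactive_percent,
      reference_rpkm = run$status$thresholds$reference_rpkm),
    motifs = if (!is.null(run$motifs))
      stats::setNames(as.list(run$motifs$n_peaks_with_motif),
                      run$motifs$motif))
  jsonlite::write_json(summary_json, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  inputs <- Filter(function(x) is.character(x) && length(x) == 1 &&
                     file.exists(x),
                   run$config[c("rep1", "rep2", "gene_models", "polii",
                                "fasta", "ct")])
  manifest <- list(
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(unname(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = run$config[intersect(names(run$config),
                                      c("max_gap", "window",
                                        "reference_symbol",
                                        "reference_rpkm", "low_fraction",
                                        "high_fraction", "library_size"))],
    package_version = as.character(utils::packageVersion("chiptargets")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.tf_target_run <- function(x, ...) {
  cat("ChIP-seq target analysis run\n")
  cat(sprintf("  replicate peaks: %d / %d -> %d consensus peaks\n",
              x$counts["rep1"], x$counts["rep2"], x$counts["consensus"]))
  cat(sprintf("  associated genes: %d\n", x$counts["genes"]))
  loc <- x$location
  cat("  locations: ",
      paste(sprintf("%s %.1f%%", loc$category, loc$percent),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  status: zero %d%%, very_low %d%%, combined inactive %d%%\n",
              x$status$percent_rounded["zero"],
              x$status$percent_rounded["very_low"],
              x$status$combined_inactive_percent))
  if (!is.null(x$motifs)) {
    cat("  motif-bearing peaks: ",
        paste(sprintf("%s %d", x$motifs$motif, x$motifs$n_peaks_with_motif),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$qpcr)) {
    cat(sprintf("  qPCR targets: %d (%d significant at p < 0.05)\n",
                nrow(x$qpcr), sum(x$qpcr$p_value < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}

#' @method summary tf_target_run
#' @export
summary.tf_target_run <- function(object, ...) {
  list(counts = object$counts,
       location = object$location,
       status_counts = object$status$counts,
       status_percent = object$status$percent_rounded,
       combined_inactive_percent = object$status$combined_inactive_percent,
       motifs = object$motifs,
       qpcr = object$qpcr)
}
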