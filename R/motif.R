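IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Define an IUPAC consensus motif
#'
#' @param name motif name.
#' @param iupac consensus string over the IUPAC nucleotide alphabet
#'   (A C G T R Y S W K M B D H V N).
#' @param cap_per_peak when `TRUE` (default), peak-level counting records
#'   each peak at most once per motif (0-or-1 occurrence), regardless of how
#'   many sites it contains.
#' @return an object of class `motif_definition`.
#' @export
motif_definition <- function(name, iupac, cap_per_peak = TRUE) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "")[[1]]
  if (length(chars) == 0 || !all(chars %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC motif '", iupac,
         "': alphabet must be A C G T R Y S W K M B D H V N", call. = FALSE)
  }
  structure(list(name = name, iupac = iupac,
                 cap_per_peak = isTRUE(cap_per_peak)),
            class = "motif_definition")
}

#' Default consensus motif set
#'
#' Canonical consensi for the four motif families enriched in muscle
#' transcription-factor binding sites: the Sox heptamer (WWCAAWG; its
#' functional instance TACAAAG matches, the binding-dead variant TCAGAAG
#' does not), the muscle E-box CAGSTG (i.e. CAG[C/G]TG), the Runx core
#' TGYGGT, and the Tead/MCAT element CATTCCW.  All are overridable with
#' user-supplied IUPAC strings via [motif_definition()].
#'
#' @return named list of [motif_definition()] objects.
#' @export
default_motifs <- function() {
  list(Sox = motif_definition("Sox", "WWCAAWG"),
       Ebox = motif_definition("Ebox", "CAGSTG"),
       Runx = motif_definition("Runx", "TGYGGT"),
       Tead = motif_definition("Tead", "CATTCCW"))
}

# Zero-width lookahead regex for an IUPAC motif, so overlapping matches are
# all found.  N in the scanned sequence is matched only by an explicit N in
# the motif (each non-N code expands to its base set without N).
iupac_regex <- function(iupac) {
  chars <- strsplit(iupac, "")[[1]]
  paste0("(?=", paste0("[", IUPAC_SETS[chars], "]", collapse = ""), ")")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param x character vector of sequences (plain A/C/G/T/N or degenerate
#'   IUPAC codes).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(toupper(x), function(s) {
    chars <- rev(strsplit(s, "")[[1]])
    comp <- IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) {
      stop("cannot reverse-complement non-IUPAC character(s) in: ", s,
           call. = FALSE)
    }
    paste0(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Reports every offset where the motif matches the forward sequence, and
#' every offset where its reverse complement matches (a minus-strand site),
#' under IUPAC semantics.  Overlapping sites are all reported.  For
#' palindromic motifs a minus-strand hit spans exactly the same bases as the
#' plus-strand hit at the same offset; such duplicates are collapsed to the
#' plus-strand hit, so a single CAGCTG is one site, not two.
#'
#' @param seq a single DNA string over A/C/G/T/N (case-insensitive).
#' @param motif a [motif_definition()].
#' @return data frame with columns `position` (0-based offset of the site in
#'   the forward sequence), `strand` ("+" or "-") and `width`.
#' @export
scan_sequence <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_definition"), length(seq) == 1)
  seq <- toupper(seq)
  k <- nchar(motif$iupac)
  find <- function(pattern) {
    hits <- gregexpr(iupac_regex(pattern), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  }
  fwd <- find(motif$iupac)
  rev <- find(reverse_complement(motif$iupac))
  rev <- setdiff(rev, fwd)  # palindrome: same bases, report once as "+"
  pos <- c(fwd, rev)
  out <- data.frame(position = pos,
                    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                    width = rep(k, length(pos)), stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Count peaks containing a motif
#'
#' Scans every peak sequence with [scan_sequence()].  With the per-peak cap
#' (the default) the headline count is the number of peaks containing at
#' least one site — each peak contributes 0 or 1 — while the per-peak table
#' still records every site.  Without the cap the count is the total number
#' of sites.
#'
#' @param peak_seqs named character vector (or `DNAStringSet`) of peak
#'   sequences; names are peak ids.
#' @param motif a [motif_definition()].
#' @return list with `n_peaks_with_motif` (or total sites if uncapped, as
#'   `count`), `per_peak` (peak, n_sites, has_motif) and `hits` (peak,
#'   position, strand).
#' @export
count_peaks_with_motif <- function(peak_seqs, motif) {
  if (methods::is(peak_seqs, "DNAStringSet")) {
    peak_seqs <- stats::setNames(as.character(peak_seqs), names(peak_seqs))
  }
  stopifnot(inherits(motif, "motif_definition"))
  if (length(peak_seqs) == 0) {
    stop("count_peaks_with_motif: empty peak set", call. = FALSE)
  }
  if (is.null(names(peak_seqs))) {
    names(peak_seqs) <- sprintf("peak_%d", seq_along(peak_seqs))
  }
  scans <- lapply(peak_seqs, scan_sequence, motif = motif)
  n_sites <- vapply(scans, nrow, 1L)
  per_peak <- data.frame(peak = names(peak_seqs),
                         n_sites = n_sites,
                         has_motif = n_sites > 0L,
                         stringsAsFactors = FALSE)
  rownames(per_peak) <- NULL
  hits <- do.call(rbind, lapply(names(scans), function(id) {
    s <- scans[[id]]
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(peak = id, stringsAsFactors = FALSE), s)
  }))
  if (is.null(hits)) {
    hits <- data.frame(peak = character(), position = integer(),
                       strand = character(), width = integer(),
                       stringsAsFactors = FALSE)
  }
  count <- if (motif$cap_per_peak) sum(per_peak$has_motif) else sum(n_sites)
  list(n_peaks_with_motif = as.integer(count),
       per_peak = per_peak, hits = hits)
}

#' Motif counts over a peak set for several motifs
#'
#' @param peak_seqs named character vector (or `DNAStringSet`) of peak
#'   sequences.
#' @param motifs list of [motif_definition()] objects (default
#'   [default_motifs()]).
#' @return data frame: motif, iupac, n_peaks_with_motif, n_sites.
#' @export
motif_summary <- function(peak_seqs, motifs = default_motifs()) {
  rows <- lapply(motifs, function(m) {
    res <- count_peaks_with_motif(peak_seqs, m)
    data.frame(motif = m$name, iupac = m$iupac,
               n_peaks_with_motif = res$n_peaks_with_motif,
               n_sites = sum(res$per_peak$n_sites),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read peak sequences from a FASTA file
#'
#' Record ids are peak ids (the first whitespace-delimited token of each
#' header).
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_peak_sequences <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write peak sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_peak_sequences <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
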