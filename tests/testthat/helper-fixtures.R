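# Fixture builders and independent brute-force oracles used across tests.

# Build a gene-model data frame by writing refFlat text and parsing it, so
# fixtures exercise the same constructor path users take.
make_models <- function(symbol, accession, chrom, strand, start, end,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(symbol)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (is.null(exon_starts)) {
    exon_starts <- as.list(start)
    exon_ends <- as.list(end)
  }
  lines <- vapply(seq_len(n), function(i) {
    paste(symbol[i], accession[i], chrom[i], strand[i], start[i], end[i],
          start[i], end[i], length(exon_starts[[i]]),
          paste0(paste(exon_starts[[i]], collapse = ","), ","),
          paste0(paste(exon_ends[[i]], collapse = ","), ","), sep = "\t")
  }, character(1))
  tmp <- tempfile(fileext = ".refflat")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  read_refflat(tmp)
}

make_peaks <- function(chrom, start, end, fe = 1, name = NULL,
                       tag_count = NULL) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   name = name %||% sprintf("p%03d", seq_along(start)),
                   fold_enrichment = rep_len(fe, length(start)),
                   strand = ".", stringsAsFactors = FALSE)
  if (!is.null(tag_count)) df$tag_count <- as.integer(tag_count)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force oracles ---------------------------------------------------

# Exhaustive all-pairs greedy matcher: every candidate pair within max_gap,
# smallest gap first, symmetric tie-breaks, one-to-one.  Returns the matched
# (name_a, name_b) pairs sorted.
bf_match_pairs <- function(a, b, max_gap) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      gap <- max(0L, max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]))
      if (gap <= max_gap) {
        pairs[[length(pairs) + 1L]] <- c(i, j, gap,
                                         min(a$start[i], b$start[j]),
                                         max(a$start[i], b$start[j]),
                                         min(a$end[i], b$end[j]),
                                         max(a$end[i], b$end[j]))
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(name_a = character(), name_b = character()))
  }
  m <- do.call(rbind, pairs)
  ord <- order(m[, 3], m[, 4], m[, 5], m[, 6], m[, 7])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- c()
  for (k in ord) {
    if (!used_a[m[k, 1]] && !used_b[m[k, 2]]) {
      used_a[m[k, 1]] <- TRUE; used_b[m[k, 2]] <- TRUE
      keep <- c(keep, k)
    }
  }
  out <- data.frame(name_a = a$name[m[keep, 1]], name_b = b$name[m[keep, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$name_a), , drop = FALSE]
}

# Position-by-position location classifier over a whole chromosome, written
# as global boolean algebra (is the position inside any gene / any exon /
# any promoter window / any downstream window) rather than per-peak
# candidate ranking.  Assumes non-overlapping genes on one chromosome.
bf_classify_positions <- function(positions, models, window) {
  inside_any <- rep(FALSE, length(positions))
  exon_any <- rep(FALSE, length(positions))
  up_any <- rep(FALSE, length(positions))
  down_any <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(models))) {
    s <- models$start[i]; e <- models$end[i]
    inside <- positions >= s & positions < e
    inside_any <- inside_any | inside
    for (k in seq_along(models$exon_starts[[i]])) {
      exon_any <- exon_any | (positions >= models$exon_starts[[i]][k] &
                                positions < models$exon_ends[[i]][k])
    }
    if (models$strand[i] == "+") {
      up_any <- up_any | (positions < s & s - positions <= window)
      down_any <- down_any | (positions > e - 1 & positions - (e - 1) <= window)
    } else {
      up_any <- up_any | (positions > e - 1 & positions - (e - 1) <= window)
      down_any <- down_any | (positions < s & s - positions <= window)
    }
  }
  ifelse(inside_any, ifelse(exon_any, "exonic", "intronic"),
         ifelse(up_any, "five_prime_upstream",
                ifelse(down_any, "three_prime_downstream", "intergenic")))
}

# Plain reverse complement for test sequences (ACGT only).
bf_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Reference copy of largest-remainder allocation (independent of the
# package's internal helper).
largest_remainder_ref <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  rem <- round(total - sum(base))
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
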