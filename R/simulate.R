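#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults
#' describe the study conditions the generators emulate: a cohort of
#' transcription-factor-bound genes on a small genome, two replicate peak
#' sets jittered around shared true binding sites, Pol II tag counts
#' realizing prescribed occupancy tiers against an 8.60-RPKM housekeeping
#' reference with a 2.8 million read library, peak sequences with consensus
#' motifs planted at prescribed per-peak probabilities on a 42% GC
#' background, and two-group Ct matrices with prescribed fold changes and
#' Gaussian Ct noise (n = 3 per group).  Location-category and status-tier
#' fractions default to 13.6/0/48.4/8.8/29.2% and 51/33/13/3%; planted
#' partitions are realized exactly by largest-remainder allocation, never by
#' sampling.
#'
#' All generators are pure functions of (config, seed): each derives its own
#' random stream from the master seed by a fixed label, so reruns are
#' byte-identical and adding a generator never perturbs another's output.
#'
#' @param seed master integer seed.
#' @param n_chroms,chrom_length genome shape (bp).
#' @param n_genes number of gene models (includes the reference gene).
#' @param gene_length_range,exon_count_range per-gene transcript length (bp)
#'   and exon count ranges.
#' @param min_gene_gap minimum intergenic gap (bp); kept above twice the
#'   annotation window so planted categories cannot collide across genes.
#' @param n_true_peaks,peak_width true binding sites and their width (bp).
#' @param location_fractions named fractions over the five location
#'   categories (must sum to 1).
#' @param jitter_sd,dropout,n_background replicate noise: Gaussian positional
#'   jitter SD (bp), per-replicate site dropout rate, expected Poisson count
#'   of unrelated background peaks per replicate.
#' @param fe_meanlog,fe_sdlog log-normal fold-enrichment parameters.
#' @param status_fractions named fractions over the four occupancy tiers.
#' @param reference_symbol,reference_rpkm housekeeping yardstick gene and its
#'   planted occupancy.
#' @param library_size total mapped reads for the Pol II data set.
#' @param motif_probs named per-peak motif planting probabilities (names must
#'   exist in [default_motifs()]).
#' @param gc GC fraction of background sequence.
#' @param qpcr_folds named planted KO/control fold changes per qPCR target.
#' @param ct_noise_sd Gaussian Ct noise SD (cycles).
#' @param n_per_group qPCR samples per group.
#' @param window,max_gap annotation window and consensus matching gap (bp),
#'   carried along so a pipeline run can reuse the generating conditions.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 3500000L,
                       n_genes = 101L,
                       gene_length_range = c(2000L, 20000L),
                       exon_count_range = c(2L, 8L),
                       min_gene_gap = 45000L,
                       n_true_peaks = 400L,
                       peak_width = 200L,
                       location_fractions = c(five_prime_upstream = 0.136,
                                              exonic = 0,
                                              intronic = 0.484,
                                              three_prime_downstream = 0.088,
                                              intergenic = 0.292),
                       jitter_sd = 10,
                       dropout = 0.1,
                       n_background = 20,
                       fe_meanlog = log(10),
                       fe_sdlog = 0.5,
                       status_fractions = c(zero = 0.51, very_low = 0.33,
                                            low_moderate = 0.13,
                                            high = 0.03),
                       reference_symbol = "Actb",
                       reference_rpkm = 8.60,
                       library_size = 2800000,
                       motif_probs = c(Sox = 0.68, Ebox = 0.60,
                                       Runx = 0.52, Tead = 0.19),
                       gc = 0.42,
                       qpcr_folds = c(Myh7 = 779.78, Prox1 = 29.26,
                                      Myog = 3.64, Sdha = 1.02,
                                      Myh4 = 0.03),
                       ct_noise_sd = 0.3,
                       n_per_group = 3L,
                       window = 20000L,
                       max_gap = 50L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              exon_count_range = as.integer(exon_count_range),
              min_gene_gap = as.integer(min_gene_gap),
              n_true_peaks = as.integer(n_true_peaks),
              peak_width = as.integer(peak_width),
              location_fractions = location_fractions,
              jitter_sd = jitter_sd, dropout = dropout,
              n_background = n_background,
              fe_meanlog = fe_meanlog, fe_sdlog = fe_sdlog,
              status_fractions = status_fractions,
              reference_symbol = reference_symbol,
              reference_rpkm = reference_rpkm,
              library_size = library_size,
              motif_probs = motif_probs, gc = gc,
              qpcr_folds = qpcr_folds, ct_noise_sd = ct_noise_sd,
              n_per_group = as.integer(n_per_group),
              window = as.integer(window), max_gap = as.integer(max_gap))
  stopifnot(cfg$n_chroms > 0, cfg$chrom_length > 0, cfg$n_genes > 0,
            cfg$n_true_peaks > 0, cfg$peak_width > 0,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$jitter_sd >= 0, cfg$gc > 0, cfg$gc < 1,
            cfg$library_size > 0, cfg$reference_rpkm > 0,
            cfg$n_per_group >= 1)
  if (abs(sum(cfg$location_fractions) - 1) > 1e-8 ||
      is.null(names(cfg$location_fractions)) ||
      !all(names(cfg$location_fractions) %in% LOCATION_LEVELS)) {
    stop("location_fractions must be named over the location categories and sum to 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$status_fractions) - 1) > 1e-8 ||
      !setequal(names(cfg$status_fractions), STATUS_LEVELS)) {
    stop("status_fractions must be named zero/very_low/low_moderate/high and sum to 1",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome: gene models, chromosome sizes, sequence
#'
#' Genes are placed without overlap, separated by at least `min_gene_gap`,
#' with valid exon structure (exons tile the body boundaries, introns in
#' between).  The first gene is the housekeeping reference
#' (`config$reference_symbol`).  Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param with_sequence also generate background chromosome sequence at the
#'   configured GC fraction (off by default; peak sequences are generated
#'   separately by [simulate_peak_sequences()]).
#' @return list with `models` (gene-model data frame), `chrom_sizes` (named
#'   integer vector) and `sequence` (named character vector or `NULL`).
#' @export
simulate_genome <- function(config, with_sequence = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config$seed, "genome"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    per_chrom <- largest_remainder(
      stats::setNames(rep(1 / config$n_chroms, config$n_chroms), chroms),
      config$n_genes)
    rows <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      k <- per_chrom[ci]
      if (k == 0) next
      len <- as.integer(round(stats::runif(k, config$gene_length_range[1],
                                           config$gene_length_range[2])))
      extra <- config$chrom_length - sum(len) -
        (k + 1) * config$min_gene_gap
      if (extra < 0) {
        stop("cannot place ", k, " genes on a ", config$chrom_length,
             " bp chromosome at the requested density", call. = FALSE)
      }
      u <- sort(stats::runif(k))
      props <- diff(c(0, u, 1))
      gaps <- config$min_gene_gap + floor(props * extra)
      starts <- as.integer(cumsum(gaps[seq_len(k)]) +
                             cumsum(c(0L, len[-k])))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      for (j in seq_len(k)) {
        gi <- gi + 1L
        n_ex <- sample(seq(config$exon_count_range[1],
                           config$exon_count_range[2]), 1)
        m <- 2L * n_ex - 1L  # exon/intron segments
        if (len[j] < 20L * m) n_ex <- max(1L, (len[j] %/% 20L + 1L) %/% 2L)
        m <- 2L * n_ex - 1L
        seg <- rep(20L, m)
        remn <- len[j] - sum(seg)
        wgt <- stats::runif(m)
        add <- floor(wgt / sum(wgt) * remn)
        seg <- seg + as.integer(add)
        seg[1] <- seg[1] + (len[j] - sum(seg))
        bounds <- starts[j] + cumsum(c(0L, seg))
        ex_idx <- seq(1, m, by = 2)
        rows[[gi]] <- list(
          accession = sprintf("NM_%06d", gi),
          symbol = if (gi == 1L) config$reference_symbol else
            sprintf("G%04d", gi),
          chrom = chroms[ci], strand = strand[j],
          start = starts[j], end = starts[j] + len[j],
          exon_starts = bounds[ex_idx],
          exon_ends = bounds[ex_idx + 1L])
      }
    }
    models <- new_gene_models(
      accession = vapply(rows, `[[`, character(1), "accession"),
      symbol = vapply(rows, `[[`, character(1), "symbol"),
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      start = vapply(rows, `[[`, numeric(1), "start"),
      end = vapply(rows, `[[`, numeric(1), "end"),
      exon_starts = lapply(rows, `[[`, "exon_starts"),
      exon_ends = lapply(rows, `[[`, "exon_ends"))
    sizes <- stats::setNames(rep(config$chrom_length, length(chroms)),
                             chroms)
    sequence <- NULL
    if (with_sequence) {
      p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
      sequence <- stats::setNames(vapply(chroms, function(ch) {
        paste0(sample(names(p), config$chrom_length, replace = TRUE,
                      prob = p), collapse = "")
      }, character(1)), chroms)
    }
    list(models = models, chrom_sizes = sizes, sequence = sequence)
  })
}

# Pick a uniform midpoint for one true site of the requested category.
place_site_midpoint <- function(category, gene, models_by_chrom, config) {
  w <- config$window
  margin <- 200L
  switch(category,
    intronic = {
      es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
      istart <- ee[-length(ee)]; iend <- es[-1]
      ok <- which(iend - istart >= 3L)
      i <- ok[sample.int(length(ok), 1)]
      sample(seq(istart[i], iend[i] - 1L), 1)
    },
    exonic = {
      es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
      ok <- which(ee - es >= 3L)
      i <- ok[sample.int(length(ok), 1)]
      sample(seq(es[i], ee[i] - 1L), 1)
    },
    five_prime_upstream = {
      d <- sample(seq(margin, w - margin), 1)
      if (gene$strand == "+") gene$start - d else (gene$end - 1L) + d
    },
    three_prime_downstream = {
      d <- sample(seq(margin, w - margin), 1)
      if (gene$strand == "+") (gene$end - 1L) + d else gene$start - d
    },
    stop("unsupported planted category: ", category, call. = FALSE))
}

#' Generate two replicate peak sets around shared true binding sites
#'
#' True sites realize the configured location-category fractions exactly
#' (largest-remainder allocation); when there are at least as many
#' gene-proximal sites as genes, every gene receives at least one, so the
#' gene cohort and the peak-associated gene set coincide.  Each replicate
#' contains each true site independently with probability `1 - dropout`,
#' positionally jittered by round(Normal(0, jitter_sd)), with log-normal
#' fold enrichments, plus a Poisson number of unrelated background peaks.
#'
#' @param config a [sim_config()].
#' @param models gene models from [simulate_genome()].
#' @return list with `rep1`, `rep2` (peak data frames) and `truth` (per-site
#'   chrom/start/end, planted category, planted gene, per-replicate
#'   presence).
#' @export
simulate_peak_replicates <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  validate_gene_models(models)
  with_seed(stream_seed(config$seed, "peaks"), {
    n <- config$n_true_peaks
    w <- config$peak_width
    half <- w %/% 2L
    counts <- largest_remainder(config$location_fractions, n)
    categories <- rep(names(counts), counts)
    categories <- sample(categories)  # interleave before gene assignment
    genic <- which(categories != "intergenic")
    gene_for <- rep(NA_integer_, n)
    ng <- nrow(models)
    if (length(genic) > 0) {
      first <- utils::head(genic, ng)
      gene_for[first] <- sample.int(ng, length(first))
      restn <- length(genic) - length(first)
      if (restn > 0) {
        gene_for[genic[-seq_along(first)]] <-
          sample.int(ng, restn, replace = TRUE)
      }
    }
    # per-chromosome intergenic pockets: > window from every gene boundary
    pockets <- list()
    for (ch in unique(models$chrom)) {
      ms <- models[models$chrom == ch, , drop = FALSE]
      ms <- ms[order(ms$start), , drop = FALSE]
      edges <- c(0L, rbind(ms$start, ms$end), config$chrom_length)
      lo <- edges[seq(1, length(edges) - 1, by = 2)] + config$window + 500L
      hi <- edges[seq(2, length(edges), by = 2)] - config$window - 500L
      ok <- hi - lo >= 1L
      pockets[[ch]] <- data.frame(chrom = ch, lo = lo[ok], hi = hi[ok])
    }
    pockets <- do.call(rbind, pockets)
    if (any(categories == "intergenic") && nrow(pockets) == 0) {
      stop("no intergenic pocket wide enough for planted intergenic sites",
           call. = FALSE)
    }
    mid <- integer(n)
    chrom <- character(n)
    used <- lapply(unique(models$chrom), function(x) integer(0))
    names(used) <- unique(models$chrom)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        if (categories[i] == "intergenic") {
          pk <- pockets[sample.int(nrow(pockets), 1,
                                   prob = pockets$hi - pockets$lo), ]
          ch <- pk$chrom
          m <- pk$lo + sample.int(pk$hi - pk$lo + 1L, 1) - 1L
        } else {
          g <- models[gene_for[i], , drop = FALSE]
          ch <- g$chrom
          m <- place_site_midpoint(categories[i], g, NULL, config)
        }
        if (all(abs(used[[ch]] - m) >= 2L * w)) break
      }
      used[[ch]] <- c(used[[ch]], m)
      mid[i] <- m
      chrom[i] <- ch
    }
    truth <- data.frame(
      site = sprintf("site_%04d", seq_len(n)),
      chrom = chrom, start = mid - half, end = mid - half + w,
      category = factor(categories, levels = LOCATION_LEVELS),
      gene_symbol = ifelse(is.na(gene_for), NA_character_,
                           models$symbol[gene_for]),
      stringsAsFactors = FALSE)
    # generator self-check: planted categories must be what the annotator sees
    ann <- annotate_peaks(truth, models, window = config$window)
    stopifnot(identical(as.character(ann$category),
                        as.character(truth$category)))
    make_rep <- function(r) {
      present <- stats::runif(n) >= config$dropout
      shift <- as.integer(round(stats::rnorm(n, 0, config$jitter_sd)))
      fe <- stats::rlnorm(n, config$fe_meanlog, config$fe_sdlog)
      df <- data.frame(chrom = truth$chrom,
                       start = pmax(0L, truth$start + shift),
                       end = pmax(0L, truth$start + shift) + w,
                       name = paste0(truth$site, "_r", r),
                       fold_enrichment = fe,
                       strand = ".", stringsAsFactors = FALSE)
      df <- df[present, , drop = FALSE]
      nb <- stats::rpois(1, config$n_background)
      if (nb > 0) {
        bch <- sample(names(used), nb, replace = TRUE)
        bst <- vapply(bch, function(ch)
          sample.int(config$chrom_length - w, 1), integer(1))
        df <- rbind(df, data.frame(
          chrom = bch, start = bst, end = bst + w,
          name = sprintf("bg_r%d_%03d", r, seq_len(nb)),
          fold_enrichment = stats::rlnorm(nb, config$fe_meanlog,
                                          config$fe_sdlog),
          strand = ".", stringsAsFactors = FALSE))
      }
      df <- df[order(df$chrom, df$start, df$end, method = "radix"), ,
               drop = FALSE]
      rownames(df) <- NULL
      list(peaks = df, present = present)
    }
    r1 <- make_rep(1)
    r2 <- make_rep(2)
    truth$in_rep1 <- r1$present
    truth$in_rep2 <- r2$present
    list(rep1 = r1$peaks, rep2 = r2$peaks, truth = truth)
  })
}

#' Generate a Pol II peak profile realizing planted occupancy tiers
#'
#' Every non-reference gene is assigned a tier by largest-remainder
#' allocation of `status_fractions`; the reference gene is pinned at
#' `reference_rpkm`.  For each non-zero gene a target RPKM is drawn from the
#' interior of its tier (at least 1.5 tag-equivalents from either boundary,
#' so integer tag rounding cannot change the tier), tag counts are
#' back-solved as C = round(rpkm * (L/1000) * (N/1e6)) with L the effective
#' region length including any planted peak protrusions, and the tags are
#' multinomially distributed over 1-3 peaks inside (or slightly protruding
#' from) the gene.  Zero-tier genes emit no peaks.
#'
#' @param config a [sim_config()].
#' @param models gene models (must contain the reference gene).
#' @return list with `peaks` (Pol II peak data frame with tag counts) and
#'   `truth` (per-gene tier, target and achieved RPKM, tag count, effective
#'   length).
#' @export
simulate_polii <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  validate_gene_models(models)
  if (!config$reference_symbol %in% models$symbol) {
    stop("reference gene '", config$reference_symbol,
         "' missing from the gene models", call. = FALSE)
  }
  with_seed(stream_seed(config$seed, "polii"), {
    N <- config$library_size
    R <- config$reference_rpkm
    th <- status_thresholds(R, config$reference_symbol)
    is_ref <- models$symbol == config$reference_symbol
    others <- which(!is_ref)
    tier_counts <- largest_remainder(
      config$status_fractions[STATUS_LEVELS], length(others))
    tier <- rep(NA_character_, nrow(models))
    tier[sample(others)] <- rep(STATUS_LEVELS, tier_counts)
    tier[is_ref] <- "high"  # 8.60 > R/2 by construction
    tier_bounds <- list(very_low = c(0, 0.1 * R),
                        low_moderate = c(0.1 * R, 0.5 * R),
                        high = c(0.5 * R, 2.5 * R))
    peak_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(models))) {
      g <- models[i, , drop = FALSE]
      sym <- g$symbol
      if (tier[i] == "zero") {
        truth_rows[[i]] <- data.frame(
          symbol = sym, tier = "zero", target_rpkm = 0,
          achieved_rpkm = 0, tag_count = 0L,
          effective_length = g$end - g$start, stringsAsFactors = FALSE)
        next
      }
      len <- g$end - g$start
      left_ext <- if (stats::runif(1) < 0.3) sample(50:300, 1) else 0L
      right_ext <- if (stats::runif(1) < 0.3) sample(50:300, 1) else 0L
      L <- len + left_ext + right_ext
      tag_unit <- (1 / (L / 1000)) / (N / 1e6)  # RPKM of a single tag
      if (is_ref[i]) {
        target <- R
      } else {
        b <- tier_bounds[[tier[i]]]
        marg <- max(1.5 * tag_unit, 0.02 * (b[2] - b[1]))
        lo <- b[1] + marg
        hi <- b[2] - marg
        target <- if (lo < hi) stats::runif(1, lo, hi) else mean(b)
      }
      C <- max(1L, as.integer(round(target * (L / 1000) * (N / 1e6))))
      achieved <- (C / (L / 1000)) / (N / 1e6)
      if (!is_ref[i]) {
        stopifnot(as.character(classify_status(achieved, th)) == tier[i])
      }
      npk <- if (len < 1500) 1L else sample(1:3, 1)
      if (npk > 1) {  # cuts on a 100 bp grid so trimmed segments stay wide
        grid <- seq(g$start + 200L, g$end - 200L, by = 100L)
        cuts <- sort(sample(grid, npk - 1L))
      } else cuts <- integer(0)
      bounds <- c(g$start - left_ext, cuts, g$end + right_ext)
      pstart <- bounds[-length(bounds)]
      pend <- bounds[-1]
      if (npk > 1) {  # trim interior edges so peaks are visibly separate
        trim <- sample(10:40, npk - 1L, replace = TRUE)
        pend[-npk] <- pend[-npk] - trim
        pstart[-1] <- pstart[-1] + sample(10:40, npk - 1L, replace = TRUE)
      }
      tags <- as.integer(stats::rmultinom(1, C, prob = pend - pstart))
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = as.integer(pstart), end = as.integer(pend),
        name = sprintf("polii_%s_%d", sym, seq_len(npk)),
        fold_enrichment = round(stats::rlnorm(npk, log(5), 0.4), 3),
        strand = ".", tag_count = tags, stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        symbol = sym, tier = tier[i], target_rpkm = target,
        achieved_rpkm = achieved, tag_count = C,
        effective_length = as.integer(L), stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$chrom, peaks$start, method = "radix"), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(peaks = peaks, truth = truth)
  })
}

# Realize one concrete instance of an IUPAC consensus (no N emitted).
realize_iupac <- function(iupac) {
  chars <- strsplit(iupac, "")[[1]]
  paste0(vapply(chars, function(cc) {
    set <- setdiff(strsplit(IUPAC_SETS[[cc]], "")[[1]], "N")
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

#' Generate peak sequences with planted motifs
#'
#' Each peak gets an i.i.d. background sequence at the configured GC
#' fraction; each configured motif is inserted (one concrete instance,
#' random strand and offset, non-overlapping with other insertions in the
#' same peak) with its per-peak planting probability.
#'
#' @param config a [sim_config()].
#' @param peaks peak data frame (needs name, start, end) — typically the
#'   truth sites from [simulate_peak_replicates()] or consensus peaks.
#' @return list with `seqs` (named character vector) and `truth` (one row
#'   per peak x motif: planted flag, offset, strand, instance).
#' @export
simulate_peak_sequences <- function(config, peaks) {
  stopifnot(inherits(config, "sim_config"))
  assert_cols(peaks, c("start", "end"), "peaks")
  motifs <- default_motifs()
  use <- names(config$motif_probs)
  if (!all(use %in% names(motifs))) {
    stop("motif_probs names must be among: ",
         paste(names(motifs), collapse = ", "), call. = FALSE)
  }
  widths <- peaks$end - peaks$start
  maxlen <- max(vapply(motifs[use], function(m) nchar(m$iupac), 1L))
  if (any(widths < maxlen)) {
    stop("peak(s) shorter than the longest motif cannot carry a planted instance",
         call. = FALSE)
  }
  ids <- if (!is.null(peaks$name)) peaks$name else
    if (!is.null(peaks$site)) peaks$site else
      sprintf("peak_%04d", seq_len(nrow(peaks)))
  with_seed(stream_seed(config$seed, "seqs"), {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- character(nrow(peaks))
    truth <- list()
    for (i in seq_len(nrow(peaks))) {
      chars <- sample(names(p), widths[i], replace = TRUE, prob = p)
      occupied <- matrix(numeric(0), ncol = 2)
      for (mn in use) {
        m <- motifs[[mn]]
        k <- nchar(m$iupac)
        planted <- stats::runif(1) < config$motif_probs[[mn]]
        off <- NA_integer_; strand <- NA_character_; inst <- NA_character_
        if (planted) {
          for (try in 1:50) {
            cand <- sample.int(widths[i] - k + 1L, 1) - 1L  # 0-based
            clash <- nrow(occupied) > 0 &&
              any(cand < occupied[, 2] & cand + k > occupied[, 1])
            if (!clash) break
          }
          off <- cand
          strand <- sample(c("+", "-"), 1)
          inst <- realize_iupac(m$iupac)
          put <- if (strand == "+") inst else reverse_complement(inst)
          chars[(off + 1):(off + k)] <- strsplit(put, "")[[1]]
          occupied <- rbind(occupied, c(off, off + k))
        }
        truth[[length(truth) + 1L]] <- data.frame(
          peak = ids[i], motif = mn, planted = planted,
          position = off, strand = strand, instance = inst,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- paste0(chars, collapse = "")
    }
    list(seqs = stats::setNames(seqs, ids), truth = do.call(rbind, truth))
  })
}

#' Generate a two-group qPCR Ct matrix with planted fold changes
#'
#' Each target gets a control delta-Ct baseline (uniform 3-9 cycles above
#' the reference); knockout samples are shifted by -log2(planted fold);
#' Gaussian Ct noise is added to every sample's target Ct.  The reference Ct
#' is held at 20 cycles.
#'
#' @param config a [sim_config()].
#' @return list with `ct` (data frame: sample, group, target, ct_target,
#'   ct_reference) and `truth` (per-target planted fold).
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config$seed, "ct"), {
    n <- config$n_per_group
    rows <- list()
    for (target in names(config$qpcr_folds)) {
      fold <- config$qpcr_folds[[target]]
      base <- stats::runif(1, 3, 9)
      dct <- c(base + stats::rnorm(n, 0, config$ct_noise_sd),
               base - log2(fold) + stats::rnorm(n, 0, config$ct_noise_sd))
      rows[[target]] <- data.frame(
        sample = c(sprintf("control_%d", seq_len(n)),
                   sprintf("ko_%d", seq_len(n))),
        group = rep(c("control", "ko"), each = n),
        target = target,
        ct_target = 20 + dct,
        ct_reference = 20,
        stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    list(ct = ct,
         truth = data.frame(target = names(config$qpcr_folds),
                            fold = unname(config$qpcr_folds),
                            stringsAsFactors = FALSE))
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Runs every generator and writes the same formats the pipeline reads:
#' refFlat gene models, a chromosome-sizes TSV, two replicate peak BEDs, a
#' Pol II peak BED with tag counts, a peak-sequence FASTA (for the true
#' sites), a Ct TSV, and a truth JSON.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with `files` (named paths), `truth` (per-stage
#'   truth tables) and `config`.
#' @export
simulate_inputs <- function(config = sim_config(), outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  reps <- simulate_peak_replicates(config, genome$models)
  polii <- simulate_polii(config, genome$models)
  seqs <- simulate_peak_sequences(
    config, stats::setNames(reps$truth[c("chrom", "start", "end", "site")],
                            c("chrom", "start", "end", "name")))
  ctm <- simulate_ct(config)
  paths <- c(gene_models = file.path(outdir, "genes.refflat"),
             chrom_sizes = file.path(outdir, "chrom.sizes"),
             rep1 = file.path(outdir, "rep1.bed"),
             rep2 = file.path(outdir, "rep2.bed"),
             polii = file.path(outdir, "polii.bed"),
             fasta = file.path(outdir, "peaks.fasta"),
             ct = file.path(outdir, "ct.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_refflat(genome$models, paths["gene_models"])
  utils::write.table(data.frame(names(genome$chrom_sizes),
                                unname(genome$chrom_sizes)),
                     paths["chrom_sizes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_peak_bed(reps$rep1, paths["rep1"], extra = character(0))
  write_peak_bed(reps$rep2, paths["rep2"], extra = character(0))
  write_peak_bed(polii$peaks, paths["polii"], extra = "tag_count")
  write_peak_sequences(seqs$seqs, paths["fasta"])
  write_tsv(ctm$ct, paths["ct"])
  truth <- list(sites = reps$truth, polii = polii$truth,
                motifs = seqs$truth, qpcr = ctm$truth)
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       na = "null", digits = NA)
  invisible(list(files = paths, truth = truth, config = config))
}
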