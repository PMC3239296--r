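noiseless <- function(seed = 31, ...) {
  sim_config(seed = seed, jitter_sd = 0, dropout = 0, n_background = 0, ...)
}

test_that("generators are byte-identical across reruns with the same seed", {
  cfg <- sim_config(seed = 17, n_genes = 25, n_true_peaks = 50)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("independent random streams: one generator does not perturb another", {
  cfg <- sim_config(seed = 17, n_genes = 25, n_true_peaks = 50)
  g <- simulate_genome(cfg)
  ct_a <- simulate_ct(cfg)
  invisible(simulate_peak_replicates(cfg, g$models))  # interleaved call
  ct_b <- simulate_ct(cfg)
  expect_identical(ct_a$ct, ct_b$ct)
})

test_that("the synthetic genome honours its contract and density limits", {
  cfg <- sim_config(seed = 3, n_genes = 100)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$models), 100)
  expect_true(cfg$reference_symbol %in% g$models$symbol)
  # non-overlapping with the configured minimum gap, per chromosome
  for (ch in names(g$chrom_sizes)) {
    ms <- g$models[g$models$chrom == ch, ]
    ms <- ms[order(ms$start), ]
    if (nrow(ms) > 1) {
      expect_true(all(ms$start[-1] - ms$end[-nrow(ms)] >= cfg$min_gene_gap))
    }
    expect_true(all(ms$end <= g$chrom_sizes[ch]))
  }
  expect_error(simulate_genome(sim_config(seed = 3, n_genes = 500)),
               "density")
})

test_that("noiseless replicates recover every true site and planted category", {
  cfg <- noiseless(seed = 21)
  g <- simulate_genome(cfg)
  reps <- simulate_peak_replicates(cfg, g$models)
  cons <- match_peak_sets(reps$rep1, reps$rep2, max_gap = cfg$max_gap)
  expect_equal(nrow(cons), cfg$n_true_peaks)
  ann <- annotate_peaks(cons, g$models, window = cfg$window)
  got <- location_summary(ann)
  want <- table(factor(as.character(reps$truth$category),
                       levels = levels(reps$truth$category)))
  expect_equal(got$count, as.integer(want))
  # planted genes annotate back to themselves
  truth_gene <- reps$truth$gene_symbol[match(sub("_r1$", "", cons$name_rep1),
                                             reps$truth$site)]
  genic <- !is.na(truth_gene)
  expect_equal(ann$gene_symbol[genic], truth_gene[genic])
})

test_that("dropout thins the consensus near its (1-d)^2 expectation", {
  cfg <- sim_config(seed = 29, dropout = 0.2, n_background = 0,
                    n_true_peaks = 400)
  g <- simulate_genome(cfg)
  reps <- simulate_peak_replicates(cfg, g$models)
  cons <- match_peak_sets(reps$rep1, reps$rep2, max_gap = cfg$max_gap)
  p <- (1 - cfg$dropout)^2
  sd3 <- 3 * sqrt(cfg$n_true_peaks * p * (1 - p))
  expect_lt(abs(nrow(cons) - cfg$n_true_peaks * p), sd3)
  # both-replicate presence in the truth table matches the observed pairs
  expect_gte(nrow(cons), sum(reps$truth$in_rep1 & reps$truth$in_rep2))
})

test_that("planted occupancy tiers are realized exactly, with the reference pinned", {
  cfg <- sim_config(seed = 37, n_genes = 101)
  g <- simulate_genome(cfg)
  pol <- simulate_polii(cfg, g$models)
  occ <- polii_occupancy(g$models, pol$peaks, cfg$library_size)
  # reference gene within one tag of the configured value
  ref <- occ$rpkm[occ$symbol == cfg$reference_symbol]
  L <- pol$truth$effective_length[pol$truth$symbol == cfg$reference_symbol]
  tag_unit <- (1 / (L / 1000)) / (cfg$library_size / 1e6)
  expect_lt(abs(ref - cfg$reference_rpkm), tag_unit)
  # recovered tiers equal the planted allocation
  s <- status_summary(occ, reference_symbol = cfg$reference_symbol)
  planted <- table(factor(pol$truth$tier[pol$truth$symbol !=
                                           cfg$reference_symbol],
                          levels = names(s$counts)))
  expect_equal(unname(s$counts), as.integer(planted))
  expect_equal(unname(s$percent_rounded[c("zero", "very_low")]),
               c(51L, 33L))
  expect_equal(s$combined_inactive_percent, 84L)
})

test_that("motif planting saturates at probability 1 and vanishes at 0 within the analytic rate", {
  peaks <- data.frame(name = sprintf("pk%03d", 1:500),
                      chrom = "chr1",
                      start = seq(0, by = 1000, length.out = 500))
  peaks$end <- peaks$start + 200L
  cfg1 <- sim_config(seed = 41, motif_probs = c(Sox = 1), gc = 0.5)
  seqs1 <- simulate_peak_sequences(cfg1, peaks)
  sox <- default_motifs()$Sox
  expect_equal(count_peaks_with_motif(seqs1$seqs, sox)$n_peaks_with_motif,
               500L)
  # probability 0: observed positives are chance background matches
  cfg0 <- sim_config(seed = 43, motif_probs = c(Sox = 0), gc = 0.5)
  seqs0 <- simulate_peak_sequences(cfg0, peaks)
  obs <- count_peaks_with_motif(seqs0$seqs, sox)$n_peaks_with_motif
  k <- nchar(sox$iupac)
  p_window <- prod(c(0.5, 0.5, 0.25, 0.25, 0.25, 0.5, 0.25))  # WWCAAWG
  p_hit <- 1 - (1 - 2 * p_window)^(200 - k + 1)
  sd3 <- 3 * sqrt(500 * p_hit * (1 - p_hit))
  expect_lt(abs(obs - 500 * p_hit), sd3)
})

test_that("planted motif instances are always detected and truth marks them", {
  peaks <- data.frame(name = sprintf("pk%03d", 1:200), chrom = "chr1",
                      start = 0L, end = 200L)
  cfg <- sim_config(seed = 47)
  seqs <- simulate_peak_sequences(cfg, peaks)
  for (mn in names(cfg$motif_probs)) {
    m <- default_motifs()[[mn]]
    res <- count_peaks_with_motif(seqs$seqs, m)
    planted <- seqs$truth$peak[seqs$truth$motif == mn & seqs$truth$planted]
    expect_true(all(res$per_peak$has_motif[res$per_peak$peak %in% planted]))
  }
})

test_that("noiseless Ct matrices return the planted folds exactly", {
  cfg <- sim_config(seed = 53, ct_noise_sd = 0)
  ctm <- simulate_ct(cfg)
  tab <- fold_change_table(ctm$ct)
  want <- ctm$truth$fold[match(tab$target, ctm$truth$target)]
  expect_equal(tab$fold, want, tolerance = 1e-12)
})
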