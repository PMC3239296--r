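one_gene <- function(start = 1000, end = 3000) {
  make_models("GENE", "NM_1", "chr1", "+", start, end)
}

test_that("fully contained peaks add nothing to the effective region", {
  gene <- one_gene()
  peaks <- make_peaks("chr1", 1500, 2500, tag_count = 100)
  reg <- effective_gene_region(gene, peaks)
  expect_equal(reg$effective_length, 2000L)
  expect_equal(nrow(reg$overlapping), 1)
})

test_that("peak protrusions extend the effective region by their footprint", {
  gene <- one_gene()
  # one peak protruding 500 bp past the 3' end
  reg <- effective_gene_region(gene, make_peaks("chr1", 2500, 3500,
                                                tag_count = 10))
  expect_equal(reg$effective_length, 2500L)
  # protrusions on both sides: 300 left + 200 right
  reg <- effective_gene_region(gene, make_peaks("chr1", c(700, 2800),
                                                c(1200, 3200),
                                                tag_count = c(5, 5)))
  expect_equal(reg$effective_length, 2500L)
  # overlapping protrusions on the same side are merged, not summed
  reg <- effective_gene_region(gene, make_peaks("chr1", c(700, 800),
                                                c(1200, 1300),
                                                tag_count = c(5, 5)))
  expect_equal(reg$effective_length, 2300L)
  # a non-overlapping peak is ignored entirely
  reg <- effective_gene_region(gene, make_peaks("chr1", 5000, 6000,
                                                tag_count = 50))
  expect_equal(reg$effective_length, 2000L)
  expect_equal(nrow(reg$overlapping), 0)
})

test_that("compute_rpkm evaluates the closed-form RPKM", {
  gene <- one_gene()  # 2000 bp
  # C=100, L=2000, N=1e6 -> (100/2)/1 = 50
  rec <- compute_rpkm(gene, make_peaks("chr1", 1500, 2500, tag_count = 100),
                      library_size = 1e6)
  expect_equal(rec$rpkm, 50)
  expect_equal(rec$tag_count, 100L)
  expect_equal(rec$effective_length, 2000L)
  # no overlapping peak -> exactly 0
  rec <- compute_rpkm(gene, make_peaks("chr1", 9000, 9500, tag_count = 7),
                      library_size = 1e6)
  expect_equal(rec$rpkm, 0)
})

test_that("rpkm is invariant to joint scaling of tags and library size", {
  gene <- one_gene()
  p1 <- make_peaks("chr1", 1500, 2500, tag_count = 120)
  p2 <- p1; p2$tag_count <- p1$tag_count * 2L
  r1 <- compute_rpkm(gene, p1, library_size = 2e6)
  r2 <- compute_rpkm(gene, p2, library_size = 4e6)
  expect_equal(r1$rpkm, r2$rpkm)
})

test_that("splitting a contained peak into adjacent peaks with the same tags preserves rpkm", {
  gene <- one_gene()
  whole <- make_peaks("chr1", 1400, 2600, tag_count = 90)
  split2 <- make_peaks("chr1", c(1400, 2000), c(2000, 2600),
                       tag_count = c(40, 50))
  expect_equal(compute_rpkm(gene, whole, 1e6)$rpkm,
               compute_rpkm(gene, split2, 1e6)$rpkm)
})

test_that("rpkm is monotone in tags and decreasing in length and library size", {
  gene <- one_gene()
  base <- compute_rpkm(gene, make_peaks("chr1", 1500, 2500, tag_count = 50),
                       1e6)$rpkm
  more_tags <- compute_rpkm(gene, make_peaks("chr1", 1500, 2500,
                                             tag_count = 80), 1e6)$rpkm
  longer <- compute_rpkm(gene, make_peaks("chr1", 500, 2500,
                                          tag_count = 50), 1e6)$rpkm
  deeper <- compute_rpkm(gene, make_peaks("chr1", 1500, 2500,
                                          tag_count = 50), 2e6)$rpkm
  expect_gt(more_tags, base)
  expect_lt(longer, base)
  expect_lt(deeper, base)
})

test_that("peaks without tag counts are rejected by name", {
  gene <- one_gene()
  peaks <- make_peaks("chr1", 1500, 2500, name = "orphan")
  expect_error(compute_rpkm(gene, peaks, 1e6), "orphan")
})

test_that("a planted occupancy cohort is recovered to floating-point accuracy", {
  cfg <- sim_config(seed = 5, n_genes = 40)
  g <- simulate_genome(cfg)
  pol <- simulate_polii(cfg, g$models)
  occ <- polii_occupancy(g$models, pol$peaks, cfg$library_size)
  truth <- pol$truth[match(occ$symbol, pol$truth$symbol), ]
  expect_equal(occ$rpkm, truth$achieved_rpkm, tolerance = 1e-12)
  expect_equal(occ$tag_count, truth$tag_count)
  expect_equal(occ$effective_length, truth$effective_length)
  # zero-tier genes emit no peaks and score exactly 0
  zero_sym <- truth$symbol[truth$tier == "zero"]
  expect_true(all(occ$rpkm[occ$symbol %in% zero_sym] == 0))
})
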