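# One +-strand gene [50000, 60000) with exons [50000,51000) and [58000,60000),
# and one --strand gene [200000, 210000) far away.
toy_models <- function() {
  make_models(symbol = c("GPLUS", "GMINUS"),
              accession = c("NM_10", "NM_20"),
              chrom = "chr1", strand = c("+", "-"),
              start = c(50000, 200000), end = c(60000, 210000),
              exon_starts = list(c(50000, 58000), c(200000, 208000)),
              exon_ends = list(c(51000, 60000), c(201000, 210000)))
}

test_that("peak midpoints classify into the five location categories", {
  models <- toy_models()
  mk <- function(mid) make_peaks("chr1", mid - 100, mid + 100)
  # 10 kb upstream of the + TSS
  ann <- annotate_peaks(mk(40000), models)
  expect_equal(as.character(ann$category), "five_prime_upstream")
  expect_equal(ann$gene_symbol, "GPLUS")
  expect_equal(ann$distance, -10000L)
  # 25 kb from every TSS and transcript end
  ann <- annotate_peaks(mk(110000), models)
  expect_equal(as.character(ann$category), "intergenic")
  expect_false(is.na(ann$gene_symbol))  # nearest gene still recorded
  # inside intron 1
  ann <- annotate_peaks(mk(53000), models)
  expect_equal(as.character(ann$category), "intronic")
  # inside exon 1
  ann <- annotate_peaks(mk(50500), models)
  expect_equal(as.character(ann$category), "exonic")
  # 5 kb past the + transcript end
  ann <- annotate_peaks(mk(65000), models)
  expect_equal(as.character(ann$category), "three_prime_downstream")
  # upstream of the minus-strand gene lies to its right
  ann <- annotate_peaks(mk(215000), models)
  expect_equal(as.character(ann$category), "five_prime_upstream")
  expect_equal(ann$gene_symbol, "GMINUS")
  expect_equal(ann$distance, -(215000L - 209999L))
})

test_that("peaks on a chromosome without models are intergenic with no gene", {
  ann <- annotate_peaks(make_peaks("chrX", 100, 300), toy_models())
  expect_equal(as.character(ann$category), "intergenic")
  expect_true(is.na(ann$gene_symbol))
})

test_that("annotation is translation invariant", {
  models <- toy_models()
  set.seed(77)
  mids <- sample(0:300000, 200)
  peaks <- make_peaks("chr1", mids - 100, mids + 100)
  base <- annotate_peaks(peaks, models)
  delta <- 12345L
  shifted_models <- models
  shifted_models$start <- models$start + delta
  shifted_models$end <- models$end + delta
  shifted_models$exon_starts <- lapply(models$exon_starts, `+`, delta)
  shifted_models$exon_ends <- lapply(models$exon_ends, `+`, delta)
  shifted_peaks <- peaks
  shifted_peaks$start <- peaks$start + delta
  shifted_peaks$end <- peaks$end + delta
  shifted <- annotate_peaks(shifted_peaks, shifted_models)
  expect_equal(as.character(shifted$category), as.character(base$category))
  expect_equal(shifted$distance, base$distance)
})

test_that("mirroring coordinates and flipping strands preserves categories", {
  models <- toy_models()
  G <- 400000L
  set.seed(78)
  mids <- sample(0:300000, 200)
  peaks <- make_peaks("chr1", mids - 100, mids + 100)
  base <- annotate_peaks(peaks, models)
  mirror_models <- models
  mirror_models$start <- G - models$end
  mirror_models$end <- G - models$start
  mirror_models$strand <- ifelse(models$strand == "+", "-", "+")
  mirror_models$exon_starts <- lapply(seq_len(nrow(models)), function(i)
    rev(G - models$exon_ends[[i]]))
  mirror_models$exon_ends <- lapply(seq_len(nrow(models)), function(i)
    rev(G - models$exon_starts[[i]]))
  # mirror each midpoint m -> G - 1 - m; a width-1 peak has exactly that
  # midpoint
  mmid <- G - 1L - (peaks$start + 100L)
  mirror_peaks <- make_peaks("chr1", mmid, mmid + 1)
  mirrored <- annotate_peaks(mirror_peaks, mirror_models)
  expect_equal(as.character(mirrored$category), as.character(base$category))
})

test_that("location_summary reports counts and one-decimal percentages that partition the peaks", {
  one <- data.frame(category = "intronic")
  s <- location_summary(one)
  expect_equal(s$count[s$category == "intronic"], 1L)
  expect_equal(s$percent[s$category == "intronic"], 100)
  # planted cohort: 484/292/136/88 over 1000 peaks
  planted <- data.frame(category = rep(c("intronic", "intergenic",
                                         "five_prime_upstream",
                                         "three_prime_downstream"),
                                       c(484, 292, 136, 88)))
  s <- location_summary(planted)
  expect_equal(s$percent[s$category == "intronic"], 48.4)
  expect_equal(s$percent[s$category == "intergenic"], 29.2)
  expect_equal(s$percent[s$category == "five_prime_upstream"], 13.6)
  expect_equal(s$percent[s$category == "three_prime_downstream"], 8.8)
  expect_equal(sum(s$count), 1000L)
  expect_error(location_summary(planted[0, , drop = FALSE]), "empty")
})
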