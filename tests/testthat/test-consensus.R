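test_that("identical single-peak sets yield one consensus peak equal to the shared interval", {
  a <- make_peaks("chr1", 1000, 1100, fe = 12)
  b <- make_peaks("chr1", 1000, 1100, fe = 9)
  cons <- match_peak_sets(a, b)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 1000L)
  expect_equal(cons$end, 1100L)
  expect_equal(cons$fe_rep1, 12)
  expect_equal(cons$fe_rep2, 9)
  expect_equal(cons$representative_fe, 12)  # replicate 1 supplies it
})

test_that("peaks separated by more than max_gap intervening bases do not match", {
  a <- make_peaks("chr1", 1000, 1100)
  b <- make_peaks("chr1", 1160, 1260)  # 60 intervening bases
  expect_equal(nrow(match_peak_sets(a, b, max_gap = 50)), 0)
  expect_equal(nrow(match_peak_sets(a, b, max_gap = 60)), 1)
  # the consensus interval is the union of the pair
  cons <- match_peak_sets(a, b, max_gap = 60)
  expect_equal(cons$start, 1000L)
  expect_equal(cons$end, 1260L)
})

test_that("max_gap = 0 reduces matching to interval intersection (edge gap 0)", {
  a <- make_peaks("chr1", c(100, 500, 900), c(200, 600, 1000))
  b <- make_peaks("chr1", c(150, 610, 1000), c(250, 700, 1100))
  cons <- match_peak_sets(a, b, max_gap = 0)
  # overlap (100-200 vs 150-250) and book-ended (900-1000 vs 1000-1100)
  # qualify at gap 0; the 10-base separated pair does not
  expect_equal(nrow(cons), 2)
  expect_setequal(cons$name_rep1, c("p001", "p003"))
})

test_that("matching is symmetric in the replicates and bounded by the smaller set", {
  set.seed(101)
  for (rep in 1:3) {
    a <- make_peaks("chr1", s <- sort(sample(0:999000, 40)), s + 150,
                    fe = runif(40, 1, 30))
    b <- make_peaks("chr1", s2 <- sort(sample(0:999000, 55)), s2 + 150,
                    fe = runif(55, 1, 30))
    ab <- match_peak_sets(a, b)
    ba <- match_peak_sets(b, a)
    expect_lte(nrow(ab), min(nrow(a), nrow(b)))
    pairs_ab <- paste(ab$name_rep1, ab$name_rep2)
    pairs_ba <- paste(ba$name_rep2, ba$name_rep1)
    expect_setequal(pairs_ab, pairs_ba)
  }
})

test_that("greedy matching agrees with the exhaustive all-pairs brute-force matcher", {
  set.seed(202)
  for (rep in 1:3) {
    a <- make_peaks("chr1", s <- sort(sample(0:990000, 50)), s + sample(80:300, 50, TRUE))
    b <- make_peaks("chr1", s2 <- sort(sample(0:990000, 50)), s2 + sample(80:300, 50, TRUE))
    a$name <- sprintf("a%03d", 1:50)
    b$name <- sprintf("b%03d", 1:50)
    cons <- match_peak_sets(a, b, max_gap = 50)
    got <- data.frame(name_a = cons$name_rep1, name_b = cons$name_rep2)
    got <- got[order(got$name_a), , drop = FALSE]
    want <- bf_match_pairs(a, b, max_gap = 50)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("peaks on chromosomes outside the known set raise an error listing them", {
  a <- make_peaks(c("chr1", "chrUn"), c(0, 0), c(100, 100))
  b <- make_peaks("chr1", 0, 100)
  expect_error(match_peak_sets(a, b, known_chroms = "chr1"), "chrUn")
  expect_silent(match_peak_sets(a[1, ], b, known_chroms = "chr1"))
})

test_that("jittered replicates recover all true pairs when jitter stays within the gap", {
  set.seed(303)
  true_start <- seq(1000, by = 5000, length.out = 100)
  a <- make_peaks("chr1", true_start + sample(-25:25, 100, TRUE),
                  true_start + 200 + sample(-25:25, 100, TRUE))
  a$end <- pmax(a$end, a$start + 50)
  b <- make_peaks("chr1", true_start + sample(-25:25, 100, TRUE),
                  true_start + 200 + sample(-25:25, 100, TRUE))
  b$end <- pmax(b$end, b$start + 50)
  cons <- match_peak_sets(a, b, max_gap = 50)
  expect_equal(nrow(cons), 100)
  expect_equal(cons$name_rep1, cons$name_rep2)
})

test_that("best_peak_per_gene keeps the highest fold enrichment per gene", {
  ann <- data.frame(chrom = "chr1",
                    start = c(100, 900, 5000), end = c(300, 1100, 5200),
                    gene_symbol = c("GENEX", "GENEX", "GENEY"),
                    representative_fe = c(12, 30, 7),
                    stringsAsFactors = FALSE)
  best <- best_peak_per_gene(ann)
  expect_equal(nrow(best), 2)
  expect_equal(best$representative_fe[best$gene_symbol == "GENEX"], 30)
  expect_equal(best$representative_fe[best$gene_symbol == "GENEY"], 7)
})

test_that("best_peak_per_gene agrees with a naive per-gene maximum scan", {
  set.seed(404)
  n_genes <- 200
  rows <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    k <- sample(1:4, 1)
    data.frame(chrom = "chr1", start = sample(0:1e6, k),
               gene_symbol = sprintf("G%03d", g),
               representative_fe = round(runif(k, 1, 50), 6),
               stringsAsFactors = FALSE)
  }))
  rows$end <- rows$start + 200L
  best <- best_peak_per_gene(rows)
  naive <- vapply(split(rows$representative_fe, rows$gene_symbol), max,
                  numeric(1))
  expect_equal(nrow(best), n_genes)
  expect_equal(best$representative_fe,
               unname(naive[best$gene_symbol]))
})
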