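test_that("error-free simulation emits windows equal to their origin barcode", {
  sim <- small_sim(n_barcodes = 10, n_reads = 500, lambda = 0)
  expect_true(all(sim$windows$bases == sim$truth$barcode))
  expect_true(all(nchar(sim$windows$bases) == 12L))
  expect_true(all(!is.na(sim$windows$next_base)))
})

test_that("single deletions keep the window length and stay within edit distance 2", {
  sim <- small_sim(n_barcodes = 10, n_reads = 2000, lambda = 1,
                   type = "deletion", seed = 12)
  one <- sim$truth$n_errors == 1L
  expect_gt(sum(one), 100)
  w <- sim$windows$bases[one]
  o <- sim$truth$barcode[one]
  expect_true(all(nchar(w) == 12L))
  # deletion plus backfill: at most one deletion + one trailing extra base
  expect_true(all(levenshtein(w, o) <= 2))
  # register shift makes hamming systematically exceed levenshtein
  expect_gt(mean(hamming(w, o)), mean(levenshtein(w, o)))
})

test_that("datasets are byte-identical under the same seed", {
  cfg <- simulation_config(n_barcodes = 8, n_reads = 300, error_lambda = 1.5,
                           seed = 77)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$windows, s2$windows)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_sim_fastq(s1, f1)
  write_sim_fastq(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and differ under another seed
  s3 <- generate_dataset(simulation_config(n_barcodes = 8, n_reads = 300,
                                           error_lambda = 1.5, seed = 78))
  expect_false(identical(s1$windows$bases, s3$windows$bases))
})

test_that("realized error counts and abundances match the configuration", {
  sim <- small_sim(n_barcodes = 50, n_reads = 20000, lambda = 1.5, seed = 19)
  m <- mean(sim$truth$n_errors)
  se <- sqrt(1.5 / 20000)
  expect_lt(abs(m - 1.5), 3 * se)
  # chi-square sanity on per-barcode read counts vs configured abundances
  obs <- table(factor(sim$truth$barcode, levels = sim$barcodes))
  expected <- sim$abundance * 20000
  chi <- sum((obs - expected)^2 / expected)
  expect_lt(chi, qchisq(1 - 1e-6, df = 49))
})

test_that("barcode scoring counts set overlaps and read outcomes", {
  sim <- small_sim(n_barcodes = 12, n_reads = 400, lambda = 0)
  truth <- sim$barcodes
  perfect <- score_barcodes(truth, sim)
  expect_equal(perfect$tp, 12L)
  expect_equal(perfect$fp, 0L)
  expect_equal(perfect$fn, 0L)
  empty <- score_barcodes(character(0), sim)
  expect_equal(empty$tp, 0L)
  expect_equal(empty$fn, length(unique(sim$truth$barcode)))
  # tp + fp = called, tp + fn = truth barcodes with reads
  some <- score_barcodes(c(truth[1:5], "ACGTACGTACGT"), sim)
  expect_equal(some$tp + some$fp, 6L)
  expect_equal(some$tp + some$fn, length(unique(sim$truth$barcode)))
})

test_that("the naive exact-counting baseline calls clean data but misses indels", {
  sim0 <- small_sim(n_barcodes = 20, n_reads = 4000, lambda = 0, seed = 33)
  # with no errors every distinct window is a true barcode; no knee exists,
  # so the caller accepts all distinct windows
  nb <- tryCatch(naive_baseline(sim0$windows, window = 11),
                 error = function(e) NULL)
  if (is.null(nb)) {
    expect_setequal(unique(sim0$windows$bases), sim0$barcodes)
  } else {
    expect_setequal(nb$called, sim0$barcodes)
  }
  # deletion-heavy data: the full pipeline identifies every barcode among
  # its paths, and exact-match assignment leaves the naive caller far
  # behind on reads (it can only assign the error-free ones)
  simd <- small_sim(n_barcodes = 20, n_reads = 8000, lambda = 2,
                    type = "deletion", seed = 34)
  nbd <- naive_baseline(simd$windows)
  full <- call_barcodes(simd$windows, k = 7, L = 12, breadth = 300, depth = 5)
  expect_lte(score_barcodes(nbd$called, simd)$tp,
             sum(full$barcode %in% simd$barcodes))
  nsc <- score_barcodes(nbd$called, simd, nbd$assignments)
  fsc <- score_barcodes(nbd$called, simd,
                        assign_by_levenshtein(simd$windows,
                                              intersect(full$barcode,
                                                        simd$barcodes), 2))
  expect_lt(nsc$read_fractions[["correct"]] + 0.1,
            fsc$read_fractions[["correct"]])
  # a read matching no called barcode is unassigned
  expect_true(all(is.na(
    nbd$assignments[!(nbd$assignments$barcode %in% nbd$called) |
                      is.na(nbd$assignments$barcode), ]$barcode)))
})

test_that("the benchmark grid enumerates 180 dataset configurations", {
  grid <- methods_grid()
  expect_length(grid, 180L)
  key <- vapply(grid, function(g)
    paste(g$abundance, g$error_type, g$error_lambda, g$replicate), "")
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(vapply(grid, function(g) g$error_lambda, 1) <= 3))
})

test_that("fastq output round-trips through the reader", {
  sim <- small_sim(n_barcodes = 5, n_reads = 100, lambda = 1, seed = 3)
  fq <- withr::local_tempfile(fileext = ".fastq")
  tt <- withr::local_tempfile(fileext = ".tsv")
  write_sim_fastq(sim, fq, truth_tsv = tt)
  win <- read_barcode_fastq(fq)
  expect_equal(win$bases, sim$windows$bases)
  expect_equal(win$next_base, sim$windows$next_base)
  expect_equal(nrow(data.table::fread(tt)), 100L)
})
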