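test_that("poly-N splitting follows the run-length threshold exactly", {
  s <- paste0("ACGT", strrep("N", 500), "ACGT")
  cs <- split_on_n_runs(c(chr = s), split_threshold = 500)
  expect_equal(nrow(cs$contigs), 2)
  expect_equal(cs$contigs$length, c(4, 4))
  expect_equal(cs$contigs$start, c(1, 505))

  s2 <- paste0("ACGT", strrep("N", 499), "ACGT")
  cs2 <- split_on_n_runs(c(chr = s2), split_threshold = 500)
  expect_equal(nrow(cs2$contigs), 1)
  expect_equal(cs2$contigs$length, 507)

  expect_equal(nrow(split_on_n_runs(c(chr = strrep("N", 2000)))$contigs), 0)

  # min length filter drops short flanks
  s3 <- paste0("AC", strrep("N", 600), strrep("ACGT", 100))
  cs3 <- split_on_n_runs(c(chr = s3), 500, min_contig_length = 200)
  expect_equal(nrow(cs3$contigs), 1)
  expect_equal(cs3$contigs$length, 400)
})

test_that("splitting conserves every base of the source", {
  set.seed(41)
  for (i in 1:20) {
    n_seg <- sample(1:6, 1)
    parts <- character(0)
    for (k in seq_len(n_seg)) {
      parts <- c(parts, rand_seq(sample(1:800, 1)),
                 strrep("N", sample(c(3, 100, 499, 500, 750), 1)))
    }
    s <- paste(parts, collapse = "")
    cs <- split_on_n_runs(c(x = s), 500, min_contig_length = 5)
    expect_equal(sum(cs$contigs$length) + cs$removed_n + cs$dropped_short,
                 nchar(s))
    # no contig retains a splittable N run
    expect_false(any(grepl("N{500,}", cs$contigs$sequence)))
    # contigs are ordered and non-overlapping
    if (nrow(cs$contigs) > 1)
      expect_true(all(diff(cs$contigs$start) >
                        head(cs$contigs$length, -1)))
  }
})

test_that("n50 matches a brute-force oracle on random length lists", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(10), 10)
  expect_equal(n50(c(1, 1, 1, 1)), 1)
  expect_error(n50(numeric(0)), "empty")
  set.seed(42)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("no-break N50 is never below the break-500 N50", {
  sim <- tiny_sim(seed = 29, L = 1e5, coverage = 3)
  pile <- build_pileup(map_reads(sim$reads, sim$ref))
  cons <- call_consensus(pile, consensus_params(2))
  broken <- split_on_n_runs(cons, 500)
  unbroken <- split_on_n_runs(cons, .Machine$integer.max)
  expect_gte(n50(unbroken$contigs$length), n50(broken$contigs$length))
  # split at infinity is the identity on the assembly
  expect_equal(sum(unbroken$contigs$length), nchar(cons$seq))
})

test_that("fold coverage divides total bases by genome size", {
  expect_equal(fold_coverage(4662514211, 1.32e9), 3.53)
  expect_equal(fold_coverage(7135441227, 1.32e9), 5.41)
  expect_equal(fold_coverage(0, 1.32e9), 0)
  expect_error(fold_coverage(100, 0), "positive")
})

test_that("length histogram uses the standard log-spaced bins", {
  h <- length_histogram(c(100, 250, 600, 1500, 3000, 7000, 50000))
  expect_equal(sum(h), 7)
  expect_equal(unname(h["[200,500)"]), 1)
  expect_equal(unname(h["[10000,Inf)"]), 1)
})

test_that("repeat-library masking recovers planted repeat content", {
  set.seed(43)
  lib <- rand_seq(400)
  # a contig that is exactly one library element
  expect_equal(repeat_library_content(c(x = lib), lib), 1.0)
  # no shared k-mers: nothing masked
  expect_equal(repeat_library_content(c(x = rand_seq(2000)),
                                      strrep("AC", 200)), 0)

  # ~10% planted repeat bases, no mutation
  n_copies <- 25
  pieces <- character(0)
  for (i in seq_len(n_copies))
    pieces <- c(pieces, rand_seq(3600), lib)
  genome <- paste(pieces, collapse = "")
  frac <- repeat_library_content(c(g = genome), lib)
  expect_lt(abs(frac - n_copies * 400 / nchar(genome)), 0.01)
  expect_error(repeat_library_content(c(x = "ACGT"), character(0)),
               "non-empty")
})

test_that("contiguity report aggregates the metrics coherently", {
  s <- paste0(rand_seq(1000), strrep("N", 600), rand_seq(300))
  cs <- split_on_n_runs(c(chr = s), 500)
  rep <- contiguity_report(cs, assembly = s, genome_size = 1.32e9,
                           total_bases = 4662514211)
  expect_equal(rep$n_contigs, 2)
  expect_equal(rep$total_length, 1300)
  expect_equal(rep$n50, 1000)
  expect_equal(rep$max_length, 1000)
  expect_equal(rep$fold_coverage, 3.53)
  expect_equal(rep$pct_n, 100 * 600 / nchar(s))
})
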