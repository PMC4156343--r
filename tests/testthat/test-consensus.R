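test_that("consensus boundary rules match the stated thresholds", {
  # {A:8, G:2}: 2 >= 2 reads and 2/10 >= 10% -> IUPAC R (A/G)
  # {A:9, G:1}: 1 < 2 alternative reads -> A
  # position 3 uncovered -> N
  p <- make_pileup(list(c(A = 8, G = 2), c(A = 9, G = 1), c(),
                        c(C = 4)), ref_length = 4)
  cons1 <- call_consensus(p, consensus_params(min_coverage = 1))
  expect_equal(strsplit(cons1$seq, "")[[1]], c("R", "A", "N", "C"))

  # depth 4 below a min coverage of 5 -> N
  cons5 <- call_consensus(p, consensus_params(min_coverage = 5))
  expect_equal(substr(cons5$seq, 4, 4), "N")
  # reference-anchored: length never changes
  expect_equal(nchar(cons5$seq), 4)

  # exact alt_fraction boundary: 1/10 with alt_min_reads 1 is inclusive
  pb <- make_pileup(list(c(A = 9, G = 1)))
  cb <- call_consensus(pb, consensus_params(min_coverage = 1,
                                            alt_fraction = 0.10,
                                            alt_min_reads = 1))
  expect_equal(cb$seq, "R")
})

test_that("%N is pointwise monotone in the coverage threshold", {
  sim <- tiny_sim(seed = 17, L = 1e5, coverage = 4)
  aln <- map_reads(sim$reads, sim$ref)
  pile <- build_pileup(aln)
  seqs <- lapply(c(1, 2, 5), function(t)
    charToRaw(call_consensus(pile, consensus_params(t))$seq))
  isN <- lapply(seqs, function(b) b == charToRaw("N"))
  # every position that is N at a lower threshold stays N at a higher one
  expect_true(all(isN[[2]][isN[[1]]]))
  expect_true(all(isN[[3]][isN[[2]]]))
  pcts <- vapply(isN, mean, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("error-free haploid reads reproduce the reference exactly", {
  cfg <- simulation_config(seed = 19, genome_length = 5e4,
                           isochore_block_length = 5e3, coverage = 40,
                           divergence_rate = 0, indel_rate = 0,
                           heterozygosity = 0,
                           error_rate_start = 0, error_rate_end = 0,
                           ssr_densities = c(`2` = 0, `3` = 0, `4` = 0,
                                             `5` = 0, `6` = 0),
                           repeat_library = data.frame(seq = character(),
                                                       copies = integer()))
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg)
  pile <- build_pileup(map_reads(reads, ref))
  d <- pileup_depth(pile)
  # the first/last few positions can be uncovered (fragment edge effect)
  expect_true(all(d[200:(5e4 - 200)] >= 1))
  cons <- call_consensus(pile, consensus_params(min_coverage = 1))
  ch_c <- strsplit(cons$seq, "")[[1]]
  ch_r <- strsplit(ref$sequence, "")[[1]]
  expect_identical(ch_c[d >= 1], ch_r[d >= 1])
  expect_true(all(ch_c[d == 0] == "N"))
})

test_that("planted heterozygous SNVs surface as IUPAC codes", {
  cfg <- simulation_config(seed = 23, genome_length = 1e5,
                           isochore_block_length = 1e4, coverage = 30,
                           indel_rate = 0, heterozygosity = 2e-3,
                           het_class_mix = c(SNV = 1, deletion = 0,
                                             insertion = 0, MNV = 0,
                                             replacement = 0),
                           error_rate_start = 0, error_rate_end = 0)
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg)
  pile <- build_pileup(map_reads(reads, ref))
  cons <- call_consensus(pile, consensus_params(min_coverage = 1))
  het <- dip$truth$het_sites
  got <- substring(cons$seq, het$pos, het$pos)
  want <- mapply(function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")[key]
  }, het$allele_a, het$allele_b)
  # recovery at 30x with both alleles expected well covered
  expect_gt(mean(got == want), 0.9)
})

test_that("composition fractions are exhaustive and sum to one", {
  expect_equal(consensus_composition("NNNN")$pct_n, 100)
  comp <- consensus_composition("ACGT")
  expect_equal(unname(comp$fractions[c("A", "C", "G", "T")]),
               rep(0.25, 4))
  expect_equal(comp$pct_n, 0)
  comp2 <- consensus_composition(paste0(strrep("N", 2), "AC"))
  expect_equal(comp2$pct_n, 50)
  expect_equal(unname(comp2$fractions[["A"]]), 0.25)
  expect_equal(unname(comp2$fractions[["C"]]), 0.25)
  expect_equal(sum(comp2$fractions), 1)
  expect_error(consensus_composition(""), "empty")
})

test_that("coverage track round-trips the depth vector", {
  p <- make_pileup(list(c(A = 3), c(A = 3), c(G = 1), c()),
                   ref_length = 4)
  cons <- call_consensus(p, consensus_params(1))
  td <- withr::local_tempdir()
  f <- write_coverage_track(cons, file.path(td, "cov.bed"))
  bed <- read.delim(f, header = FALSE)
  expect_equal(sum((bed$V3 - bed$V2) * bed$V4), sum(cons$depth))
})
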