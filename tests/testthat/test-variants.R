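test_that("the heterozygous posterior behaves like the binomial model", {
  # balanced 10/10 at Q40: overwhelming heterozygous evidence
  p <- make_pileup(list(c(A = 10, G = 10)), qual = "I")  # Q40
  calls <- call_heterozygous(p)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$class, "SNV")
  expect_setequal(c(calls$allele_a, calls$allele_b), c("A", "G"))
  expect_gt(calls$probability, 0.99)

  # independent oracle: explicit Bayes computation with the same model
  e <- 1e-4
  priors <- c(hom1 = 1 - 1e-3 - 0.05, het = 1e-3, hom2 = 0.05)
  lik <- c(dbinom(10, 20, e), dbinom(10, 20, 0.5), dbinom(10, 20, 1 - e))
  post <- lik * priors / sum(lik * priors)
  expect_equal(calls$probability, unname(post[2]), tolerance = 1e-6)

  # a single alternative read never qualifies (alt reads < 2)
  p2 <- make_pileup(list(c(A = 19, G = 1)))
  expect_equal(nrow(call_heterozygous(p2)), 0)
})

test_that("strand and allele-count rules gate stage 1", {
  # all alternative reads on the forward strand: rejected
  aln <- data.frame(qname = sprintf("r%02d", 1:20), mapped = TRUE,
                    pos = 1L,
                    strand = c(rep("+", 14), rep("-", 6)),
                    cigar = "1M", cost = 0L, matches = 1L, cols = 1L,
                    identity = 1, frac_aligned = 1, nonspecific = FALSE,
                    seq = c(rep("G", 8), rep("A", 6),
                            revcomp(rep("A", 6))),
                    qual = "I", stringsAsFactors = FALSE)
  attr(aln, "ref_name") <- "ref"; attr(aln, "ref_length") <- 1L
  class(aln) <- c("refguide_alignments", "data.frame")
  p <- build_pileup(aln)
  expect_equal(p$counts_fwd[3, 1], 8)   # G fwd only
  expect_equal(nrow(call_heterozygous(p)), 0)

  # three alleles with >= 2 reads each: rejected by the 2-allele cap
  p3 <- make_pileup(list(c(A = 8, G = 6, C = 6)))
  expect_equal(nrow(call_heterozygous(p3)), 0)
})

test_that("stage 2 applies its boundary rules literally", {
  base <- data.frame(pos = 1:5, class = "SNV", allele_a = "A",
                     allele_b = "G", depth = c(20, 5, 20, 20, 20),
                     alt_reads = 8,
                     alt_fraction = c(0.30, 0.5, 0.29, 0.5, 0.5),
                     fwd_fraction = c(0.5, 0.5, 0.5, 0.5, 0.29),
                     rev_fraction = 0.5,
                     mean_phred = c(41, 41, 41, 40, 41),
                     probability = 0.99, del_len = 0L,
                     stringsAsFactors = FALSE)
  class(base) <- c("variant_calls", "data.frame")
  out <- apply_stage2(base)
  # row 1: AF exactly 0.30 is retained (inclusive bound)
  # row 2: depth 5 removed ("greater than 5" strict)
  # row 3: AF 0.29 below the window
  # row 4: mean PHRED exactly 40 removed (strict)
  # row 5: forward support below 30%
  expect_equal(out$pos, 1L)

  # stage-2 output is always a subset of stage-1 output
  sim <- tiny_sim(seed = 71, L = 1e5, coverage = 15)
  pile <- build_pileup(map_reads(sim$reads, sim$ref))
  s1 <- call_heterozygous(pile)
  s2 <- apply_stage2(s1)
  expect_true(all(paste(s2$pos, s2$class) %in% paste(s1$pos, s1$class)))
  # and deterministic
  s1b <- call_heterozygous(pile)
  expect_identical(s1, s1b)
})

test_that("the spectrum separates transitions from transversions", {
  calls <- data.frame(pos = 1:4, class = "SNV",
                      allele_a = c("A", "G", "C", "A"),
                      allele_b = c("G", "A", "T", "C"),
                      stringsAsFactors = FALSE)
  sp <- spectrum_summary(calls)
  expect_equal(sp$ts, 3)
  expect_equal(sp$tv, 1)
  expect_equal(sp$tstv, 3)
  expect_equal(unname(sp$class_counts[["SNV"]]), 4)

  empty <- spectrum_summary(calls[0, ])
  expect_true(all(empty$class_counts == 0))
  expect_true(is.na(empty$tstv))
  expect_match(empty$note, "undefined")
})

test_that("planted heterozygosity is recovered from deep coverage", {
  cfg <- simulation_config(seed = 73, genome_length = 5e5, coverage = 20)
  res <- run_recovery_experiment(cfg)
  expect_gt(res$assessment$recall_snv, 0.9)
  expect_lt(res$assessment$false_snv_per_mb, 10)
  expect_lt(abs(res$assessment$tstv - 2.0) / 2.0, 0.25)
  # MNVs merged from adjacent substitutions carry 2-base alleles
  mnv <- res$calls[res$calls$class == "MNV", ]
  if (nrow(mnv)) expect_true(all(nchar(mnv$allele_b) >= 2))
})

test_that("heterozygous indels are called and VCF output is well-formed", {
  cfg <- simulation_config(seed = 74, genome_length = 2e5,
                           isochore_block_length = 2e4, coverage = 25,
                           het_class_mix = c(SNV = 0.4, deletion = 0.4,
                                             insertion = 0.2, MNV = 0,
                                             replacement = 0))
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg)
  aln <- map_reads(reads, ref)
  pile <- build_pileup(aln)
  calls <- call_heterozygous(pile, aln = aln)
  truth <- dip$truth$het_sites
  dels <- truth[truth$class == "deletion", ]
  ins <- truth[truth$class == "insertion", ]
  hit_del <- mean(dels$pos %in% calls$pos[calls$class == "deletion"])
  hit_ins <- mean(ins$pos %in% calls$pos[calls$class == "insertion"])
  expect_gt(hit_del, 0.5)
  expect_gt(hit_ins, 0.5)

  td <- withr::local_tempdir()
  f <- write_vcf(calls, file.path(td, "calls.vcf"), "ref")
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), nrow(calls))
  expect_true(all(grepl("DP=\\d+;AF=", body)))
})
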