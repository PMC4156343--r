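test_that("simulated reference matches its GC specification", {
  cfg <- simulation_config(seed = 3, genome_length = 1e6,
                           isochore_block_length = 1e5,
                           isochore_gc_levels = 0.5)
  ref <- simulate_reference(cfg)
  expect_equal(nchar(ref$sequence), 1e6)
  b <- charToRaw(ref$sequence)
  gc <- mean(b == charToRaw("G") | b == charToRaw("C"))
  # binomial: sd = sqrt(0.25/1e6) = 5e-4; 6 sd band
  expect_gt(gc, 0.497)
  expect_lt(gc, 0.503)

  # two-level blocks are bimodal around their design values
  cfg2 <- simulation_config(seed = 4, genome_length = 5e5,
                            isochore_block_length = 1e4,
                            isochore_gc_levels = c(0.3, 0.7))
  ref2 <- simulate_reference(cfg2)
  ann <- ref2$annotations
  gcs <- vapply(seq_len(nrow(ann)), function(i) {
    bb <- charToRaw(substr(ref2$sequence, ann$start[i], ann$end[i]))
    mean(bb == charToRaw("G") | bb == charToRaw("C"))
  }, numeric(1))
  lev <- as.numeric(ann$payload)
  # per-block GC within 5 binomial sd of the block's design level
  sd_block <- sqrt(lev * (1 - lev) / 1e4)
  expect_true(all(abs(gcs - lev) < 5 * sd_block))
  expect_setequal(unique(lev), c(0.3, 0.7))
})

test_that("the generator is deterministic in the seed", {
  cfg <- simulation_config(seed = 9, genome_length = 1e5,
                           isochore_block_length = 1e4, coverage = 2)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$sequence, r2$sequence)
  d1 <- derive_target_diploid(r1, cfg)
  d2 <- derive_target_diploid(r2, cfg)
  expect_identical(d1$hap_a$sequence, d2$hap_a$sequence)
  expect_identical(d1$hap_b$sequence, d2$hap_b$sequence)
  expect_identical(d1$truth$het_sites, d2$truth$het_sites)
  s1 <- simulate_reads(d1$hap_a, d1$hap_b, cfg)
  s2 <- simulate_reads(d2$hap_a, d2$hap_b, cfg)
  expect_identical(s1$r1, s2$r1)
  expect_identical(s1$r2, s2$r2)
})

test_that("a mutation-free configuration reproduces the reference", {
  cfg <- simulation_config(seed = 2, genome_length = 1e5,
                           isochore_block_length = 1e4,
                           divergence_rate = 0, indel_rate = 0,
                           heterozygosity = 0,
                           ssr_densities = c(`2` = 0, `3` = 0, `4` = 0,
                                             `5` = 0, `6` = 0),
                           repeat_library = data.frame(seq = character(),
                                                       copies = integer()))
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  expect_identical(dip$hap_a$sequence, ref$sequence)
  expect_identical(dip$hap_b$sequence, ref$sequence)
  expect_equal(nrow(dip$truth$het_sites), 0)
  expect_equal(nrow(dip$truth$divergence_sites), 0)
})

test_that("divergence and Ts/Tv rates recover their design values", {
  cfg <- simulation_config(seed = 6, genome_length = 1e6,
                           isochore_block_length = 1e5,
                           divergence_rate = 0.05, indel_rate = 0,
                           heterozygosity = 0, tstv_ratio = 2.0)
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  n <- nrow(dip$truth$divergence_sites)
  # eligible sites are slightly fewer than 1e6 (planted features are
  # protected); 4 binomial sd around the design rate
  eligible <- 1e6 - sum(with(dip$truth$repeat_intervals, end - start + 1)) -
    sum(nchar(dip$truth$planted_ssrs$motif) * dip$truth$planted_ssrs$repeats)
  expect_lt(abs(n - 0.05 * eligible), 4 * sqrt(0.05 * 0.95 * eligible))

  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  ts <- sum(transition_of[dip$truth$divergence_sites$ref_base] ==
              dip$truth$divergence_sites$target_base)
  tv <- n - ts
  # planted at odds 2:1; binomial sampling error on the ratio
  p_hat <- ts / n
  expect_lt(abs(p_hat - 2 / 3), 4 * sqrt(2 / 9 / n))
  expect_lt(abs(ts / tv - 2.0), 0.2)
})

test_that("every truth record verifies against the haplotype strings", {
  sim <- tiny_sim(seed = 13, L = 2e5, coverage = 1)
  truth <- sim$dip$truth
  ha <- sim$dip$hap_a$sequence
  hb <- sim$dip$hap_b$sequence

  # divergence substitutions appear in both haplotypes
  div <- truth$divergence_sites
  pa <- liftover_positions(truth, div$pos, "a")
  pb <- liftover_positions(truth, div$pos, "b")
  ok <- !is.na(pa) & !is.na(pb)
  expect_gt(mean(ok), 0.99)
  expect_identical(substring(ha, pa[ok], pa[ok]), div$target_base[ok])
  expect_identical(substring(hb, pb[ok], pb[ok]), div$target_base[ok])

  # heterozygous SNVs/MNVs: hap A carries allele_a, hap B allele_b
  het <- truth$het_sites
  sub <- het[het$class %in% c("SNV", "MNV"), ]
  pa <- liftover_positions(truth, sub$pos, "a")
  pb <- liftover_positions(truth, sub$pos, "b")
  la <- nchar(sub$allele_a)
  expect_identical(substring(ha, pa, pa + la - 1), sub$allele_a)
  expect_identical(substring(hb, pb, pb + la - 1), sub$allele_b)

  # planted SSRs are perfect tandems at their annotated positions
  ann <- sim$dip$hap_a$annotations
  ssr <- ann[ann$kind == "ssr", ]
  got <- substring(ha, ssr$start, ssr$end)
  want <- vapply(seq_len(nrow(ssr)), function(i)
    strrep(ssr$payload[i],
           (ssr$end[i] - ssr$start[i] + 1) / nchar(ssr$payload[i])),
    character(1))
  expect_identical(got, want)
})

test_that("read simulation hits its coverage and error contracts", {
  cfg <- simulation_config(seed = 8, genome_length = 1e6,
                           isochore_block_length = 1e5, coverage = 5.41,
                           divergence_rate = 0, indel_rate = 0,
                           heterozygosity = 0,
                           error_rate_start = 0, error_rate_end = 0,
                           insert_sd = 0,
                           ssr_densities = c(`2` = 0, `3` = 0, `4` = 0,
                                             `5` = 0, `6` = 0),
                           repeat_library = data.frame(seq = character(),
                                                       copies = integer()))
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg)
  total <- sum(nchar(reads$r1)) + sum(nchar(reads$r2))
  expect_lt(abs(total - 5.41e6) / 5.41e6, 0.02)

  # error rate 0: every read base matches its source haplotype exactly
  idx <- sample(length(reads$r1), 200)
  src1 <- substring(ref$sequence, reads$truth$start[idx],
                    reads$truth$start[idx] + cfg$read_length - 1)
  expect_identical(reads$r1[idx], src1)
  ends <- reads$truth$start[idx] + reads$truth$insert[idx] - 1
  src2 <- substring(ref$sequence, ends - cfg$read_length + 1, ends)
  expect_identical(reads$r2[idx], revcomp(src2))

  # insert_sd 0 and no errors: constant mate gap
  expect_true(all(reads$truth$insert == 205))

  # zero reads is an explicit error
  cfg0 <- cfg; cfg0$coverage <- 1e-6
  expect_error(simulate_reads(dip$hap_a, dip$hap_b, cfg0), "coverage")
})

test_that("FASTA/FASTQ/truth round-trips preserve the simulation", {
  sim <- tiny_sim(seed = 21, L = 5e4, coverage = 3)
  td <- withr::local_tempdir()
  write_fasta(sim$ref, file.path(td, "ref.fa"))
  back <- read_fasta(file.path(td, "ref.fa"))
  expect_identical(unname(back["ref"]), sim$ref$sequence)

  write_fastq_pair(sim$reads, file.path(td, "reads"))
  rb <- read_fastq_pair(file.path(td, "reads_1.fastq"),
                        file.path(td, "reads_2.fastq"))
  expect_identical(rb$r1, unname(sim$reads$r1))
  expect_identical(rb$r2, unname(sim$reads$r2))
  expect_identical(rb$qual, sim$reads$qual)

  write_truth_tsv(sim$dip$truth, file.path(td, "truth.tsv"))
  tt <- read.delim(file.path(td, "truth.tsv"))
  expect_equal(sum(tt$kind == "het"), nrow(sim$dip$truth$het_sites))
})
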