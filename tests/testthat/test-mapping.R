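test_that("exact reads map at their source position with identity 1", {
  set.seed(101)
  ref <- genome_sequence("chr", rand_seq(5000))
  starts <- c(1, 777, 2500, 5000 - 119)
  reads <- substring(ref$sequence, starts, starts + 119)
  aln <- map_reads(reads, ref)
  expect_true(all(aln$mapped))
  expect_equal(aln$pos, starts)
  expect_true(all(aln$identity == 1))
  expect_true(all(aln$strand == "+"))
  expect_false(any(aln$nonspecific))

  # reverse-complemented reads map at the same loci on the minus strand
  aln_rc <- map_reads(revcomp(reads), ref)
  expect_equal(aln_rc$pos, starts)
  expect_true(all(aln_rc$strand == "-"))
})

test_that("similarity and length fraction rejections are exact", {
  set.seed(102)
  ref <- genome_sequence("chr", rand_seq(4000))
  base <- substring(ref$sequence, 1001, 1120)
  # substitutions spaced 4 apart stay below the end-trim score drop and
  # leave an intact seed at the read tail: 24/120 mismatches -> identity
  # exactly 0.8 (accepted), 25 -> 0.792 (rejected)
  r24 <- with_substitutions(base, seq(2, by = 4, length.out = 24))
  r25 <- with_substitutions(base, c(seq(2, by = 4, length.out = 24), 97))
  aln <- map_reads(c(r24, r25), ref)
  expect_true(aln$mapped[1])
  expect_equal(aln$identity[1], 0.8, tolerance = 1e-12)
  expect_false(aln$mapped[2])

  # length fraction: a read half off the reference end is accepted at
  # exactly 0.5 aligned fraction, and rejected one base further out
  tail60 <- substring(ref$sequence, 4000 - 59, 4000)
  r_half <- paste0(tail60, rand_seq(60))       # 60 aligned / 120
  r_less <- paste0(substring(ref$sequence, 4000 - 58, 4000), rand_seq(61))
  aln2 <- map_reads(c(r_half, r_less), ref)
  expect_true(aln2$mapped[1])
  expect_equal(aln2$frac_aligned[1], 0.5)
  expect_false(aln2$mapped[2])
})

test_that("reads matching two identical loci are flagged non-specific", {
  set.seed(103)
  copy <- rand_seq(300)
  ref <- genome_sequence("chr",
                         paste0(rand_seq(500), copy, rand_seq(500), copy,
                                rand_seq(500)))
  inside <- substring(copy, 50, 169)
  unique_read <- substring(ref$sequence, 100, 219)
  aln <- map_reads(c(inside, unique_read), ref)
  expect_true(all(aln$mapped))
  expect_true(aln$nonspecific[1])
  expect_false(aln$nonspecific[2])

  # the non-specific read does not change the pileup
  p1 <- build_pileup(aln)
  aln_unique <- map_reads(unique_read, ref)
  p2 <- build_pileup(aln_unique)
  expect_equal(sum(pileup_depth(p1)), sum(pileup_depth(p2)))
})

test_that("reported cost equals the exhaustive alignment oracle", {
  set.seed(104)
  for (case in 1:40) {
    ref <- rand_seq(2000)
    m <- sample(30:60, 1)
    s0 <- sample(seq_len(2000 - m), 1)
    read <- substr(ref, s0, s0 + m - 1)
    # mutations confined to the first 2/3 so the tail seed survives;
    # net indel drift stays within the mapper's band
    nmut <- sample(0:3, 1)
    if (nmut > 0)
      read <- with_substitutions(read, sample(seq_len(max(1, m - 20)), nmut))
    if (runif(1) < 0.4) {
      p <- sample(seq(3, m - 22), 1)
      if (runif(1) < 0.5) {
        read <- paste0(substr(read, 1, p), sample(BASES, 1),
                       substr(read, p + 1, m))  # insertion
      } else {
        read <- paste0(substr(read, 1, p), substr(read, p + 2, m))
      }
    }
    aln <- map_reads(read, genome_sequence("r", ref),
                     mapping_params(similarity_fraction = 0.5))
    if (!aln$mapped[1]) next
    expect_equal(aln$cost[1], oracle_semiglobal_cost(read, ref),
                 info = sprintf("case %d", case))
  }
})

test_that("mapping is symmetric under reverse complement of both", {
  set.seed(105)
  ref <- rand_seq(3000)
  s0 <- 1203
  read <- with_substitutions(substr(ref, s0, s0 + 99), c(10, 50))
  a1 <- map_reads(read, genome_sequence("r", ref))
  a2 <- map_reads(revcomp(read), genome_sequence("r", revcomp(ref)))
  expect_true(a1$mapped[1] && a2$mapped[1])
  expect_equal(a1$cost[1], a2$cost[1])
  # mirrored coordinates: start' = L - end + 1
  end1 <- a1$pos[1] + sum(ref_span_oracle(a1$cigar[1])) - 1
  expect_equal(a2$pos[1], 3000 - end1 + 1)
})

test_that("SAM round-trip and external-alignment ingestion work", {
  skip_if_not_installed("Rsamtools")
  set.seed(106)
  ref <- genome_sequence("chr1", rand_seq(2000))
  reads <- c(substring(ref$sequence, 301, 420),
             revcomp(substring(ref$sequence, 901, 1020)))
  aln <- map_reads(reads, ref)
  td <- withr::local_tempdir()
  sam <- file.path(td, "aln.sam")
  write_sam(aln, sam)
  back <- read_alignment_file(sam)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$strand, aln$strand)
  expect_identical(toupper(back$seq), aln$seq)

  # a full-length match gives depth 120 over its span
  p <- build_pileup(read_alignment_file(sam))
  expect_equal(sum(pileup_depth(p)), 240)
  expect_true(all(pileup_depth(p)[301:420] == 1))

  # hand-constructed record with a 1-base deletion
  del_read <- paste0(substring(ref$sequence, 501, 550),
                     substring(ref$sequence, 552, 601))
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:2000",
               sprintf("del1\t0\tchr1\t501\t60\t50M1D50M\t*\t0\t0\t%s\t%s",
                       del_read, strrep("I", 100))),
             file.path(td, "del.sam"))
  pd <- build_pileup(read_alignment_file(file.path(td, "del.sam")))
  expect_equal(pd$del[551], 1)
  expect_equal(unname(pileup_depth(pd)[551]), 1)

  # header-only file yields an empty stream; headerless input errors
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:2000"),
             file.path(td, "empty.sam"))
  expect_equal(nrow(read_alignment_file(file.path(td, "empty.sam"))), 0)
  writeLines("not a sam line", file.path(td, "bad.sam"))
  expect_error(read_alignment_file(file.path(td, "bad.sam")), "parse|header")
})

test_that("pileup counts, strand resolution and conservation hold", {
  # 8 reads A + 2 reads G at one site
  p <- make_pileup(list(c(A = 8, G = 2)))
  expect_equal(p$counts_fwd[1, 1] + p$counts_rev[1, 1], 8)
  expect_equal(p$counts_fwd[3, 1] + p$counts_rev[3, 1], 2)
  expect_equal(unname(pileup_depth(p)[1]), 10)

  # 10 identical full-match reads: depth 10 across the span
  set.seed(107)
  ref <- genome_sequence("chr", rand_seq(500))
  reads <- rep(substring(ref$sequence, 101, 220), 10)
  aln <- map_reads(reads, ref)
  p2 <- build_pileup(aln)
  expect_true(all(pileup_depth(p2)[101:220] == 10))
  # conservation: total depth equals aligned reference bases consumed
  expect_equal(sum(pileup_depth(p2)), 10 * 120)

  # alignments beyond the reference end raise an error naming a position
  bad <- aln; bad$pos[1] <- 450
  expect_error(build_pileup(bad), "beyond reference end")
})

test_that("paired mapping estimates the insert distribution", {
  sim <- tiny_sim(seed = 30, L = 1e5, coverage = 8)
  aln <- map_reads(sim$reads, sim$ref)
  est <- attr(aln, "insert_est")
  expect_lt(abs(est["mean"] - 205), 5)
  expect_lt(abs(est["sd"] - 30), 6)
  expect_gt(mean(aln$proper[aln$mapped]), 0.95)
})
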