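# Independent oracles used across the suite.  These deliberately share no
# code with the package: the aligner oracle is a plain dynamic program over
# the full matrix, the SSR oracle enumerates every (start, motif length)
# pair, and the N50 oracle scans every candidate length.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# full semi-global edit alignment: the whole read against any reference
# substring (free reference start/end), unit costs; returns the minimal cost
oracle_semiglobal_cost <- function(read, ref, mm = 2, ci = 3, cd = 3) {
  q <- strsplit(read, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q)
  L <- length(r)
  prev <- rep(0, L + 1)  # free start on the reference
  for (i in seq_len(n)) {
    cur <- numeric(L + 1)
    cur[1] <- prev[1] + ci
    sub <- prev[1:L] + ifelse(r == q[i], 0, mm)
    ins <- prev[2:(L + 1)] + ci
    # deletions need a left-to-right pass
    best <- pmin(sub, ins)
    cur[2:(L + 1)] <- best
    for (j in 2:(L + 1)) {
      if (cur[j - 1] + cd < cur[j]) cur[j] <- cur[j - 1] + cd
    }
    prev <- cur
  }
  min(prev)
}

# brute-force perfect-SSR enumeration: tests every (start, motif length)
oracle_find_ssrs <- function(seq,
                             thr = c(`2` = 6L, `3` = 4L, `4` = 3L,
                                     `5` = 3L, `6` = 3L)) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  acgt <- s %in% BASES
  is_prim <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(m - 1)) {
      if (m %% d == 0 &&
          motif == strrep(substr(motif, 1, d), m / d)) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (m in 2:6) {
    i <- 1L
    while (i <= n - m) {
      if (!(acgt[i] && s[i] == s[i + m])) { i <- i + 1L; next }
      j <- i
      while (j <= n - m && acgt[j] && s[j] == s[j + m]) j <- j + 1L
      run <- j - i               # matching comparisons
      count <- (run + m) %/% m
      motif <- paste(s[i:(i + m - 1L)], collapse = "")
      if (count >= thr[[as.character(m)]] && is_prim(motif))
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = i + count * m - 1L, motif = motif,
          motif_length = m, repeats = count, stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_length = integer(),
                      repeats = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# N50 by scanning every candidate length
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  min(lengths)
}

# plant SSR loci into a random background without disturbing flanks
plant_ssrs_into <- function(seq, n_per_m = 2, thr = c(`2` = 6L, `3` = 4L,
                                                      `4` = 3L, `5` = 3L,
                                                      `6` = 3L)) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  for (m in 2:6) {
    for (k in seq_len(n_per_m)) {
      count <- thr[[as.character(m)]] + sample(0:3, 1)
      len <- m * count
      pos <- sample(seq(10, n - len - 10), 1)
      motif <- paste(sample(BASES, m, replace = TRUE), collapse = "")
      s[pos:(pos + len - 1)] <- rep(strsplit(motif, "")[[1]], count)
    }
  }
  paste(s, collapse = "")
}

# mutate an exact read: k substitutions at given positions
with_substitutions <- function(read, pos) {
  ch <- strsplit(read, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# small end-to-end simulation shared by several tests
tiny_sim <- function(seed = 5, L = 2e5, coverage = 10, ...) {
  cfg <- simulation_config(seed = seed, genome_length = L,
                           isochore_block_length = L / 10,
                           coverage = coverage, ...)
  ref <- simulate_reference(cfg)
  dip <- derive_target_diploid(ref, cfg)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg)
  list(cfg = cfg, ref = ref, dip = dip, reads = reads)
}

# pileup from hand-specified base counts at consecutive positions:
# counts is a list of named vectors, e.g. list(c(A = 8, G = 2));
# bases alternate strands so both strands carry every allele
make_pileup <- function(counts, ref_length = length(counts), qual = "I") {
  pos <- integer(); seq <- character(); strand <- character()
  for (i in seq_along(counts)) {
    cc <- counts[[i]]
    for (b in names(cc)) {
      k <- cc[[b]]
      if (k == 0) next
      pos <- c(pos, rep(i, k))
      seq <- c(seq, rep(b, k))
      strand <- c(strand, rep(c("+", "-"), length.out = k))
    }
  }
  aln <- data.frame(qname = sprintf("r%04d", seq_along(pos)),
                    mapped = TRUE, pos = pos, strand = strand,
                    cigar = "1M", cost = 0L, matches = 1L, cols = 1L,
                    identity = 1, frac_aligned = 1, nonspecific = FALSE,
                    seq = ifelse(strand == "-", revcomp(seq), seq),
                    qual = qual, stringsAsFactors = FALSE)
  attr(aln, "ref_name") <- "ref"
  attr(aln, "ref_length") <- as.integer(ref_length)
  class(aln) <- c("refguide_alignments", "data.frame")
  build_pileup(aln)
}

# reference bases consumed by a CIGAR, independent of the package
ref_span_oracle <- function(cg) {
  lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}
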