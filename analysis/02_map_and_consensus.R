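#!/usr/bin/env Rscript

# Stage 2: reference-guided assembly.
#
# Maps each simulated read set against the reference with the unit-cost
# seed-and-extend contract (mismatch 2, insertion 3, deletion 3, length
# fraction 0.5, similarity fraction 0.8), reduces alignments to a pileup,
# and exports consensus genomes at minimum-coverage thresholds 1x, 2x and
# 5x (N below threshold, IUPAC codes at polymorphic sites).

library(refguide)

sim <- "results/sim"
out <- "results/assembly"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref_seq <- read_fasta(file.path(sim, "reference.fasta"))
ref <- genome_sequence(names(ref_seq)[1], ref_seq[[1]])

for (cov in c("3.53x", "5.41x")) {
  reads <- read_fastq_pair(file.path(sim, sprintf("reads_%s_1.fastq", cov)),
                           file.path(sim, sprintf("reads_%s_2.fastq", cov)))
  aln <- map_reads(reads, ref)
  message(sprintf("%s: %.2f%% mapped, %.2f%% non-specific, insert %.0f +/- %.0f",
                  cov, 100 * mean(aln$mapped),
                  100 * mean(aln$nonspecific[aln$mapped]),
                  attr(aln, "insert_est")["mean"],
                  attr(aln, "insert_est")["sd"]))
  write_sam(aln, file.path(out, sprintf("aln_%s.sam", cov)))
  pile <- build_pileup(aln)
  for (thr in c(1L, 2L, 5L)) {
    cons <- call_consensus(pile, consensus_params(min_coverage = thr))
    comp <- consensus_composition(cons)
    message(sprintf("  >=%dx consensus: %.2f%% N, %.2f%% ambiguity codes",
                    thr, comp$pct_n, comp$pct_ambiguous))
    write_fasta(cons, file.path(out, sprintf("consensus_%s_min%d.fasta",
                                             cov, thr)))
    write_coverage_track(cons, file.path(out, sprintf("coverage_%s.bed",
                                                      cov)))
  }
}
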