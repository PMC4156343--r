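#!/usr/bin/env Rscript

# Stage 1: generate the study system.
#
# A 5 Mb reference genome with block-wise GC structure, a target individual
# whose species diverged ~5% from the reference (plus shared indels), two
# haplotypes separated by 1e-3/site heterozygosity with a transition bias,
# planted SSR loci and repeat elements, and 120 bp paired-end reads at the
# two coverages of the study design (3.53x and 5.41x).  Everything is
# written under results/sim/ with a full ground-truth table.

library(refguide)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20140905, genome_length = 5e6)
print(cfg)

ref <- simulate_reference(cfg)
dip <- derive_target_diploid(ref, cfg)
print(dip$truth)

write_fasta(ref, file.path(out, "reference.fasta"))
write_fasta(dip$hap_a, file.path(out, "hap_a.fasta"))
write_fasta(dip$hap_b, file.path(out, "hap_b.fasta"))
write_truth_tsv(dip$truth, file.path(out, "truth.tsv"))
write_fasta(setNames(dip$truth$repeat_library$seq,
                     paste0("repeat_el", seq_len(nrow(dip$truth$repeat_library)))),
            file.path(out, "repeat_library.fasta"))

for (cov in c(3.53, 5.41)) {
  cfg_c <- cfg
  cfg_c$coverage <- cov
  reads <- simulate_reads(dip$hap_a, dip$hap_b, cfg_c)
  message(sprintf("coverage %.2fx: %d pairs, %d bp total", cov,
                  length(reads$r1), 2L * cfg$read_length * length(reads$r1)))
  write_fastq_pair(reads, file.path(out, sprintf("reads_%.2fx", cov)))
}

# the fold-coverage bookkeeping of the raw data, as for the real libraries
fc <- data.frame(
  run = sprintf("%.2fx", c(3.53, 5.41)),
  total_bp = round(c(3.53, 5.41) * cfg$genome_length),
  genome_size = cfg$genome_length)
fc$estimated_fold_coverage <- fold_coverage(fc$total_bp, fc$genome_size)
write.table(fc, file.path(out, "fold_coverage.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(fc)
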