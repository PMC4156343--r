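#!/usr/bin/env Rscript

# Stage 4: heterozygous-variant spectrum.
#
# Maps each read set back to its own 1x guided consensus (the assembly
# design's substrate for variant detection), applies the two-stage filter
# ladder, and summarises the class spectrum and Ts/Tv ratio.  Call counts
# between the two coverages are compared: the better-covered run is
# expected to yield roughly proportionally more calls of every class while
# the relative class fractions stay put.

library(refguide)
library(jsonlite)

out <- "results/variants"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spectra <- list()
for (cov in c("3.53x", "5.41x")) {
  reads <- read_fastq_pair(
    sprintf("results/sim/reads_%s_1.fastq", cov),
    sprintf("results/sim/reads_%s_2.fastq", cov))
  cons <- read_fasta(sprintf("results/assembly/consensus_%s_min1.fasta",
                             cov))
  substrate <- genome_sequence(names(cons)[1], cons[[1]])
  aln <- map_reads(reads, substrate)
  pile <- build_pileup(aln)
  calls <- call_heterozygous(pile, aln = aln)
  calls2 <- apply_stage2(calls)
  sp <- spectrum_summary(calls)
  print(sp)
  write_vcf(calls, file.path(out, sprintf("variants_%s.vcf", cov)),
            ref_name = substrate$name)
  spectra[[cov]] <- list(
    n_stage1 = nrow(calls), n_stage2 = nrow(calls2),
    class_counts = as.list(sp$class_counts),
    class_fractions = as.list(round(sp$class_fractions, 4)),
    ts = sp$ts, tv = sp$tv, tstv = sp$tstv)
}

ratio <- spectra[["5.41x"]]$n_stage1 / spectra[["3.53x"]]$n_stage1
message(sprintf("stage-1 calls: %d (3.53x) vs %d (5.41x); ratio %.2f",
                spectra[["3.53x"]]$n_stage1, spectra[["5.41x"]]$n_stage1,
                ratio))
spectra$call_ratio_hi_over_lo <- ratio
write_json(spectra, file.path(out, "spectra.json"), auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
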