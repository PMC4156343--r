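#!/usr/bin/env Rscript

# Stage 3: genome-content statistics of the guided assemblies.
#
# Splits each consensus at poly-N runs of 500+ and tabulates, per
# coverage and threshold, N50 (with and
# without breaking), length histograms, %N, perfect-SSR densities per Mb,
# GC standard deviation across window sizes against the homogeneous null,
# and repeat-library masking of the contigs.

library(refguide)
library(jsonlite)

out <- "results/content"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- read.delim("results/sim/truth.tsv")
rows <- list()

for (cov in c("3.53x", "5.41x")) {
  for (thr in c(1L, 2L, 5L)) {
    fa <- sprintf("results/assembly/consensus_%s_min%d.fasta", cov, thr)
    cons <- read_fasta(fa)
    contigs <- split_on_n_runs(cons, split_threshold = 500)
    unbroken <- split_on_n_runs(cons, .Machine$integer.max)
    rep <- contiguity_report(contigs, assembly = cons)
    loci <- find_ssrs(contigs)
    dens <- ssr_density(loci, non_n_length(contigs$contigs$sequence))
    gc <- sd_scaling_curve(contigs, c(3000, 5000, 10000, 20000))
    write.table(loci, file.path(out, sprintf("ssr_%s_min%d.tsv", cov, thr)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(gc, file.path(out, sprintf("gc_%s_min%d.tsv", cov, thr)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    rows[[sprintf("%s_min%d", cov, thr)]] <- c(
      list(coverage = cov, min_coverage = thr,
           pct_n = rep$pct_n, n_contigs = rep$n_contigs,
           n50_break500 = rep$n50,
           n50_no_break = n50(unbroken$contigs$length),
           max_contig = rep$max_length),
      as.list(dens))
    message(sprintf("%s >=%dx: %%N %.2f, %d contigs, N50 %s (break) / %s (no break)",
                    cov, thr, rep$pct_n, rep$n_contigs,
                    format(rep$n50, big.mark = ","),
                    format(n50(unbroken$contigs$length), big.mark = ",")))
  }
}

tab <- do.call(rbind, lapply(rows, function(r)
  as.data.frame(r, check.names = FALSE)))
write.table(tab, file.path(out, "assembly_content.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write_json(rows, file.path(out, "assembly_content.json"),
           auto_unbox = TRUE, digits = NA, pretty = TRUE)

# repeat-library masking of the 1x contigs against the planted library
# (simplified local-match masker; a stand-in for full repeat annotation)
cons1 <- read_fasta("results/assembly/consensus_5.41x_min1.fasta")
contigs1 <- split_on_n_runs(cons1, 500)
libseqs <- read_fasta("results/sim/repeat_library.fasta")
planted <- truth[truth$kind == "repeat", ]
planted_bp <- sum(as.integer(planted$ref_allele) - planted$pos + 1)

# on the target genome itself the masker recovers the planted fraction
hap_a <- read_fasta("results/sim/hap_a.fasta")
masked_target <- repeat_library_content(hap_a, libseqs)
# the guided consensus is expected to under-represent target-only
# repeats: reads from inside them cannot map to the reference
masked_guided <- repeat_library_content(contigs1, libseqs)
message(sprintf(
  "repeat masking: target genome %.4f (planted %.4f), 1x guided contigs %.4f",
  masked_target, planted_bp / sum(nchar(hap_a)), masked_guided))
write_json(list(masked_fraction_target = masked_target,
                masked_fraction_guided_1x = masked_guided,
                planted_fraction = planted_bp / sum(nchar(hap_a))),
           file.path(out, "repeat_masking.json"), auto_unbox = TRUE,
           digits = NA)
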