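---
title: "Reference-guided low-coverage assembly: models, parameters and design choices"
author: "refguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided low-coverage assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a species has no assembled genome, low-coverage (roughly 3-6x)
paired-end sequencing is far too shallow for a useful *de novo* assembly:
contigs come out a few hundred bases long and most genes are fragmentary.
If a related species with a high-quality genome exists — as is common in
birds, whose karyotypes and synteny are strongly conserved — the reads can
instead be mapped onto that *guide* genome and a per-position consensus
exported. `refguide` implements this reference-guided procedure end to
end, together with the genome-content statistics used to judge what such a
draft contains: contiguity (N50 before and after splitting at long N
runs), base composition, perfect microsatellite (SSR) densities, windowed
GC heterogeneity against the homogeneous-genome null, and a two-stage
filtered heterozygous-variant spectrum.

Because real experiments of this kind involve tens of gigabases of reads
and proprietary software, every stage here is verified instead on
*synthetic* diverged diploid genomes in which every substitution, indel,
heterozygous site, SSR locus and repeat element is planted by a generator
that records the ground truth. The generator is first-class, tested code:
the pipeline's statistical claims are all claims about what it recovers
from these known inputs.

## The synthetic study system

`simulation_config()` holds the experiment's givens. Its defaults describe
the study design the package targets:

* **Reference genome** — `genome_length` (default 5 Mb for desk-scale runs)
  built from `isochore_block_length` (50 kb) blocks whose GC level is drawn
  from `isochore_gc_levels` (0.35-0.65). Within a block, bases are i.i.d.;
  across blocks this produces the regional GC heterogeneity ("isochore
  structure") that the windowed GC statistics are designed to detect.
  Real isochores are longer-range and autocorrelated; a block model is the
  simplest structure with a known mixture variance, which is what the
  closed-form oracles need.
* **Divergence** — the target species differs from the reference by
  `divergence_rate` substitutions/site (default 0.05, a plausible neutral
  distance for bird species pairs tens of millions of years apart) with
  transition:transversion odds `tstv_ratio` (2.0), plus `indel_rate`
  (1e-3/site) shared indels with geometric lengths (mean
  `1/indel_length_geometric_p` = 2 bp).
* **Heterozygosity** — the two haplotypes differ at `heterozygosity`
  (1e-3/site) events drawn from `het_class_mix`: SNV 0.70, deletion 0.15,
  insertion 0.07, MNV 0.05, replacement 0.03 (a "replacement" is a
  combined substitution + length-change event: k reference bases replaced
  by j != k new bases). Haplotype A always carries the shared target
  allele and haplotype B the variant; reads are drawn from both equally,
  so the caller sees a 50/50 allele mix regardless.
* **Planted features** — perfect SSR loci per `ssr_densities` (40, 20, 10,
  5, 5 loci/Mb for motif lengths 2-6) and repeat-library elements
  (default two random 400 bp elements, 10 copies each). Features are
  planted into the *target* lineage by overwriting equal-length intervals,
  so all truth coordinates stay in reference coordinates; mutations avoid
  planted intervals, and SSR flanks are guarded so each planted run is
  maximal exactly as recorded. Note that random background sequence also
  contains genuine SSR loci (for example, three tandem copies of a 4-mer
  arise spontaneously about once per 10^5 bases), so the *total* scanned
  density exceeds the planted density by a background term; recovery is
  therefore always assessed against the truth table, not by comparing
  total density to planted density.
* **Reads** — 120 bp paired-end reads at `coverage` (default 5.41x, the
  better-covered of the study's two designs; the other is 3.53x), insert
  ~Normal(205, 30) bp. The 205 bp default is the library's ~325 bp mean
  size minus two ~60 bp adapters; the adapter share is not documented, so
  this is a stated assumption. Per-base error is linear from
  `error_rate_start` 1e-4 (Q40) at cycle 1 to `error_rate_end` 1e-3 (Q30)
  at cycle 120, and the quality string encodes the *true* error rate.
  These defaults emulate **quality-trimmed** reads — the real pipeline
  Mott-trims raw reads before mapping — not raw flow-cell output; raw-like
  rates (1e-3 to 1e-2) can be set explicitly, at the cost of many more
  low-frequency error alleles for the variant caller's second filter
  stage to remove.

All randomness derives from `config$seed` through per-stage derived seeds,
so a config reproduces its genome, truth tables and reads byte for byte,
and the caller's own RNG state is left untouched.

What the generator deliberately does *not* model: GC-biased or otherwise
non-uniform coverage, PCR duplicates, adapter read-through, empirically
trained error profiles, and long-range repeat families. Consequently,
coverage gaps in simulated consensus genomes come almost entirely from
unmappable target-only sequence rather than from coverage clumping, and
simulated %N at a given coverage is lower than in the real data; passing
tests certify the *procedures*, not field performance on real libraries.

## Mapping contract

The guide study used a proprietary mapper with unit costs mismatch 2,
insertion 3, deletion 3, length fraction 0.5 and similarity fraction 0.8.
`map_reads()` fixes an open, oracle-checkable contract with those
parameters:

* exact-match seeding (15-mers at half-overlapping offsets; seeds hitting
  more than `max_hits_per_seed` reference positions are skipped),
* banded semi-global alignment around each candidate diagonal (band =
  10% of read length, at least 6), free start/end on the reference side,
* acceptance iff aligned read fraction >= `length_fraction` *and*
  identity within the aligned region >= `similarity_fraction`, where
  identity = matches / aligned columns and indel columns count as
  mismatches,
* reads whose minimal cost is achieved at more than one accepted locus
  are flagged **non-specific** (and excluded from pileups by default)
  rather than placed arbitrarily.

Two deliberate refinements beyond the plain model:

* **End trimming.** A read that runs off the end of a diverged insertion
  (sequence present in the target but absent from the reference) aligns
  its overhang as a dense mismatch stretch; such tails systematically
  deposit false low-frequency alleles in the pileup. After traceback, the
  aligner soft-clips each alignment end whose running score (+1 match, -2
  mismatch/indel) dips below -5 — the same idea as the local-alignment
  soft-clipping of production mappers. The *cost* reported for an
  alignment remains that of the untrimmed semi-global alignment, so it
  stays comparable with an exhaustive dynamic-programming oracle; the
  length-fraction rule is applied to the trimmed extent, which is exactly
  what a "length fraction" acceptance threshold is for.
* **Insert-size estimation.** Proper pairs are those in
  forward/reverse orientation with an implied insert within mean +/- 4 sd,
  the distribution being estimated from the first 10,000
  correctly-oriented pairs. Broken pairs are excluded from pileups by
  default, as the variant analysis requires.

On references up to a few kilobases the reported best cost is tested for
equality with a full (unbanded) dynamic program for reads whose true
alignment lies within the band; the banded search is exact in that regime
and the band is a documented approximation outside it.

## Consensus rules

`call_consensus()` is reference-anchored: the consensus has exactly the
reference length. Per position, with depth = base evidence + deletion
evidence:

* depth < `min_coverage` (or no base evidence at all) gives `N`;
* otherwise the majority base is emitted, unless the best alternative
  allele has at least `alt_min_reads` reads (2) *and* at least
  `alt_fraction` (10%) of total depth — both inclusive, "at least" — in
  which case the IUPAC code of the two alleles is emitted.

Ambiguity is capped at two alleles; ties among alternatives resolve by
higher summed base quality, then alphabetically, so output is
deterministic. The 10% rule uses total depth (whether the original used
total or high-quality depth is unstated). Indel evidence never changes
the consensus length — insertions are reported by the variant caller
instead — which keeps every downstream statistic in reference
coordinates. Raising `min_coverage` can only turn bases into `N`
(pointwise monotonicity), which is the mechanism behind the %N increase
across the 1x/2x/5x export ladder.

## Contiguity, SSR and GC statistics

`split_on_n_runs()` removes maximal N runs of >= 500 (the methods text
says "greater than 500", the results "at least 500"; the inclusive
reading is implemented and the threshold is configurable) and keeps
source coordinates on the resulting contigs. The conservation identity —
contig bases + removed N-run bases + dropped short-contig bases = source
length — is tested on random mosaics. `n50()` uses the sorted-descending
cumulative convention: the largest L such that contigs >= L cover half
the assembly; it is tested against exhaustive enumeration. Length
histograms use the conventional log-spaced bins ([0,200), [200,500), ...,
[10k, Inf)).

`find_ssrs()` reports *perfect* tandem repeats of primitive 2-6 bp motifs
meeting the thresholds {2-mer: 6, 3-mer: 4, 4-6-mer: 3} repeats. A
maximal run is one locus, reported once under the leftmost phase of its
primitive motif; non-ACGT characters terminate runs; truncated runs at
sequence ends count if they meet the thresholds. Densities are loci per
Mb of non-N sequence, so assemblies with very different %N remain
comparable. The scanner is tested for set equality against a brute-force
enumerator over every (start, motif-length) pair.

`gc_profile()` tiles non-overlapping windows from each contig's start
(remainder discarded; windows never span contigs), discards windows with
more than `max_n_fraction` = 0.2 ambiguous bases (guided contigs contain
interior short N runs), computes GC over non-N bases, and reports the
sample standard deviation (n-1). Under a compositionally homogeneous
genome the closed form is sd(w) = sqrt(p(1-p)/w), so the spread halves as
the window size quadruples; `sd_scaling_curve()` anchors that null at the
smallest usable window and reports the excess sd(w)/sd_null(w) as the
isochore-structure signal. Fewer than two usable windows is an explicit
"insufficient windows" status, never a silent zero.

`compare_window_samples()` draws a seed-reproducible subsample of windows
and compares it to the full set with a two-sample asymptotic
Kolmogorov-Smirnov test. Because the subsample is contained in the full
set, this comparison is *conservative* (p-values lean towards 1); that is
the intended behavior of the sampling experiment it reproduces — asking
whether a reduced window sample is representative — and the test suite
checks conservativeness rather than exact uniformity of the null
p-values.

`repeat_library_content()` is a deliberately simplified masker: local
seed-and-extend matches of library elements (same unit-cost model as read
mapping) of at least `min_match` bases and `min_identity` identity are
merged and the covered fraction reported. It stands in for full
repeat-annotation pipelines, which are out of scope. On guided
assemblies of the default simulation it reports ~0: reads from
target-only repeat copies cannot map to the reference, so the consensus
does not contain them — the under-representation of repeats in guided
assemblies, reproduced in miniature.

## Heterozygous-variant model and filters

`call_heterozygous()` evaluates each site's top two alleles under a
binomial read-sampling model with allele-b fractions {e, 0.5, 1-e} for
the genotypes {hom-majority, het, hom-alternative}. The error rate e of
a site comes from the *alternative allele's own* mean base quality (and
the majority allele's for the hom-alternative branch): coincident
late-cycle errors carry low qualities and are priced accordingly.

The genotype prior is weakly informative — P(het) = `het_prior` (1e-3,
the design heterozygosity), P(hom-alt) = `hom_alt_prior` (0.05, the
design divergence) — rather than flat. A flat prior is untenable here:
two coincident high-quality errors at a site of depth <= ~26 always give
P(het) > 0.8 under it, which floods the genome with false calls at a rate
two orders of magnitude above the true heterozygous-site density. The
prior suppresses exactly those 2-read cases at high depth while leaving
low-coverage true heterozygotes (where 2 supporting reads out of 5 are
entirely expected) untouched; setting both priors to 1/3 recovers the
flat model.

Stage 1 keeps sites with depth >= 4, alternative reads >= 2, P(het) >=
0.80, the alternative on both strands, and at most 2 alleles. Two
artifact guards, both restricted to calls below the 30% allele-frequency
bound (true heterozygotes live near 50%), handle reference-guided
pathologies: substitutions within `snp_gap` (5 bp) of indel evidence are
suppressed (indel-flank misalignment; the same idea as `bcftools`'
SnpGap), and substitutions whose alternative-allele reads align
systematically worse than the site's other reads (mean cost excess >
`max_alt_cost_excess`) are suppressed.

Adjacent substitution calls merge into an MNV only with phase evidence:
at least two reads carrying both alternative alleles, and at least 80% of
alternative-carrying reads in phase. An indel call immediately adjacent
to a substitution call merges into a "replacement". In practice planted
replacements are usually recovered as separate deletion + SNV calls
(alignment places the length change wherever it is cheapest), so the
replacement class is under-called; the misclassification is consistent
across coverages, which is what the cross-coverage spectrum comparison
needs.

`apply_stage2()` implements the robust subset literally: depth strictly
greater than 5, allele frequency within [30%, 70%] (inclusive — the
source's "between" is not qualified), each strand's supporting fraction
at least 30%, and mean supporting-base PHRED strictly greater than 40.
On simulated data whose quality scale tops out at Q40 the last criterion
retains nothing, so stage 2 is exercised on constructed call tables in
the tests and parameter-recovery experiments are evaluated on stage-1
calls; on recalibrated real-world qualities the threshold is meaningful.
`spectrum_summary()` splits SNVs into the 4 transition and 8 transversion
ordered types and reports Ts/Tv (explicitly undefined with no SNVs).

Variant calling defaults to the 1x consensus as mapping substrate in
`run_pipeline()` (the design it reproduces); `run_recovery_experiment()`
uses the reference pileup directly, since truth positions are reference
coordinates.

## Problem sizes and numerical choices

The bundled experiments use 5 Mb genomes: recovery at 20x for caller
quality (measured recall ~0.96, false heterozygous SNVs ~2-4/Mb, Ts/Tv
within ~7% of the planted 2.0 across seeds), and matched 3.53x/5.41x runs
for the coverage scaling of call counts (ratio ~2, with class fractions
stable). GC-null checks use 10 Mb i.i.d. genomes; at the largest windows
the sd estimator's own sampling error (~2.5% at 125 windows of 80 kb)
approaches the 5% check tolerance, so the test suite takes the median
over three independent genomes while single-genome values are still
reported by the acceptance script. Thresholds compared against stated
fractions (similarity 0.8, allele frequencies) use an epsilon of 1e-9 to
keep exact boundary cases (96/120 = 0.8) on the inclusive side of
floating-point division.

## Known limitations

* Desk-scale mapper: a sorted k-mer array, not a BWT index; intended for
  references up to tens of megabases.
* The banded alignment is exact only for alignments within the band; a
  true alignment with net indel drift beyond 10% of the read length is
  found suboptimally or not at all.
* Uniform coverage in the generator understates real %N at a given
  coverage (no GC bias or clumping).
* Replacement-class variants are systematically under-called (above).
* Isochore structure is modelled as independent constant-GC blocks; no
  segmentation or boundary calling is attempted on real genomes.
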