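#' Assess heterozygous-variant recovery against simulation truth
#'
#' Matches substitution calls to planted heterozygous events and summarises
#' detection quality.  A SNV call counts as a true detection when a planted
#' het SNV exists at exactly its position; recall is the fraction of
#' planted het SNVs with a SNV (or merged MNV) call covering their
#' position.  A call is counted false only when no planted heterozygous
#' event of any class lies within `window` bases — calls inside that
#' window are mislocalised or partially-classified detections of real
#' events (e.g. the substitution component of a replacement), not false
#' positives.
#'
#' @param calls a `variant_calls` data.frame.
#' @param truth a `simulation_truth` (or its `het_sites` data.frame).
#' @param genome_length genome length in bases, for the per-Mb rate.
#' @param window matching window in bases for the false-call rule.
#' @return list: `recall_snv`, `false_snv_per_mb`, `tstv` (of all SNV
#'   calls), `n_called_snv`, `n_truth_snv`.
#' @export
assess_het_recovery <- function(calls, truth, genome_length,
                                window = 10L) {
  het <- if (inherits(truth, "simulation_truth")) truth$het_sites else truth
  snv_truth <- het[het$class == "SNV", , drop = FALSE]
  snv_calls <- calls[calls$class == "SNV", , drop = FALSE]
  mnv_calls <- calls[calls$class == "MNV", , drop = FALSE]
  covered <- snv_truth$pos %in% snv_calls$pos |
    snv_truth$pos %in% mnv_calls$pos |
    snv_truth$pos %in% (mnv_calls$pos + 1L)
  recall <- mean(covered)
  false_snv <- if (nrow(snv_calls)) {
    vapply(snv_calls$pos, function(p)
      min(abs(p - het$pos)) > window, logical(1))
  } else logical(0)
  sp <- spectrum_summary(calls)
  list(recall_snv = recall,
       false_snv_per_mb = sum(false_snv) / (genome_length / 1e6),
       tstv = sp$tstv,
       n_called_snv = nrow(snv_calls),
       n_truth_snv = nrow(snv_truth))
}

#' Run the simulate-map-call recovery experiment
#'
#' Generates a diverged diploid genome and reads under `config`, maps the
#' reads back to the reference, calls stage-1 heterozygous variants on the
#' reference pileup, and assesses them against the planted truth.  This is
#' the package's parameter-recovery experiment: at ~20x it measures caller
#' quality; matched runs at low coverages reproduce the qualitative
#' coverage scaling of call counts.
#'
#' @param config a [simulation_config()].
#' @param mapping a [mapping_params()].
#' @param variants a [variant_filter_params()].
#' @return list with the recovery summary (`assessment`), the `calls`, the
#'   `truth`, and mapping statistics.
#' @export
run_recovery_experiment <- function(config,
                                    mapping = mapping_params(),
                                    variants = variant_filter_params()) {
  ref <- simulate_reference(config)
  dip <- derive_target_diploid(ref, config)
  reads <- simulate_reads(dip$hap_a, dip$hap_b, config)
  aln <- map_reads(reads, ref, mapping)
  pile <- build_pileup(aln)
  calls <- call_heterozygous(pile, variants, aln = aln)
  list(assessment = assess_het_recovery(calls, dip$truth,
                                        config$genome_length),
       calls = calls, truth = dip$truth,
       spectrum = spectrum_summary(calls),
       frac_mapped = mean(aln$mapped),
       mean_depth = mean(pileup_depth(pile)))
}
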