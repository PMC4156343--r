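#' Two-stage heterozygous-variant filter parameters
#'
#' Stage 1 (detection): minimum coverage 4 reads, at least 2 reads
#' supporting the variant, posterior heterozygosity probability at least
#' 80%, variant present on both strands, at most 2 alleles per position.
#' Stage 2 (robust subset): coverage strictly greater than 5 reads, allele
#' frequency between 30% and 70% (inclusive), each strand supporting the
#' variant in at least 30% of its reads, and mean PHRED quality of the
#' variant-supporting bases strictly greater than 40.
#'
#' @param min_coverage,min_alt_reads,min_probability,require_both_strands,max_alleles
#'   stage-1 thresholds.
#' @param min_coverage_exclusive,allele_freq_min,allele_freq_max,per_strand_min_fraction,min_mean_phred
#'   stage-2 thresholds.
#' @param max_alt_cost_excess artifact guard used when alignments are
#'   available to the caller: a substitution call is suppressed when the
#'   mean alignment cost of its alternative-allele reads exceeds that of
#'   the site's other reads by more than this (misaligned-minority
#'   signature of indel-flank and diverged-insertion-boundary artifacts).
#'   `Inf` disables the guard.
#' @param het_prior,hom_alt_prior genotype prior probabilities for the
#'   heterozygous and homozygous-alternative genotypes (remainder to
#'   homozygous-majority), reflecting the expected heterozygosity and
#'   target-reference divergence; a flat prior (1/3 each) is recovered
#'   with `het_prior = hom_alt_prior = 1/3`.
#' @param snp_gap substitution calls with allele frequency below
#'   `allele_freq_min` lying within this many bases of indel evidence
#'   (2+ reads) are suppressed as indel-flank misalignment artifacts;
#'   0 disables.
#' @return object of class `variant_filter_params`.
#' @export
variant_filter_params <- function(min_coverage = 4L, min_alt_reads = 2L,
                                  min_probability = 0.80,
                                  require_both_strands = TRUE,
                                  max_alleles = 2L,
                                  min_coverage_exclusive = 5L,
                                  allele_freq_min = 0.30,
                                  allele_freq_max = 0.70,
                                  per_strand_min_fraction = 0.30,
                                  min_mean_phred = 40,
                                  max_alt_cost_excess = 6,
                                  het_prior = 1e-3,
                                  hom_alt_prior = 0.05,
                                  snp_gap = 5L) {
  p <- list(min_coverage = as.integer(min_coverage),
            min_alt_reads = as.integer(min_alt_reads),
            min_probability = min_probability,
            require_both_strands = isTRUE(require_both_strands),
            max_alleles = as.integer(max_alleles),
            min_coverage_exclusive = as.integer(min_coverage_exclusive),
            allele_freq_min = allele_freq_min,
            allele_freq_max = allele_freq_max,
            per_strand_min_fraction = per_strand_min_fraction,
            min_mean_phred = min_mean_phred,
            max_alt_cost_excess = max_alt_cost_excess,
            het_prior = het_prior, hom_alt_prior = hom_alt_prior,
            snp_gap = as.integer(snp_gap))
  stopifnot(p$min_coverage > 0, p$min_alt_reads >= 1,
            p$min_probability >= 0, p$min_probability <= 1,
            p$allele_freq_min >= 0, p$allele_freq_max <= 1,
            p$allele_freq_min <= p$allele_freq_max)
  class(p) <- "variant_filter_params"
  p
}

# posterior P(het) from top-two allele counts under a binomial read-sampling
# model: allele-b fractions {e, 0.5, 1-e_ref} under genotypes
# {hom-majority, het, hom-alternative}
het_posterior <- function(n1, n2, e, e_ref = e, prior_het = 1e-3,
                          prior_hom_alt = 0.05) {
  e <- pmin(pmax(e, 1e-6), 0.25)
  e_ref <- pmin(pmax(e_ref, 1e-6), 0.25)
  prior_hom1 <- max(1 - prior_het - prior_hom_alt, 1e-12)
  ll_hom1 <- n2 * log(e) + n1 * log1p(-e) + log(prior_hom1)
  ll_het <- (n1 + n2) * log(0.5) + log(prior_het)
  ll_hom2 <- n1 * log(e_ref) + n2 * log1p(-e_ref) + log(prior_hom_alt)
  m <- pmax(ll_hom1, ll_het, ll_hom2)
  exp(ll_het - m) /
    (exp(ll_hom1 - m) + exp(ll_het - m) + exp(ll_hom2 - m))
}

#' Call heterozygous variants from a pileup
#'
#' Per site a posterior over genotypes (homozygous majority, heterozygous,
#' homozygous alternative) is computed from a binomial read-sampling
#' likelihood with the per-base error implied by the site's mean PHRED
#' quality and a flat genotype prior; "variant probability" is the
#' posterior probability of the heterozygous genotype.  Sites pass stage 1
#' iff depth >= 4, alternative reads >= 2, P(het) >= 0.80, the alternative
#' is seen on both strands, and at most 2 alleles are supported.  Adjacent
#' qualifying substitutions are merged into an MNV when reads carrying both
#' alternative alleles in phase support the merge; an indel call
#' immediately adjacent to a substitution call is merged into a
#' "replacement" (a combined substitution + length-change event).
#' The pileup should have been built with non-specific matches and broken
#' pairs excluded (the default in [build_pileup()]).
#'
#' @param pileup a `refguide_pileup`.
#' @param params a [variant_filter_params()].
#' @param aln optional alignments (as passed to [build_pileup()]); when
#'   provided, adjacent substitution calls are phase-checked and merged
#'   into MNVs.  Without alignments adjacent SNVs stay separate.
#' @param indel_error assumed per-read indel observation error rate used in
#'   the posterior for insertion/deletion/replacement calls.
#' @return data.frame of class `variant_calls`: `pos` (1-based), `class`
#'   (`SNV`, `MNV`, `insertion`, `deletion`, `replacement`), `allele_a`
#'   (majority), `allele_b` (alternative), `depth`, `alt_reads`,
#'   `alt_fraction`, `fwd_fraction`, `rev_fraction` (per-strand fraction of
#'   that strand's reads supporting the alternative), `mean_phred` (of
#'   alternative-supporting bases), `probability` (posterior P(het)).
#' @export
call_heterozygous <- function(pileup, params = variant_filter_params(),
                              aln = NULL, indel_error = 1e-3) {
  stopifnot(inherits(pileup, "refguide_pileup"))
  cand <- variant_candidates_cpp(pileup$counts_fwd, pileup$counts_rev,
                                 pileup$qual_sum, pileup$del,
                                 params$min_coverage, params$min_alt_reads)
  calls <- NULL
  if (nrow(cand)) {
    # error rate from the alternative allele's own mean base quality, so
    # that low-quality (late-cycle) error pileups are not mistaken for
    # heterozygosity
    prob <- het_posterior(cand$n1, cand$n2, phred_to_error(cand$qual_b),
                          phred_to_error(cand$qual_a),
                          params$het_prior, params$hom_alt_prior)
    ok <- prob >= params$min_probability &
      cand$n_alleles <= params$max_alleles
    if (params$require_both_strands)
      ok <- ok & cand$n2_fwd >= 1 & cand$n2_rev >= 1
    calls <- data.frame(
      pos = cand$pos[ok], class = rep("SNV", sum(ok)),
      allele_a = cand$allele_a[ok], allele_b = cand$allele_b[ok],
      depth = cand$depth[ok], alt_reads = cand$n2[ok],
      alt_fraction = cand$n2[ok] / cand$depth[ok],
      fwd_fraction = ifelse(cand$depth_fwd[ok] > 0,
                            cand$n2_fwd[ok] / cand$depth_fwd[ok], 0),
      rev_fraction = ifelse(cand$depth_rev[ok] > 0,
                            cand$n2_rev[ok] / cand$depth_rev[ok], 0),
      mean_phred = cand$qual_b[ok], probability = prob[ok],
      stringsAsFactors = FALSE)
  }

  ## indel candidates from the pileup's indel-allele table
  ind <- pileup$indels
  if (!is.null(ind) && nrow(ind)) {
    depth_tot <- pileup_depth(pileup)
    dsub_f <- colSums(pileup$counts_fwd)
    dsub_r <- colSums(pileup$counts_rev)
    alt <- ind$fwd + ind$rev
    depth <- depth_tot[ind$pos]
    keep <- depth >= params$min_coverage & alt >= params$min_alt_reads
    if (params$require_both_strands)
      keep <- keep & ind$fwd >= 1 & ind$rev >= 1
    ind <- ind[keep, , drop = FALSE]
    if (nrow(ind)) {
      alt <- ind$fwd + ind$rev
      depth <- depth_tot[ind$pos]
      n1 <- pmax(depth - alt, 0L)
      prob <- het_posterior(n1, alt, indel_error,
                            prior_het = params$het_prior,
                            prior_hom_alt = params$hom_alt_prior)
      okI <- prob >= params$min_probability
      ind <- ind[okI, , drop = FALSE]
      if (nrow(ind)) {
        alt <- ind$fwd + ind$rev
        depth <- depth_tot[ind$pos]
        dls <- integer(nrow(ind))
        isD <- ind$type == "D"
        dls[isD] <- as.integer(ind$allele[isD])
        icalls <- data.frame(
          pos = ind$pos,
          class = ifelse(ind$type == "I", "insertion", "deletion"),
          allele_a = "", allele_b = ifelse(ind$type == "I", ind$allele, ""),
          depth = depth, alt_reads = alt, alt_fraction = alt / depth,
          fwd_fraction = ifelse(dsub_f[ind$pos] + ind$fwd > 0,
                                ind$fwd / pmax(dsub_f[ind$pos], 1), 0),
          rev_fraction = ifelse(dsub_r[ind$pos] + ind$rev > 0,
                                ind$rev / pmax(dsub_r[ind$pos], 1), 0),
          mean_phred = ind$mean_qual, probability = prob[okI],
          stringsAsFactors = FALSE)
        icalls$del_len <- dls
        if (is.null(calls)) calls <- icalls
        else { calls$del_len <- 0L; calls <- rbind(calls, icalls) }
      }
    }
  }
  if (is.null(calls))
    calls <- data.frame(pos = integer(), class = character(),
                        allele_a = character(), allele_b = character(),
                        depth = integer(), alt_reads = integer(),
                        alt_fraction = numeric(), fwd_fraction = numeric(),
                        rev_fraction = numeric(), mean_phred = numeric(),
                        probability = numeric(), stringsAsFactors = FALSE)
  if (is.null(calls$del_len)) calls$del_len <- integer(nrow(calls))
  calls <- calls[order(calls$pos, calls$class), , drop = FALSE]

  if (params$snp_gap > 0 && nrow(calls)) {
    ie <- which(pileup$ins >= 2L | pileup$del >= 2L)
    if (length(ie)) {
      lowaf <- calls$class == "SNV" &
        calls$alt_fraction < params$allele_freq_min
      nearest <- findInterval(calls$pos, ie)
      d1 <- abs(calls$pos - ie[pmax(nearest, 1L)])
      d2 <- abs(ie[pmin(nearest + 1L, length(ie))] - calls$pos)
      calls <- calls[!(lowaf & pmin(d1, d2) <= params$snp_gap), ,
                     drop = FALSE]
    }
  }
  if (!is.null(aln) && nrow(calls)) {
    calls <- filter_misaligned_alt(calls, aln, params$max_alt_cost_excess,
                                   params$allele_freq_min)
    calls <- merge_adjacent_snvs(calls, aln)
  }
  calls <- merge_replacements(calls)
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

# suppress substitution calls whose alternative-allele reads are
# systematically worse-aligned than the site's other reads: the signature
# of boundary reads from diverged insertions and of indel-flank
# misalignment, which produce consistent low-frequency false alleles
filter_misaligned_alt <- function(calls, aln, max_excess = 6,
                                  max_af = 0.5) {
  if (!is.finite(max_excess)) return(calls)
  snv <- which(calls$class == "SNV" & calls$alt_fraction < max_af)
  if (!length(snv) || is.null(aln$cost) || all(is.na(aln$cost)))
    return(calls)
  use <- aln$mapped & !aln$nonspecific
  if (!is.null(aln$proper)) use <- use & !is.na(aln$proper) & aln$proper
  sub <- aln[use, , drop = FALSE]
  o <- order(sub$pos)
  sub <- sub[o, , drop = FALSE]
  max_span <- 200L
  drop <- logical(nrow(calls))
  lo_all <- findInterval(calls$pos[snv] - max_span, sub$pos)
  hi_all <- findInterval(calls$pos[snv], sub$pos)
  for (k in seq_along(snv)) {
    i <- snv[k]
    rows <- seq.int(lo_all[k] + 1L, hi_all[k])
    if (!length(rows)) next
    s <- sub[rows, , drop = FALSE]
    bb <- read_bases_at_cpp(s$pos, s$cigar, s$seq, s$strand == "-",
                            calls$pos[i])[, 1]
    is_alt <- bb == calls$allele_b[i]
    is_other <- bb != "" & !is_alt
    if (sum(is_alt) == 0 || sum(is_other) == 0) next
    if (mean(s$cost[is_alt]) - mean(s$cost[is_other]) > max_excess)
      drop[i] <- TRUE
  }
  calls[!drop, , drop = FALSE]
}

# merge runs of adjacent SNV calls into MNVs when individual reads carry
# both alternative alleles (phase evidence); at least 2 phased reads and
# at least 80% of alternative reads in phase are required
merge_adjacent_snvs <- function(calls, aln) {
  snv <- which(calls$class == "SNV")
  if (length(snv) < 2) return(calls)
  drop <- logical(nrow(calls))
  for (k in seq_len(length(snv) - 1)) {
    i <- snv[k]; j <- snv[k + 1]
    if (drop[i] || calls$pos[j] != calls$pos[i] + 1L) next
    sites <- c(calls$pos[i], calls$pos[j])
    sub <- aln[aln$mapped & aln$pos <= sites[1] &
                 aln$pos + 200L >= sites[2], , drop = FALSE]
    if (!nrow(sub)) next
    bb <- read_bases_at_cpp(sub$pos, sub$cigar, sub$seq,
                            sub$strand == "-", sites)
    covered <- bb[, 1] != "" & bb[, 2] != ""
    both_alt <- covered & bb[, 1] == calls$allele_b[i] &
      bb[, 2] == calls$allele_b[j]
    one_alt <- covered & xor(bb[, 1] == calls$allele_b[i],
                             bb[, 2] == calls$allele_b[j])
    if (sum(both_alt) >= 2 &&
        sum(both_alt) >= 0.8 * (sum(both_alt) + sum(one_alt))) {
      calls$class[i] <- "MNV"
      calls$allele_a[i] <- paste0(calls$allele_a[i], calls$allele_a[j])
      calls$allele_b[i] <- paste0(calls$allele_b[i], calls$allele_b[j])
      drop[j] <- TRUE
    }
  }
  calls[!drop, , drop = FALSE]
}

# an indel call immediately adjacent to a substitution call is a combined
# substitution + length-change event ("replacement")
merge_replacements <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  drop <- logical(nrow(calls))
  o <- order(calls$pos)
  for (k in seq_len(length(o) - 1)) {
    i <- o[k]; j <- o[k + 1]
    if (drop[i] || drop[j]) next
    sub_i <- calls$class[i] %in% c("SNV", "MNV")
    ind_j <- calls$class[j] %in% c("insertion", "deletion")
    ind_i <- calls$class[i] %in% c("insertion", "deletion")
    sub_j <- calls$class[j] %in% c("SNV", "MNV")
    span_i <- calls$pos[i] + max(nchar(calls$allele_a[i]),
                                 calls$del_len[i], 1L) - 1L
    if (calls$pos[j] - span_i != 1L) next
    if ((sub_i && ind_j) || (ind_i && sub_j)) {
      calls$class[i] <- "replacement"
      calls$allele_a[i] <- paste0(calls$allele_a[i], calls$allele_a[j])
      calls$allele_b[i] <- paste0(calls$allele_b[i], calls$allele_b[j])
      calls$del_len[i] <- calls$del_len[i] + calls$del_len[j]
      drop[j] <- TRUE
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Apply the stage-2 robust filter to variant calls
#'
#' Retains calls with depth strictly greater than 5, allele frequency in
#' `[0.30, 0.70]` (inclusive), both strand fractions at least 0.30, and
#' mean PHRED of the variant-supporting bases strictly greater than 40.
#'
#' @param calls a `variant_calls` data.frame from [call_heterozygous()].
#' @param params a [variant_filter_params()].
#' @return the retained subset, same class.
#' @export
apply_stage2 <- function(calls, params = variant_filter_params()) {
  keep <- calls$depth > params$min_coverage_exclusive &
    calls$alt_fraction >= params$allele_freq_min - 1e-9 &
    calls$alt_fraction <= params$allele_freq_max + 1e-9 &
    calls$fwd_fraction >= params$per_strand_min_fraction - 1e-9 &
    calls$rev_fraction >= params$per_strand_min_fraction - 1e-9 &
    !is.na(calls$mean_phred) & calls$mean_phred > params$min_mean_phred
  out <- calls[keep, , drop = FALSE]
  class(out) <- class(calls)
  out
}

#' Summarise the variant-class and Ts/Tv spectrum
#'
#' @param calls a `variant_calls` data.frame.
#' @return list of class `variant_spectrum`: `class_counts`,
#'   `class_fractions` over the five classes, `snv_types` (counts of the 12
#'   ordered substitution types, majority allele to alternative),
#'   `ts`, `tv` and `tstv` (NA with an explanatory `note` when no SNVs).
#' @export
spectrum_summary <- function(calls) {
  classes <- c("SNV", "MNV", "insertion", "deletion", "replacement")
  cc <- table(factor(calls$class, levels = classes))
  snv <- calls[calls$class == "SNV", , drop = FALSE]
  types <- paste0(snv$allele_a, ">", snv$allele_b)
  all_types <- as.vector(outer(.BASES, .BASES, function(a, b)
    paste0(a, ">", b)))
  all_types <- all_types[substr(all_types, 1, 1) !=
                           substr(all_types, 3, 3)]
  tcount <- table(factor(types, levels = sort(all_types)))
  is_ts <- vapply(names(tcount), function(t)
    is_transition(substr(t, 1, 1), substr(t, 3, 3)), logical(1))
  ts <- sum(tcount[is_ts]); tv <- sum(tcount[!is_ts])
  structure(list(
    class_counts = c(cc),
    class_fractions = if (sum(cc) > 0) c(cc) / sum(cc) else c(cc) * NA,
    snv_types = c(tcount), ts = ts, tv = tv,
    tstv = if (tv > 0) ts / tv else NA_real_,
    note = if (nrow(snv) == 0) "no SNVs: Ts/Tv undefined" else NULL),
    class = "variant_spectrum")
}

#' @export
print.variant_spectrum <- function(x, ...) {
  cat("variant spectrum:\n")
  print(x$class_counts)
  cat(sprintf("Ts/Tv: %s (%d transitions, %d transversions)\n",
              ifelse(is.na(x$tstv), "undefined", sprintf("%.3f", x$tstv)),
              x$ts, x$tv))
  invisible(x)
}

#' Write variant calls as a VCF file
#'
#' Minimal VCF 4.2 text with INFO keys DP (depth), AF (alternative allele
#' fraction), SB (forward,reverse strand fractions), MQ (mean PHRED of
#' supporting bases), PHET (posterior heterozygosity probability) and
#' CLASS.
#'
#' @param calls a `variant_calls` data.frame.
#' @param path output file.
#' @param ref_name reference sequence name for the CHROM column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, ref_name = "ref") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", ref_name),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt fraction\">",
               "##INFO=<ID=SB,Number=2,Type=Float,Description=\"Strand fractions\">",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean PHRED of alt bases\">",
               "##INFO=<ID=PHET,Number=1,Type=Float,Description=\"P(het)\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    ref_col <- ifelse(calls$class == "deletion",
                      strrep("N", pmax(calls$del_len, 1L)),
                      ifelse(nzchar(calls$allele_a), calls$allele_a, "N"))
    alt_col <- ifelse(nzchar(calls$allele_b), calls$allele_b, "<DEL>")
    lines <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.3f;SB=%.2f,%.2f;MQ=%.1f;PHET=%.3f;CLASS=%s",
      ref_name, calls$pos, ref_col, alt_col, calls$depth,
      calls$alt_fraction, calls$fwd_fraction, calls$rev_fraction,
      calls$mean_phred, calls$probability, calls$class)
    writeLines(lines, con)
  }
  invisible(path)
}
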