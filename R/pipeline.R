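#' Run the full reference-guided assembly and assessment pipeline
#'
#' Orchestrates simulate -> map -> consensus (one per coverage threshold) ->
#' split/contiguity metrics -> SSR scan -> GC scaling -> heterozygous
#' variants, entirely from a [simulation_config()], and returns a
#' consolidated report with one block per consensus threshold.  The run is
#' deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param mapping a [mapping_params()].
#' @param consensus_thresholds strictly increasing minimum-coverage
#'   thresholds; one consensus block per value.
#' @param split_threshold poly-N split threshold in bases.
#' @param min_contig_length minimum contig length after splitting.
#' @param ssr an [ssr_params()].
#' @param gc_windows window sizes for the GC scaling curve.
#' @param variants a [variant_filter_params()].
#' @param variant_substrate `"consensus"` maps the reads back to the 1x
#'   consensus for variant calling (the study's design); `"reference"`
#'   reuses the reference pileup.
#' @param out_dir optional directory; when given, FASTA/FASTQ/VCF/JSON
#'   artifacts are written there.
#' @param verbose log each stage to stderr.
#' @return list of class `pipeline_report`: `config` summary, `mapping`
#'   stats, `thresholds` (named blocks with composition, contiguity, SSR
#'   densities and GC curve), and `variants` (stage-1/stage-2 spectra).
#' @export
run_pipeline <- function(config = simulation_config(),
                         mapping = mapping_params(),
                         consensus_thresholds = c(1L, 2L, 5L),
                         split_threshold = 500L,
                         min_contig_length = 1L,
                         ssr = ssr_params(),
                         gc_windows = c(3000, 5000, 10000, 20000),
                         variants = variant_filter_params(),
                         variant_substrate = c("consensus", "reference"),
                         out_dir = NULL, verbose = FALSE) {
  variant_substrate <- match.arg(variant_substrate)
  if (any(diff(consensus_thresholds) <= 0))
    stop("consensus thresholds must be strictly increasing")
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose)
      message(sprintf("[%s] %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  ref <- log_stage("simulate_reference", simulate_reference(config))
  dip <- log_stage("derive_target_diploid", derive_target_diploid(ref, config))
  reads <- log_stage("simulate_reads",
                     simulate_reads(dip$hap_a, dip$hap_b, config))
  if (!length(reads$r1)) stop("pipeline stage 'simulate_reads' failed: ",
                              "empty read set")
  aln <- log_stage("map_reads", map_reads(reads, ref, mapping))
  pile <- log_stage("build_pileup", build_pileup(aln))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ref, file.path(out_dir, "reference.fasta"))
    write_fasta(dip$hap_a, file.path(out_dir, "hap_a.fasta"))
    write_fasta(dip$hap_b, file.path(out_dir, "hap_b.fasta"))
    write_fastq_pair(reads, file.path(out_dir, "reads"))
    write_truth_tsv(dip$truth, file.path(out_dir, "truth.tsv"))
  }

  blocks <- list()
  cons1 <- NULL
  for (thr in consensus_thresholds) {
    name <- paste0(thr, "x")
    block <- log_stage(paste0("consensus_", name), {
      cons <- call_consensus(pile, consensus_params(min_coverage = thr))
      comp <- consensus_composition(cons)
      contigs <- split_on_n_runs(cons, split_threshold, min_contig_length)
      nobreak_lens <- split_on_n_runs(cons, .Machine$integer.max,
                                      min_contig_length)$contigs$length
      rep_con <- contiguity_report(contigs, assembly = cons,
                                   genome_size = config$genome_length,
                                   total_bases = 2 * config$read_length *
                                     length(reads$r1))
      loci <- find_ssrs(contigs, ssr)
      dens <- ssr_density(loci, non_n_length(contigs$contigs$sequence))
      gc <- sd_scaling_curve(contigs, gc_windows)
      if (!is.null(out_dir))
        write_fasta(cons, file.path(out_dir, paste0("consensus_", name,
                                                    ".fasta")))
      if (thr == min(consensus_thresholds)) cons1 <- cons
      list(min_coverage = thr,
           pct_n = comp$pct_n,
           pct_ambiguous = comp$pct_ambiguous,
           n50_no_break = if (length(nobreak_lens)) n50(nobreak_lens)
                          else NA_real_,
           n50_break = rep_con$n50,
           n_contigs = rep_con$n_contigs,
           total_length = rep_con$total_length,
           length_histogram = rep_con$length_histogram,
           fold_coverage = rep_con$fold_coverage,
           ssr_density = dens,
           gc_curve = gc)
    })
    blocks[[name]] <- block
  }

  var_block <- log_stage("variants", {
    if (variant_substrate == "consensus") {
      aln2 <- map_reads(reads, genome_sequence("cons", cons1$seq), mapping)
      pile2 <- build_pileup(aln2)
    } else {
      aln2 <- aln
      pile2 <- pile
    }
    calls1 <- call_heterozygous(pile2, variants, aln = aln2)
    calls2 <- apply_stage2(calls1, variants)
    if (!is.null(out_dir))
      write_vcf(calls1, file.path(out_dir, "variants.vcf"),
                ref_name = pile2$ref_name)
    list(substrate = variant_substrate,
         n_stage1 = nrow(calls1), n_stage2 = nrow(calls2),
         spectrum_stage1 = spectrum_summary(calls1),
         spectrum_stage2 = spectrum_summary(calls2),
         calls_stage1 = calls1, calls_stage2 = calls2)
  })

  report <- structure(list(
    config = config,
    truth = dip$truth,
    mapping = list(n_reads = 2L * length(reads$r1),
                   frac_mapped = mean(aln$mapped),
                   frac_nonspecific = mean(aln$nonspecific[aln$mapped]),
                   insert_est = attr(aln, "insert_est")),
    thresholds = blocks,
    variants = var_block), class = "pipeline_report")
  if (!is.null(out_dir))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# numeric summary of a report, suitable for JSON serialisation
report_to_json <- function(report) {
  list(
    genome_length = report$config$genome_length,
    coverage = report$config$coverage,
    mapping = report$mapping[c("n_reads", "frac_mapped",
                               "frac_nonspecific")],
    thresholds = lapply(report$thresholds, function(b)
      b[c("min_coverage", "pct_n", "pct_ambiguous", "n50_no_break",
          "n50_break", "n_contigs", "total_length", "fold_coverage",
          "ssr_density")]),
    variants = list(n_stage1 = report$variants$n_stage1,
                    n_stage2 = report$variants$n_stage2,
                    tstv = report$variants$spectrum_stage1$tstv))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %s bp genome at %.2fx\n",
              format(x$config$genome_length, big.mark = ","),
              x$config$coverage))
  for (b in x$thresholds)
    cat(sprintf("  >=%dx: %%N %.2f, N50(break) %s, %d contigs\n",
                b$min_coverage, b$pct_n,
                format(b$n50_break, big.mark = ","), b$n_contigs))
  cat(sprintf("  variants: %d stage-1, %d stage-2, Ts/Tv %.2f\n",
              x$variants$n_stage1, x$variants$n_stage2,
              x$variants$spectrum_stage1$tstv))
  invisible(x)
}

#' Side-by-side comparison of pipeline reports
#'
#' @param reports named list of at least two `pipeline_report` objects (or
#'   threshold blocks sharing metric keys).
#' @return data.frame, one row per metric, one column per report; %N rows
#'   allow checking the monotone increase of ambiguity with the coverage
#'   threshold across assemblies.
#' @export
compare_assemblies <- function(reports) {
  if (length(reports) < 2)
    stop("at least two reports are required for a comparison")
  if (is.null(names(reports)))
    names(reports) <- paste0("report", seq_along(reports))
  metrics <- function(r) {
    if (inherits(r, "pipeline_report")) {
      out <- unlist(lapply(r$thresholds, function(b)
        setNames(c(b$pct_n, b$n50_no_break, b$n50_break, b$n_contigs,
                   b$total_length),
                 paste0(c("pct_n_", "n50_no_break_", "n50_break_",
                          "n_contigs_", "total_length_"),
                        b$min_coverage, "x"))))
      c(out, n_variants_stage1 = r$variants$n_stage1,
        n_variants_stage2 = r$variants$n_stage2,
        tstv = r$variants$spectrum_stage1$tstv)
    } else unlist(r)
  }
  cols <- lapply(reports, metrics)
  keys <- names(cols[[1]])
  for (i in seq_along(cols)) {
    missing <- setdiff(keys, names(cols[[i]]))
    extra <- setdiff(names(cols[[i]]), keys)
    if (length(missing) || length(extra))
      stop("reports do not share metric keys; missing: ",
           paste(c(missing, extra), collapse = ", "))
  }
  out <- data.frame(metric = keys, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]][keys])
  out
}
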