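#' Read-mapping parameters
#'
#' The mapping contract: reads are anchored by exact seed matches of
#' `seed_length` bases and extended by banded edit alignment with unit costs
#' (match 0, mismatch `mismatch_cost`, insertion `insertion_cost`, deletion
#' `deletion_cost`; band = `band_fraction` of the read length, at least 6).
#' An alignment is reported only when the aligned read fraction is at least
#' `length_fraction` and the identity within the aligned region (matches /
#' aligned columns, indel columns counting as non-matches) is at least
#' `similarity_fraction`.  Reads whose minimal cost is achieved at more
#' than one accepted locus are flagged non-specific rather than placed
#' arbitrarily.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive integer unit
#'   costs.
#' @param length_fraction,similarity_fraction acceptance fractions in (0,1].
#' @param seed_length exact-match anchor length in bases.
#' @param band_fraction alignment band as a fraction of read length.
#' @param max_hits_per_seed seeds occurring more often than this in the
#'   reference are skipped (repeat protection).
#' @param max_candidates candidate loci examined per read and strand.
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(mismatch_cost = 2L, insertion_cost = 3L,
                           deletion_cost = 3L, length_fraction = 0.5,
                           similarity_fraction = 0.8, seed_length = 15L,
                           band_fraction = 0.1, max_hits_per_seed = 64L,
                           max_candidates = 24L) {
  p <- list(mismatch_cost = as.integer(mismatch_cost),
            insertion_cost = as.integer(insertion_cost),
            deletion_cost = as.integer(deletion_cost),
            length_fraction = length_fraction,
            similarity_fraction = similarity_fraction,
            seed_length = as.integer(seed_length),
            band_fraction = band_fraction,
            max_hits_per_seed = as.integer(max_hits_per_seed),
            max_candidates = as.integer(max_candidates))
  stopifnot(p$mismatch_cost > 0, p$insertion_cost > 0, p$deletion_cost > 0,
            p$length_fraction > 0, p$length_fraction <= 1,
            p$similarity_fraction > 0, p$similarity_fraction <= 1,
            p$seed_length >= 4)
  class(p) <- "mapping_params"
  p
}

#' Map reads against a reference
#'
#' Maps single-end reads (a character vector) or a paired `read_set` against
#' one reference sequence.  For pairs, the insert-size distribution is
#' estimated from the first 10,000 forward/reverse-oriented pairs and pairs
#' outside mean +/- 4 sd (or in the wrong orientation) are flagged broken.
#'
#' @param reads character vector of read sequences, or a `read_set`.
#' @param ref reference ([genome_sequence()] or character scalar).
#' @param params a [mapping_params()].
#' @param quals optional quality strings (single-end only); defaults to
#'   maximum quality.
#' @return a data.frame of class `refguide_alignments`, one row per read:
#'   `qname`, `mapped`, `pos` (1-based), `strand`, `cigar`, `cost`,
#'   `matches`, `cols`, `identity`, `frac_aligned`, `nonspecific`, `seq`,
#'   `qual`, and for paired input `mate` (1/2) and `proper`.  The reference
#'   name/length and the estimated insert distribution are attached as
#'   attributes.
#' @export
map_reads <- function(reads, ref, params = mapping_params(), quals = NULL) {
  refseq <- toupper(as_sequence(ref))
  if (nchar(refseq) == 0) stop("empty reference")
  refname <- if (inherits(ref, "genome_sequence")) ref$name else "ref"

  paired <- inherits(reads, "read_set")
  if (paired) {
    seqs <- c(reads$r1, reads$r2)
    n <- length(reads$r1)
    qdefault <- reads$qual
    qs <- c(if (is.null(reads$qual1)) rep(qdefault, n) else reads$qual1,
            if (is.null(reads$qual2)) rep(qdefault, n) else reads$qual2)
    qnames <- c(reads$names, reads$names)
    mate <- rep(1:2, each = n)
  } else {
    seqs <- as.character(reads)
    qs <- if (is.null(quals))
      vapply(nchar(seqs), function(k) strrep("I", k), character(1))
    else quals
    qnames <- if (!is.null(names(seqs))) names(seqs)
      else sprintf("read%07d", seq_along(seqs))
    mate <- rep(NA_integer_, length(seqs))
  }
  seqs <- toupper(seqs)

  res <- map_batch_cpp(refseq, seqs, params$seed_length,
                       params$band_fraction, params$mismatch_cost,
                       params$insertion_cost, params$deletion_cost,
                       params$length_fraction, params$similarity_fraction,
                       params$max_hits_per_seed, params$max_candidates)
  aln <- data.frame(qname = qnames, mate = mate,
                    mapped = res$mapped, pos = res$pos,
                    strand = as.character(res$strand),
                    cigar = as.character(res$cigar), cost = res$cost,
                    matches = res$matches, cols = res$cols,
                    identity = res$identity,
                    frac_aligned = res$frac_aligned,
                    nonspecific = res$nonspecific,
                    seq = seqs, qual = qs, stringsAsFactors = FALSE)

  ins_est <- c(mean = NA_real_, sd = NA_real_)
  if (paired) {
    n <- length(reads$r1)
    i1 <- seq_len(n); i2 <- n + i1
    span <- function(i) {
      w <- ref_span(aln$cigar[i])
      aln$pos[i] + w - 1L
    }
    ok <- aln$mapped[i1] & aln$mapped[i2] & aln$strand[i1] != aln$strand[i2]
    left <- ifelse(aln$strand[i1] == "+", i1, i2)
    right <- ifelse(aln$strand[i1] == "+", i2, i1)
    fr <- ok & aln$pos[left] <= aln$pos[right]
    insert <- rep(NA_real_, n)
    insert[fr] <- span(right[fr]) - aln$pos[left][fr] + 1
    est_set <- head(which(fr), 10000L)
    if (length(est_set) >= 2) {
      ins_est <- c(mean = mean(insert[est_set]), sd = sd(insert[est_set]))
      tol <- max(4 * ins_est["sd"], 10)
      proper <- fr & !is.na(insert) &
        abs(insert - ins_est["mean"]) <= tol
    } else {
      proper <- fr
    }
    aln$proper <- c(proper, proper)
    aln$insert <- c(insert, insert)
  }

  structure(aln, class = c("refguide_alignments", "data.frame"),
            ref_name = refname, ref_length = nchar(refseq),
            paired = paired, insert_est = ins_est)
}

# reference bases consumed by a CIGAR string
ref_span <- function(cigar) {
  cigar[is.na(cigar)] <- ""
  ref_span_cpp(cigar)
}

#' Build a per-position pileup from alignments
#'
#' Reduces accepted alignments to strand-resolved base counts, insertion and
#' deletion evidence, and per-base quality sums over every reference
#' position.  Non-specific alignments and broken pairs are excluded by
#' default, as variant calling ignores them.
#'
#' @param aln alignments from [map_reads()] or [read_alignment_file()].
#' @param ref_length reference length; taken from `aln` if absent.
#' @param include_nonspecific,include_broken include alignments flagged
#'   non-specific / pairs flagged broken.
#' @return an object of class `refguide_pileup`: strand-resolved 4 x L count
#'   matrices, deletion and insertion evidence vectors, a 4 x L quality-sum
#'   matrix, and a table of observed indel alleles.
#' @export
build_pileup <- function(aln, ref_length = attr(aln, "ref_length"),
                         include_nonspecific = FALSE,
                         include_broken = FALSE) {
  if (is.null(ref_length)) stop("ref_length must be provided")
  use <- aln$mapped
  if (!include_nonspecific) use <- use & !aln$nonspecific
  if (!is.null(aln$proper) && !include_broken)
    use <- use & !is.na(aln$proper) & aln$proper
  res <- pileup_cpp(as.integer(ref_length), aln$pos, aln$cigar, aln$seq,
                    aln$qual, aln$strand == "-", use)
  structure(list(ref_name = attr(aln, "ref_name"),
                 ref_length = as.integer(ref_length),
                 counts_fwd = res$counts_fwd, counts_rev = res$counts_rev,
                 del = res$del, ins = res$ins, qual_sum = res$qual_sum,
                 indels = res$indels, n_used = sum(use)),
            class = "refguide_pileup")
}

#' @export
print.refguide_pileup <- function(x, ...) {
  d <- pileup_depth(x)
  cat(sprintf("refguide_pileup over %s bp (%d alignments): mean depth %.2f\n",
              format(x$ref_length, big.mark = ","), x$n_used, mean(d)))
  invisible(x)
}

#' Total depth per reference position
#'
#' Depth is the sum of base counts on both strands plus deletion evidence.
#'
#' @param pileup a `refguide_pileup`.
#' @return integer vector of length `ref_length`.
#' @export
pileup_depth <- function(pileup) {
  colSums(pileup$counts_fwd) + colSums(pileup$counts_rev) + pileup$del
}

#' Write alignments as a SAM file
#'
#' Minimal text alignments: flags encode strand/pairing, MAPQ is 0 for
#' non-specific and 60 otherwise, SEQ is reverse-complemented for
#' minus-strand records.
#'
#' @param aln alignments from [map_reads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  refname <- attr(aln, "ref_name")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", refname,
                       attr(aln, "ref_length"))), con)
  paired <- isTRUE(attr(aln, "paired"))
  flag <- integer(nrow(aln))
  if (paired) {
    flag <- flag + 1L +
      ifelse(!is.na(aln$proper) & aln$proper, 2L, 0L) +
      ifelse(aln$mate == 1L, 64L, 128L)
  }
  flag <- flag + ifelse(aln$mapped, 0L, 4L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L)
  seqout <- aln$seq
  qualout <- aln$qual
  minus <- aln$mapped & aln$strand == "-"
  seqout[minus] <- revcomp(seqout[minus])
  qualout[minus] <- vapply(strsplit(qualout[minus], ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   aln$qname, flag,
                   ifelse(aln$mapped, refname, "*"),
                   ifelse(aln$mapped, aln$pos, 0L),
                   ifelse(aln$mapped, ifelse(aln$nonspecific, 0L, 60L), 0L),
                   ifelse(aln$mapped, aln$cigar, "*"),
                   seqout, qualout)
  writeLines(lines, con)
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' Ingests externally produced alignments through Rsamtools and converts
#' them to the package's alignment table.  MAPQ 0 is interpreted as
#' non-specific; flag bit 0x2 as a proper pair.
#'
#' @param path SAM (text) or BAM file with header.
#' @return a `refguide_alignments` data.frame, as from [map_reads()].
#' @export
read_alignment_file <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignment_file() requires the Rsamtools package")
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("failed to parse alignment file '", path,
                             "': ", conditionMessage(e)))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (!length(hdr$targets))
    stop("alignment file '", path, "' has no sequence header")
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(b$qname)) {
    empty <- data.frame(qname = character(), mate = integer(),
                        mapped = logical(), pos = integer(),
                        strand = character(), cigar = character(),
                        cost = integer(), matches = integer(),
                        cols = integer(), identity = numeric(),
                        frac_aligned = numeric(), nonspecific = logical(),
                        seq = character(), qual = character(),
                        stringsAsFactors = FALSE)
    return(structure(empty,
                     class = c("refguide_alignments", "data.frame"),
                     ref_name = names(hdr$targets)[1],
                     ref_length = unname(hdr$targets[1]), paired = FALSE,
                     insert_est = c(mean = NA_real_, sd = NA_real_)))
  }
  mapped <- !bitwAnd(b$flag, 4L)
  minus <- bitwAnd(b$flag, 16L) > 0
  paired <- bitwAnd(b$flag, 1L) > 0
  proper <- bitwAnd(b$flag, 2L) > 0
  seqs <- as.character(b$seq)
  quals <- as.character(b$qual)
  # convert minus-strand records back to original read orientation
  seqs[mapped & minus] <- revcomp(seqs[mapped & minus])
  quals[mapped & minus] <- vapply(strsplit(quals[mapped & minus], ""),
                                  function(ch) paste(rev(ch), collapse = ""),
                                  character(1))
  aln <- data.frame(qname = b$qname,
                    mate = ifelse(paired, ifelse(bitwAnd(b$flag, 64L) > 0,
                                                 1L, 2L), NA_integer_),
                    mapped = mapped,
                    pos = ifelse(mapped, b$pos, 0L),
                    strand = ifelse(minus, "-", "+"),
                    cigar = ifelse(mapped, b$cigar, ""),
                    cost = NA_integer_, matches = NA_integer_,
                    cols = NA_integer_, identity = NA_real_,
                    frac_aligned = NA_real_,
                    nonspecific = mapped & b$mapq == 0L,
                    seq = seqs, qual = quals, stringsAsFactors = FALSE)
  if (any(paired)) aln$proper <- proper
  structure(aln, class = c("refguide_alignments", "data.frame"),
            ref_name = names(hdr$targets)[1],
            ref_length = unname(hdr$targets[1]),
            paired = any(paired),
            insert_est = c(mean = NA_real_, sd = NA_real_))
}
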