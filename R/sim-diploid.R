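#' Derive a diverged diploid target genome from a reference
#'
#' Produces the two haplotypes of a target individual whose species diverged
#' from the reference species, together with a ground-truth record of every
#' planted event.  In order:
#'
#' 1. Repeat-library elements and perfect SSR loci are planted by
#'    overwriting reference-length intervals (coordinates are preserved, so
#'    all truth positions are reference coordinates).
#' 2. Shared divergence substitutions (transition/transversion odds =
#'    `tstv_ratio`) and shared indels are applied to both haplotypes.
#' 3. Heterozygous events (SNV, MNV, insertion, deletion, replacement per
#'    `het_class_mix`) are planted between the haplotypes; haplotype A
#'    carries `allele_a` (the shared target base) and haplotype B `allele_b`.
#'
#' Planted features are protected from subsequent mutation, and no two
#' events overlap, so every truth record is verifiable against the emitted
#' haplotypes by direct string comparison.  Indels shift haplotype
#' coordinates; `truth$liftover_a` / `liftover_b` map reference positions to
#' haplotype offsets.
#'
#' @param ref a [genome_sequence()] (the reference).
#' @param config a [simulation_config()].
#' @return list with elements `hap_a`, `hap_b` ([genome_sequence()] objects)
#'   and `truth` (class `simulation_truth`: data.frames `divergence_sites`,
#'   `het_sites`, `planted_ssrs`, `repeat_intervals`, `shared_indels`,
#'   liftover tables, and the repeat library used).
#' @export
derive_target_diploid <- function(ref, config) {
  validate_simulation_config(config)
  seqc <- as_sequence(ref)
  L <- nchar(seqc)
  if (L == 0) stop("reference must be non-empty")

  with_stage_seed(config$seed, 2L, {
    base <- charToRaw(seqc)
    occupied <- logical(L)
    thr <- c(`2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

    place_interval <- function(len, margin = 0L) {
      for (try in 1:200) {
        s <- sample.int(L - len + 1L, 1L)
        lo <- max(1L, s - margin); hi <- min(L, s + len - 1L + margin)
        if (!any(occupied[lo:hi])) return(s)
      }
      stop("could not place a feature of length ", len,
           " without overlap after 200 tries")
    }

    ## --- repeat library -------------------------------------------------
    lib <- config$repeat_library
    if (is.null(lib)) {
      lib <- data.frame(
        seq = vapply(1:2, function(i) random_bases(400L, 0.5), character(1)),
        copies = c(10L, 10L), stringsAsFactors = FALSE)
    }
    rep_start <- integer(); rep_end <- integer(); rep_el <- integer()
    if (nrow(lib)) {
      for (e in seq_len(nrow(lib))) {
        el <- charToRaw(lib$seq[e]); len <- length(el)
        for (cp in seq_len(lib$copies[e])) {
          s <- place_interval(len)
          base[s:(s + len - 1L)] <- el
          occupied[s:(s + len - 1L)] <- TRUE
          rep_start <- c(rep_start, s); rep_end <- c(rep_end, s + len - 1L)
          rep_el <- c(rep_el, e)
        }
      }
    }

    ## --- SSR loci --------------------------------------------------------
    is_primitive <- function(motif) {
      m <- nchar(motif)
      for (d in seq_len(m - 1)) {
        if (m %% d == 0 &&
            motif == paste(rep(substr(motif, 1, d), m / d), collapse = ""))
          return(FALSE)
      }
      TRUE
    }
    ssr_pos <- integer(); ssr_motif <- character(); ssr_rep <- integer()
    for (m in 2:6) {
      dens <- config$ssr_densities[[as.character(m)]]
      n_loci <- round(dens * L / 1e6)
      for (k in seq_len(n_loci)) {
        repeat {
          motif <- paste(sample(.BASES, m, replace = TRUE), collapse = "")
          if (is_primitive(motif)) break
        }
        count <- thr[[as.character(m)]] + rgeom(1, 0.5)
        len <- m * count
        s <- place_interval(len, margin = 1L)
        tandem <- charToRaw(paste(rep(motif, count), collapse = ""))
        base[s:(s + len - 1L)] <- tandem
        # guard flanks so the planted run is maximal exactly as recorded
        mraw <- charToRaw(motif)
        if (s > 1) {
          forb <- mraw[m]
          base[s - 1L] <- sample(.BASE_RAW[.BASE_RAW != forb], 1L)
        }
        e <- s + len - 1L
        if (e < L) {
          forb <- mraw[1]
          base[e + 1L] <- sample(.BASE_RAW[.BASE_RAW != forb], 1L)
        }
        occupied[max(1L, s - 1L):min(L, e + 1L)] <- TRUE
        ssr_pos <- c(ssr_pos, s); ssr_motif <- c(ssr_motif, motif)
        ssr_rep <- c(ssr_rep, count)
      }
    }

    ## --- shared divergence substitutions --------------------------------
    mutate_bases <- function(bases) {
      # substitute with transition odds tstv_ratio : 1
      n <- length(bases)
      ts <- runif(n) < config$tstv_ratio / (config$tstv_ratio + 1)
      tv_first <- runif(n) < 0.5
      out <- character(n)
      tv1 <- c(A = "C", G = "C", C = "A", T = "A")
      tv2 <- c(A = "T", G = "T", C = "G", T = "G")
      out[ts] <- .TRANSITION[bases[ts]]
      out[!ts & tv_first] <- tv1[bases[!ts & tv_first]]
      out[!ts & !tv_first] <- tv2[bases[!ts & !tv_first]]
      unname(out)
    }

    div_idx <- which(runif(L) < config$divergence_rate & !occupied)
    div_ref <- strsplit(rawToChar(base[div_idx]), "")[[1]]
    if (length(div_idx) == 0) div_ref <- character(0)
    div_alt <- mutate_bases(div_ref)
    if (length(div_idx)) {
      base[div_idx] <- charToRaw(paste(div_alt, collapse = ""))
      occupied[div_idx] <- TRUE
    }

    ## --- shared indels ---------------------------------------------------
    geo_p <- config$indel_length_geometric_p
    ind_pos <- integer(); ind_type <- character(); ind_len <- integer()
    ind_seq <- character()
    for (p in which(runif(L) < config$indel_rate & !occupied)) {
      len <- min(50L, 1L + rgeom(1, geo_p))
      if (runif(1) < 0.5) {  # deletion of base[p .. p+len-1]
        if (p + len - 1L > L || any(occupied[p:(p + len - 1L)])) next
        occupied[p:(p + len - 1L)] <- TRUE
        ind_pos <- c(ind_pos, p); ind_type <- c(ind_type, "del")
        ind_len <- c(ind_len, len); ind_seq <- c(ind_seq, "")
      } else {               # insertion after base[p]
        if (occupied[p]) next
        occupied[p] <- TRUE
        ind_pos <- c(ind_pos, p); ind_type <- c(ind_type, "ins")
        ind_len <- c(ind_len, len)
        ind_seq <- c(ind_seq, random_bases(len, 0.5))
      }
    }

    ## --- heterozygous events ---------------------------------------------
    het_pos <- integer(); het_class <- character()
    het_a <- character(); het_b <- character()
    classes <- names(config$het_class_mix)
    cand <- which(runif(L) < config$heterozygosity & !occupied)
    cls <- sample(classes, length(cand), replace = TRUE,
                  prob = config$het_class_mix)
    for (i in seq_along(cand)) {
      p <- cand[i]
      if (occupied[p]) next
      cl <- cls[i]
      if (cl == "SNV") {
        a <- rawToChar(base[p])
        b <- mutate_bases(a)
        occupied[p] <- TRUE
      } else if (cl == "MNV") {
        if (p + 1L > L || occupied[p + 1L]) next
        a <- rawToChar(base[p:(p + 1L)])
        ach <- strsplit(a, "")[[1]]
        b <- paste(mutate_bases(ach), collapse = "")
        occupied[p:(p + 1L)] <- TRUE
      } else if (cl == "deletion") {
        len <- min(20L, 1L + rgeom(1, geo_p))
        if (p + len - 1L > L || any(occupied[p:(p + len - 1L)])) next
        a <- rawToChar(base[p:(p + len - 1L)])
        b <- ""
        occupied[p:(p + len - 1L)] <- TRUE
      } else if (cl == "insertion") {
        a <- ""
        b <- random_bases(min(20L, 1L + rgeom(1, geo_p)), 0.5)
        occupied[p] <- TRUE
      } else {  # replacement: k1 reference bases -> k2 != k1 new bases
        k1 <- min(10L, 1L + rgeom(1, geo_p))
        k2 <- k1 + sample(c(-1L, 1L), 1L)
        if (k2 < 1L) k2 <- k1 + 1L
        if (p + k1 - 1L > L || any(occupied[p:(p + k1 - 1L)])) next
        a <- rawToChar(base[p:(p + k1 - 1L)])
        b <- random_bases(k2, 0.5)
        occupied[p:(p + k1 - 1L)] <- TRUE
      }
      het_pos <- c(het_pos, p); het_class <- c(het_class, cl)
      het_a <- c(het_a, a); het_b <- c(het_b, b)
    }

    ## --- assemble haplotypes ---------------------------------------------
    # events are encoded as (cut, del_len, ins_seq): the haplotype keeps
    # base[cursor .. cut-1], inserts ins_seq, and resumes at cut + del_len
    shared_ev <- data.frame(
      cut = ifelse(ind_type == "del", ind_pos, ind_pos + 1L),
      del_len = ifelse(ind_type == "del", ind_len, 0L),
      ins_seq = ind_seq, stringsAsFactors = FALSE)

    hetB_structural <- het_class %in% c("deletion", "insertion", "replacement")
    hb <- which(hetB_structural)
    hetB_ev <- data.frame(
      cut = ifelse(het_class[hb] == "insertion", het_pos[hb] + 1L,
                   het_pos[hb]),
      del_len = ifelse(het_class[hb] == "insertion", 0L,
                       nchar(het_a[hb])),
      ins_seq = ifelse(het_class[hb] == "deletion", "", het_b[hb]),
      stringsAsFactors = FALSE)

    # haplotype B also differs by substitution-type het events
    baseB <- base
    subs <- which(het_class %in% c("SNV", "MNV"))
    for (i in subs) {
      b <- charToRaw(het_b[i])
      baseB[het_pos[i]:(het_pos[i] + length(b) - 1L)] <- b
    }

    assemble <- function(raw, events) {
      if (!nrow(events)) return(rawToChar(raw))
      events <- events[order(events$cut), , drop = FALSE]
      pieces <- character(2L * nrow(events) + 1L)
      cursor <- 1L
      k <- 0L
      for (i in seq_len(nrow(events))) {
        cut <- events$cut[i]
        if (cut > cursor) {
          k <- k + 1L
          pieces[k] <- rawToChar(raw[cursor:(cut - 1L)])
        }
        if (nzchar(events$ins_seq[i])) {
          k <- k + 1L
          pieces[k] <- events$ins_seq[i]
        }
        cursor <- cut + events$del_len[i]
      }
      if (cursor <= length(raw)) {
        k <- k + 1L
        pieces[k] <- rawToChar(raw[cursor:length(raw)])
      }
      paste(pieces[seq_len(k)], collapse = "")
    }

    liftover <- function(events) {
      if (!nrow(events))
        return(data.frame(ref_pos = integer(), shift = integer()))
      events <- events[order(events$cut), , drop = FALSE]
      data.frame(ref_pos = events$cut,
                 shift = cumsum(nchar(events$ins_seq) - events$del_len))
    }

    evA <- shared_ev
    evB <- rbind(shared_ev, hetB_ev)
    seq_a <- assemble(base, evA)
    seq_b <- assemble(baseB, evB)
    lift_a <- liftover(evA)
    lift_b <- liftover(evB)

    shift_at <- function(lift, pos) {
      if (!nrow(lift)) return(rep(0L, length(pos)))
      i <- findInterval(pos, lift$ref_pos)
      ifelse(i == 0L, 0L, lift$shift[pmax(i, 1L)])
    }

    feat_ann <- function(lift) {
      n_ssr <- length(ssr_pos)
      df <- data.frame(
        start = c(ssr_pos + shift_at(lift, ssr_pos - 1L),
                  rep_start + shift_at(lift, rep_start - 1L)),
        end = c(ssr_pos + nchar(ssr_motif) * ssr_rep - 1L +
                  shift_at(lift, ssr_pos - 1L),
                rep_end + shift_at(lift, rep_start - 1L)),
        kind = c(rep("ssr", n_ssr), rep("repeat", length(rep_start))),
        payload = c(ssr_motif, as.character(rep_el)),
        stringsAsFactors = FALSE)
      df
    }

    truth <- structure(list(
      divergence_sites = data.frame(pos = div_idx, ref_base = div_ref,
                                    target_base = div_alt,
                                    stringsAsFactors = FALSE),
      het_sites = data.frame(pos = het_pos, class = het_class,
                             allele_a = het_a, allele_b = het_b,
                             stringsAsFactors = FALSE),
      planted_ssrs = data.frame(pos = ssr_pos, motif = ssr_motif,
                                repeats = ssr_rep,
                                stringsAsFactors = FALSE),
      repeat_intervals = data.frame(start = rep_start, end = rep_end,
                                    element = rep_el),
      shared_indels = data.frame(pos = ind_pos, type = ind_type,
                                 len = ind_len, seq = ind_seq,
                                 stringsAsFactors = FALSE),
      liftover_a = lift_a, liftover_b = lift_b,
      repeat_library = lib), class = "simulation_truth")

    list(hap_a = genome_sequence("hap_a", seq_a, feat_ann(lift_a)),
         hap_b = genome_sequence("hap_b", seq_b, feat_ann(lift_b)),
         truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(paste0("simulation_truth: %d divergence substitutions, ",
                     "%d shared indels, %d het sites, %d SSR loci, ",
                     "%d repeat copies\n"),
              nrow(x$divergence_sites), nrow(x$shared_indels),
              nrow(x$het_sites), nrow(x$planted_ssrs),
              nrow(x$repeat_intervals)))
  invisible(x)
}

#' Map reference positions to haplotype coordinates
#'
#' Applies the cumulative indel offsets recorded in the simulation truth to
#' translate 1-based reference positions into coordinates on a haplotype.
#' Positions inside deleted segments have no image and return NA.
#'
#' @param truth a `simulation_truth`.
#' @param pos integer vector of reference positions (1-based).
#' @param hap `"a"` or `"b"`.
#' @return integer vector of haplotype positions (NA where deleted).
#' @export
liftover_positions <- function(truth, pos, hap = c("a", "b")) {
  hap <- match.arg(hap)
  lift <- if (hap == "a") truth$liftover_a else truth$liftover_b
  if (!nrow(lift)) return(as.integer(pos))
  i <- findInterval(pos, lift$ref_pos)
  shift <- ifelse(i == 0L, 0L, lift$shift[pmax(i, 1L)])
  out <- as.integer(pos + shift)
  # positions consumed by a deletion have no haplotype image
  prev_shift <- ifelse(i <= 1L, 0L, lift$shift[pmax(i - 1L, 1L)])
  del_span <- ifelse(i == 0L, 0L, prev_shift - shift)
  inside_del <- i > 0L & pos < lift$ref_pos[pmax(i, 1L)] +
    pmax(del_span, 0L)
  out[inside_del] <- NA_integer_
  out
}
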