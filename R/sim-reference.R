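#' Simulate a reference genome with block-wise GC structure
#'
#' The genome is a concatenation of fixed-length blocks; within each block
#' bases are drawn i.i.d. at a GC level sampled from
#' `config$isochore_gc_levels`.  This emulates the large-scale regional
#' heterogeneity in nucleotide composition (isochore structure) of amniote
#' genomes, against which windowed GC statistics are later tested.
#'
#' @param config a [simulation_config()].
#' @return a [genome_sequence()] named "ref" with one `isochore_block`
#'   annotation per block (payload = the block's GC level).
#' @export
simulate_reference <- function(config) {
  validate_simulation_config(config)
  L <- config$genome_length
  if (L <= 0) stop("genome_length must be positive")
  bl <- config$isochore_block_length
  with_stage_seed(config$seed, 1L, {
    n_blocks <- ceiling(L / bl)
    block_gc <- sample(config$isochore_gc_levels, n_blocks, replace = TRUE)
    gc_per_base <- rep(block_gc, each = bl)[seq_len(L)]
    seq <- random_bases(L, gc_per_base)
    starts <- (seq_len(n_blocks) - 1L) * bl + 1L
    ann <- data.frame(start = starts,
                      end = pmin(starts + bl - 1L, L),
                      kind = "isochore_block",
                      payload = as.character(block_gc))
    genome_sequence("ref", seq, ann)
  })
}
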