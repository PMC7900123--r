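# Synthetic genome generation: random scaffolds with planted N gaps and a
# callability mask.

#' Generate a synthetic genome with N gaps
#'
#' Scaffolds are uniform random A/C/G/T sequence; each scaffold receives a
#' Poisson-distributed number of N runs (expected `n_gap_rate`) with lengths
#' uniform in `n_gap_len`, placed away from scaffold edges and from each
#' other. The callability mask is the complement of the N runs; its total
#' width is the effective (callable) genome length used downstream as the
#' variant-rate denominator.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome`: `genome` (named `DNAStringSet`),
#'   `mask` (`GRanges` of callable intervals), `seqlens`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 202L)
  n <- as.integer(config$n_scaffolds)
  len <- as.integer(config$scaffold_length)
  names_scf <- sprintf("scf_%02d", seq_len(n))
  seqs <- character(n)
  gap_list <- list()
  for (i in seq_len(n)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    n_gaps <- stats::rpois(1L, config$n_gap_rate)
    gaps <- IRanges::IRanges()
    tries <- 0L
    while (length(gaps) < n_gaps && tries < 200L) {
      tries <- tries + 1L
      glen <- as.integer(round(runif(1, config$n_gap_len[1L],
                                     config$n_gap_len[2L])))
      gstart <- as.integer(sample.int(len - glen - 200L, 1L)) + 100L
      cand <- IRanges::IRanges(gstart, gstart + glen - 1L)
      if (length(gaps) == 0L ||
          !any(IRanges::overlapsAny(cand + 10L, gaps))) {
        gaps <- c(gaps, cand)
      }
    }
    gaps <- gaps[order(IRanges::start(gaps))]
    if (length(gaps)) {
      for (j in seq_along(gaps)) {
        substr(s, IRanges::start(gaps)[j], IRanges::end(gaps)[j]) <-
          strrep("N", IRanges::width(gaps)[j])
      }
    }
    seqs[i] <- s
    gap_list[[names_scf[i]]] <- gaps
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, names_scf))
  seqlens <- stats::setNames(rep(len, n), names_scf)
  callable <- lapply(names_scf, function(nm) {
    IRanges::setdiff(IRanges::IRanges(1L, len), gap_list[[nm]])
  })
  mask <- GenomicRanges::GRanges(
    rep(names_scf, vapply(callable, length, integer(1))),
    do.call(c, callable),
    seqinfo = GenomeInfoDb::Seqinfo(names_scf, unname(seqlens)))
  structure(list(genome = genome, mask = mask, seqlens = seqlens),
            class = "sim_genome")
}

#' Effective (callable) length of a mask
#' @param mask `GRanges` of callable intervals.
#' @export
effective_length <- function(mask) {
  sum(as.numeric(GenomicRanges::width(mask)))
}
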