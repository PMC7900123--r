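# Assembly contiguity statistics and k-mer-spectrum genome-size estimation.

#' Break scaffolds into contigs at long N runs
#'
#' Splits each scaffold at runs of `N` (case-insensitive) of length at least
#' `min_n_run`; shorter N runs are retained inside a contig. This is the usual
#' convention for deriving contig statistics from a scaffolded assembly.
#'
#' @param sequences A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a path to a FASTA file.
#' @param min_n_run Minimum N-run length that breaks a contig (default 10).
#' @return Integer vector of contig lengths, in input order, left to right.
#'   Ambiguity codes other than N count as ordinary bases.
#' @export
#' @examples
#' break_scaffolds(c(s1 = paste0("ACGT", strrep("N", 10), "ACGT")))
break_scaffolds <- function(sequences, min_n_run = 10L) {
  if (min_n_run < 1) stop_config("min_n_run must be >= 1")
  seqs <- as_sequence_characters(sequences)
  if (length(seqs) == 0L) return(integer(0))
  out <- lapply(seqs, function(s) {
    s <- toupper(s)
    len <- nchar(s)
    if (len == 0L) return(integer(0))
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) return(len)
    starts <- as.integer(m)
    widths <- attr(m, "match.length")
    keep <- widths >= min_n_run
    starts <- starts[keep]
    widths <- widths[keep]
    if (length(starts) == 0L) return(len)
    # contigs are the gaps between breaking N runs
    contig_start <- c(1L, starts + widths)
    contig_end <- c(starts - 1L, len)
    w <- contig_end - contig_start + 1L
    w[w > 0L]
  })
  as.integer(unlist(out, use.names = FALSE))
}

as_sequence_characters <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    return(as.character(sequences))
  }
  if (is.character(sequences) && length(sequences) == 1L &&
      nchar(sequences) < 1000L && file.exists(sequences)) {
    return(as.character(Biostrings::readDNAStringSet(sequences)))
  }
  if (is.character(sequences)) return(sequences)
  stop_config("unsupported sequence input of class %s", class(sequences)[1L])
}

#' Contiguity statistics (Nx/Lx) for a set of sequence lengths
#'
#' Nx is the length of the sequence at which the cumulative sum of lengths,
#' taken in descending order, first reaches x percent of the total; Lx is the
#' number of sequences needed to reach it. The boundary is inclusive: if the
#' cumulative sum hits exactly x percent at a sequence, that sequence's length
#' is Nx.
#'
#' @param lengths Positive sequence lengths (bp).
#' @param n_bp Number of N bases in the underlying assembly (for `pct_n`).
#' @param ambiguous_bp Number of non-ACGTN bases (tallied, not interpreted).
#' @return An object of class `contiguity_stats`: a list with `n_sequences`,
#'   `total_bp`, `n_bp`, `pct_n`, `N50`, `N90`, `L50`, `L90`, `min_length`,
#'   `max_length`, `mean_length`.
#' @export
#' @examples
#' contiguity_stats(c(10, 9, 8, 7, 6))  # N50 = 8, L50 = 3
contiguity_stats <- function(lengths, n_bp = 0L, ambiguous_bp = 0L) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop_config("lengths must be non-empty")
  if (any(lengths <= 0)) stop_config("all lengths must be > 0")
  srt <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(srt)
  total <- cum[length(cum)]
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[1L]
    list(N = srt[i], L = i)
  }
  s50 <- nx(50)
  s90 <- nx(90)
  structure(list(
    n_sequences = length(lengths),
    total_bp = total,
    n_bp = as.numeric(n_bp),
    ambiguous_bp = as.numeric(ambiguous_bp),
    pct_n = 100 * as.numeric(n_bp) / total,
    N50 = s50$N, L50 = s50$L,
    N90 = s90$N, L90 = s90$L,
    min_length = min(lengths),
    max_length = max(lengths),
    mean_length = mean(lengths)
  ), class = "contiguity_stats")
}

#' @export
print.contiguity_stats <- function(x, ...) {
  cat(sprintf(
    "%d sequences, %.0f bp total (%.2f%% N)\nN50 %.0f (L50 %d)  N90 %.0f (L90 %d)\nmin/mean/max %.0f / %.1f / %.0f\n",
    x$n_sequences, x$total_bp, x$pct_n, x$N50, x$L50, x$N90, x$L90,
    x$min_length, x$mean_length, x$max_length))
  invisible(x)
}

#' Scaffold- and contig-level assembly statistics
#'
#' Computes contiguity statistics for the scaffolds as given and for the
#' contigs obtained by breaking at N runs of length `break_at_n` or more.
#'
#' @param sequences As in [break_scaffolds()].
#' @param break_at_n N-run length at which scaffolds are broken (default 10).
#' @return List with elements `scaffolds` and `contigs`, each a
#'   `contiguity_stats` object.
#' @export
assembly_stats <- function(sequences, break_at_n = 10L) {
  seqs <- toupper(as_sequence_characters(sequences))
  if (length(seqs) == 0L) stop_config("no sequences")
  lens <- nchar(seqs)
  n_bp <- sum(vapply(seqs, function(s) {
    lengths <- attr(gregexpr("N+", s)[[1L]], "match.length")
    if (identical(lengths, -1L)) 0L else sum(lengths)
  }, integer(1)))
  amb <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  contig_lens <- break_scaffolds(seqs, min_n_run = break_at_n)
  list(
    scaffolds = contiguity_stats(lens, n_bp = n_bp, ambiguous_bp = amb),
    contigs = contiguity_stats(contig_lens, n_bp = 0L, ambiguous_bp = amb)
  )
}

#' Genome-size estimate from a k-mer multiplicity spectrum
#'
#' Uses the standard peak method: the haploid genome size is the total number
#' of k-mer observations above the error region divided by the depth of the
#' spectrum's main peak. The low-depth error spike (sequencing errors produce
#' a large mass of singleton k-mers) is skipped by only considering depths at
#' or above `min_depth_for_peak`.
#'
#' @param hist Data frame with columns `depth` (strictly increasing positive
#'   integers) and `count` (number of distinct k-mers seen at that depth).
#' @param min_depth_for_peak Smallest depth eligible to be the main peak.
#' @return List with `estimate` (bp) and `peak_depth`.
#' @export
estimate_genome_size <- function(hist, min_depth_for_peak = 4L) {
  stopifnot(is.data.frame(hist), all(c("depth", "count") %in% names(hist)))
  d <- as.numeric(hist$depth)
  cnt <- as.numeric(hist$count)
  if (any(diff(d) <= 0)) stop_config("depths must be strictly increasing")
  if (any(cnt < 0)) stop_config("counts must be >= 0")
  eligible <- which(d >= min_depth_for_peak)
  if (length(eligible) == 0L) {
    stop_config("no histogram entries at depth >= %d", min_depth_for_peak)
  }
  i_peak <- eligible[which.max(cnt[eligible])]
  # require a genuine local maximum, not the shoulder of the error spike
  left_higher <- i_peak > 1L && cnt[i_peak - 1L] > cnt[i_peak]
  right_higher <- i_peak < length(d) && cnt[i_peak + 1L] > cnt[i_peak]
  if (left_higher || right_higher) {
    stop_config(paste0(
      "no coverage peak found at depth >= %d (spectrum is monotone there); ",
      "raise min_depth_for_peak or inspect the histogram"), min_depth_for_peak)
  }
  peak_depth <- d[i_peak]
  keep <- d >= min_depth_for_peak
  estimate <- sum(d[keep] * cnt[keep]) / peak_depth
  list(estimate = estimate, peak_depth = peak_depth)
}
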