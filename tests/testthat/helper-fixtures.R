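# Shared fixtures: a small simulated bundle (memoised across test files) and
# a hand-built gene-model fixture with known window coordinates.

small_sim_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, scaffold_length = 40000L,
             n_genes = 25L, n_go_terms = 20L, dag_depth = 3L,
             n_enriched_genes = 10L, ...)
}

.fixtures <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- simulate_bundle(small_sim_config())
  }
  .fixtures$bundle
}

shared_bundle_dir <- function() {
  if (is.null(.fixtures$bundle_dir)) {
    dir <- file.path(tempdir(), "crossvar-shared-bundle")
    write_bundle(shared_bundle(), dir)
    .fixtures$bundle_dir <- dir
  }
  .fixtures$bundle_dir
}

shared_index <- function() {
  if (is.null(.fixtures$index)) {
    b <- shared_bundle()
    .fixtures$index <- build_region_index(b$models, b$seqlens)
  }
  .fixtures$index
}

# Hand-built two-gene fixture on one 30 kbp scaffold:
#   gene_plus:  TSS at 10,000 (+), two exons 10,000-10,999 / 11,101-12,100,
#               intron 11,000-11,100 (1-based), CDS 10,050-10,999 + 11,101-11,250
#   gene_minus: TSS at 20,000 (-), single exon 19,001-20,000, CDS 19,101-19,900
hand_models <- function() {
  genes <- data.frame(
    gene_id = c("gP", "gM"),
    scaffold = "s1",
    start = c(10000L, 19001L), end = c(12100L, 20000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("tP", "tM"), gene_id = c("gP", "gM"),
    scaffold = "s1",
    start = c(10000L, 19001L), end = c(12100L, 20000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("tP", "tP", "tM"),
    start = c(10000L, 11101L, 19001L),
    end = c(10999L, 12100L, 20000L), stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("tP", "tP", "tM"),
    start = c(10050L, 11101L, 19101L),
    end = c(10999L, 11250L, 19900L), stringsAsFactors = FALSE)
  list(genes = genes, transcripts = transcripts, exons = exons, cds = cds)
}

hand_seqlens <- function() c(s1 = 30000L)

# Mirror a gene-model fixture: reverse-complement coordinates and flip
# strands on a scaffold of length L.
mirror_models <- function(models, L) {
  flip <- function(df) {
    new_start <- L - df$end + 1L
    new_end <- L - df$start + 1L
    df$start <- new_start
    df$end <- new_end
    if (!is.null(df$strand)) {
      df$strand <- ifelse(df$strand == "+", "-", "+")
    }
    df
  }
  lapply(models, flip)
}

# Per-position painter: fills a class vector per scaffold by painting region
# rows from lowest to highest severity so the highest-severity label wins.
# Independent of the GRanges set arithmetic used by genome_coverage().
paint_regions <- function(index) {
  regions <- index$regions
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions), end = GenomicRanges::end(regions),
    class = regions$class, stringsAsFactors = FALSE)
  out <- lapply(names(index$seqlens), function(scf) {
    v <- rep("INTERGENIC", index$seqlens[[scf]])
    for (cl in rev(setdiff(REGION_CLASSES, "INTERGENIC"))) {
      rows <- df[df$scaffold == scf & df$class == cl, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        v[rows$start[i]:rows$end[i]] <- cl
      }
    }
    v
  })
  names(out) <- names(index$seqlens)
  out
}

# Exhaustive hypergeometric over-representation tail by direct enumeration.
hyper_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Quadratic brute-force sharing comparator for small variants.
brute_sharing <- function(intra, inter) {
  lab_one <- function(scaffold, pos, alts, other, unique_label) {
    found_same <- FALSE
    found_any <- FALSE
    for (j in seq_len(nrow(other))) {
      if (other$scaffold[j] == scaffold && other$pos[j] == pos) {
        found_any <- TRUE
        if (length(intersect(alts, other$alts[[j]]))) found_same <- TRUE
      }
    }
    if (found_same) "IDENTICAL"
    else if (found_any) "NONIDENTICAL"
    else unique_label
  }
  ia <- index_by_position(intra)
  ib <- index_by_position(inter)
  la <- vapply(seq_len(nrow(ia)), function(i)
    lab_one(ia$scaffold[i], ia$pos[i], ia$alts[[i]], ib, "UNIQUE_INTRA"),
    character(1))
  lb <- vapply(seq_len(nrow(ib)), function(i)
    lab_one(ib$scaffold[i], ib$pos[i], ib$alts[[i]], ia, "UNIQUE_INTER"),
    character(1))
  list(intra = la, inter = lb)
}

# Sort-and-scan contiguity oracle.
nx_oracle <- function(lengths, x) {
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  acc <- 0
  for (i in seq_along(srt)) {
    acc <- acc + srt[i]
    if (acc >= x / 100 * total) return(list(N = srt[i], L = i))
  }
}
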