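# Synthetic gene models: multi-exon, both strands, valid ORFs spliced into
# the genome, plus gene -> GO annotations.

#' Generate synthetic gene models and GO annotations
#'
#' Places `n_genes` non-overlapping multi-exon genes on the genome (both
#' strands), rewrites the genome so every CDS starts with ATG, ends with a
#' stop codon, has length divisible by 3 and no internal stop, and assigns
#' GO terms: a configurable fraction of genes receives none (excluded from
#' the enrichment universe), the rest draw 1-3 terms biased towards deeper
#' ontology terms. Planted enrichment terms get a fixed-size member set.
#'
#' @param sim_genome A [generate_genome()] result (the genome is modified
#'   and returned).
#' @param dag The [generate_ontology()] DAG.
#' @param config A [sim_config()].
#' @return List of class `sim_genes`: `models` (list with `genes`,
#'   `transcripts`, `exons`, `cds` data frames), `genome` (rewritten
#'   `DNAStringSet`), `gene2go` (named list), `enriched` (data frame
#'   `term`, `multiplier`, and member genes as attribute), `enriched_genes`.
#' @export
generate_gene_models <- function(sim_genome, dag, config) {
  validate_sim_config(config)
  set.seed(config$seed + 303L)
  chars <- as.character(sim_genome$genome)
  seqlens <- sim_genome$seqlens
  n_genes <- as.integer(config$n_genes)
  margin <- 7500L  # keep full flank + promoter windows on-scaffold

  gaps_by_scf <- lapply(names(seqlens), function(nm) {
    m <- sim_genome$mask[GenomeInfoDb::seqnames(sim_genome$mask) == nm]
    IRanges::setdiff(IRanges::IRanges(1L, seqlens[[nm]]),
                     IRanges::ranges(m))
  })
  names(gaps_by_scf) <- names(seqlens)
  occupied <- lapply(seqlens, function(...) IRanges::IRanges())

  genes <- list(); txs <- list(); exons <- list(); cds_rows <- list()
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene_%04d", g)
    txid <- sprintf("tx_%04d", g)
    n_ex <- sample(config$exons_per_gene[1L]:config$exons_per_gene[2L], 1L)
    # CDS split over exons; each CDS chunk a positive multiple of 1 bp,
    # total divisible by 3
    n_codons <- sample(40:120, 1L)
    cds_len <- 3L * n_codons
    cuts <- sort(sample_from(seq_len(cds_len - 1L), n_ex - 1L))
    chunk <- diff(c(0L, cuts, cds_len))
    # pad chunks to the mean exon length by resampling tiny chunks
    chunk <- pmax(chunk, 20L)
    cds_len <- sum(chunk)
    cds_len <- cds_len + (3L - cds_len %% 3L) %% 3L
    chunk[n_ex] <- chunk[n_ex] + cds_len - sum(chunk)
    n_codons <- cds_len %/% 3L
    utr5 <- sample(config$utr_len[1L]:config$utr_len[2L], 1L)
    utr3 <- sample(config$utr_len[1L]:config$utr_len[2L], 1L)
    introns <- if (n_ex > 1L) {
      pmax(50L, as.integer(round(stats::rexp(n_ex - 1L,
                                             1 / config$mean_intron_len))))
    } else integer(0)
    # exon lengths in transcription order; genomic order mirrors them on the
    # minus strand
    tx_exon_len <- chunk
    tx_exon_len[1L] <- tx_exon_len[1L] + utr5
    tx_exon_len[n_ex] <- tx_exon_len[n_ex] + utr3
    span <- sum(tx_exon_len) + sum(introns)

    # placement with rejection: within scaffold margins, clear of N gaps and
    # other gene bodies (plus a small spacer)
    placed <- FALSE
    for (attempt in seq_len(300L)) {
      scf <- sample_from(names(seqlens), 1L)
      max_start <- seqlens[[scf]] - margin - span
      if (max_start <= margin) next
      gstart <- margin + sample.int(max_start - margin, 1L)
      body <- IRanges::IRanges(gstart, gstart + span - 1L)
      if (IRanges::overlapsAny(body, gaps_by_scf[[scf]])) next
      if (IRanges::overlapsAny(body + 100L, occupied[[scf]])) next
      occupied[[scf]] <- c(occupied[[scf]], body)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop_config("genome too small for %d genes (placed %d)", n_genes, g - 1L)
    }
    strand <- if (runif(1) < config$strand_fraction) "-" else "+"
    exon_len <- if (strand == "+") tx_exon_len else rev(tx_exon_len)

    # genomic exon coordinates, ascending
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    posn <- gstart
    for (j in seq_len(n_ex)) {
      ex_start[j] <- posn
      ex_end[j] <- posn + exon_len[j] - 1L
      posn <- ex_end[j] + 1L + (if (j < n_ex) introns[j] else 0L)
    }
    gend <- ex_end[n_ex]

    # transcript sequence: UTR5 + CDS + UTR3 in transcription order
    cds_seq <- paste0("ATG",
                      paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                            collapse = ""),
                      sample_from(stops, 1L))
    stopifnot(nchar(cds_seq) == cds_len)
    tx_seq <- paste0(
      paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
      cds_seq,
      paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = ""))

    # write exon slices into the genome; exon order in transcription
    # direction is ascending (+) or descending (-) genomic
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    offset <- 0L
    for (j in ord) {
      piece <- substr(tx_seq, offset + 1L, offset + exon_len[j])
      offset <- offset + exon_len[j]
      if (strand == "-") {
        piece <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(piece)))
      }
      substr(chars[[scf]], ex_start[j], ex_end[j]) <- piece
    }

    # CDS genomic intervals: exon intervals minus the UTR portions
    if (strand == "+") {
      cds_start_g <- ex_start; cds_end_g <- ex_end
      cds_start_g[1L] <- ex_start[1L] + utr5
      cds_end_g[n_ex] <- ex_end[n_ex] - utr3
    } else {
      cds_start_g <- ex_start; cds_end_g <- ex_end
      cds_end_g[n_ex] <- ex_end[n_ex] - utr5
      cds_start_g[1L] <- ex_start[1L] + utr3
    }
    keep <- cds_end_g >= cds_start_g
    # phase: transcription-order cumulative CDS length before each piece
    tord <- if (strand == "+") which(keep) else rev(which(keep))
    w <- (cds_end_g - cds_start_g + 1L)[tord]
    phase <- (3L - (cumsum(c(0L, w))[seq_along(w)] %% 3L)) %% 3L
    phase_by_idx <- stats::setNames(phase, tord)

    genes[[g]] <- data.frame(gene_id = gid, scaffold = scf,
                             start = gstart, end = gend, strand = strand,
                             stringsAsFactors = FALSE)
    txs[[g]] <- data.frame(transcript_id = txid, gene_id = gid,
                           scaffold = scf, start = gstart, end = gend,
                           strand = strand, stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(transcript_id = txid, scaffold = scf,
                             start = ex_start, end = ex_end, strand = strand,
                             stringsAsFactors = FALSE)
    cds_rows[[g]] <- data.frame(
      transcript_id = txid, scaffold = scf,
      start = cds_start_g[keep], end = cds_end_g[keep], strand = strand,
      phase = as.integer(phase_by_idx[as.character(which(keep))]),
      stringsAsFactors = FALSE)
  }

  models <- list(genes = do.call(rbind, genes),
                 transcripts = do.call(rbind, txs),
                 exons = do.call(rbind, exons),
                 cds = do.call(rbind, cds_rows))

  # GO annotation: bias the random term draw towards deeper terms; planted
  # enrichment terms are reserved so their membership is exactly the planted
  # gene set (an uncontaminated ground truth)
  gene_ids <- models$genes$gene_id
  n_annot <- round((1 - config$fraction_unannotated) * length(gene_ids))
  annotated <- gene_ids[seq_len(n_annot)]
  enriched <- config$enriched_terms
  if (is.null(enriched)) {
    leaf <- dag_leaves(dag)[1L]
    enriched <- data.frame(term = leaf,
                           multiplier = config$enrichment_multiplier,
                           stringsAsFactors = FALSE)
  }
  pool <- setdiff(dag$terms, enriched$term)
  if (length(pool) == 0L) pool <- dag$terms
  lv <- dag_levels(dag)
  term_weight <- lv[pool]^2
  gene2go <- stats::setNames(lapply(annotated, function(g) {
    k <- sample(config$terms_per_gene[1L]:config$terms_per_gene[2L], 1L)
    unique(sample_from(pool, min(k, length(pool)), prob = term_weight))
  }), annotated)
  enriched_genes <- list()
  for (i in seq_len(nrow(enriched))) {
    members <- sample_from(annotated,
                           min(config$n_enriched_genes, length(annotated)))
    for (g in members) {
      gene2go[[g]] <- unique(c(gene2go[[g]], enriched$term[i]))
    }
    enriched_genes[[enriched$term[i]]] <- members
  }

  structure(list(models = models, genome = Biostrings::DNAStringSet(chars),
                 gene2go = gene2go,
                 enriched = enriched, enriched_genes = enriched_genes),
            class = "sim_genes")
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS rows (1-based inclusive, phase set on CDS) via
#' the standard GFF3 exporter.
#'
#' @param models The `models` element of a [generate_gene_models()] result.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  mk <- function(df, type, id, parent, phase = NULL) {
    gr <- GenomicRanges::GRanges(
      df$scaffold, IRanges::IRanges(df$start, df$end),
      strand = df$strand %||% "*")
    gr$source <- "crossvar_sim"
    gr$type <- type
    gr$score <- NA_real_
    gr$phase <- if (!is.null(phase)) as.integer(phase) else NA_integer_
    gr$ID <- id
    gr$Parent <- parent
    gr
  }
  g <- mk(models$genes, "gene", id = models$genes$gene_id,
          parent = NA_character_)
  t <- mk(models$transcripts, "mRNA", id = models$transcripts$transcript_id,
          parent = models$transcripts$gene_id)
  e <- mk(models$exons, "exon",
          id = paste0(models$exons$transcript_id, ".exon",
                      seq_len(nrow(models$exons))),
          parent = models$exons$transcript_id)
  cds <- mk(models$cds, "CDS",
            id = paste0(models$cds$transcript_id, ".cds"),
            parent = models$cds$transcript_id,
            phase = models$cds$phase)
  all <- c(g, t, e, cds)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all),
                   match(all$type, c("gene", "mRNA", "exon", "CDS")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Write a gene -> GO map as two-column TSV
#' @param gene2go Named list gene -> terms.
#' @param path Output path.
#' @export
write_gene2go <- function(gene2go, path) {
  df <- data.frame(gene = rep(names(gene2go), lengths(gene2go)),
                   term = unlist(gene2go, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
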