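# Functional-region model: promoter / UTR / CDS / splice / intron / flank /
# intergenic classification of the genome, genome-coverage fractions (GCOV)
# and interval lookup.

#' Region classes, in decreasing severity
#'
#' When a position or interval carries several labels, the single flattened
#' label is the highest-severity one in this order.
#' @export
REGION_CLASSES <- c("SPLICE", "CODING", "UTR5", "UTR3", "INTRON",
                    "PROMOTER", "UPSTREAM", "DOWNSTREAM", "INTERGENIC")

region_severity <- function(class) {
  match(class, REGION_CLASSES)
}

flatten_classes <- function(classes) {
  if (length(classes) == 0L) return("INTERGENIC")
  REGION_CLASSES[min(region_severity(classes))]
}

#' Region window configuration
#'
#' @param promoter_up Promoter extent upstream of the TSS, bp (default 2000).
#' @param promoter_down Promoter extent downstream of the TSS, bp (default
#'   200); these bases may fall inside the transcript, in which case they are
#'   labelled both PROMOTER and the transcript class.
#' @param gene_flank Up-/downstream flank beyond the gene body, bp (default
#'   5000). Also the window used for mutation-load counting.
#' @param splice_core Intronic bases at each end of every intron labelled
#'   SPLICE (default 2, the canonical donor/acceptor dinucleotides).
#' @return A list of class `region_config`.
#' @export
region_config <- function(promoter_up = 2000L, promoter_down = 200L,
                          gene_flank = 5000L, splice_core = 2L) {
  cfg <- list(promoter_up = as.integer(promoter_up),
              promoter_down = as.integer(promoter_down),
              gene_flank = as.integer(gene_flank),
              splice_core = as.integer(splice_core))
  if (any(unlist(cfg) < 0L)) stop_config("region_config values must be >= 0")
  class(cfg) <- "region_config"
  cfg
}

# Normalise gene models to flat feature tables. Accepts a GFF3 path, a GRanges
# imported from GFF3 (rtracklayer), or a gene_models list from the simulator.
normalize_gene_models <- function(gene_models) {
  if (is.list(gene_models) && !is.null(gene_models$exons) &&
      !is.null(gene_models$genes)) {
    return(gene_models[c("genes", "transcripts", "exons", "cds")])
  }
  if (is.character(gene_models) && length(gene_models) == 1L) {
    gene_models <- rtracklayer::import(gene_models, format = "gff3")
  }
  if (!methods::is(gene_models, "GRanges")) {
    stop_config("gene_models must be a GFF3 path, GRanges, or simulator models")
  }
  gr <- gene_models
  type <- as.character(gr$type)
  get_id <- function(x) as.character(x$ID)
  get_parent <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v)[1L] else NA_character_,
           character(1))
  }
  g <- gr[type == "gene"]
  tx <- gr[type %in% c("mRNA", "transcript")]
  ex <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  genes <- data.frame(
    gene_id = get_id(g),
    scaffold = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = get_id(tx),
    gene_id = get_parent(tx),
    scaffold = as.character(GenomicRanges::seqnames(tx)),
    start = GenomicRanges::start(tx), end = GenomicRanges::end(tx),
    strand = as.character(GenomicRanges::strand(tx)),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = get_parent(ex),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)
  cds_df <- data.frame(
    transcript_id = get_parent(cds),
    start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
    stringsAsFactors = FALSE)
  list(genes = genes, transcripts = transcripts, exons = exons, cds = cds_df)
}

#' Build the functional-region index from gene models
#'
#' Derives, per transcript, the promoter (orientation-aware TSS window),
#' 5'/3' UTRs, coding intervals, splice cores, introns, and the up-/downstream
#' flank windows beyond the gene body (the promoter takes precedence over the
#' upstream flank where the two windows would overlap). All windows are
#' clipped at scaffold edges. Transcripts without exons, CDS outside exons or
#' unknown strands are skipped with a warning and counted in `$rejects`.
#'
#' @param gene_models GFF3 path, imported GFF3 `GRanges`, or simulator models.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param config A [region_config()].
#' @return An object of class `region_index`: list with `regions` (a
#'   `GRanges` with columns `gene_id`, `transcript_id`, `class`), `genes`,
#'   `cds_by_tx` (per-transcript CDS layout for codon reconstruction),
#'   `seqlens`, `config`, `rejects`.
#' @export
build_region_index <- function(gene_models, scaffold_lengths,
                               config = region_config()) {
  models <- normalize_gene_models(gene_models)
  stopifnot(!is.null(names(scaffold_lengths)))
  seqlens <- scaffold_lengths

  # accumulate region rows as parallel vectors (fast append via lists)
  acc <- list(scaffold = list(), start = list(), end = list(),
              gene = list(), tx = list(), class = list())
  n_acc <- 0L
  cds_by_tx <- list()
  rejects <- character(0)
  add <- function(scaffold, start, end, gene, tx, class) {
    start <- max(1L, as.integer(start))
    end <- min(as.integer(seqlens[[scaffold]]), as.integer(end))
    if (end < start) return(invisible(NULL))
    n_acc <<- n_acc + 1L
    acc$scaffold[[n_acc]] <<- scaffold
    acc$start[[n_acc]] <<- start
    acc$end[[n_acc]] <<- end
    acc$gene[[n_acc]] <<- gene
    acc$tx[[n_acc]] <<- tx
    acc$class[[n_acc]] <<- class
    invisible(NULL)
  }

  txs <- models$transcripts
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    if (!tx$strand %in% c("+", "-")) {
      rejects <- c(rejects, sprintf("%s: unknown strand '%s'",
                                    tx$transcript_id, tx$strand))
      next
    }
    ex <- models$exons[models$exons$transcript_id == tx$transcript_id, ,
                       drop = FALSE]
    if (nrow(ex) == 0L) {
      rejects <- c(rejects, sprintf("%s: no exons", tx$transcript_id))
      next
    }
    cds <- models$cds[models$cds$transcript_id == tx$transcript_id, ,
                      drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(cds) > 0L) {
      exr <- IRanges::IRanges(ex$start, ex$end)
      cdsr <- IRanges::IRanges(cds$start, cds$end)
      outside <- IRanges::setdiff(cdsr, IRanges::intersect(cdsr, exr))
      if (sum(IRanges::width(outside)) > 0L) {
        rejects <- c(rejects, sprintf("%s: CDS outside exons", tx$transcript_id))
        next
      }
    }
    scaf <- tx$scaffold
    gene <- tx$gene_id
    txid <- tx$transcript_id
    plus <- tx$strand == "+"
    tss <- if (plus) tx$start else tx$end

    # promoter: orientation-aware TSS window
    if (plus) {
      add(scaf, tss - config$promoter_up,
                               tss + config$promoter_down - 1L,
                               gene, txid, "PROMOTER")
    } else {
      add(scaf, tss - config$promoter_down + 1L,
                               tss + config$promoter_up,
                               gene, txid, "PROMOTER")
    }

    # coding
    for (j in seq_len(nrow(cds))) {
      add(scaf, cds$start[j], cds$end[j],
                               gene, txid, "CODING")
    }

    # UTRs: exonic sequence outside the CDS span, split by orientation
    if (nrow(cds) > 0L) {
      cs <- min(cds$start); ce <- max(cds$end)
      exr <- IRanges::IRanges(ex$start, ex$end)
      left <- IRanges::restrict(exr, end = cs - 1L)
      right <- IRanges::restrict(exr, start = ce + 1L)
      left <- left[IRanges::width(left) > 0L]
      right <- right[IRanges::width(right) > 0L]
      left_class <- if (plus) "UTR5" else "UTR3"
      right_class <- if (plus) "UTR3" else "UTR5"
      for (j in seq_along(left)) {
        add(scaf, IRanges::start(left)[j],
                                 IRanges::end(left)[j], gene, txid, left_class)
      }
      for (j in seq_along(right)) {
        add(scaf, IRanges::start(right)[j],
                                 IRanges::end(right)[j], gene, txid, right_class)
      }
    }

    # introns and splice cores
    if (nrow(ex) > 1L) {
      for (j in seq_len(nrow(ex) - 1L)) {
        istart <- ex$end[j] + 1L
        iend <- ex$start[j + 1L] - 1L
        if (iend < istart) next
        ilen <- iend - istart + 1L
        core <- min(config$splice_core, ceiling(ilen / 2))
        if (core > 0L) {
          add(scaf, istart, istart + core - 1L,
                                   gene, txid, "SPLICE")
          add(scaf, iend - core + 1L, iend,
                                   gene, txid, "SPLICE")
        }
        if (ilen > 2L * core) {
          add(scaf, istart + core, iend - core,
                                   gene, txid, "INTRON")
        }
      }
    }

    # flanks beyond the gene body, minus the promoter on the TSS side
    gstart <- tx$start; gend <- tx$end
    if (plus) {
      up <- c(gstart - config$gene_flank, gstart - 1L)
      prom_lo <- tss - config$promoter_up
      up[2L] <- min(up[2L], prom_lo - 1L)
      add(scaf, up[1L], up[2L], gene, txid, "UPSTREAM")
      add(scaf, gend + 1L, gend + config$gene_flank,
                               gene, txid, "DOWNSTREAM")
    } else {
      up <- c(gend + 1L, gend + config$gene_flank)
      prom_hi <- tss + config$promoter_up
      up[1L] <- max(up[1L], prom_hi + 1L)
      add(scaf, up[1L], up[2L], gene, txid, "UPSTREAM")
      add(scaf, gstart - config$gene_flank, gstart - 1L,
                               gene, txid, "DOWNSTREAM")
    }


    # CDS layout in transcription order, for codon reconstruction
    if (nrow(cds) > 0L) {
      ord <- if (plus) order(cds$start) else order(-cds$start)
      cds_by_tx[[txid]] <- list(
        scaffold = scaf, strand = tx$strand, gene_id = gene,
        start = cds$start[ord], end = cds$end[ord])
    }
  }

  if (length(rejects)) {
    warning(sprintf("%d gene-model record(s) skipped: %s", length(rejects),
                    paste(utils::head(rejects, 3L), collapse = "; ")),
            call. = FALSE)
  }
  if (n_acc > 0L) {
    regions <- GenomicRanges::GRanges(
      seqnames = unlist(acc$scaffold, use.names = FALSE),
      ranges = IRanges::IRanges(unlist(acc$start, use.names = FALSE),
                                unlist(acc$end, use.names = FALSE)),
      gene_id = unlist(acc$gene, use.names = FALSE),
      transcript_id = unlist(acc$tx, use.names = FALSE),
      class = unlist(acc$class, use.names = FALSE),
      seqinfo = GenomeInfoDb::Seqinfo(names(seqlens), as.integer(seqlens)))
  } else {
    regions <- GenomicRanges::GRanges(
      seqinfo = GenomeInfoDb::Seqinfo(names(seqlens), as.integer(seqlens)))
    regions$gene_id <- character(0)
    regions$transcript_id <- character(0)
    regions$class <- character(0)
  }
  structure(list(regions = regions, genes = models$genes,
                 cds_by_tx = cds_by_tx, seqlens = seqlens,
                 config = config, rejects = rejects),
            class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("region_index: %d scaffolds (%.0f bp), %d genes, %d region rows\n",
              length(x$seqlens), sum(as.numeric(x$seqlens)),
              nrow(x$genes), length(x$regions)))
  invisible(x)
}

#' Genome coverage (GCOV) per region class
#'
#' Every genomic position is counted once under its highest-severity label;
#' positions under no label are INTERGENIC. Fractions are over the total
#' genome length and sum to 1.
#'
#' @param index A [build_region_index()] result.
#' @return Data frame of class `gcov_table` with columns `class`, `bp`,
#'   `fraction`, ordered by severity.
#' @export
genome_coverage <- function(index) {
  stopifnot(inherits(index, "region_index"))
  total <- sum(as.numeric(index$seqlens))
  taken <- GenomicRanges::GRanges(
    seqinfo = GenomeInfoDb::seqinfo(index$regions))
  bp <- stats::setNames(numeric(length(REGION_CLASSES)), REGION_CLASSES)
  for (cl in setdiff(REGION_CLASSES, "INTERGENIC")) {
    gr <- GenomicRanges::reduce(index$regions[index$regions$class == cl])
    new <- GenomicRanges::setdiff(gr, taken)
    bp[cl] <- sum(as.numeric(GenomicRanges::width(new)))
    taken <- GenomicRanges::reduce(GenomicRanges::union(taken, gr))
  }
  bp["INTERGENIC"] <- total - sum(bp)
  out <- data.frame(class = REGION_CLASSES, bp = as.numeric(bp),
                    fraction = as.numeric(bp) / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("gcov_table", "data.frame")
  out
}

#' Classify an interval against the region index
#'
#' Returns every (gene, class) pair the interval intersects plus the single
#' flattened class by severity (INTERGENIC when nothing overlaps). An interval
#' covering any splice-core base carries SPLICE among its labels.
#'
#' @param index A `region_index`.
#' @param scaffold Scaffold name.
#' @param start,end 1-based inclusive interval (point query: `end = start`).
#' @return List with `labels` (data frame `gene_id`, `transcript_id`,
#'   `class`) and `flattened` (single class).
#' @export
locate <- function(index, scaffold, start, end = start) {
  stopifnot(inherits(index, "region_index"))
  if (!scaffold %in% names(index$seqlens)) {
    stop_config("unknown scaffold '%s'", scaffold)
  }
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(index$regions)
  hits <- GenomicRanges::findOverlaps(q, index$regions)
  sub <- index$regions[S4Vectors::subjectHits(hits)]
  labels <- unique(data.frame(
    gene_id = sub$gene_id, transcript_id = sub$transcript_id,
    class = sub$class, stringsAsFactors = FALSE))
  list(labels = labels, flattened = flatten_classes(labels$class))
}

# Vectorised overlap of many query intervals with the index; returns one row
# per (query, gene, class) combination. Used by effect annotation and the
# distributions.
locate_many <- function(index, scaffold, start, end) {
  known <- scaffold %in% names(index$seqlens)
  if (!all(known)) {
    stop_config("unknown scaffold '%s'", scaffold[!known][1L])
  }
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(index$regions)
  hits <- GenomicRanges::findOverlaps(q, index$regions)
  sub <- index$regions[S4Vectors::subjectHits(hits)]
  unique(data.frame(
    query = S4Vectors::queryHits(hits),
    gene_id = sub$gene_id, transcript_id = sub$transcript_id,
    class = sub$class, stringsAsFactors = FALSE))
}

#' Export the flattened region partition as BED
#'
#' 0-based half-open intervals named by region class, one row per maximal run
#' of a single flattened class.
#'
#' @param index A `region_index`.
#' @param path Output BED path.
#' @export
export_region_bed <- function(index, path) {
  taken <- GenomicRanges::GRanges(
    seqinfo = GenomeInfoDb::seqinfo(index$regions))
  out <- list()
  for (cl in setdiff(REGION_CLASSES, "INTERGENIC")) {
    gr <- GenomicRanges::reduce(index$regions[index$regions$class == cl])
    new <- GenomicRanges::setdiff(gr, taken)
    if (length(new)) {
      new$name <- cl
      out[[cl]] <- new
    }
    taken <- GenomicRanges::reduce(GenomicRanges::union(taken, gr))
  }
  whole <- GenomicRanges::GRanges(
    names(index$seqlens), IRanges::IRanges(1L, as.integer(index$seqlens)))
  inter <- GenomicRanges::setdiff(whole, taken)
  if (length(inter)) {
    inter$name <- "INTERGENIC"
    out[["INTERGENIC"]] <- inter
  }
  all <- sort(do.call(c, unname(out)))
  rtracklayer::export(all, path, format = "bed")
  invisible(path)
}
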