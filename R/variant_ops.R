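# Variant reading, filtering, typing, effect annotation and summaries.

#' Variant filter configuration
#'
#' Post-calling inclusion filters: small variants need a phred-scaled quality
#' of at least `min_qual`; structural variants need at least
#' `min_support_pairs` broken read pairs, and deletions, inversions and
#' duplications additionally a length of at least `min_sv_len` (translocations
#' and insertions are exempt from the length rule).
#'
#' @param min_qual Minimum QUAL for small variants (default 30).
#' @param min_support_pairs Minimum supporting read pairs for SVs (default 5).
#' @param min_sv_len Minimum SV length for DEL/INV/DUP (default 300).
#' @export
filter_config <- function(min_qual = 30, min_support_pairs = 5L,
                          min_sv_len = 300L) {
  cfg <- list(min_qual = min_qual,
              min_support_pairs = as.integer(min_support_pairs),
              min_sv_len = as.integer(min_sv_len))
  if (any(unlist(cfg) < 0)) stop_config("filter_config values must be >= 0")
  class(cfg) <- "filter_config"
  cfg
}

#' Classify a small-variant allele pair
#'
#' Single-base substitutions are SNPs; a longer alt is an INS, a shorter one a
#' DEL (left-anchored convention). Equal-length multi-base pairs (MNPs) are
#' decomposed into one SNP per mismatching base for counting.
#'
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of types (length > 1 only for MNPs).
#' @export
#' @examples
#' classify_smv("A", "T")   # SNP
#' classify_smv("A", "AT")  # INS
#' classify_smv("AT", "A")  # DEL
classify_smv <- function(ref, alt) {
  stopifnot(nzchar(ref), nzchar(alt))
  if (grepl("[][<>]", alt)) {
    stop_config("symbolic or breakend alt '%s' is not a small variant", alt)
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SNP")
  if (na > nr) return("INS")
  if (na < nr) return("DEL")
  # MNP: per-base decomposition
  rb <- strsplit(ref, "")[[1L]]
  ab <- strsplit(alt, "")[[1L]]
  rep("SNP", sum(rb != ab))
}

#' Read and filter a small-variant VCF
#'
#' Keeps records with `QUAL >= min_qual`; records with missing QUAL are
#' dropped and logged in the report. Multi-allelic records are expanded to one
#' row per alternate allele but keep their record identity.
#'
#' @param path VCF path.
#' @param cfg A [filter_config()].
#' @return List with `variants` (data frame: `record`, `scaffold`, `pos`,
#'   `ref`, `alt`, `qual`, `type`, `multiallelic`) and `report`
#'   (`n_read`, `kept`, `dropped`, `dropped_missing_qual`).
#' @export
read_and_filter_smv <- function(path, cfg = filter_config()) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_read <- length(rr)
  if (n_read == 0L) {
    return(list(variants = empty_smv_frame(),
                report = list(n_read = 0L, kept = 0L, dropped = 0L,
                              dropped_missing_qual = 0L)))
  }
  qual <- rr$QUAL
  missing_q <- is.na(qual)
  keep <- !missing_q & qual >= cfg$min_qual
  report <- list(n_read = n_read, kept = sum(keep),
                 dropped = sum(!keep),
                 dropped_missing_qual = sum(missing_q))
  rr <- rr[keep]
  if (length(rr) == 0L) {
    return(list(variants = empty_smv_frame(), report = report))
  }
  alts <- VariantAnnotation::alt(vcf)[keep]
  n_alt <- S4Vectors::elementNROWS(alts)
  idx <- rep(seq_along(rr), n_alt)
  df <- data.frame(
    record = names(rr)[idx] %||% as.character(idx),
    scaffold = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(rr$REF)[idx],
    alt = as.character(unlist(alts)),
    qual = as.numeric(rr$QUAL)[idx],
    multiallelic = (n_alt > 1L)[idx],
    stringsAsFactors = FALSE)
  df$type <- vapply(seq_len(nrow(df)), function(i) {
    t <- classify_smv(df$ref[i], df$alt[i])
    if (length(t) == 1L) t else "MNP"
  }, character(1))
  list(variants = df, report = report)
}

empty_smv_frame <- function() {
  data.frame(record = character(0), scaffold = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             qual = numeric(0), multiallelic = logical(0),
             type = character(0), stringsAsFactors = FALSE)
}

empty_sv_frame <- function() {
  data.frame(id = character(0), scaffold = character(0), start = integer(0),
             end = integer(0), svtype = character(0), support = integer(0),
             length = numeric(0), scaffold2 = character(0), pos2 = integer(0),
             stringsAsFactors = FALSE)
}

#' Read and filter a structural-variant VCF
#'
#' Requires INFO fields `SVTYPE` and `PE` (supporting read-pair count); `END`
#' for intervals and `MATEID` for breakend pairs. Breakend (BND) mate pairs
#' are collapsed to a single translocation (TRA) event anchored at the
#' lexicographically first mate. Records with unknown SVTYPE are skipped with
#' a warning.
#'
#' @inheritParams read_and_filter_smv
#' @return List with `variants` (data frame: `id`, `scaffold`, `start`,
#'   `end`, `svtype`, `support`, `length`, `scaffold2`, `pos2`) and `report`.
#' @export
read_and_filter_sv <- function(path, cfg = filter_config()) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n_read <- length(rr)
  if (n_read == 0L) {
    return(list(variants = empty_sv_frame(),
                report = list(n_read = 0L, n_events = 0L, kept = 0L,
                              dropped = 0L, skipped_unknown_type = 0L)))
  }
  svtype <- as.character(info$SVTYPE)
  known <- svtype %in% c("DEL", "DUP", "INV", "INS", "TRA", "BND")
  if (any(!known)) {
    warning(sprintf("%d SV record(s) with unknown SVTYPE skipped", sum(!known)),
            call. = FALSE)
  }
  df <- data.frame(
    id = names(rr) %||% as.character(seq_along(rr)),
    scaffold = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr),
    end = if (!is.null(info$END)) as.integer(info$END) else GenomicRanges::start(rr),
    svtype = svtype,
    support = as.integer(info$PE),
    mateid = if (!is.null(info$MATEID)) {
      vapply(as.list(info$MATEID), function(v)
        if (length(v)) as.character(v)[1L] else NA_character_, character(1))
    } else NA_character_,
    chr2 = if (!is.null(info$CHR2)) as.character(info$CHR2) else NA_character_,
    stringsAsFactors = FALSE)
  df <- df[known, , drop = FALSE]

  # collapse BND mate pairs into one TRA event
  bnd <- df[df$svtype == "BND", , drop = FALSE]
  rest <- df[df$svtype != "BND", , drop = FALSE]
  events <- list()
  if (nrow(bnd) > 0L) {
    seen <- character(0)
    for (i in seq_len(nrow(bnd))) {
      if (bnd$id[i] %in% seen) next
      mate_i <- match(bnd$mateid[i], bnd$id)
      if (!is.na(mate_i)) seen <- c(seen, bnd$id[mate_i])
      seen <- c(seen, bnd$id[i])
      events[[length(events) + 1L]] <- data.frame(
        id = bnd$id[i], scaffold = bnd$scaffold[i], start = bnd$start[i],
        end = bnd$start[i], svtype = "TRA", support = bnd$support[i],
        length = NA_real_,
        scaffold2 = if (!is.na(mate_i)) bnd$scaffold[mate_i] else bnd$chr2[i],
        pos2 = if (!is.na(mate_i)) bnd$start[mate_i] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(rest) > 0L) {
    rest$length <- ifelse(rest$svtype %in% c("DEL", "DUP", "INV"),
                          rest$end - rest$start + 1, NA_real_)
    rest$scaffold2 <- NA_character_
    rest$pos2 <- NA_integer_
    rest$mateid <- NULL
    rest$chr2 <- NULL
    events <- c(events, list(rest))
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_sv_frame()
  n_events <- nrow(ev)
  if (n_events > 0L) {
    pass_support <- ev$support >= cfg$min_support_pairs
    needs_len <- ev$svtype %in% c("DEL", "INV", "DUP")
    pass_len <- !needs_len | (!is.na(ev$length) & ev$length >= cfg$min_sv_len)
    keep <- pass_support & pass_len
  } else {
    keep <- logical(0)
  }
  list(variants = ev[keep, , drop = FALSE],
       report = list(n_read = n_read, n_events = n_events,
                     kept = sum(keep), dropped = sum(!keep),
                     skipped_unknown_type = sum(!known)))
}

#' Predict variant effects per overlapped gene
#'
#' Each variant contributes one effect per gene whose region model it
#' intersects (and a single intergenic MODIFIER effect when it intersects no
#' gene). For coding SNPs, the affected codon is rebuilt in transcript
#' orientation (reverse-complemented on the minus strand) and translated with
#' the standard genetic code: a gained stop is NONSENSE (HIGH), an amino-acid
#' change MISSENSE (MODERATE), a synonymous change SILENT (LOW). Any overlap
#' of a splice-core base is HIGH. Coding InDels are HIGH when frameshifting
#' (length difference not divisible by 3), MODERATE otherwise; their
#' consequence is reported as NONE and excluded from the coding-change
#' denominator. Everything else is MODIFIER.
#'
#' @param smv Small-variant data frame from [read_and_filter_smv()] (or NULL).
#' @param sv Structural-variant data frame from [read_and_filter_sv()] (or
#'   NULL).
#' @param index A [build_region_index()] result.
#' @param genome Named `DNAStringSet` matching the index (needed for coding
#'   SNP consequences; the variant REF is checked against it).
#' @return Data frame with one row per (variant, gene): `variant_id`,
#'   `variant_class` (SMV/SV), `type`, `scaffold`, `pos`, `gene_id`,
#'   `labels` (comma-collapsed classes for that gene), `region` (flattened),
#'   `impact`, `coding_consequence`.
#' @export
annotate_effects <- function(smv = NULL, sv = NULL, index, genome = NULL) {
  stopifnot(inherits(index, "region_index"))
  out <- list()
  if (!is.null(smv) && nrow(smv) > 0L) {
    end <- smv$pos + pmax(nchar(smv$ref) - 1L, 0L)
    out[[length(out) + 1L]] <- effects_for(
      index, genome,
      id = paste0(smv$record, ":", smv$alt),
      class = "SMV", type = smv$type,
      scaffold = smv$scaffold, start = smv$pos, end = end,
      ref = smv$ref, alt = smv$alt)
  }
  if (!is.null(sv) && nrow(sv) > 0L) {
    out[[length(out) + 1L]] <- effects_for(
      index, genome,
      id = sv$id, class = "SV", type = sv$svtype,
      scaffold = sv$scaffold, start = sv$start,
      end = ifelse(is.na(sv$end), sv$start, sv$end),
      ref = NA_character_, alt = NA_character_)
  }
  if (length(out) == 0L) {
    return(data.frame(variant_id = character(0), variant_class = character(0),
                      type = character(0), scaffold = character(0),
                      pos = integer(0), gene_id = character(0),
                      labels = character(0), region = character(0),
                      impact = character(0), coding_consequence = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

effects_for <- function(index, genome, id, class, type, scaffold, start, end,
                        ref, alt) {
  hits <- locate_many(index, scaffold, start, end)
  chars <- if (!is.null(genome)) {
    if (inherits(genome, "DNAStringSet")) as.character(genome) else genome
  } else NULL

  # grouped per (variant, gene) aggregation
  if (nrow(hits) > 0L) {
    key <- paste(hits$query, hits$gene_id, sep = "\r")
    grp <- split(seq_len(nrow(hits)), key)
    q_i <- vapply(grp, function(ix) hits$query[ix[1L]], numeric(1))
    g_i <- vapply(grp, function(ix) hits$gene_id[ix[1L]], character(1))
    labels <- vapply(grp, function(ix)
      paste(sort(unique(hits$class[ix])), collapse = ","), character(1))
    flat <- vapply(grp, function(ix)
      flatten_classes(hits$class[ix]), character(1))
    has_coding <- vapply(grp, function(ix)
      "CODING" %in% hits$class[ix], logical(1))
    has_splice <- vapply(grp, function(ix)
      "SPLICE" %in% hits$class[ix], logical(1))
    tx_coding <- vapply(grp, function(ix) {
      c_ix <- ix[hits$class[ix] == "CODING"]
      if (length(c_ix)) hits$transcript_id[c_ix[1L]] else NA_character_
    }, character(1))
  } else {
    q_i <- numeric(0); g_i <- character(0); labels <- character(0)
    flat <- character(0); has_coding <- logical(0); has_splice <- logical(0)
    tx_coding <- character(0)
  }

  consequence <- rep("NONE", length(q_i))
  impact <- rep("MODIFIER", length(q_i))
  vclass_snp <- class == "SMV" & type[q_i] == "SNP"
  vclass_indel <- class == "SMV" & type[q_i] %in% c("INS", "DEL")
  cod_snp <- which(has_coding & vclass_snp)
  for (k in cod_snp) {
    i <- q_i[k]
    consequence[k] <- coding_snp_consequence(index, chars, tx_coding[k],
                                             scaffold[i], start[i],
                                             ref[i], alt[i])
    impact[k] <- switch(consequence[k],
                        NONSENSE = "HIGH", MISSENSE = "MODERATE",
                        SILENT = "LOW", "MODIFIER")
  }
  cod_indel <- has_coding & vclass_indel
  if (any(cod_indel)) {
    shift <- abs(nchar(alt[q_i]) - nchar(ref[q_i]))
    impact[cod_indel] <- ifelse(shift[cod_indel] %% 3L != 0L,
                                "HIGH", "MODERATE")
  }
  impact[has_splice] <- "HIGH"

  genic <- data.frame(
    variant_id = id[q_i], variant_class = class, type = type[q_i],
    scaffold = scaffold[q_i], pos = start[q_i], gene_id = g_i,
    labels = unname(labels), region = unname(flat), impact = impact,
    coding_consequence = consequence, stringsAsFactors = FALSE)

  no_hit <- setdiff(seq_along(id), unique(q_i))
  if (length(no_hit)) {
    inter <- data.frame(
      variant_id = id[no_hit], variant_class = class, type = type[no_hit],
      scaffold = scaffold[no_hit], pos = start[no_hit],
      gene_id = NA_character_, labels = "INTERGENIC", region = "INTERGENIC",
      impact = "MODIFIER", coding_consequence = "NONE",
      stringsAsFactors = FALSE)
    genic <- rbind(genic, inter)
  }
  rownames(genic) <- NULL
  genic
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Rebuild the codon containing a coding SNP and translate old vs new.
# `chars` is the genome as a named character vector.
coding_snp_consequence <- function(index, chars, txid, scaffold, pos,
                                   ref, alt) {
  if (is.null(chars)) return("NONE")
  layout <- index$cds_by_tx[[txid]]
  if (is.null(layout)) return("NONE")
  plus <- layout$strand == "+"
  # local (transcription-order) coordinate of pos within the CDS
  widths <- layout$end - layout$start + 1L
  offsets <- cumsum(c(0L, widths))[seq_along(widths)]
  local <- NA_integer_
  for (j in seq_along(widths)) {
    if (pos >= layout$start[j] && pos <= layout$end[j]) {
      local <- offsets[j] +
        (if (plus) pos - layout$start[j] else layout$end[j] - pos) + 1L
      break
    }
  }
  if (is.na(local)) return("NONE")
  seq <- chars[[scaffold]]
  genome_base <- substr(seq, pos, pos)
  if (!identical(toupper(genome_base), toupper(ref))) {
    stop_config("REF allele '%s' disagrees with genome base '%s' at %s:%d",
                ref, genome_base, scaffold, pos)
  }
  codon_idx <- (local - 1L) %/% 3L
  codon_pos <- (local - 1L) %% 3L + 1L
  # extract the codon's three transcript-order bases from the genome
  codon_local <- codon_idx * 3L + 1:3
  bases <- vapply(codon_local, function(l) {
    # map local coordinate back to genomic position
    j <- findInterval(l - 1L, offsets)
    within <- l - offsets[j] - 1L
    gpos <- if (plus) layout$start[j] + within else layout$end[j] - within
    b <- toupper(substr(seq, gpos, gpos))
    if (plus) b else unname(REV_COMP[b])
  }, character(1))
  alt_tx <- if (plus) toupper(alt) else unname(REV_COMP[toupper(alt)])
  old_codon <- paste(bases, collapse = "")
  new_bases <- bases
  new_bases[codon_pos] <- alt_tx
  new_codon <- paste(new_bases, collapse = "")
  code <- Biostrings::GENETIC_CODE
  old_aa <- unname(code[toupper(old_codon)])
  new_aa <- unname(code[toupper(new_codon)])
  if (is.na(old_aa) || is.na(new_aa)) return("NONE")
  if (new_aa == "*" && old_aa != "*") return("NONSENSE")
  if (new_aa == old_aa) return("SILENT")
  "MISSENSE"
}

#' Per-dataset variant summary
#'
#' Tallies processed records, multi-allelic records, per-type allele events,
#' and the variant rate in bases per variant, `floor(effective_length /
#' n_processed)` (truncated, matching how such rates are conventionally
#' printed).
#'
#' @param variants Small-variant data frame from [read_and_filter_smv()].
#' @param genome_total_length Total reference length, bp.
#' @param effective_length Callable (assessed) reference length, bp; the
#'   variant-rate denominator.
#' @return List of class `dataset_summary`.
#' @export
summarize_dataset <- function(variants, genome_total_length,
                              effective_length) {
  if (effective_length <= 0) stop_config("effective_length must be > 0")
  if (effective_length > genome_total_length) {
    stop_config("effective_length exceeds genome_total_length")
  }
  n_processed <- length(unique(variants$record))
  multi <- unique(variants[, c("record", "multiallelic")])
  type_events <- unlist(lapply(seq_len(nrow(variants)), function(i) {
    classify_smv(variants$ref[i], variants$alt[i])
  }))
  structure(list(
    n_processed = n_processed,
    n_multiallelic = sum(multi$multiallelic),
    n_snp = sum(type_events == "SNP"),
    n_ins = sum(type_events == "INS"),
    n_del = sum(type_events == "DEL"),
    genome_total_length = genome_total_length,
    effective_length = effective_length,
    rate_bases = variant_rate(n_processed, effective_length)
  ), class = "dataset_summary")
}

#' Variant rate in bases per variant
#'
#' `floor(effective_length / n_variants)`; `NA` for an empty variant set.
#'
#' @param n_variants Number of variant records.
#' @param effective_length Callable reference length, bp.
#' @export
#' @examples
#' variant_rate(4105604, 906396323)  # 220
variant_rate <- function(n_variants, effective_length) {
  if (n_variants == 0) return(NA_real_)
  floor(effective_length / n_variants)
}

#' Impact and coding-consequence distribution of annotated effects
#'
#' Percentages are per impact class over all effects, and per coding
#' consequence over NONSENSE + MISSENSE + SILENT only, rounded half-up to two
#' decimals.
#'
#' @param effects Either an effects data frame from [annotate_effects()], or
#'   a list with named numeric vectors `impact` (HIGH/MODERATE/LOW/MODIFIER
#'   counts) and `coding` (NONSENSE/MISSENSE/SILENT counts) to compute the
#'   distribution from pre-tabulated counts.
#' @return List of class `effect_distribution` with data frames `impact` and
#'   `coding` (`count`, `pct`).
#' @export
effect_distribution <- function(effects) {
  if (is.data.frame(effects)) {
    if (nrow(effects) == 0L) stop_config("no effects to summarise")
    impact_counts <- vapply(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                            function(k) sum(effects$impact == k), numeric(1))
    coding_counts <- vapply(c("NONSENSE", "MISSENSE", "SILENT"), function(k)
      sum(effects$coding_consequence == k), numeric(1))
  } else if (is.list(effects) && !is.null(effects$impact)) {
    impact_counts <- effects$impact[c("HIGH", "MODERATE", "LOW", "MODIFIER")]
    coding_counts <- (effects$coding %||%
                        c(NONSENSE = 0, MISSENSE = 0, SILENT = 0))[
                          c("NONSENSE", "MISSENSE", "SILENT")]
    names(impact_counts) <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
    names(coding_counts) <- c("NONSENSE", "MISSENSE", "SILENT")
    impact_counts[is.na(impact_counts)] <- 0
    coding_counts[is.na(coding_counts)] <- 0
  } else {
    stop_config("effects must be a data frame or list of counts")
  }
  if (sum(impact_counts) == 0) stop_config("no effects to summarise")
  impact <- data.frame(
    impact = names(impact_counts), count = as.numeric(impact_counts),
    pct = round_half_up(100 * impact_counts / sum(impact_counts), 2),
    row.names = NULL, stringsAsFactors = FALSE)
  coding_total <- sum(coding_counts)
  coding <- data.frame(
    consequence = names(coding_counts), count = as.numeric(coding_counts),
    pct = if (coding_total > 0)
      round_half_up(100 * coding_counts / coding_total, 2) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(impact = impact, coding = coding),
            class = "effect_distribution")
}

#' Variant location distribution versus genome coverage
#'
#' Each variant contributes its single flattened label (highest severity over
#' all overlapped genes). The representation ratio divides the variant
#' fraction by the genome-coverage fraction of the class (1 = neutral); when
#' a class has zero coverage but variants, the ratio is `Inf` with a warning.
#'
#' @param effects Effects data frame from [annotate_effects()].
#' @param gcov A [genome_coverage()] table from the same index.
#' @return Data frame: `class`, `n`, `fraction`, `gcov`, `ratio`.
#' @export
location_distribution <- function(effects, gcov) {
  stopifnot(inherits(gcov, "gcov_table"))
  sev <- region_severity(effects$region)
  flat <- tapply(sev, effects$variant_id, min)
  flat_class <- REGION_CLASSES[flat]
  n <- vapply(REGION_CLASSES, function(cl) sum(flat_class == cl), numeric(1))
  frac <- n / sum(n)
  g <- gcov$fraction[match(REGION_CLASSES, gcov$class)]
  ratio <- frac / g
  if (any(is.infinite(ratio))) {
    warning("class with zero genome coverage has variants; ratio is Inf",
            call. = FALSE)
  }
  data.frame(class = REGION_CLASSES, n = as.numeric(n), fraction = frac,
             gcov = g, ratio = ratio, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-class proportion of genes hit by at least one variant
#'
#' Uses the full per-gene label set: a gene scores for PROMOTER if any
#' variant overlaps its promoter, regardless of other labels the same variant
#' carries.
#'
#' @param effects Effects data frame from [annotate_effects()].
#' @param genes Character vector of all gene ids (the denominator).
#' @return Data frame: `class`, `n_genes`, `proportion`; plus an `ANY` row.
#' @export
gene_hit_proportions <- function(effects, genes) {
  eff <- effects[!is.na(effects$gene_id), , drop = FALSE]
  lab <- strsplit(eff$labels, ",", fixed = TRUE)
  long <- data.frame(gene_id = rep(eff$gene_id, lengths(lab)),
                     class = unlist(lab), stringsAsFactors = FALSE)
  rows <- lapply(setdiff(REGION_CLASSES, "INTERGENIC"), function(cl) {
    hit <- unique(long$gene_id[long$class == cl])
    data.frame(class = cl, n_genes = length(intersect(hit, genes)),
               proportion = length(intersect(hit, genes)) / length(genes),
               stringsAsFactors = FALSE)
  })
  any_hit <- unique(eff$gene_id)
  rows[[length(rows) + 1L]] <- data.frame(
    class = "ANY", n_genes = length(intersect(any_hit, genes)),
    proportion = length(intersect(any_hit, genes)) / length(genes),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
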