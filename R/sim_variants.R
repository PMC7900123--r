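# Variant planting: four SMV and four SV call sets with controlled sharing
# structure, filter-failing fractions and planted per-term excess load.

#' Plant variants on a simulated genome
#'
#' Generates the four small-variant and four structural-variant call sets
#' (within-A, within-B, between A-B, between B-A) on the shared reference
#' coordinate system. Within-set positions are unique (collisions are
#' rejection-resampled); each intra variant is re-emitted in the paired
#' inter set with the configured identical / nonidentical / absent
#' probabilities; genes annotated to planted enrichment terms receive a
#' multiplied variant intensity over their gene region (body plus 5 kbp).
#' QUAL and SV support/length are drawn so configured fractions fail the
#' standard filters.
#'
#' @param sim_genes A [generate_gene_models()] result (carries the rewritten
#'   genome).
#' @param sim_genome The [generate_genome()] result (callability mask).
#' @param config A [sim_config()].
#' @return List of class `sim_variants`: `smv` and `sv` (named lists of
#'   data frames per dataset), `truth` (one row per VCF record),
#'   `loads` (planted per-gene load per category, passing variants only).
#' @export
plant_variants <- function(sim_genes, sim_genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 404L)
  genome <- sim_genes$genome
  mask <- sim_genome$mask
  seqlens <- sim_genome$seqlens
  models <- sim_genes$models

  mask_df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(mask)),
    start = GenomicRanges::start(mask), end = GenomicRanges::end(mask),
    stringsAsFactors = FALSE)
  call_kbp <- sum(mask_df$end - mask_df$start + 1) / 1000
  call_mbp <- call_kbp / 1000

  # enriched gene regions (body +- 5 kbp, callable part)
  enriched_gene_ids <- unique(unlist(sim_genes$enriched_genes,
                                     use.names = FALSE))
  enr <- models$genes[models$genes$gene_id %in% enriched_gene_ids, ,
                      drop = FALSE]
  enr_gr <- if (nrow(enr)) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      enr$scaffold,
      IRanges::IRanges(pmax(1L, enr$start - 5000L), enr$end + 5000L)))
  } else GenomicRanges::GRanges()
  enr_gr <- suppressWarnings(GenomicRanges::intersect(
    enr_gr, GenomicRanges::GRanges(mask_df$scaffold,
                                   IRanges::IRanges(mask_df$start,
                                                    mask_df$end))))
  enr_df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(enr_gr)),
    start = GenomicRanges::start(enr_gr), end = GenomicRanges::end(enr_gr),
    stringsAsFactors = FALSE)
  enr_kbp <- if (nrow(enr_df)) sum(enr_df$end - enr_df$start + 1) / 1000 else 0
  mult <- if (nrow(sim_genes$enriched))
    max(sim_genes$enriched$multiplier) else 1

  sample_positions <- function(n, intervals) {
    if (n == 0L || nrow(intervals) == 0L) {
      return(data.frame(scaffold = character(0), pos = integer(0)))
    }
    w <- intervals$end - intervals$start + 1
    i <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
    pos <- intervals$start[i] +
      floor(runif(n) * (intervals$end[i] - intervals$start[i] + 1))
    data.frame(scaffold = intervals$scaffold[i], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }

  chars <- as.character(genome)
  base_at <- function(scaffold, pos) {
    substring(chars[scaffold], pos, pos)
  }
  substring_at <- function(scaffold, pos, len) {
    substring(chars[scaffold], pos, pos + len - 1L)
  }
  alt_table <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
  other_base <- function(b) {
    alt_table[cbind(match(b, rownames(alt_table)),
                    sample.int(3L, length(b), replace = TRUE))]
  }
  rand_seq <- function(len) {
    vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
  }

  # draw a new SMV event table of n variants of given type at fresh positions
  make_smv <- function(n, type, taken_keys) {
    out <- NULL
    guard <- 0L
    while (n > 0L && guard < 50L) {
      guard <- guard + 1L
      cand <- sample_positions(n, mask_df)
      if (type == "DEL") {
        dlen <- sample(2:9, nrow(cand), replace = TRUE)
        ok <- cand$pos + dlen <= seqlens[cand$scaffold] - 1L
        cand <- cand[ok, , drop = FALSE]; dlen <- dlen[ok]
      }
      key <- paste(cand$scaffold, cand$pos)
      fresh <- !duplicated(key) & !(key %in% taken_keys)
      cand <- cand[fresh, , drop = FALSE]
      if (type == "DEL") dlen <- dlen[fresh]
      if (nrow(cand) == 0L) next
      ref <- switch(type,
        SNP = base_at(cand$scaffold, cand$pos),
        INS = base_at(cand$scaffold, cand$pos),
        DEL = substring_at(cand$scaffold, cand$pos, dlen))
      bad <- grepl("N", ref)
      cand <- cand[!bad, , drop = FALSE]; ref <- ref[!bad]
      if (nrow(cand) == 0L) next
      alt <- switch(type,
        SNP = other_base(ref),
        INS = paste0(ref, rand_seq(sample(1:8, length(ref), replace = TRUE))),
        DEL = substr(ref, 1L, 1L))
      add <- data.frame(scaffold = cand$scaffold, pos = cand$pos,
                        ref = ref, alt = alt, type = type,
                        stringsAsFactors = FALSE)
      taken_keys <- c(taken_keys, paste(add$scaffold, add$pos))
      out <- rbind(out, add)
      n <- n - nrow(add)
    }
    list(events = out, taken = taken_keys)
  }

  empty_events <- function() {
    data.frame(scaffold = character(0), pos = integer(0),
               ref = character(0), alt = character(0), type = character(0),
               stringsAsFactors = FALSE)
  }

  plant_smv_set <- function(intensities) {
    taken <- character(0)
    out <- NULL
    for (type in c("SNP", "INS", "DEL")) {
      lambda <- intensities[[type]] * call_kbp
      n_base <- stats::rpois(1L, lambda)
      r <- make_smv(n_base, type, taken)
      taken <- r$taken
      out <- rbind(out, r$events)
      if (enr_kbp > 0 && mult > 1) {
        n_extra <- stats::rpois(1L, (mult - 1) * intensities[[type]] * enr_kbp)
        if (n_extra > 0L) {
          r2 <- make_smv_in(n_extra, type, taken, enr_df)
          taken <- r2$taken
          out <- rbind(out, r2$events)
        }
      }
    }
    out %||% empty_events()
  }
  make_smv_in <- function(n, type, taken_keys, intervals) {
    saved <- mask_df
    # temporary closure over a different interval set
    out <- NULL
    guard <- 0L
    while (n > 0L && guard < 50L) {
      guard <- guard + 1L
      cand <- sample_positions(n, intervals)
      if (type == "DEL") {
        dlen <- sample(2:9, nrow(cand), replace = TRUE)
        ok <- cand$pos + dlen <= seqlens[cand$scaffold] - 1L
        cand <- cand[ok, , drop = FALSE]; dlen <- dlen[ok]
      }
      key <- paste(cand$scaffold, cand$pos)
      fresh <- !duplicated(key) & !(key %in% taken_keys)
      cand <- cand[fresh, , drop = FALSE]
      if (type == "DEL") dlen <- dlen[fresh]
      if (nrow(cand) == 0L) next
      ref <- switch(type,
        SNP = base_at(cand$scaffold, cand$pos),
        INS = base_at(cand$scaffold, cand$pos),
        DEL = substring_at(cand$scaffold, cand$pos, dlen))
      bad <- grepl("N", ref)
      cand <- cand[!bad, , drop = FALSE]; ref <- ref[!bad]
      if (nrow(cand) == 0L) next
      alt <- switch(type,
        SNP = other_base(ref),
        INS = paste0(ref, rand_seq(sample(1:8, length(ref), replace = TRUE))),
        DEL = substr(ref, 1L, 1L))
      add <- data.frame(scaffold = cand$scaffold, pos = cand$pos,
                        ref = ref, alt = alt, type = type,
                        stringsAsFactors = FALSE)
      taken_keys <- c(taken_keys, paste(add$scaffold, add$pos))
      out <- rbind(out, add)
      n <- n - nrow(add)
    }
    invisible(saved)
    list(events = out, taken = taken_keys)
  }

  finalize_smv <- function(events, prefix) {
    if (is.null(events) || nrow(events) == 0L) {
      return(data.frame(record = character(0), scaffold = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), alt2 = character(0),
                        qual = numeric(0), type = character(0),
                        sharing = character(0), stringsAsFactors = FALSE))
    }
    events <- events[order(events$scaffold, events$pos), , drop = FALSE]
    n <- nrow(events)
    events$record <- sprintf("%s%06d", prefix, seq_len(n))
    fail <- runif(n) < config$qual_fail_fraction
    qual <- round(ifelse(fail, runif(n, 5, 29.9),
                         pmax(30, stats::rnorm(n, 58, 12))), 2)
    events$qual <- qual
    # a second alt on a fraction of SNP records
    alt2 <- rep(NA_character_, n)
    cand <- which(events$type == "SNP" &
                    runif(n) < config$multiallelic_fraction)
    for (i in cand) {
      alt2[i] <- sample_from(setdiff(c("A", "C", "G", "T"),
                                     c(events$ref[i], events$alt[i])), 1L)
    }
    events$alt2 <- alt2
    events
  }

  # --- SMV pairings ---------------------------------------------------
  smv_sets <- list()
  truth_rows <- list()
  for (pairing in list(c("intra_A", "inter_AB"), c("intra_B", "inter_BA"))) {
    intra_key <- pairing[1L]; inter_key <- pairing[2L]
    intra <- plant_smv_set(config$smv_per_kbp[[intra_key]])
    intra$sharing <- rep("UNIQUE_INTRA", nrow(intra))
    # re-emit intra positions into the inter set
    u <- runif(nrow(intra))
    f_id <- config$sharing[["identical"]]
    f_non <- config$sharing[["nonidentical"]]
    reemit_id <- u < f_id
    reemit_non <- u >= f_id & u < f_id + f_non
    intra$sharing[reemit_id] <- "IDENTICAL"
    intra$sharing[reemit_non] <- "NONIDENTICAL"
    inter_re <- intra[reemit_id | reemit_non,
                      c("scaffold", "pos", "ref", "alt", "type"),
                      drop = FALSE]
    if (nrow(inter_re)) {
      flip <- intra$sharing[reemit_id | reemit_non] == "NONIDENTICAL"
      if (any(flip)) {
        # different allele at the same location: SNP alt swap, or type swap
        snp <- flip & inter_re$type == "SNP"
        for (i in which(snp)) {
          inter_re$alt[i] <- sample_from(
            setdiff(c("A", "C", "G", "T"),
                    c(inter_re$ref[i], inter_re$alt[i])), 1L)
        }
        nonsnp <- which(flip & inter_re$type != "SNP")
        for (i in nonsnp) {
          b <- base_at(inter_re$scaffold[i], inter_re$pos[i])
          inter_re$ref[i] <- b
          inter_re$alt[i] <- other_base(b)
          inter_re$type[i] <- "SNP"
        }
      }
      inter_re$sharing <- ifelse(flip, "NONIDENTICAL", "IDENTICAL")
    }
    taken_inter <- paste(inter_re$scaffold, inter_re$pos)
    inter_own <- NULL
    for (type in c("SNP", "INS", "DEL")) {
      lambda <- config$smv_per_kbp[[inter_key]][[type]] * call_kbp
      r <- make_smv(stats::rpois(1L, lambda), type, taken_inter)
      taken_inter <- r$taken
      inter_own <- rbind(inter_own, r$events)
      if (enr_kbp > 0 && mult > 1) {
        n_extra <- stats::rpois(
          1L, (mult - 1) * config$smv_per_kbp[[inter_key]][[type]] * enr_kbp)
        if (n_extra > 0L) {
          r2 <- make_smv_in(n_extra, type, taken_inter, enr_df)
          taken_inter <- r2$taken
          inter_own <- rbind(inter_own, r2$events)
        }
      }
    }
    if (!is.null(inter_own) && nrow(inter_own)) {
      inter_own$sharing <- "UNIQUE_INTER"
    }
    inter <- rbind(inter_re, inter_own)
    smv_sets[[intra_key]] <- finalize_smv(intra, substr(intra_key, 7, 7))
    smv_sets[[inter_key]] <- finalize_smv(
      inter, paste0("x", substr(inter_key, 7, 8)))
  }

  # --- SV sets --------------------------------------------------------
  make_sv_set <- function(intensities, prefix, reemit_from = NULL) {
    rows <- NULL
    for (type in c("DEL", "DUP", "INV", "TRA", "INS")) {
      n <- stats::rpois(1L, intensities[[type]] * call_mbp)
      if (enr_kbp > 0 && mult > 1) {
        n <- n + stats::rpois(1L, (mult - 1) * intensities[[type]] *
                                enr_kbp / 1000)
      }
      if (n == 0L) next
      cand <- sample_positions(n, mask_df)
      short <- runif(n) < config$sv_short_fail_fraction
      len <- ifelse(short, as.integer(runif(n, 50, 299)),
                    as.integer(runif(n, 300, 4000)))
      if (type %in% c("DEL", "DUP", "INV")) {
        end <- pmin(cand$pos + len - 1L, seqlens[cand$scaffold] - 1L)
      } else if (type == "INS") {
        end <- cand$pos
      } else {
        end <- cand$pos
      }
      r <- data.frame(scaffold = cand$scaffold, start = cand$pos, end = end,
                      svtype = type, sharing = "UNIQUE_INTRA",
                      stringsAsFactors = FALSE)
      if (type == "TRA") {
        mate <- sample_positions(n, mask_df)
        r$scaffold2 <- mate$scaffold
        r$pos2 <- mate$pos
      } else {
        r$scaffold2 <- NA_character_
        r$pos2 <- NA_integer_
      }
      rows <- rbind(rows, r)
    }
    if (is.null(rows)) rows <- data.frame()
    rows
  }

  finalize_sv <- function(rows, prefix) {
    if (is.null(rows) || nrow(rows) == 0L) {
      return(data.frame(id = character(0), scaffold = character(0),
                        start = integer(0), end = integer(0),
                        svtype = character(0), support = integer(0),
                        scaffold2 = character(0), pos2 = integer(0),
                        sharing = character(0), stringsAsFactors = FALSE))
    }
    rows <- rows[order(rows$scaffold, rows$start), , drop = FALSE]
    n <- nrow(rows)
    rows$id <- sprintf("%s%05d", prefix, seq_len(n))
    fail <- runif(n) < config$sv_support_fail_fraction
    rows$support <- ifelse(fail, sample(1:4, n, replace = TRUE),
                           4L + stats::rpois(n, 11))
    rows
  }

  sv_sets <- list()
  for (pairing in list(c("intra_A", "inter_AB"), c("intra_B", "inter_BA"))) {
    intra_key <- pairing[1L]; inter_key <- pairing[2L]
    intra <- make_sv_set(config$sv_per_mbp[[intra_key]])
    u <- runif(max(nrow(intra), 0L))
    f_id <- config$sharing[["identical"]]
    reemit <- nrow(intra) > 0 & u < f_id
    if (nrow(intra)) {
      intra$sharing <- ifelse(reemit, "IDENTICAL", "UNIQUE_INTRA")
    }
    inter_re <- if (nrow(intra)) {
      intra[reemit, setdiff(names(intra), c("sharing")), drop = FALSE]
    } else NULL
    if (!is.null(inter_re) && nrow(inter_re)) inter_re$sharing <- "IDENTICAL"
    inter_own <- make_sv_set(config$sv_per_mbp[[inter_key]])
    if (nrow(inter_own)) inter_own$sharing <- "UNIQUE_INTER"
    inter <- rbind(inter_re, inter_own)
    sv_sets[[intra_key]] <- finalize_sv(intra, tolower(substr(intra_key, 7, 7)))
    sv_sets[[inter_key]] <- finalize_sv(
      inter, paste0("y", tolower(substr(inter_key, 7, 8))))
  }

  # --- ground truth ---------------------------------------------------
  region_idx <- build_region_index(models, seqlens)
  flattened_regions <- function(scaf, s, e) {
    if (length(s) == 0L) return(character(0))
    hits <- locate_many(region_idx, scaf, s, e)
    out <- rep("INTERGENIC", length(s))
    if (nrow(hits)) {
      best <- tapply(region_severity(hits$class), hits$query, min)
      out[as.integer(names(best))] <- REGION_CLASSES[best]
    }
    out
  }
  truth <- list()
  for (ds in names(SIM_DATASETS)) {
    s <- smv_sets[[ds]]
    if (nrow(s)) {
      reg <- flattened_regions(s$scaffold, s$pos, s$pos)
      truth[[length(truth) + 1L]] <- data.frame(
        dataset = ds, category = SIM_DATASETS[[ds]], record = s$record,
        scaffold = s$scaffold, pos = s$pos, end = s$pos, class = "SMV",
        type = s$type, sharing = s$sharing, region = reg,
        pass_filter = s$qual >= 30, stringsAsFactors = FALSE)
    }
    v <- sv_sets[[ds]]
    if (nrow(v)) {
      reg <- flattened_regions(v$scaffold, v$start, pmax(v$start, v$end))
      pass <- v$support >= 5 &
        (!(v$svtype %in% c("DEL", "DUP", "INV")) |
           (v$end - v$start + 1) >= 300)
      rows <- data.frame(
        dataset = ds, category = SIM_DATASETS[[ds]], record = v$id,
        scaffold = v$scaffold, pos = v$start, end = pmax(v$start, v$end),
        class = "SV", type = v$svtype,
        sharing = v$sharing, region = reg, pass_filter = pass,
        stringsAsFactors = FALSE)
      # translocations emit two VCF records (one per breakend)
      tra <- v$svtype == "TRA"
      if (any(tra)) {
        mates <- rows[tra, , drop = FALSE]
        mates$record <- paste0(mates$record, "_2")
        mates$scaffold <- v$scaffold2[tra]
        mates$pos <- v$pos2[tra]
        mates$end <- v$pos2[tra]
        rows <- rbind(rows, mates)
      }
      truth[[length(truth) + 1L]] <- rows
    }
  }
  truth <- do.call(rbind, truth) %||% data.frame(
    dataset = character(0), category = character(0), record = character(0),
    scaffold = character(0), pos = integer(0), end = integer(0),
    class = character(0), type = character(0), sharing = character(0),
    region = character(0), pass_filter = logical(0),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$dataset, truth$scaffold, truth$pos), ,
                 drop = FALSE]
  rownames(truth) <- NULL

  # planted per-gene loads over passing variants (simple per-gene scan,
  # independent of the pipeline's overlap machinery)
  loads <- planted_loads(truth, models$genes)

  structure(list(smv = smv_sets, sv = sv_sets, truth = truth, loads = loads),
            class = "sim_variants")
}

# Per-gene, per-category counts of passing variants within body +- 5 kbp,
# by direct comparison (no interval index).
planted_loads <- function(truth, genes, flank = 5000L) {
  pass <- truth[truth$pass_filter, , drop = FALSE]
  if (nrow(pass) == 0L) {
    return(data.frame(gene_id = character(0), category = character(0),
                      smv = numeric(0), sv = numeric(0), total = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # one event per record; translocation mate records collapse to the event
  pass$event <- sub("_2$", "", pass$record)
  out <- list()
  for (cat in unique(pass$category)) {
    sub <- pass[pass$category == cat, , drop = FALSE]
    for (g in seq_len(nrow(genes))) {
      lo <- genes$start[g] - flank
      hi <- genes$end[g] + flank
      hit <- sub$scaffold == genes$scaffold[g] & sub$pos <= hi & sub$end >= lo
      smv_n <- length(unique(sub$event[hit & sub$class == "SMV"]))
      sv_n <- length(unique(sub$event[hit & sub$class == "SV"]))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g], category = cat,
        smv = smv_n, sv = sv_n, total = smv_n + sv_n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
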