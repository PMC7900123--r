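# Cross-indexing of intra- and inter-comparison variant sets: sharing labels,
# per-gene mutation loads, and quantile-based candidate gene selection.

#' Comparison categories and their legal pairings
#'
#' AA (within species A) pairs with AB (A reads against B's genome projected
#' on A coordinates) on the A coordinate system; BB pairs with BA on the B
#' coordinate system.
#' @export
COMPARISON_PAIRINGS <- list(AA = "AB", BB = "BA")

#' Index small variants by genomic position
#'
#' Multi-allelic rows contribute all alternate alleles at their position.
#'
#' @param smv Small-variant data frame (`scaffold`, `pos`, `alt`).
#' @return Object of class `position_index`: data frame with `scaffold`,
#'   `pos`, and list-column `alts`.
#' @export
index_by_position <- function(smv) {
  if (is.null(smv) || nrow(smv) == 0L) {
    out <- data.frame(scaffold = character(0), pos = integer(0))
    out$alts <- list()
    class(out) <- c("position_index", "data.frame")
    return(out)
  }
  key <- paste(smv$scaffold, smv$pos, sep = ":")
  alts <- split(smv$alt, key)
  u <- !duplicated(key)
  out <- data.frame(scaffold = smv$scaffold[u], pos = smv$pos[u],
                    stringsAsFactors = FALSE)
  out$alts <- unname(lapply(alts[key[u]], unique))
  class(out) <- c("position_index", "data.frame")
  out
}

#' Classify variant sharing between an intra- and an inter-comparison set
#'
#' Small variants match by exact position; the label is IDENTICAL when the
#' alternate-allele sets at the position intersect, NONIDENTICAL when both
#' sets have a variant there but the alleles are disjoint, and UNIQUE_INTRA /
#' UNIQUE_INTER when only one side has a variant. Structural variants match
#' on the same type with a start within `sv_tol` bp and (for interval types)
#' reciprocal overlap of at least `sv_recip`.
#'
#' @param intra,inter For SMVs, data frames (`scaffold`, `pos`, `alt`) or
#'   [index_by_position()] results; both must share a coordinate system.
#' @param intra_sv,inter_sv Optional SV data frames from
#'   [read_and_filter_sv()].
#' @param sv_tol Start-position tolerance for SV matching, bp (default 50).
#' @param sv_recip Minimum reciprocal overlap for DEL/DUP/INV/INS matching
#'   (default 0.8).
#' @return List with `intra` and `inter` label data frames (`scaffold`,
#'   `pos`, `class` (SMV/SV), `label`).
#' @export
classify_sharing <- function(intra, inter, intra_sv = NULL, inter_sv = NULL,
                             sv_tol = 50L, sv_recip = 0.8) {
  ia <- if (inherits(intra, "position_index")) intra else index_by_position(intra)
  ib <- if (inherits(inter, "position_index")) inter else index_by_position(inter)
  if (nrow(ia) > 0L && nrow(ib) > 0L &&
      length(intersect(unique(ia$scaffold), unique(ib$scaffold))) == 0L) {
    stop_config(paste0("intra and inter sets share no scaffold names; ",
                       "sharing requires one coordinate system"))
  }
  key_a <- paste(ia$scaffold, ia$pos, sep = ":")
  key_b <- paste(ib$scaffold, ib$pos, sep = ":")
  m_ab <- match(key_a, key_b)
  lab_a <- ifelse(is.na(m_ab), "UNIQUE_INTRA", NA)
  shared <- which(!is.na(m_ab))
  for (i in shared) {
    common <- intersect(ia$alts[[i]], ib$alts[[m_ab[i]]])
    lab_a[i] <- if (length(common)) "IDENTICAL" else "NONIDENTICAL"
  }
  m_ba <- match(key_b, key_a)
  lab_b <- ifelse(is.na(m_ba), "UNIQUE_INTER", lab_a[m_ba])

  intra_out <- data.frame(scaffold = ia$scaffold, pos = ia$pos,
                          class = rep("SMV", nrow(ia)), label = lab_a,
                          stringsAsFactors = FALSE)
  inter_out <- data.frame(scaffold = ib$scaffold, pos = ib$pos,
                          class = rep("SMV", nrow(ib)), label = lab_b,
                          stringsAsFactors = FALSE)

  if (!is.null(intra_sv) || !is.null(inter_sv)) {
    svl <- classify_sv_sharing(intra_sv, inter_sv, sv_tol, sv_recip)
    intra_out <- rbind(intra_out, svl$intra)
    inter_out <- rbind(inter_out, svl$inter)
  }
  list(intra = intra_out, inter = inter_out)
}

classify_sv_sharing <- function(intra_sv, inter_sv, sv_tol, sv_recip) {
  a <- intra_sv %||% empty_sv_frame()
  b <- inter_sv %||% empty_sv_frame()
  match_one <- function(x, pool) {
    cand <- which(pool$svtype == x$svtype &
                    pool$scaffold == x$scaffold &
                    abs(pool$start - x$start) <= sv_tol)
    if (length(cand) == 0L) return(FALSE)
    if (x$svtype %in% c("TRA", "INS")) return(TRUE)
    any(vapply(cand, function(j) {
      ov <- min(x$end, pool$end[j]) - max(x$start, pool$start[j]) + 1
      if (ov <= 0) return(FALSE)
      ov / (x$end - x$start + 1) >= sv_recip &&
        ov / (pool$end[j] - pool$start[j] + 1) >= sv_recip
    }, logical(1)))
  }
  sv_match_types <- function(x, pool) {
    # any variant of any type at (approximately) the same location?
    any(pool$scaffold == x$scaffold & abs(pool$start - x$start) <= sv_tol)
  }
  lab <- function(x, pool, unique_label) {
    if (nrow(x) == 0L) return(character(0))
    vapply(seq_len(nrow(x)), function(i) {
      xi <- x[i, ]
      if (match_one(xi, pool)) "IDENTICAL"
      else if (sv_match_types(xi, pool)) "NONIDENTICAL"
      else unique_label
    }, character(1))
  }
  list(
    intra = data.frame(scaffold = a$scaffold, pos = a$start,
                       class = rep("SV", nrow(a)),
                       label = lab(a, b, "UNIQUE_INTRA"),
                       stringsAsFactors = FALSE),
    inter = data.frame(scaffold = b$scaffold, pos = b$start,
                       class = rep("SV", nrow(b)),
                       label = lab(b, a, "UNIQUE_INTER"),
                       stringsAsFactors = FALSE))
}

#' Accumulate per-gene mutation loads
#'
#' Each variant increments every gene whose region (gene body plus `flank` bp
#' on both sides, clipped to the scaffold) it intersects, once per gene per
#' variant; small and structural variants are tallied separately. For
#' translocations both breakends are considered but the event counts at most
#' once per gene.
#'
#' @param variant_sets Named list (one element per comparison category, e.g.
#'   `AA`, `AB`) of lists with elements `smv` (data frame with `record`,
#'   `scaffold`, `pos`) and/or `sv` (data frame from [read_and_filter_sv()]).
#' @param index A [build_region_index()] result (supplies gene bodies).
#' @param flank Region extension, bp (default 5000).
#' @return Data frame of class `mutation_load`: `gene_id`, `category`,
#'   `smv`, `sv`, `total`; genes with zero load in a category are included
#'   with zeros.
#' @export
mutation_load <- function(variant_sets, index, flank = 5000L) {
  stopifnot(inherits(index, "region_index"))
  genes <- index$genes
  regions <- GenomicRanges::GRanges(
    genes$scaffold,
    IRanges::IRanges(pmax(1L, genes$start - flank), genes$end + flank))
  count_hits <- function(ids, scaffold, pos, end = pos) {
    if (length(ids) == 0L) {
      return(stats::setNames(numeric(nrow(genes)), genes$gene_id))
    }
    q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, end))
    hits <- GenomicRanges::findOverlaps(q, regions)
    pairs <- unique(data.frame(id = ids[S4Vectors::queryHits(hits)],
                               gene = S4Vectors::subjectHits(hits)))
    n <- tabulate(pairs$gene, nbins = nrow(genes))
    stats::setNames(as.numeric(n), genes$gene_id)
  }
  rows <- lapply(names(variant_sets), function(cat) {
    vs <- variant_sets[[cat]]
    smv_n <- if (!is.null(vs$smv) && nrow(vs$smv) > 0L) {
      count_hits(vs$smv$record, vs$smv$scaffold, vs$smv$pos)
    } else stats::setNames(numeric(nrow(genes)), genes$gene_id)
    sv <- vs$sv
    if (!is.null(sv) && nrow(sv) > 0L) {
      # one row per breakend/interval, event id carries uniqueness
      ids <- sv$id
      scaf <- sv$scaffold
      s <- sv$start
      e <- ifelse(is.na(sv$end), sv$start, sv$end)
      extra <- !is.na(sv$scaffold2) & !is.na(sv$pos2)
      if (any(extra)) {
        ids <- c(ids, sv$id[extra])
        scaf <- c(scaf, sv$scaffold2[extra])
        s <- c(s, sv$pos2[extra])
        e <- c(e, sv$pos2[extra])
      }
      sv_n <- count_hits(ids, scaf, s, e)
    } else {
      sv_n <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
    }
    data.frame(gene_id = genes$gene_id, category = cat,
               smv = as.numeric(smv_n), sv = as.numeric(sv_n),
               total = as.numeric(smv_n + sv_n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mutation_load", "data.frame")
  out
}

#' Select candidate genes by load quantile
#'
#' Per category, the quantile at `p` is computed over genes with load > 0 and
#' genes with load strictly greater than that quantile are selected (or
#' greater-or-equal with `strict = FALSE`). With all loads equal the strict
#' rule selects nothing.
#'
#' @param load A [mutation_load()] table.
#' @param p Quantile in (0, 1); default 0.5 (the median).
#' @param strict Use strictly-greater thresholding (default TRUE).
#' @param measure Which load column to rank on: `total` (default), `smv` or
#'   `sv`.
#' @return Named list: category -> character vector of selected gene ids.
#' @export
select_candidate_genes <- function(load, p = 0.5, strict = TRUE,
                                   measure = c("total", "smv", "sv")) {
  measure <- match.arg(measure)
  if (!(p > 0 && p < 1)) stop_config("p must be in (0, 1)")
  if (nrow(load) == 0L) stop_config("empty mutation-load table")
  out <- lapply(split(load, load$category), function(tab) {
    x <- tab[[measure]]
    pos <- x > 0
    if (!any(pos)) {
      warning("all loads zero in a category; empty selection", call. = FALSE)
      return(character(0))
    }
    q <- stats::quantile(x[pos], p, names = FALSE)
    keep <- if (strict) x > q else x >= q
    sort(tab$gene_id[keep & pos])
  })
  out[unique(load$category)]
}
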