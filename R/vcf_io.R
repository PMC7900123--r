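# VCF 4.2 emission for the simulator. Reading goes through
# VariantAnnotation; the emitter produces sorted, contig-headered files that
# round-trip through that parser.

vcf_header <- function(contigs, seqlens, info_lines = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=crossvar_sim",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            as.integer(seqlens[contigs])),
    info_lines,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
}

#' Write a small-variant call set as VCF 4.2
#'
#' @param smv Data frame with `record`, `scaffold`, `pos`, `ref`, `alt`,
#'   optional `alt2` (second alternate allele), `qual`.
#' @param path Output path.
#' @param seqlens Named scaffold lengths for the contig header.
#' @export
write_smv_vcf <- function(smv, path, seqlens) {
  lines <- vcf_header(names(seqlens), seqlens)
  if (nrow(smv)) {
    smv <- smv[order(smv$scaffold, smv$pos), , drop = FALSE]
    alt <- smv$alt
    if (!is.null(smv$alt2)) {
      has2 <- !is.na(smv$alt2)
      alt[has2] <- paste(smv$alt[has2], smv$alt2[has2], sep = ",")
    }
    lines <- c(lines, paste(smv$scaffold, smv$pos, smv$record, smv$ref, alt,
                            sprintf("%.2f", smv$qual), "PASS", ".",
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

SV_INFO_LINES <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
  '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
  '##INFO=<ID=PE,Number=1,Type=Integer,Description="Supporting read pairs">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
  '##INFO=<ID=MATEID,Number=1,Type=String,Description="Breakend mate id">',
  '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate scaffold">')

#' Write a structural-variant call set as VCF 4.2
#'
#' DEL/DUP/INV/INS become symbolic-allele records with `SVTYPE`, `END`, `PE`
#' and `SVLEN`; translocations become a pair of BND records linked by
#' `MATEID`.
#'
#' @param sv Data frame with `id`, `scaffold`, `start`, `end`, `svtype`,
#'   `support`, `scaffold2`, `pos2`.
#' @inheritParams write_smv_vcf
#' @export
write_sv_vcf <- function(sv, path, seqlens) {
  rows <- list()
  if (nrow(sv)) {
    for (i in seq_len(nrow(sv))) {
      x <- sv[i, ]
      if (x$svtype == "TRA") {
        id1 <- x$id; id2 <- paste0(x$id, "_2")
        info1 <- sprintf("SVTYPE=BND;MATEID=%s;PE=%d;CHR2=%s",
                         id2, x$support, x$scaffold2)
        info2 <- sprintf("SVTYPE=BND;MATEID=%s;PE=%d;CHR2=%s",
                         id1, x$support, x$scaffold)
        alt1 <- sprintf("N[%s:%d[", x$scaffold2, x$pos2)
        alt2 <- sprintf("N]%s:%d]", x$scaffold, x$start)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = c(x$scaffold, x$scaffold2),
          pos = c(x$start, x$pos2), id = c(id1, id2), ref = "N",
          alt = c(alt1, alt2), info = c(info1, info2),
          stringsAsFactors = FALSE)
      } else {
        svlen <- if (x$svtype == "INS") NA_integer_ else x$end - x$start + 1L
        info <- sprintf("SVTYPE=%s;END=%d;PE=%d", x$svtype, x$end, x$support)
        if (!is.na(svlen)) info <- paste0(info, sprintf(";SVLEN=%d", svlen))
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = x$scaffold, pos = x$start, id = x$id, ref = "N",
          alt = sprintf("<%s>", x$svtype), info = info,
          stringsAsFactors = FALSE)
      }
    }
  }
  lines <- vcf_header(names(seqlens), seqlens, SV_INFO_LINES)
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order(df$scaffold, df$pos), , drop = FALSE]
    lines <- c(lines, paste(df$scaffold, df$pos, df$id, df$ref, df$alt,
                            "60", "PASS", df$info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
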