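# Published summary counts from the Tropheus moorii (TM) / Petrochromis
# trewavasae (PT) genome comparison, shipped as package data. These are the
# printed per-comparison inputs that the summary operations reproduce.

#' Published variant-call summary counts (TM/PT comparison)
#'
#' Per-comparison counts for the four datasets of the two-cichlid study
#' system: small-variant totals and per-type counts, structural-variant
#' per-type counts, multi-allelic record counts, and the genome total and
#' effective lengths the variant rates are computed over. Categories are
#' `PT_vs_TM` and `TM_vs_PT` (between species) and `PT_vs_PT`, `TM_vs_TM`
#' (within species).
#'
#' @return Data frame with columns `comparison`, `metric`, `value`.
#' @export
published_variant_counts <- function() {
  path <- system.file("extdata", "cichlid_variant_counts.tsv",
                      package = "crossvar")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Published variant-effect counts (TM/PT comparison)
#'
#' Impact-category counts (HIGH/MODERATE/LOW/MODIFIER) and coding-sequence
#' consequence counts (NONSENSE/MISSENSE/SILENT) per comparison.
#'
#' @return Data frame with columns `comparison`, `group`, `class`, `count`.
#' @export
published_effect_counts <- function() {
  path <- system.file("extdata", "cichlid_effect_counts.tsv",
                      package = "crossvar")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Convenience accessor: one comparison's metrics as a named vector.
published_metrics <- function(counts, comparison) {
  sub <- counts[counts$comparison == comparison, , drop = FALSE]
  stats::setNames(sub$value, sub$metric)
}
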