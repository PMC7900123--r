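# Simulation configuration for the self-contained two-comparison fixture
# bundle.

#' Simulation configuration
#'
#' Defaults emulate, at reduced scale, the variant densities observed in a
#' comparison of two recently diverged fish genomes: roughly one small
#' variant per 220 bp between the groups and one per 1500-2500 bp within
#' each group, with structural variants around 100 per Mbp between groups
#' dominated by deletions. The four datasets are the two within-group call
#' sets (categories AA and BB) and the two between-group call sets (AB paired
#' with AA, BA paired with BB) on one shared reference coordinate system.
#'
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   config including this seed.
#' @param n_scaffolds,scaffold_length Genome shape (default 6 x 120 kbp).
#' @param n_gap_rate Expected number of N gaps per scaffold (Poisson).
#' @param n_gap_len Length range of an N gap, bp.
#' @param n_genes Number of genes (default 150).
#' @param exons_per_gene Range of exon counts per gene.
#' @param mean_exon_len,mean_intron_len Mean exon/intron lengths, bp.
#' @param utr_len Range of UTR lengths, bp (each side).
#' @param strand_fraction Fraction of genes on the minus strand.
#' @param fraction_unannotated Fraction of genes receiving no GO term
#'   (excluded from the enrichment universe).
#' @param n_go_terms,dag_depth Ontology size and depth (root = level 1).
#' @param terms_per_gene Range of direct GO terms per annotated gene.
#' @param smv_per_kbp Named list (`intra_A`, `intra_B`, `inter_AB`,
#'   `inter_BA`) of named vectors (`SNP`, `INS`, `DEL`): expected variants
#'   per kbp of callable sequence. The inter intensities are for
#'   inter-unique variants; shared positions re-emitted from the paired
#'   intra set come on top.
#' @param sv_per_mbp Same shape for SVs (`DEL`, `DUP`, `INV`, `TRA`, `INS`),
#'   per Mbp.
#' @param sharing Named vector `identical`, `nonidentical`: probability that
#'   an intra variant position is re-emitted in the paired inter set with
#'   the same / a different alternate allele; the remainder stays unique to
#'   the intra set. Must sum to at most 1.
#' @param multiallelic_fraction Fraction of SMV records given a second
#'   alternate allele (free parameter; callers differ on this).
#' @param qual_fail_fraction Fraction of SMV records emitted with QUAL below
#'   the quality filter (to exercise filtering).
#' @param sv_support_fail_fraction Fraction of SV records with fewer than the
#'   minimum supporting pairs.
#' @param sv_short_fail_fraction Fraction of DEL/DUP/INV records shorter than
#'   the minimum SV length.
#' @param enriched_terms Data frame (`term`, `multiplier`) of ontology terms
#'   planted with excess mutation load, or NULL to pick one deep term at
#'   bundle time with `enrichment_multiplier`.
#' @param n_enriched_genes Number of member genes assigned to a planted term.
#' @param enrichment_multiplier Load multiplier for planted-term gene regions.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 6L,
                       scaffold_length = 120000L,
                       n_gap_rate = 2,
                       n_gap_len = c(10L, 60L),
                       n_genes = 150L,
                       exons_per_gene = c(2L, 4L),
                       mean_exon_len = 150L,
                       mean_intron_len = 220L,
                       utr_len = c(40L, 120L),
                       strand_fraction = 0.5,
                       fraction_unannotated = 0.1,
                       n_go_terms = 40L,
                       dag_depth = 4L,
                       terms_per_gene = c(1L, 3L),
                       smv_per_kbp = list(
                         intra_A = c(SNP = 0.27, INS = 0.06, DEL = 0.07),
                         intra_B = c(SNP = 0.46, INS = 0.08, DEL = 0.10),
                         inter_AB = c(SNP = 3.40, INS = 0.56, DEL = 0.57),
                         inter_BA = c(SNP = 3.44, INS = 0.53, DEL = 0.58)),
                       sv_per_mbp = list(
                         intra_A = c(DEL = 13, DUP = 3, INV = 2, TRA = 13, INS = 2),
                         intra_B = c(DEL = 23, DUP = 4, INV = 2, TRA = 17, INS = 2),
                         inter_AB = c(DEL = 62, DUP = 4, INV = 2, TRA = 21, INS = 15),
                         inter_BA = c(DEL = 66, DUP = 3, INV = 1, TRA = 14, INS = 19)),
                       sharing = c(identical = 0.45, nonidentical = 0.15),
                       multiallelic_fraction = 0.006,
                       qual_fail_fraction = 0.08,
                       sv_support_fail_fraction = 0.08,
                       sv_short_fail_fraction = 0.05,
                       enriched_terms = NULL,
                       n_enriched_genes = 15L,
                       enrichment_multiplier = 6) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$seed)) stop_config("seed must be a non-negative integer")
  if (cfg$n_scaffolds < 1) stop_config("n_scaffolds must be >= 1")
  if (cfg$scaffold_length < 1000) stop_config("scaffold_length must be >= 1 kbp")
  if (cfg$n_go_terms < 1) stop_config("n_go_terms must be >= 1")
  if (cfg$n_go_terms > 1 && cfg$dag_depth < 2) {
    stop_config("dag_depth must be >= 2")
  }
  if (cfg$n_go_terms < cfg$dag_depth && cfg$n_go_terms > 1) {
    stop_config("n_go_terms must be >= dag_depth")
  }
  ints <- c(unlist(cfg$smv_per_kbp), unlist(cfg$sv_per_mbp))
  if (any(ints < 0)) stop_config("variant intensities must be >= 0")
  sh <- cfg$sharing
  if (!all(c("identical", "nonidentical") %in% names(sh)) ||
      any(sh < 0) || sum(sh) > 1) {
    stop_config("sharing fractions must be >= 0 and sum to <= 1")
  }
  fr <- c(cfg$strand_fraction, cfg$fraction_unannotated,
          cfg$multiallelic_fraction, cfg$qual_fail_fraction,
          cfg$sv_support_fail_fraction, cfg$sv_short_fail_fraction)
  if (any(fr < 0 | fr > 1)) stop_config("fractions must lie in [0, 1]")
  invisible(cfg)
}

# dataset key -> comparison category
SIM_DATASETS <- c(intra_A = "AA", intra_B = "BB",
                  inter_AB = "AB", inter_BA = "BA")
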