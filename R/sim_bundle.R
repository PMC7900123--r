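# Bundle orchestration: one call produces the full self-contained fixture
# (genome, mask, gene models, ontology, annotations, eight VCFs, ground
# truth), in memory and optionally on disk.

#' Simulate a complete analysis bundle
#'
#' Runs ontology, genome, gene-model and variant generation under the config
#' seed. Identical configs produce byte-identical output bundles.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all files are written
#'   (FASTA genome, BED callability mask, GFF3 gene models, OBO ontology,
#'   gene-to-GO TSV, four SMV and four SV VCFs, ground-truth TSVs).
#' @return Object of class `sim_bundle`: `config`, `dag`, `genome`
#'   (rewritten `DNAStringSet`), `mask`, `seqlens`, `models`, `gene2go`,
#'   `enriched`, `enriched_genes`, `smv`, `sv`, `truth`, `loads`, and
#'   `paths` (named file paths when written).
#' @export
simulate_bundle <- function(config = sim_config(), out_dir = NULL) {
  validate_sim_config(config)
  dag <- generate_ontology(config)
  sg <- generate_genome(config)
  genes <- generate_gene_models(sg, dag, config)
  vars <- plant_variants(genes, sg, config)
  bundle <- structure(list(
    config = config, dag = dag, genome = genes$genome, mask = sg$mask,
    seqlens = sg$seqlens, models = genes$models, gene2go = genes$gene2go,
    enriched = genes$enriched, enriched_genes = genes$enriched_genes,
    smv = vars$smv, sv = vars$sv, truth = vars$truth, loads = vars$loads,
    paths = NULL), class = "sim_bundle")
  if (!is.null(out_dir)) {
    bundle$paths <- write_bundle(bundle, out_dir)
  }
  bundle
}

#' Write a simulated bundle to disk
#' @param bundle A [simulate_bundle()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- list(genome = p("genome.fa"), mask = p("callable.bed"),
                gff3 = p("genes.gff3"), obo = p("ontology.obo"),
                gene2go = p("gene2go.tsv"),
                truth = p("truth_variants.tsv"),
                loads = p("truth_loads.tsv"),
                enriched = p("truth_enriched.tsv"))
  Biostrings::writeXStringSet(bundle$genome, paths$genome, width = 70L)
  rtracklayer::export(bundle$mask, paths$mask, format = "bed")
  write_gene_models_gff3(bundle$models, paths$gff3)
  write_obo(bundle$dag, paths$obo)
  write_gene2go(bundle$gene2go, paths$gene2go)
  for (ds in names(SIM_DATASETS)) {
    smv_path <- p(sprintf("smv_%s.vcf", SIM_DATASETS[[ds]]))
    sv_path <- p(sprintf("sv_%s.vcf", SIM_DATASETS[[ds]]))
    write_smv_vcf(bundle$smv[[ds]], smv_path, bundle$seqlens)
    write_sv_vcf(bundle$sv[[ds]], sv_path, bundle$seqlens)
    paths[[paste0("smv_", SIM_DATASETS[[ds]])]] <- smv_path
    paths[[paste0("sv_", SIM_DATASETS[[ds]])]] <- sv_path
  }
  write_tsv(bundle$truth, paths$truth)
  write_tsv(bundle$loads, paths$loads)
  write_tsv(bundle$enriched, paths$enriched)
  paths
}

#' @export
print.sim_bundle <- function(x, ...) {
  n_smv <- vapply(x$smv, nrow, integer(1))
  n_sv <- vapply(x$sv, nrow, integer(1))
  cat(sprintf(
    "sim_bundle: %d scaffolds x %d bp, %d genes, %d GO terms\nSMV records: %s\nSV events:   %s\n",
    x$config$n_scaffolds, x$config$scaffold_length,
    nrow(x$models$genes), length(x$dag$terms),
    paste(sprintf("%s=%d", SIM_DATASETS[names(n_smv)], n_smv), collapse = " "),
    paste(sprintf("%s=%d", SIM_DATASETS[names(n_sv)], n_sv), collapse = " ")))
  invisible(x)
}
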