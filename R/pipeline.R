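# End-to-end orchestration: filter -> annotate -> summarize -> compare ->
# load -> select -> enrich, with validation and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param genome FASTA path.
#' @param mask BED path of callable intervals (effective-length source).
#' @param gff3 Gene-model GFF3 path.
#' @param obo Ontology OBO path.
#' @param gene2go Two-column gene-to-term TSV path.
#' @param smv Named list of SMV VCF paths: `AA`, `BB`, `AB`, `BA`.
#' @param sv Named list of SV VCF paths, same names.
#' @param region [region_config()].
#' @param filter [filter_config()].
#' @param selection List with `p` (quantile, default 0.5) and `strict`.
#' @param enrichment List with `alpha` (default 0.001) and `method`
#'   (default "weight").
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, mask, gff3, obo, gene2go,
                            smv, sv,
                            region = region_config(),
                            filter = filter_config(),
                            selection = list(p = 0.5, strict = TRUE),
                            enrichment = list(alpha = 0.001,
                                              method = "weight"),
                            seed = 1L) {
  cfg <- list(genome = genome, mask = mask, gff3 = gff3, obo = obo,
              gene2go = gene2go, smv = smv, sv = sv, region = region,
              filter = filter, selection = selection,
              enrichment = enrichment, seed = seed)
  need <- c("AA", "BB", "AB", "BA")
  if (!all(need %in% names(smv)) || !all(need %in% names(sv))) {
    stop_config("smv and sv must name the four categories AA, BB, AB, BA")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration for a written simulation bundle
#'
#' Convenience constructor pointing a [pipeline_config()] at the files of a
#' [simulate_bundle()] written with `out_dir`.
#'
#' @param bundle_dir Directory a bundle was written to.
#' @param ... Passed to [pipeline_config()].
#' @export
bundle_pipeline_config <- function(bundle_dir, ...) {
  p <- function(f) file.path(bundle_dir, f)
  pipeline_config(
    genome = p("genome.fa"), mask = p("callable.bed"), gff3 = p("genes.gff3"),
    obo = p("ontology.obo"), gene2go = p("gene2go.tsv"),
    smv = list(AA = p("smv_AA.vcf"), BB = p("smv_BB.vcf"),
               AB = p("smv_AB.vcf"), BA = p("smv_BA.vcf")),
    sv = list(AA = p("sv_AA.vcf"), BB = p("sv_BB.vcf"),
              AB = p("sv_AB.vcf"), BA = p("sv_BA.vcf")),
    ...)
}

#' Validate pipeline inputs
#'
#' Checks that the referenced files exist and parse, that VCF and GFF3
#' coordinates fall on genome scaffolds, and that the GO map covers genes;
#' genes without GO terms are warnings (they are excluded from the
#' enrichment universe), coordinate-system mismatches are errors.
#'
#' @param config A [pipeline_config()].
#' @return Data frame of class `validation_report` with `level`
#'   (`error`/`warning`) and `message`; zero error rows means valid.
#' @export
validate_inputs <- function(config) {
  rows <- list()
  add <- function(level, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(level = level, message = msg,
                                             stringsAsFactors = FALSE)
  }
  files <- c(genome = config$genome, mask = config$mask, gff3 = config$gff3,
             obo = config$obo, gene2go = config$gene2go,
             unlist(config$smv), unlist(config$sv))
  for (nm in names(files)) {
    if (!file.exists(files[[nm]])) {
      add("error", sprintf("missing file (%s): %s", nm, files[[nm]]))
    }
  }
  if (length(rows) == 0L) {
    genome <- tryCatch(Biostrings::readDNAStringSet(config$genome),
                       error = function(e) NULL)
    if (is.null(genome)) {
      add("error", "genome FASTA failed to parse")
    } else {
      scf <- names(genome)
      scf <- sub("\\s.*$", "", scf)
      models <- tryCatch(normalize_gene_models(config$gff3),
                         error = function(e) NULL)
      if (is.null(models)) {
        add("error", "gene-model GFF3 failed to parse")
      } else {
        bad <- setdiff(unique(models$genes$scaffold), scf)
        if (length(bad)) {
          add("error", sprintf("GFF3 scaffold(s) absent from FASTA: %s",
                               paste(bad, collapse = ",")))
        }
        g2g <- tryCatch(read_gene2go(config$gene2go),
                        error = function(e) NULL)
        if (is.null(g2g)) {
          add("error", "gene2go TSV failed to parse")
        } else {
          no_go <- setdiff(models$genes$gene_id, names(g2g))
          if (length(no_go)) {
            add("warning",
                sprintf("%d gene(s) without GO terms (excluded from universe)",
                        length(no_go)))
          }
        }
      }
      dag <- tryCatch(read_obo(config$obo), error = function(e) NULL)
      if (is.null(dag)) add("error", "OBO ontology failed to parse")
      for (cat in names(config$smv)) {
        v <- tryCatch(VariantAnnotation::readVcf(config$smv[[cat]]),
                      error = function(e) NULL)
        if (is.null(v)) {
          add("error", sprintf("SMV VCF %s failed to parse", cat))
        } else if (length(v) > 0L) {
          vs <- unique(as.character(GenomeInfoDb::seqnames(
            SummarizedExperiment::rowRanges(v))))
          bad <- setdiff(vs, scf)
          if (length(bad)) {
            add("error", sprintf("SMV VCF %s scaffold(s) absent from FASTA: %s",
                                 cat, paste(bad, collapse = ",")))
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), message = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Run the comparative analysis on in-memory inputs
#'
#' The computational core of [run_pipeline()]: takes parsed inputs, returns
#' every analysis table. All stages are deterministic.
#'
#' @param genome Named `DNAStringSet`.
#' @param mask `GRanges` of callable intervals.
#' @param index A [build_region_index()] result.
#' @param smv_sets Named list (`AA`, `BB`, `AB`, `BA`) of filtered SMV data
#'   frames.
#' @param sv_sets Named list of filtered SV data frames.
#' @param dag An `ontology_dag`.
#' @param gene2go Named gene-to-terms list.
#' @param selection,enrichment As in [pipeline_config()].
#' @return List with `summary`, `effects`, `effect_distribution`,
#'   `location`, `gene_hits`, `sharing`, `load`, `candidates`,
#'   `enrichment` components.
#' @export
run_bundle_analysis <- function(genome, mask, index, smv_sets, sv_sets,
                                dag, gene2go,
                                selection = list(p = 0.5, strict = TRUE),
                                enrichment = list(alpha = 0.001,
                                                  method = "weight")) {
  cats <- c("AA", "BB", "AB", "BA")
  total_len <- sum(as.numeric(index$seqlens))
  eff_len <- effective_length(mask)
  gcov <- genome_coverage(index)

  summaries <- lapply(cats, function(cat)
    summarize_dataset(smv_sets[[cat]], total_len, eff_len))
  names(summaries) <- cats
  summary_df <- do.call(rbind, lapply(cats, function(cat) {
    s <- summaries[[cat]]
    data.frame(category = cat, n_processed = s$n_processed,
               n_multiallelic = s$n_multiallelic, n_snp = s$n_snp,
               n_ins = s$n_ins, n_del = s$n_del,
               n_sv = nrow(sv_sets[[cat]]),
               genome_total_length = s$genome_total_length,
               effective_length = s$effective_length,
               rate_bases = s$rate_bases, stringsAsFactors = FALSE)
  }))

  effects <- lapply(cats, function(cat)
    annotate_effects(smv_sets[[cat]], sv_sets[[cat]], index, genome))
  names(effects) <- cats
  eff_dist <- lapply(effects, effect_distribution)
  loc <- lapply(effects, function(e) location_distribution(e, gcov))
  hits <- lapply(effects, function(e)
    gene_hit_proportions(e, index$genes$gene_id))

  sharing <- lapply(names(COMPARISON_PAIRINGS), function(intra_cat) {
    inter_cat <- COMPARISON_PAIRINGS[[intra_cat]]
    classify_sharing(smv_sets[[intra_cat]], smv_sets[[inter_cat]],
                     sv_sets[[intra_cat]], sv_sets[[inter_cat]])
  })
  names(sharing) <- names(COMPARISON_PAIRINGS)

  variant_sets <- lapply(cats, function(cat)
    list(smv = smv_sets[[cat]], sv = sv_sets[[cat]]))
  names(variant_sets) <- cats
  load <- mutation_load(variant_sets, index)
  candidates <- select_candidate_genes(load, p = selection$p %||% 0.5,
                                       strict = selection$strict %||% TRUE)

  enr <- lapply(cats, function(cat) {
    study <- candidates[[cat]]
    if (length(study) == 0L) return(NULL)
    res <- go_enrichment(dag, gene2go, study,
                         method = enrichment$method %||% "weight")
    rep <- enrichment_report(res, alpha = enrichment$alpha %||% 0.001)
    if (nrow(rep)) cbind(category = cat, rep) else NULL
  })
  enr <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])

  list(summary = summary_df, effects = effects,
       effect_distribution = eff_dist, location = loc, gene_hits = hits,
       sharing = sharing, load = load, candidates = candidates,
       enrichment = enr)
}

#' Run the full pipeline from files
#'
#' Validates inputs, loads them, runs [run_bundle_analysis()], writes the
#' eight analysis artifacts plus a JSON manifest (input checksums, effective
#' parameters, artifact checksums) to `out_dir`. Reruns on identical inputs
#' are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The analysis list (invisibly), with `manifest` added.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- validate_inputs(config)
  if (any(report$level == "error")) {
    stop_config("input validation failed: %s",
                paste(report$message[report$level == "error"],
                      collapse = "; "))
  }
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  mask <- rtracklayer::import(config$mask, format = "bed")
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  index <- build_region_index(config$gff3, seqlens, config$region)
  dag <- read_obo(config$obo)
  gene2go <- read_gene2go(config$gene2go)

  cats <- c("AA", "BB", "AB", "BA")
  smv_sets <- list(); sv_sets <- list()
  filter_reports <- list()
  for (cat in cats) {
    r1 <- read_and_filter_smv(config$smv[[cat]], config$filter)
    r2 <- read_and_filter_sv(config$sv[[cat]], config$filter)
    smv_sets[[cat]] <- r1$variants
    sv_sets[[cat]] <- r2$variants
    filter_reports[[cat]] <- list(smv = r1$report, sv = r2$report)
  }

  res <- run_bundle_analysis(genome, mask, index, smv_sets, sv_sets,
                             dag, gene2go, config$selection,
                             config$enrichment)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  artifacts <- c(
    summary = "summary.tsv", effect_distribution = "effect_distribution.tsv",
    location = "location_distribution.tsv",
    gene_hits = "gene_hit_proportions.tsv", sharing = "sharing_labels.tsv",
    load = "mutation_load.tsv", candidates = "candidate_genes.tsv",
    enrichment = "enrichment.tsv")

  write_tsv(res$summary, p(artifacts[["summary"]]),
            comment = "per-dataset variant summary")
  ed <- do.call(rbind, lapply(cats, function(cat) {
    d <- res$effect_distribution[[cat]]
    rbind(data.frame(category = cat, group = "impact",
                     class = d$impact$impact, count = d$impact$count,
                     pct = d$impact$pct, stringsAsFactors = FALSE),
          data.frame(category = cat, group = "coding",
                     class = d$coding$consequence, count = d$coding$count,
                     pct = d$coding$pct, stringsAsFactors = FALSE))
  }))
  write_tsv(ed, p(artifacts[["effect_distribution"]]),
            comment = "impact and coding-consequence distribution")
  loc <- do.call(rbind, lapply(cats, function(cat)
    cbind(category = cat, res$location[[cat]])))
  write_tsv(loc, p(artifacts[["location"]]),
            comment = "variant location distribution vs genome coverage")
  gh <- do.call(rbind, lapply(cats, function(cat)
    cbind(category = cat, res$gene_hits[[cat]])))
  write_tsv(gh, p(artifacts[["gene_hits"]]),
            comment = "proportion of genes with a variant per region class")
  sh <- do.call(rbind, lapply(names(res$sharing), function(intra_cat) {
    s <- res$sharing[[intra_cat]]
    rbind(cbind(pairing = intra_cat, side = "intra", s$intra),
          cbind(pairing = intra_cat, side = "inter", s$inter))
  }))
  write_tsv(sh, p(artifacts[["sharing"]]),
            comment = "per-position sharing labels")
  write_tsv(res$load, p(artifacts[["load"]]),
            comment = "per-gene mutation loads")
  cand <- do.call(rbind, lapply(names(res$candidates), function(cat) {
    g <- res$candidates[[cat]]
    if (length(g) == 0L) return(NULL)
    data.frame(category = cat, gene_id = g, stringsAsFactors = FALSE)
  }))
  write_tsv(cand %||% data.frame(category = character(0),
                                 gene_id = character(0)),
            p(artifacts[["candidates"]]),
            comment = "candidate genes above the load quantile")
  write_tsv(res$enrichment %||%
              data.frame(category = character(0), term = character(0)),
            p(artifacts[["enrichment"]]),
            comment = "enriched GO terms at the configured cutoff")

  manifest <- list(
    package = "crossvar",
    version = as.character(utils::packageVersion("crossvar")),
    seed = config$seed,
    parameters = list(
      region = unclass(config$region), filter = unclass(config$filter),
      selection = config$selection, enrichment = config$enrichment),
    inputs = as.list(tools::md5sum(c(config$genome, config$mask, config$gff3,
                                     config$obo, config$gene2go,
                                     unlist(config$smv), unlist(config$sv)))),
    filter_reports = filter_reports,
    artifacts = as.list(tools::md5sum(file.path(out_dir, artifacts))),
    validation_warnings = report$message[report$level == "warning"])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
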