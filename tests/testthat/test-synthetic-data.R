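# The simulator: ontology, genome, gene models, planted variants.

test_that("generated ontologies are single-rooted, acyclic and reachable", {
  cfg <- sim_config(seed = 7, n_go_terms = 10, dag_depth = 3)
  dag <- generate_ontology(cfg)
  expect_length(dag$terms, 10L)
  expect_length(dag$root, 1L)
  # every non-root term has at least one parent and reaches the root
  for (t in setdiff(dag$terms, dag$root)) {
    expect_gte(length(dag$parents[[t]]), 1L)
    expect_true(dag$root %in% go_ancestors(dag, t))
  }
  # topological order exists (no NA levels = acyclic, all reachable)
  lv <- crossvar:::dag_levels(dag)
  expect_false(anyNA(lv))
  expect_true(all(lv[unlist(dag$parents)] <
                    rep(lv[names(dag$parents)], lengths(dag$parents))))

  # degenerate single-term ontology
  dag1 <- generate_ontology(sim_config(n_go_terms = 1))
  expect_equal(dag1$terms, dag1$root)
  expect_length(dag1$parents[[dag1$root]], 0L)
})

test_that("identical configs give byte-identical OBO files", {
  cfg <- sim_config(seed = 11, n_go_terms = 18, dag_depth = 3)
  p1 <- tempfile(); p2 <- tempfile()
  write_obo(generate_ontology(cfg), p1)
  write_obo(generate_ontology(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("genomes have uppercase ACGTN and a complementary mask", {
  cfg <- sim_config(seed = 3, n_scaffolds = 2, scaffold_length = 20000)
  g <- generate_genome(cfg)
  chars <- as.character(g$genome)
  expect_false(any(grepl("[^ACGTN]", chars)))
  n_count <- sum(vapply(strsplit(chars, ""), function(x) sum(x == "N"),
                        numeric(1)))
  expect_equal(effective_length(g$mask), sum(nchar(chars)) - n_count)

  # no gaps requested: fully callable
  g0 <- generate_genome(sim_config(seed = 3, n_gap_rate = 0,
                                   n_scaffolds = 1,
                                   scaffold_length = 5000))
  expect_equal(effective_length(g0$mask), 5000)
})

test_that("a single 15 bp gap leaves 985 callable bases of 1000", {
  s <- paste0(strrep("A", 500), strrep("N", 15), strrep("G", 485))
  contigs <- break_scaffolds(s)
  expect_equal(sum(contigs), 985)
})

test_that("gene models are valid: ORFs, phases, non-overlap, GO fractions", {
  b <- shared_bundle()
  m <- b$models
  code <- Biostrings::GENETIC_CODE
  for (txid in m$transcripts$transcript_id) {
    cds <- m$cds[m$cds$transcript_id == txid, ]
    cds <- cds[order(cds$start), ]
    pieces <- vapply(seq_len(nrow(cds)), function(j)
      as.character(Biostrings::subseq(b$genome[[cds$scaffold[1]]],
                                      cds$start[j], cds$end[j])),
      character(1))
    seq <- paste(pieces, collapse = "")
    if (cds$strand[1] == "-") {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    }
    expect_equal(nchar(seq) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    # phase of the first transcription-order CDS piece is 0
    first <- if (cds$strand[1] == "+") which.min(cds$start) else
      which.max(cds$start)
    expect_equal(cds$phase[first], 0L)
  }
  # gene bodies do not overlap
  genes <- m$genes
  for (scf in unique(genes$scaffold)) {
    gs <- genes[genes$scaffold == scf, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1) {
      expect_true(all(gs$start[-1] > gs$end[-nrow(gs)]))
    }
  }
  # annotated fraction honours the config
  n_annot <- round((1 - b$config$fraction_unannotated) * nrow(genes))
  expect_equal(length(b$gene2go), n_annot)
  expect_true(all(lengths(b$gene2go) >= 1))
})

test_that("GFF3 round-trips through the standard parser", {
  b <- shared_bundle()
  dir <- shared_bundle_dir()
  models2 <- crossvar:::normalize_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(models2$genes$gene_id, b$models$genes$gene_id)
  g1 <- b$models$genes[order(b$models$genes$gene_id), ]
  g2 <- models2$genes[order(models2$genes$gene_id), ]
  expect_equal(g2$start, g1$start)
  expect_equal(g2$end, g1$end)
  expect_equal(g2$strand, g1$strand)
  expect_equal(nrow(models2$exons), nrow(b$models$exons))
  expect_equal(nrow(models2$cds), nrow(b$models$cds))
})

test_that("VCF record counts equal ground-truth rows per dataset", {
  b <- shared_bundle()
  dir <- shared_bundle_dir()
  map <- c(intra_A = "AA", intra_B = "BB", inter_AB = "AB", inter_BA = "BA")
  for (ds in names(map)) {
    smv_vcf <- VariantAnnotation::readVcf(
      file.path(dir, sprintf("smv_%s.vcf", map[[ds]])))
    sv_vcf <- VariantAnnotation::readVcf(
      file.path(dir, sprintf("sv_%s.vcf", map[[ds]])))
    truth_n <- sum(b$truth$dataset == ds)
    expect_equal(length(smv_vcf) + length(sv_vcf), truth_n)
    # VCFs are position-sorted within scaffold
    rr <- SummarizedExperiment::rowRanges(smv_vcf)
    pos <- GenomicRanges::start(rr)
    scf <- as.character(GenomicRanges::seqnames(rr))
    expect_false(is.unsorted(order(scf, pos)))
    for (s in unique(scf)) expect_false(is.unsorted(pos[scf == s]))
  }
})

test_that("zero intensities give header-only VCFs and empty truth", {
  zero <- lapply(list(SNP = 0, INS = 0, DEL = 0), identity)
  cfg <- sim_config(
    seed = 2, n_scaffolds = 1, scaffold_length = 40000, n_genes = 5,
    n_go_terms = 8, dag_depth = 2,
    smv_per_kbp = list(intra_A = unlist(zero), intra_B = unlist(zero),
                       inter_AB = unlist(zero), inter_BA = unlist(zero)),
    sv_per_mbp = list(
      intra_A = c(DEL = 0, DUP = 0, INV = 0, TRA = 0, INS = 0),
      intra_B = c(DEL = 0, DUP = 0, INV = 0, TRA = 0, INS = 0),
      inter_AB = c(DEL = 0, DUP = 0, INV = 0, TRA = 0, INS = 0),
      inter_BA = c(DEL = 0, DUP = 0, INV = 0, TRA = 0, INS = 0)),
    enrichment_multiplier = 1)
  dir <- tempfile()
  b <- simulate_bundle(cfg, out_dir = dir)
  expect_true(all(vapply(b$smv, nrow, integer(1)) == 0))
  expect_true(all(vapply(b$sv, nrow, integer(1)) == 0))
  expect_true(is.null(b$truth) || nrow(b$truth) == 0)
  v <- VariantAnnotation::readVcf(file.path(dir, "smv_AA.vcf"))
  expect_equal(length(v), 0L)
})

test_that("identical-fraction 1 re-emits every intra position identically", {
  cfg <- sim_config(seed = 9, n_scaffolds = 1, scaffold_length = 30000,
                    n_genes = 8, n_go_terms = 10,
                    sharing = c(identical = 1, nonidentical = 0),
                    qual_fail_fraction = 0)
  b <- simulate_bundle(cfg)
  intra <- b$smv$intra_A
  inter <- b$smv$inter_AB
  key <- function(d) paste(d$scaffold, d$pos, d$alt)
  expect_true(all(key(intra) %in% key(inter)))
  expect_true(all(b$truth$sharing[b$truth$dataset == "intra_A" &
                                    b$truth$class == "SMV"] == "IDENTICAL"))
})

test_that("planted terms multiply member-gene loads over clean background", {
  cfg <- sim_config(seed = 21, n_scaffolds = 6, scaffold_length = 100000,
                    n_genes = 60, n_go_terms = 30,
                    n_enriched_genes = 20, enrichment_multiplier = 10)
  b <- simulate_bundle(cfg)
  members <- b$enriched_genes[[b$enriched$term[1]]]
  expect_length(members, 20L)
  expect_true(b$enriched$term[1] %in% b$dag$terms)
  loads <- b$loads[b$loads$category == "AB", ]
  genes <- b$models$genes
  flank <- 5000L
  reg <- data.frame(scaffold = genes$scaffold,
                    lo = genes$start - flank, hi = genes$end + flank,
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  enr_reg <- reg[reg$gene_id %in% members, ]
  clean_bg <- vapply(seq_len(nrow(reg)), function(i) {
    if (reg$gene_id[i] %in% members) return(FALSE)
    !any(enr_reg$scaffold == reg$scaffold[i] &
           enr_reg$lo <= reg$hi[i] & enr_reg$hi >= reg$lo[i])
  }, logical(1))
  mean_members <- mean(loads$total[loads$gene_id %in% members])
  mean_bg <- mean(loads$total[loads$gene_id %in% reg$gene_id[clean_bg]])
  ratio <- mean_members / mean_bg
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("every ground-truth row describes exactly one VCF record", {
  b <- shared_bundle()
  expect_false(any(duplicated(paste(b$truth$dataset, b$truth$record))))
  # planted enriched terms are a subset of the ontology
  expect_true(all(b$enriched$term %in% b$dag$terms))
})

test_that("identical configs give byte-identical bundles on disk", {
  cfg <- sim_config(seed = 33, n_scaffolds = 1, scaffold_length = 30000,
                    n_genes = 6, n_go_terms = 10)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_bundle(cfg, out_dir = d1)
  simulate_bundle(cfg, out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(n_go_terms = 0), "n_go_terms")
  expect_error(sim_config(dag_depth = 1), "dag_depth")
  expect_error(sim_config(scaffold_length = 500), "kbp")
  expect_error(sim_config(sharing = c(identical = 0.8, nonidentical = 0.4)),
               "sharing")
  expect_error(sim_config(qual_fail_fraction = 1.2), "fraction")
  bad <- sim_config()
  bad$smv_per_kbp$intra_A[["SNP"]] <- -1
  expect_error(crossvar:::validate_sim_config(bad), "intensities")
})
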