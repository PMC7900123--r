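# Variant typing, filtering, effect annotation and summary statistics.

test_that("allele pairs classify into SNP/INS/DEL with MNP decomposition", {
  expect_equal(classify_smv("A", "T"), "SNP")
  expect_equal(classify_smv("A", "AT"), "INS")
  expect_equal(classify_smv("AT", "A"), "DEL")
  expect_equal(classify_smv("ACG", "ATT"), c("SNP", "SNP"))
  expect_error(classify_smv("A", "<DEL>"), "symbolic")
})

test_that("quality filtering keeps records at or above the threshold", {
  dir <- tempfile(); dir.create(dir)
  seqlens <- c(s1 = 1000L)
  smv <- data.frame(record = c("r1", "r2", "r3"), scaffold = "s1",
                    pos = c(10L, 20L, 30L), ref = "A", alt = "T",
                    alt2 = NA_character_, qual = c(29.9, 30, 31),
                    stringsAsFactors = FALSE)
  path <- file.path(dir, "q.vcf")
  write_smv_vcf(smv, path, seqlens)
  res <- read_and_filter_smv(path, filter_config(min_qual = 30))
  expect_equal(res$report$kept, 2L)
  expect_equal(res$report$dropped, 1L)
  expect_setequal(res$variants$record, c("r2", "r3"))

  # empty VCF round-trips to an empty set
  empty_path <- file.path(dir, "empty.vcf")
  write_smv_vcf(smv[0, ], empty_path, seqlens)
  res0 <- read_and_filter_smv(empty_path)
  expect_equal(nrow(res0$variants), 0L)
  expect_equal(res0$report$kept, 0L)
})

test_that("filtered record count equals a direct recount on random QUALs", {
  set.seed(31)
  n <- 100
  smv <- data.frame(record = sprintf("r%03d", 1:n), scaffold = "s1",
                    pos = sort(sample.int(5000, n)), ref = "A", alt = "T",
                    alt2 = NA_character_,
                    qual = round(runif(n, 0, 60), 2),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_smv_vcf(smv, path, c(s1 = 6000L))
  res <- read_and_filter_smv(path, filter_config(min_qual = 30))
  expect_equal(res$report$kept, sum(smv$qual >= 30))
})

test_that("SV filters: support always, length only for DEL/INV/DUP", {
  sv <- data.frame(
    id = sprintf("sv%d", 1:5), scaffold = "s1",
    start = c(100L, 600L, 1200L, 2000L, 3000L),
    end = c(398L, 1100L, 1200L, 2000L, 3500L),
    svtype = c("DEL", "DEL", "TRA", "INS", "DUP"),
    support = c(10L, 10L, 5L, 4L, 8L),
    scaffold2 = c(NA, NA, "s2", NA, NA),
    pos2 = c(NA, NA, 50L, NA, NA), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(sv, path, c(s1 = 5000L, s2 = 5000L))
  res <- read_and_filter_sv(path, filter_config())
  kept <- res$variants
  expect_false("sv1" %in% kept$id)       # DEL length 299: dropped
  expect_true("sv2" %in% kept$id)        # DEL length 501: kept
  expect_true(any(kept$svtype == "TRA")) # TRA support 5, no length: kept
  expect_false("sv4" %in% kept$id)       # INS support 4: dropped
  expect_true("sv5" %in% kept$id)        # DUP length 501: kept
  # the BND mate pair collapsed to one TRA event with both breakends
  tra <- kept[kept$svtype == "TRA", ]
  expect_equal(nrow(tra), 1L)
  expect_equal(tra$scaffold2, "s2")
})

test_that("coding SNP consequences follow the genetic code on both strands", {
  # plus-strand gene: CDS 'ATG AAA TAA' at s1:101-109
  seq <- paste0(strrep("C", 100), "ATGAAATAA", strrep("C", 91))
  genome <- Biostrings::DNAStringSet(c(s1 = seq))
  models <- list(
    genes = data.frame(gene_id = "g1", scaffold = "s1", start = 101L,
                       end = 109L, strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1",
                             scaffold = "s1", start = 101L, end = 109L,
                             strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = "t1", start = 101L, end = 109L,
                       stringsAsFactors = FALSE),
    cds = data.frame(transcript_id = "t1", start = 101L, end = 109L,
                     stringsAsFactors = FALSE))
  idx <- build_region_index(models, c(s1 = 200L))
  mk <- function(pos, ref, alt) data.frame(
    record = "r1", scaffold = "s1", pos = pos, ref = ref, alt = alt,
    qual = 50, multiallelic = FALSE, type = "SNP", stringsAsFactors = FALSE)
  # codon 2 AAA -> TAA: gained stop
  eff <- annotate_effects(mk(104L, "A", "T"), NULL, idx, genome)
  g <- eff[!is.na(eff$gene_id), ]
  expect_equal(g$coding_consequence, "NONSENSE")
  expect_equal(g$impact, "HIGH")
  # codon 2 AAA -> AAG: both Lys
  eff <- annotate_effects(mk(106L, "A", "G"), NULL, idx, genome)
  g <- eff[!is.na(eff$gene_id), ]
  expect_equal(g$coding_consequence, "SILENT")
  expect_equal(g$impact, "LOW")
  # codon 2 AAA -> ACA: Lys -> Thr
  eff <- annotate_effects(mk(105L, "A", "C"), NULL, idx, genome)
  g <- eff[!is.na(eff$gene_id), ]
  expect_equal(g$coding_consequence, "MISSENSE")
  expect_equal(g$impact, "MODERATE")
  # REF mismatch with the genome is an integrity error
  expect_error(annotate_effects(mk(104L, "G", "T"), NULL, idx, genome),
               "disagrees")

  # the mirrored minus-strand gene gives the same consequences
  L <- 200L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  genome_m <- Biostrings::DNAStringSet(c(s1 = rc))
  models_m <- mirror_models(models, L)
  idx_m <- build_region_index(models_m, c(s1 = L))
  flip_pos <- function(p) L - p + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (case in list(list(104L, "A", "T", "NONSENSE"),
                    list(106L, "A", "G", "SILENT"),
                    list(105L, "A", "C", "MISSENSE"))) {
    eff <- annotate_effects(
      mk(flip_pos(case[[1]]), unname(comp[case[[2]]]),
         unname(comp[case[[3]]])), NULL, idx_m, genome_m)
    g <- eff[!is.na(eff$gene_id), ]
    expect_equal(g$coding_consequence, case[[4]])
  }
})

test_that("non-coding variants are MODIFIER; coding InDels split by frame", {
  b <- shared_bundle()
  idx <- shared_index()
  # intron SNP outside the splice core
  regions <- idx$regions
  intr <- regions[regions$class == "INTRON"][1]
  pos <- GenomicRanges::start(intr) + 5L
  scf <- as.character(GenomicRanges::seqnames(intr))
  ref <- as.character(Biostrings::subseq(b$genome[[scf]], pos, pos))
  smv <- data.frame(record = "i1", scaffold = scf, pos = pos, ref = ref,
                    alt = setdiff(c("A", "C"), ref)[1], qual = 50,
                    multiallelic = FALSE, type = "SNP",
                    stringsAsFactors = FALSE)
  eff <- annotate_effects(smv, NULL, idx, b$genome)
  expect_true(all(eff$impact == "MODIFIER" | eff$region != "INTRON"))
  row <- eff[eff$region == "INTRON", ][1, ]
  expect_equal(row$impact, "MODIFIER")
  expect_equal(row$coding_consequence, "NONE")

  # frameshifting vs in-frame InDel in a CDS
  cds <- regions[regions$class == "CODING"][1]
  cpos <- GenomicRanges::start(cds) + 3L
  cscf <- as.character(GenomicRanges::seqnames(cds))
  cref <- as.character(Biostrings::subseq(b$genome[[cscf]], cpos, cpos))
  ins1 <- data.frame(record = "d1", scaffold = cscf, pos = cpos, ref = cref,
                     alt = paste0(cref, "GG"), qual = 50,
                     multiallelic = FALSE, type = "INS",
                     stringsAsFactors = FALSE)
  ins3 <- ins1
  ins3$alt <- paste0(cref, "GGG")
  e1 <- annotate_effects(ins1, NULL, idx, b$genome)
  e3 <- annotate_effects(ins3, NULL, idx, b$genome)
  expect_true("HIGH" %in% e1$impact[e1$region == "CODING"])
  expect_true("MODERATE" %in% e3$impact[e3$region == "CODING"])
})

test_that("dataset summaries reproduce printed rate arithmetic", {
  expect_equal(variant_rate(4105604, 906396323), 220)
  expect_equal(variant_rate(356428, 905543956), 2540)
  expect_equal(variant_rate(1, 100), 100)
  expect_true(is.na(variant_rate(0, 100)))

  # a multi-allelic row types per alt but counts once as a record
  smv <- data.frame(
    record = c("r1", "r1", "r2"), scaffold = "s1", pos = c(5L, 5L, 9L),
    ref = c("A", "A", "G"), alt = c("T", "AT", "GA"),
    qual = 50, multiallelic = c(TRUE, TRUE, FALSE),
    type = c("SNP", "INS", "INS"), stringsAsFactors = FALSE)
  s <- summarize_dataset(smv, 1000, 900)
  expect_equal(s$n_processed, 2L)
  expect_equal(s$n_multiallelic, 1L)
  expect_equal(s$n_snp, 1L)
  expect_equal(s$n_ins, 2L)
  expect_equal(s$n_del, 0L)
  expect_equal(s$rate_bases, 450)
  expect_error(summarize_dataset(smv, 1000, 0))
  expect_error(summarize_dataset(smv, 1000, 2000))
})

test_that("type counts equal a naive per-alt recount on a simulated set", {
  b <- shared_bundle()
  smv <- b$smv$inter_AB
  df <- data.frame(record = smv$record, scaffold = smv$scaffold,
                   pos = smv$pos, ref = smv$ref, alt = smv$alt,
                   qual = smv$qual,
                   multiallelic = !is.na(smv$alt2), stringsAsFactors = FALSE)
  extra <- df[!is.na(smv$alt2), ]
  extra$alt <- smv$alt2[!is.na(smv$alt2)]
  df <- rbind(df, extra)
  s <- summarize_dataset(df, sum(b$seqlens), effective_length(b$mask))
  naive <- table(unlist(lapply(seq_len(nrow(df)), function(i)
    classify_smv(df$ref[i], df$alt[i]))))
  expect_equal(s$n_snp, unname(naive[["SNP"]]))
  expect_equal(s$n_ins, unname(naive[["INS"]]))
  expect_equal(s$n_del, unname(naive[["DEL"]]))
  expect_equal(s$n_processed, length(unique(df$record)))
})

test_that("effect distributions reproduce printed percentage arithmetic", {
  d <- effect_distribution(list(
    impact = c(HIGH = 13761, MODERATE = 84185, LOW = 149561,
               MODIFIER = 8799110),
    coding = c(NONSENSE = 788, MISSENSE = 78503, SILENT = 101260)))
  expect_equal(d$impact$pct[d$impact$impact == "MODIFIER"], 97.26)
  expect_equal(d$coding$pct[d$coding$consequence == "MISSENSE"], 43.48)
  expect_equal(d$coding$pct[d$coding$consequence == "SILENT"], 56.08)
  expect_equal(sum(d$impact$pct), 100, tolerance = 0.02)

  single <- data.frame(impact = "MODIFIER", coding_consequence = "NONE",
                       stringsAsFactors = FALSE)
  ds <- effect_distribution(single)
  expect_equal(ds$impact$pct[ds$impact$impact == "MODIFIER"], 100.00)
  expect_error(effect_distribution(single[0, ]))
})

test_that("location distribution degenerates correctly and flags zero-GCOV", {
  idx <- build_region_index(hand_models(), hand_seqlens())
  gcov <- genome_coverage(idx)
  eff <- data.frame(variant_id = c("v1", "v2"), variant_class = "SMV",
                    type = "SNP", scaffold = "s1", pos = c(11050L, 11060L),
                    gene_id = "gP", labels = "INTRON", region = "INTRON",
                    impact = "MODIFIER", coding_consequence = "NONE",
                    stringsAsFactors = FALSE)
  loc <- location_distribution(eff, gcov)
  expect_equal(loc$fraction[loc$class == "INTRON"], 1)
  expect_true(all(loc$fraction[loc$class != "INTRON"] == 0))

  one <- data.frame(variant_id = "v1", variant_class = "SMV", type = "SNP",
                    scaffold = "s1", pos = 9000L, gene_id = "gP",
                    labels = "PROMOTER", region = "PROMOTER",
                    impact = "MODIFIER", coding_consequence = "NONE",
                    stringsAsFactors = FALSE)
  hp <- gene_hit_proportions(one, "gP")
  expect_equal(hp$proportion[hp$class == "PROMOTER"], 1)
  expect_equal(hp$proportion[hp$class == "CODING"], 0)
})
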