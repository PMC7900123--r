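# Sharing classification, mutation loads and candidate selection.

smv_df <- function(scaffold, pos, alt, record = NULL) {
  data.frame(record = record %||% sprintf("r%d", seq_along(pos)),
             scaffold = rep_len(scaffold, length(pos)), pos = pos,
             ref = rep_len("A", length(pos)), alt = alt,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("position indexing merges alleles at a site", {
  ix <- index_by_position(smv_df("s1", c(100L, 100L), c("T", "G")))
  expect_equal(nrow(ix), 1L)
  expect_setequal(ix$alts[[1]], c("T", "G"))
  expect_equal(nrow(index_by_position(smv_df("s1", integer(0),
                                             character(0)))), 0L)
})

test_that("indexed key count equals the distinct-position count", {
  set.seed(17)
  n <- 1000
  df <- smv_df(sample(c("s1", "s2"), n, TRUE),
               sample.int(2000, n, TRUE),
               sample(c("A", "C", "G", "T"), n, TRUE))
  ix <- index_by_position(df)
  expect_equal(nrow(ix),
               length(unique(paste(df$scaffold, df$pos))))
})

test_that("sharing labels follow the allele-aware position rules", {
  # same position, same alt
  r <- classify_sharing(smv_df("s1", 100L, "T"), smv_df("s1", 100L, "T"))
  expect_equal(r$intra$label, "IDENTICAL")
  expect_equal(r$inter$label, "IDENTICAL")
  # same position, different alt (the A->T within vs A->G between case)
  r <- classify_sharing(smv_df("s1", 100L, "T"), smv_df("s1", 100L, "G"))
  expect_equal(r$intra$label, "NONIDENTICAL")
  expect_equal(r$inter$label, "NONIDENTICAL")
  # only one side has the position
  r <- classify_sharing(smv_df("s1", 100L, "T"),
                        smv_df("s1", integer(0), character(0)))
  expect_equal(r$intra$label, "UNIQUE_INTRA")
  r <- classify_sharing(smv_df("s1", integer(0), character(0)),
                        smv_df("s1", 100L, "T"))
  expect_equal(r$inter$label, "UNIQUE_INTER")
  # disjoint coordinate systems are rejected
  expect_error(classify_sharing(smv_df("s1", 100L, "T"),
                                smv_df("other", 100L, "T")),
               "coordinate system")
})

test_that("sharing matches a quadratic brute-force comparator", {
  set.seed(23)
  for (rep in 1:4) {
    n_a <- sample(200:600, 1)
    n_b <- sample(200:600, 1)
    mk <- function(n) smv_df(sample(c("s1", "s2"), n, TRUE),
                             sample.int(500, n, TRUE),
                             sample(c("A", "C", "G", "T"), n, TRUE))
    a <- mk(n_a); b <- mk(n_b)
    fast <- classify_sharing(a, b)
    slow <- brute_sharing(a, b)
    expect_equal(fast$intra$label[fast$intra$class == "SMV"], slow$intra)
    expect_equal(fast$inter$label[fast$inter$class == "SMV"], slow$inter)
    # label partition: intra side splits the intra set size
    expect_equal(length(slow$intra), nrow(index_by_position(a)))
    # symmetry: swapping sides swaps UNIQUE labels, preserves shared counts
    swapped <- classify_sharing(b, a)
    t1 <- table(factor(fast$intra$label,
                       c("IDENTICAL", "NONIDENTICAL", "UNIQUE_INTRA")))
    t2 <- table(factor(swapped$inter$label,
                       c("IDENTICAL", "NONIDENTICAL", "UNIQUE_INTER")))
    expect_equal(unname(t1[["IDENTICAL"]]), unname(t2[["IDENTICAL"]]))
    expect_equal(unname(t1[["NONIDENTICAL"]]), unname(t2[["NONIDENTICAL"]]))
    expect_equal(unname(t1[["UNIQUE_INTRA"]]), unname(t2[["UNIQUE_INTER"]]))
  }
})

test_that("SV sharing matches on type, start tolerance and overlap", {
  sv <- function(start, end, type, scaffold = "s1")
    data.frame(id = sprintf("v%d", seq_along(start)), scaffold = scaffold,
               start = start, end = end, svtype = type, support = 10L,
               length = end - start + 1, scaffold2 = NA_character_,
               pos2 = NA_integer_, stringsAsFactors = FALSE)
  empty <- smv_df("s1", integer(0), character(0))
  # near-identical deletion: start within 50, reciprocal overlap >= 0.8
  r <- classify_sharing(empty, empty,
                        sv(1000L, 2000L, "DEL"), sv(1040L, 2040L, "DEL"))
  expect_equal(r$intra$label, "IDENTICAL")
  # same start, different type: a different variant at the same location
  r <- classify_sharing(empty, empty,
                        sv(1000L, 2000L, "DEL"), sv(1000L, 2000L, "INV"))
  expect_equal(r$intra$label, "NONIDENTICAL")
  # too far apart
  r <- classify_sharing(empty, empty,
                        sv(1000L, 2000L, "DEL"), sv(1200L, 2200L, "DEL"))
  expect_equal(r$intra$label, "UNIQUE_INTRA")
  # same type nearby but poor reciprocal overlap
  r <- classify_sharing(empty, empty,
                        sv(1000L, 1310L, "DEL"), sv(1040L, 3000L, "DEL"))
  expect_equal(r$intra$label, "NONIDENTICAL")
})

test_that("mutation load counts the gene body plus 5 kbp, once per variant", {
  models <- list(
    genes = data.frame(gene_id = "g1", scaffold = "s1", start = 10000L,
                       end = 20000L, strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "t1", gene_id = "g1",
                             scaffold = "s1", start = 10000L, end = 20000L,
                             strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = "t1", start = 10000L, end = 20000L,
                       stringsAsFactors = FALSE),
    cds = data.frame(transcript_id = "t1", start = 10000L, end = 20000L,
                     stringsAsFactors = FALSE))
  idx <- build_region_index(models, c(s1 = 40000L))
  mk <- function(pos) list(smv = data.frame(
    record = sprintf("r%d", seq_along(pos)), scaffold = "s1", pos = pos,
    stringsAsFactors = FALSE))
  expect_equal(mutation_load(list(AA = mk(5500L)), idx)$smv, 1)
  expect_equal(mutation_load(list(AA = mk(5000L)), idx)$smv, 1)
  expect_equal(mutation_load(list(AA = mk(4999L)), idx)$smv, 0)
  expect_equal(mutation_load(list(AA = mk(25000L)), idx)$smv, 1)
  expect_equal(mutation_load(list(AA = mk(25001L)), idx)$smv, 0)
  # a multi-row record still counts once
  two_alt <- list(smv = data.frame(record = c("r1", "r1"), scaffold = "s1",
                                   pos = c(15000L, 15000L),
                                   stringsAsFactors = FALSE))
  expect_equal(mutation_load(list(AA = two_alt), idx)$smv, 1)
})

test_that("pipeline loads equal the generator's planted loads exactly", {
  b <- shared_bundle()
  idx <- shared_index()
  cats <- c(AA = "intra_A", BB = "intra_B", AB = "inter_AB", BA = "inter_BA")
  variant_sets <- lapply(cats, function(ds) {
    smv <- b$smv[[ds]]
    sv <- b$sv[[ds]]
    smv <- smv[smv$qual >= 30, , drop = FALSE]
    keep <- sv$support >= 5 &
      (!(sv$svtype %in% c("DEL", "DUP", "INV")) |
         (sv$end - sv$start + 1) >= 300)
    sv <- sv[keep, , drop = FALSE]
    sv$length <- ifelse(sv$svtype %in% c("DEL", "DUP", "INV"),
                        sv$end - sv$start + 1, NA_real_)
    list(smv = smv, sv = sv)
  })
  names(variant_sets) <- names(cats)
  got <- mutation_load(variant_sets, idx)
  want <- b$loads
  key <- function(d) d[order(d$gene_id, d$category), c("gene_id", "category",
                                                       "smv", "sv", "total")]
  g <- key(as.data.frame(got))
  w <- key(want)
  rownames(g) <- rownames(w) <- NULL
  expect_equal(g, w)
})

test_that("candidate selection thresholds at the load quantile", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"), category = "AA",
                    smv = c(10, 5, 1), sv = 0, total = c(10, 5, 1),
                    stringsAsFactors = FALSE)
  class(tab) <- c("mutation_load", "data.frame")
  expect_equal(select_candidate_genes(tab)$AA, "g1")
  expect_setequal(select_candidate_genes(tab, strict = FALSE)$AA,
                  c("g1", "g2"))
  ties <- tab
  ties$total <- ties$smv <- 4
  expect_length(select_candidate_genes(ties)$AA, 0L)
  expect_setequal(select_candidate_genes(ties, strict = FALSE)$AA,
                  c("g1", "g2", "g3"))
  zero <- tab
  zero$total <- zero$smv <- 0
  expect_warning(sel <- select_candidate_genes(zero), "zero")
  expect_length(sel$AA, 0L)
  expect_error(select_candidate_genes(tab, p = 1.5))
})

test_that("selection recalls planted high-load genes", {
  set.seed(77)
  n <- 500
  planted <- sprintf("g%03d", 1:50)  # top decile
  loads <- c(rpois(50, 60), rpois(450, 8))
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n), category = "AA",
                    smv = loads, sv = 0, total = loads,
                    stringsAsFactors = FALSE)
  class(tab) <- c("mutation_load", "data.frame")
  sel <- select_candidate_genes(tab)$AA
  recall <- mean(planted %in% sel)
  expect_gte(recall, 0.95)
})
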