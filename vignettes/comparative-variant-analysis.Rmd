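---
title: "Methods: comparative variant analysis between closely related genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`crossvar` implements the downstream half of a two-genome comparison such as
is done for recently diverged species pairs (the worked system is the
Tanganyikan cichlids *Tropheus moorii*, "TM"/"B", and *Petrochromis
trewavasae*, "PT"/"A"): read mapping and variant calling themselves are out
of scope — the package consumes the resulting VCFs. Four call sets are
analysed jointly: reads of each species against its own genome (the
within-species sets, categories **AA** and **BB**) and against the other
species' genome (the between-species sets, **AB** paired with AA on the A
coordinate system, **BA** paired with BB on B's). The pipeline is:

1. **Filter.** Small variants (SMV: SNPs and short InDels) are kept at a
   phred quality of at least 30. Structural variants (SV: deletions,
   duplications, inversions, translocations, insertions) need at least 5
   supporting broken read pairs, and DEL/INV/DUP additionally a length of
   at least 300 bp; translocations and insertions are exempt from the
   length rule because callers report them without a meaningful interval
   length.
2. **Type and summarise.** Per-alternate-allele typing (SNP/INS/DEL, with
   equal-length multi-base pairs decomposed into per-base SNPs), counts of
   multi-allelic records, and the variant rate
   `floor(effective_length / n_records)` in bases per variant. The
   *effective length* is the callable portion of the reference, supplied as
   a mask; it is deliberately an input rather than "total minus N", because
   callability depends on the mapping, not only on the assembly.
3. **Annotate.** A region model assigns every position one or more of
   SPLICE > CODING > 5'UTR > 3'UTR > INTRON > PROMOTER > UPSTREAM >
   DOWNSTREAM > INTERGENIC (the order is the severity used when one label
   must be chosen). Coding SNPs are translated codon-wise
   (reverse-complemented on minus-strand transcripts) into
   NONSENSE/MISSENSE/SILENT, mapped to impact HIGH/MODERATE/LOW; splice-core
   overlaps are HIGH; frameshifting coding InDels HIGH, in-frame ones
   MODERATE; everything else is MODIFIER. One variant yields one effect per
   overlapped gene, so effect counts exceed record counts — mirroring how
   standard effect annotators fan out over gene contexts.
4. **Compare.** Within each legal pairing (AA–AB, BB–BA; enforced, since the
   comparison requires one coordinate system), variants are matched by
   position. Matching is allele-aware: same position and intersecting
   alternate alleles is IDENTICAL, same position but disjoint alleles is
   NONIDENTICAL (the "A→T within, A→G between" case), otherwise
   UNIQUE_INTRA / UNIQUE_INTER. SVs match on type, start within 50 bp and
   reciprocal overlap ≥ 0.8 (configurable; position-only for breakends).
5. **Rank.** Every variant increments the *mutation load* of each gene
   whose region — gene body ± 5 kbp — it intersects, once per gene per
   variant. Per category, genes with load strictly above the load median
   (quantile p = 0.5 over genes with positive load) become candidates.
6. **Enrich.** Candidate sets are tested against the universe of all genes
   with at least one GO annotation using Fisher's exact test with a raw
   cutoff of p ≤ 0.001 and the topology-decorrelating *weight* method.

# Region model parameters

| parameter | default | meaning |
|---|---|---|
| `promoter_up` | 2000 bp | promoter extent upstream of the TSS |
| `promoter_down` | 200 bp | promoter extent past the TSS (may lie inside the transcript) |
| `gene_flank` | 5000 bp | up-/downstream windows, and the mutation-load window |
| `splice_core` | 2 bp | intronic bases at each intron end labelled SPLICE |

Promoter and flank widths are the conventional TSS-window definitions for
this kind of survey. The splice-core width is our own choice — the canonical
donor/acceptor dinucleotides — because no wider consensus window is defined
by the upstream tooling; it is configurable. Two further conventions are
deliberate: the promoter wins over the upstream flank where the windows
would overlap, and promoter bases inside the transcript carry *both* labels
— coverage tallies flatten them into the transcript class (no
double-counting), while per-gene "promoter hit" tallies still register them.
Coordinates are 1-based inclusive at the GFF3/VCF interfaces and 0-based
half-open internally (BED exports follow BED).

# Enrichment: classic, weight, elim

Annotations are first closed under the true-path rule (a gene annotated to
a term is annotated to all its ancestors). The classic test is the
hypergeometric tail. The *weight* method processes terms bottom-up by level
(longest path from the root). At each term it compares the term's locally
computed significance with its already-processed children's: when a child
explains the signal better, the child's genes are down-weighted in the term
and all its ancestors before the term's weighted statistic is recomputed;
when the term beats its children, the children's member genes are
down-weighted instead and their recorded p-values updated. Weighted counts
are rounded before the hypergeometric tail is taken. On a flat ontology
this reduces exactly to the classic test; a parent whose signal is fully
explained by a child ends up at or above its classic p-value. The published
description of the method leaves the significance-ratio function open; we
use the plain p-value ratio. `elim` — removing a significant term's genes
from its ancestors entirely (cutoff 0.01) — is provided as the simpler
alternative. No multiple-testing correction is applied by default, matching
the raw-cutoff convention of this analysis style; a `p.adjust` flag exists.

Terms with fewer than 2 annotated genes in the universe are untestable and
skipped. In the bottom-up traversal, testable descendants reached through
untestable intermediates attach to their nearest testable ancestor.

# The simulator

The simulator exists so the full pipeline is exercisable without any
download: it emits a genome FASTA with N gaps, a BED callability mask,
GFF3 gene models, a minimal OBO ontology, a gene→GO map, eight VCFs (SMV
and SV for the four categories), and ground-truth tables (per-record
sharing labels and region classes, per-gene planted loads, planted terms).
Identical configurations produce byte-identical bundles.

Default intensities mirror the observed magnitudes of the worked system at
reduced scale: between-species SMV densities around one variant per 220 bp
(split ~75% SNP, ~12.5% each InDel class), within-species densities around
one per 2500 (A) and 1560 (B) bp, and SV densities of roughly 100 (between)
and 30–50 (within) per Mbp dominated by deletions. Sharing defaults plant
45% of within-species positions as IDENTICAL re-emissions into the paired
between-species set and 15% as NONIDENTICAL (different allele at the same
position); the between-set intensity parameters govern its *unique*
variants, with re-emissions added on top. Gene models are multi-exon on
both strands with valid ORFs spliced into the genome (so codon-level
consequences are well defined); gene bodies do not overlap in simulation —
a simplification — but the downstream modules tolerate overlap and are
tested on overlapping hand-built fixtures. A configurable fraction of
records is emitted below the quality/support/length filters to exercise
filtering.

Planted enrichment assigns a chosen (by default deepest-leaf) term to a
fixed member set of genes whose regions receive a multiplied variant
intensity (default 6×). The planted term is excluded from the random
annotation draw so its membership is exactly the planted set — an
uncontaminated ground truth; random background annotations draw 1–3 terms
per gene, biased towards deeper terms, and 10% of genes receive no
annotation (testing universe exclusion). The multi-allelic fraction
(0.6%) is a free parameter: upstream callers differ and the source
analysis does not constrain it.

What the simulator does *not* emulate: read-level errors, diploid phasing,
repeat content, assembly artefacts, and a second genuinely different
coordinate system (both pairings live on one reference). Passing tests
therefore demonstrate the correctness of the downstream arithmetic and the
recoverability of planted signal under idealised calls — not robustness to
caller-specific artefacts on real data.

# Recovery experiment and problem sizes

The headline property is parameter recovery: across 20 seeded replicates,
the planted term must be reported at p ≤ 0.001 in the within-A category in
at least 90% of replicates, running the entire file-based pipeline. The
replicate problem size — 4 scaffolds × 100 kbp, 100 genes, a 30-term
ontology — was chosen so one replicate takes a few seconds while the
per-category variant sets stay in the thousands; all effect-size
parameters are the simulator defaults. One geometric constraint matters:
the enriched genes' ±5 kbp regions must cover a minority of the genome,
otherwise the extra intensity spreads over everything and no load contrast
exists to recover. The shared test fixture is smaller still (2 × 40 kbp,
25 genes — too dense for a load contrast by construction) since most tests
check exact arithmetic, not power.

# Numerical choices and edge cases

* Variant rates truncate (`floor`) rather than round — forced by the
  printed arithmetic of the worked system (220 from 220.77); percentages
  round half-up to two decimals.
* Nx/Lx use the inclusive boundary rule: if the descending cumulative sum
  reaches x% exactly at a sequence, that sequence's length is Nx. The
  upstream tool lineage for such tables is rarely stated; the rule is
  documented and tested rather than assumed.
* The k-mer-spectrum genome size is total k-mer mass at or above the
  error-cutoff depth divided by the main peak depth; a spectrum that is
  monotone beyond the cutoff (error-only) is refused rather than guessed
  at.
* The load quantile is taken over genes with positive load only — with
  nearly all genes hit this barely differs from using all genes, but it
  keeps the rule meaningful on sparse fixtures — and thresholding is
  strictly-greater so heavy ties at the median do not select half the
  genome (`strict = FALSE` is one flag away).
* Weighted Fisher p-values are floored at 1e-300 to keep significance
  ratios finite.
* Missing QUAL drops an SMV record (logged); unknown SVTYPE skips an SV
  record with a warning; a VCF REF disagreeing with the genome at a coding
  position is a hard integrity error naming the position.
* Translocations are emitted and consumed as BND mate pairs (MATEID
  convention); a pair is one event — both breakends count for gene
  overlap, but at most once per gene.

# Known limitations

* The IDENTICAL/NONIDENTICAL distinction for SVs uses interval geometry
  (type + tolerance + reciprocal overlap), not breakpoint-resolved alleles.
* Coding consequences are computed per SNP against the reference codon;
  multi-nucleotide haplotype effects within one codon are not composed.
* The region model unions labels across transcripts of a gene; it does not
  model transcript-specific severity.
* Enrichment p-values are reported raw by design; with thousands of terms
  a raw 0.001 cutoff implies a handful of false positives, which the
  type-I simulation in the test suite quantifies loosely.
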