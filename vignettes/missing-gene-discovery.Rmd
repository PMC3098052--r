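---
title: "Discovering missing genes in prokaryotic annotations with orfmiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering missing genes in prokaryotic annotations with orfmiss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfmiss)
```

## The problem

Prokaryotic gene finders systematically struggle with small protein-coding
genes: a short open reading frame (ORF) carries little statistical signal,
and annotation projects often drop short predictions to avoid
over-prediction. A gene family that every gene finder misses leaves the
same trace in every genome: a conserved, unannotated intergenic ORF. The
comparative strategy implemented here exploits that trace. If an
intergenic ORF in genome A aligns strongly to an intergenic ORF in a
distantly related genome B — and to nothing that is already annotated —
conservation across that phylogenetic distance is evidence that both are
real genes missing from their annotations.

`orfmiss` implements this strategy end to end for desk-scale datasets:
ORF enumeration, genomic-context partition, screened all-vs-all protein
alignment, a two-stage classification with a taxonomy filter and
single-linkage clustering, a per-call uniqueness score, and supporting
metrics (GC3, MUM-index genome distance, flank ultra-conservation). A
seeded synthetic pan-genome generator with exact ground truth makes the
whole pipeline testable without any external data.

## The procedure

### 1. Maximal ORFs

For every replicon (chromosome or plasmid), both strands are scanned in
all three frames for ORFs with start codons ATG/GTG/TTG and stop codons
TAA/TAG/TGA. For each in-frame stop codon the *maximal* ORF is kept: the
one anchored at the furthest-upstream start codon with no intervening
in-frame stop. The stored coding interval excludes the stop codon, so the
default 99 bp minimum corresponds exactly to proteins of at least 33
amino acids. Internally all coordinates are 0-based half-open on the
forward strand; every emitted file uses the 1-based inclusive convention.
Two edge policies are deliberate:

* ORFs truncated by a linear replicon end (no stop codon) are discarded —
  without a stop codon they are not maximal ORFs.
* Replicons flagged circular are scanned across the origin and an
  origin-spanning ORF is reported once, with `end` exceeding the replicon
  length (positions taken modulo the length). Linear is the default
  because source records rarely state topology reliably.

### 2. Genomic context

Each ORF is compared with the existing annotation and labelled:

* **annotated** — a gene feature on the same strand shares the ORF's
  stop-codon position. Annotations frequently differ in their chosen
  start codon, so requiring the exact interval would misclassify those
  genes as "overlapping"; sharing the 3' boundary and frame is the right
  notion of "the same gene".
* **entity_overlapping** — any annotated feature (gene, RNA, pseudogene,
  anything) overlaps at least 1 bp of the ORF's span, strand-blind, with
  the stop codon included in the span.
* **intergenic** — no overlap with any annotated entity.

Because maximality prefers the furthest-upstream start, an ORF can
falsely overlap an upstream feature. Such ORFs are *rescued*: the
sequence is rescanned for the 5'-most in-frame start codon that removes
all overlap while keeping at least 99 bp, and the ORF is re-anchored
there and re-classified. Overlap at the stop end cannot be rescued — the
stop is fixed.

### 3. Alignment and screening

Intergenic ORFs become queries; all ORFs (annotated, entity-overlapping
and intergenic) form the subject database, so a conserved intergenic ORF
must out-compete every annotated explanation. Translated queries are
aligned with a Smith-Waterman local aligner (BLOSUM62, affine gaps
11/1); e-values follow the Karlin-Altschul form
$E = K m n e^{-\lambda S}$ with the standard gapped constants
$\lambda = 0.267$, $K = 0.041$, $m$ the query length and $n$ the total
database size. Production-scale runs can instead ingest the 12-column
tabular report of an external search tool; both routes feed the same
screen: e-value at most $10^{-5}$, coverage of **both** query and
subject at least 80% (coverage is aligned span over sequence length),
at most 1000 hits per query (lowest e-values kept), and self-hits
removed — the query set is a subset of the database, so every query
would otherwise trivially "align to an intergenic sequence".

### 4. Two-stage classification

Per query, hits are partitioned by subject context. Hits to intergenic
subjects support a missing call **only when query and subject come from
two different taxonomic families**; close relatives share intergenic
sequence through lack of divergence alone, and family is the lowest rank
that is reasonably stable across prokaryotes. No family requirement
applies to hits against annotated or entity-overlapping subjects, which
makes the missing call conservative: far more evidence can vote against
it than for it.

Stage 1 labels, in order of precedence:

1. **potentially missing** — cross-family intergenic support exists and
   every hit to an annotated gene or entity-overlapping ORF has an
   average percent coverage at least 20 percentage points below that of
   the top-scoring (lowest e-value) intergenic hit;
2. **absent annotation** — otherwise, any hit to an annotated gene: the
   query is a gene that its own genome's annotation missed;
3. **genomic artifact** — otherwise, any hit to an entity-overlapping
   ORF (a shadow-ORF match or an annotation error elsewhere);
4. **unclassified** — no qualifying hits at all.

The 20-point rule is read as absolute percentage points (the quantities
compared are already percentages); "top-scoring" is read as lowest
e-value with ties broken by higher identity. Both readings are package
decisions where the procedure's prose admits two interpretations.

Stage 2 clusters the potentially-missing ORFs by single linkage over
their qualifying alignments (both endpoints must themselves be
potentially missing) and promotes clusters containing **at least two
ORFs from at least two families** to missing-gene groups; members of
failing clusters are demoted to unclassified, with the near-miss reason
reported for triage.

### 5. The uniqueness score

Every missing gene and absent annotation receives
$\alpha = I_1 - I_2$, where $I$ is the average of the percent identity
computed with respect to the query length and with respect to the
subject length, $I_1$ is the best $I$ among supporting alignments and
$I_2$ the best $I$ among conflicting ones ($\alpha = I_1$ when nothing
conflicts). For missing genes every gene or entity hit conflicts; for
absent annotations only entity hits do — a second gene hit supports,
rather than undermines, "this is a real gene". A supporting alignment at
$I_1 = 80$ against a conflicting one at $I_2 = 60$ gives $\alpha = 20$.
Alpha is reported unclamped, so it can in principle be negative for an
absent annotation whose entity evidence outscores its gene evidence.

### 6. Group-level checks

* **MUM index (MUMi)** — a genome distance in $[0,1]$ from maximal exact
  matches that are unique in both sequences (both strands considered,
  minimum 19 bp), greedily tiled longest-first without overlap:
  $1 - L_{\mathrm{mum}} / \bar\ell$ with $\bar\ell$ the mean sequence
  length. Identical genomes score 0. Per group, one representative
  replicon per family (lexicographically smallest id) is chosen and the
  distance averaged over family pairs; a high average confirms the
  conservation spans a real phylogenetic distance rather than recent
  common ancestry.
* **Ultra-conservation** — a group is flagged when the 30 bp flanks
  upstream and downstream of every member (in gene orientation) are
  exactly identical across members. Exact flank identity is equivalent
  to perfectly conserved flanking columns in a multiple alignment, so no
  alignment tool is needed. Such groups may be ORFs embedded in
  conserved non-coding elements and deserve scrutiny.
* **GC3** — the fraction of codons with G or C in the third position,
  informative because short genes in GC-rich taxa often show weaker
  codon bias than long genes.

## The synthetic pan-genome generator

`generate_pangenome()` builds a deterministic toy dataset with exact
ground truth for every label. Its defaults are the package's reference
study conditions: 4 families × 2 replicons of 15 kb, 8 annotated genes
and 2 RNA features per replicon, 10 planted missing-gene families (two
identical copies in two different families, with shared 30 bp flanks),
5 absent-annotation plants (an exact intergenic copy of an annotated
gene from another family), 10 shadow ORFs (a complete reverse-strand ORF
embedded in a carrier gene) each with one intergenic copy planted
elsewhere (the intended genomic artifacts), 2 same-family-only conserved
families that the phylogenetic filter must reject, and mutation rate 0.
A nonzero `mutation_rate` applies per-base substitutions to each planted
copy without ever creating an in-frame stop or destroying the start.

Two constructive devices keep the ground truth exact:

* **Stop cassettes.** Spacer DNA and planted coding sequences are
  interleaved with short cassettes that place stop codons in every
  unintended reading frame at least every ~75 bp. A stray ORF (≥ 99 bp)
  must therefore cross an element boundary, so at most ~75 bp of it can
  be shared between replicons — below the 80% dual-coverage screen.
  Only the cassettes' stop-codon skeleton is fixed; stop choices and
  filler bases are randomised per instance, so cassette copies
  contribute mismatches rather than shared identity and local alignments
  trim back to the genuinely shared region. An in-frame TAA guard
  immediately upstream of every planted ATG pins the scanner's maximal
  start to the planted one, making truth coordinates exact.
* **Joint shadow construction.** The reverse complement of a complete
  shadow ORF is embedded at a codon boundary of its carrier gene,
  resampled until the embedding reads as sense codons in the carrier
  frame; a TTA codon 3' of the embedding reads TAA on the reverse
  strand, pinning the shadow's maximal start.

What the generator does **not** emulate: indels, rearrangements,
codon-model substitution, gene families with more than two planted
copies, operon structure, or realistic GC/codon-usage heterogeneity.
Passing the planted-truth checks therefore demonstrates that the
pipeline's logic is correct under clean conditions, not that its
thresholds are optimal for real genomes.

## Worked example

```{r example}
dataset <- generate_pangenome(seed = 1)
result <- run_pipeline(dataset$replicons, dataset$features,
                       dataset$taxonomy)
as.data.frame(result$summary)
score_against_truth(result, dataset$truth)
head(result$groups[, c("group_id", "n_members", "n_families",
                       "avg_alpha", "avg_mumi", "ultra_conserved")])
```

All 20 planted missing copies and all 5 absent annotations are recovered
with no false calls; every group has $\alpha = 100$ and identical flanks.
The unclassified queries are the same-family plants (rejected by design)
plus boundary-crossing stray ORFs unique to one replicon — exactly the
population the method is built to ignore.

## Numerical and design notes

* **Problem sizes.** The reference synthetic conditions produce roughly
  150 ORFs and 65 queries per run; the test suite's oracle checks use
  100 random 2 kb sequences (ORF scanner), 200 random protein pairs
  (alignment DP) and 50 random graphs (clustering). These sizes were
  chosen to exercise every code path while keeping a full check run in
  well under a minute each.
* **E-value constants** are fixed rather than estimated, so the built-in
  aligner is exactly reproducible; absolute e-values shift with the
  constants but every screening decision at $10^{-5}$ on desk-scale data
  is dominated by the score term.
* **Ties** are always broken deterministically (e-value, then identity,
  then lexicographic id), and group representatives default to the
  smallest member id; a seed restores randomised selection where wanted.
* **Degenerate inputs.** Codons containing N translate to X and never
  act as start or stop codons; empty hit sets flow through every stage;
  a replicon without a taxonomy record is a hard error because the
  family filter is mandatory.
* **Limitations.** The built-in aligner is quadratic and intended for
  desk-scale data — genuine surveys should ingest an external search
  tool's tabular report. MUMi here uses direct k-mer anchoring rather
  than suffix structures, appropriate for toy replicons. The family
  filter inherits the weaknesses of the underlying taxonomy: families
  with unusually diverse or unusually similar genomes bias the missing
  call conservative or permissive, which is why group MUMi is reported
  alongside.
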