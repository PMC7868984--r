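---
title: "Methods: long-read SV post-processing for polyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read SV post-processing for polyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`polysv` — what each stage assumes, which knobs matter, and what the
synthetic-data generator does and does not emulate.

## The analysis model

The package starts from per-sample structural-variant (SV) calls produced
by a long-read caller in the Sniffles dialect (INFO keys `SVTYPE`,
`SVLEN`, `END`, `RE`, `SUPTYPE`; FILTER `PASS`/`UNRESOLVED`). In highly
duplicated allopolyploid genomes a large share of raw calls reflects
reference mis-assembly rather than biology, so the analysis is built
around a deliberately stringent filter followed by cross-sample
consolidation:

1. **Filter** — keep a record iff its type is not in `{TRA, DUP}`, its
   FILTER is `PASS`, its support includes within-alignment (`AL`)
   evidence, and its size lies in [30, 30 000] bp. Translocations and
   duplications are dominated by mis-positioned reference fragments and
   cannot be PCR-validated; split-read-only events are large/complex
   calls that cannot be distinguished from assembly errors. The filter is
   a pointwise predicate, hence idempotent and order-independent. This
   costs sensitivity for genuinely large or complex SVs — a documented,
   accepted bias.
2. **Merge** — records from different samples describing the same event
   are clustered by single linkage within each (chromosome, SV type)
   stratum: two records link when both their left and their right
   breakpoints differ by at most `max_dist` (default 1000 bp). Every
   record belongs to exactly one cluster; unmatched records stay as
   singletons (minimum supporting caller = 1). Cluster representatives
   are member medians, rounded to integer bp.
3. **Force-call** — presence of each merged cluster in a sample is
   re-genotyped geometrically: a record of the cluster's type with both
   breakpoints within `max_dist` of the representatives marks the cluster
   present. Each record supports at most one cluster (nearest by
   `|Δpos| + |Δend|`, ties to the leftmost cluster) so one call cannot
   light up two adjacent clusters. Re-examining raw reads is out of
   scope; this geometric re-matching is reproducible from VCFs alone.
4. **Annotate** — a gene *carries* an SV iff they overlap by ≥ 1 bp
   (bedtools-intersect default semantics). Deletions/inversions use their
   `[pos, end]` span; an insertion is the point `pos`. Intragenic SVs are
   *exonic* if they overlap ≥ 1 exon base of that gene, else *intronic*;
   an SV overlapping no gene at all but lying within `promoter_flank`
   (default 2000 bp) upstream of a 5′ end, strand-aware, is a *promoter*
   hit for that gene. An SV overlapping several genes counts toward each
   gene but remains one event in genome-wide totals.
5. **Window counts and subgenome rates** — chromosomes are tiled with
   1 Mbp windows from position 1 (last window truncated); each SV is
   counted once, in the window containing its left breakpoint, so window
   sums equal per-chromosome call counts. Per-chromosome rates
   (SV per Mbp) of the A- and C-subgenome chromosome sets are compared
   with a two-sided Wilcoxon rank-sum test, exact when rates are
   tie-free — a distribution-free choice appropriate for ~10 vs ~9
   chromosomes. Fully tied rates return p = 1 by definition.
6. **Read-depth CNV** — per-base depth is summarized as the median over
   1000 bp blocks; per chromosome, blocks whose median exceeds
   (chromosome median + k·SD), k = 1 by default, are flagged and maximal
   runs of adjacent flagged blocks become duplication segments. The SD is
   the population SD over block medians (declared so results are
   bit-stable); when it is 0 the threshold degenerates to strictly above
   the median. Whole-chromosome loss — the signature of a chromosome
   replaced by its homoeologue — is flagged when a chromosome's median
   block depth falls below `loss_fraction` (default 0.1) of the
   genome-wide median.
7. **PAV phylogeny** — force-called presence/absence across samples forms
   a binary matrix (no missing state: force-call absence is 0), exported
   to relaxed sequential PHYLIP so external maximum-likelihood tools can
   be used. Internally the package builds a neighbor-joining tree on
   Hamming distances (proportion of differing sites). NJ trees are
   unrooted; clade statements use midpoint rooting as the declared,
   deterministic rooting.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_dist` (merge/force-call) | 1000 | bp | breakpoint scatter between platforms/callers is typically a few hundred bp |
| `type_aware` | TRUE | — | a DEL and an INS at the same spot are different events |
| filter size bounds | 30, 30 000 | bp | the small/mid-scale range the analysis targets; `NULL` disables |
| size-class boundary | 10 000 | bp | 10 000 bp belongs to "small", making the two classes a partition |
| `promoter_flank` | 2000 | bp | conventional upstream regulatory window; configurable |
| window size | 1 000 000 | bp | chromosome-scale density maps |
| CNV block width | 1000 | bp | balances breakpoint resolution against median stability |
| CNV `k` | 1 | SD | flags clear excess while tolerating per-block noise; monotone: larger k never flags more blocks |
| `loss_fraction` | 0.1 | — | a lost chromosome retains only stray cross-mapping reads |

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure the analysis
assumes, with every planted feature tracked in a truth table:

- **Panel structure**: 3 ecotype groups × 4 samples. Each sample's calls
  are its group's shared loci (150 per group) plus private loci (50 per
  sample) plus decoys. Group-shared loci are what make ecotypes
  recoverable as clades.
- **Sizes**: two-piece log-uniform — half the mass log-uniform on
  [30, median], half on [median, 30 000], median 300 bp. The draw is a
  stratified inverse CDF (one draw per probability stratum per role
  class), so the configured median holds tightly in every realization,
  not just in expectation. Only summary statistics of real size
  distributions are being emulated, not their shape.
- **Types**: DEL 45%, INS 45%, INV 10%, drawn with exact marginal counts
  (largest-remainder apportionment).
- **Decoys**: per sample, fractions of the real call count emitted as
  `UNRESOLVED` (8%), split-read-only (8%), TRA (4%) and DUP (4%) records.
  They are indistinguishable in the emitted VCF but labelled in truth, so
  filter tests can assert exact removal.
- **Breakpoint jitter**: each realized record's breakpoints are perturbed
  by rounded Normal(0, 30 bp) noise, emulating cross-platform scatter;
  realized sizes are re-clamped into the configured range.
- **Subgenome bias**: A-chromosome placement probability is scaled by 1.3
  relative to C, matching the direction and rough magnitude of the
  A-subgenome SV excess in allopolyploid rapeseed.
- **Genes**: non-overlapping gene models at 30 genes/Mbp with 4 exons
  each (exons/introns as an equal partition of the span), alternating
  strand; a configurable fraction (30%) of real loci is planted inside
  genes, at most one planted locus per gene.
- **Coverage**: per-base depth = round(Normal(30, 2)), floored at 0,
  drawn on `noise_run` bp tiles (1 bp = fully per-base; the pipeline
  examples use coarser tiles only to keep emitted bedGraph files small).
  Planted duplications multiply depth by their fold over block-aligned
  spans; lost chromosomes are scaled to 2% of the mean.
- **Determinism**: all stages draw from seeds derived from the master
  seed by fixed offsets; regenerating with the same seed is
  bit-identical, and configured marginal counts (loci per role, types)
  are exact by construction under every seed.

The defaults are a desk-scale analog of a 12-genotype,
30–50× long-read study on a 4-chromosome 36 Mbp layout
(A01 10 Mbp, A02 8 Mbp, C01 10 Mbp, C02 8 Mbp). What the generator does
**not** emulate: read-level error profiles, alignment artefacts,
reference mis-assembly hotspots, segmental homoeologous exchanges,
LD/pedigree structure, or realistic gene architecture. Passing tests
therefore demonstrate correctness of the post-processing logic under the
stated statistical assumptions — not caller accuracy on real reads.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive internally (VCF convention);
  bedGraph's 0-based half-open intervals are converted at the I/O
  boundary. Insertions use `end = pos`; `SVLEN` is written negative for
  deletions and stored as magnitude.
- Records lacking `SUPTYPE` are treated as split-read-only (they fail the
  AL filter — the conservative reading); FILTER values outside
  `{PASS, UNRESOLVED}` map to `UNRESOLVED` with a warning.
- Median of an even count is the midpoint of the central pair throughout.
- Cluster ids are assigned in (chromosome, representative position)
  order; all tie-breaks (force-call assignment, NJ on equal distances via
  `ape::nj`) are deterministic under fixed input order.
- Empty inputs are legal where scientifically meaningful (empty call set
  filters to an empty call set; header-only VCFs round-trip); they error
  where a statistic is undefined (< 2 blocks per chromosome, < 2
  chromosomes per subgenome, zero-site distance matrices), and
  percentages with zero denominators are returned as `NA` with a
  warning or flag rather than invented.

## Design choices where the design was open

- **Merging semantics**: published merge tools do not document their
  exact linkage; single linkage on both breakpoints within `max_dist` is
  adopted because it reproduces the stated parameter semantics and is
  verifiable against an O(n²) brute-force oracle (the test suite checks
  exact partition equality on hundreds of random instances).
- **CNV threshold**: "above median + 1 SD" with configurable k, and
  population rather than sample SD — declared choices where the
  read-depth literature is loose. Deletion-side calling exists behind a
  flag but is off by default (depth loss is asymmetric in noisy data).
- **Window assignment** by left breakpoint rather than every overlapped
  window, so counts are conserved.
- **Group gene sets** are unions over member samples (a gene "carried by
  winter types" is one carried by any winter accession);
  `mode = "intersection"` is available.
- **ML trees are out of scope**: the package exports PHYLIP for external
  ML tools and implements NJ internally, which suffices for the testable
  claim — that planted ecotype groups come out monophyletic.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` run at desk scale, chosen so
the full suite completes in minutes on one CPU: merge-oracle equality on
200 (suite) / 50 (script) random instances of up to 500 records;
annotation oracle on 100 / 30 instances of 30 SVs × 300 genes-per-100 kbp;
CNV recovery of a planted 50-block 2× duplication on a 300 kbp chromosome
over 50 / 25 seeds; subgenome power on a 10 + 9 × 1 Mbp layout over 100
seeds; ecotype monophyly over 100 / 50 replicates of a reduced
12-sample panel (40 shared + 10 private loci per sample on 10 Mbp); and
one full default-panel pipeline run with a bit-identity re-run check.

## Known limitations

- Force-calling is geometric; it cannot rescue a variant the caller
  missed entirely in a sample, so absence conflates "not present" with
  "not called".
- The stringent filter under-calls large/complex and split-read-only
  events by design.
- Hamming distance treats shared absence as agreement; with very
  unbalanced presence frequencies this can compress between-group
  distances.
- CNV calling has no GC or mappability correction and expects depth
  tracks as input (alignment is out of scope).
- `venn_regions()` supports at most 4 groups; report pairwise beyond
  that.
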