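---
title: "From windowed divergence to gene editing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From windowed divergence to gene editing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divedit)
library(dplyr)
```

divedit implements the computational arc of a butterfly functional-genomics
study: scan three closely related *Papilio* genomes for unusually divergent
50-kb windows, intersect the outliers across all three pairwise comparisons,
overlay positive-selection and developmental differential-expression
evidence to nominate candidate diversification genes, then design CRISPR/Cas9
reagents against a candidate, audit their genome-wide specificity, and type
the mutations recovered from injected individuals. This vignette explains the
statistical model behind each stage, the tunable parameters, what the
synthetic-data generators do and do not emulate, and the design choices made
where the underlying procedures were open to interpretation.

## The divergence scan

### Fixed differences

The unit of divergence is the *fixed difference*: a site at which two taxa
carry different homozygous alleles relative to a shared reference. Given two
per-taxon variant tables, `call_fixed_differences()` applies the rule

* both taxa homozygous with different alternate alleles → fixed difference;
* exactly one taxon homozygous non-reference, the other with no record
  (reference) → fixed difference;
* a heterozygous or missing genotype in either taxon → the site is excluded.

The heterozygous exclusion is deliberate and strict. Wild-caught butterflies
are highly heterozygous (species-level heterozygosities above 1% are
typical), so a substantial fraction of called sites segregate within taxa;
such sites say nothing about fixation between taxa and would otherwise
inflate every window's density.

### Windows, densities and the smoothed quantile cutoff

`tile_windows()` tiles each scaffold with non-overlapping windows of
`window_length` bp (default 50,000) starting at position 0. A terminal
partial window is kept iff it is at least `min_window_fraction` (default
0.5) of the full length; densities are always normalised by the actual
window length, so short terminal windows are not biased upwards. Tiled
rather than sliding windows were chosen because region counts are defined by
merging *adjacent* outlier windows; sliding windows would count each hot
locus many times over.

Each pairwise comparison gets its own cutoff (three comparisons, three
cutoffs), computed by `smoothed_quantile_cutoff()` from that comparison's
window densities. The estimator is a Gaussian-kernel smoothed empirical CDF,

$$\hat F_h(x) = \frac{1}{n}\sum_{i=1}^{n}\Phi\!\left(\frac{x - d_i}{h}\right),$$

with the cutoff the smallest $x$ such that $\hat F_h(x) \ge q$ (default
$q = 0.95$). The bandwidth $h$ defaults to Silverman's rule of thumb
(`stats::bw.nrd0`); $h = 0$ (or a degenerate, zero-variance sample)
degenerates exactly to the plain empirical quantile with type-7
interpolation, which is also the limit of the smoothed cutoff as
$h \to 0$. Smoothing matters when the density distribution is grainy — at a
background of $10^{-3}$ differences per bp a 50-kb window can only take
densities in steps of $2\times10^{-5}$ — and the kernel estimate removes the
resulting staircase artifacts from the upper tail.

A window is an outlier for a comparison iff its density is *strictly* above
that comparison's cutoff (ties at the cutoff do not qualify; `strict =
FALSE` relaxes this). `divergent_regions()` then intersects: a window must
be an outlier in **all three** comparisons, and runs of adjacent tri-pair
outlier windows merge into one divergent region. The funnel — windows
scanned, outliers per pair, merged regions, genes hit — is recorded in the
`run_discovery()` manifest, because the interesting claims live in exactly
those counts.

### From regions to candidate genes

`genes_in_regions()` includes a gene iff its genomic span overlaps a region
by at least 1 bp. Span overlap (rather than exon-restricted overlap) is a
deliberate choice: divergence signals of regulatory interest can sit in a
UTR-containing window while the coding exons lie outside it, and such genes
must not be dropped.

Differential expression across development uses replicate-free RPKM
matrices, one row per gene, one column per stage (ten stages: egg, five
larval instars, pupa and adult each split by sex). Without replicates no
count-based test is available, so `de_across_all_stages()` applies a
pseudocounted fold-change rule: gene $g$ (paired through the ortholog table)
is flagged iff

$$\left|\log_2\frac{A_{gs} + c}{B_{gs} + c}\right| \ge \log_2 f
\quad\text{at every stage } s,$$

with the same sign at every stage (configurable). Defaults: fold threshold
$f = 2$, pseudocount $c = 1$ RPKM. The pseudocount keeps low-expression
noise from generating spurious large ratios; its side effect — genes
expressed near $c$ can never show a large fold change — is intentional, as
ratios below the measurement floor are not evidence.

`integrate_candidates()` emits every divergent gene with three boolean
flags (divergent, positively selected, DE at all stages). A *strong
candidate* is a divergent gene with at least one additional evidence layer
(OR logic). OR rather than AND was chosen because the two extra layers are
different kinds of evidence arriving from different analyses, and because
the flags and per-combination counts are exposed, an AND reading can always
be audited downstream (`glance()` on the candidate set reports every
combination).

## CRISPR/Cas9 design

### Site enumeration and filters

`enumerate_targets()` finds every N20–NGG site (20-nt protospacer followed
by an NGG PAM) on either strand whose full 23-nt footprint lies within a
single exon. The footprint-in-exon rule is conservative — a cut at an
exon–intron junction is hard to interpret — and can be relaxed to
protospacer-only containment. Two filters follow:

* **5' dinucleotide** (`filter_five_prime()`): keep protospacers starting
  GG, GA or AG. This is a synthesis constraint, not a specificity one: the
  sgRNA template is transcribed in vitro from a T7 promoter, which initiates
  efficiently on G-rich 5' ends.
* **Seed uniqueness** (`seed_uniqueness()`): the 12 PAM-proximal protospacer
  nucleotides (the seed) dominate Cas9 specificity. A site is designable
  only if seed + NGG — with the first PAM base treated as N, since Cas9
  ignores it — occurs exactly once in the whole genome, counting both
  strands. The scan is an exact string count (Biostrings pattern matching
  with N as a wildcard), not a heuristic alignment, so short perfect
  repeats cannot slip through.

`forward_oligo()` assembles the synthesis-ready 62-nt forward PCR oligo:
22-nt T7 promoter + protospacer + 20-nt sgRNA scaffold overlap. The 80-nt
reverse oligo encoding the rest of the scaffold is a fixed sequence
(`sgrna_reverse_oligo()`).

### Off-target enumeration

`find_offtargets()` reports every genomic 20-mer, on either strand, followed
by an allowed PAM and within a Hamming-distance budget of the guide
(default 5 mismatches, PAMs NGG and NAG — the canonical strict and lax Cas9
PAMs). Mismatches are substitutions only; RNA or DNA bulges are out of
scope. The implementation accumulates per-position match counts in 20
vectorised passes; `offtarget_oracle()` is an independent naive
re-implementation (locate PAMs, then compare each candidate 20-mer
elementwise) kept in the package because the two must agree bit-exactly,
and the tests and acceptance script hold them to that.

## Mutation typing

Sanger-sequenced TA clones — one amplicon haplotype per clone — are aligned
to the wild-type amplicon with global Needleman–Wunsch and affine gap
penalties: match +2, mismatch −2, a gap of length $L$ costs
$10 + 0.5L$. These scores favour one long gap over scattered short ones,
matching the biology (a single repair event per allele). Three
normalisations make event coordinates canonical and deterministic:

1. **Gap left-shifting.** Within repeats the optimal gap placement is
   ambiguous; every gap run is shifted as far left as score-equivalence
   allows, so a deletion in a homopolymer always reports the leftmost
   coordinate. Determinism comes from the DP's fixed traversal order plus
   this normalisation (rather than from re-implementing the tie-breaking
   rules inside the DP).
2. **Run extraction.** Alignment columns classify as D (gap in clone), I
   (gap in reference) or M (mismatch); maximal runs become events with
   0-based reference coordinates, a D/M event spanning `[ref_start,
   ref_end)` and an insertion anchored at a point.
3. **Substitution-tract normalisation.** Under these scores a substitution
   run longer than ~20 bp is *cheaper* for the aligner to represent as an
   insertion plus a deletion of equal length with interleaved
   accidental-match columns than as a mismatch run ($2L > 20 + L$). Events
   separated by at most 12 match columns are therefore clustered, and a
   cluster whose inserted and deleted lengths balance (net indel zero) is
   re-read from the direct gapless comparison of the two sequences: the
   reported M event spans the first to the last differing base. This
   restores the biological reading — a length-preserving mutated tract —
   and trims flank bases the aligner absorbed by accident.

`classify_clone()` then gates events by geometry: the expected Cas9 blunt
cut sits 3 bp 5' of the PAM (`cut_positions()` computes this for designed
sites), and an event qualifies iff its reference span intersects
`[cut − r, cut + r]` for any cut site, with $r = 20$ bp by default. The
window is deliberately generous: paired sgRNAs with nearby cut sites excise
fragments *between* the cuts, and a span-intersection rule catches those
without special-casing. `min_event_length` defaults to 1 bp — observed
minima of 3 bp in real data are data, not a filter — and can be raised to 3
for stricter emulation. A clone is mutant iff at least one event qualifies.

`summarize_mutagenesis()` produces the efficiency table: the phenotype rate
is 100 × mutant / observed injected individuals; the mutation rate is 100 ×
mutant clones / sequenced clones; per-type event-length ranges print as
`D: 3–73; I: 3–64; M: 3–29` with single-length types printed alone.
Percentages display with half-up rounding to two decimals, trailing zeros
stripped.

## The synthetic-data generators

Every stage is testable without downloads because the generators produce
inputs with known ground truth. What they emulate, and what they do not:

* **Reference + annotation** (`simulate_reference()`): uniform-random
  A/C/G/T scaffolds (no GC skew or repeats), non-overlapping genes on both
  strands with 1–5 exons each. Real genomes have repeat structure that makes
  seed-uniqueness filtering *harder* than in this fixture; passing tests
  here demonstrate rule correctness, not genome-scale designability rates.
* **Divergence** (`simulate_divergence()`): per-window fixed-difference
  counts are binomial at a background rate (default $10^{-3}$ per bp,
  giving the ~50 differences per 50-kb window scale typical of congeneric
  butterflies) and at a hotspot rate (default $2\times10^{-2}$) in planted
  windows, by default the same windows for all three pairs (tri-pair
  hotspots). All three pairs' sites are placed jointly without replacement,
  so every drawn site is realized. With three taxa on one reference, any
  single-taxon variant would create differences in *two* comparisons; to
  give each pair exact, independent control the generator emits each drawn
  site as homozygous-alt in one taxon of its pair and as a *heterozygous*
  record in the third taxon, which the caller's het-exclusion rule then
  discards for the other two comparisons. This uses a real feature of the
  rule, and it means realized per-pair densities match the drawn rates
  exactly. It does not emulate shared ancestral polymorphism or
  lineage-specific rate variation. The generator also accepts bare scaffold
  lengths instead of sequence when only positions and densities matter.
* **Expression** (`simulate_expression()`): baseline RPKM is log-normal
  (median 50 RPKM, log-sd 1 — a right-skewed abundance distribution),
  stage-independent in expectation, with independent multiplicative
  log-normal noise per species × gene × stage at a default CV of 0.2.
  Planted DE genes are drawn among clearly expressed genes (baseline ≥ 20
  RPKM) and one species, chosen at random per gene, is elevated by the fold
  change over the shared baseline at every stage. Both choices reflect what
  an all-stage DE candidate is: a gene near the pseudocount floor cannot
  exhibit a resolvable fold change under the pseudocounted rule at any real
  measurement scale, and the candidates this emulates are robustly
  expressed developmental genes. The generator does not model
  stage-specific trajectories, partial-stage DE, or count overdispersion.
* **Editing** (`simulate_editing_experiment()`): each mutant clone carries
  exactly one planted event — a deletion centred on a cut site, an insertion
  of random bases at the cut, or a substitution run with every base changed
  — with lengths drawn from a spectrum whose defaults span the observed
  ranges (D 3–73, I 3–64, M 3–29 bp). One event per clone keeps the truth
  unambiguous for round-trip testing; real injected individuals are mosaics
  and real clones can carry compound events, which the classifier would
  report as multiple events rather than one. Phenotype counts are binomial
  in the number of injected individuals.

All generators are deterministic given their seed (`withr::with_seed`, so
the caller's RNG state is untouched) and byte-identical across runs.

## Numerical and edge-case conventions

* Coordinates are 0-based half-open everywhere inside the package; GFF3 and
  VCF (1-based) are converted at the I/O boundary, BED passes through
  unchanged.
* `smoothed_quantile_cutoff()` refuses fewer than 10 windows — an upper-tail
  quantile from less than that is folklore, not an estimate. The root of
  $\hat F_h(x) = q$ is found by `uniroot` on
  $[\min d - 10h,\ \max d + 10h]$; $\hat F_h$ is continuous and strictly
  increasing there, so the root is unique.
* Difference sites falling outside all retained windows (in dropped
  terminal stubs) are counted nowhere and reported via a message, never
  silently re-assigned.
* A pair's cutoff is strict (`>`); a tie at the cutoff is not an outlier.
* `phenotype_rate()` requires `0 ≤ mutant ≤ observed` and a positive
  denominator; display rounding is half-up, two decimals, trailing zeros
  stripped.
* Off-target hit order is deterministic (scaffold, start, strand), and
  `exclude` drops the on-target locus by exact coordinates rather than by
  sequence identity, so a genuine second perfect-match locus is never
  silently removed.

## Problem sizes used in the tests

The shipped test-and-acceptance workloads are sized to exercise each claim
at full statistical strength while staying comfortable on a single CPU: the
hotspot-recovery study uses 20 seeded fixtures of 200 × 50-kb windows
(10 Mb, three comparisons each); off-target equivalence uses seeded panels
of 100-kb genomes with 50 guides each at up to 5 mismatches; mutation-typing
round-trips 500 clones of a 400-bp amplicon against two cut sites; DE
recovery uses 20 seeded 200-gene, 10-stage fixtures with 20 planted DE
genes. These sizes are choices, not limits — every generator and scanner
takes its dimensions as arguments.

## Known limitations

* The scan measures fixed-difference density only; it is not an $F_{ST}$ or
  $d_{XY}$ estimator and has no coverage/callability correction, so real
  resequencing data should be pre-filtered for callable sites.
* Off-target search is Hamming-only (no bulges) and unscored; it enumerates
  candidates rather than ranking cleavage likelihood.
* The DE rule is a fold-change screen for replicate-free stage profiles; it
  is not a differential-expression *test* and reports no error rates on
  real data.
* Mutation typing assumes clean single-haplotype clone sequences; it does
  not parse chromatograms or model sequencing error, and compound repair
  events in one clone are reported as multiple events.
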