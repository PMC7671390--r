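---
title: "Methods: detecting, assembling and dating nuclear mitochondrial insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, assembling and dating nuclear mitochondrial insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Nuclear mitochondrial insertions (NumtS) are fragments of mitochondrial
DNA integrated into the nuclear genome. Once inserted they mutate at the
(roughly ten-fold slower) nuclear rate, so each Numt is a fossil of the
mtDNA as it existed at its insertion time. `numtforge` implements a
comparative NumtS analysis for cohorts of related species sequenced with
short paired-end reads: detection of polymorphic (segregating) NumtS
from alignment signals, reconstruction of their sequences, cataloguing
of fixed NumtS already present in reference assemblies, unification of
insertion coordinates across species through chain-file liftover,
gene-level insertion-bias testing, cross-species insertion hotspots, and
insertion dating against ancestral mtDNA.

Because real cohorts of this kind require terabytes of raw reads and
curated reference assemblies, the package ships a fully seeded synthetic
cohort generator with planted ground truth. The generator is first-class
code: every statistical property the analysis assumes is represented in
it, and the test suite measures the pipeline against the generator's
truth tables.

# The synthetic cohort

## Species tree and mtDNA lineage

The cohort is organised around an ultrametric species tree with branch
lengths in million years (MY). The demo tree is
`((human:6,chimp:6)hominini:19,macaque:25)`, the consensus divergence
times for the human–chimpanzee and catarrhine splits. mtDNA evolves down
the tree under Jukes–Cantor substitution (uniform rates, no indels):
per-branch substitution counts are Poisson with mean
`rate x branch_length x genome_length`, and every event (position, both
alleles, time) is recorded, so the lineage's sequence at any historical
time can be reconstructed exactly. The no-indel convention keeps a
single mtDNA coordinate system across all nodes, which the consensus,
annotation, and dating modules rely on.

The default rate is 0.01 substitutions/site/MY, i.e. the ~1e-8/site/year
primate mtDNA clock. Over the 6 MY human–chimp branch this yields ~6%
diagnostic-site density, so even a 500 bp Numt covers dozens of
informative positions.

## Genomes, indels and chains

Each species' nuclear genome is expressed as a shared random base genome
plus seeded small indels (1–50 bp) private to the species; these indels
are exactly what gives inter-species chain files their block structure.
All coordinates are tracked through an explicit event table, from which
the package emits valid UCSC chain files (species as target, frame
species as query). Planted fixed NumtS are themselves insertion events:
when an insertion is shared between a species and the frame (an
ancestral insertion), the chain carries it as an aligned block;
private insertions become one-sided gaps. This makes interval liftover
exactly checkable against a per-base brute-force mapper, which the tests
do.

## Planting NumtS

A planted Numt copies a circular mtDNA segment — `(start, end)` 0-based
half-open, `end <= start` wrapping the replication origin as
D-loop-spanning fragments do — from the lineage sequence as it existed
`age` MY ago on the insertion branch. Fixed NumtS (tip or internal
branches) enter every descendant species' reference; polymorphic NumtS
exist only in carrier samples. Defaults describing the reference cohort:

* 15 polymorphic NumtS per sampled species (30 in the demo), lengths
  log-normal around 300 bp (recent insertions are predominantly
  sub-kilobase), ages exponential with mean 1.2 MY (most insertions are
  recent).
* 10 fixed NumtS overall (3 per sampled species, 2 on the frame
  lineage, 2 ancestral on the shared internal branch), lengths
  log-normal around 800 bp, ages capped at 10 MY. The cap is a
  deliberate consequence of the reference scan's 80% identity floor: at
  0.01 subs/site/MY a 10 MY-old Numt has diverged ~9% from the modern
  consensus, near the floor; older fixed NumtS would require a lower
  floor and longer seeds, which the scan exposes as parameters.
* Carrier frequencies are Beta(0.5, 1.5), conditioned on at least one
  carrier: this produces both sample-specific and widely shared events.
  The carrier-frequency spectrum of real polymorphic NumtS is not well
  characterised; this is a modelling choice, not an empirical claim.

## Idealized alignments

Reads are *placed*, not aligned: a read wholly inside reference sequence
maps concordantly; a read wholly inside an insertion maps onto the mtDNA
contig at the segment offset it was copied from (wrapping reads are
clipped at the contig end); a read crossing a junction is soft-clipped
at the exact breakpoint, preferring the nuclear side when its anchor is
at least 20 bp. Mate flags follow the FR convention, which fixes the
orientation signature the caller uses: a "+" insertion produces
opposite-strand nuclear/mt mates (like an ordinary pair), a "-"
insertion same-strand mates. A uniform per-base error rate (default
0.1%) is applied; no indel errors, PCR duplicates or quality decay are
modelled. Passing tests therefore demonstrate algorithmic correctness
under clean signal structure — they do not certify performance on real
aligner output, where mapping ambiguity, chimeric artefacts and
duplicated Numt loci add noise the caller's thresholds must absorb.

mtDNA (organelle) reads are simulated at 30x (default) against the
sample's own mtDNA: the species consensus plus a few private SNPs that
the consensus module must recover.

# Detection

The per-sample mtDNA consensus is an iterative majority pileup
(substitutions only, minimum depth 2, strict majority, ties keep the
previous base, at most 5 iterations — a convergence cap chosen here, as
upstream tools do not document theirs). The consensus is appended to the
species reference as an extra contig; in a real deployment reads are
realigned against this augmented reference, while the simulator emits
alignments against it directly.

The caller collects (i) discordant pairs with exactly one mate on the
mtDNA contig and a nuclear mate of mapping quality >= 20, and (ii)
soft-clipped nuclear reads whose >= 10 bp clipped tail matches the mtDNA
(either strand, doubled for circularity, at most 1 mismatch per 15 bp).
Nuclear mates cluster by single linkage at `insert_mean + 3 insert_sd`;
a call needs >= 4 discordant pairs (`min_support`). The support floor
and mapping-quality default follow common structural-variant practice
and the four-read support floor used for long-read confirmation of such
insertions; the upstream short-read caller's exact thresholds are not
published, so this package documents its own filter set rather than
claiming identity. Breakpoints are the modal soft-clip position when
clip evidence exists (ties to the smaller coordinate), else the midpoint
of the innermost discordant mates, with the CI spanning those bounds —
the standard imprecise-breakpoint convention. Per-sample calls merge
into species call sets within ±500 bp, a window reused from the
long-read intersection rule; the merged breakpoint is the
support-weighted median and carriers are unioned.

# Assembly and annotation

Reads for one call are pooled across carriers (discordant mt-side
mates, soft-clipped reads, unmapped mates anchored within 1 kb),
deduplicated by read name and mate, and mt-side mates are re-orientated
to the nuclear strand using the call's orientation class. Assembly is a
greedy overlap-consensus: repeatedly merge the highest-scoring
suffix–prefix overlap (>= 16 bp at >= 95% identity, containment
allowed; score = overlap length − 4 x mismatches), consensus by
per-column majority, ties broken lexicographically by read name so the
result is independent of input order. Overlap candidates are seeded by
exact 16-mers of the incoming read's prefix; a sequencing error inside
that seed can hide an individual overlap, which coverage redundancy
absorbs.

Contigs align locally against the *doubled* mtDNA (match 1, mismatch
−2, gap open 4, gap extend 1 — conventional short-contig parameters,
stated for reproducibility) on both strands; doubling resolves
origin-wrapping segments, and coordinates are reported modulo the mtDNA
length. Junction recovery is decided by 30 bp nuclear flank probes on
either side of the breakpoint: a single contig with both flanks is
`full`; separate left- and right-junction contigs give
`partial-two-side` with the insertion length estimated as the circular
distance between the two junction mtDNA coordinates; one junction is
`partial-one-side`. Insertions much longer than the insert size cannot
be tiled by junction-anchored reads — their interiors are occupied by
pairs that map cleanly to the mtDNA contig — so full-length assembly is
bounded by roughly twice the insert size; the length estimate from
partial two-sided assemblies is the designed fallback.

# Reference scan

Fixed NumtS in a reference assembly are found by exact 11-mer seeding of
the doubled mtDNA (both strands) against each nuclear contig, clustering
of seeds by alignment diagonal (64 bp bands, 1 kb gaps, >= 3 seeds
spread over more than ~2 word lengths, so a single chance exact match
cannot trigger work), local alignment of each candidate window, and
merging of same-strand HSPs within 5 kb into one record with a fragment
count. The 80% identity floor and the 5 kb merge gap are exposed
parameters: the floor bounds the age of detectable fixed NumtS (see
above), and reference NumtS genuinely fragment in assemblies, but no
published merging rule exists to copy.

# Comparative unification

Interval liftover has explicit semantics: an interval maps when >= 95%
(`min_map_ratio`) of its bases land on one frame chromosome and strand;
the result spans the outermost mapped bases; multi-chromosome or
multi-strand results are `split`, insufficient coverage is `unmapped`.
Failed events are excluded from sharing denominators and reported — the
choice had to be made somewhere, and silently dropping them would bias
per-species totals.

Pairwise sharing uses greedy nearest-neighbour matching within ±500 bp,
each call matched at most once, ties to the smaller coordinate. Greedy
matching is deterministic and, at realistic call densities (events
megabases apart, windows of 500 bp), agrees with optimal bipartite
matching; the tests keep a brute-force matcher as the oracle.

Ancestral assignment walks the frame species' lineage from the
shallowest divergence node to the root: an event is ancestral at a node
if the frame species has it and, for every node up to and including that
one, at least one species of the clade diverging there shares it. The
cumulative definition makes node sets nested by construction — deeper
nodes can only lose events — which mirrors the monotone decline such
analyses report.

# Gene enrichment

Observed statistics are complete-gene insertion counts: gene `g` counts
once per Numt whose circular segment fully contains it. The null places
each observed fragment length at an independent uniform start on the
circle (1000 sets by default). Uniform placement is the maximum-entropy
reading of "random insertion coordinates"; origin-wrapping placements
are allowed since the mtDNA is a circle. For a fragment of length L and
gene of length G on a circle of length M, the per-set containment
probability is (L − G + 1)/M, which the tests verify by simulation.
Z = (x − mu)/sigma with the permutation mean and SD; |z| >= 1 classes a
gene enriched/depleted, zero-variance genes are flagged neutral. tRNA
genes are counted but excluded from headline reports by default.

# Hotspots

Unified calls are binned into fixed-width windows (25 Mb for real
genomes; the demo pipeline uses 250 kb against its 5 Mb genome — the
statistic is bin-count-scale-free). The per-bin statistic is
`D = sqrt(sum_i (xbar_i − x_i)^2)` over species. The null redistributes
each species' calls uniformly over the binned genome (multinomial,
probability proportional to bin width, preserving per-species totals),
matching the enrichment module's null philosophy. The threshold is the
smallest observed D whose estimated FDR — mean permuted exceedance count
over observed exceedance count — is at or below the target. Counting is
inclusive (`D >= t`): with a strict inequality the top-ranked bin could
never satisfy its own candidate threshold and a single strong hotspot
would be undetectable. The threshold is global across chromosomes, and
raw counts are used rather than length-normalised frequencies, with an
option to drop short terminal bins.

# Dating

The diagnostic profile lists every position where the ancestral mtDNA
(at the species' divergence node, T MY ago) differs from the modern
consensus. A Numt frozen `a` MY ago carries the derived allele exactly
at sites whose substitution predates `a`; under uniform substitution
timing the expected derived fraction is (T − a)/T, giving the estimator
`age = (1 − f_derived) x T`. Sites matching neither allele are excluded
from the ratio by default ("post-correction": they are post-insertion
nuclear mutations or assembly error); counting them as ancestral is
available behind a flag since the original correction rule is not
published. Calls covering fewer than 5 diagnostic sites are QC-flagged:
below that the ratio's sampling error exceeds T/2. The estimator's
variance shrinks with diagnostic-site count; the acceptance checks date
segments with >= 20 sites and require a mean absolute error below 20%
of T.

# Problem sizes and seeds

The reference cohort used throughout the tests is 2 sampled species x 3
samples, 5 Mb genomes, a 16.5 kb mtDNA, 30 polymorphic + 10 fixed
NumtS, 10x nuclear coverage with 100 bp reads and 400 ± 50 bp inserts.
The false-positive control simulates Numt-free single samples on 0.5 Mb
genomes across 20 seeds — about ten million sequenced bases with no
true signal. Statistical calibrations run at reduced Monte-Carlo sizes
(200 permutation sets/permutations, 50 replicates) — enough to resolve
the tested tolerances. Dating recovery is measured on a dedicated
two-species lineage (3 kb mtDNA, 1.2 kb segments covering ~70
diagnostic sites) over 100 seeds and three planted ages. Every stochastic step draws from a seed derived from
one master seed, and all seeded outputs are byte-identical across
reruns; order-sensitive steps (clustering, merging, assembly) sort their
inputs so results are independent of record order.

# Known limitations

* The simulator's idealized placement sidesteps mapping ambiguity;
  results on real alignments depend on aligner behaviour near repeats
  and existing reference NumtS.
* The consensus builder is substitution-only; mtDNA indel variation
  would shift coordinates and is out of scope.
* Full-length assembly is bounded by the library insert size.
* The reference scan's identity floor bounds the age of catalogued
  fixed NumtS; deep-time catalogues need relaxed parameters.
* Post-insertion nuclear mutations are not simulated, so dating
  accuracy on real data is bounded below by the (excluded) third-allele
  rate rather than by the clean-model error measured here.
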