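---
title: "Assigning COS markers to Aegilops chromosomes and mapping synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning COS markers to Aegilops chromosomes and mapping synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmap)
```

## The problem

Wild goatgrasses carrying the U genome (*Aegilops umbellulata*), the M genome
(*Ae. comosa*) and their natural allotetraploids (*Ae. biuncialis*,
U^b^U^b^M^b^M^b^; *Ae. geniculata*, U^g^U^g^M^g^M^g^) are donors of disease-
and stress-tolerance alleles for bread wheat. Introgression breeding needs
cheap PCR markers that flag U- or M-genome chromatin in a wheat background,
and comparative maps that say which wheat chromosome an alien segment can
compensate for. Conserved orthologous set (COS) markers — primer pairs
designed over exon–intron boundaries of single-copy genes conserved across
grasses — amplify across all these species, so a marker assigned to, say,
chromosome 2U immediately provides both.

`cosmap` implements the full analysis chain for such a study:

1. **Genotyping classification** — which Aegilops amplicons are
   length-polymorphic relative to the wheat parents;
2. **Chromosome assignment** — placing each amplicon on chromosomes using
   (a) wheat–Aegilops introgression lines, (b) PCR yields on DNA amplified
   from flow-sorted chromosome fractions, and (c) a cross-species transfer
   rule;
3. **Duplication detection** — markers with several loci in one genome,
   grouped into duplication events across species;
4. **Synteny mapping** — placing marker source ESTs on model genomes
   (*Brachypodium*, rice) from tabular alignment hits, building colour-track
   synteny blocks, and calling rearrangement regions where genome tracks
   disagree;
5. **Simulation** — a generator that emits every input with planted ground
   truth, so each stage is testable without any external data.

## Evidence streams and the assignment model

### Introgression lines

A wheat line carrying an added Aegilops chromosome C amplifies the Aegilops
allele of every marker locus on C. A product (matched across samples within
a 1 bp fragment-analyser bin) is placed on C when it is present in the
Aegilops parent, present in *every* line carrying C, absent from all lines
not carrying C, and absent — or shifted by at least 2 bp — in the wheat
background. Multi-chromosome additions (e.g. a 1U^b^6U^b^ double addition)
support their whole added set unless a single addition disambiguates;
substitutions contribute through their added chromosome; arm-level stocks
(telosomes, centric fusions such as 3M^b^.4BS) narrow a call to one arm,
by presence on the arm stock or, when the product is present on the whole
addition but absent from the arm stock, to the opposite arm.

### Flow-sorted peak fractions

Each species' flow karyotype resolves into four peaks; DNA amplified from a
sorted peak contains its chromosomes in known proportions (the peak
*composition*). A locus's PCR yield across the four fractions then tracks
the content of its carrier chromosome: the highest yield falls in the peak
where that chromosome has its major location. We operationalise this
qualitative rule as a rank statistic: **Kendall's tau-b** between the yield
vector and each candidate chromosome's content vector across peaks, plus a
presence test (yield at background in every peak with zero recorded content,
above detection in the major-location peak). A chromosome is called when it
is the *unique* presence-consistent candidate with tau ≥ `tau_min`
(default 0.8). Chromosomes that always co-sort (identical content vectors)
are genuinely indistinguishable by this assay; the full set is returned
flagged ambiguous rather than dropped, because a later transfer or line
observation can resolve it.

Choices worth stating:

* **tau_min = 0.8.** With four peaks, tau-b of a profile that disagrees with
  the true ranking in even one minor-peak pair is at most 2/3, while the
  correct chromosome scores 1 at low noise; 0.8 separates the two regimes
  while tolerating monotone distortion from amplification bias.
* **Presence threshold = 5% of the genomic-control yield** (or of the
  maximum peak yield when no control was run). Fractions amplified by
  multiple displacement amplification show background product, so "absent"
  cannot mean exactly zero.
* **Tau-b via `stats::cor(method = "kendall")`**, cross-checked in the test
  suite against a brute-force pair-counting oracle.

### Cross-species transfer

Products of similar size in several species are usually the same locus.
When a locus is anchored unambiguously in one species and another species
shows a same-sized product whose highest-yield fraction contains the
homoeologous chromosome (same genome and group, that species' subgenome
tag), the locus is concluded to lie on that chromosome there too. Transfers
never change genome or homoeologous group — only the species tag — and
conflicting anchors across species suppress the transfer entirely. An
ambiguous co-sorted peak call does not block a transfer; an unambiguous
direct assignment does (nothing to transfer onto).

### Reconciliation

When line and peak evidence intersect, the locus takes the intersection
(`evidence = "both"`); on conflict the line evidence wins and the peak
result is logged — a sorted-fraction signal can be distorted by
contamination, whereas presence in a defined genetic stock is hard evidence.

## Duplications

A marker with ≥ 2 confidently assigned loci within one genome of one
species yields a duplication record: distinct sizes on different
chromosomes, one size on two chromosomes, or two sizes on one chromosome
(the repeated-group case, e.g. 7M/7M, which the multiset pattern keeps
distinct from a single 7M locus). Records merge into an *event* by (genome,
multiset of homoeologous groups) after stripping subgenome tags, so the
same duplication seen in a diploid and its tetraploid — or found by two
different markers — counts once. Ambiguous co-sorted assignments never
feed duplication records; transferred (predicted) assignments do.

## Synteny maps and rearrangements

Marker source ESTs are matched to model genomes through 12-column tabular
alignment hits. Hits are significant when E-value < 2.8e-08, identity
> 58.44% and alignment length > 100 bp — all three strict, so a hit exactly
on a threshold is discarded (the boundary behaviour is unit-tested). The
best hit per marker and model genome is the highest score, with ties broken
by lower E-value, then smaller start, then chromosome name, making the map
fully deterministic. Start positions are scaled to canvas pixels by
`floor((start - 1) / length * width)`.

Each marker carries labels on up to seven tracks: D (the wheat-D
homoeologous group, taken from curated annotation rather than from hits,
since wheat positions are prior knowledge) and U/M per species. Maximal
runs of consecutive markers sharing a group label merge into blocks — the
"gap filling" that renders a syntenic interval; a duplicated marker belongs
to blocks of both its labels. A rearrangement call is a maximal run of
shared markers on which two tracks' label sets are disjoint; runs with
≥ `min_support` markers (default 2) are the large-scale calls, single-marker
discordances are reported separately. Calls are reported as marker
intervals, not base-pair breakpoints: flanking markers are what the assay
resolves.

## The synthetic-data generator

The generator emulates the study design: four species over the U/M genome
structure, seven homoeologous groups, four flow-karyotype peaks, an
introgression-line panel, and one model genome (five chromosomes of 50 Mb)
on which each homoeologous group owns a segment. It plants, and records,
every feature the pipeline is meant to find:

* **Loci**: one U- and one M-genome locus per marker (diploids carry their
  own genome, tetraploids both, with tags), with amplicon sizes 120–600 bp
  kept ≥ 4 bp apart within a marker;
* **Wheat alleles**: offset from the Aegilops allele by 2–10 bp — i.e.
  diagnostic — with a 10% null-allele rate; the polymorphism threshold is
  the study's 2 bp rule, and line-diagnostic loci are the condition under
  which full recovery is a meaningful expectation;
* **Duplications**: a second locus for a configurable fraction of markers
  (default 10%), same-chromosome with probability 0.25;
* **Rearrangements**: contiguous marker runs (default 5, length 2–3) whose
  U-genome group is shifted away from the wheat/M group, kept interior to
  their segment so planted intervals cannot merge;
* **Composition**: either the study's peak membership made quantitative
  (88% major content, 30% for a second carrier peak, small deterministic
  cross-contamination whose per-chromosome ordering cycles through distinct
  permutations), or a fully rank-distinct layout in which every chromosome
  is resolvable from yields alone;
* **Panel**: a complete addition series (default, the condition for exact
  line-based recovery), the study's partial stock list, or none (peak-only
  assignment).

Noise is multiplicative lognormal on yields (unit mean, CV default 0.2),
Bernoulli dropout of introgression-line presence calls (allele dropout;
missing fraction rows would be indistinguishable from measured zero yield,
which is a different failure), and ±1 bp size jitter. A single random
stream is seeded once per run, so `(config, seed)` reproduces every file
byte for byte.

What passing simulated tests does **not** show: real flow-sorted fractions
have composition estimated with error and amplification bias that is not
monotone; real panels segregate and carry background polymorphism; real
marker systems produce stutter and null alleles beyond the simple dropout
model. The simulation validates the inference logic, not the wet-lab error
model.

## Validation summary

The test suite checks, among others:

* label parsing round-trips over the full nomenclature;
* the polymorphism boundary (Δ of 0–3 bp against the 2 bp rule) and
  monotonicity in the threshold;
* introgression assignment against a brute-force consistency oracle over
  all presence patterns of a three-line panel;
* the monotone peak-profile example (strictly decreasing yields against the
  published umbellulata composition assigns 1U uniquely, tau = 1);
* the transfer worked example (a 558 bp product anchored on 2U^g^ transfers
  to 2U and 2U^b^ and nothing else);
* the strict threshold boundaries via the full 2^3 enumeration;
* published-table fixtures: 51 distinct suitable markers, 6 U-genome and
  7 M-genome duplication events with the 2M/3M event supported by 11
  markers;
* zero-noise end-to-end recovery of a 60-marker simulated study
  (assignment accuracy, duplication precision/recall and exact
  rearrangement-interval recall all 1.0), and monotone degradation of
  peak-only accuracy over 20 replicates per noise level.

Problem sizes in tests (30–60 markers, 20 replicates) keep the whole suite
around two minutes while every property is exercised at full structural
complexity; `sim_config()` defaults to the study-scale 140 markers.

## Worked example

```{r example, eval = FALSE}
library(cosmap)

# a synthetic 60-marker study, recovered end to end at zero noise
res <- run_simulated_pipeline(
  sim_config(n_markers = 60, duplication_rate = 0.1, n_rearrangements = 3),
  seed = 101, noise = sim_noise(0, 0, 0))
unlist(res$metrics)
#> assignment_accuracy duplication_precision duplication_recall rearrangement_recall
#>                   1                     1                  1                    1

# the published suitability catalogue
loci <- read_locus_table(system.file("extdata", "table2_suitable_loci.tsv",
                                     package = "cosmap"))
select_suitable_markers(loci)$n_markers
#> [1] 51
```

## Known limitations

* Peak-composition deconvolution is rank-based, not a mixture model; two
  chromosomes with identical content vectors are reported as an ambiguous
  set by design (`Non-goal`: probabilistic deconvolution).
* The "highest yield" tolerance between near-equal peaks is our tau +
  presence operationalisation; the underlying qualitative rule does not fix
  a numeric cut-off.
* Rearrangement calls are marker intervals; breakpoint positions between
  flanking markers are outside the assay's resolution.
* The mean-products summary reports the per-(marker × genotype) mean and
  documents that choice; other denominators (e.g. per marker) are easily
  derived from the returned pair table.
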