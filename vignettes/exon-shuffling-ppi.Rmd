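---
title: "Exon shuffling signals and PPI network topology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon shuffling signals and PPI network topology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exshuffle)
```

## The question

Exon shuffling — intron-mediated recombination that inserts an exon-borne
segment of one gene into a non-homologous gene — has been a major route to
new multidomain proteins in metazoans. If shuffled segments carry protein
domains with interaction capabilities, genes shaped by exon shuffling should
be over-represented among well-connected vertices of protein–protein
interaction (PPI) networks. This package implements the full analysis chain
needed to ask that question on any species' data: detect candidate shuffling
events from sequence, classify genes, build gene-level PPI networks, and
compare the resulting gene classes with statistics that respect the heavy
tails and confounds of degree data.

## Gene classification: ES, SS, WS

Every gene is represented by one protein of maximal length; its CDS length
is exactly three times the protein length (the stop codon is never touched
by protein-level alignments or domain hits, so it is excluded throughout).
Intron positions are stored as *junction offsets*: offset $j$ means an
intron interrupts the CDS between nucleotides $j$ and $j+1$. Storing
junctions rather than nucleotide indices makes window membership a plain
interval query and leaves no ambiguity about introns "at" a boundary.

Candidate shuffling evidence is a local protein alignment between two genes
that passes two strict filters: e-value below $10^{-3}$ and aligned span
below 50% of the shorter protein. The coverage cap is what excludes
paralogous pairs, whose homology extends over most of the protein; a
separate, stricter 70% rule (below) defines paralogy itself.

Each qualifying region has two borders on each gene. Projecting residues
$r_1..r_2$ to nucleotides gives the span $[3r_1-2,\,3r_2]$; the 5' border
junction is $3r_1-3$ and the 3' border junction $3r_2$. Around each border a
window over junction offsets extends 20 nt toward the region exterior and
3 nt toward the interior, giving four windows per region (two genes × two
borders). Windows are clipped to the valid junction range rather than
discarded — bilateral flanking is not required, because intron loss and the
age of many events erase flanks asymmetrically. A gene is:

* **ES** (exon shuffling) if *any* of its regions has at least
  `min_intron_windows` of the four windows containing an intron junction —
  3 for intron-rich lineages (human, mouse), 2 for lineages with extensive
  intron loss (fly, worm, fungus, plant). The call applies to both genes of
  the region, whichever gene carries the introns.
* **SS** (sequence shuffling) if it has regions but none reaches the
  threshold.
* **WS** (without shuffling) if it has no qualifying region at all.

The three categories partition the gene set by construction. Two anchoring
choices deserve note, because the verbal definition ("from the third
nucleotide toward the interior to the twentieth toward the exterior") does
not pin them down: windows are intervals over *junctions*, closed on both
ends, anchored at the border junctions defined above; and an intron falling
in the overlap of a short region's 5' and 3' windows counts toward both
windows, since counts are per-window by definition. Both extents are
arguments (`exterior`, `interior`) so sensitivity to the anchoring can be
checked directly.

## Local alignment

`local_align()` wraps a Smith–Waterman alignment (BLOSUM62, gap open 11,
extend 1 — the classic BLASTP parameterization) and attaches a
Karlin–Altschul e-value $E = K m n e^{-\lambda S}$ with the constants
conventionally paired with that scoring ($\lambda = 0.267$, $K = 0.041$).
This exists so the homology path can be exercised end-to-end on synthetic
sequences without an external aligner; real analyses will usually feed
`read_blast_tab()` with precomputed all-vs-all BLAST output. The scores are
verified in the test suite against an independent full Gotoh dynamic
program on random sequence pairs.

## PPI networks

`build_network()` applies the conventions that make degree comparable
across source databases: records whose detection method matches a
mass-spectrometry pattern are dropped (the technique cannot distinguish
direct from indirect association), as are genetic/functional interaction
types; all protein identifiers of a gene collapse into a single vertex;
edges are unordered and deduplicated across databases. Degree counts
*distinct partners only*. Self-interactions are a separate per-vertex flag,
never a degree contribution: the analyses treat self-interaction as its own
attribute, and no loop-degree convention would be testable downstream. A
vertex kept only by a self-interaction record stays in the network with
degree 0; vertices with neither edges nor a self record are discarded.

`project_by_orthology()` transfers a well-studied network into a species
with sparse interaction data: a target pair interacts iff both genes have
(one-to-one) orthologs and those orthologs interact in the source network.

## Paralogy, confluence and 1/k weighting

Gene duplication inflates any per-gene count and could mimic a shuffling
signal through a few expanded families. Three devices control for it:

* **Families.** Two genes are paralogs when the summed span of
  non-overlapping HSPs between them (greedily selected by bitscore on the
  query) reaches 70% of the *longer* protein; paralogy is closed
  transitively, so families are connected components. Curated paralog lists,
  when available, take precedence over alignment detection.
* **Confluence.** Within a family, network vertices of the same shuffling
  category are replaced by one statistical unit carrying the arithmetic
  mean degree and mean protein length, and the disjunction of
  self-interaction flags. Categories are never merged across, so a family
  split between ES and SS contributes one unit to each. Edges are not
  rewired: the merged vertex exists to enter the degree and
  self-interaction comparisons as a single observation.
* **1/k weighting.** In domain counts, an occurrence in a gene whose family
  has $k$ members contributes $1/k$, so each family contributes one
  gene-equivalent in total. $k$ includes the gene itself — a singleton
  weighs 1, and weights within a family always sum to 1.

## Domain properties

Domain occurrences (Pfam-style hits, e-value strictly below $10^{-2}$) are
classified through a domain–domain interaction (DDI) table of type pairs:

* **promiscuity** — a type with ≥ 6 distinct partner types is promiscuous;
  1–5 makes it a non-promiscuous interacting type; 0 makes it non-DI. The
  self-pair counts as one partner, since the table lists it as one
  interaction of the type.
* **self-interaction** — the type's self-pair is present in the DDI table.
* **abundance** — ≥ 4 occurrences proteome-wide is "high", ≤ 3 "low".

An occurrence is *intron-flanked* when both of its flanking windows (3 nt
toward the domain interior, 32 nt toward the exterior, clipped) contain at
least one junction — bilateral by requirement, unlike the gene classifier's
windows, because here the question is whether the domain unit itself moved.
`weighted_flank_table()` then accumulates 1/k-weighted flanked and total
counts per domain class, and class differences are tested with the
continuity-corrected chi-square below. Associations *between* the type-level
properties use plain type counts restricted to DI types (self-interaction is
undefined for a type never seen in the DDI table), so all three association
tables share one denominator set.

## Statistics

**Continuity-corrected chi-square.** For a 2×2 table the statistic is
$n\,(\max(|ad-bc| - n/2,\,0))^2 / (r_1 r_2 c_1 c_2)$, one degree of freedom.
The formula is well-defined for fractional counts, which the 1/k-weighted
tables produce; the correction clamps at zero so balanced tables score 0.
Exact degree-1 homogeneity in $n$ holds only without the correction term —
the $n/2$ term is lower order, so the property is asymptotic, and the tests
check it on large tables.

**Resampling test.** Degree distributions are heavy-tailed, so mean
differences are tested by resampling: draw `n_iter` samples of the size of
the smaller set, without replacement, from the union of the two sets; the
observed statistic is the (arithmetic or geometric) mean of the smaller real
set; count the fraction of null samples at least as extreme on the side of
the pooled mean where the observation falls, double it (two-sided intent),
cap at 1. When no null sample is as extreme the p-value is reported as the
bound `2/n_iter` with `p_is_bound = TRUE` rather than as zero. A z-score
(observed vs null mean and SD) accompanies every test. The default
`n_iter = 100000` resolves bounds below $3\times10^{-5}$; tests and examples
use 2,000–10,000 for speed, which only coarsens p resolution, never the
direction of a call.

**Length control.** Degree correlates with protein length, so a length-
biased gene set can show a degree "effect" with no biology in it. The
matched variant builds each null sample by one-to-one correspondence: for
every real vertex, a pool vertex whose length is within a relative tolerance
(default 10%) of the real vertex's length, drawn without replacement within
a sample, scarcest-first. This holds the null samples' length profile at the
real set's. Exact length equality would leave most vertices without
candidates, hence the tolerance; it is configurable. Two limitations are
worth knowing. First, for real sets concentrated at the extreme of the
length distribution the candidate windows are asymmetric (more candidates
below than above), which biases matched samples slightly toward shorter —
hence lower-degree — vertices. Second, when degree is (nearly) a
deterministic function of length, the null distribution has almost no
variance and even that small residual bias can surface as a small p-value.
The test suite therefore exercises the control with a length-biased subset
drawn from the interior of the length distribution, where matching is
unbiased; with real data, whose degree noise dwarfs the matching bias, the
control behaves as intended, but matched p-values for extreme-length gene
sets should be read with care.

**Mann–Whitney U** complements the resampling test (exact enumeration for
tie-free samples of up to 8 per side, normal approximation with tie and
continuity corrections otherwise), and the three pairwise category
comparisons per species are **Bonferroni**-corrected with $m = 3$ (as are
the three pairwise domain-class comparisons; two-class abundance comparisons
are single tests, $m = 1$).

## Reference counts and what they validate

`reference_tables()` ships the 2×2 contingency inputs of a published
comparative analysis of six eukaryotes together with the chi-square
statistics printed alongside them, and `replicate_printed_tables()`
recomputes every statistic from the raw cells. Integer-count tables
reproduce to the printed precision; the 1/k-weighted tables were printed
with cells rounded to 0.1, so their statistics are reproduced within 0.5.
Two printed statistics are *not* derivable from their own printed cells —
one association row whose printed value appears to use a different
denominator set, and one flanking comparison that duplicates another row of
its table — and independent implementations (R's `chisq.test`, SciPy)
confirm the recomputed values, so those rows are flagged
`reproducible = FALSE` rather than matched. This validates the statistical
pipeline; it does not re-derive the counts themselves, which would require
the original database snapshots.

## The synthetic-data generator

Real inputs at proteome scale are not distributable, so `simulate_bundle()`
generates data with exactly the structure the analysis assumes, in exactly
the file formats the readers consume. Defaults describe the simulated study
conditions used throughout the tests: 500 genes; lognormal protein lengths
(mean 400 residues, sdlog 0.25, clipped at 150 so a planted segment never
trips the 50% coverage filter); 6 intron junctions per kb of CDS placed
uniformly (a metazoan-like density); 40 planted shuffling events copying a
60-residue donor segment into a distinct acceptor gene at the sequence
level, with introns planted at all four border junctions and each planted
intron independently deleted at the configured loss rate; 20 pairs carrying
the copied segment with *no* intron support — for these, background
junctions inside the four flanking windows are removed, because "homology
without intron support" is the definition of that truth label, and leaving
metazoan-density background introns in place would contradict it. The PPI
network is an expected-degree (Chung–Lu) random graph: baseline mean degree
4, multiplied by 3 for truth-ES genes; self-interaction flags drawn per
category at 0.30/0.25/0.20, mirroring the gradient reported in human data.
All randomness flows from one mandatory seed through fixed per-stage
substreams, so any stage can be regenerated alone.

What the generator does *not* emulate: realistic sequence evolution
(substitution processes, codon bias, domain architecture), network motifs
beyond the degree sequence, correlated intron loss, or length–degree
coupling. Passing tests therefore demonstrate that the pipeline recovers
planted signals of the assumed structure — not that real data contain such
signals.

## Problem sizes and numerical choices

The test suite runs the generator at 200–500 genes and resampling at
2,000–10,000 iterations; the power and calibration checks use 200 replicate
networks over one fixed genome (rejection at $\alpha = 0.05$). All
threshold comparisons in filters are strict (`<` for e-values and coverage,
matching the stated "less than" rules; `>=` for the promiscuity and
abundance bins). Greedy HSP selection breaks bitscore ties by query start;
`set.seed` is applied per stage or per test so every reported number is
bit-reproducible. Degenerate inputs (empty hit sets, empty ortholog maps,
single-member families) return empty-but-well-formed objects rather than
errors; genuinely contradictory records (a stated CDS length that is not
three times the protein length, junctions outside the CDS interior) are
rejected per record with a diagnostic, never silently fixed.

## Known limitations

* The classifier sees only the maximal-length isoform; shuffling evidence
  confined to minor isoforms is invisible.
* Window anchoring at borders is junction-based by design; a
  nucleotide-index reading of the same verbal rule would shift windows by
  one position, and the `exterior`/`interior` arguments are the place to
  probe such sensitivity.
* The length-matched control's relative-tolerance rule is a pragmatic
  substitute for an exact-equality pairing that would rarely have
  candidates; see the caveats above.
* Confluence averages degrees without rewiring edges, so the merged network
  is a set of statistical units, not a graph to run further topology on.
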