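---
title: "Screening genomes for NRSE/RE1 sites and testing their regulatory associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for NRSE/RE1 sites and testing their regulatory associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrsescan)
```

## The biological problem

REST (RE1-silencing transcription factor, also called NRSF) represses
neuronal genes in non-neuronal cells by binding the neuron-restrictive
silencer element (NRSE, or RE1). The element is highly degenerate: a
conserved 5′ half-site and a conserved 3′ half-site separated by a
short, poorly conserved linker. `nrsescan` implements the
computational side of an NRSE screen: find every occurrence of the
degenerate consensus in a genome, relate occurrences to gene models,
characterise the motif repertoire, and ask — against an explicit null
model — whether occurrences associate with particular gene classes
(especially long non-coding RNAs) more often than chance placement
would predict.

## The motif model

The screen uses a 17-bp degenerate IUPAC consensus,
`NTYAGMRCCNNRGMSAG`, with the linker at positions 10–11. Matching is
**exact** per position: a window matches if and only if each base lies
in the degeneracy set of the corresponding code. There is no
position-weight scoring and no mismatch tolerance; the degeneracy of
the consensus *is* the tolerance. Two consequences follow:

* The pattern defines a finite set of concrete sequences
  ("permutations"): the per-position degeneracy product, which is
  `r prod(c(4,1,2,1,1,2,2,1,1,4,4,2,1,2,2,1,1))` = 4096 for the default
  consensus. `expand_iupac()` enumerates them; every scanner hit's
  matched sequence is a member of this set.
* Ambiguous *genome* bases (assembly `N`s and any other non-ACGT
  letter) match nothing — not even pattern code `N`. Gap runs can
  therefore never produce hits. Matching is case-insensitive, so
  soft-masked (lowercase) sequence is scanned like any other; no repeat
  filtering is applied.

Both strands are scanned, since the consensus is non-palindromic and
occurrences are biologically meaningful in either orientation. A `-`
hit is reported with forward-strand coordinates and the reverse
complement of the genomic slice as its matched sequence. Because of the
`N` positions an interval can in principle match in both orientations;
such an interval is emitted once, with strand `+` and a logged note, so
locus counts are unambiguous. Overlapping hits at distinct intervals
are all reported.

The scanner encodes bases as 4-bit masks and slides the pattern with
vectorised bitwise AND, applying pattern positions most-selective
first. This is an implementation detail: the test suite holds it
byte-identical to a naive character-by-character sliding-window matcher
on randomly generated sequences, and that equivalence — not the
bitmask code — is the scanner's contract.

Partial-motif search reuses the halves of the same consensus: 5′-half
hits match positions 1–9, 3′-half hits positions 12–17, and bipartite
hits are a 5′ and a 3′ half on the same strand separated by a linker of
3 to `max_linker` nucleotides (2 is the canonical linker, so "more than
2" defines bipartite). No consensus upper bound for the linker exists,
so `max_linker` is an explicit parameter with no privileged default.

## Coordinates and gene distances

All in-memory coordinates are 0-based half-open (BED convention); GTF
input is converted on read and only `gene` features are kept, so
multi-transcript genes count once. Distance is **gene-body gap
distance**, strand-agnostic: 0 for overlap, otherwise the number of
bases strictly between the intervals, `Inf` across chromosomes. "Within
*D* of a gene" is defined as *gap < D*, which is exactly overlap with
the gene interval extended by *D* on each side under half-open
semantics — the extend-and-intersect idiom of interval tools. The
location bins follow the same strict convention: intragenic (overlap),
near flank (gap < 20 kb), far flank (20 kb ≤ gap < 100 kb), and
gene-distant (gap ≥ 100 kb, or no gene on the chromosome). A hit at a
gap of exactly 100 kb is therefore gene-distant; the boundary case has
measure zero but the convention is fixed and tested. Nearest-gene ties
break by smaller gene start, then lexicographic gene id, making
annotation output deterministic. Class association uses
each-hit-counted-once semantics: a hit within *D* of three lncRNAs
contributes one to the lncRNA count.

## The shuffle null model and the association test

Expected association counts come from re-placing hit intervals at
random: each interval keeps its chromosome and its length and is drawn
uniformly over all start positions at which it would overlap no
excluded region (assembly gaps; plus all 100 kb-extended protein-coding
gene intervals in gene-distant mode, so shuffled hits stay
gene-distant). Shuffled intervals may overlap one another, matching the
default behaviour of the standard interval shuffler. Placement is
implemented by enumerating the feasible start windows exactly —
excluded intervals are expanded by `length − 1` on the left,
complemented within the chromosome, and a start is drawn by inverse
lookup on cumulative window widths. This gives exactly uniform
placement over feasible starts, detects infeasibility (a fully
excluded chromosome) as a hard, named error rather than a timeout, and
needs no rejection loop. Per-shuffle seeds are derived from the root
seed by shuffle index, so results are reproducible and independent of
evaluation order.

With `n` shuffles the expected count *E* for a class is the mean of the
per-shuffle counts (the default `n_shuffles = 1000` matches standard
practice for this design; the per-shuffle counts are returned for
audit). The observed count *O* over *N* total hits is then tested with
a two-cell goodness-of-fit chi-square,

$$\chi^2 = \frac{(O-E)^2}{E} + \frac{((N-O)-(N-E))^2}{N-E},
\qquad \mathrm{df} = 1,$$

which is the natural reading of "observed versus expected count" for a
single association count; the form is two-sided (equal-sized enrichment
and depletion score identically). When *E* is 0 or *N* the statistic is
undefined and the result is flagged rather than forced. Each gene class
is tested separately and no multiple-testing correction is applied by
default (a Bonferroni flag exists), mirroring how such screens report
one p-value per class.

Monte-Carlo error in *E* adds slight extra dispersion relative to a
known-expectation chi-square; the calibration study below shows the
realised type-I rate stays near nominal at the study sizes used.

## Chain alignments and homology

UCSC chain files are parsed with full validation: block sizes plus gap
lengths must span the stated target and query extents, and only the
final block may omit gap fields; violations are rejected with the chain
id. Chain coordinates are strand-local — on a `-` strand sequence they
are measured from the sequence end — and are converted to forward
coordinates as `size − strand_local_end`. A "homologous region" is an
**ungapped aligned block** of a score-filtered chain, not a whole
chain: block sizes are the scale at which motif-in-homolog questions
are meaningful, while chains span orders of magnitude more (a
`block|chain` choice is exposed, block the default via `merge`
semantics). Blocks from different chains that overlap in species-1
coordinates are merged before counting, so one locus is never counted
twice; a merged region's query-side flag is true if any contributing
block's query interval contains a hit.

## The synthetic-data generator

The generator emulates the statistical structure the association test
assumes, with known ground truth:

* **Genome** — i.i.d. background bases at a configurable GC content
  (default 0.40, a vertebrate-like value), with concrete motif
  instances written at non-overlapping positions and random strands.
  Background matches can arise by chance (about
  4096/4¹⁷ ≈ 2.4×10⁻⁷ per window per strand); they are kept, and
  scan-level truth is defined as the oracle's output on the emitted
  sequence, with planted loci verified to be a subset. This keeps
  scanner acceptance exact rather than probabilistic.
* **Annotation** — protein-coding genes placed uniformly without
  overlap (1–10 kb); each ncRNA gene is, with probability `rho`, placed
  uniformly within an enrichment window of a randomly chosen planted
  motif, otherwise uniformly (0.2–2 kb sizes). The mixture form is the
  simplest structure under which "associated more often than chance"
  has a planted truth; `rho = 0` is the null.
* **Gaps** — non-overlapping intervals totalling `gap_fraction` of each
  chromosome (default 5 %), never overlapping planted motifs, as N-runs
  in a real assembly cannot contain motif instances.
* **Chain pairs** — planned segments copied into a second genome with
  optional point substitutions, optional reverse-complement
  orientation, and optionally a targeted substitution at a
  non-degenerate pattern position to destroy a contained motif; each
  segment becomes one single-block chain with consistent arithmetic.
  Chain scores are configured constants; realistic alignment scoring is
  out of scope.

All generators are deterministic given the spec's seed (annotation,
gaps and chain generation derive fixed offsets from it).

### Study geometry and scaling

The default spec is a 2 Mb genome in 3 chromosomes with 40 planted
motifs, 20 protein-coding genes, and 30 lncRNAs (plus small counts of
the other ncRNA classes). At genome scale the canonical association
cutoff is 100 kb, but 30 genes each extended ±100 kb would cover a 2 Mb
genome entirely, leaving the association test no variance. The
synthetic study therefore uses a 10 kb enrichment window, and the
association cutoff applied to synthetic data equals that window: 30
genes × ~20.5 kb of extended interval cover roughly a quarter of the
genome, which preserves the coverage regime of the full-scale screen
(thousands of genes × 200 kb windows on a multi-Gb genome). This
geometry was fixed as part of the study design; the calibration and
power analyses below use it unchanged.

### What the simulations do and do not show

The calibration study (200 replicate datasets at `rho = 0`, 200
shuffles each, α = 0.05) checks that the shuffle-derived chi-square
rejects at near-nominal rate when ncRNAs are placed with no relation to
motifs. The power study (100 replicates at `rho = 0.8`) checks that a
strong planted enrichment is detected essentially always at these
sizes. Passing both says the *machinery* is calibrated and sensitive
under the generator's assumptions — i.i.d. background, uniform gene
placement, mixture enrichment. Real genomes violate all three
(isochores, gene clusters, repeat structure, biased gap placement), so
these results validate the implementation, not any biological claim
about a particular genome.

## Motif statistics conventions

* **PFM weighting.** A position frequency matrix counts one observation
  per supplied sequence. Passing every hit's matched sequence weights
  by genomic locus; passing `unique()` of the permutations weights by
  distinct permutation. Both are legitimate summaries (locus-weighted
  for "what does the genome's motif population look like",
  permutation-weighted for comparing repertoires), so the choice is the
  caller's.
* **Information content** is `2 − H` bits from the empirical
  frequencies, with no small-sample correction — deterministic in the
  counts, and deliberately divergent from WebLogo's corrected letter
  heights.
* **Consensus calls** report, per position, the minimal IUPAC code
  covering all bases at frequency ≥ τ (default τ = 0.25, the uniform
  frequency, so a base must merely exceed its chance share); `N` when
  no base reaches τ.
* **Per-position chi-square** between two motif sets is Pearson's
  statistic, without continuity correction, on the 2 × k table of base
  counts at that position, where k counts base categories with nonzero
  column total across both sets; df = k − 1, and fewer than two
  categories yields a flagged, undefined result.

## Numerical and degenerate-input choices

* Scanner, expansion, and PFM routines reject invalid input (bad IUPAC
  codes with the offending position, unequal sequence lengths,
  non-ACGT sequences in PFMs) rather than coercing.
* Empty inputs flow through: empty FASTA → empty hit table, empty hit
  list → empty catalogue, zero-gene class → zero counts.
* `gene_distant` mode with no gene-distant hits yields flagged results,
  not errors; `chi_square_association` flags `E ∈ {0, N}`.
* Extended gene intervals are clipped at 0; right-clipping at
  chromosome ends is unnecessary for overlap counting and is omitted.
* Unplaced-scaffold hits can be dropped from distance analyses by
  name-pattern configuration, since distances on unassigned scaffolds
  are unreliable.

## Pipeline and reproducibility

`run_screen()` executes scan → annotation → statistics → association →
homology from one validated `screen_config()` whose defaults are the
screen's canonical constants (pattern, 100 kb cutoff, 20 kb bin edge,
chain score cutoff 5000, 1000 shuffles). Every stage's outputs are
written to the output directory, failures abort naming the stage, and
`report.json` records each constant, seed, and row count actually used.
Deterministic stages are byte-reproducible; stochastic stages are
reproducible given the seed.

## Known limitations

* Exact IUPAC matching cannot score near-miss sites; a PWM scanner is
  out of scope by design.
* Distance annotation is quadratic per chromosome (hits × genes) in the
  nearest-gene step; adequate for screen-scale hit counts, not for
  millions of features.
* The shuffle null preserves length and chromosome but not local
  sequence composition (no GC matching), matching the standard
  shuffle-based design it emulates.
* The homology module consumes chain files only; net/axt formats and
  general liftover are not implemented.
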