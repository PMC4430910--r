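# nrsescan

Genome-wide screening and regulatory association analysis of **NRSE/RE1**
binding sites — the DNA elements bound by the transcriptional repressor
REST (NRSF), which silences neuronal genes in non-neuronal tissue.

## What it does

REST recognises the neuron-restrictive silencer element through a
degenerate consensus. `nrsescan` screens a genome for the 17-bp
degenerate motif

```
NTYAGMRCCNNRGMSAG
```

(IUPAC codes; positions 1–9 form the conserved 5′ half, 10–11 the
poorly conserved linker, 12–17 the conserved 3′ half; the pattern admits
4096 concrete "permutations"), and then asks the downstream questions a
regulatory screen needs answered:

* **Scanning** — exact, both-strand, case-insensitive location of every
  motif occurrence in a FASTA genome, including half-site and bipartite
  variants (5′ and 3′ halves separated by a >2 nt linker). Assembly
  `N`s never match. The scanner is bitmask-based and provably identical
  to a naive sliding-window matcher.
* **Gene annotation** — distance of each hit to gene models parsed from
  GTF (gene features only, Ensembl `gene_biotype` or GENCODE
  `gene_type`), location bins (intragenic / <20 kb / 20–100 kb /
  gene-distant), motifs-per-gene histograms, and the "gene-distant"
  subset >100 kb from any protein-coding gene.
* **Motif statistics** — permutation catalogues and frequency tables,
  three-way cross-species permutation Venn counts, position frequency
  matrices, per-position information content `IC = 2 − H` (bits), IUPAC
  consensus calls, and per-position chi-square comparison of motif
  sets.
* **Association testing** — a gap-aware, within-chromosome
  interval-shuffling null model: hit coordinates are re-placed uniformly
  over feasible positions (avoiding assembly gaps, and avoiding
  100 kb-extended protein-coding genes in gene-distant mode), expected
  counts are shuffle means, and each ncRNA class (lncRNA, miRNA, rRNA,
  snRNA, snoRNA) is tested with a two-cell goodness-of-fit chi-square
  `(O−E)²/E + ((N−O)−(N−E))²/(N−E)`, df = 1.
* **Homology** — UCSC chain alignment parsing (with block-arithmetic
  validation and minus-strand coordinate conversion), score filtering,
  and cross-species motif co-occurrence in ungapped aligned blocks.
* **Synthetic data** — seeded generators for genomes with planted motif
  instances, annotations with a controllable ncRNA enrichment `rho`,
  gap tracks, and toy chain pairs, all with recorded ground truth.

## Worked example

```r
library(nrsescan)

spec   <- synthetic_spec(enrichment_rho = 0.8, seed = 42)  # 2 Mb, 40 motifs
bundle <- simulate_dataset(spec)
hits   <- scan_genome(bundle$genome)
head(hits, 3)
#>   chrom start   end strand       matched_seq
#> 1  chr1 32635 32652      - TTCAGCGCCCCAGCCAG
#> 2  chr1 40233 40250      + GTCAGAGCCTTAGAGAG
#> 3  chr1 57407 57424      - CTCAGCACCCGGGCCAG

pc  <- bundle$genes[bundle$genes$biotype == "protein_coding", ]
ann <- annotate_hits(hits, pc, cutoff = 10000, bin_edge = 2000)
table(ann$location_bin)
#> flank_20_100kb   gene_distant     intragenic
#>              3             35              2

res <- run_association_suite(hits, bundle$genes, bundle$chrom_sizes,
                             bundle$gaps, mode = "genome_wide",
                             classes = c("lncRNA", "miRNA"),
                             cutoff = 10000, n_shuffles = 200, seed = 42)
res[, c("class_label", "observed", "expected", "chi2", "p_value")]
#>   class_label observed expected  chi2   p_value
#> 1      lncRNA       20   10.270 12.40 0.0004287
#> 2       miRNA        6    1.845  9.81 0.0017360

consensus_from_pfm(build_pfm(hits$matched_seq))
#> [1] "HTYAGMRCCYCRGMSAG"
```

The hits table gives 0-based half-open coordinates and the matched
17-mer in pattern orientation (for `-` hits, the reverse complement of
the genomic slice). With 80 % of the 30 simulated lncRNAs planted near
motifs, 20 of the 40 hits fall within 10 kb of a lncRNA against a
shuffle expectation of 10.3, and the chi-square test rejects the null
(p ≈ 4×10⁻⁴); the miRNA class, also enriched here, rejects as well.

A command-line wrapper with `simulate`, `scan`, `annotate`, `stats`,
`compare`, `homology`, `assoc` and `run-all` subcommands lives at
`inst/cli/nrse.R`:

```sh
Rscript inst/cli/nrse.R scan --fasta genome.fa --out hits.bed
Rscript inst/cli/nrse.R assoc --hits hits.bed --gtf genes.gtf \
    --gaps gaps.bed --chrom-sizes chrom.sizes --n 1000 --seed 17
```

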