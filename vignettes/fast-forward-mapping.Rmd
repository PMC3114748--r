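---
title: "Bulk-segregant mapping of EMS mutations from pooled sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk-segregant mapping of EMS mutations from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffg)
```

## The problem and the two-step design

A recessive mutant recovered from an EMS screen carries hundreds to
thousands of induced point mutations; phenotype alone cannot say which one
is causal. `ffg` implements the two-step pooled-sequencing strategy for
resolving this:

1. **Mapping by bulk segregants.** The mutant (in its "reference" ecotype
   background) is outcrossed to a polymorphic mapping ecotype, the F1
   selfed, and the F2 sorted by phenotype into a mutant pool (homozygous
   for the causal allele) and a wild-type pool (1/3 homozygous wild type,
   2/3 heterozygous). Light shotgun sequencing of both pools (~1-10x) read
   out the mapping-ecotype allele frequency along the genome: ~50% at
   unlinked markers, falling toward 0% in the mutant pool and rising toward
   67% in the wild-type pool as markers approach the causal locus.
2. **Enrichment and deep sequencing.** The linked interval (typically
   ~1 Mb) is captured with a dense tiling of 60-mer probes and the mutant
   pool deep-sequenced (~1,000x+). Every position with a high-frequency
   novel allele (> 70% non-reference, not attributable to ecotype
   polymorphism) is a candidate causal mutation, annotated for its coding
   effect.

The package provides a forward simulator of the entire experiment, the
strict pooled SNP caller, the binned mapping statistic, the candidate
caller with effect annotation, the probe designer, and an orchestrating
pipeline — each usable separately on real pileup data in the `ffpileup v1`
TSV dialect.

## Genetic model

### Expected allele-frequency curves

For a marker at recombination fraction $r$ from the causal locus, gametes
carry (causal, marker) combinations with probabilities $(1-r)/2$ (parental)
and $r/2$ (recombinant). Conditioning F2 individuals on phenotype gives the
expected mapping-allele frequency

$$f_\text{mut}(r) = r, \qquad f_\text{wt}(r) = \frac{2 - r}{3},$$

so $f_\text{mut}(0) = 0$, $f_\text{wt}(0) = 2/3 \approx 67\%$, and both
equal $1/2$ at $r = 1/2$. `expected_map_fraction()` implements the closed
forms; the test suite verifies them against a brute-force enumeration of
all sixteen F2 gamete pairs on a grid of $r$.

### Meiosis

Crossovers per chromosome per gamete are Poisson with mean equal to the
genetic length in Morgans, placed uniformly on the genetic map, without
interference; the implied map function is Haldane's
$r = (1 - e^{-2d})/2$. This is the simplest standard model consistent with
the pool-size-limited resolution argument: with $n$ pooled mutants
($2n$ informative gametes) the distance from the causal locus to the
nearest flanking crossover on each side is approximately
$\mathrm{Exp}(2n)$ in Morgans, so the expected minimal mapping interval is
$1/n$ Morgans — ~1 cM for a pool of 100 (`mapping_resolution()` measures
exactly this on simulated pools). A sequencing-accuracy corollary: one
chromosome in a pool of $n$ contributes allele frequency $1/2n$, so with
500 individuals a 99.9%-accurate platform reads error and single-crossover
signal at the same rate (`error_floor_accuracy()`).

### EMS mutagenesis

Mutations are placed uniformly on unmasked, non-marker bases at a default
rate of 1/100 kb. EMS alkylates guanine, so G/C sites transition to A/T
with probability `gc_to_at_bias` (default 0.85 — the source data show 5/6
such changes and the literature spectrum is strongly G/C→A/T biased; the
value is configurable because the observed ratio is an estimate from six
events). One mutation is flagged causal; if the Poisson draw is zero the
causal mutation is still created, so the zero-rate limit yields exactly
one mutation.

## The strict pooled SNP filter

Discovery merges both pools into a *virtual F1*, heterozygous at every
ecotype polymorphism, then requires at each site: accepted coverage ≥ 20;
more than 3 unique read start sites per called allele; variant quality
> 10; variant alleles observed on both strands; and at most
2 × (pooled individuals) identical reads per (allele, start, strand)
clonality key (best base quality kept first, then input order).

Two definitions are deliberately pinned down where the prose description
is ambiguous:

* **Variant quality** is the phred-scaled probability that the variant
  read count arises from sequencing error alone under a binomial error
  model (`-10 log10 P[X >= k]`, `X ~ Bin(coverage, error_rate)`). The
  original aligner-specific consensus quality is not reproducible from a
  pileup; this replacement preserves the filter's intent (reject
  error-explainable alleles) with a fully specified statistic.
* **A "called allele"** for the unique-start-sites rule is the variant
  allele always, and the reference allele only when it reaches ≥ 10% of
  accepted reads. At 1,600x a homozygous-variant site carries ~1.6
  reference-calling *error* reads; treating those as a called allele would
  fail every deep causal site on the start-site rule. The 10% bound
  mirrors the triallelic-ambiguity rule (sites where a third allele
  exceeds 10% of accepted reads are flagged ambiguous and kept out of
  bins).

After discovery, each pool is genotyped at the discovered positions with a
*permissive* criteria set (coverage ≥ 1, clonality cap only): at 6-10x
per-pool coverage the strict thresholds would reject nearly every site,
and the mapping statistic needs raw ratios plus the fully-reference check,
not strict re-calling. Strict per-pool criteria remain available through
the `pool_criteria` argument.

A consequence worth knowing: with two pools at ~10x each the virtual F1
runs ~20x, and the coverage filter alone caps discovery near
$P[\mathrm{Pois}(20) \ge 20] \approx 53\%$ of markers. That is the regime
the method was designed for — mapping needs only thousands of markers
genome-wide, not all of them.

## Binned mapping and region calling

Bins are consecutive runs of 25 genotyped sites per chromosome (trailing
bins under half size are dropped). Within a bin, reads are pooled before
the ratio is taken (`map_fraction = sum(alt) / sum(ref + alt)`), following
the raw-read description of the source procedure; a per-SNP-mean mode is
available for comparison. Both pools are first restricted to their common
genotypable site set (`align_pool_calls()`) so the two tracks cover the
same SNPs.

Region detection thresholds are invented plumbing (the original analysis
read regions off plots): a region is a run of ≥ 2 bins with mutant-pool
`map_fraction` < 0.25, *supported* when the wild-type pool averages > 0.55
over the same bins. Because the frequency gradient crosses 0.25 smoothly,
binomial noise flickers bins around the threshold in the transition zone
(measured flicker gaps run 6–10 bins at fractions 0.25–0.33). Dip runs are
therefore consolidated: a separating gap is bridged when it is short
(≤ `max_gap = 5` bins) or when every one of its bins stays below
`gap_fraction = 0.35`, midway between the dip threshold and the unlinked
expectation. Unlinked bins sit at ~0.5 with a standard deviation of ~0.03
at default read depths — at least 5σ above the bound — so consolidation
cannot merge genuinely distinct loci. The capture interval for step 2 is
the consolidated run of bins below 0.05 around the minimum bin: at
10 cM/Mb that is roughly ±0.5-1 Mb around the causal locus, matching the
~1 Mb capture designs used in practice.

## Candidate calling

A candidate is a strict-filter PASS site in the enriched region with
non-reference fraction strictly above 0.70 — deliberately loose, to absorb
sequencing noise and pool missorting (2% missorting lowers the causal
site to ~0.97-0.98) — that is not explainable as ecotype polymorphism.
Ecotype filtering uses the known marker panel if available plus the
wild-type pool, with one important refinement: a position is excluded only
when the *wild-type* pool also shows it above 0.70. Fixed
ecotype-vs-reference differences appear near 100% in both pools; the
causal mutation segregates at ~1/3 in the wild-type pool, so a literal
"any wild-type-variable position" filter would delete the causal variant
itself (and did, in early testing, whenever the wild-type pool happened to
be covered there).

Effects are annotated against gene models (GFF3 via `rtracklayer`, or
constructed with `gene_model()`): a pseudogene hit dominates; then CDS
(spliced, strand-aware, translated with the standard nuclear code — labels
like `Q467X`, `A345T`, `S558S` with `X` for stops), UTRs, intron,
intergenic. The test oracle translates the entire mutated CDS and diffs
the proteins, an independent path from the per-codon arithmetic.

## Probe design

Capture probes are 60-mers chosen per design window: windows are anchored
every 2 bp, each window of 10 candidate starts emits its best-scoring
eligible probe (ties to the earliest start), and the reverse-strand design
is run independently on the reverse complement with the first window
offset by 1. Probes touching any masked or ambiguous base are ineligible.
The score is

$$-|T_m - 90| - 20 \cdot d(\mathrm{GC}, [0.35, 0.65]) \cdot 100 - 5 \cdot \max(0, H - 5)$$

with $T_m = 81.5 + 0.41\,\mathrm{GC\%} - 675/60$ (the GC-fraction
approximation) and $H$ the longest homopolymer. The melting formula,
window width, weights and offset are not specified by the source
procedure; these defaults are standard and config-exposed.

Uniqueness filtering discards probes with more than 2 genomic loci (both
strands) at > 60% full-length ungapped identity, found by exact 12-mer
seeding (three seeds per probe) and extension — a light stand-in for the
original BLAST scan; ">60% match" is read as identity over the full probe
length, which the original leaves unstated. Like any seed-and-extend scan
it can miss a > 60% locus that shares no exact 12-mer with the probe.

## What the simulator does and does not emulate

Simulated: the cross and its Mendelian segregation, marker panels on
repeat-masked genomes, the EMS burden and spectrum, phenotype sorting with
optional missorting, and pooled sequencing at pileup level (Poisson
coverage, uniform haplotype sampling, uniform substitution errors,
Bernoulli strands, uniform read starts, phred-of-error-rate base qualities
with ±3 jitter — quality feeds only the > 10 filter, so higher fidelity is
not needed).

Not emulated: read alignment and mapability artifacts (the pipeline's
entry format is the pileup), colorspace chemistry, indels and structural
variants, library-preparation biases, non-uniform error profiles,
interference in meiosis, and selfing beyond F2. A green end-to-end test
therefore establishes that the statistical machinery recovers a causal
variant under the stated sampling model — not that any particular aligner
or chemistry would deliver pileups this clean.

The pipeline emits pileups at polymorphic candidate sites (panel +
mutations) plus a random sample of monomorphic background sites rather
than at every base: whole-genome emission at 10x (or 1,600x over 1 Mb)
would mean 10^8-10^9 observation rows with no statistical content —
monomorphic sites can only produce fully-reference or error-driven records
that never approach the 70% bound. `sequence_pool(positions =
"whole-genome")` exists and is exercised on small genomes in the tests.

## Defaults that matter

| parameter | default | why |
|---|---|---|
| EMS rate | 1e-5 /bp | the literature 1/100 kb figure; ~10 candidates per Mb |
| `gc_to_at_bias` | 0.85 | qualitative spectrum (5/6 observed); configurable |
| pool size | 200 | the sequenced experiment pooled 200 + 200 plants |
| F2 size | 1,000 | pooling 200 mutants needs E[mutants] comfortably above 200; 1,000 gives 250 ± 13.7 |
| light / enriched depth | 10x / 1,600x | the reported coverage regime |
| error rate | 1e-3 | "99.9% accuracy" platform claim; also the variant-quality prior |
| read length | 50 bp | the reported read length |
| bin size | 25 SNPs | the reported window size |
| dip / support / capture thresholds | 0.25 / 0.55 / 0.05 | invented detection plumbing, config-exposed |
| genome default | 1 chromosome, 10 Mb, 10 cM/Mb | a genome-scale mapping problem in miniature: 100 cM gives genuinely unlinked flanks at ~50% |
| `wt_exclude_threshold` | 0.70 | ecotype-difference filter that cannot self-exclude a segregating causal variant |

## Numerical and degenerate-input choices

Ties in variant-allele selection break lexicographically; clonality
retention prefers higher base quality, then input order; probe-window ties
prefer the earliest start. Variant quality is capped at phred 3000 to keep
JSON/TSV finite. Empty pileup columns are coverage failures, not errors;
zero-coverage candidate regions return an empty list plus a coverage
report; a region shorter than one probe warns and returns an empty design.
Merging unsorted pileups is an error rather than a silent re-sort. All
coordinates are 1-based closed inside R (the Bioconductor convention);
`ffpileup v1`, VCF and GFF3 are 1-based, BED 0-based half-open on disk.

## Known limitations

* Detection thresholds are tuned for the default depth regime; very deep
  light sequencing would narrow the binomial noise and could justify a
  tighter dip threshold.
* The uniqueness scanner's identity computation is exact but its seeding
  can miss low-identity repeats, as noted above.
* The per-chromosome recombination rate is constant; hotspots and
  centromeric suppression are not modeled, so physical↔genetic scaling is
  uniform within a chromosome.
* `multiplex()` shares one simulated genome across mutants but simulates
  pools independently; barcode collisions and index hopping are out of
  scope.
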