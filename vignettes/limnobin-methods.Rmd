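---
title: "Methods: genome-resolved metagenomics with limnobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved metagenomics with limnobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

limnobin re-implements, as a tested and reusable pipeline, the
genome-resolved workflow used to recover metagenome-assembled genomes
(MAGs) of freshwater bacterioplankton — in particular underexplored phyla
such as *Verrucomicrobia* — from shotgun metagenomes of lakes and
reservoirs. This vignette explains the models and procedures, the
parameters that matter, what the synthetic data generator does and does
not emulate, and the design choices made where the methodology left
genuine freedom.

## The pipeline at a glance

Stage order in `run_pipeline()`:

1. **16S screening** of unassembled reads (`screen_ssu_reads()`):
   candidacy against a dereplicated reference set, profile verification,
   two-threshold classification, per-taxon relative abundance.
2. **Recruitment** of reads against contigs (`recruit()`) to obtain
   per-contig coverage and, per genome and sample, the RPKG abundance.
3. **Binning** (`contig_features()`, `cluster_contigs()`): the taxonomic
   gene-vote filter, canonical tetranucleotide PCA, GC, coverage,
   k-medoids.
4. **Quality control** (`mag_table()`): single-copy-marker completeness
   and contamination, contamination-corrected genome size, GC, coding
   density, median intergenic spacer.
5. **Dereplication** (`ani_matrix()`, `dereplicate_bins()`): fragment ANI
   and single-linkage grouping of same-organism bins.

Every numeric cutoff lives in one object, `pipeline_thresholds()`, and is
echoed in the header of every table the pipeline writes. No stage
hard-codes a threshold.

## The internal aligner

All sequence comparison — 16S candidacy and classification, ANI
fragments, read recruitment — goes through one seed-and-extend local
aligner (`search_hits()`), so the pipeline carries no external search
dependency. The design is conventional: exact k-mer seeds over a hashed
index of the subject set, seeds grouped by diagonal, and a banded
(half-width 16) affine-gap Smith–Waterman extension with full traceback,
which yields the match count and alignment length the identity filters
need. Significance follows Karlin–Altschul statistics,
$E = K\,m\,n\,e^{-\lambda S}$, with $m$ the query length and $n$ the total
subject length (database-size correction, as external search tools apply
it). $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$, solved by bisection to 1e-6;
$K = 0.621$ is kept as a fixed constant because its analytic form is
impractical and only shifts e-values by a constant factor. The default
scoring is +1/−2 with gap open 5 / extend 2.

Two performance knobs matter only for bulk recruitment: the seed length
(16 for recruitment, 12 elsewhere) and an optional ungapped X-drop
pre-filter (`min_ungapped_score`) that discards single-diagonal seed
clusters which cannot reach a useful score before any gapped extension —
the standard two-stage trigger of nucleotide search tools. `recruit()`
additionally samples query seed positions at stride 4: any alignment that
can pass the recruitment filters (≥ 50 bp at > 95% identity) contains
many exact 16-mers, so the stride costs essentially no sensitivity. For
general-purpose searching both knobs stay off.

The aligner is validated against an exhaustive dynamic-programming oracle
(full local DP under the same scoring) on hundreds of random pairs with
planted homology at 0–15% divergence and small indels; the test suite
requires ≥ 95% exact score agreement.

## Synthetic communities: what they emulate, and what not

The generator exists so every downstream stage can be tested against
ground truth without any download.

* **Genomes** are emitted by per-genome order-2 Markov chains
  (`markov_transitions()`). In every context the conditional probability
  of G+C equals the genome's GC target, so realized GC is binomially
  tight around the target (±0.01 at 1 Mb is many standard deviations);
  how that probability splits between G and C (and A and T) is drawn per
  context from the composition seed, giving each genome its own
  tetranucleotide signature. Test fixtures use GC targets spanning
  52–64%, within the wide GC range freshwater MAG surveys report.
* **Markers and 16S genes** are planted as non-overlapping intervals and
  recorded as gene calls, so completeness/contamination have exact truth.
  Planted 16S copies are mutated (≤ 2%) copies of a labeled reference.
* **Mutation** (`mutate_genome()`) is substitution-only. This is a
  deliberate restriction: expected identity is exactly $1-\mu$, which
  makes ANI recovery analytically checkable (98.0 ± 0.3 at $\mu = 0.02$
  on 300 kb).
* **Contigs** (`fragment_genome()`) tile the genome with
  shifted-geometric lengths (minimum 10 kb, mean 20 kb in the fixtures),
  mimicking the size distribution of assembled contigs above the binning
  cutoff.
* **Reads** (`simulate_reads()`) are single-end, uniform-start,
  random-strand, with i.i.d. substitution errors; read count per genome
  and sample is `round(coverage × genome_length / read_length)`. A
  background "noise" genome pads samples to a requested total, so
  recruitment specificity is measurable. A guard refuses samples beyond
  10⁷ reads.
* **16S references** (`synthetic_ssu_refs()`) descend from one ancestral
  sequence produced by a strongly skewed order-2 chain; taxa diverge at
  12% and records within a taxon at 3%, so within- vs between-taxon
  identities (~94% vs ~78%) bracket the 80% classification threshold the
  way real within/between-phylum 16S distances do.

Not emulated: indels and structural variation, strain mixtures, chimeric
contigs, quality-score models, GC-biased coverage, paired-end structure
(RPKG counts reads, not pairs). Passing tests therefore demonstrate the
*arithmetic and statistical* correctness of the pipeline under its own
model assumptions — not robustness to assembler artifacts or platform
error profiles.

## 16S read screening

The cascade mirrors a two-stage screen: candidacy is decided against a
*dereplicated* reference set (greedy longest-first centroid clustering at
90% identity over ≥ 80% of the record length — the coverage rule is our
addition, since greedy centroid clustering needs one), with a strict
e-value < 1e-5; classification is decided against the *full* reference
set, keeping a read only if its best hit has identity ≥ 80% and alignment
length ≥ 90 bp (both inclusive), else it is discarded.

Between the two sits verification. Covariance-model alignment is beyond
desk scale, so the package uses a sequence-level discriminator with a
calibrated guarantee: an order-4 Markov log-odds profile trained on the
references, thresholded so that at most 1% of dinucleotide-shuffled
candidate fragments pass (`train_ssu_profile()`). The shuffle preserves
the dinucleotide multiset exactly (a restarted Eulerian walk over the
transition multiset), so the threshold calibrates against sequences with
identical low-order composition but destroyed higher-order structure.
Order 4 was chosen by measuring the sensitivity/FPR trade-off on
synthetic references: lower orders leave too little margin between true
16S fragments read at 2% error and their shuffles; order 4 passes ~99.8%
of true fragments at the 1% calibrated FPR, and its 256-context table is
still well estimated from ~90 kb of reference sequence.

On ~150 bp reads the "alignment length ≥ 90 bp" rule is applied to the
local alignment length, the natural reading for read-length fragments.

## Binning

Contigs enter binning only if longer than 10 kb (strict) and if strictly
more than 60% of their genes — unlabeled genes count in the denominator —
hit the target phylum. Each passing contig is summarized by the top-3
principal components of its canonical tetranucleotide profile (136
strand-collapsed 4-mer classes; windows containing N are skipped, so the
profile is exactly reverse-complement invariant), its GC, and
`log10(coverage + 0.1)` per sample (coverage spans orders of magnitude;
the pseudocount handles zeros).

The published workflow binned manually in PCA space; automation needs a
deterministic replacement, and ours is k-medoids with the number of bins
chosen by maximum mean silhouette over k = 2…8, falling back to a single
bin when even the best silhouette is below 0.25 (no structure). One
scaling choice required care: z-scoring every feature dimension
independently — the obvious default — inflates trailing PCA components
that carry almost pure noise (PC3 holds ~0.2% of the variance on a
three-genome community) to unit variance, and the silhouette then prefers
spurious splits. The PC block is therefore scaled jointly by the standard
deviation of PC1, preserving the eigenvalue weighting between components,
while GC and each coverage dimension are z-scored individually. On the
three-genome test community this changes the selected k from 5 (ARI 0.83)
to the true 3 (ARI 1.0). PCA follows the usual conventions: mean-centered
columns, covariance eigenvectors ordered by eigenvalue, each component's
largest-magnitude loading made positive so signs are reproducible.

## Genome quality and streamlining metrics

Completeness and contamination come from a deliberately simple
single-copy-marker estimator: completeness is the percent of expected
markers present at least once; contamination is the percent of surplus
copies. The lineage-aware, collocated-marker machinery of full QC tools
is out of scope — the downstream arithmetic consumes two percentages, and
the synthetic truth makes the simple estimator exact (planting a fraction
*f* of the marker set yields completeness 100 *f*).

The estimated genome size is the assembled length purged of the
contaminated fraction and scaled by completeness:

$$\hat{L} = L \cdot \frac{1 - c/100}{C/100}$$

with $L$ the assembled Mb, $C$ completeness and $c$ contamination,
reported at two decimals. Streamlining indicators follow the standard
definitions: coding density is the union of coding intervals over the
total length (overlaps not double-counted); the intergenic spacer between
consecutive same-contig genes is clamped at zero for overlapping genes
(an overlap is not a spacing), and the bin-level value is the median.

## ANI and dereplication

ANI follows the classical fragment scheme: the query genome is cut into
consecutive 1020 bp fragments (the trailing shorter fragment is
discarded, keeping fragment statistics homogeneous), each fragment is
aligned to the other genome, and a fragment's best hit is retained when
it covers at least 70% of the fragment at ≥ 30% identity; ANI is the mean
identity of retained hits. With zero retained fragments ANI is undefined
(`NA`) — a non-homologous pair, never silently 0. One direction is
computed per ordered pair; dereplication uses the maximum of the two
directions, the conservative choice for grouping. Bins with ANI strictly
above 98% are grouped by single linkage as one organism; each group's
representative is the most complete bin, ties broken by assembled length,
then id.

## Recruitment and RPKG

A read is recruited iff its best hit passes alignment length ≥ 50 bp
(inclusive), identity > 95% (strict), and e-value ≤ 1e-5 (inclusive) —
and each read counts at most once, with a deterministic tie rule (score,
then subject id, then position, then strand). Whether a search tool user
would count every passing hit or one per read is ambiguous; one-per-read
is the choice here, since the abundance measure is a *read* count.

RPKG is the exact quotient

$$\mathrm{RPKG} = \frac{\text{reads recruited}}
{\text{genome kb} \times \text{metagenome Gbp}}$$

with the metagenome measured in gigabase-pairs of read sequence (for
plain FASTA, bytes and bases coincide, which is how "gigabyte of
metagenome" is read here). The anchor identity — 10 RPKG equals 1×
coverage for 100 bp reads in a 1 Gbp metagenome — follows from
`coverage = RPKG × Gbp × read_length / 1000` and is reproduced end to end
by the acceptance script: a 1 Mbp genome at exactly 1× inside a 1.0 Gbp
synthetic metagenome recruits its 10,000 reads and no background, giving
RPKG 10.0.

## FISH census arithmetic

The microscopy module is intentionally minimal: the relative density of a
probe-defined population is the product of its probe-positive fraction
among DAPI-stained objects and the DAPI direct count (cells/mL), and
percent-of-group contributions are simple ratios, warned about when
counting noise pushes them above 100%. Filtration-volume and filter-area
calibration is assumed to be folded into the DAPI count, which is how
count tables are normally reported. A published revision of absolute
abundances against independent DAPI counts has no stated rule, so the raw
product is reported.

## Numerical and reproducibility choices

* Coordinates are 0-based half-open everywhere inside the package; GFF3
  conversion happens in exactly one reader/writer pair.
* All randomness goes through R's RNG; every generator takes an explicit
  seed, and `run_pipeline()` derives per-stage seeds from the global one
  by stage name, so stages are independently reproducible. Rerunning a
  config reproduces byte-identical tables; finished stage tables are
  reused when the config digest matches.
* k-medoids (`cluster::pam`) is deterministic for a given feature matrix;
  the seed argument exists for interface uniformity and future
  stochastic refinements.
* Problem sizes in the test suite — 0.4 Mb genomes, 10–20 kb contigs,
  10⁴-read 16S screens, 300 kb ANI pairs, one full 10⁷-read (1 Gbp)
  recruitment — were chosen as the smallest sizes at which the binomial
  tolerances quoted above are comfortably inside their bands.

## Known limitations

* The aligner's banded extension (half-width 16) can underestimate
  alignments with large or clustered indels; at recruitment identity
  (> 95%) this is immaterial, and the DP-oracle agreement test bounds the
  effect at search scale.
* The completeness estimator ignores marker collocation and lineage
  placement; its numbers are not comparable to lineage-aware tools on
  real data, though the downstream size formula is identical.
* Binning uses a single coverage dimension per sample and no linkage
  information; communities of genomes with both similar composition and
  similar coverage in every sample are not separable, in this or any
  composition/coverage binner.
* The 16S verification profile is trained on the supplied references; on
  a real reference database its calibration should be re-run (it is, on
  every call to `train_ssu_profile()`).
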