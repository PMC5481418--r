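---
title: "darkbin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{darkbin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkbin)
```

# Scope

`darkbin` implements an assembly-based workflow for recovering microbial
genomes from shotgun skin metagenomes, aimed at the situation where a
substantial fraction of the assembled sequence has no close relative in
reference databases ("microbial dark matter"). The workflow is:

1. **Conservative contig taxonomy** — per-contig breadth of coverage and
   nucleotide identity against the best-matching reference genome, with a
   strict 90/90 assignment rule.
2. **Dark-matter binning** — K-means clustering of unassigned contigs on
   GC content and coverage, followed by automated curation.
3. **ANI novelty calls** — fragment-based average nucleotide identity
   between curated bins and candidate references, with a strict 97.5%
   species boundary.
4. **Core-genome phylogeny** — ortholog search of a reference gene set,
   concatenation, gap trimming and a neighbor-joining placement tree.
5. **Metagenomic MLST** — consensus alleles from reads, sequence-type
   assignment, and a strain-identity rule for paired samples.
6. **Diversity and paired-site comparison** — rarefaction, richness and
   Gini–Simpson evenness, intra- vs inter-subject Bray–Curtis beta
   diversity, and a paired Wilcoxon signed-rank test of contralateral
   diseased vs unaffected sites.

Every stage can be exercised on seeded synthetic cohorts with
machine-readable ground truth (`evolveGenomeSet()`, `fragmentToContigs()`,
`simulateCohort()`, `simulateMlstScheme()`, `simulateMlstReads()`), which
is how the test suite and the acceptance script validate the pipeline
without access to raw metagenomes.

# The native aligner

Desk-scale alignment uses a deterministic seed-and-extend local aligner
(`seedExtendAlign()`): exact k-mer seeds (default `k = 15`) are extended
without gaps in both directions under an X-drop rule (match +1, mismatch
−2, abandon when the running score drops 20 below its maximum, trim back
to the maximum), and overlapping extensions on the same diagonal are
merged. Default retention thresholds (identity ≥ 0.70, length ≥ 100) sit
below every decision boundary applied downstream, so the aligner never
pre-empts a pipeline rule. Ungapped extension is exact for the synthetic
world, which is substitution-only by design; externally produced (gapped)
hits enter through `readHitTable()`, which accepts the 12-column tabular
hit format with 1-based inclusive coordinates and normalises them to the
package's 0-based half-open convention.

Because the X-drop trim discards terminal mismatches, a hit's interval can
be a few bases short of the ideal overlap. This biases per-fragment
identity upward by well under 0.2 percentage points at fragment length
1000 (measured in the calibration tests) and is immaterial against the
decision thresholds.

# Contig taxonomy

For each contig, hits are grouped by reference genome; the best reference
maximises the summed `alignedLength × identity` score (ties broken by
lexicographic genome id, which makes the choice reproducible). Against
that reference only, *breadth* is the fraction of the contig covered by
the union of the hit intervals and *identity* is the
alignment-length-weighted mean of hit identities; overlapping hits each
contribute their full length, a simple order-independent choice. A contig
receives the species of its best reference iff breadth **and** identity
both strictly exceed 0.90; equality at the boundary leaves it unassigned,
the conservative reading of "higher than 90%". Species-labelled contigs
strictly longer than 1000 nt form per-species bins; everything else is
routed to dark-matter binning.

# Dark-matter binning and curation

Unassigned contigs are clustered on `(GC, log10 coverage)` — coverage is
log-transformed because depth is multiplicative — with both features
standardized. K is selected in `2..kMax` by maximum mean silhouette, with
K-means restarted 10 times under a fixed seed. When the best silhouette is
below 0.25 the set is kept as a single bin.

A caveat discovered during development: mean silhouette for the best
2-means split of a genuinely homogeneous standardized 2-D point cloud is
typically 0.35–0.55, so the 0.25 floor does not by itself prevent
over-splitting. The safety net is the curation stage: an even split of one
cloud fails the separation criterion, and a bulk/outlier split loses its
small half to the minimum-size rule, so a homogeneous residual set never
yields more than one curated bin. The test suite asserts exactly that
combined guarantee.

Curation accepts a preliminary bin iff

* every member's GC deviates from the bin's GC median by less than 5%
  (relative),
* every member's coverage deviates from the coverage median by less than
  25% (relative),
* its *separation score* — distance from its centroid to the nearest
  other centroid in the standardized feature space, divided by its RMS
  within-bin radius — exceeds 2, and
* it holds at least 5 contigs and 50 kb (smaller bins cannot support ANI
  or phylogeny downstream).

The 5%/25% tolerances are interpreted as *relative* deviations from the
bin median, which treats GC and coverage symmetrically; both tolerances
are exposed as configuration. The separation score replaces a visual
"discrete separation" judgement with a dimensionless, reproducible ratio.

# ANI and the novelty call

`fragmentAni()` cuts the query (a bin's contigs or a genome) into
consecutive 1000-nt windows, discarding terminal fragments shorter than
500 nt, aligns each window to the reference and keeps its best hit.
Windows are retained when the hit has identity ≥ 0.70 over ≥ 70% of the
window; the report carries the mean and standard deviation of retained
window identities (×100), plus retained/total counts, so the unit of
replication for the s.d. is the fragment. On substitution-only data with
per-site divergence *p* ≤ 0.10, the measured `ani_mean` sits within 0.2
of `100(1 − p)` for 100-kb genomes. `classifyBin()` assigns the bin to
the best reference's species iff its ANI strictly exceeds 97.5%; a bin at
exactly 97.5 is called novel (conservative), and a bin with no retained
fragments against any reference is `no_signal`.

# Core-genome phylogeny

`findOrthologs()` aligns every reference gene against every genome or bin
and keeps, per (gene, genome), the best-scoring hit strictly longer than
500 bp with identity strictly above 0.70; multi-copy hits are resolved by
best score. Core genes are those present in strictly more than 95% of the
genomes. Each core gene contributes an alignment block the width of the
gene: a genome's accepted hit is placed at its gene coordinates
(substitution-only hits are already column-aligned) and a genome lacking
the gene receives an all-gap block. Columns whose gap fraction exceeds 0.2
are trimmed — a fixed single-parameter stand-in for automatic gap
trimming, chosen for reproducibility. Distances use p-distance or
Jukes–Cantor with pairwise deletion (JC is undefined at mismatch ≥ 0.75
and errors naming the offending pair), and the tree is built by neighbor
joining with negative branch lengths clamped to zero. Maximum-likelihood
inference is deliberately out of scope: the claims exercised here are
topological placements of bins, which NJ recovers exactly (Robinson–Foulds
distance 0) on planted 6–8-taxon topologies whenever all branch rates are
at least 0.02 and the concatenated core spans ≥ 20 kb.

# Metagenomic MLST

Reads are placed by exact 21-mer anchoring against the catalogued alleles
of the scheme — a desk-scale replacement for an external local-alignment
mapper that works because alleles of one locus share coordinates in the
substitution-only setting (real schemes with indel-bearing alleles would
enter through an externally produced pileup). The consensus follows a
fixed precedence: positions covered by more than one read take the
majority base, a tie takes the template base; positions covered by exactly
one read take the observed base; uncovered positions take the template
base, where the template is the catalogued allele closest (minimum
Hamming distance, ties to the lowest allele id) to a preliminary majority
sequence. Sequence types are assigned by exact allele matching: a
consensus matching no catalogued allele makes the locus "new" and the ST
"novel"; a locus without reads makes the ST "incomplete".

Two samples carry the same strain iff at most one locus differs and no
differing locus differs by more than one SNP — the "more than six of
eight loci identical, no locus by more than one SNP" rule, stated for
8-locus schemes and generalised to any scheme size as *at most one
differing locus*, since seven-locus schemes exist and the original
wording does not transfer verbatim.

At 20× coverage and 1% per-base error the consensus recovers all eight
true alleles exactly in ≥ 9/10 seeded runs; read simulation draws reads
overhanging the allele ends (clipped to the allele) so terminal positions
reach the same expected depth as the interior — without this, sparse
single-read coverage at the ends propagates read errors into the
consensus.

# Diversity and the paired-site protocol

Rarefaction is multivariate hypergeometric subsampling (without
replacement) to a fixed depth, 50,000 reads by default; a sample below the
target depth raises an explicit exclusion condition rather than being
silently truncated. Richness is the count of non-zero taxa and evenness is
the Gini–Simpson index `1 − Σ p²`. Beta diversity uses Bray–Curtis
distance on relative abundances; all pairwise distances are split into
same-patient and different-patient sets, compared descriptively by a
rank-sum test whose output carries an explicit caveat (distances sharing
samples are not independent).

The paired comparison takes, per patient and site, one diseased and one
unaffected sample on opposite sides, rarefies both members of a pair to
the pair's minimum depth (seeded), and applies a two-sided Wilcoxon
signed-rank test per taxon on relative abundances across pairs, with
Benjamini–Hochberg correction by default (Bonferroni/Holm configurable —
the choice of correction is a free parameter of the protocol). Fewer than
six pairs triggers a small-sample warning; zero differences are dropped
per the usual signed-rank convention (via `stats::wilcox.test`, exact for
small n without ties).

# The synthetic cohort: what it emulates and what it does not

The generators are pure functions of their seeds and encode the
statistical structure the analysis assumes:

* **Genomes** evolve by i.i.d. substitutions only (no indels or
  rearrangements), which keeps identity/ANI oracles exact and per-gene
  alignment trivial; the procedures being validated are threshold-based on
  identity, not on gap handling.
* **Contigs** partition their genome (coverage breadth 100%), each with a
  log-normal depth around the genome's mean (positive and right-skewed,
  like real contig depths).
* **The cohort** samples every patient at each site on both sides, one
  side diseased per site. Per-sample counts are multinomial at fixed
  depth from a profile combining the base profile, a per-patient
  log-normal offset (s.d. `subjectSd`, default 0.8) shared by all of a
  patient's samples — this single parameter reproduces the strong
  intra- < inter-subject beta-diversity structure — an independent
  per-sample log-normal noise (s.d. `sampleSd`, default 0.5), and the
  planted multiplier on the effect taxon at diseased sites.
* **MLST reads** are uniformly placed, end-overhanging substrings with
  i.i.d. substitution errors.

The per-sample noise term deserves a note: with subject offsets only,
relative abundances within a pair would differ *solely* through the
planted multiplier, and its compositional renormalisation would make
every null taxon's paired difference perfectly sign-consistent — any
planted effect would render all taxa significant. Real repeated samples of
one subject differ through sampling, temporal and technical variation;
`sampleSd = 0.5` represents that variability and gives the paired test
realistic operating characteristics (measured over 100 simulated
20-patient cohorts: type-I error ≈ 4% for any-taxon false positives,
power ≈ 97% for a 2× planted effect on a genus at 10% base abundance).

The default base profile (`skinBaseProfile()`) is a 12-genus skin-like
composition dominated by *Propionibacterium*, *Corynebacterium*,
*Staphylococcus*, *Micrococcus* and *Malassezia*, with the effect-bearing
*Staphylococcus* at 10% — within the range observed on sebaceous and dry
skin. Effect sizes and noise levels are free parameters chosen for test
power rather than fitted to any cohort.

What the generators do **not** emulate: gapped evolution, horizontal
transfer, strain mixtures within a sample, human-read contamination,
sequencing-depth variation between samples, and read-level shotgun
simulation of whole metagenomes. Passing tests therefore demonstrate the
correctness and calibration of the procedures under their stated
assumptions, not performance on real skin metagenomes.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; the tabular hit format on
  disk is 1-based inclusive, minus-strand rows are normalised on read.
* All strict thresholds (90/90, 97.5 ANI, 500 bp / 70% / 95% core
  filters, 1000 nt binning) use exclusive comparisons, following the
  "higher/longer/more than" wording of each rule.
* K-means uses 10 restarts under a local, restored RNG seed; every
  stochastic function takes an explicit `seed` and is byte-reproducible.
* Degenerate inputs have defined behaviour: empty sequences align to
  nothing (not an error); a contig with no hits gets breadth = identity
  = 0; fewer than two residual contigs form a trivial bin; an all-gap
  alignment, an empty core, a zero-variance Welch test and a too-shallow
  rarefaction each raise descriptive errors; a lone bin's separation is
  vacuously infinite, and two bins with coincident centroids are both
  rejected.
* In bin curation, a zero GC or coverage median makes the relative
  deviation infinite (rejection), avoiding division-by-zero.

# Validation problem sizes

The suite validates: the breadth/identity computation against a per-base
boolean-array oracle (200 random instances); 90/90 assignment recall on
contigs at divergence 0.01 and absence of false assignments at 0.15 (10
seeds, 30-kb genomes); recovery of 3 planted genomes by clustering +
curation (ARI, 10 seeds — the planted bins are generated with coverage
log-noise s.d. 0.06 and 8-kb contigs so that their scatter lies within
the curation tolerances they are claimed to satisfy); ANI calibration at
divergences 0.005–0.10 on 100-kb genomes and the strictness of the 97.5
boundary (20 seeds per call class); ortholog/core filters against brute
force on an enumerable pangenome; NJ topology recovery (10 seeds, 6–8
taxa, 24 genes × 1 kb); MLST allele recovery at 20× / 1% error (10
seeds) and the exhaustive strain-rule truth table (129 combinations);
closed-form diversity identities and the hypergeometric rarefaction
expectation (1000 resamples); paired-test type-I error and power (100
cohorts each); and byte-identical pipeline reports under a fixed seed.
`scripts/acceptance.R` recomputes all of these from scratch.

# Known limitations

* The ungapped native aligner is not a general-purpose BLAST replacement;
  diverged real genomes with indels need an external mapper, whose hits
  are ingested via `readHitTable()`.
* GC–coverage binning uses two features only; tetranucleotide or
  co-abundance signals across samples are out of scope.
* The MLST consensus models the dominant strain only; within-sample
  strain mixtures are not deconvolved.
* The NJ tree carries no support values; it is a placement aid, not a
  substitute for model-based phylogenetics.
* The intra/inter beta-diversity comparison is descriptive; pairwise
  distances are dependent and the reported p-value must not be read as a
  calibrated test.
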