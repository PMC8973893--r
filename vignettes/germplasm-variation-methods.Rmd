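---
title: "Methods: building and characterizing a population SNP resource for a germplasm collection"
author: "GermplasmVarKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and characterizing a population SNP resource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GermplasmVarKit)
```

## Scope and model of the data

GermplasmVarKit re-implements, as a tested and reusable pipeline, the
computations used to build and characterize a population-scale SNP resource
for a diverse crop germplasm collection containing both a domesticated
species group and its wild relative (the motivating system is soybean,
*Glycine max* and *G. soja*). The package takes a biallelic-SNP population
callset (VCF with per-genotype depth and site quality), a reference genome
(FASTA), gene models (GFF3), accession metadata, an optional chip-panel
genotype matrix and optional per-variant deleteriousness scores, and
produces:

* a filtered callset (depth, site quality, SNP-cluster windows, minor
  allele frequency, missing rate),
* a 30-category per-SNP structural/functional annotation report,
* cross-platform concordance, duplicate detection and best-match "genomic
  equivalent" accession assignment,
* population structure (identity-by-state distances, a neighbor-joining
  tree, principal components) and linkage-disequilibrium characterization
  (pruning, decay curves, decay distance at $r^2 = 0.2$),
* a PC-adjusted single-marker association scan with a Bonferroni
  genome-wide threshold.

Read alignment and variant calling are out of scope: the package consumes a
VCF. Genotypes are modelled as unordered diploid allele pairs (alt-dosage
0/1/2, `NA` missing); phase is ignored throughout, matching the unphased
output of population-scale callers. The central container is
`GenotypeData`, a `RangedSummarizedExperiment` whose rows are 1-bp SNP
ranges carrying `ref`/`alt`/`qual` and whose `"GT"`/`"DP"` assays hold
dosage and depth.

## The filter cascade

Filters run in a fixed order, and each stage's report reconciles exactly
(input = removed + surviving):

1. **Genotype masking** — calls with read depth `< 5` become missing; a
   call without depth information is retained (and this is logged once).
2. **Site quality** — sites with phred-scaled quality `< 50` are dropped.
3. **SNP-cluster windows** — any site lying in at least one 10-bp window
   containing more than 2 sites is removed, together with its whole
   cluster. Dense clusters typically mark alignment artifacts; removing the
   entire cluster (rather than retaining an arbitrary two members) keeps
   the rule order-independent and testable against an exhaustive oracle.
4. **Population filter** — per site, the missing rate must be `< 0.5`, the
   called fraction `>= 0.20`, and the minor allele frequency `> 0.001`.
   MAF is computed over non-missing alleles only; a heterozygote
   contributes one allele of each kind.

The "minimal coverage of 20%" rule is interpreted as a per-site
called-genotype fraction, the only reading available without alignments;
with the default thresholds it is implied by the missing-rate rule and acts
only when `maxMissing` is relaxed. `mafPartition()` reports site counts
above additional MAF thresholds (0.01, 0.05 by default), the usual summary
of how a permissive callset shrinks under stricter MAF cuts.

## The 30-category annotation report

Each SNP receives one report row with exactly 30 columns: location and
alleles (1-6), region and feature classification (7-12), codon-level
consequence (13-20), deleteriousness (21-22) and population/per-species
allele frequencies (23-30). Feature resolution uses the priority
`splice_site > start_codon > stop_codon > CDS > UTR5 > UTR3 > intron`,
with splice sites fixed at the first/last two intronic bases of every
intron (the canonical GT/AG donor and acceptor dinucleotides). Intergenic
SNPs carry the distance to the nearest gene boundary instead.

Codon consequences are computed on the spliced, strand-oriented CDS:
the alternative base is reverse-complemented for minus-strand transcripts,
substituted into the affected codon, and both codons are translated with
the standard nuclear genetic code. Effect classes are `synonymous`,
`stop_gained` (premature stop), `stop_lost`, `start_lost` (first codon no
longer ATG), otherwise `nonsynonymous`; substitutions that exchange one
stop codon for another at the annotated stop are synonymous but still
countable under the positional "at stop codons" tally. One transcript per
gene is assumed (the generator emits one); with multiple transcripts the
longest CDS would be annotated and recorded in the transcript column.
`stop_gained` is tallied separately from `nonsynonymous` in summaries,
since reports of this kind list premature stops as their own category.

Deleteriousness is consumed, never computed: a supplied score table keyed
by (chromosome, position, alt) sets the flag iff the SNP is nonsynonymous
and the score is at or below -4.1, the conventional cutoff for
protein-variation effect scores. Scores supplied for non-nonsynonymous
SNPs are ignored and logged.

With zero CDS SNPs the synonymous/nonsynonymous percentages are reported
as undefined (`NA`), not 0.

## Concordance and genomic equivalents

Identity between two genotype sources is the ratio of identical genotypes
to all coordinates compared, over shared (chromosome, position)
coordinates where both sources have a call; no-calls are excluded from the
denominator. Comparison is at the genotype level — a heterozygote never
matches a homozygote — which is the stricter, deterministic choice where
allele-level credit would be ambiguous. Comparisons resting on fewer than
30 coordinates are flagged low-confidence, and identities are conventionally
displayed at 0.01% precision. Chip genotypes use an `AA`/`AB`/`BB`/`NN`
coding defined against the companion VCF reference allele, so platform
allele reconciliation reduces to coordinate intersection. Best-match
assignment (`bestMatch()`, `matchAccessions()`) reports the full tie set
and picks the lexicographically smallest identifier as primary.

## Structure and linkage disequilibrium

* **IBS**: per pair of accessions, the shared-allele fraction per site of
  unordered diploid genotypes is 1, 0.5 or 0; the distance is one minus its
  mean over sites called in both.
* **Neighbor joining** is implemented in-package (Saitou-Nei agglomeration,
  three-point branch lengths, negative branches clamped to zero,
  trifurcating final join); reference implementations serve only as
  independent oracles in the tests.
* **PCA** mean-imputes missing dosages, drops zero-variance sites, and
  scales each centered site by $\sqrt{2p(1-p)}$ — the binomial
  standardization that stops common sites dominating the covariance —
  before eigen-decomposing the accession covariance.
* **LD** is the squared Pearson correlation of dosages over commonly called
  accessions. Decay curves bin mean $r^2$ by pair distance (default bin
  width `maxDist/100`); the decay distance applies a centered 3-bin moving
  average and linearly interpolates the first crossing below the threshold
  (default $r^2 = 0.2$). The maximum pair distance defaults to 1 Mb
  (the conventional reading of a "MaxDist 1000" kb setting) and is
  configurable; the desk-scale pipeline uses 50 kb to match its miniature
  chromosomes. Group-wise curves subset accessions by germplasm type
  *before* MAF filtering, because group allele frequencies differ.
* **Pruning** drops sites above 0.2 missing rate, then greedily scans left
  to right, dropping any site whose $r^2$ with an already retained site
  within the window exceeds 0.5.

## Association scan

The scan fits, per site passing the MAF filter (default 0.01), the
fixed-effect model `trait ~ intercept + PCs + dosage` on accessions with a
called genotype and a defined trait, and reports the Wald p-value for the
dosage term. This is a deliberate simplification of a kinship mixed model:
the leading genotype principal components absorb broad structure, the fit
is deterministic and dependency-free, and the planted-truth experiments
show it is sufficient at this scale (the tests verify that PCs shrink the
median chi-square inflation under a structured null, and that a planted
QTL at $h^2 = 0.3$, $n = 600$ is the genome-wide lead at the Bonferroni
threshold `0.05 / m` in at least 95% of seeds). Binary traits run through
the same linear model on 0/1 coding; there is no logistic option.
Significant sites within 200 kb on a chromosome merge into peak regions
(the scale of an LD block around a strong QTL in a diverse collection),
with the minimum p-value as lead.

## The synthetic collection

The generator defines the study conditions under which everything above is
tested; its defaults are fixed and are not tuned per experiment.

* **Genome and genes**: 2 chromosomes of 50 kb; 20 non-overlapping genes on
  random strands, each with a 5' UTR, 2-3 CDS exons (start codon, terminal
  stop, no internal in-frame stop, total length divisible by 3), GT..AG
  introns of 60-120 bp and a 3' UTR. Gene sequences are written into the
  returned reference so annotation is exact by construction.
* **Allele frequencies**: per segregating site an ancestral frequency is
  drawn uniform on (0.05, 0.95) and diverged into the wild and cultivated
  groups with the Balding-Nichols beta construction at an Fst-like
  parameter (default 0.3) — the standard single-parameter divergence model.
  Each group then keeps the site polymorphic with probability equal to its
  diversity scaler (wild 1.0 > cultivated 0.4), otherwise fixes it; this
  reproduces the strong wild > cultivated diversity contrast of such
  collections.
* **Linkage**: accession haplotypes are Li-Stephens-style mosaics of a
  founder pool, with switch probability $1 - e^{-d/L}$ between adjacent
  sites. The cultivated group uses a much smaller pool (3 vs 30 founders)
  and longer copying tracts (10 kb vs 2 kb), emulating a domestication
  bottleneck: its background $r^2$ (about $1/K$) starts well above 0.2 and
  decays slowly, while wild LD starts low and decays fast, giving the
  wild-decays-faster ordering on every seed tested. A side effect of a
  3-founder pool on a very small genome is occasional background accession
  pairs of high similarity; duplicate-detection experiments therefore use
  genome sizes (hundreds of kb, >= 10,000 sites) where planted pairs
  separate cleanly from the background.
* **Planted truth**: one site of each effect class (synonymous,
  nonsynonymous, stop_gained, stop_lost, start_lost, splice_site, UTR5,
  UTR3, intron, intergenic) is planted by searching the generated gene set
  for a substitution forcing the class; duplicate accessions are copies
  with genotypes flipped at 0.005 (matching the ~99.5% identity observed
  between re-sequenced duplicates of the same accession); a common causal
  site drives a quantitative trait with noise scaled to the requested
  heritability.
* **Depth and quality**: per-call depth is negative-binomial around a
  14-fold mean coverage (dispersion 8, floored at 1), so a few percent of
  calls fall below the depth-5 mask and both filter branches are
  exercised; site quality is uniform on (20, 80), straddling the
  quality-50 threshold.
* **Chip panel**: a uniform site subsample with independent no-calls
  (default rate 0.1), written in the `AA/AB/BB/NN` coding.

What the generator does **not** emulate: genotyping error on the chip
(platform discordance beyond no-calls), multi-allelic sites and indels,
gene-density and recombination-rate heterogeneity along chromosomes,
selection, admixture gradients between the groups, and multiple transcripts
per gene. Passing tests therefore demonstrate correctness of the
computations under a clean two-group demographic model, not robustness to
every artifact of real re-sequencing data.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its seed from the master seed by
  fixed small offsets, so a configuration is a complete recipe;
  re-running the pipeline reproduces bit-identical output digests.
* Identity with zero comparable coordinates is `NA` (an explicit
  undefined sentinel), never 0 or 100.
* An LD curve with no defined pair $r^2$ (e.g. a monomorphic population)
  is flagged degenerate and its decay distance is `NA`; a curve that never
  drops below the threshold reports `Inf` ("beyond max distance").
* Ties in best-match identity are reported in full; the primary pick is
  lexicographic, making outputs deterministic.
* NJ branch lengths are clamped at zero; the distance matrix must be
  complete, and a pruned panel that leaves an accession pair with no
  common called site falls back to the unpruned matrix for distances.
* PCA requests beyond the matrix rank are truncated with a warning.

## Problem sizes used by the test-suite experiments

The package's property experiments run at deliberately small scale chosen
to make the statistics decisive: the exhaustive codon oracle covers every
CDS position x 3 alternative alleles across 20 genes on both strands
(~10,000 substitutions); filter oracles use 200 random instances of up to
200 sites; duplicate recovery uses ~10,500 sites with three planted pairs
at 0.005 mismatch; structure and LD-ordering run 20 seeds at n = 60 + 60;
association calibration pools 20 null replicates (~28,000 tests) and QTL
power runs 20 seeds at n = 600. These sizes were chosen once, as part of
the study design, to keep every run reproducible on a single CPU.
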