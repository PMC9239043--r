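---
title: "Methods: strain-level population genetics from mapped metagenomic reads"
author: "strainpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level population genetics from mapped metagenomic reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Abundant free-living marine microbes -- the motivating case is the
ammonia-oxidizing archaeon *Candidatus* Nitrosopelagicus brevis, ubiquitous
below the euphotic zone of the oligotrophic ocean -- are not clonal: each
"population" detected in a metagenome is a cloud of closely related strains.
Deep metagenomic time series make this microdiversity measurable without
isolates. Reads mapped against a representative genome carry, in their pooled
base frequencies, the population's nucleotide diversity and site-frequency
spectrum; in their paired-end structure, the linkage between nearby variants
(hence the imprint of homologous recombination); in their per-gene depth,
which fraction of strains carries each accessory gene; and, compared between
samples, the degree of allele-frequency differentiation between oceans and
over time.

`strainpop` implements this analysis stack -- SNV profiling, diversity and
pN/pS, read-pair linkage with rarefaction, Hudson-style FST with outlier
detection and PCoA, Heaps-law pangenome openness, and environment-correlated
allele trajectories -- together with a forward simulator of strain
communities whose ground truth makes every stage testable at desk scale.
The headline field values for this kind of population (genome-wide
nucleotide diversity near 0.02, pN/pS near 0.07, neutral third-position
diversity near 0.28 implying an effective population size of order 10^9)
set the regimes the simulator and tests operate in.

## Data model and coordinates

The reference is a single annotated contig (`genome_annotation`): sequence
plus non-overlapping protein-coding genes with strand and frame. All
coordinates are 1-based and inclusive throughout the package, matching R,
Bioconductor ranges and GFF3; nothing internal uses 0-based offsets. Mapped
read pairs (`read_pair_set`) are ungapped 2 x 150 bp mates located by their
start positions; SAM import/export is provided for interoperability
(`write_sam()`, `read_sam()` via Rsamtools), and FASTA/GFF3 I/O goes through
Biostrings and rtracklayer.

One geometric convention matters. The library's "median insert of ~250 bp"
is interpreted as the **inner mate distance**, so a fragment spans about
550 bp (150 + 250 + 150). This is the only reading consistent with
computing linkage for SNV pairs up to 420 bp apart from read-pair
co-observations: with a 250 bp *outer* fragment no read pair could bridge
more than 249 bp. `insert_sizes()` therefore reports inner distances, and
the simulator's insert distribution is Normal(250, 60) truncated so mates
always fit. A side effect of this geometry, visible in real libraries too,
is a co-observation "shadow" at intermediate distances (~150-300 bp):
distances too long to fall within one mate and too short to straddle the
typical gap between mates are rarely observed, so those decay-curve bins
carry few pairs.

## SNV profiling

`build_pileup()` tabulates A/C/G/T counts per site. Mates are filtered
individually at >= 94% identity to the reference -- the conventional gate
for excluding reads from non-target relatives. Where both mates of a pair
overlap a site, the template is counted once (first mate wins): the two
mates sequence the same molecule. Coverage is the count sum; breadth is the
fraction of sites with any coverage. Population detection uses strict
inequalities, mean coverage > 5x and breadth > 0.5 (the 10x / 0.8 preset is
used when comparing diversity between populations, where estimator noise at
low depth would dominate).

`call_snvs()` declares a site an SNV when coverage >= 5 and at least two
alleles each reach frequency >= 0.05 **and** count >= 2; the count condition
suppresses sequencing-error alleles at high depth, the frequency condition at
low depth. With a per-base error rate of 10^-3 at 50x these thresholds leave
fewer than 1 in 10^3 monomorphic sites falsely called (tested). Coding SNVs
are classified against the **sample consensus codon** (majority base per
site), not the reference: classification should reflect the resident
population, which may be fixed for a non-reference allele. Multi-allelic
tie-break: if any called non-consensus allele changes the amino acid, the
SNV is nonsynonymous -- conservative for pN. Substitutions into or out of a
stop codon count as nonsynonymous.

Nucleotide diversity is the pooled-read estimator
pi_s = 1 - sum_b f_b^2, averaged over sites with coverage >= 5; sites below
threshold leave both numerator and denominator. No (n/(n-1)) small-sample
correction is applied; at the 20-50x depths this package targets the
correction is a 2-5% multiplicative factor, and leaving it out matches the
pooled definition used across metagenome profilers. Users comparing with
corrected estimators should scale accordingly.

pN/pS counts mutational opportunities Nei-Gojobori style from consensus
codons: each codon position contributes a synonymous weight equal to the
fraction of its three substitutions that are synonymous. Per gene,
pN/pS = (N_snv/N_sites)/(S_snv/S_sites); a gene with no synonymous SNVs has
an undefined ratio (not infinity), and the genome value is the unweighted
mean over genes where it is defined. The site counting is verified against
exhaustive enumeration of all single-base codon substitutions.

"Neutral" diversity is operationalized as mean per-site diversity at third
positions of 4-fold degenerate consensus codons (any third-position base
preserves the residue). This is a deliberate, stated choice: other
operationalizations of "nonconserved third positions" (e.g. including
2-fold sites, or masking cross-sample conserved sites) exist, and the
eligible-site count n is always reported alongside the estimate. The
effective population size lower bound is
N_e = 1.5 pi_neutral / (mu (3 - 4 pi_neutral)) with mu = 10^-10 per bp per
generation by default; evaluating it at pi_neutral = 0.284 gives
~2.3 x 10^9. It is a lower bound because third positions are not all
neutral and high-diversity sites approach saturation.

## Read-pair linkage

`enumerate_linked_pairs()` links SNVs co-observed on the same read pair:
an allele seen on either mate counts, and a pair whose mates disagree at a
site is discarded for that site. Each SNV is projected to its top two
alleles (consensus + most frequent called non-consensus); bases outside the
projection are ignored. Pairs up to 420 bp apart with at least 20
connecting read pairs are retained -- below 20 haplotype counts, r^2 is
dominated by sampling noise. Intergenic SNVs are excluded from the default
stratification (N-N / N-S / S-S by coding effect), which describes linkage
in protein-coding sequence.

r^2 = (f_AB - f_A f_B)^2 / (f_A(1-f_A) f_B(1-f_B)) on connecting-pair
haplotype counts. Because r^2 at fixed true linkage rises as the number of
sampled pairs falls, values are normalized by **rarefaction**: the mean of
r^2 over 100 random subsamples of exactly 20 connecting pairs (without
replacement, seeded). Subsamples with a monomorphic margin are redrawn (up
to 10 x 100 attempts; if none succeeds the value is undefined). When a pair
has exactly 20 connecting pairs the rarefied value equals the raw value.
The finite-sample null of this statistic is E[r^2] ~ 1/20, not 0 -- decay
curves flatten toward 0.05, not zero. Decay curves use 30 bp bins over
0-420 bp (14 bins, matching the granularity at which read-pair linkage is
usually displayed); empty bins are reported as empty, never as 0.

Across populations, mean genome r^2 falls as diversity rises when
recombination is what maintains the diversity. The simulator reproduces
this **only** when the pool ensemble encodes that mechanism: the package's
validation ensemble couples higher target pi with shorter ancestral block
length (2000/800/300/120 bp for pi = 0.005/0.01/0.02/0.04). With block
length held fixed, pi and r^2 are causally unlinked in the generator and
the rank correlation is near zero -- a useful reminder that the negative
correlation in field data is a statement about mechanism, not an estimator
property.

## Between-sample differentiation

Gene-level FST between two pooled samples uses the Hudson estimator with a
finite-depth correction: per locus,
num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1) and
den = p1(1-p2) + p2(1-p1), aggregated per gene as a **ratio of sums** --
lower variance than averaging per-locus ratios, at the cost of weighting
loci by their denominators. Loci are SNVs of the pooled pair profile with
depth >= 20 in both samples and within 2 SD of each sample's mean locus
depth (two-sided, per sample; the filter removes collapsed repeats and
deletions). Slightly negative gene values are legitimate finite-depth noise
and are retained in means -- clamping at zero would bias the genome-wide
mean upward. The estimator is verified against the infinite-depth
haplotype-frequency oracle and recovers simulated two-deme targets of
0.05/0.2/0.45 within 15% at 50x.

FST outliers: z = (FST_g - mean)/SD over defined genes, upper-tail normal
p, Benjamini-Hochberg, flag at adjusted p < 0.05. The normal (not t)
reference is appropriate at the gene counts this is meant for (hundreds);
the function refuses to run below 10 genes.

The pairwise mean-FST matrix (samples with genome coverage > 20x; genes
> 20x in both samples of each pair; self-pairs defined 0) is embedded by
classical PCoA after Cailliez correction: the smallest constant added to
off-diagonal dissimilarities making the configuration Euclidean, found as
the largest real eigenvalue of the standard 2n x 2n companion problem, then
`cmdscale`. Embedded distances reproduce the corrected dissimilarities to
1e-6, and the implementation is cross-checked against `ape::pcoa(...,
correction = "cailliez")` in the tests. Negative mean FSTs are clamped to 0
before embedding (a dissimilarity must be non-negative).

Divergence dating compares majority-rule consensus sequences at annotated
third codon positions covered >= 5x in both samples: d3 = differing/total,
T = d3/(2 mu) generations (both lineages accumulate mutations -- hence the
factor 2), years = T x 7/365.25 with the default 7-day generation time.
Shared polymorphism and saturation both deflate d3, so T is a lower bound.

## Pangenome flexibility

Relative gene coverage r = gene depth / genome mean depth estimates the
fraction of strains carrying a gene. Entries with r > 3 (strictly) are
masked -- such genes are usually shared with other community members or
mis-binned -- and masking is distinct from r = 0, which is evidence of
absence. Differential presence between two sites is a per-gene one-way
ANOVA on unmasked r values (>= 2 values per group), BH-adjusted, flagged at
adjusted p < 0.001. Basin-specificity is then assessed within a slightly
wider gate (adjusted p < 0.01): a gene is site-A-specific when detected
(r > 0.10, strictly) in at least one A sample and r < 0.10 in every
unmasked B sample. The two thresholds are deliberately separate presets
(`differential_p`, `basin_gate_p`): the stricter one defines the headline
differential set, the looser one admits borderline genes into the
specificity classification. The boundary r = 0.10 counts as neither
detected nor absent-qualified, so a boundary sample blocks specificity.

Pangenome openness fits Heaps' law P(N) = kappa N^gamma to the gene
accumulation curve of a genomes x gene-clusters presence/absence matrix:
100 random genome orders, median curve across permutations (robust to
extreme orders), least squares on log P vs log N. gamma near 0 is a closed
pangenome; gamma near 1 means every genome contributes novel genes. The
paired generator `simulate_presence_absence()` draws cluster occurrence
probabilities from a truncated power law and calibrates its latent
parameters numerically -- via the closed-form expected accumulation curve --
so that the *same log-log fit* applied to the expectation returns the
requested gamma; recovery of gamma = 0.18 and 0.44 is within +/- 0.05
across seeds.

## Temperature-correlated allele trajectories

The trajectory matrix fixes the SNV set and focal allele on the pooled
pileup across all samples (focal = most frequent non-consensus allele in
the pool), then records per-sample focal frequencies; entries below 20x are
missing, never zero. Correlation with the covariate is Spearman's rank
(average ranks, t-approximation p-values via `cor.test(exact = FALSE)`),
over pairwise-complete observations, BH-adjusted, flagged at adjusted
p < 0.05. Only nonsynonymous SNVs are tested by default -- the class where
environment-tracking sweeps are interpretable -- and a minimum of 8
non-missing time points is required (an artifact choice: rank correlations
on fewer points are too coarse for the t-approximation; both the class
restriction and the minimum are arguments).

## The synthetic community generator

The generator defines the study conditions downstream stages are validated
under:

* **Reference** (`simulate_reference()`): one contig, non-overlapping
  proper ORFs (ATG start, no internal stops, terminal stop), strand random,
  GC controlled within +/- 0.02.
* **Strain pools** (`simulate_strain_pool()`): strains are mosaics of
  ancestral blocks -- per block each strain draws one of 4 ancestors, and
  segregating sites inherit ancestor alleles, so linkage exists within and
  not across blocks. Site frequencies come from Beta(0.5, 0.5) (both common
  and rare variants); the site set is thinned (and, for high targets,
  rebalanced toward 50/50 splits or 4 balanced alleles) so expected pi
  matches the target exactly as computed from the emitted haplotypes. This
  is a construction with controllable pi and LD length, not a coalescent:
  it makes no claim of demographic realism.
* **Reads** (`simulate_sample_reads()`): uniform fragment starts
  (Poisson-like depth -- the per-site depth distribution is not otherwise
  specified by the analysis), strain drawn per fragment from the pool
  weights, i.i.d. substitution errors uniform over the three alternative
  bases, no indels and no quality scores (the analysis is SNV-only).
  Realized coverage (emitted bases / genome length) is within 10% of the
  request; accessory intervals a community lacks are never sampled.
* **Two demes** (`simulate_deme_pair()`): Balding-Nichols per-site
  frequencies around a shared ancestral Beta(0.5, 0.5) draw; the
  differentiation parameter is iteratively re-drawn so the truth FST
  computed from realized haplotype frequencies (ratio of sums) hits the
  target within 2%. Optional planted high-FST genes (for the outlier test)
  and site-exclusive accessory genes (for the specificity test); the deme
  that lacks a gene never emits reads from it, which also creates realistic
  coverage shoulders at the gene's flanks.
* **Time series** (`simulate_time_series()`): responsive nonsynonymous
  sites follow freq(t) = logistic(a + b T(t)) plus Gaussian jitter
  (sd 0.02) -- bounded frequencies with a monotone association a rank test
  can detect; neutral sites get exchangeable jitter. Haplotypes are
  re-realized per time point with **exactly** round(f n) alt-carrying
  strains, so the realized frequency tracks the model rather than adding
  binomial strain-sampling noise on top of the modelled jitter. A
  consequence: time-series samples carry no linkage block structure, so
  linkage analyses use dedicated recombining pools.

What the generator does **not** emulate -- and what green tests therefore
do not demonstrate about field data: selection (so SNV class fractions and
pN/pS are near-neutral expectations, not the strongly purifying ~0.07
observed in real populations of this kind), indels and structural variants,
mapping ambiguity and chimeric reads, quality-score miscalibration, and
demographic history. Estimator correctness and error control transfer to
real data; effect-size realism does not.

## Numerical choices, degenerate inputs, determinism

* Threshold semantics follow their phrasing: detection gates are strict
  (`> 5x`, `> 0.5`); calling thresholds are inclusive (`>= 5x` coverage,
  `>=` frequency/count); masking is strict (`r > 3`), detection strict
  (`r > 0.10`).
* Undefined is never silently zero: diversity with no eligible sites,
  pN/pS with no synonymous SNVs, r^2 with a monomorphic margin, FST with a
  zero denominator, and empty decay bins are all NA with the eligible count
  reported where meaningful.
* Consensus ties break deterministically toward A < C < G < T; at zero
  coverage the consensus falls back to the reference base.
* All randomness flows through mandatory `seed` arguments; the caller's RNG
  state is saved and restored, so package functions are pure functions of
  (arguments, seed) and identical configurations reproduce byte-identical
  outputs (tested).
* BH adjustment is the textbook step-up procedure (via `p.adjust`), checked
  against brute-force enumeration.

## Problem sizes

Validation and the bundled analyses run on 20 kb genomes with 20 genes,
20-40 strains, 30-60x coverage, 12 monthly time points and 20-genome
presence/absence collections. These sizes put every estimator in its
intended operating regime (hundreds of SNVs per sample, hundreds of linkage
pairs, >= 300 FST loci) while keeping any single stage under a minute; all
scale linearly if users raise them.

## Known limitations

Reference-based profiling truncates highly diverged strains: at pi ~ 0.1 a
strain is ~7% diverged from the reference and the default 94% identity
filter removes its reads, biasing pi down by a factor of ~3. Recovery
experiments at that diversity therefore disable the filter; on real data
the filter should be set below the population's expected divergence from
its reference, or the bias accepted as part of the operational definition.
Linkage is bounded by the library insert; the mid-range co-observation
shadow and the 420 bp horizon are properties of 2 x 150 bp libraries, not
of the populations. The N-N > S-S linkage excess seen in field data is a
signature of selection and is not reproduced by this neutral simulator.
Gene clustering, read mapping, binning and annotation are out of scope: the
package consumes a reference, gene models and mapped pairs.
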