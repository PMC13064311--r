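---
title: "Methods: population-genomic scans in popsweep"
author: "popsweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic scans in popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popsweep implements the post-variant-calling stage of a multi-population
resequencing study: from a jointly genotyped, phased SNP matrix to per-population
diversity, inbreeding, differentiation, linkage disequilibrium, population
structure and haplotype-based selection scans. This vignette documents the
models, the defaults and their rationale, the numerical choices, and what the
simulation-based tests do and do not establish.

## Data model and filtering

Genotypes are held as alt-allele dosages (0/1/2/NA) in a samples-by-variants
matrix (`geno_matrix`), phased haplotypes as a 0/1 matrix with two rows per
sample (`haplo_set`) in which allele 0 is the ancestral allele wherever the
ancestral state is known (INFO key `AA`; unknown sites stay reference-coded).
User-facing coordinates are 1-based inclusive throughout.

The filter cascade mirrors common GATK-style practice:

1. **Hard filters** (`apply_hard_filters`): a variant is removed when any
   *available* annotation violates its threshold — QD < 2.0, QUAL < 30.0,
   SOR > 3.0, FS > 60.0, MQ < 40.0, MQRankSum < −12.5, ReadPosRankSum < −8.0.
   All inequalities are strict, so values sitting exactly on a threshold are
   retained. Missing annotations never remove a variant; they are counted in
   the report, matching the behaviour of the usual variant-filtration tools.
2. **Site filters** (`filter_sites`): biallelic single-nucleotide variants on a
   caller-supplied autosome list, genotype call rate ≥ 50% and minor allele
   count ≥ 2, both computed jointly over all samples. The autosome set is a
   required argument rather than a built-in karyotype, because simulated and
   real assemblies name chromosomes differently.

Filter reports attribute each removed variant to the *first* criterion it
fails, in the documented order, so per-criterion counts always sum to
input − output. Multi-allelic records are kept (flagged) at read time and
removed by `filter_sites`, so they are countable.

## Windows

All windowed statistics share one grid: 40 kb windows advanced by 20 kb,
anchored at position 1 of each chromosome, the last window truncated at the
chromosome end. The anchor is a convention (any fixed anchor gives an
equivalent grid); each SNP falls in up to two windows.

## Diversity, heterozygosity and inbreeding

* Per-site nucleotide diversity is the mean pairwise difference
  `2 n_alt (n_called − n_alt) / (n_called (n_called − 1))`; windowed π divides
  the per-window sum by the full window span in bp (invariant positions count),
  and is reported in percent.
* Individual observed homozygosity `O_hom`, its expectation
  `E_hom = Σ (1 − 2p(1−p) n/(n−1))` over polymorphic sites called in the
  individual, and the method-of-moments inbreeding coefficient
  `F = (O_hom − E_hom)/(S − E_hom)`. Population-level estimates are obtained by
  subsetting to one population first, so allele frequencies are
  population-specific.
* Expected heterozygosity is the unbiased `2p(1−p) n/(n−1)` averaged over sites
  polymorphic within the population. The n/(n−1) small-sample correction is a
  design choice; with resequencing-scale sample sizes it is numerically
  negligible.

## Runs of homozygosity

`detect_roh` decodes a two-state HMM (NORMAL / AUTOZYGOUS) per sample and
chromosome by Viterbi. Emissions use the alt-allele frequency within the
sample's own population: P(het | NORMAL) = 2p(1−p)(1−e) + e(1 − 2p(1−p)),
P(het | AUTOZYGOUS) = e with e = `e_het` = 1e-3. Transitions between markers
d bp apart are 1 − exp(−t·d) with entry rate `t_in` = 1e-8/bp and exit rate
`t_out` = 1e-7/bp, which puts the prior autozygous-segment scale in the Mb
range; all three are tunable. Sites monomorphic within the population carry no
information and are excluded before decoding; missing calls are skipped with
distance accumulating across them. Segment coordinates are the first and last
marker of the autozygous run — reproducible from the SNP set alone, unlike
midpoint conventions.

Two consequences are worth noting. First, the detector can only see
autozygosity at sites that are polymorphic within the population, so in a
population that is almost completely inbred, fixed autozygous regions are
invisible (and arguably not "runs" against any reference of variation).
Second, reported length classes (0.3–1, 1–2, 2–4, 4–8, 8–10, 10–16, > 16 Mb)
partition segments ≥ 300 kb with ≥ 10 markers (inclusive bounds), and
per-individual means include individuals with no segments. F_ROH divides the
per-individual total by the autosomal genome size, 960.8 Mb for chicken by
default and configurable (whether to count only SNP-covered sequence is left
to the caller).

## Weir–Cockerham FST

`wc_components` computes the two-population variance components a, b, c from
per-site sample sizes, allele frequencies and observed heterozygote fractions.
Window and genome-wide values are the "weighted" ratio of sums Σa / Σ(a+b+c)
over informative sites — not the mean of per-window values, which is a
different (and biased) estimator. Sites monomorphic across both populations,
or with fewer than one called diploid in either, are uninformative and
excluded. Negative estimates are reported as computed.

## Linkage disequilibrium

Pairwise r² is either the haplotype-based D²/(p_A q_A p_B q_B) or the squared
Pearson correlation of dosages over jointly called samples (genotype mode, the
default — decay on unphased data is then possible and matches the behaviour of
standard decay tools). Decay curves aggregate all intra-chromosomal pairs
within 500 kb: full per-bp resolution up to 1 kb, 1 kb bins after. Pruning
follows the familiar `indep-pairwise 50 5 0.2` scheme; within each 50-SNP
window every pair of retained SNPs with r² > 0.2 drops the *later* SNP, and
the window advances by 5 SNPs. Dropping the later SNP is a determinism choice;
the convention is stated rather than prescribed by the tools this mirrors.

## PCA and admixture

PCA standardises each SNP as (g − 2p)/√(2p(1−p)) with missing entries set to 0
after centring, eigendecomposes the sample covariance, and fixes each
component's sign so its largest-magnitude coordinate is positive. Explained
variance fractions are eigenvalues over the sum of positive eigenvalues.

The admixture model maximises the binomial log-likelihood
LL = Σ g log θ + (2−g) log(1−θ), θ = QF, by plain EM with Q rows renormalised
to the simplex and F clipped to [1e-6, 1−1e-6] to avoid log(0). EM is
monotone in LL (asserted in the tests); five random restarts (default) guard
against local optima. Model selection masks random folds of non-missing
genotype *entries* (20 by default), refits, and scores held-out entries by
binomial deviance; the entry-masking scheme is this package's choice — the
common external tool does not document its internals — and behaves as expected
(deviance minimised at the simulated number of ancestral populations,
monotone increase beyond k=1 for panmictic data). CV fits use one restart for
speed.

## Selection scans

EHH at distance x from a core SNP is the probability that two random carrier
haplotypes are identical over all markers between the core (exclusive) and x
(inclusive); it starts at 1 and only decreases. Curves truncate at the first
marker where EHH < 0.05 (`ehh_floor`). iHH is the trapezoidal integral of EHH
against physical position over both flanks (no genetic map is assumed);
integration stops before the first below-floor marker. Inter-marker gaps are
not penalised by default; a `max_gap` option can truncate flanks at large gaps.

* **iHS** (within one population): raw = ln(iHH_ancestral / iHH_derived) at
  cores with known ancestral state and MAF ≥ 0.05, standardised within
  derived-allele-frequency bins of width 0.025. The floors and bin width are
  the conventional defaults of the rehh-style toolchain and are configurable.
* **XP-EHH** (between populations): allele-agnostic EHH over all haplotypes of
  each population, raw = ln(iHH_A / iHH_B), standardised genome-wide; positive
  values mean longer haplotypes (a sweep) in the first-named population.

A computational note: sites monomorphic within a population cannot split that
population's haplotype partition, so the scan skips the partition update there;
the EHH value and integral are mathematically identical, and the scan runs
several-fold faster.

Windowed |iHS| and |XP-EHH| average the absolute standardised scores in the
standard grid, dropping windows with fewer than 10 scored SNPs. Candidate
windows are those strictly above the nearest-rank (1 − 0.001) empirical
quantile, computed per comparison after the window-count filter (only analysed
windows form the distribution). Overlapping or abutting flagged windows merge
into regions; regions are annotated with overlapping features from BED
(0-based half-open) or GFF3 (1-based inclusive) input, both normalised to
1-based inclusive internally, with "gene void" regions annotated by the
nearest feature and its edge distance (ties reported together).

## The Wright–Fisher simulator

`simulate_wf` is a forward-in-time diploid Wright–Fisher simulator: discrete
non-overlapping generations, random mating with selfing excluded, per-gamete
Poisson crossovers (no interference) and infinite-sites Poisson mutations at
unique integer positions, so the ancestral allele is known by construction.
It supports a rooted population tree with per-branch sizes, bottlenecks,
biased full-sib mating, symmetric two-deme migration, and additive viability
selection at one sweep locus (fitnesses 1, 1+hs, 1+2·0.5·s·…, i.e. 1, 1+hs,
1+s). Forward simulation (rather than coalescent) keeps selection, sib mating
and pedigree inbreeding exact: a kinship matrix is propagated each generation,
so every sampled individual carries its exact pedigree F, reported relative to
its population's founders. When sib mating is requested, reproduction runs
through random monogamous couples so that full-sib pairs exist in every
generation; with sib-mating probability 1 and two individuals the classic
full-sib recursion F_t = (1 + 2F_{t−1} + F_{t−2})/4 is reproduced exactly.
A lost sweep allele triggers an internal retry from the sweep start (bounded;
then an error).

The ancestral population can start monomorphic (and burn in for e.g. 10N
generations) or at mutation–drift equilibrium: site frequencies drawn from the
neutral SFS (P(i copies) ∝ 1/i) at linkage equilibrium, followed by a burn-in
of about 2N generations during which LD builds up. Equilibrium starts make
multi-population designs affordable; the calibration checks (below) use the
monomorphic start.

### The six-population study fixture

`emulate_study()` generates the package's standing test design, modelled on a
dual-purpose chicken study: six populations with sample sizes 49 / 25 / 20 /
20 / 23 / 24 — a focal dual-purpose breed, a wild junglefowl-like outgroup,
two broiler-like lines and two layer-like lines. Parameters were fixed once,
on the reasoning below, and are deliberately scaled down: eight chromosomes of
3 Mb, μ = 3e-7 and r = 5e-8 per bp per generation, ancestral N = 125 with a
250-generation equilibrium burn-in. Scaling N down while scaling μ up keeps
per-window SNP counts well above the 10-SNP window minimum (≈ 40–90 SNPs per
40 kb window) at desk-scale cost; consequently absolute values of π, FST and
LD are not comparable to real chicken data, and all fixture-based tests assert
*orderings* and *recovery*, never absolute levels.

* The outgroup splits earliest (280 generations ago) and keeps N = 125:
  highest diversity, fastest LD decay.
* The domestic ancestor (N = 80) splits into the focal population (N = 100,
  sampled 49) and a commercial ancestor; broiler-like lines (N = 60, mild
  sib mating 0.02) are intermediate.
* Layer-like lines pass a strong recent bottleneck (N = 12 between 20 and 3
  generations before sampling, recovering to 60) with sib-mating probability
  0.3. Recent, intense inbreeding is what produces *long* (≥ 300 kb)
  homozygous tracts that remain visible against residual polymorphism; a
  population held small for its whole history instead fixes most of its
  genome, which the ROH detector (correctly) cannot see as runs.
* The focal population carries a hard sweep at chr2:1,500,000 (s = 3,
  h = 0.5) starting 12 generations before sampling, conditioned on reaching
  frequency ≥ 0.9 (bounded retries). The recorded truth interval is the sweep
  position ± its expected haplotype footprint 1/(2 r g), capped at 500 kb.
  Freshness matters: at these scaled rates, new mutations erode the swept
  haplotype at ~2μ per bp per generation, so an old sweep leaves too little
  extended homozygosity, while an effectively instantaneous one leaves a
  plateau wider than the chromosome and the peak window decouples from the
  locus.

What passing fixture tests shows: the estimators rank diversity, ROH burden
and LD decay across demographies as the theory predicts, and the full
XP-EHH → windows → top-0.1% → merge pipeline localises a strong recent sweep
in at least one of the focal-versus-other comparisons (the scan is run against
each other population, mirroring the multi-comparison design it emulates; with
only ~1200 windows per comparison the top-0.1% rule flags one or two windows,
so any single comparison is a coin-flip-free but stringent detector).
What they do not show: calibration against real chicken genomes (sequencing
error, mapping artefacts, variable recombination along chromosomes, gene
conversion and overlapping generations are all absent from the simulator).

## Calibration checks

Three closed-form checks anchor the simulator and estimators (all in the test
suite and the acceptance script):

* neutral π at mutation–drift equilibrium equals 4Nμ (N = 200, 1 Mb,
  μ = 1e-8, 10N burn-in, 50 replicates, 3 Monte-Carlo SE);
* genome-wide weighted FST between two demes at 4Nm = 1 equals
  1/(1 + 4dNm) = 1/3 at d = 2. The Weir–Cockerham estimator contrasts within-
  against between-deme coalescence times (T_w = 2dN, T_b = T_w + 1/(2m));
  definitions that average over all pairs of genes instead give the smaller
  1/(1 + 16Nm) = 0.2 for the same model. Both the closed form and the
  estimator behaviour were cross-checked against an independent coalescent
  implementation during development;
* mean r² between unlinked chromosomes equals the 1/n sampling bias
  (haplotype mode, n haplotypes).

## Problem sizes

The shipped tests and the acceptance script use the fixture sizes stated
above: 20 seeds of the six-population design for ordering/recovery rates in
the test suite (8 in the acceptance script, which also reports the rates), 50
replicates for the neutral-π check, 20 (10 in the script) island-model
replicates, and 10 seeds of a three-population fixture (k selection from
k ∈ 1..5 with 20-fold entry-masked CV on ≤ 300 pruned SNPs). These sizes were
chosen so the whole suite runs on a single desk-scale CPU while leaving the
Monte-Carlo bands meaningful.

## Known limitations

* The ROH HMM parameters are conventions, not estimates; they set the scale of
  detectable segments. The detector under-calls autozygosity in populations
  with little residual polymorphism.
* Admixture's plain EM converges slowly near degenerate optima; restarts
  mitigate but do not guarantee the global optimum.
* XP-EHH/iHS integrate over physical distance; without a genetic map,
  regional recombination-rate variation masquerades as signal (true of the
  original statistics as well).
* The simulator has no gene conversion, no interference, no overlapping
  generations and no sex chromosomes, and its scaled rates trade realism of
  absolute levels for tractable test sizes.
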