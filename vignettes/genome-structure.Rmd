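---
title: "Genome structure from half-sib SNP panels: LD, blocks, Ne and inbreeding"
author: "ldstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome structure from half-sib SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`ldstructure` analyzes diploid autosomal SNP-array genotypes collected under a
half-sib daughter design: a handful of widely used sires, each with many
genotyped daughters out of different, ungenotyped dams.  This is the standard
design of dairy-livestock QTL programs, and it shapes every stage of the
pipeline: marker QC can exploit sire-daughter Mendelian constraints, phase can
be partially deduced from sires, and LD estimation must avoid over-counting
the few sire chromosomes.

The pipeline stages, each available as an exported function and chained by
`runPipeline()`:

1. **Quality control** (`filterIndividuals`, `markerQC`): individuals with
   more than 10% missing genotypes are removed first, so that per-marker
   statistics are computed on the retained animals; markers are then filtered
   sequentially on call rate (>= 0.95), minor-allele frequency (>= 0.05) and
   the exact Hardy-Weinberg test (p > 1e-5).  A marker removed at one step is
   not counted at a later one, so the ledger rows add up — the ledger
   arithmetic (remaining = previous - removed) is asserted at run time.
2. **Mendelian cleaning and imputation** (`mendelianClean`,
   `imputeFromSire`): opposing-homozygote sire-daughter conflicts blank the
   daughter genotype, unless one sire conflicts with more than 5% of its
   daughters at a SNP, in which case the sire genotype is the suspect and is
   blanked instead.  Missing daughter genotypes are then imputed from the
   sire's transmitted-allele distribution convolved with the current
   population frequency, over 10 deterministic passes with frequencies
   re-estimated after each pass; a genotype is only filled when its posterior
   reaches `accept_prob`.
3. **Phase** (`deduceHaplotypes`, `selectIndependentHaplotypes`): only forced
   Mendelian logic is applied (homozygous daughter; heterozygous daughter
   with homozygous sire), so every deduced allele is exactly the transmitted
   allele; ambiguous sites stay missing.  Statistical phasing (HMM/haplotype
   graph) is deliberately out of scope; pipeline runs that need complete
   haplotypes use supplied phase (e.g. the simulator's truth).  For LD, each
   sire contributes its two haplotypes and each daughter only her maternal
   haplotype, which removes the over-representation of sire chromosomes.
4. **Pairwise LD** (`pairLD`, `syntenicLD`, `dprimeCI`): D' and r² are
   computed by direct counting over jointly non-missing haplotypes.
   Confidence bounds on |D'| come from the normalized multinomial likelihood
   on a |D'| grid (step 0.001) with allele frequencies fixed at their MLEs —
   the construction behind the Gabriel block rule.
5. **Blocks** (`classifyPair`, `gabrielBlocks`): a pair is in strong LD when
   CU > 0.98 and CL > 0.70, and shows historical recombination when
   CU < 0.90.  A span qualifies as a block when its boundary pair is strong
   and at least 95% of its informative pairs are strong; qualifying spans are
   accepted greedily by decreasing physical length (leftmost first).  Only
   this core criterion is implemented; the size-stratified sub-rules of
   particular GUI tools are not reproduced.  No span cap is applied by
   default because real panels show blocks beyond common 500-kb caps.
6. **Effective population size** (`bpToMorgans`, `neTrajectory`, `nePoint`):
   pairs are ordered by genetic distance c and stacked into 1,000-pair bins;
   per bin, E[r²] = 1/(1 + 4 Ne c) + 1/n is inverted at the bin means, and
   T = 1/(2c) maps the bin to generations ago.  Three cM/Mb conversion
   policies are available: uniform 1 cM/Mb, a genome-wide average rate, or
   per-chromosome rates supplied as configuration.
7. **Inbreeding** (`fPedigree`, `fMarkers`, `inbreedingTrend`): pedigree F by
   the Meuwissen-Luo ancestor-traversal algorithm (founders unrelated and
   non-inbred; unknown parents are unique founders), and three marker
   estimators — additive-genotype variance (F1), excess homozygosity (F2)
   and correlation of uniting gametes (F3) — with the analyzed sample as its
   own base population unless external frequencies are supplied.  Negative
   marker estimates are legitimate (less homozygous than the base) and are
   clamped to zero only in trend reporting, never in storage.

# Key parameters

| parameter | default | meaning |
|---|---|---|
| `max_missing` | 0.10 | per-individual missing fraction tolerated (strictly more is removed) |
| `min_call`, `min_maf`, `hwe_alpha` | 0.95, 0.05, 1e-5 | sequential marker filters, inclusive as printed |
| `accept_prob` | 0.95 | minimum imputation posterior; must exceed 0.5 |
| `cu_strong`, `cl_strong`, `cu_recomb` | 0.98, 0.70, 0.90 | Gabriel bounds on \|D'\| |
| `min_strong_fraction` | 0.95 | strong-LD share among informative pairs in a block |
| `bin_size` | 1000 | pairs per Ne bin |
| `generation_interval` | 4 years | T-to-calendar conversion in reports |

One interaction deserves a note: on a MAF-ascertained panel (MAF >= 0.05) the
largest achievable single-locus posterior is 0.95 (homozygous sire, frequency
at the ascertainment boundary), so the conservative default `accept_prob =
0.95` effectively disables imputation.  That is a defensible production
default — imputation only fires when it is essentially certain — and the
calibration property (accuracy at least `accept_prob` among imputed
genotypes) is demonstrated in the tests at `accept_prob = 0.75`.

# The simulator: what it emulates, what it does not

`simulatePopulation()` is a forward Wright-Fisher simulator with
recombination: discrete non-overlapping generations, two parents drawn
uniformly with replacement per offspring, Poisson crossovers placed uniformly
on the genetic map, founders in linkage equilibrium with allele frequencies
uniform on [0.1, 0.9], and no mutation afterwards (array sites are
pre-ascertained, and it keeps allele bookkeeping exact).  A burn-in of
4 x max(N) generations at the first trajectory size lets LD equilibrate
before the epoch of interest.  `sampleHalfSib()` draws the study design
(sires, distinct dams, one daughter each; dams not genotyped) with MAF-based
ascertainment, and `degradeGenotypes()` adds missingness and genotyping
error.  Everything is deterministic given the seed, and true phase,
transmission and per-generation N are emitted, so each pipeline stage is
testable against truth.

It does **not** emulate: selection, migration, overlapping generations, sex
chromosomes, genotyping-intensity artifacts, or assembly errors in the
marker map.  Passing tests therefore demonstrate correctness of the
estimators under drift-recombination dynamics, not robustness to
map errors or selection signals in real data.

## Problem sizes

The default desk scale is 4 chromosomes x 500 SNPs x 100 cM (physical map
1 cM ~ 1 Mb), N <= 120 with a burn-in of 4 x max(N), and a 4-sire x
15-daughter design; a full pipeline run takes about half a minute.  The
effective-size validations use 2,000 SNPs per chromosome: with no mutation
and a 4N burn-in, most founder sites fix, and roughly 500-700 segregating
ascertained SNPs per genome are needed so that 1,000-pair bins cover
T in [5, 50].

## Validation conditions chosen for identifiability

Two validation design choices are worth recording explicitly.

First, the chromosomes of the validation cohort are drawn as *fresh
recombinant gametes* from the final generation (`sampleGametes`), not by
subsampling pool rows without replacement: drawing n of the 2N existing
chromosomes hypergeometrically understates sampling variance relative to the
multinomial model behind the 1/n term, which at n = 2N/2 inflates recovered
Ne by roughly a quarter.  Gamete draws are also what genotyping a new cohort
of animals actually samples.

Second, the declining-history check uses a recent, sharp contraction
(120 to 30 diploids over the last 10 generations) rather than a gradual
decline.  LD at genetic distance c relaxes toward its new equilibrium at
roughly 2c + 1/(2N) per generation, so with desk-scale N every usable bin
forgets a decades-old gradual decline; after a recent contraction the
short-range bins re-equilibrate to the small size quickly while long-range
bins still remember the ancestral size, making the monotone trend
identifiable.  At study scale (tens of millions of pairs, N in the hundreds)
the gradual decline is the realistic picture; the contraction is its
desk-scale analogue, not a claim about any real population.

For the same reason, the cross-mode agreement of the three cM/Mb conversion
policies is checked through its exact content — a genome-wide rate R rescales
the binned trajectory exactly (same bins, T -> T/R, Ne -> Ne/R), and a
per-chromosome map with equal rates is identical to the genome-wide one —
rather than through a correlation of noisy desk-scale curves evaluated at
face-value T, which would compare different physical distances.

The non-syntenic background check compares mean between-chromosome r² to the
1/n sampling floor on a large population in linkage equilibrium: in a small
equilibrated population, between-chromosome r² carries an additional drift
component of order 1/(3N) and the floor is no longer the right reference.

# Numerical choices and degenerate inputs

* Missing genotypes are `NA` throughout — never a numeric code that could
  enter arithmetic; dosages are integers in {0, 1, 2, NA}, haplotype alleles
  in {0, 1, NA}.
* Pairs whose jointly-observed sample is monomorphic at either locus are
  flagged undefined and excluded from every summary (not scored as zero).
* D' is 0 when D = 0; summaries use |D'|.
* The |D'| likelihood grid clamps floating-point negatives at the boundary
  to zero, and a zero-probability cell with a positive count sends the grid
  point to log-likelihood -Inf, as it should.
* `nePoint` reports NA (undefined) when the bin mean r² does not exceed the
  1/n floor; estimates are never clamped.
* `halfLengthR2` requires the maximum in the first 1-Mb bin and errors with
  "no decay" when the curve never crosses half its maximum.
* Block candidates tie-break leftmost at equal physical span; accepted
  blocks never overlap and their boundary pair is always strong LD.
* The Ne time-point lookup resolves ties toward the smaller mean distance.
* Pedigree validity enforces acyclicity (reporting one cycle), unique ids,
  and birth-year consistency with recorded parents.

# Known limitations

* LD is computed from phased haplotypes only; there is no EM path from
  unphased genotypes, by design.
* The greedy longest-first block selection makes total blocked length
  non-monotone in `min_strong_fraction` (a long qualifying candidate can be
  replaced by two shorter disjoint blocks when it disqualifies); the
  monotone object is the qualifying-candidate set, and that is what the
  tests assert.
* Sved's relationship is itself an approximation to drift-recombination
  dynamics; recovered Ne carries a residual upward bias of order 5-15% at
  intermediate 4Nc even under ideal sampling.
* Pedigree F treats founders as unrelated and non-inbred; with shallow
  pedigrees most individuals are reported non-inbred, which is a property
  of the data, not the algorithm.
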