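---
title: "Models and methods for NOR copy-number inheritance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for NOR copy-number inheritance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(norinherit)
```

`norinherit` analyses the inheritance and stability of 45S rRNA gene
copy number at the two *Arabidopsis thaliana* nucleolus organizer
regions (NOR2 and NOR4, pinned to the tops of chromosomes 2 and 4).
This vignette documents the models the package implements, the
parameters that matter, the numerical choices behind the
implementations, and what the synthetic-data generator does and does
not emulate.

## The inheritance model

Each individual carries two haplotypes per chromosome. A haplotype
holds an ordered vector of founder-origin labels (one per 100-kb
window) and, on a NOR chromosome, a single copy count `C` for its NOR
array. Three modelling commitments shape everything downstream:

* **Crossovers follow a Haldane (no-interference) model.** Crossover
  counts per meiosis are Poisson with mean equal to the chromosome's
  genetic length in Morgans, positions uniform on the genetic map, and
  window alleles are read off window midpoints assuming uniform cM/bp.
  No map function is implied by the data the package emulates; Haldane
  was chosen because it is the standard analytically tractable choice —
  the map distance `d = -50 ln(1 - 2r)` inverts exactly, which the
  tests exploit.
* **NORs do not recombine between homologs.** The NOR copy count
  always travels with the topmost window of its chromosome: whichever
  homolog donates window 0 donates its array, intact. This encodes the
  observation that homologous NORs exchange material rarely if at all
  in this species; intra-array structure is not modelled.
* **Copy number mutates by unequal crossing-over, modelled as rare
  jumps.** With probability `jump_probability` per NOR per meiosis the
  transmitted count is perturbed by a rounded draw from
  N(0, `jump_sd`) and floored at zero. Defaults are
  `jump_probability = 0.02` and `jump_sd = 100` copies. No measured
  rate exists for these parameters; the defaults were fixed once so
  that excursions of one to a few hundred copies — the magnitude seen
  between sibling inbred lines — become visible within roughly ten to
  thirty generations of single-seed descent. They are calibration
  choices, not measured quantities, and analyses that depend on them
  say so.

Pedigree designs: `F2` (two inbred founders, one F1, selfed),
`RIL` (F2s advanced by single-seed descent; `n_generations` counts
selfing generations since the F1, nine by default, so residual
heterozygosity is about `0.5^9`), and `MA` (independent single-seed
descent lineages from one founder, 31 generations by default, each
line then producing replicate sub-lineages measured in the two
consecutive generations 32 and 33).

## The observation models

**Sequencing depth.** The depth-ratio estimator divides mean per-base
depth over the annotated 18S interval of the rRNA reference unit
(coordinates 2195–4002, 1808 bases, zero-depth bases included in the
mean) by mean depth over the first 10 Mb of chromosome 3, a region
carrying neither centromere nor 5S/45S arrays. The simulator draws
per-base depths as negative binomial with variance
`mu(1 + dispersion)`; `dispersion = 0` returns exact expectations, and
the 18S mean has expectation `depth × C_total/2`, so the ratio's
expectation is copies per haploid genome. The baseline mean is taken
over a 10,000-position subsample of the 10-Mb region rather than all
ten million positions; this preserves the estimator's bias properties
(the Jensen term from a noisy denominator is of order 1e-5 at depth 20)
at a fraction of the cost. For real data the package consumes
precomputed per-base depth tables (`coverage_from_depth()`); the
documented contract is that depth should be computed *before*
duplicate removal, where the depth ratio tracks qPCR estimates best.

**qPCR.** Relative abundance against the single-copy *ACT2* gene is
`2^(Ct(ACT2) - Ct(18S))`. The simulator writes noiseless cycles
satisfying `Ct(18S) = Ct(ACT2) - log2(C)` and adds three disturbances:
a shared per-plate offset (cancels exactly in the difference), an
optional target-specific plate offset (does not cancel — this is the
bias that plate standardization exists to remove), and
N(0, `replicate_sd`) per technical replicate, default 0.038 cycles to
match the replicate error magnitude of the plate design it emulates
(14 plates, four technical replicates, a common control on every
plate). Control standardization divides each plate's values by that
plate's control estimate over the control's grand mean across plates —
leaving the control's corrected values equal everywhere. The
alternative replicate-regression mode fits multiplicative per-plate
factors by least squares on the log2 scale (`log2(value) =
sample + plate`), with the first plate as reference; the model form is
a design choice, since only "a simple linear regression on technical
replicates" is specified by the workflow being reproduced, and a
multiplicative plate effect is the physically sensible reading for an
exponential assay. Plates with no replicate links to the rest are a
singular design and raise an error rather than a silent guess.

**FISH ratios.** `signal_ratio()` divides two signal areas (pixels)
and truncates toward zero at two decimals. Truncation, not half-up
rounding, is used deliberately: it is the convention that reproduces
both published worked values this package checks against (2.39 and
1.49) — half-up rounding would turn 1.4964 into 1.50.

**Window SNP calls.** Per window, segregating-site counts are Poisson
around `snp_density` (default 300 per 100 kb, with a 5% admixture of
low-diversity windows at mean 50 to exercise the discard rule), calls
are Binomial(`n_segregating`, `call_rate`), and each call reports the
class implied by the true window diplotype, flipped to one of the two
wrong classes with probability `error_rate` (split equally).

## Genotyping rules and their edge cases

Windows with fewer than 100 segregating SNPs or fewer than 40 calls
are discarded (NA). Otherwise, with all fractions taken over the
called-SNP count: A if maternal fraction > 0.90; else B if paternal
fraction > 0.90; else H if heterozygous fraction > 0.25 **or** the
absolute maternal–paternal difference < 0.30; else NA. Two choices
deserve emphasis because the source rules do not pin them down:

* *Precedence*: A/B are tested before H, in the order the rules are
  stated; the homozygous rule is the stricter claim, so it wins where
  both could fire.
* *Denominator*: every fraction is of `n_called`, heterozygous calls
  included. All comparisons are strict, exactly as the thresholds are
  printed.

The test suite pins the whole rule table to an independently written
brute-force oracle over roughly 1e5 count vectors spanning every
threshold boundary.

## Genetic maps and genotype probabilities

Adjacent-window recombination fractions are estimated by maximum
likelihood from observed transitions: for F2s, by numerical
maximization of the nine-cell two-locus likelihood (closed-form cell
probabilities, `optimize()` on (1e-6, 0.5), tolerance 1e-6); for RILs,
from the observed recombinant fraction mapped back through
`R = 2r/(1+2r)`. Estimates at or above 0.5 are capped at 0.4999 with a
warning; adjacent pairs with fewer than 20 jointly informative samples
fall back to the chromosome's median distance; windows below 50% call
rate are excluded from the map. Distances use the Haldane inverse and
are cumulated per chromosome. In RILs heterozygous calls are treated
as missing (residual heterozygosity is rare and carries almost no map
information); F2s use the full three-state coding. No smoothing or
imputation of NA windows is applied — deliberately, so that genotyping
artefacts remain visible rather than silently smoothed away.

Genotype probabilities on the scan grid (markers plus pseudomarkers
every `step_cM`, default 2 cM) condition on the nearest informative
flanking markers under the Haldane model, treating the two gametes as
independent Markov chains and enumerating the phase configurations
consistent with the flanking genotypes. At an observed marker the
distribution is the indicator of the observed state; with one flank
the chain is conditioned one-sided; with no informative marker the
prior (1/4, 1/2, 1/4) applies (for RILs (1/2, 0, 1/2), with
heterozygote mass identically zero). This flanking-marker conditioning
is exact for complete data and a close approximation to a full hidden
Markov model when missingness is light, which is the regime the
genotyper's discard rules produce.

## The QTL scan

Interval mapping is realized as Haley–Knott regression: at each grid
position the phenotype is regressed on expected dosages (additive
`P(AB) + 2 P(BB)` and dominance `P(AB)` for F2; additive only for
RILs) and `LOD = (n/2) log10(RSS0/RSS1)` against the intercept-only
fit. Haley–Knott was chosen over EM-based normal-mixture interval
mapping because it is deterministic, fast enough to permute
thousands of times, and identical at fully observed markers — which is
where the closed-form test oracles live. Numerical guards: rank
deficiency is handled by QR with pivoting (the dominance column
collapses at fixed markers); zero phenotypic variance yields an
all-zero scan with a warning; RSS1 below 1e-12 of RSS0 is reported as
the cap LOD 300 rather than infinity.

Genome-wide significance comes from permuting the phenotype `n_perm`
times (1000 by default) and taking the empirical type-7 quantile of
the per-permutation genome-wide maximum LOD at level `1 - alpha`. The
permutation machinery shares one orthonormal-basis precomputation
across all permutations, so a 1000-permutation threshold on a
93-individual, ~1400-position scan costs under a second.

The cofactor scan approximates multiple-QTL mapping in the
composite-interval-mapping style: selected cofactor dosages enter the
model as covariates except within a 10-cM exclusion window of the test
position (the window is read as centimorgans; the alternative reading
in marker counts has no support in the workflow being reproduced), and
the LOD compares against the cofactor-only model at each position.
The exact backward-elimination multiple-QTL algorithm of dedicated QTL
software is intentionally not reproduced; with no cofactors the scan
reduces exactly to the single-QTL scan, which the tests assert.

## The stability model

Mutation-accumulation measurements `value ~ line + generation +
(1 | line:replicate)` are fitted by full maximum likelihood — not REML,
because the likelihood-ratio tests compare models with different fixed
structures, and REML likelihoods are not comparable across those. The
fitter profiles the fixed effects and residual variance out
analytically, reducing the problem to one dimension in the variance
ratio `lambda = sigma2_rep / sigma2_e`: a bracketing grid on
`log10(lambda)` from 1e-6 to 1e6 (quarter-decade steps, plus
`lambda = 0`) followed by golden-section refinement
(`stats::optimize`, tolerance 1e-8). Per-group sufficient statistics
make each likelihood evaluation O(p²·groups); the test suite checks
the result against a dense generalized-least-squares oracle on a
lambda grid (agreement within 1e-6 in log-likelihood) and against an
independent mixed-model implementation. Generation is coded as a
categorical fixed effect (two levels); replicates are nested within
lines via their interaction. Degrees of freedom for each
likelihood-ratio test are computed from the actual design-matrix
parameter difference — ten lines give df 9 for dropping line, two
generations give df 1 for dropping generation — rather than taken from
any reported labels, which cannot be reconciled with such a design.

One calibration note: maximum-likelihood ratio tests are
anticonservative in small samples (the statistic inflates by roughly
`n/(n - p)`). The suite's type-I-error check therefore simulates a
balanced design with 10 lines × 20 replicate lineages × 2 generations
(n = 400, p = 11), chosen by that analytic argument so the chi-square
reference is adequate; at the 10 × 5 × 2 scale of a typical wet-lab
design the same test runs slightly hot, which users should keep in mind
when interpreting borderline p-values on small panels.

The coefficient of variation `CV = sd/mean` (n−1 denominator) is
computed per group of NOR-genotype-matched individuals per generation;
groups need at least two values, and a zero mean yields NA with a
warning. CV is scale-invariant, so it can mix depth-ratio and qPCR
estimates across generations.

## The pipeline

`run_pipeline()` chains simulate → estimate → genotype → scan (F2/RIL)
or simulate → estimate → stability (MA) from a single nested
configuration (R list or YAML file — YAML is the package's
configuration format). One master seed drives everything; each stage
derives its own child seed from the master and the stage name, so
stages are independently reproducible and a rerun is byte-identical.
Every intermediate table is materialized as TSV/JSON — there is no
in-memory-only mode — so each stage can be rerun and inspected in
isolation; a manifest records the config, seed and file checksums. A
stage failure aborts with the stage named and earlier outputs
retained. The `exec/nor-inherit` script is a thin command-line wrapper
over the same function.

## What the generator emulates — and what it does not

It emulates: Mendelian segregation of chromosome-linked NOR size with
rare stochastic jumps; F2/RIL/MA pedigree structures at realistic
sizes (93 F2s; nine selfing generations; 31 + 2 generations of
single-seed descent); overdispersed coverage whose rRNA-region mean is
proportional to copy number; window-level SNP-call counts with
genotyping error and low-diversity windows; and qPCR plates with
shared and target-specific offsets plus technical-replicate noise.

It does not emulate: read-level data (no FASTQ/BAM; depth summaries
are generated directly), the sequence content or internal structure of
the 45S unit, methylation or chromatin state of the NORs, segregation
distortion, interference (crossovers are Haldane by construction), or
multiparent (MAGIC) founder mosaics. Consequently, green tests
demonstrate that the statistical machinery is correct under the stated
generative model — they do not validate alignment, variant calling, or
any upstream processing of real sequencing data, and mapping
resolution on real data will degrade with marker informativeness in
ways the clean generator understates.

## Problem sizes used by the test suite

The acceptance-style checks run at the scale of the designs they
mirror, trimmed where a smaller size measures the same property: the
F2 parameter-recovery study uses 100 independent 93-individual runs
with full 1000-permutation thresholds; permutation calibration uses
500 null scans with 200-permutation thresholds; estimator bias uses
200 coverage replicates at depth 20; LRT calibration uses 1000 null
simulations; and the instability trend uses 100 mutation-accumulation
runs of 20 lineages over 32 generations (CV read every fourth
generation). Unit tests use a four-chromosome miniature genome with the
same NOR layout wherever chromosome count is immaterial.

## Known limitations

* Map estimation near `r = 0` is boundary-limited: with few
  individuals, short intervals estimate to zero distance and total map
  length is biased downward; peak *locations* are unaffected, but
  distances on estimated maps should be read comparatively, not
  absolutely.
* The flanking-marker probability model ignores genotyping error at
  the flanks (no error-aware HMM); the genotyper's window-level
  filtering makes residual window errors rare, but heavily
  error-contaminated inputs would bias dosages.
* The cofactor scan is a CIM-style approximation, not a full
  multiple-QTL model search; forward selection of cofactors is left to
  the user.
* qPCR amplification efficiency is assumed to be exactly 2 per cycle;
  efficiency modelling and melting-curve QC are out of scope.
* The unequal-crossover jump model is phenomenological: a Bernoulli
  jump with Gaussian size, not a mechanistic misalignment model, and
  its two parameters are calibration choices.
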