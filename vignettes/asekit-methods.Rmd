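---
title: "Quantifying allele-specific expression from allelic peak heights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression from allelic peak heights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asekit)
```

## The measurement problem

When a regulatory variant sits in a promoter in heterozygous state, the two
alleles of the gene may be transcribed at different rates — allele-specific
expression (ASE).  Quantitative allele-discriminating assays (here,
capillary-electrophoresis SSCP of fluorescently post-labelled PCR products)
read each allele of a transcribed marker SNP out as a separate peak, so the
peak-height ratio estimates the allelic abundance ratio.  Two complications
stand between the raw ratio and an ASE call:

1. **Signal bias.** The two alleles of a marker are not detected with equal
   efficiency (dye incorporation, conformer separation), so even an
   equimolar mixture can show a ratio far from 1.  The bias is measured
   with standard mixtures of in-vitro-transcribed allele templates at known
   molar ratios.
2. **Copy-number imbalance.** In tumours, somatic mono-allelic
   amplification skews the *genomic* allelic ratio; expression measured
   against such a genome cannot be attributed to regulation, so these
   samples must be excluded.

## The calling model

For each marker locus, the calibration model is a single multiplicative
bias $b$: the observed height ratio of a standard with known molar ratio
$m$ is $b\,m$ up to noise.  `fit_calibration()` estimates it in log space,

$$\hat b = \exp\Big(\tfrac1K \sum_k \big[\log r^{obs}_k - \log m_k\big]\Big),$$

which is the maximum-likelihood estimator under multiplicative log-normal
noise and is invariant to which allele is numerator.  The spread of the
log-residuals (`residual_sd`) diagnoses whether a constant bias describes
the series.

Per sample, both the gDNA and cDNA height ratios are divided by $\hat b$.
With $g$ and $c$ the corrected gDNA and cDNA ratios, the relative
expression ratio is $\rho = c/g$ — a per-sample normalisation that cancels
any residual sample-specific genomic skew — and the imbalance statistic is
$\max(\rho, 1/\rho) - 1$.  A sample is:

* `not_heterozygous` if the minor/major gDNA peak fraction is below the
  gate (default 0.10, inclusive boundary; a supplied genotype table
  overrides the peak-based gate);
* `excluded_monoallelic` if $\max(g, 1/g)$ exceeds `mono_tau` (default 3);
* `ase_positive` if the imbalance strictly exceeds `ase_threshold`
  (default 0.20, the conventional "20 % difference between alleles");
* `ase_negative` otherwise.

The symmetric form in $\rho$ and $1/\rho$ makes every verdict invariant
under allele relabelling and under rescaling all peak heights of a sample,
two properties the test suite checks explicitly.  The mono-allelic
exclusion bound is a numeric operationalisation chosen here: published
analyses report the exclusion without a criterion, and a corrected gDNA
ratio of 3 is far outside what sampling noise produces at realistic CVs
while comfortably below a genuine 4:1 amplification.

Both normalisations are applied deliberately: the cohort-level calibration
removes the assay's allele bias, and the per-sample division by $g$ removes
residual per-sample genomic skew.  Each corrected ratio is retained in the
output so either convention can be inspected on its own.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `ase_threshold` | 0.20 | relative difference | ASE call boundary (strict) |
| `mono_tau` | 3.0 | ratio | gDNA-skew exclusion bound |
| `min_minor_fraction` | 0.10 | fraction | heterozygote gate on gDNA peaks |

## What the synthetic cohort emulates

The generator reproduces the statistical structure the pipeline assumes,
so every stage is testable without clinical material:

* **Haplotypes.** Samples are two gametes drawn independently from a
  haplotype frequency table (random union of gametes, hence
  Hardy-Weinberg genotype proportions in expectation).  The default table
  is the published cancer-free two-locus distribution for SNP55-SNP309
  (counts 16/42/32/0 of 90 chromosomes), extended to the two transcribed
  markers by complete linkage (SNP55-C with rs1690916-G/rs937283-A), the
  dominant phase pattern in the genotyped cancer cohort.
* **Expression truth.** A configurable fraction (default 0.12, matching 2
  ASE-positive of 17 evaluable heterozygotes) of cancer samples
  heterozygous at the functional locus receive a fold-imbalance (default
  1.5) oriented so the C-carrying haplotype is the weaker one, modelling
  repressor recruitment to the C allele; everyone else, and every
  cancer-free sample, expresses both alleles equally.  Samples homozygous
  at the read-out marker keep their imbalance but are flagged unobservable.
* **Peaks.** Expected height ratios are bias x copy ratio (gDNA) and
  bias x expression ratio (cDNA); each height carries independent
  multiplicative log-normal noise with the configured CV (default 0.05),
  mean-one parameterised.  Default biases are 1.0 for rs1690916 and 1.8
  for rs937283, whose raw heterozygote ratios are visibly off unity in
  this assay.  Mono-allelic amplification (default fraction 3/45) draws a
  4:1 gDNA copy ratio on a random haplotype, gDNA only.
* **Standards.** Mixture series default to molar ratios
  {0.25, 0.5, 1, 2, 4} with 3 replicates — a symmetric two-fold ladder
  around equimolar, a standard design for such calibrations.

One root seed drives everything; per-stage child streams (haplotypes,
expression, peaks, standards) let a stage be regenerated without replaying
the others, and identical configurations produce byte-identical output
tables.

What the generator does *not* model: electrophoretic trace shapes or
migration, PCR competition between alleles beyond a constant bias,
degradation differences between gDNA and RNA, or genotyping error.
Passing recovery tests therefore show the *calling logic* is correct under
the stated noise model, not that the assay's real error structure is this
simple.

### What the noise model implies for error rates

With per-height log-normal noise of CV $\sigma$, each observed log ratio
carries variance $2\sigma^2$ and $\log\rho$ carries $4\sigma^2$.  The
false-positive probability of the 20 % rule for a truly balanced sample is
$2\,\Phi\!\big({-\log(1.2)}/{(2\sigma)}\big)$: about $10^{-5}$ at
$\sigma = 0.02$ but about 6.8 % at $\sigma = 0.05$.  The unit tests
exercise the recovery experiment at CV 0.02, where sensitivity $\ge 0.9$
and FPR $\le 0.05$ hold with large margin; the acceptance suite also runs
the same experiment at CV 0.05, where the 5 % FPR bound is analytically
unattainable — that check documents the boundary rather than the
package's intended operating point.  At the default 1.5-fold effect size,
sensitivity remains above 0.98 even at CV 0.05.

## The population-genetics layer

* **Tables.** Genotype and allele frequency tables use half-up rounding to
  one decimal, matching how such case-control tables are conventionally
  printed; machine outputs keep full precision.
* **Fisher's exact test** (`fisher_exact()`) enumerates all 2xC tables
  with the observed margins and sums point probabilities no larger than
  the observed one (two-sided point-probability convention, relative tie
  tolerance 1e-7).  This convention reproduces the published two-decimal
  p-values (0.87/0.88/0.85/1.00) for the case-control comparisons.
* **Hardy-Weinberg** (`hwe_exact()`) is the exact conditional test —
  appropriate at n = 45 where chi-square is fragile — enumerating
  heterozygote counts compatible with the allele counts; a chi-square
  variant is available for comparison.
* **Haplotypes.** `haplotype_frequencies_direct()` counts phased gametes;
  `haplotype_frequencies_em()` handles unphased two-locus genotypes, where
  only the double heterozygote is phase-ambiguous.  The EM starts at
  linkage equilibrium, stops when the log-likelihood improves by less than
  1e-10 (cap 1000 iterations), and is deterministic: for the biallelic
  two-locus case the incomplete-data likelihood is unimodal in the
  double-heterozygote allocation, so random restarts add nothing.  Every
  EM iterate preserves the observed allele-frequency margins, which is
  why a dense one-dimensional profile search is an exhaustive oracle for
  the maximiser (used in the tests).
* **LD.** $D = f_{11} - p_1 p_2$, $D' = |D|/D_{\max}$, and
  $r^2 = D^2/(p_1 q_1 p_2 q_2)$.  Input frequencies are renormalised to
  sum to 1 before use: published tables print 3-decimal frequencies whose
  sum can be 0.999-1.001, and without renormalisation the rounding error
  propagates into the third decimal of $r^2$ (0.486 instead of 0.483 for
  the packaged cancer-free table).  Monomorphic loci yield defined fields
  only, with a warning.
* **Constraint solving.** `solve_two_locus_haplotypes()` closes the
  three-parameter haplotype system using the two allele frequencies plus
  one haplotype declared absent — the situation in the cancer-free cohort,
  where the 55T-309G haplotype was not observed.

## Motif differential scanning

The regulatory question — which transcription-factor sites does the
promoter variant create or destroy? — is answered with transparent
primitives rather than a legacy black-box tool: IUPAC consensus matching
(subject base matches pattern base iff their base sets intersect) and
position weight matrices scored by log-odds against a background model
(pseudocount 0.5 per base per column; uniform background by default).
Coordinates are 0-based half-open internally and 1-based closed in
rendered reports; minus-strand hits are reported in plus-strand
coordinates with the matched site given on the motif's strand.

The packaged motif fixtures are editable JSON: a 7-bp kB core `GGGRNNY`,
the 10-bp kB consensus family `GGGRNNYYCC`, an Sp1 GC-box `KRGGCKRRK` and
an Sp1 GT-box `GGTGTSSY`.  The GT-box's terminal position is a pyrimidine
degeneracy: the Sp1 site in the packaged 22-mer promoter probe spans the
variant position, and Sp1 binding tolerates either allele there, so a
pattern hard-coding C would contradict the biology the fixture is meant to
express.  On the packaged probe the kB core matches the C allele only (on
the minus strand) and the Sp1 GT-box matches both alleles — the
differential that motivates the repressor model above.  Only these
relational claims are asserted; the exact matrices used by legacy scanning
tools are not recoverable, so absolute scores carry no meaning beyond the
packaged fixture definitions.

`allele_differential_scan()` proves rather than assumes locality: hits
whose window does not overlap the variant are identical between alleles
and reported once; gained/lost classifications are antisymmetric under
allele swap (both properties are tested on randomised inputs).

## Numerical and degenerate-input choices

* Exact-test tie comparison uses a 1e-7 *relative* tolerance so
  floating-point ties in point probabilities are counted as ties.
* Zero-margin contingency tables return p = 1 with a warning rather than
  an error; monomorphic loci likewise in the HWE and LD routines.
* Calibration refuses zero peak heights (standards are two-allele
  mixtures by construction); the heterozygote gate refuses records with
  both gDNA heights zero.
* The heterozygote gate boundary is inclusive at exactly
  `min_minor_fraction`; the ASE threshold is strict.
* Percentage rounding is half-up (so 53.35 prints 53.4), not banker's.

## Problem sizes in the test suite

The suite runs in well under a minute: haplotype-sampling convergence uses
5 000 samples; EM recovery 2 000; the recovery experiment 200 informative
heterozygotes with 50-replicate calibration checks; oracle sweeps use a
few dozen randomised tables/sequences per property under fixed seeds.
These sizes put Monte-Carlo assertions at 3-standard-error tolerances
derived from the models being tested, not from runtime constraints.

## Known limitations

* The calibration assumes one constant multiplicative bias per marker; a
  concentration-dependent bias would show up in `residual_sd` but is not
  modelled.
* ASE orientation ties the imbalance to a single functional locus and a
  single suppressed allele; compound regulatory heterozygosity is out of
  scope, as are more than two loci in the EM and any phasing beyond the
  double-heterozygote split.
* The motif layer makes no claim about binding affinity; a consensus match
  is necessary, not sufficient, for occupancy.
* Confidence intervals on $r^2$ and odds-ratio modelling are deliberately
  absent; the source tables report none.
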