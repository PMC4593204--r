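# asekit

Allele-specific expression (ASE) calling from allelic peak heights, with
the population-genetics and promoter-motif companions such a study needs.

## The problem

When a promoter variant is heterozygous, the two alleles of a gene can be
transcribed at different rates.  Allele-discriminating capillary
electrophoresis reads each allele of a transcribed marker SNP as a
separate fluorescent peak, so the peak-height ratio measures the allelic
abundance ratio — but only after correcting the assay's allele-specific
signal bias, gating on true heterozygotes, and excluding tumours whose
*genomic* ratio is skewed by mono-allelic amplification.  The motivating
system is the *MDM2* P2 promoter: the SNP55/SNP309 promoter haplotypes,
the transcribed markers rs1690916 (3'UTR) and rs937283 (exon 1), and the
question of whether an NF&kappa;B repressor site created by the SNP55 C
allele silences one copy of the gene in endometrial cancers.

`asekit` implements, as tidy tibble-in/tibble-out functions:

* **Calibration and calling** — per-marker signal bias from standard
  mixtures, `b = exp(mean(log r_obs − log m))`; corrected ratios
  `g = r_gDNA/b`, `c = r_cDNA/b`; relative expression ratio `ρ = c/g`;
  ASE-positive iff `max(ρ, 1/ρ) − 1 > 0.20` (strict), with exclusion when
  `max(g, 1/g) > 3` and a minor/major ≥ 0.10 heterozygote gate.
* **Population genetics** — genotype/allele frequency tables, two-sided
  Fisher exact tests by margin-preserving enumeration (point-probability
  convention), the exact conditional Hardy–Weinberg test, two-locus
  haplotype frequencies by direct counting, EM, or constraint solving,
  and LD statistics `D`, `D'`, `r²`.
* **Motif differentials** — IUPAC consensus and PWM log-odds scanning on
  both strands, and gained/lost site reports between the two alleles of a
  promoter variant.
* **A synthetic cohort generator** — phased haplotype sampling (random
  union of gametes), configurable ASE prevalence/magnitude, signal bias,
  log-normal peak noise and mono-allelic fractions, so the whole pipeline
  is testable end to end with no external data.

## Worked example

Simulate a two-cohort study under the packaged haplotype distribution,
calibrate, and call ASE:

```r
library(asekit)

sim <- simulate_cohort(sim_config(n_per_cohort = 45, seed = 1))
res <- run_ase_pipeline(sim$signals, sim$standards)

glance(res$calibrations$rs937283)
#> # A tibble: 1 × 4
#>   locus_id  bias n_points residual_sd
#>   <chr>    <dbl>    <int>       <dbl>
#> 1 rs937283  1.75       15      0.0743

res$summary
#> # A tibble: 2 × 7
#>   locus_id      n heterozygous excluded missing_cdna evaluable ase_positive
#>   <chr>     <int>        <int>    <int>        <int>     <int>        <int>
#> 1 rs1690916    90           40        2            0        38            3
#> 2 rs937283     90           40        2            0        38            5
```

The rs937283 calibration recovers the simulated 1.8-fold allele-1 signal
excess (1.75 from 15 noisy standards); of 90 samples, 40 pass the
heterozygote gate, 2 are excluded for genomic skew, and the ASE-positive
counts at the default 5 % peak CV include a few threshold-grazing false
positives alongside the planted imbalances (see the methods vignette for
the error-rate analysis).  `tidy(res)` returns the per-sample calls and
`autoplot(res)` draws the corrected gDNA/cDNA bar chart.

The published case-control tables and LD reproduce directly:

```r
cohort <- emca_cohort()   # packaged 45-sample cancer cohort listing
genotype_summary(list("cancer-free" = rep(c("C/C","C/T","T/T"), c(17,24,4)),
                      "cancer" = cohort$SNP55), mdm2_loci()[1, ])
#> Locus SNP55  (genotype p = 0.87, allele p = 0.88)
#> ... 17/24/4 (37.8/53.3/8.9 %) vs 17/22/6; alleles 58/32 (64.4/35.6 %)

ld_from_haplotypes(cancer_free_haplotypes())
#> # A tibble: 1 × 5
#>      p1    p2      D D_prime r_squared
#>   <dbl> <dbl>  <dbl>   <dbl>     <dbl>
#> 1 0.644 0.533 -0.166       1     0.483
```

And the promoter variant's motif differential:

```r
allele_differential_scan(mdm2_snp55_probe("C"), 10, "C", "T",
                         default_motifs(), seq_id = "MDM2-P2")
#> Allele-differential motif report at MDM2-P2 position 11 (C -> T)
#>   lost: 1, gained: 0, shared at variant: 1, unchanged: 0
```

The C→T substitution destroys the NF&kappa;B core site (`GGGACAC` on the
minus strand, lost) while the Sp1 GT-box spanning the variant matches
both alleles (shared) — the C allele alone carries the repressor site.

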