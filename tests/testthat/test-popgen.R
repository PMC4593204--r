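snp55 <- locus_definition("SNP55", c("C", "T"), role = "functional")
snp309 <- locus_definition("SNP309", c("T", "G"), role = "functional")

test_that("genotype tables reproduce the published cancer-free percentages", {
  g <- c(rep("C/C", 17), rep("C/T", 24), rep("T/T", 4))
  tab <- genotype_frequency_table(g, snp55)
  expect_equal(tab$count, c(17, 24, 4))
  expect_equal(tab$pct, c(37.8, 53.3, 8.9))

  empty <- genotype_frequency_table(character(0), snp55)
  expect_equal(empty$count, c(0, 0, 0))
  expect_true(all(is.na(empty$pct)))

  single <- genotype_frequency_table("C/T", snp55)
  expect_equal(single$count, c(0, 1, 0))
  expect_equal(single$pct, c(0, 100, 0))

  # shorthand and reversed order normalise; bad alleles name the sample
  expect_equal(genotype_frequency_table(c("C", "T/C"), snp55)$count,
               c(1, 1, 0))
  expect_error(genotype_frequency_table("A/G", snp55,
                                        sample_ids = "EMCA-99"), "EMCA-99")
})

test_that("allele counts derive from genotype counts and sum to 2n", {
  a <- allele_counts_from_genotypes(c(17, 24, 4), snp55)
  expect_equal(a$count, c(58, 32))
  expect_equal(a$pct, c(64.4, 35.6))
  b <- allele_counts_from_genotypes(c(12, 24, 9), snp309)
  expect_equal(b$count, c(48, 42))
  expect_equal(b$pct, c(53.3, 46.7))
  expect_equal(sum(b$count), 2 * 45)
  z <- allele_counts_from_genotypes(c(0, 0, 0), snp55)
  expect_equal(z$count, c(0, 0))
})

test_that("Fisher exact p-values reproduce the published comparisons", {
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2))$p_value, 1.0)
  p_allele55 <- fisher_exact(rbind(c(58, 32), c(56, 34)))$p_value
  expect_equal(round(p_allele55, 2), 0.88)
  p_geno55 <- fisher_exact(rbind(c(17, 24, 4), c(17, 22, 6)))$p_value
  expect_equal(round(p_geno55, 2), 0.87)
  p_geno309 <- fisher_exact(rbind(c(12, 24, 9), c(14, 21, 10)))$p_value
  expect_equal(round(p_geno309, 2), 0.85)
  p_allele309 <- fisher_exact(rbind(c(48, 42), c(49, 41)))$p_value
  expect_equal(round(p_allele309, 2), 1.00)
})

test_that("fisher_exact agrees with enumeration and stats::fisher.test", {
  set.seed(424)
  for (i in 1:30) {
    nc <- sample(2:3, 1)
    m <- matrix(rpois(2 * nc, lambda = 4), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact(m)$p_value
    expect_equal(p, oracle_fisher_2xc(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
  expect_warning(p0 <- fisher_exact(rbind(c(0, 0), c(3, 4)))$p_value,
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("HWE exact test matches enumeration and flags monomorphism", {
  expect_equal(hwe_exact(c(20, 0, 0))$p_value, 1)
  expect_equal(hwe_exact(c(20, 0, 0))$note, "monomorphic locus")
  expect_gt(hwe_exact(c(17, 24, 4))$p_value, 0.05)
  expect_gt(hwe_exact(c(12, 24, 9))$p_value, 0.05)
  set.seed(77)
  for (i in 1:40) {
    n <- sample(3:20, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(hwe_exact(counts)$p_value, oracle_hwe(counts),
                 tolerance = 1e-12)
  }
  # chi-square variant agrees with the textbook statistic
  chs <- hwe_exact(c(17, 24, 4), method = "chisq")
  p <- 58 / 90
  expected <- 45 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(chs$statistic, sum((c(17, 24, 4) - expected)^2 / expected))
})

test_that("direct haplotype counting reproduces the published frequencies", {
  haps <- rep(c("C-T", "C-G", "T-T"), c(16, 42, 32))
  tab <- haplotype_frequencies_direct(haps, mdm2_loci()[1:2, ])
  f <- setNames(tab$freq, tab$haplotype)
  expect_equal(round(f[["C-T"]], 3), 0.178)
  expect_equal(round(f[["C-G"]], 3), 0.467)
  expect_equal(round(f[["T-T"]], 3), 0.356)
  expect_equal(f[["T-G"]], 0)
  expect_equal(sum(tab$freq), 1)

  expect_equal(haplotype_frequencies_direct(rep("C-G", 5),
                                            mdm2_loci()[1:2, ])$freq |>
                 max(), 1)
  half <- haplotype_frequencies_direct(c("C-G", "T-T"), mdm2_loci()[1:2, ])
  expect_equal(sort(half$freq), c(0, 0, 0.5, 0.5))
  expect_error(haplotype_frequencies_direct(character(0),
                                            mdm2_loci()[1:2, ]), "empty")
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  joint <- matrix(c(5, 2, 0,
                    3, 0, 1,
                    0, 2, 4), 3, byrow = TRUE)
  em <- haplotype_frequencies_em(joint)
  n2 <- 2 * sum(joint)
  direct <- c(2 * 5 + 2 + 3, 2 * 0 + 2 + 1, 2 * 0 + 3 + 2,
              2 * 4 + 1 + 2) / n2
  expect_equal(em$frequencies$freq, direct, tolerance = 1e-9)
})

test_that("EM maximises the two-locus likelihood on the cancer cohort", {
  cohort <- emca_cohort()
  joint <- two_locus_genotype_counts(cohort$SNP55, cohort$SNP309,
                                     mdm2_loci()[1:2, ])
  expect_equal(unname(rowSums(joint)), c(17, 22, 6))
  expect_equal(unname(colSums(joint)), c(14, 21, 10))
  em <- haplotype_frequencies_em(joint)
  expect_true(em$converged)
  # log-likelihood is monotone non-decreasing
  expect_true(all(diff(em$loglik_trace) > -1e-10))
  # EM margins equal the sample allele frequencies (EM preserves them)...
  f <- em$frequencies$freq
  n <- sum(joint)
  expect_equal(f[1] + f[2], (2 * 17 + 22) / (2 * n), tolerance = 1e-9)
  expect_equal(f[1] + f[3], (2 * 14 + 21) / (2 * n), tolerance = 1e-9)
  # ...so a dense profile search over the remaining free coordinate is an
  # exhaustive oracle for the maximiser
  gs <- oracle_grid_search(joint, step = 0.001)
  expect_lt(abs(f[1] - gs$f[1]), 0.001)
  expect_gte(em$loglik_trace[length(em$loglik_trace)], gs$loglik - 1e-6)
})

test_that("EM recovers known haplotype frequencies from sampled genotypes", {
  truth <- c(0.4, 0.3, 0.2, 0.1)
  loci <- mdm2_loci()[1:2, ]
  tab <- hap_table(loci, c("C-T", "C-G", "T-T", "T-G"), truth)
  coh <- sample_haplotype_pairs(tab, 2000, seed = 13)
  g55 <- paste(substr(coh$hap1, 1, 1), substr(coh$hap2, 1, 1), sep = "/")
  g309 <- paste(substr(coh$hap1, 3, 3), substr(coh$hap2, 3, 3), sep = "/")
  joint <- two_locus_genotype_counts(g55, g309, loci)
  em <- haplotype_frequencies_em(joint)
  f <- setNames(em$frequencies$freq, em$frequencies$haplotype)
  se <- sqrt(truth * (1 - truth) / 4000)
  expect_true(all(abs(f[c("C-T", "C-G", "T-T", "T-G")] - truth) < 3 * se))
})

test_that("LD statistics reproduce r^2 = 0.483 and behave at the extremes", {
  ld <- ld_from_haplotypes(c(0.178, 0.467, 0.356, 0.000))
  expect_equal(round(ld$r_squared, 3), 0.483)
  ld_counts <- ld_from_haplotypes(c(16, 42, 32, 0) / 90)
  expect_equal(round(ld_counts$r_squared, 3), 0.483)
  ld_tab <- ld_from_haplotypes(cancer_free_haplotypes())
  expect_equal(round(ld_tab$r_squared, 3), 0.483)

  indep <- outer(c(0.6, 0.4), c(0.3, 0.7))
  ld0 <- ld_from_haplotypes(as.vector(t(indep)))
  expect_equal(ld0$D, 0, tolerance = 1e-12)
  expect_equal(ld0$r_squared, 0, tolerance = 1e-12)

  perfect <- ld_from_haplotypes(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r_squared, 1)

  expect_warning(mono <- ld_from_haplotypes(c(0.5, 0.5, 0, 0)),
                 "monomorphic")
  expect_true(is.na(mono$r_squared))
})

test_that("r^2 is invariant under allele relabelling, D flips sign", {
  set.seed(5)
  for (i in 1:20) {
    f <- as.vector(stats::rmultinom(1, 200, runif(4, 0.05, 1))) / 200
    if (any(c(f[1] + f[2], f[1] + f[3]) %in% c(0, 1))) next
    base <- ld_from_haplotypes(f)
    swapA <- ld_from_haplotypes(f[c(3, 4, 1, 2)])
    expect_equal(swapA$r_squared, base$r_squared, tolerance = 1e-12)
    expect_equal(swapA$D, -base$D, tolerance = 1e-12)
    expect_equal(swapA$D_prime, base$D_prime, tolerance = 1e-12)
    expect_true(base$r_squared >= 0 && base$r_squared <= 1)
    expect_true(base$D_prime >= 0 && base$D_prime <= 1 + 1e-12)
  }
})

test_that("the two-locus system solves under an absent-haplotype constraint", {
  sol <- solve_two_locus_haplotypes(c(58, 32), c(48, 42), absent = "a2b2",
                                    loci = mdm2_loci()[1:2, ])
  f <- setNames(sol$freq, sol$haplotype)
  expect_equal(round(f[["C-T"]], 3), 0.178)
  expect_equal(round(f[["C-G"]], 3), 0.467)
  expect_equal(round(f[["T-T"]], 3), 0.356)
  expect_equal(f[["T-G"]], 0)
  expect_equal(sum(sol$freq), 1)
  # infeasible constraint is refused
  expect_error(solve_two_locus_haplotypes(c(10, 90), c(10, 90),
                                          absent = "a2b2"), "incompatible")
})

test_that("inline table strings parse", {
  expect_equal(parse_table_string("58,32;56,34"),
               rbind(c(58L, 32L), c(56L, 34L)))
  expect_error(parse_table_string("a,b"), "parse")
})
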