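make_standards <- function(locus = "m1", observed_over_known = 2,
                           known = c(0.5, 1, 2)) {
  tibble::tibble(
    locus_id = locus, known_ratio = known,
    height_allele1 = 1000 * observed_over_known * known,
    height_allele2 = 1000
  )
}

test_that("calibration recovers the multiplicative bias", {
  one <- tibble::tibble(locus_id = "m1", known_ratio = 1,
                        height_allele1 = 500, height_allele2 = 500)
  expect_equal(fit_calibration(one)$bias, 1.0)

  cal <- fit_calibration(make_standards(observed_over_known = 2))
  expect_equal(cal$bias, 2.0)
  expect_equal(cal$residual_sd, 0)
  expect_equal(cal$n_points, 3)

  zero <- tibble::tibble(locus_id = "m1", known_ratio = 1,
                         height_allele1 = 0, height_allele2 = 100)
  expect_error(fit_calibration(zero), "zero")
})

test_that("noisy replicate calibration lands near the true bias", {
  cfg <- sim_config(noise_cv = 0.05, bias_per_marker = c(m = 1.5), seed = 8)
  std <- emit_standard_series("m", 1.0, cfg, replicates = 50)
  cal <- fit_calibration(std)
  expect_gt(cal$bias, 1.4)
  expect_lt(cal$bias, 1.6)
  # corrected equimolar standards centre on log-ratio 0
  corrected <- correct_ratio(std$height_allele1 / std$height_allele2, cal)
  expect_equal(mean(log(corrected)), 0, tolerance = 1e-10)
})

test_that("correct_ratio divides out the bias", {
  expect_equal(correct_ratio(1.8, calibration_override("m", 1.8)), 1.0)
  expect_equal(correct_ratio(1.0, calibration_override("m", 1.0)), 1.0)
  expect_equal(correct_ratio(2.4, calibration_override("m", 1.2)), 2.0)
  expect_error(correct_ratio(-1, calibration_override("m", 1)), "positive")
})

test_that("heterozygote gate applies the inclusive minor-fraction boundary", {
  cfg <- pipeline_config(min_minor_fraction = 0.10)
  expect_true(classify_heterozygote(1000, 950, cfg))
  expect_false(classify_heterozygote(1000, 0, cfg))
  expect_false(classify_heterozygote(1000, 99, cfg))   # 0.099 < 0.10
  expect_true(classify_heterozygote(1000, 100, cfg))   # exactly 0.10
  expect_error(classify_heterozygote(0, 0, cfg), "unusable")
})

test_that("ASE verdicts follow the symmetric 20% rule and exclusions", {
  expect_equal(call_ase(1.0, 1.0)$status, "ase_negative")
  expect_equal(call_ase(1.0, 1.0)$imbalance, 0)
  expect_equal(call_ase(1.0, 1.25)$status, "ase_positive")
  expect_equal(call_ase(1.0, 0.8)$status, "ase_positive")  # 1/0.8 = 1.25
  expect_equal(call_ase(1.0, 1.2)$status, "ase_negative")  # not strict >
  expect_equal(call_ase(4.0, 4.0)$status, "excluded_monoallelic")
  expect_error(call_ase(-1, 1), "positive")
})

test_that("verdicts are invariant under allele relabelling and scaling", {
  g <- c(0.9, 1.1, 2.5, 3.5, 1.0)
  c_ <- c(1.2, 0.7, 2.4, 3.4, 1.19)
  direct <- call_ase(g, c_)
  swapped <- call_ase(1 / g, 1 / c_)
  expect_equal(direct$status, swapped$status)
  expect_equal(direct$imbalance, swapped$imbalance)
})

test_that("imbalance grows monotonically with |log rho|", {
  rho <- exp(seq(-2, 2, length.out = 41))
  imb <- call_ase(rep(1, 41), rho,
                  pipeline_config(mono_tau = 100))$imbalance
  ord <- order(abs(log(rho)))
  expect_true(all(diff(imb[ord]) > -1e-12))
})

test_that("the pipeline books heterozygous, excluded and evaluable counts", {
  # 20 heterozygotes, 3 with a 4:1 gDNA imbalance, plus 5 homozygotes
  n_het <- 20
  peaks <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("h%02d", 1:n_het), locus_id = "m1",
                   analyte = "gDNA",
                   height_allele1 = c(rep(1000, 17), rep(4000, 3)),
                   height_allele2 = 1000),
    tibble::tibble(sample_id = sprintf("h%02d", 1:n_het), locus_id = "m1",
                   analyte = "cDNA",
                   height_allele1 = c(rep(1000, 16), 1500, rep(4000, 3)),
                   height_allele2 = 1000),
    tibble::tibble(sample_id = sprintf("o%02d", 1:5), locus_id = "m1",
                   analyte = "gDNA", height_allele1 = 2000,
                   height_allele2 = 0),
    tibble::tibble(sample_id = sprintf("o%02d", 1:5), locus_id = "m1",
                   analyte = "cDNA", height_allele1 = 2000,
                   height_allele2 = 0)
  ) |> dplyr::mutate(known_ratio = NA_real_)
  res <- run_ase_pipeline(peaks, bias_override = c(m1 = 1))
  s <- res$summary
  expect_equal(s$heterozygous, 20)
  expect_equal(s$excluded, 3)
  expect_equal(s$evaluable, 17)
  expect_equal(s$evaluable, s$heterozygous - s$excluded)
  expect_equal(s$ase_positive, 1)
  expect_equal(res$calls$status[res$calls$sample_id == "h17"], "ase_positive")

  # homozygotes only: nothing evaluable
  hom <- peaks |> dplyr::filter(grepl("^o", sample_id))
  s0 <- run_ase_pipeline(hom, bias_override = c(m1 = 1))$summary
  expect_equal(s0$evaluable, 0)
  expect_equal(s0$ase_positive, 0)
})

test_that("gDNA records without cDNA are flagged, not dropped", {
  peaks <- tibble::tibble(
    sample_id = "s1", locus_id = "m1", analyte = "gDNA",
    known_ratio = NA_real_, height_allele1 = 1000, height_allele2 = 900)
  res <- run_ase_pipeline(peaks, bias_override = c(m1 = 1))
  expect_equal(res$calls$status, "missing_cdna")
  expect_equal(res$summary$missing_cdna, 1)
})

test_that("supplied genotypes override the peak-based heterozygote gate", {
  peaks <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", locus_id = "m1", analyte = "gDNA",
                   height_allele1 = 1000, height_allele2 = 950),
    tibble::tibble(sample_id = "s1", locus_id = "m1", analyte = "cDNA",
                   height_allele1 = 1000, height_allele2 = 950)
  )
  geno <- tibble::tibble(sample_id = "s1", locus_id = "m1",
                         genotype = "A/A")
  res <- run_ase_pipeline(peaks, bias_override = c(m1 = 1),
                          genotypes = geno)
  expect_equal(res$calls$status, "not_heterozygous")
})

test_that("zero-noise pipeline reproduces the simulation truth exactly", {
  cfg <- sim_config(n_per_cohort = 60, noise_cv = 0, ase_prevalence = 0.3,
                    ase_magnitude = 1.5, seed = 21)
  sim <- simulate_cohort(cfg)
  res <- run_ase_pipeline(sim$signals, sim$standards)
  marker <- cfg$readout_marker
  calls <- res$calls |> dplyr::filter(locus_id == marker)
  truth <- sim$truth
  joined <- dplyr::left_join(calls, truth, by = "sample_id")
  called_pos <- joined$status == "ase_positive"
  expect_equal(called_pos, joined$ase_truth & !joined$monoallelic_truth)
  excluded <- joined$status == "excluded_monoallelic"
  het <- joined$status != "not_heterozygous"
  expect_equal(excluded, joined$monoallelic_truth & het)
})

test_that("pipeline recovery at study-like noise meets sensitivity and FPR", {
  # 200 informative heterozygotes, bias 1.5, CV 2%, 1.5-fold ASE; at this
  # noise level the per-height noise model puts the expected false-positive
  # rate far below the 5% bound (4 sigma^2 on log rho, |log rho| > log 1.2)
  het <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:400), cohort = "cancer",
    hap1 = rep(c("C-G-G-A", "T-T-A-G"), 200),
    hap2 = rep(c("T-T-A-G", "C-G-G-A"), 200)
  )
  attr(het, "hap_table") <- default_sim_haplotypes()
  cfg <- sim_config(ase_prevalence = 0.1, ase_magnitude = 1.5,
                    noise_cv = 0.02, monoallelic_fraction = 0,
                    bias_per_marker = c(rs1690916 = 1.5, rs937283 = 1.5),
                    seed = 31)
  truth <- assign_expression_model(het, cfg)
  keep <- truth[1:200, ]
  attr(keep, "hap_table") <- default_sim_haplotypes()
  peaks <- emit_peak_signals(keep, cfg)
  std <- emit_standard_series("rs1690916", cfg$standard_ratios, cfg,
                              replicates = 10)
  res <- run_ase_pipeline(
    peaks |> dplyr::filter(locus_id == "rs1690916"), std)
  joined <- dplyr::left_join(res$calls, keep, by = "sample_id")
  pos <- joined$status == "ase_positive"
  sens <- mean(pos[joined$ase_truth])
  fpr <- mean(pos[!joined$ase_truth])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
  # and the calibration is recovered within +-0.1
  expect_lt(abs(fit_calibration(std)$bias - 1.5), 0.1)
})
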