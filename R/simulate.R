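#' Four-locus haplotype panel used by the default simulation
#'
#' Extends the published two-locus (SNP55-SNP309) cancer-free haplotype
#' frequencies to the two transcribed marker SNPs by complete linkage:
#' promoter haplotypes carrying SNP55-C are coupled to rs1690916-G and
#' rs937283-A, and SNP55-T haplotypes to rs1690916-A / rs937283-G.  This is
#' the dominant phase pattern in the genotyped cancer cohort and makes every
#' functional-locus heterozygote readable at both markers.
#'
#' @return A `hap_table` over SNP55, SNP309, rs1690916 and rs937283.
#' @export
default_sim_haplotypes <- function() {
  counts <- cancer_free_haplotypes(as_counts = TRUE)
  ext <- c("C-T" = "C-T-G-A", "C-G" = "C-G-G-A", "T-T" = "T-T-A-G",
           "T-G" = "T-G-A-G")
  keep <- counts > 0
  hap_table(mdm2_loci(), unname(ext[names(counts)[keep]]),
            as.numeric(counts[keep]) / sum(counts))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator.  Defaults mirror
#' the study design the generator emulates: 45 samples per cohort, the
#' published cancer-free haplotype distribution, an ASE prevalence of 0.12
#' among eligible cancer heterozygotes (2 of 17 evaluable), a mono-allelic
#' amplification fraction of 3/45, a 1.8-fold allele-1 signal excess at
#' rs937283 (whose raw heterozygote ratios were visibly off unity) and
#' unbiased rs1690916 signal.
#'
#' @param n_per_cohort Samples per cohort (cancer-free and cancer).
#' @param haplotype_table `hap_table` to draw gametes from.
#' @param ase_prevalence Fraction of eligible (functional-locus
#'   heterozygous) cancer samples assigned an expression imbalance.
#' @param ase_magnitude True fold-imbalance assigned to ASE-positive
#'   samples (> 0); orientation follows `suppressed_allele`.
#' @param bias_per_marker Named positive numerics, one per marker locus:
#'   multiplicative allele-1 signal excess.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied to every peak height.
#' @param monoallelic_fraction Fraction of cancer samples given a somatic
#'   gDNA copy-number imbalance.
#' @param mono_copy_ratio Copy ratio of the amplified over the other allele
#'   in mono-allelic samples (gDNA only).
#' @param functional_locus,readout_marker Locus ids of the causal promoter
#'   SNP and of the marker whose heterozygosity makes ASE observable.
#' @param suppressed_allele Base whose haplotype is transcribed less in
#'   ASE-positive samples.
#' @param standard_ratios Known molar ratios of the calibration series.
#' @param standard_replicates Replicates per calibration ratio.
#' @param seed Root seed; per-stage child seeds are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = 45,
                       haplotype_table = default_sim_haplotypes(),
                       ase_prevalence = 0.12,
                       ase_magnitude = 1.5,
                       bias_per_marker = c(rs1690916 = 1.0, rs937283 = 1.8),
                       noise_cv = 0.05,
                       monoallelic_fraction = 3 / 45,
                       mono_copy_ratio = 4,
                       functional_locus = "SNP55",
                       readout_marker = "rs1690916",
                       suppressed_allele = "C",
                       standard_ratios = c(0.25, 0.5, 1, 2, 4),
                       standard_replicates = 3,
                       seed = 1L) {
  if (ase_prevalence < 0 || ase_prevalence > 1) {
    abort("ase_prevalence must lie in [0, 1]")
  }
  if (monoallelic_fraction < 0 || monoallelic_fraction > 1) {
    abort("monoallelic_fraction must lie in [0, 1]")
  }
  if (!is.finite(ase_magnitude) || ase_magnitude <= 0) {
    abort("ase_magnitude must be positive")
  }
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  if (mono_copy_ratio <= 0) abort("mono_copy_ratio must be positive")
  if (any(!is.finite(bias_per_marker)) || any(bias_per_marker <= 0)) {
    abort("bias_per_marker entries must be positive")
  }
  structure(list(
    n_per_cohort = as.integer(n_per_cohort),
    haplotype_table = haplotype_table,
    ase_prevalence = ase_prevalence,
    ase_magnitude = ase_magnitude,
    bias_per_marker = bias_per_marker,
    noise_cv = noise_cv,
    monoallelic_fraction = monoallelic_fraction,
    mono_copy_ratio = mono_copy_ratio,
    functional_locus = functional_locus,
    readout_marker = readout_marker,
    suppressed_allele = suppressed_allele,
    standard_ratios = standard_ratios,
    standard_replicates = as.integer(standard_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

hap_alleles_at <- function(haplotype, table, locus_id) {
  loci <- attr(table, "loci")
  j <- match(locus_id, loci$locus_id)
  if (is.na(j)) abort(paste0("locus '", locus_id, "' not in haplotype panel"))
  map_chr(strsplit(haplotype, "-", fixed = TRUE), j)
}

cohort_genotype_at <- function(cohort, table, locus_id) {
  a1 <- hap_alleles_at(cohort$hap1, table, locus_id)
  a2 <- hap_alleles_at(cohort$hap2, table, locus_id)
  paste(a1, a2, sep = "/")
}

is_het_at <- function(cohort, table, locus_id) {
  a1 <- hap_alleles_at(cohort$hap1, table, locus_id)
  a2 <- hap_alleles_at(cohort$hap2, table, locus_id)
  a1 != a2
}

#' Draw phased samples from a haplotype frequency table
#'
#' Each sample's two haplotypes are drawn independently from the table
#' (random union of gametes, the Hardy-Weinberg generative assumption).
#'
#' @param table A `hap_table`.
#' @param n Number of samples (>= 0).
#' @param seed Integer seed (the stage draws from a child stream).
#' @param cohort Cohort label stored on every sample.
#' @param prefix Prefix for generated sample ids.
#' @return Tibble with columns `sample_id`, `cohort`, `hap1`, `hap2`,
#'   carrying the haplotype panel as attribute `"hap_table"`.
#' @export
sample_haplotype_pairs <- function(table, n, seed = 1L, cohort = "cancer",
                                   prefix = cohort) {
  stopifnot(inherits(table, "hap_table"))
  if (n < 0) abort("n must be non-negative")
  haps <- if (n == 0) character(0) else with_seed(
    child_seed(seed, "haplotypes"),
    sample(table$haplotype, size = 2 * n, replace = TRUE, prob = table$freq)
  )
  out <- tibble(
    sample_id = if (n == 0) character(0) else sprintf("%s-%03d", prefix, seq_len(n)),
    cohort = rep(cohort, n),
    hap1 = haps[seq_len(n) * 2 - 1],
    hap2 = haps[seq_len(n) * 2]
  )
  attr(out, "hap_table") <- table
  out
}

#' Assign the expression-imbalance truth model to a phased cohort
#'
#' An `ase_prevalence` fraction of cancer samples heterozygous at the
#' functional locus receive `true_expression_ratio = ase_magnitude`,
#' oriented so the haplotype carrying the suppressed allele is the weaker
#' one (the ratio is haplotype-1 output over haplotype-2 output); everyone
#' else gets 1.  `ase_truth` is additionally forced to `FALSE` for samples
#' homozygous at the read-out marker, where an imbalance exists but cannot
#' be observed.  A `monoallelic_fraction` of cancer samples is flagged with
#' a somatic gDNA copy imbalance.
#'
#' @param cohort Output of [sample_haplotype_pairs()] (cohorts may be mixed;
#'   only rows with `cohort == "cancer"` are eligible).
#' @param config A [sim_config()].
#' @return The cohort with columns `true_expression_ratio`, `ase_truth`,
#'   `monoallelic_truth` added.
#' @export
assign_expression_model <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  table <- attr(cohort, "hap_table") %||% config$haplotype_table
  n <- nrow(cohort)
  het_fun <- is_het_at(cohort, table, config$functional_locus)
  marker_present <- config$readout_marker %in% attr(table, "loci")$locus_id
  het_marker <- if (marker_present) {
    is_het_at(cohort, table, config$readout_marker)
  } else {
    rep(TRUE, n)
  }
  is_cancer <- cohort$cohort == "cancer"
  draws <- with_seed(child_seed(config$seed, "expression"), list(
    ase = runif(n) < config$ase_prevalence,
    mono = runif(n) < config$monoallelic_fraction,
    amp_hap1 = runif(n) < 0.5
  ))
  assigned <- is_cancer & het_fun & draws$ase
  hap1_suppressed <- hap_alleles_at(cohort$hap1, table,
                                    config$functional_locus) ==
    config$suppressed_allele
  ratio <- rep(1, n)
  ratio[assigned] <- if_else(hap1_suppressed[assigned],
                             1 / config$ase_magnitude, config$ase_magnitude)
  out <- cohort
  out$true_expression_ratio <- ratio
  out$ase_truth <- assigned & het_marker
  out$monoallelic_truth <- is_cancer & draws$mono
  out$mono_amplified_hap1 <- out$monoallelic_truth & draws$amp_hap1
  attr(out, "hap_table") <- table
  out
}

lognormal_noise <- function(k, cv, seed_val) {
  if (cv == 0) return(rep(1, k))
  sigma <- sqrt(log(1 + cv^2))
  with_seed(seed_val, exp(rnorm(k, mean = -sigma^2 / 2, sd = sigma)))
}

#' Emit gDNA and cDNA peak-height observations for a cohort
#'
#' For each sample and each marker-role locus of the panel, produces one
#' gDNA and one cDNA record of the two allele peak heights.  For a
#' heterozygote the expected height ratio (allele1/allele2) is the
#' marker-specific signal bias times the allelic abundance ratio: the gDNA
#' copy ratio (1, or the configured imbalance for mono-allelic samples) for
#' gDNA, and bias times the allele-oriented true expression ratio for cDNA.
#' Homozygotes emit zero height for the absent allele.  Every non-zero
#' height carries independent multiplicative log-normal noise of the
#' configured CV.
#'
#' @param cohort Output of [assign_expression_model()].
#' @param config A [sim_config()].
#' @param base_height Arbitrary fluorescence scale of the allele-2 peak.
#' @return Tibble `sample_id`, `locus_id`, `analyte`, `known_ratio` (NA),
#'   `height_allele1`, `height_allele2`.
#' @export
emit_peak_signals <- function(cohort, config, base_height = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cohort$true_expression_ratio)) {
    abort("cohort has no expression model; run assign_expression_model() first")
  }
  table <- attr(cohort, "hap_table") %||% config$haplotype_table
  loci <- attr(table, "loci")
  markers <- loci$locus_id[loci$role == "marker"]
  missing_bias <- setdiff(markers, names(config$bias_per_marker))
  if (length(missing_bias)) {
    abort(paste0("no bias entry for marker '", missing_bias[1], "'"))
  }
  rows <- list()
  for (locus in markers) {
    bias <- config$bias_per_marker[[locus]]
    a1 <- hap_alleles_at(cohort$hap1, table, locus)
    a2 <- hap_alleles_at(cohort$hap2, table, locus)
    allele1 <- loci$allele1[match(locus, loci$locus_id)]
    het <- a1 != a2
    # allelic copy ratio in gDNA (allele1 over allele2), heterozygotes only
    amp_is_allele1 <- if_else(cohort$mono_amplified_hap1,
                              a1 == allele1, a2 == allele1)
    gratio <- if_else(cohort$monoallelic_truth,
                      if_else(amp_is_allele1, config$mono_copy_ratio,
                              1 / config$mono_copy_ratio),
                      1)
    # expression ratio oriented to allele1/allele2 at this locus
    hap1_is_allele1 <- a1 == allele1
    eratio <- if_else(hap1_is_allele1, cohort$true_expression_ratio,
                      1 / cohort$true_expression_ratio)
    for (analyte in c("gDNA", "cDNA")) {
      ab_ratio <- if (analyte == "gDNA") gratio else eratio
      e1 <- if_else(het, base_height * bias * ab_ratio,
                    if_else(a1 == allele1, 2 * base_height, 0))
      e2 <- if_else(het, base_height,
                    if_else(a1 == allele1, 0, 2 * base_height))
      rows[[paste(locus, analyte)]] <- tibble(
        sample_id = cohort$sample_id, locus_id = locus, analyte = analyte,
        known_ratio = NA_real_, e1 = e1, e2 = e2
      )
    }
  }
  out <- bind_rows(rows)
  k <- nrow(out)
  noise <- lognormal_noise(2 * k, config$noise_cv,
                           child_seed(config$seed, "peaks"))
  out$height_allele1 <- out$e1 * if_else(out$e1 > 0, noise[seq_len(k)], 1)
  out$height_allele2 <- out$e2 * if_else(out$e2 > 0, noise[k + seq_len(k)], 1)
  out |>
    select("sample_id", "locus_id", "analyte", "known_ratio",
           "height_allele1", "height_allele2") |>
    arrange(.data$locus_id, .data$analyte, .data$sample_id)
}

#' Emit a calibration standard series for one marker locus
#'
#' Mimics in-vitro-transcribed RNA mixtures of the two alleles at known
#' molar ratios: each replicate's expected observed ratio is the marker's
#' signal bias times the molar ratio, with the configured noise.
#'
#' @param locus Marker locus id (must have a bias entry in `config`).
#' @param mix_ratios Known molar ratios allele1:allele2, all > 0.
#' @param config A [sim_config()].
#' @param replicates Replicates per ratio.
#' @param base_height Fluorescence scale of the allele-2 peak.
#' @return Tibble in the peak-signal schema with `analyte = "standard"` and
#'   `known_ratio` filled.
#' @export
emit_standard_series <- function(locus, mix_ratios, config, replicates = 3,
                                 base_height = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (length(mix_ratios) == 0) abort("mix_ratios must be non-empty")
  if (any(!is.finite(mix_ratios) | mix_ratios <= 0)) {
    abort("every mix ratio must be positive")
  }
  if (!locus %in% names(config$bias_per_marker)) {
    abort(paste0("no bias entry for marker '", locus, "'"))
  }
  bias <- config$bias_per_marker[[locus]]
  grid <- tidyr::expand_grid(known_ratio = mix_ratios,
                             rep = seq_len(replicates))
  k <- nrow(grid)
  noise <- lognormal_noise(
    2 * k, config$noise_cv,
    child_seed(config$seed, "standards") + match(locus, names(config$bias_per_marker))
  )
  tibble(
    sample_id = sprintf("STD-%s-%g-%d", locus, grid$known_ratio, grid$rep),
    locus_id = locus, analyte = "standard", known_ratio = grid$known_ratio,
    height_allele1 = base_height * bias * grid$known_ratio * noise[seq_len(k)],
    height_allele2 = base_height * noise[k + seq_len(k)]
  )
}

#' Simulate a full two-cohort study
#'
#' Draws a cancer-free and a cancer cohort from the configured haplotype
#' distribution, assigns the expression-imbalance truth, and emits peak
#' signals plus a calibration standard series for every marker locus.
#'
#' @param config A [sim_config()].
#' @return List of class `ase_simulation` with elements `truth` (one row
#'   per sample, phased haplotypes and truth flags), `signals` (gDNA/cDNA
#'   peak heights) and `standards` (calibration series), plus the config.
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_cohort = 10, seed = 7))
#' head(sim$signals)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  free <- sample_haplotype_pairs(config$haplotype_table, config$n_per_cohort,
                                 seed = config$seed, cohort = "cancer-free",
                                 prefix = "FREE")
  canc <- sample_haplotype_pairs(config$haplotype_table, config$n_per_cohort,
                                 seed = config$seed + 10000L,
                                 cohort = "cancer", prefix = "EMCA")
  cohort <- bind_rows(free, canc)
  attr(cohort, "hap_table") <- config$haplotype_table
  cohort <- assign_expression_model(cohort, config)
  signals <- emit_peak_signals(cohort, config)
  loci <- attr(config$haplotype_table, "loci")
  standards <- bind_rows(lapply(
    intersect(loci$locus_id[loci$role == "marker"],
              names(config$bias_per_marker)),
    emit_standard_series, mix_ratios = config$standard_ratios,
    config = config, replicates = config$standard_replicates
  ))
  truth <- cohort |>
    mutate(haplotypes = paste(.data$hap1, .data$hap2, sep = "|")) |>
    select("sample_id", "cohort", "haplotypes", "true_expression_ratio",
           "ase_truth", "monoallelic_truth")
  structure(list(truth = truth, signals = signals, standards = standards,
                 config = config),
            class = "ase_simulation")
}

#' @export
print.ase_simulation <- function(x, ...) {
  cat("Synthetic ASE study:", nrow(x$truth), "samples,",
      nrow(x$signals), "peak records,", nrow(x$standards),
      "calibration standards\n")
  invisible(x)
}

#' Read or write the tidy peak-signal TSV schema
#'
#' One row per (sample, locus, analyte) with the two allele peak heights;
#' `known_ratio` is NA except for calibration standards.
#'
#' @param x Signals tibble (for writing).
#' @param path File path.
#' @return `read_signals_tsv` returns the tibble; `write_signals_tsv`
#'   returns `path` invisibly.
#' @export
write_signals_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_signals_tsv
#' @export
read_signals_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), locus_id = readr::col_character(),
    analyte = readr::col_character(), known_ratio = readr::col_double(),
    height_allele1 = readr::col_double(),
    height_allele2 = readr::col_double()
  ))
}

#' Serialise a simulation config to JSON (and back)
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `sim_config_from_json` returns a `sim_config`.
#' @export
sim_config_to_json <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$haplotype_table <- list(
    loci = as.data.frame(attr(config$haplotype_table, "loci")),
    haplotype = config$haplotype_table$haplotype,
    freq = config$haplotype_table$freq
  )
  x$bias_per_marker <- as.list(x$bias_per_marker)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname sim_config_to_json
#' @export
sim_config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ht <- hap_table(as_tibble(x$haplotype_table$loci),
                  x$haplotype_table$haplotype, x$haplotype_table$freq)
  x$haplotype_table <- ht
  x$bias_per_marker <- unlist(x$bias_per_marker)
  do.call(sim_config, x)
}
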