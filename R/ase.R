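#' ASE-calling configuration
#'
#' @param ase_threshold Relative difference between corrected cDNA and gDNA
#'   allelic ratios above which (strictly) a sample is called ASE-positive.
#'   The conventional threshold is a 20 percent difference.
#' @param mono_tau Corrected gDNA ratio (or its reciprocal) above which a
#'   sample is excluded as mono-allelic amplification.
#' @param min_minor_fraction Heterozygote gate on gDNA peaks: minimum
#'   minor/major height fraction (inclusive).
#' @return A list of class `ase_config`.
#' @export
pipeline_config <- function(ase_threshold = 0.20, mono_tau = 3.0,
                            min_minor_fraction = 0.10) {
  if (ase_threshold <= 0) abort("ase_threshold must be positive")
  if (mono_tau <= 1) abort("mono_tau must exceed 1")
  if (min_minor_fraction <= 0 || min_minor_fraction >= 0.5) {
    abort("min_minor_fraction must lie in (0, 0.5)")
  }
  structure(list(ase_threshold = ase_threshold, mono_tau = mono_tau,
                 min_minor_fraction = min_minor_fraction),
            class = "ase_config")
}

#' Gate heterozygotes on gDNA peak heights
#'
#' A sample is usable as a heterozygote only if both allele peaks are
#' present in genomic DNA: the minor/major height fraction must reach
#' `min_minor_fraction` (inclusive boundary).
#'
#' @param height_allele1,height_allele2 Non-negative gDNA peak heights
#'   (vectorised).
#' @param config An [pipeline_config()].
#' @return Logical vector: `TRUE` for heterozygous.
#' @export
classify_heterozygote <- function(height_allele1, height_allele2,
                                  config = pipeline_config()) {
  if (any(height_allele1 < 0 | height_allele2 < 0, na.rm = TRUE)) {
    abort("peak heights must be non-negative")
  }
  both_zero <- height_allele1 == 0 & height_allele2 == 0
  if (any(both_zero, na.rm = TRUE)) {
    abort("record with both gDNA peak heights zero is unusable")
  }
  pmin(height_allele1, height_allele2) /
    pmax(height_allele1, height_allele2) >= config$min_minor_fraction
}

#' Call allele-specific expression for one sample
#'
#' Applies the detection rule to calibration-corrected allelic ratios: a
#' sample whose corrected gDNA ratio (either orientation) exceeds
#' `mono_tau` is excluded as mono-allelic amplification; otherwise the
#' relative expression ratio is `rho = cDNA / gDNA` and the sample is
#' ASE-positive iff `max(rho, 1/rho) - 1` strictly exceeds the threshold.
#' The symmetric form makes the verdict independent of which allele is the
#' ratio numerator.
#'
#' @param corrected_gdna_ratio,corrected_cdna_ratio Positive corrected
#'   ratios (vectorised).
#' @param config An [pipeline_config()].
#' @return Tibble with `corrected_gdna_ratio`, `corrected_cdna_ratio`,
#'   `expression_ratio`, `imbalance`, `status`.
#' @examples
#' call_ase(1.0, 1.25)  # imbalance 0.25 -> ase_positive
#' @export
call_ase <- function(corrected_gdna_ratio, corrected_cdna_ratio,
                     config = pipeline_config()) {
  g <- corrected_gdna_ratio
  c_ <- corrected_cdna_ratio
  if (any(!is.finite(g) | g <= 0) || any(!is.finite(c_) | c_ <= 0)) {
    abort("corrected ratios must be positive")
  }
  rho <- c_ / g
  imbalance <- pmax(rho, 1 / rho) - 1
  excluded <- pmax(g, 1 / g) > config$mono_tau
  status <- if_else(excluded, "excluded_monoallelic",
                    if_else(imbalance > config$ase_threshold,
                            "ase_positive", "ase_negative"))
  tibble(corrected_gdna_ratio = g, corrected_cdna_ratio = c_,
         expression_ratio = rho, imbalance = imbalance, status = status)
}

#' Run the full peak-to-call ASE pipeline
#'
#' For every marker locus: fit the calibration from its standards (or use
#' an override), correct each sample's gDNA and cDNA height ratios, gate
#' heterozygotes on gDNA peaks (or on supplied genotypes), exclude
#' mono-allelic amplification, and call ASE.  Samples with a gDNA record
#' but no matching cDNA record are reported with status `missing_cdna`
#' rather than dropped.
#'
#' @param peaks Peak-signal tibble (`sample_id`, `locus_id`, `analyte` in
#'   gDNA/cDNA, `height_allele1`, `height_allele2`).
#' @param standards Calibration standards table, or `NULL` if
#'   `bias_override` covers every locus.
#' @param config An [pipeline_config()].
#' @param bias_override Named numeric vector `locus_id = bias` taking
#'   precedence over fitted calibrations.
#' @param genotypes Optional tibble (`sample_id`, `locus_id`, `genotype`
#'   as `"A/G"`): when present, heterozygosity is taken from it instead of
#'   the gDNA peak gate.
#' @return Object of class `ase_result`: list with `calls` (per-sample
#'   tibble: ratios, imbalance, status), `summary` (per cohort-free counts
#'   per locus: n, heterozygous, excluded, evaluable, ase_positive) and
#'   `calibrations`.
#' @export
run_ase_pipeline <- function(peaks, standards = NULL,
                             config = pipeline_config(),
                             bias_override = NULL, genotypes = NULL) {
  loci <- unique(peaks$locus_id)
  calibrations <- list()
  for (locus in loci) {
    if (!is.null(bias_override) && locus %in% names(bias_override)) {
      calibrations[[locus]] <- calibration_override(locus, bias_override[[locus]])
    } else {
      std <- if (is.null(standards)) NULL else
        standards[standards$locus_id == locus, , drop = FALSE]
      if (is.null(std) || nrow(std) == 0) {
        abort(paste0("marker '", locus,
                     "' has neither standards nor a bias override"))
      }
      calibrations[[locus]] <- fit_calibration(std)
    }
  }
  wide <- peaks |>
    filter(.data$analyte %in% c("gDNA", "cDNA")) |>
    mutate(raw_ratio = .data$height_allele1 / .data$height_allele2) |>
    select("sample_id", "locus_id", "analyte", "height_allele1",
           "height_allele2", "raw_ratio") |>
    tidyr::pivot_wider(names_from = "analyte",
                       values_from = c("height_allele1", "height_allele2",
                                       "raw_ratio"))
  for (col in c("height_allele1_gDNA", "height_allele2_gDNA",
                "raw_ratio_gDNA", "raw_ratio_cDNA")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  bias <- map_dbl(calibrations, "bias")[wide$locus_id]
  wide$het <- classify_heterozygote(wide$height_allele1_gDNA,
                                    wide$height_allele2_gDNA, config)
  wide$het[is.na(wide$het)] <- FALSE  # no gDNA record -> not gateable
  if (!is.null(genotypes)) {
    g <- genotypes |>
      mutate(het_geno = map_lgl(strsplit(.data$genotype, "/", fixed = TRUE),
                                ~ length(unique(.x)) == 2)) |>
      select("sample_id", "locus_id", "het_geno")
    wide <- left_join(wide, g, by = c("sample_id", "locus_id"))
    wide$het <- if_else(!is.na(wide$het_geno), wide$het_geno, wide$het)
    wide$het_geno <- NULL
  }
  n <- nrow(wide)
  calls <- tibble(
    sample_id = wide$sample_id, locus_id = wide$locus_id,
    corrected_gdna_ratio = NA_real_, corrected_cdna_ratio = NA_real_,
    expression_ratio = NA_real_, imbalance = NA_real_,
    status = rep("not_heterozygous", n)
  )
  missing_cdna <- wide$het & is.na(wide$raw_ratio_cDNA)
  calls$status[missing_cdna] <- "missing_cdna"
  idx <- which(wide$het & !missing_cdna)
  if (length(idx)) {
    cg <- wide$raw_ratio_gDNA[idx] / bias[idx]
    cc <- wide$raw_ratio_cDNA[idx] / bias[idx]
    verdict <- call_ase(cg, cc, config)
    calls$corrected_gdna_ratio[idx] <- verdict$corrected_gdna_ratio
    calls$corrected_cdna_ratio[idx] <- verdict$corrected_cdna_ratio
    calls$expression_ratio[idx] <- verdict$expression_ratio
    calls$imbalance[idx] <- verdict$imbalance
    calls$status[idx] <- verdict$status
  }
  summary <- calls |>
    group_by(.data$locus_id) |>
    summarise(
      n = n(),
      heterozygous = sum(.data$status != "not_heterozygous"),
      excluded = sum(.data$status == "excluded_monoallelic"),
      missing_cdna = sum(.data$status == "missing_cdna"),
      evaluable = sum(.data$status %in% c("ase_positive", "ase_negative")),
      ase_positive = sum(.data$status == "ase_positive"),
      .groups = "drop"
    )
  structure(list(calls = calls, summary = summary,
                 calibrations = calibrations, config = config),
            class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  cat("ASE pipeline result\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ase_result <- function(x, ...) x$calls

#' @export
glance.ase_result <- function(x, ...) x$summary

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-sample corrected-ratio bar plot for an ASE result
#'
#' Paired bars of corrected genomic and cDNA allelic ratios per evaluable
#' sample, one panel per marker locus; the classic per-sample ASE display.
#'
#' @param object An `ase_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_result <- function(object, ...) {
  df <- object$calls |>
    filter(.data$status %in% c("ase_positive", "ase_negative")) |>
    tidyr::pivot_longer(c("corrected_gdna_ratio", "corrected_cdna_ratio"),
                        names_to = "analyte", values_to = "ratio") |>
    mutate(analyte = if_else(.data$analyte == "corrected_gdna_ratio",
                             "gDNA", "cDNA"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$ratio,
                                   fill = .data$analyte)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~locus_id, scales = "free_x") +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::labs(x = NULL, y = "corrected allelic ratio") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write per-sample calls to TSV
#'
#' @param result An `ase_result`.
#' @param path Output path.
#' @export
write_calls_tsv <- function(result, path) {
  readr::write_tsv(result$calls, path)
  invisible(path)
}
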