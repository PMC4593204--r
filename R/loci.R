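#' Define a biallelic locus
#'
#' A locus definition fixes the orientation of every allelic ratio computed
#' downstream: `allele1` is always the numerator.  `role` distinguishes the
#' putatively causal promoter SNP (`"functional"`) from transcribed marker
#' SNPs used only to tell the two alleles' transcripts apart (`"marker"`).
#'
#' @param locus_id Short unique label, e.g. `"SNP55"` or `"rs1690916"`.
#' @param alleles Character vector of two distinct single bases (A/C/G/T);
#'   the first is the numerator allele of every ratio at this locus.
#' @param role `"functional"` or `"marker"`.
#' @return A one-row tibble with columns `locus_id`, `role`, `allele1`,
#'   `allele2`.
#' @examples
#' locus_definition("SNP55", c("C", "T"), role = "functional")
#' @export
locus_definition <- function(locus_id, alleles, role = c("marker", "functional")) {
  role <- match.arg(role)
  if (length(locus_id) != 1 || !nzchar(locus_id)) {
    abort("locus_id must be a single non-empty string")
  }
  alleles <- toupper(as.character(alleles))
  if (length(alleles) != 2 || !all(alleles %in% c("A", "C", "G", "T")) ||
      alleles[1] == alleles[2]) {
    abort(paste0("alleles for '", locus_id,
                 "' must be two distinct bases from A,C,G,T"))
  }
  tibble(locus_id = locus_id, role = role,
         allele1 = alleles[1], allele2 = alleles[2])
}

#' Locus panel for the MDM2 promoter/marker system
#'
#' The four-SNP panel used throughout the package examples: the functional
#' promoter SNPs SNP55 (C/T) and SNP309 (T/G) in the P2 promoter, plus the
#' transcribed marker SNPs rs1690916 (3'UTR, read out as G/A) and rs937283
#' (exon 1, read out as A/G).
#'
#' @return A four-row locus tibble (see [locus_definition()]).
#' @export
mdm2_loci <- function() {
  bind_rows(
    locus_definition("SNP55", c("C", "T"), role = "functional"),
    locus_definition("SNP309", c("T", "G"), role = "functional"),
    locus_definition("rs1690916", c("G", "A"), role = "marker"),
    locus_definition("rs937283", c("A", "G"), role = "marker")
  )
}

#' Build a haplotype frequency table
#'
#' @param loci Locus tibble (rows from [locus_definition()]); order defines
#'   the allele order within each haplotype string.
#' @param haplotypes Character vector of haplotype labels, alleles joined by
#'   `"-"` in locus order, e.g. `"C-T"` for a two-locus table.
#' @param freq Numeric frequencies, same length; must be non-negative and
#'   sum to 1 (a tolerance of `tol` is accepted and renormalised away, so
#'   published 3-decimal frequencies can be passed as printed).
#' @param tol Acceptable deviation of `sum(freq)` from 1 before rejection.
#' @return A tibble with columns `haplotype` and `freq` (renormalised),
#'   carrying the locus panel as attribute `"loci"`; class `hap_table`.
#' @examples
#' cancer_free_haplotypes()
#' @export
hap_table <- function(loci, haplotypes, freq, tol = 0.002) {
  if (anyDuplicated(loci$locus_id)) abort("duplicate locus_id in panel")
  if (length(haplotypes) != length(freq)) {
    abort("haplotypes and freq lengths differ")
  }
  if (anyDuplicated(haplotypes)) abort("duplicate haplotype labels")
  bad <- which(!is.finite(freq) | freq < 0)
  if (length(bad)) {
    abort(paste0("invalid frequency for haplotype '", haplotypes[bad[1]],
                 "': ", freq[bad[1]]))
  }
  s <- sum(freq)
  if (abs(s - 1) > tol) {
    abort(paste0("haplotype frequencies sum to ", format(s), ", not 1"))
  }
  split_ok <- map_lgl(strsplit(haplotypes, "-", fixed = TRUE),
                      ~ length(.x) == nrow(loci))
  if (!all(split_ok)) {
    abort(paste0("haplotype '", haplotypes[which(!split_ok)[1]],
                 "' does not have one allele per locus"))
  }
  alleles <- do.call(rbind, strsplit(haplotypes, "-", fixed = TRUE))
  for (j in seq_len(nrow(loci))) {
    ok <- alleles[, j] %in% c(loci$allele1[j], loci$allele2[j])
    if (!all(ok)) {
      abort(paste0("haplotype '", haplotypes[which(!ok)[1]],
                   "' carries an allele not defined for ", loci$locus_id[j]))
    }
  }
  out <- tibble(haplotype = haplotypes, freq = freq / s)
  attr(out, "loci") <- loci
  class(out) <- c("hap_table", class(out))
  out
}

#' @export
print.hap_table <- function(x, ...) {
  loci <- attr(x, "loci")
  cat("Haplotype frequency table (", paste(loci$locus_id, collapse = ", "),
      ")\n", sep = "")
  NextMethod()
}

#' Cancer-free two-locus haplotype frequencies for SNP55/SNP309
#'
#' The published haplotype distribution over 90 cancer-free chromosomes
#' (counts 16, 42, 32, 0 for C-T, C-G, T-T, T-G), used as the default
#' generative distribution of the synthetic cohort module.
#'
#' @param as_counts If `TRUE`, return the integer chromosome counts instead
#'   of frequencies.
#' @return A `hap_table` (or a named integer vector when `as_counts`).
#' @export
cancer_free_haplotypes <- function(as_counts = FALSE) {
  counts <- c("C-T" = 16L, "C-G" = 42L, "T-T" = 32L, "T-G" = 0L)
  if (as_counts) return(counts)
  loci <- mdm2_loci()[1:2, ]
  hap_table(loci, names(counts), as.numeric(counts) / sum(counts))
}
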