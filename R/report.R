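#' Parse a cohort genotype table
#'
#' Reads a TSV/CSV with one row per sample: `sample_id`, optional `age`
#' and `histology`, and one genotype column per locus of the panel.
#' Single-base homozygote shorthand (`"A"`) is expanded to `"A/A"`;
#' heterozygotes are normalised to allele1/allele2 order.
#'
#' @param path File path (tab- or comma-separated, with header).
#' @param loci Locus panel naming the expected genotype columns; columns
#'   absent from the file are skipped.
#' @return Tibble with normalised genotype columns; attribute `"loci"`
#'   records the panel.
#' @export
parse_cohort_table <- function(path, loci = mdm2_loci()) {
  first <- readLines(path, n = 1)
  delim <- if (length(first) && grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (nrow(df) == 0) {
    warn("empty cohort table")
    return(structure(df, loci = loci))
  }
  if (!"sample_id" %in% names(df)) abort("cohort table needs a sample_id column")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample_id '", dup[1], "'"))
  for (j in seq_len(nrow(loci))) {
    id <- loci$locus_id[j]
    if (!id %in% names(df)) next
    df[[id]] <- normalise_genotypes(df[[id]], loci[j, ], df$sample_id)
  }
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  attr(df, "loci") <- loci
  df
}

#' The packaged endometrial-cancer cohort genotype fixture
#'
#' A verbatim transcription of the published per-sample listing of 45
#' endometrial cancer (EMCA) samples: age, histology and genotypes at
#' rs937283, rs1690916, SNP55 and SNP309.
#'
#' @return Parsed cohort tibble (see [parse_cohort_table()]).
#' @export
emca_cohort <- function() {
  parse_cohort_table(system.file("extdata", "emca_genotypes.tsv",
                                 package = "asekit"))
}

#' Pivot a parsed cohort table to long genotype records
#'
#' @param cohort Output of [parse_cohort_table()].
#' @return Tibble: `sample_id`, `locus_id`, `genotype`.
#' @export
cohort_genotypes_long <- function(cohort) {
  loci <- attr(cohort, "loci")
  cols <- intersect(loci$locus_id, names(cohort))
  cohort |>
    select("sample_id", all_of(cols)) |>
    tidyr::pivot_longer(all_of(cols), names_to = "locus_id",
                        values_to = "genotype")
}

#' Genotype/allele frequency comparison between cohorts at one locus
#'
#' Builds the classic case-control summary: genotype counts and
#' percentages per cohort, allele counts and percentages, and the
#' two-sided Fisher exact p-values for the genotype (2 x 3) and allele
#' (2 x 2) tables.
#'
#' @param genotypes_by_cohort Named list, cohort label -> genotype vector.
#' @param locus One-row locus tibble.
#' @return List of class `genotype_summary`: `genotype` and `allele`
#'   tibbles (per cohort), `p_genotype`, `p_allele`.
#' @export
genotype_summary <- function(genotypes_by_cohort, locus) {
  stopifnot(length(genotypes_by_cohort) >= 1)
  gt <- imap(genotypes_by_cohort, function(g, nm) {
    genotype_frequency_table(g, locus) |> mutate(cohort = nm)
  }) |> bind_rows()
  at <- imap(genotypes_by_cohort, function(g, nm) {
    allele_counts_from_genotypes(genotype_frequency_table(g, locus)) |>
      mutate(cohort = nm)
  }) |> bind_rows()
  p_gen <- p_all <- NA_real_
  if (length(genotypes_by_cohort) == 2) {
    gmat <- do.call(rbind, split(gt$count, gt$cohort) |> unname() |>
                      lapply(as.integer))
    keep <- colSums(gmat) > 0
    p_gen <- fisher_exact(gmat[, keep, drop = FALSE])$p_value
    amat <- do.call(rbind, split(at$count, at$cohort) |> unname() |>
                      lapply(as.integer))
    p_all <- fisher_exact(amat)$p_value
  }
  structure(list(locus_id = locus$locus_id, genotype = gt, allele = at,
                 p_genotype = p_gen, p_allele = p_all),
            class = "genotype_summary")
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf("Locus %s  (genotype p = %s, allele p = %s)\n", x$locus_id,
              format_p(x$p_genotype), format_p(x$p_allele)))
  print(x$genotype)
  print(x$allele)
  invisible(x)
}

format_p <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.2f", round_half_up(p, 2)))
}

#' Render a combined study report
#'
#' Writes a deterministic human-readable text report (percentages to one
#' decimal, p-values to two, frequencies and r-squared to three) plus a
#' machine-readable JSON with full precision.  Sections left `NULL` are
#' omitted.
#'
#' @param out_dir Output directory (created if needed).
#' @param calls An `ase_result`, or `NULL`.
#' @param popgen A list of `genotype_summary` objects, or `NULL`.
#' @param ld LD tibble from [ld_from_haplotypes()], or `NULL`.
#' @param diff An `allele_diff_report`, or `NULL`.
#' @return Invisibly, the paths of the two report files.
#' @export
render_summary <- function(out_dir, calls = NULL, popgen = NULL, ld = NULL,
                           diff = NULL) {
  if (is.null(calls) && is.null(popgen) && is.null(ld) && is.null(diff)) {
    abort("at least one report section must be supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character(0)
  json <- list()
  if (!is.null(calls)) {
    lines <- c(lines, "== ASE calls ==")
    s <- calls$summary
    lines <- c(lines, sprintf(
      "%s: n=%d heterozygous=%d excluded=%d evaluable=%d ase_positive=%d",
      s$locus_id, s$n, s$heterozygous, s$excluded, s$evaluable,
      s$ase_positive))
    pos <- calls$calls |> filter(.data$status == "ase_positive")
    if (nrow(pos)) {
      lines <- c(lines, sprintf("  %s @ %s: gDNA %.2f cDNA %.2f (imbalance %.2f)",
                                pos$sample_id, pos$locus_id,
                                round_half_up(pos$corrected_gdna_ratio, 2),
                                round_half_up(pos$corrected_cdna_ratio, 2),
                                round_half_up(pos$imbalance, 2)))
    }
    json$ase <- list(summary = s, calls = calls$calls)
  }
  if (!is.null(popgen)) {
    lines <- c(lines, "== Genotype and allele frequencies ==")
    for (gs in popgen) {
      lines <- c(lines, sprintf("%s (genotype p = %s, allele p = %s)",
                                gs$locus_id, format_p(gs$p_genotype),
                                format_p(gs$p_allele)))
      lines <- c(lines, sprintf("  %s %s: %d (%.1f%%)", gs$genotype$cohort,
                                gs$genotype$genotype, gs$genotype$count,
                                gs$genotype$pct))
      lines <- c(lines, sprintf("  %s allele %s: %d (%.1f%%)",
                                gs$allele$cohort, gs$allele$allele,
                                gs$allele$count, gs$allele$pct))
    }
    json$popgen <- lapply(popgen, function(gs) {
      list(locus_id = gs$locus_id, genotype = gs$genotype,
           allele = gs$allele, p_genotype = gs$p_genotype,
           p_allele = gs$p_allele)
    })
  }
  if (!is.null(ld)) {
    lines <- c(lines, "== Linkage disequilibrium ==", sprintf(
      "p1 = %.3f  p2 = %.3f  D = %.3f  D' = %.3f  r^2 = %.3f",
      ld$p1, ld$p2, ld$D, ld$D_prime, ld$r_squared))
    json$ld <- ld
  }
  if (!is.null(diff)) {
    lines <- c(lines, "== Allele-differential motif scan ==", sprintf(
      "%s pos %d: %s -> %s; lost %d, gained %d, shared %d", diff$seq_id,
      diff$variant_pos + 1, diff$alleleA, diff$alleleB, nrow(diff$lost),
      nrow(diff$gained), nrow(diff$shared_at_variant)))
    if (nrow(diff$lost)) {
      lines <- c(lines, sprintf("  lost: %s (%s strand, site %s)",
                                diff$lost$motif_id, diff$lost$strand,
                                diff$lost$site))
    }
    if (nrow(diff$gained)) {
      lines <- c(lines, sprintf("  gained: %s (%s strand, site %s)",
                                diff$gained$motif_id, diff$gained$strand,
                                diff$gained$site))
    }
    json$motif_diff <- list(
      seq_id = diff$seq_id, variant_pos = diff$variant_pos,
      alleleA = diff$alleleA, alleleB = diff$alleleB,
      lost = diff$lost, gained = diff$gained,
      shared_at_variant = diff$shared_at_variant)
  }
  txt_path <- file.path(out_dir, "report.txt")
  json_path <- file.path(out_dir, "report.json")
  writeLines(lines, txt_path)
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(txt = txt_path, json = json_path))
}

#' Build a run manifest
#'
#' Captures everything needed to re-run an analysis bit-identically: the
#' package version, the fully resolved configuration, md5 digests of the
#' input files, and the seed.
#'
#' @param config Named list of resolved configuration values.
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed used for the run.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), inputs = character(0), seed = NA) {
  digests <- if (length(inputs)) {
    setNames(unname(tools::md5sum(inputs)), basename(inputs))
  } else {
    character(0)
  }
  structure(list(
    tool = "asekit",
    version = as.character(utils::packageVersion("asekit")),
    config = config,
    input_digests = as.list(digests),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}
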