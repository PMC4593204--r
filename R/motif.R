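IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param seq Character vector of sequences over the IUPAC alphabet.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  flipped <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  vapply(strsplit(flipped, ""), \(x) paste(rev(x), collapse = ""),
         character(1))
}

check_iupac <- function(s, what = "sequence") {
  chars <- unique(strsplit(toupper(s), "")[[1]])
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    abort(paste0(what, " contains invalid character '", bad[1], "'"))
  }
  toupper(s)
}

#' Construct motifs
#'
#' `iupac_motif()` wraps a consensus pattern; `pwm_motif()` wraps a
#' position probability matrix scored by log-odds against a background;
#' `pwm_from_sites()` builds the matrix from aligned example binding sites
#' with a pseudocount.
#'
#' @param motif_id Motif label.
#' @param pattern IUPAC consensus string.
#' @param tf Optional transcription-factor name.
#' @return A list of class `motif` with fields `motif_id`, `kind`
#'   (`"iupac"` or `"pwm"`), `tf`, and kind-specific fields (`pattern`, or
#'   `matrix`/`background`/`threshold`).
#' @export
iupac_motif <- function(motif_id, pattern, tf = NA_character_) {
  pattern <- check_iupac(pattern, paste0("pattern of '", motif_id, "'"))
  if (!nzchar(pattern)) abort("empty IUPAC pattern")
  structure(list(motif_id = motif_id, kind = "iupac", tf = tf,
                 pattern = pattern),
            class = "motif")
}

#' @rdname iupac_motif
#' @param matrix 4 x L numeric matrix with rownames A, C, G, T; columns are
#'   probability vectors (sum 1, no zero entries).
#' @param background Named base frequencies (positive, sum 1).
#' @param threshold Minimum log-odds score for a window to be reported.
#' @export
pwm_motif <- function(motif_id, matrix, background = rep(0.25, 4),
                      threshold = 0, tf = NA_character_) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  stopifnot(nrow(matrix) == 4, all(rownames(matrix) == c("A", "C", "G", "T")))
  if (any(matrix <= 0)) abort("PWM columns must have no zero entries (apply a pseudocount)")
  if (any(abs(colSums(matrix) - 1) > 1e-9)) {
    abort("PWM columns must sum to 1")
  }
  background <- setNames(as.numeric(background), c("A", "C", "G", "T"))
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    abort("background frequencies must be positive and sum to 1")
  }
  structure(list(motif_id = motif_id, kind = "pwm", tf = tf, matrix = matrix,
                 background = background, threshold = threshold),
            class = "motif")
}

#' @rdname iupac_motif
#' @param sites Character vector of equal-length example binding sites
#'   (A/C/G/T only).
#' @param pseudocount Added per base per column before normalising.
#' @export
pwm_from_sites <- function(motif_id, sites, pseudocount = 0.5,
                           background = rep(0.25, 4), threshold = 0,
                           tf = NA_character_) {
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1) abort("binding sites must have equal length")
  chars <- do.call(rbind, strsplit(sites, ""))
  m <- vapply(seq_len(L), function(j) {
    counts <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    as.numeric(counts + pseudocount) / (length(sites) + 4 * pseudocount)
  }, numeric(4))
  rownames(m) <- c("A", "C", "G", "T")
  pwm_motif(motif_id, m, background = background, threshold = threshold,
            tf = tf)
}

#' @export
print.motif <- function(x, ...) {
  if (x$kind == "iupac") {
    cat(sprintf("IUPAC motif %s: %s\n", x$motif_id, x$pattern))
  } else {
    cat(sprintf("PWM motif %s: %d columns, threshold %.3f\n", x$motif_id,
                ncol(x$matrix), x$threshold))
  }
  invisible(x)
}

motif_width <- function(motif) {
  if (motif$kind == "iupac") nchar(motif$pattern) else ncol(motif$matrix)
}

empty_hits <- function() {
  tibble(motif_id = character(), seq_id = character(), start = integer(),
         strand = character(), site = character(), score = double())
}

substr_vec <- function(s, starts0, L) {
  if (length(starts0) == 0) return(character(0))
  substring(s, starts0 + 1, starts0 + L)
}

iupac_match_starts <- function(sequence, pattern) {
  L <- nchar(pattern)
  n <- nchar(sequence)
  if (L > n) return(integer(0))
  seq_chars <- strsplit(sequence, "")[[1]]
  pat_sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  ok <- vapply(seq_len(n - L + 1), function(i) {
    all(vapply(seq_len(L), function(j) {
      any(IUPAC_SETS[[seq_chars[i + j - 1]]] %in% pat_sets[[j]])
    }, logical(1)))
  }, logical(1))
  which(ok) - 1L  # 0-based
}

#' Scan a sequence with an IUPAC consensus motif
#'
#' Reports every window whose bases are compatible with the pattern under
#' IUPAC base-set semantics (a subject base matches a pattern base iff
#' their base sets intersect).  Minus-strand hits are found on the reverse
#' complement and reported in plus-strand coordinates.
#'
#' @param sequence Subject DNA string (IUPAC alphabet).
#' @param motif An `iupac` [iupac_motif()].
#' @param strands `"both"`, `"+"` or `"-"`.
#' @param seq_id Identifier carried into the hit table.
#' @return Hit tibble: `motif_id`, `seq_id`, `start` (0-based, half-open
#'   window `[start, start + L)`), `strand`, `site` (matched subsequence on
#'   the motif's strand), `score` (NA for consensus motifs).
#' @examples
#' iupac_scan(mdm2_snp55_probe("C"), iupac_motif("kB_core", "GGGRNNY"))
#' @export
iupac_scan <- function(sequence, motif, strands = c("both", "+", "-"),
                       seq_id = "seq") {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif"), motif$kind == "iupac")
  sequence <- check_iupac(sequence)
  L <- nchar(motif$pattern)
  n <- nchar(sequence)
  out <- list()
  if (strands %in% c("both", "+")) {
    st <- iupac_match_starts(sequence, motif$pattern)
    out$plus <- tibble(motif_id = motif$motif_id, seq_id = seq_id,
                       start = st, strand = "+",
                       site = substr_vec(sequence, st, L),
                       score = NA_real_)
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp(sequence)
    st_rc <- iupac_match_starts(rc, motif$pattern)
    st <- n - L - st_rc  # mirror to plus-strand coordinates
    out$minus <- tibble(motif_id = motif$motif_id, seq_id = seq_id,
                        start = st, strand = "-",
                        site = substr_vec(rc, st_rc, L),
                        score = NA_real_)
  }
  bind_rows(c(list(empty_hits()), out)) |> arrange(.data$start, .data$strand)
}

pwm_score_site <- function(site, motif) {
  bases <- strsplit(site, "")[[1]]
  ridx <- match(bases, rownames(motif$matrix))
  sum(log(motif$matrix[cbind(ridx, seq_along(bases))] /
            motif$background[bases]))
}

#' Scan a sequence with a position weight matrix
#'
#' Windows on both strands scoring at least the motif threshold (log-odds
#' versus the background model) are reported.  Subject sequences must be
#' unambiguous A/C/G/T.
#'
#' @inheritParams iupac_scan
#' @param motif A `pwm` motif.
#' @return Hit tibble as in [iupac_scan()], with `score` filled.
#' @export
pwm_scan <- function(sequence, motif, strands = c("both", "+", "-"),
                     seq_id = "seq") {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif"), motif$kind == "pwm")
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]),
                 names(motif$background))
  if (length(bad)) {
    abort(paste0("sequence base '", bad[1],
                 "' is absent from the PWM background model"))
  }
  L <- ncol(motif$matrix)
  n <- nchar(sequence)
  scan_one <- function(s) {
    if (L > nchar(s)) return(tibble(start = integer(), site = character(),
                                    score = double()))
    st <- 0:(nchar(s) - L)
    site <- substring(s, st + 1, st + L)
    tibble(start = st, site = site,
           score = map_dbl(site, pwm_score_site, motif = motif))
  }
  out <- list()
  if (strands %in% c("both", "+")) {
    h <- scan_one(sequence) |> filter(.data$score >= motif$threshold)
    out$plus <- tibble(motif_id = motif$motif_id, seq_id = seq_id,
                       start = h$start, strand = "+", site = h$site,
                       score = h$score)
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp(sequence)
    h <- scan_one(rc) |> filter(.data$score >= motif$threshold)
    out$minus <- tibble(motif_id = motif$motif_id, seq_id = seq_id,
                        start = n - L - h$start, strand = "-",
                        site = h$site, score = h$score)
  }
  bind_rows(c(list(empty_hits()), out)) |> arrange(.data$start, .data$strand)
}

#' Scan with a motif of either kind, or a list of motifs
#'
#' @inheritParams iupac_scan
#' @param motifs A `motif` or list of motifs.
#' @return Combined hit tibble.
#' @export
scan_motifs <- function(sequence, motifs, strands = "both", seq_id = "seq") {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  bind_rows(lapply(motifs, function(m) {
    if (m$kind == "iupac") {
      iupac_scan(sequence, m, strands = strands, seq_id = seq_id)
    } else {
      pwm_scan(sequence, m, strands = strands, seq_id = seq_id)
    }
  }))
}

#' Compare motif hits between the two alleles of a variant
#'
#' Substitutes each allele into the template at `variant_pos`, scans both
#' allele sequences with every motif, and classifies hits whose window
#' overlaps the variant as `lost` (allele A only), `gained` (allele B
#' only) or `shared_at_variant` (both).  Hits not overlapping the variant
#' are identical between alleles and reported once as `unchanged`.
#'
#' @param template DNA string carrying either allele (or N) at the variant.
#' @param variant_pos 0-based position of the variant in `template`.
#' @param alleleA,alleleB Single reference/alternative bases.
#' @param motifs A `motif` or list of motifs (see [default_motifs()]).
#' @param seq_id Sequence identifier for the report.
#' @return List of class `allele_diff_report`: the substituted sequences,
#'   per-class hit tibbles, and the full per-allele hit lists.
#' @examples
#' rep <- allele_differential_scan(mdm2_snp55_probe("C"), 10, "C", "T",
#'                                 default_motifs())
#' rep$lost  # kB hit present for C only
#' @export
allele_differential_scan <- function(template, variant_pos, alleleA, alleleB,
                                     motifs, seq_id = "seq") {
  template <- check_iupac(template)
  n <- nchar(template)
  if (variant_pos < 0 || variant_pos >= n) {
    abort("variant_pos outside the template")
  }
  ok_base <- function(a) nchar(a) == 1 && toupper(a) %in% c("A", "C", "G", "T")
  if (!ok_base(alleleA) || !ok_base(alleleB)) {
    abort("alleles must be single A/C/G/T bases")
  }
  substitute_at <- function(base) {
    paste0(substring(template, 1, variant_pos), toupper(base),
           substring(template, variant_pos + 2, n))
  }
  seqA <- substitute_at(alleleA)
  seqB <- substitute_at(alleleB)
  hitsA <- scan_motifs(seqA, motifs, seq_id = seq_id)
  hitsB <- scan_motifs(seqB, motifs, seq_id = seq_id)
  overlaps <- function(h) {
    h$start <= variant_pos & variant_pos < h$start + nchar(h$site)
  }
  key <- function(h) paste(h$motif_id, h$start, h$strand)
  ovA <- hitsA[overlaps(hitsA), ]
  ovB <- hitsB[overlaps(hitsB), ]
  lost <- ovA[!key(ovA) %in% key(ovB), ]
  gained <- ovB[!key(ovB) %in% key(ovA), ]
  shared <- ovA[key(ovA) %in% key(ovB), ]
  unchanged <- hitsA[!overlaps(hitsA), ]
  structure(list(
    seq_id = seq_id, template = template, variant_pos = variant_pos,
    alleleA = toupper(alleleA), alleleB = toupper(alleleB),
    sequenceA = seqA, sequenceB = seqB,
    hitsA = hitsA, hitsB = hitsB,
    lost = lost, gained = gained, shared_at_variant = shared,
    unchanged = unchanged
  ), class = "allele_diff_report")
}

#' @export
print.allele_diff_report <- function(x, ...) {
  cat(sprintf("Allele-differential motif report at %s position %d (%s -> %s)\n",
              x$seq_id, x$variant_pos + 1, x$alleleA, x$alleleB))
  cat(sprintf("  lost: %d, gained: %d, shared at variant: %d, unchanged: %d\n",
              nrow(x$lost), nrow(x$gained), nrow(x$shared_at_variant),
              nrow(x$unchanged)))
  invisible(x)
}

#' @export
tidy.allele_diff_report <- function(x, ...) {
  bind_rows(
    mutate(x$lost, change = "lost"),
    mutate(x$gained, change = "gained"),
    mutate(x$shared_at_variant, change = "shared_at_variant"),
    mutate(x$unchanged, change = "unchanged")
  )
}

#' Packaged default motif set
#'
#' IUPAC consensus motifs for the NFkB kB site (7-bp core and 10-bp
#' consensus family) and Sp1 (GC-box and GT-box variants), read from the
#' packaged editable JSON fixture, plus a kB position weight matrix built
#' from the packaged set of documented kB binding sites (pseudocount 0.5,
#' uniform background).
#'
#' @param include_pwm Also build and append the kB PWM.
#' @param pwm_threshold Log-odds threshold of the kB PWM.
#' @return Named list of `motif` objects.
#' @export
default_motifs <- function(include_pwm = FALSE, pwm_threshold = 0) {
  motifs <- read_motifs(system.file("extdata", "motifs_default.json",
                                    package = "asekit"))
  if (include_pwm) {
    motifs$kB_pwm <- kb_pwm(threshold = pwm_threshold)
  }
  motifs
}

#' @rdname default_motifs
#' @param threshold Log-odds threshold.
#' @export
kb_pwm <- function(threshold = 0) {
  sites <- kb_site_fixtures()
  pwm_from_sites("kB_pwm", sites$site, pseudocount = 0.5,
                 threshold = threshold, tf = "NFkB")
}

#' @rdname default_motifs
#' @export
kb_site_fixtures <- function() {
  readr::read_tsv(system.file("extdata", "kb_sites.txt", package = "asekit"),
                  comment = "#", col_names = c("site", "source_gene"),
                  col_types = "cc")
}

#' Read motifs from a JSON file
#'
#' Each entry needs `motif_id`, `kind` (`iupac` or `pwm`) and either
#' `pattern` or `matrix` (+ optional `background`, `threshold`).
#'
#' @param path JSON file path.
#' @return Named list of `motif` objects.
#' @export
read_motifs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  motifs <- lapply(raw, function(m) {
    if (m$kind == "iupac") {
      iupac_motif(m$motif_id, m$pattern, tf = m$tf %||% NA_character_)
    } else {
      mat <- do.call(cbind, lapply(m$matrix, unlist))
      pwm_motif(m$motif_id, mat,
                background = unlist(m$background %||% rep(0.25, 4)),
                threshold = m$threshold %||% 0,
                tf = m$tf %||% NA_character_)
    }
  })
  setNames(motifs, map_chr(motifs, "motif_id"))
}

#' The published 22-mer promoter probe around SNP55
#'
#' `GACGGTGTCC[C/T]TTCTATCGCTG`: the double-stranded 22-mer representing
#' the MDM2-P2 promoter around SNP55; the variant base sits at 0-based
#' position 10.
#'
#' @param allele `"C"`, `"T"` or `"N"`.
#' @return The 22-base sequence string.
#' @export
mdm2_snp55_probe <- function(allele = c("C", "T", "N")) {
  allele <- match.arg(allele)
  paste0("GACGGTGTCC", allele, "TTCTATCGCTG")
}

#' 0-based position of SNP55 within [mdm2_snp55_probe()]
#' @export
mdm2_snp55_probe_pos <- function() 10L

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file.
#' @return Tibble: `seq_id`, `sequence` (uppercase).
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(seq_id = names(x), sequence = toupper(as.character(x)))
}

#' Write motif hits as a 1-based TSV report
#'
#' @param hits Hit tibble (0-based `start` as produced by the scanners).
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  hits |>
    mutate(start_1based = .data$start + 1L,
           end = .data$start + nchar(.data$site)) |>
    select("motif_id", "seq_id", "start_1based", "end", "strand", "site",
           "score") |>
    readr::write_tsv(path)
  invisible(path)
}
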