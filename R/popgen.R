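#' Tabulate genotype counts and percentages at a biallelic locus
#'
#' @param genotypes Character vector of genotypes over the locus's two
#'   alleles, `"C/T"` style (order within a genotype is ignored);
#'   single-base homozygote shorthand (`"C"`) is accepted.
#' @param locus One-row locus tibble from [locus_definition()].
#' @param sample_ids Optional ids used in error messages.
#' @return Tibble with one row per genotype class (`a1/a1`, `a1/a2`,
#'   `a2/a2`): `genotype`, `count`, `pct` (percent, one decimal, half-up;
#'   NA when the input is empty).
#' @examples
#' snp55 <- locus_definition("SNP55", c("C", "T"))
#' genotype_frequency_table(c(rep("C/C", 17), rep("C/T", 24), rep("T/T", 4)),
#'                          snp55)
#' @export
genotype_frequency_table <- function(genotypes, locus, sample_ids = NULL) {
  a1 <- locus$allele1
  a2 <- locus$allele2
  ids <- sample_ids %||% paste0("sample ", seq_along(genotypes))
  norm <- normalise_genotypes(genotypes, locus, ids)
  classes <- c(paste(a1, a1, sep = "/"), paste(a1, a2, sep = "/"),
               paste(a2, a2, sep = "/"))
  counts <- as.integer(table(factor(norm, levels = classes)))
  n <- sum(counts)
  tibble(
    locus_id = locus$locus_id, genotype = classes, count = counts,
    pct = if (n == 0) NA_real_ else round_half_up(100 * counts / n, 1)
  )
}

normalise_genotypes <- function(genotypes, locus, ids) {
  a1 <- locus$allele1
  a2 <- locus$allele2
  parts <- strsplit(toupper(genotypes), "/", fixed = TRUE)
  map_chr(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) == 1) p <- c(p, p)  # homozygote shorthand
    if (length(p) != 2 || !all(p %in% c(a1, a2))) {
      abort(paste0("invalid genotype '", genotypes[i], "' at ",
                   locus$locus_id, " for ", ids[i]))
    }
    paste(sort(factor(p, levels = c(a1, a2))) |> as.integer() |>
            (\(k) c(a1, a2)[k])(), collapse = "/")
  })
}

#' Allele counts from genotype counts
#'
#' @param gc Genotype table from [genotype_frequency_table()], or an
#'   integer vector `c(n11, n12, n22)`.
#' @param locus Locus tibble (needed when `gc` is a bare vector).
#' @return Tibble: `allele`, `count` (`2*n11 + n12` and `2*n22 + n12`),
#'   `pct` (one decimal, half-up).
#' @examples
#' allele_counts_from_genotypes(c(17, 24, 4),
#'                              locus_definition("SNP55", c("C", "T")))
#' @export
allele_counts_from_genotypes <- function(gc, locus = NULL) {
  if (is.data.frame(gc)) {
    counts <- gc$count
    a <- strsplit(gc$genotype[c(1, 3)], "/", fixed = TRUE)
    alleles <- c(a[[1]][1], a[[2]][1])
    locus_id <- gc$locus_id[1]
  } else {
    stopifnot(!is.null(locus))
    counts <- gc
    alleles <- c(locus$allele1, locus$allele2)
    locus_id <- locus$locus_id
  }
  stopifnot(length(counts) == 3, all(counts >= 0))
  ac <- c(2 * counts[1] + counts[2], 2 * counts[3] + counts[2])
  tot <- sum(ac)
  tibble(locus_id = locus_id, allele = alleles, count = as.integer(ac),
         pct = if (tot == 0) NA_real_ else round_half_up(100 * ac / tot, 1))
}

#' Fisher's exact test for 2 x C contingency tables by enumeration
#'
#' Two-sided p-value under the point-probability convention: all tables
#' with the observed margins are enumerated and the (multivariate)
#' hypergeometric probabilities of those no more probable than the
#' observed table (within a relative tie tolerance of 1e-7) are summed.
#'
#' @param x Integer matrix with 2 rows (2 or more columns) of non-negative
#'   counts.
#' @return Tibble: `method`, `p_value`.
#' @examples
#' fisher_exact(matrix(c(58, 32, 56, 34), nrow = 2, byrow = TRUE))
#' @export
fisher_exact <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != 2 || ncol(x) < 2) abort("fisher_exact expects a 2 x C table")
  if (any(x < 0) || any(x != round(x))) abort("counts must be non-negative integers")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    warn("table has a zero margin; no association is testable")
    return(tibble(method = "fisher_exact", p_value = 1))
  }
  n <- sum(x)
  # log-probability of a 2xC table given margins (multivariate hypergeom.)
  logp_row <- function(row1) {
    sum(lchoose(cs, row1)) - lchoose(n, rs[1])
  }
  obs <- logp_row(x[1, ])
  # enumerate all first rows summing to rs[1] with 0 <= x1j <= cs[j]
  total <- 0
  rec <- function(j, remaining, acc) {
    if (j == length(cs)) {
      if (remaining <= cs[j]) {
        lp <- acc + lchoose(cs[j], remaining) - lchoose(n, rs[1])
        if (lp <= obs + log(1 + 1e-7)) total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (v in 0:min(remaining, cs[j])) {
      rec(j + 1, remaining - v, acc + lchoose(cs[j], v))
    }
  }
  rec(1, rs[1], 0)
  tibble(method = "fisher_exact", p_value = min(1, total))
}

#' Parse an inline contingency table string
#'
#' `"58,32;56,34"` becomes a 2 x 2 matrix (rows separated by `;`).
#'
#' @param s Table string.
#' @return Integer matrix.
#' @export
parse_table_string <- function(s) {
  rows <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(rows, ",", fixed = TRUE),
                             \(r) suppressWarnings(as.integer(trimws(r)))))
  if (anyNA(m)) abort("could not parse table string")
  m
}

#' Exact conditional test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, every compatible heterozygote
#' count is enumerated; the p-value sums the probabilities of
#' configurations no more probable than the observed one (relative tie
#' tolerance 1e-7).  A chi-square goodness-of-fit variant is available for
#' comparison.
#'
#' @param counts Integer vector `c(n11, n12, n22)` of genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return Tibble: `method`, `statistic` (chisq only), `p_value`, `note`.
#' @examples
#' hwe_exact(c(17, 24, 4))
#' @export
hwe_exact <- function(counts, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3, all(counts >= 0), all(counts == round(counts)))
  n11 <- counts[1]; n12 <- counts[2]; n22 <- counts[3]
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  n2 <- 2 * n22 + n12
  if (n1 == 0 || n2 == 0) {
    return(tibble(method = paste0("hwe_", method), statistic = NA_real_,
                  p_value = 1, note = "monomorphic locus"))
  }
  if (method == "chisq") {
    p <- n1 / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expected)^2 / expected)
    return(tibble(method = "hwe_chisq", statistic = stat,
                  p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  note = NA_character_))
  }
  hets <- seq(n1 %% 2, min(n1, n2), by = 2)
  logp <- vapply(hets, function(h) {
    na <- (n1 - h) / 2
    nb <- (n2 - h) / 2
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) + lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == n12]
  tibble(method = "hwe_exact", statistic = NA_real_,
         p_value = sum(prob[prob <= obs * (1 + 1e-7)]), note = NA_character_)
}

#' Haplotype frequencies by direct gamete counting
#'
#' @param haplotypes Character vector of phased haplotype labels (one entry
#'   per chromosome), `"C-T"` style.
#' @param loci Locus panel defining the label alphabet.
#' @return A `hap_table` over the observed (and any zero-count canonical)
#'   haplotypes, frequencies summing to 1.
#' @export
haplotype_frequencies_direct <- function(haplotypes, loci) {
  if (length(haplotypes) == 0) abort("empty haplotype list")
  combos <- expand.grid(lapply(seq_len(nrow(loci)),
                               \(j) c(loci$allele1[j], loci$allele2[j])),
                        stringsAsFactors = FALSE)
  labels <- apply(combos, 1, paste, collapse = "-")
  counts <- table(factor(haplotypes, levels = labels))
  if (sum(counts) != length(haplotypes)) {
    bad <- setdiff(unique(haplotypes), labels)
    abort(paste0("haplotype '", bad[1], "' not expressible over the panel"))
  }
  hap_table(loci, labels, as.numeric(counts) / length(haplotypes))
}

#' Aggregate per-sample two-locus genotypes into a 3 x 3 joint table
#'
#' @param genoA,genoB Genotype vectors (normalised or shorthand) at the two
#'   loci, same length.
#' @param lociAB Two-row locus panel.
#' @return 3 x 3 integer matrix; rows index locus A genotypes
#'   (`a1a1`, `a1a2`, `a2a2`), columns locus B likewise.
#' @export
two_locus_genotype_counts <- function(genoA, genoB, lociAB) {
  stopifnot(nrow(lociAB) == 2, length(genoA) == length(genoB))
  code <- function(geno, locus) {
    norm <- normalise_genotypes(geno, locus, paste0("sample ", seq_along(geno)))
    a1 <- locus$allele1
    hom1 <- paste(a1, a1, sep = "/")
    het <- paste(a1, locus$allele2, sep = "/")
    ifelse(norm == hom1, 1L, ifelse(norm == het, 2L, 3L))
  }
  ia <- code(genoA, lociAB[1, ])
  ib <- code(genoB, lociAB[2, ])
  m <- matrix(0L, 3, 3,
              dimnames = list(A = c("11", "12", "22"), B = c("11", "12", "22")))
  for (k in seq_along(ia)) m[ia[k], ib[k]] <- m[ia[k], ib[k]] + 1L
  m
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies from unphased joint genotype
#' counts of two biallelic loci.  Only the double heterozygote class is
#' phase-ambiguous; the E step splits it between the cis (a1b1/a2b2) and
#' trans (a1b2/a2b1) configurations in proportion to their current
#' expected frequencies.  Started from linkage equilibrium; the
#' log-likelihood is non-decreasing and the trace is returned.
#'
#' @param joint 3 x 3 joint genotype count matrix (see
#'   [two_locus_genotype_counts()]).
#' @param loci Two-row locus panel used to label the haplotypes.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap.
#' @return List of class `hap_em`: `frequencies` (a `hap_table`),
#'   `loglik_trace`, `n_iter`, `converged`.
#' @export
haplotype_frequencies_em <- function(joint, loci = mdm2_loci()[1:2, ],
                                     tol = 1e-10, max_iter = 1000) {
  joint <- as.matrix(joint)
  stopifnot(all(dim(joint) == c(3, 3)), all(joint >= 0))
  if (tol <= 0) abort("tol must be positive")
  n <- sum(joint)
  if (n == 0) abort("all-zero genotype table")
  # haplotype order: 11, 12, 21, 22 (locusA allele - locusB allele)
  pA <- (2 * sum(joint[1, ]) + sum(joint[2, ])) / (2 * n)
  pB <- (2 * sum(joint[, 1]) + sum(joint[, 2])) / (2 * n)
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  f <- pmax(f, 1e-12)
  f <- f / sum(f)
  ll <- function(f) em_loglik(joint, f)
  trace <- ll(f)
  converged <- FALSE
  # fixed counts of each haplotype contributed by unambiguous classes
  base <- c(
    2 * joint[1, 1] + joint[1, 2] + joint[2, 1],          # 11
    2 * joint[1, 3] + joint[1, 2] + joint[2, 3],          # 12
    2 * joint[3, 1] + joint[2, 1] + joint[3, 2],          # 21
    2 * joint[3, 3] + joint[2, 3] + joint[3, 2]           # 22
  )
  ndh <- joint[2, 2]
  for (it in seq_len(max_iter)) {
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    expected <- base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- expected / (2 * n)
    new_ll <- ll(f_new)
    trace <- c(trace, new_ll)
    delta <- new_ll - trace[length(trace) - 1]
    f <- f_new
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  labels <- c(paste0(loci$allele1[1], "-", loci$allele1[2]),
              paste0(loci$allele1[1], "-", loci$allele2[2]),
              paste0(loci$allele2[1], "-", loci$allele1[2]),
              paste0(loci$allele2[1], "-", loci$allele2[2]))
  structure(list(frequencies = hap_table(loci, labels, f),
                 loglik_trace = trace, n_iter = length(trace) - 1,
                 converged = converged),
            class = "hap_em")
}

em_loglik <- function(joint, f) {
  # class probabilities under random union of gametes
  p <- matrix(0, 3, 3)
  p[1, 1] <- f[1]^2;        p[1, 2] <- 2 * f[1] * f[2]; p[1, 3] <- f[2]^2
  p[2, 1] <- 2 * f[1] * f[3]
  p[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  p[2, 3] <- 2 * f[2] * f[4]
  p[3, 1] <- f[3]^2;        p[3, 2] <- 2 * f[3] * f[4]; p[3, 3] <- f[4]^2
  keep <- joint > 0
  sum(joint[keep] * log(pmax(p[keep], 1e-300)))
}

#' @export
print.hap_em <- function(x, ...) {
  cat(sprintf("Two-locus EM: %d iterations, logLik %.6f%s\n", x$n_iter,
              x$loglik_trace[length(x$loglik_trace)],
              if (x$converged) "" else " (not converged)"))
  print(x$frequencies)
  invisible(x)
}

#' @export
tidy.hap_em <- function(x, ...) as_tibble(x$frequencies)

#' @export
glance.hap_em <- function(x, ...) {
  tibble(logLik = x$loglik_trace[length(x$loglik_trace)],
         n_iter = x$n_iter, converged = x$converged)
}

#' Linkage disequilibrium statistics from two-locus haplotype frequencies
#'
#' `D = f11 - p1 p2`; `D'` normalises `|D|` by its maximum given the allele
#' frequencies; `r^2 = D^2 / (p1 q1 p2 q2)`.  Input frequencies are
#' renormalised to sum exactly to 1 (so published rounded frequencies can
#' be used as printed).
#'
#' @param h `hap_table` over two biallelic loci (4 entries), or a numeric
#'   vector of 4 frequencies ordered a1b1, a1b2, a2b1, a2b2.
#' @return Tibble: `p1`, `p2`, `D`, `D_prime`, `r_squared` (the latter two
#'   NA with a warning when a locus is monomorphic).
#' @examples
#' ld_from_haplotypes(c(0.178, 0.467, 0.356, 0.000))
#' @export
ld_from_haplotypes <- function(h) {
  if (inherits(h, "hap_table")) {
    loci <- attr(h, "loci")
    stopifnot(nrow(loci) == 2)
    order_labels <- c(paste0(loci$allele1[1], "-", loci$allele1[2]),
                      paste0(loci$allele1[1], "-", loci$allele2[2]),
                      paste0(loci$allele2[1], "-", loci$allele1[2]),
                      paste0(loci$allele2[1], "-", loci$allele2[2]))
    f <- setNames(rep(0, 4), order_labels)
    f[h$haplotype] <- h$freq
  } else {
    stopifnot(length(h) == 4, all(h >= 0))
    f <- as.numeric(h)
  }
  f <- f / sum(f)
  p1 <- f[1] + f[2]
  p2 <- f[1] + f[3]
  q1 <- 1 - p1
  q2 <- 1 - p2
  D <- f[1] - p1 * p2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    warn("monomorphic locus: D' and r^2 undefined")
    return(tibble(p1 = p1, p2 = p2, D = D, D_prime = NA_real_,
                  r_squared = NA_real_))
  }
  dmax <- if (D > 0) min(p1 * q2, q1 * p2) else min(p1 * p2, q1 * q2)
  tibble(p1 = unname(p1), p2 = unname(p2), D = unname(D),
         D_prime = unname(if (D == 0) 0 else abs(D) / dmax),
         r_squared = unname(D^2 / (p1 * q1 * p2 * q2)))
}

#' Solve two-locus haplotype frequencies from allele counts and one absent
#' haplotype
#'
#' With two biallelic loci the four haplotype frequencies have three free
#' parameters; the two allele frequencies fix two of them, and declaring
#' one haplotype absent closes the system:
#' `f(a2b2) = 0` gives `f(a2b1) = q1`, `f(a1b1) = p2 - q1`,
#' `f(a1b2) = 1 - p2` (and analogously for the other corners).
#'
#' @param countsA Integer vector `c(allele1, allele2)` at locus A.
#' @param countsB Likewise at locus B.
#' @param absent Which haplotype is absent: `"a1b1"`, `"a1b2"`, `"a2b1"`
#'   or `"a2b2"`.
#' @param loci Optional two-row locus panel for labelling.
#' @return Tibble: `haplotype`, `freq` (order a1b1, a1b2, a2b1, a2b2).
#' @examples
#' # published cancer-free allele counts, 55T-309G declared absent
#' solve_two_locus_haplotypes(c(58, 32), c(48, 42), absent = "a2b2")
#' @export
solve_two_locus_haplotypes <- function(countsA, countsB,
                                       absent = c("a2b2", "a2b1", "a1b2", "a1b1"),
                                       loci = NULL) {
  absent <- match.arg(absent)
  stopifnot(length(countsA) == 2, length(countsB) == 2)
  if (sum(countsA) != sum(countsB)) {
    abort("allele counts at the two loci must cover the same chromosomes")
  }
  p1 <- countsA[1] / sum(countsA)
  p2 <- countsB[1] / sum(countsB)
  q1 <- 1 - p1
  q2 <- 1 - p2
  f <- switch(absent,
    a2b2 = c(p2 - q1, 1 - p2, q1, 0),
    a2b1 = c(p2, p1 - p2, 0, q1),      # valid when p1 >= p2
    a1b2 = c(p1, 0, p2 - p1, q2),
    a1b1 = c(0, p1, p2, 1 - p1 - p2)
  )
  if (any(f < -1e-12)) {
    abort(paste0("allele counts are incompatible with haplotype '", absent,
                 "' being absent"))
  }
  f <- pmax(f, 0)
  labels <- if (!is.null(loci)) {
    c(paste0(loci$allele1[1], "-", loci$allele1[2]),
      paste0(loci$allele1[1], "-", loci$allele2[2]),
      paste0(loci$allele2[1], "-", loci$allele1[2]),
      paste0(loci$allele2[1], "-", loci$allele2[2]))
  } else {
    c("a1b1", "a1b2", "a2b1", "a2b2")
  }
  tibble(haplotype = labels, freq = f)
}
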