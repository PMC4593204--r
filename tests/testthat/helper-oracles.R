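# Independent brute-force oracles used to cross-check the package's exact
# tests and scanners.  They deliberately take the dumbest correct route.

# Two-sided Fisher p for a 2 x C table: enumerate EVERY candidate first row
# over a full grid (no structural pruning) and sum point probabilities no
# larger than the observed one.
oracle_fisher_2xc <- function(x) {
  rs <- rowSums(x)
  cs <- colSums(x)
  n <- sum(x)
  grid <- expand.grid(lapply(cs, function(cj) 0:cj))
  grid <- grid[rowSums(grid) == rs[1], , drop = FALSE]
  logp <- apply(grid, 1, function(r) sum(lchoose(cs, r)) - lchoose(n, rs[1]))
  obs <- sum(lchoose(cs, x[1, ])) - lchoose(n, rs[1])
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

# Exact HWE p by enumerating every genotype configuration (n11, n12, n22)
# with the observed allele counts, probabilities computed from first
# principles via the permanental count of distinguishable orderings.
oracle_hwe <- function(counts) {
  n11 <- counts[1]; n12 <- counts[2]; n22 <- counts[3]
  n <- sum(counts)
  n1 <- 2 * n11 + n12
  configs <- list()
  for (h in 0:min(n1, 2 * n - n1)) {
    a <- (n1 - h) / 2
    b <- (2 * n - n1 - h) / 2
    if (a == floor(a) && b == floor(b) && a >= 0 && b >= 0) {
      configs[[length(configs) + 1]] <- c(a, h, b)
    }
  }
  logw <- vapply(configs, function(cf) {
    lfactorial(n) - sum(lfactorial(cf)) + cf[2] * log(2)
  }, numeric(1))
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  obs <- which(vapply(configs, function(cf) all(cf == counts), logical(1)))
  sum(p[p <= p[obs] * (1 + 1e-7)])
}

# Window-by-window IUPAC matcher on explicit base sets, both strands.
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac_scan <- function(sequence, pattern) {
  match_at <- function(s, p) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(p, "")[[1]]
    all(mapply(function(a, b) {
      length(intersect(oracle_iupac_sets[[a]], oracle_iupac_sets[[b]])) > 0
    }, sc, pc))
  }
  L <- nchar(pattern)
  n <- nchar(sequence)
  hits <- list()
  if (L <= n) {
    for (i in 0:(n - L)) {
      w <- substring(sequence, i + 1, i + L)
      if (match_at(w, pattern)) {
        hits[[length(hits) + 1]] <- data.frame(start = i, strand = "+",
                                               site = w)
      }
      wrc <- oracle_revcomp(w)
      if (match_at(wrc, pattern)) {
        hits[[length(hits) + 1]] <- data.frame(start = i, strand = "-",
                                               site = wrc)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      site = character()))
  }
  do.call(rbind, hits)
}

# Dense grid search over the haplotype 3-simplex for the two-locus
# likelihood, used to corroborate the EM maximiser.
oracle_grid_search <- function(joint, step = 0.001) {
  best <- NULL
  best_ll <- -Inf
  f1s <- seq(0, 1, by = step)
  # exploit that given f1 (cis a1b1), the margins fix f2, f3 up to the
  # double-het split; search f1 only, margins give the rest
  n <- sum(joint)
  pA <- (2 * sum(joint[1, ]) + sum(joint[2, ])) / (2 * n)
  pB <- (2 * sum(joint[, 1]) + sum(joint[, 2])) / (2 * n)
  for (f1 in f1s) {
    f2 <- pA - f1
    f3 <- pB - f1
    f4 <- 1 - f1 - f2 - f3
    if (min(f1, f2, f3, f4) < -1e-12) next
    f <- pmax(c(f1, f2, f3, f4), 1e-12)
    ll <- asekit:::em_loglik(joint, f)
    if (ll > best_ll) {
      best_ll <- ll
      best <- f
    }
  }
  list(f = best, loglik = best_ll)
}

random_iupac_pattern <- function(len) {
  paste(sample(names(oracle_iupac_sets), len, replace = TRUE,
               prob = c(rep(4, 4), rep(2, 6), rep(1, 4), 3)),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
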