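# Small in-code fixture builders shared across the suite.

# Genotype matrix from a plain integer matrix (sites x samples).
make_gm <- function(geno, pos = NULL, chrom = "chr1", ref = "A", alt = "T",
                    ...) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n)
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = ref, alt = alt, ...)
  geno_matrix(sites, geno, paste0("s", seq_len(ncol(geno))))
}

# Labels for a matrix whose columns are grouped by population counts.
make_labels <- function(n_p1 = 0, n_p2 = 0, n_hyb = 0, n_out = 0,
                        samples = NULL) {
  pops <- c(rep("P1", n_p1), rep("P2", n_p2), rep("HYB", n_hyb),
            rep("OUT", n_out))
  if (is.null(samples)) samples <- paste0("s", seq_along(pops))
  tibble::tibble(sample = samples, population = pops, source = "genome")
}

# Random genotype matrix for property tests.
random_gm <- function(n_sites, n_samples, miss_rate = 0.05) {
  p <- stats::runif(n_sites, 0.05, 0.95)
  geno <- matrix(stats::rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
                 nrow = n_sites)
  if (miss_rate > 0) {
    geno[stats::runif(length(geno)) < miss_rate] <- NA_integer_
  }
  make_gm(geno)
}

# Independent oracle for window diversity: per-site mean pairwise haplotype
# difference from allele counts, summed and divided by window length.
pi_pairwise_oracle <- function(gm, cols, L) {
  g <- gm$geno[, cols, drop = FALSE]
  per_site <- apply(g, 1, function(row) {
    row <- row[!is.na(row)]
    n <- 2 * length(row)
    if (n < 2) return(0)
    a <- sum(row)
    a * (n - a) / choose(n, 2)
  })
  sum(per_site) / L
}

# Direct evaluation of the Hudson estimator for a window (oracle).
fst_hand_oracle <- function(gm, cols_a, cols_b) {
  stats_for <- function(cols) {
    g <- gm$geno[, cols, drop = FALSE]
    n <- 2 * rowSums(!is.na(g))
    p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA)
    list(p = p, n = n)
  }
  a <- stats_for(cols_a); b <- stats_for(cols_b)
  num <- den <- 0
  for (i in seq_len(nrow(gm$sites))) {
    if (is.na(a$p[i]) || is.na(b$p[i]) || a$n[i] < 2 || b$n[i] < 2) next
    num <- num + (a$p[i] - b$p[i])^2 -
      a$p[i] * (1 - a$p[i]) / (a$n[i] - 1) -
      b$p[i] * (1 - b$p[i]) / (b$n[i] - 1)
    den <- den + a$p[i] * (1 - b$p[i]) + b$p[i] * (1 - a$p[i])
  }
  if (den > 0) num / den else NA_real_
}
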