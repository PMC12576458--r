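#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Pearson chi-square (1 df, no continuity correction) of observed genotype
#' counts against the Hardy-Weinberg expectation at the sample allele
#' frequency. Monomorphic sites return p = 1. Vectorised.
#'
#' @param n_aa,n_ab,n_bb Counts of hom-ref, het, hom-alt genotypes.
#' @return A tibble with columns `chi2`, `p`.
#' @export
hwe_chi2 <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative counts", call. = FALSE)
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) stop("each site needs at least one genotype", call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e_aa <- n * p^2; e_ab <- 2 * n * p * q; e_bb <- n * q^2
  mono <- p == 0 | p == 1
  chi2 <- ifelse(mono, 0,
                 (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                   (n_bb - e_bb)^2 / e_bb)
  tibble::tibble(chi2 = chi2,
                 p = ifelse(mono, 1, stats::pchisq(chi2, df = 1,
                                                   lower.tail = FALSE)))
}

#' Pairwise linkage disequilibrium (r-squared) profile
#'
#' Composite (phase-free) LD from unphased genotypes: r-squared is the
#' squared Pearson correlation of genotype-dosage vectors over jointly
#' non-missing samples. Sites are pre-filtered Haploview-style — minor
#' allele frequency, genotyping rate and a Hardy-Weinberg cutoff — and only
#' pairs within `max_distance` are evaluated.
#'
#' @param gm A [geno_matrix()].
#' @param chrom Chromosome to profile (required when `gm` spans several).
#' @param start,end Optional 1-based inclusive bounds restricting the sites.
#' @param samples Optional sample subset (names or indices).
#' @param max_distance Maximum pair distance in bp (default 50000).
#' @param min_maf Minimum minor-allele frequency (inclusive, default 0.05).
#' @param hwe_cutoff Minimum Hardy-Weinberg p-value (default 0.001; sites
#'   with p below the cutoff are excluded).
#' @param min_geno Minimum genotyping rate (inclusive, default 0.6).
#' @param bin_width Distance-bin width in bp for the binned means
#'   (default 5000).
#' @return A list of class `ld_profile`: `pairs` (tibble `dist`, `r2`),
#'   `bins` (tibble `bin`, `mid`, `mean_r2`, `n_pairs`), `n_sites`, and the
#'   applied `filters`.
#' @export
ld_r2_profile <- function(gm, chrom = NULL, start = NULL, end = NULL,
                          samples = NULL, max_distance = 50000,
                          min_maf = 0.05, hwe_cutoff = 0.001, min_geno = 0.6,
                          bin_width = 5000) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!is.null(samples)) gm <- gm_subset(gm, samples = samples)
  keep <- rep(TRUE, nrow(gm$sites))
  if (!is.null(chrom)) keep <- keep & gm$sites$chrom == chrom
  if (!is.null(start)) keep <- keep & gm$sites$pos >= start
  if (!is.null(end)) keep <- keep & gm$sites$pos <= end
  if (is.null(chrom) && length(unique(gm$sites$chrom[keep])) > 1) {
    stop("profile spans several chromosomes; supply `chrom`", call. = FALSE)
  }
  gm <- gm_subset(gm, sites = which(keep))
  g <- gm$geno
  n_samp <- length(gm$samples)
  n_aa <- rowSums(g == 0L, na.rm = TRUE)
  n_ab <- rowSums(g == 1L, na.rm = TRUE)
  n_bb <- rowSums(g == 2L, na.rm = TRUE)
  n_called <- n_aa + n_ab + n_bb
  ok <- n_called >= 1
  p <- ifelse(ok, (2 * n_bb + n_ab) / (2 * pmax(n_called, 1)), NA_real_)
  maf <- pmin(p, 1 - p)
  geno_rate <- n_called / n_samp
  hwe_p <- rep(1, nrow(g))
  hwe_p[ok] <- hwe_chi2(n_aa[ok], n_ab[ok], n_bb[ok])$p
  pass <- ok & maf >= min_maf & geno_rate >= min_geno & hwe_p >= hwe_cutoff
  filters <- list(max_distance = max_distance, min_maf = min_maf,
                  hwe_cutoff = hwe_cutoff, min_geno = min_geno)
  empty <- function() {
    warning("fewer than 2 sites survive the LD filters", call. = FALSE)
    structure(list(pairs = tibble::tibble(dist = numeric(), r2 = numeric()),
                   bins = tibble::tibble(bin = integer(), mid = numeric(),
                                         mean_r2 = numeric(),
                                         n_pairs = integer()),
                   n_sites = sum(pass), filters = filters),
              class = "ld_profile")
  }
  if (sum(pass) < 2) return(empty())
  idx <- which(pass)
  pos <- gm$sites$pos[idx]
  dos <- t(g[idx, , drop = FALSE])  # samples x sites
  cc <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))
  pair <- which(upper.tri(cc), arr.ind = TRUE)
  dist <- pos[pair[, 2]] - pos[pair[, 1]]
  in_range <- dist <= max_distance & !is.na(cc[pair])
  pairs <- tibble::tibble(dist = dist[in_range],
                          r2 = cc[pair][in_range]^2)
  if (nrow(pairs) == 0) return(empty())
  pairs$bin <- pmin(floor(pairs$dist / bin_width),
                    floor((max_distance - 1) / bin_width))
  bins <- pairs |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(mid = (dplyr::first(.data$bin) + 0.5) * bin_width,
                     mean_r2 = mean(.data$r2),
                     n_pairs = dplyr::n(), .groups = "drop")
  structure(list(pairs = pairs[, c("dist", "r2", "bin")], bins = bins,
                 n_sites = length(idx), filters = filters),
            class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("<ld_profile> %d sites, %d pairs, mean r2 = %s\n",
              x$n_sites, nrow(x$pairs),
              if (nrow(x$pairs)) sprintf("%.3f", mean(x$pairs$r2)) else "NA"))
  invisible(x)
}

#' @export
autoplot.ld_profile <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mid / 1000, y = .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
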