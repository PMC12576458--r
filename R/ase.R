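#' Find parental diagnostic SNPs
#'
#' A diagnostic site is one at which the two parental populations are fixed
#' for opposite homozygous genotypes: the P1 modal genotype and the P2 modal
#' genotype are opposite homozygotes and each population's fraction of
#' non-missing samples carrying that homozygote exceeds `consistency`
#' (criteria: fixed homozygous discordance, > 80% within-population
#' genotype consistency). Sites where either parental population has no
#' non-missing call are skipped.
#'
#' @param gm A [geno_matrix()] (SNPs and InDels; only SNP sites qualify).
#' @param labels Label tibble.
#' @param consistency Within-population consistency threshold (strict;
#'   default 0.8).
#' @return A tibble with one row per evaluated site: `site` (row index into
#'   `gm$sites`), `chrom`, `pos`, `gene_id`, `region`, `p1_allele`,
#'   `p2_allele` (`"ref"`/`"alt"`), `p1_consistency`, `p2_consistency` and
#'   `qualifies`.
#' @export
find_diagnostic_sites <- function(gm, labels, consistency = 0.8) {
  p1_cols <- pop_columns(gm, labels, "P1")
  p2_cols <- pop_columns(gm, labels, "P2")
  if (length(p1_cols) < 2 || length(p2_cols) < 2) {
    stop("need at least 2 samples per parental population", call. = FALSE)
  }
  pop_hom <- function(cols) {
    g <- gm$geno[, cols, drop = FALSE]
    n <- rowSums(!is.na(g))
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    # modal genotype among {0,1,2}; consistency = fraction of non-missing
    # samples homozygous for the population's modal homozygote
    n1 <- n - n0 - n2
    modal <- max.col(cbind(n0, n1, n2), ties.method = "first") - 1L
    list(n = n, modal = modal,
         hom_frac0 = ifelse(n > 0, n0 / n, NA_real_),
         hom_frac2 = ifelse(n > 0, n2 / n, NA_real_))
  }
  a <- pop_hom(p1_cols)
  b <- pop_hom(p2_cols)
  s <- gm$sites
  discordant <- (a$modal == 0L & b$modal == 2L) |
    (a$modal == 2L & b$modal == 0L)
  p1_cons <- ifelse(a$modal == 0L, a$hom_frac0,
                    ifelse(a$modal == 2L, a$hom_frac2, NA_real_))
  p2_cons <- ifelse(b$modal == 0L, b$hom_frac0,
                    ifelse(b$modal == 2L, b$hom_frac2, NA_real_))
  usable <- a$n > 0 & b$n > 0
  qualifies <- usable & s$site_class == "SNP" & discordant &
    !is.na(p1_cons) & !is.na(p2_cons) &
    p1_cons > consistency & p2_cons > consistency
  tibble::tibble(
    site = seq_len(nrow(s)),
    chrom = s$chrom, pos = s$pos,
    gene_id = s$gene_id, region = s$region,
    p1_allele = dplyr::case_when(a$modal == 0L ~ "ref",
                                 a$modal == 2L ~ "alt",
                                 TRUE ~ NA_character_),
    p2_allele = dplyr::case_when(b$modal == 0L ~ "ref",
                                 b$modal == 2L ~ "alt",
                                 TRUE ~ NA_character_),
    p1_consistency = p1_cons,
    p2_consistency = p2_cons,
    qualifies = qualifies
  )[usable, ]
}

#' Genotype hybrids at diagnostic sites
#'
#' Counts heterozygous hybrid samples at each diagnostic site and keeps
#' sites with at least `min_het` heterozygous hybrids (the "at least three
#' heterozygous hybrid samples" rule).
#'
#' @param diag Diagnostic-site tibble from [find_diagnostic_sites()].
#' @param gm The [geno_matrix()] used to find the sites.
#' @param labels Label tibble; must contain `HYB` samples.
#' @param min_het Minimum heterozygous hybrid count (default 3).
#' @return `diag` with columns `n_hyb_het`, `n_hyb_called` appended and
#'   `qualifies` updated (`qualifies` from the parental criteria AND the
#'   hybrid heterozygosity criterion).
#' @export
genotype_hybrids <- function(diag, gm, labels, min_het = 3) {
  hyb_cols <- pop_columns(gm, labels, "HYB")
  if (length(hyb_cols) == 0) stop("no hybrid samples", call. = FALSE)
  g <- gm$geno[diag$site, hyb_cols, drop = FALSE]
  diag$n_hyb_het <- rowSums(g == 1L, na.rm = TRUE)
  diag$n_hyb_called <- rowSums(!is.na(g))
  diag$qualifies <- diag$qualifies & diag$n_hyb_het >= min_het
  diag
}

#' Aggregate diagnostic sites into gene-level diagnoses
#'
#' A gene is usable for allele-specific genotyping when it carries at least
#' one qualifying diagnostic site, at least one of those sites is exonic,
#' and the per-site hybrid allelic imbalances of its qualifying sites are
#' not in opposing directions (no mix of strictly positive and strictly
#' negative deviations of the P1-read fraction from 0.5; a fraction of
#' exactly 0.5 is concordant with anything).
#'
#' @param diag Diagnostic tibble from [genotype_hybrids()] (must carry
#'   `gene_id` and `region`).
#' @param site_ratios Optional tibble (`site`, `p1_fraction`) of per-site
#'   hybrid P1-read fractions; sites without a ratio are treated as 0.5.
#' @return A tibble with one row per gene carrying any diagnostic site:
#'   `gene_id`, `n_sites`, `has_exonic_site`, `direction_concordant`,
#'   `usable`, `reason`.
#' @export
assemble_gene_diagnoses <- function(diag, site_ratios = NULL) {
  d <- diag[!is.na(diag$gene_id), , drop = FALSE]
  if (!is.null(site_ratios)) {
    d$p1_fraction <- site_ratios$p1_fraction[match(d$site, site_ratios$site)]
  } else {
    d$p1_fraction <- NA_real_
  }
  d$p1_fraction[is.na(d$p1_fraction)] <- 0.5
  d |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(
      n_sites = sum(.data$qualifies),
      has_exonic_site = any(.data$qualifies & .data$region == "exon"),
      direction_concordant = {
        dev <- .data$p1_fraction[.data$qualifies] - 0.5
        !(any(dev > 0) && any(dev < 0))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      usable = .data$n_sites >= 1 & .data$has_exonic_site &
        .data$direction_concordant,
      reason = dplyr::case_when(
        .data$n_sites < 1 ~ "no_diagnostic_sites",
        !.data$has_exonic_site ~ "no_exonic_site",
        !.data$direction_concordant ~ "opposing_directions",
        TRUE ~ "ok"
      )
    )
}

# Two-sided exact tail probability for k successes in n trials at null 0.5,
# binomial or (rho > 0) beta-binomial: twice the smaller tail, capped at 1.
imbalance_pvalue <- function(k, n, rho = 0) {
  if (n == 0) return(NA_real_)
  if (rho <= 0) {
    lo <- stats::pbinom(k, n, 0.5)
    hi <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    a <- (1 / rho - 1) / 2  # symmetric beta-binomial centred on 0.5
    x <- 0:n
    logpmf <- lchoose(n, x) + lbeta(x + a, n - x + a) - lbeta(a, a)
    pmf <- exp(logpmf - max(logpmf))
    pmf <- pmf / sum(pmf)
    lo <- sum(pmf[x <= k])
    hi <- sum(pmf[x >= k])
  }
  min(1, 2 * min(lo, hi))
}

# Method-of-moments intraclass correlation from replicate-level counts.
replicate_rho <- function(k, n) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(n) < 2) return(0)
  p_hat <- sum(k) / sum(n)
  if (p_hat <= 0 || p_hat >= 1) return(0)
  x <- k / n
  chi <- sum(n * (x - p_hat)^2) / (p_hat * (1 - p_hat))
  rho <- (chi / (length(n) - 1) - 1) / (mean(n) - 1)
  max(0, min(rho, 0.99))
}

#' Allelic-imbalance test per gene, tissue and condition
#'
#' Sums replicate allele counts within each gene x tissue x condition cell,
#' computes the pseudocounted log2 fold change
#' `log2((P1 + c) / (P2 + c))` and an exact two-sided allelic-imbalance
#' p-value against the balanced null (binomial at 0.5, with a symmetric
#' beta-binomial fallback whenever the replicate-level method-of-moments
#' dispersion exceeds binomial expectation). P-values are BH-adjusted across
#' all tested cells, and a cell is called biased only when
#' `|log2fc| > lfc_threshold` and `padj < padj_threshold`.
#'
#' @param counts Allele-count tibble (see [read_allele_counts()]).
#' @param pseudocount Pseudocount `c` for the fold change (default 0.5).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @return A tibble with one row per gene x tissue x condition: `gene_id`,
#'   `tissue`, `condition`, `total_p1`, `total_p2`, `n_replicates`,
#'   `log2fc`, `rho`, `p`, `padj`, `bias` (`"P1"`, `"P2"`, `"none"`;
#'   `NA` for untested zero-count cells).
#' @export
ase_test <- function(counts, pseudocount = 0.5, lfc_threshold = 1,
                     padj_threshold = 0.05) {
  res <- counts |>
    dplyr::group_by(gene_id = .data$gene_id, tissue = .data$tissue,
                    condition = .data$condition) |>
    dplyr::summarise(
      total_p1 = sum(.data$count_p1),
      total_p2 = sum(.data$count_p2),
      n_replicates = dplyr::n(),
      rho = replicate_rho(.data$count_p1, .data$count_p1 + .data$count_p2),
      .groups = "drop"
    )
  tot <- res$total_p1 + res$total_p2
  res$log2fc <- log2((res$total_p1 + pseudocount) /
                       (res$total_p2 + pseudocount))
  res$p <- purrr::pmap_dbl(list(res$total_p1, tot, res$rho),
                           function(k, n, r) imbalance_pvalue(k, n, r))
  res$log2fc[tot == 0] <- NA_real_
  res$padj <- bh_fdr(res$p)
  res$bias <- dplyr::case_when(
    is.na(res$p) ~ NA_character_,
    abs(res$log2fc) > lfc_threshold & res$padj < padj_threshold &
      res$log2fc > 0 ~ "P1",
    abs(res$log2fc) > lfc_threshold & res$padj < padj_threshold ~ "P2",
    TRUE ~ "none"
  )
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' missing values propagate and are excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify ASE genes across tissues and conditions
#'
#' Partitions tested genes into four classes from their per-cell bias calls:
#' `not_aseg` (no significant cell), `consistent` (significant in all
#' observed cells, one direction), `direction_shifting` (significant toward
#' P1 in at least one cell and toward P2 in at least one other) and
#' `non_directional` (significant in some but not all cells, single
#' direction).
#'
#' @param results Tibble from [ase_test()].
#' @return A list of class `aseg_classification`: `genes` (tibble `gene_id`,
#'   `n_cells`, `n_sig`, `n_p1`, `n_p2`, `class`) and `summary` (class
#'   counts).
#' @export
classify_asegs <- function(results) {
  genes <- results |>
    dplyr::filter(!is.na(.data$bias)) |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_sig = sum(.data$bias != "none"),
      n_p1 = sum(.data$bias == "P1"),
      n_p2 = sum(.data$bias == "P2"),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_sig == 0 ~ "not_aseg",
      .data$n_p1 > 0 & .data$n_p2 > 0 ~ "direction_shifting",
      .data$n_sig == .data$n_cells ~ "consistent",
      TRUE ~ "non_directional"
    ))
  lvls <- c("consistent", "direction_shifting", "non_directional", "not_aseg")
  summary <- tibble::tibble(
    class = lvls,
    n = vapply(lvls, function(cl) sum(genes$class == cl), integer(1))
  )
  structure(list(genes = genes, summary = summary),
            class = "aseg_classification")
}

#' @export
print.aseg_classification <- function(x, ...) {
  n_aseg <- sum(x$summary$n[x$summary$class != "not_aseg"])
  cat(sprintf("<aseg_classification> %d genes tested, %d ASEGs\n",
              sum(x$summary$n), n_aseg))
  print(x$summary)
  invisible(x)
}

#' @export
glance.aseg_classification <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "class", values_from = "n")
}

#' @export
autoplot.aseg_classification <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$class, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' One-tailed binomial test for genome-wide parental bias
#'
#' Upper-tail exact binomial probability of observing at least
#' `max(n_p1, n_p2)` successes in `n_p1 + n_p2` trials at success
#' probability 0.5 — the test used to ask whether one parental direction
#' dominates (e.g. paternally biased ASEGs outnumbering maternal ones).
#'
#' @param n_p1,n_p2 Non-negative counts of P1- and P2-biased entities.
#' @return The one-tailed p-value.
#' @export
bias_binomial_test <- function(n_p1, n_p2) {
  stopifnot(n_p1 >= 0, n_p2 >= 0)
  n <- n_p1 + n_p2
  if (n < 1) stop("both counts are zero", call. = FALSE)
  k <- max(n_p1, n_p2)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}
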