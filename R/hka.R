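#' Count within-group polymorphic SNPs for one gene
#'
#' Number of the gene's assigned SNP sites that segregate (carry at least
#' two distinct alleles) among the non-missing calls of the pooled
#' hybrid-plus-paternal group.
#'
#' @param gm A [geno_matrix()] with `gene_id` filled.
#' @param labels Label tibble.
#' @param gene Gene identifier.
#' @param group Populations pooled as the within-group (default P1 + HYB).
#' @return Integer count.
#' @export
count_gene_polymorphism <- function(gm, labels, gene,
                                    group = c("P1", "HYB")) {
  idx <- which(gm$sites$gene_id %in% gene & gm$sites$site_class == "SNP")
  if (!length(idx)) return(0L)
  cols <- pop_columns(gm, labels, group)
  g <- gm$geno[idx, cols, drop = FALSE]
  alt <- rowSums(g, na.rm = TRUE)
  n_hap <- 2L * rowSums(!is.na(g))
  sum(alt > 0 & alt < n_hap)
}

#' Count fixed differences for one gene
#'
#' Fixed differences are the gene's SNP sites whose per-site Hudson Fst
#' between the pooled hybrid-plus-paternal group and the maternal population
#' strictly exceeds `fst_threshold` (default 0.95). The subset annotated
#' nonsynonymous is counted separately. Sites with undefined per-site Fst
#' are skipped.
#'
#' @inheritParams count_gene_polymorphism
#' @param ref_pop Population contrasted with the group (default `"P2"`).
#' @param fst_threshold Strict per-site Fst threshold (default 0.95).
#' @return A list with `n_fixed`, `n_fixed_nonsyn` and `fixed_sites`
#'   (site row indices).
#' @export
count_fixed_differences <- function(gm, labels, gene, group = c("P1", "HYB"),
                                    ref_pop = "P2", fst_threshold = 0.95) {
  idx <- which(gm$sites$gene_id %in% gene & gm$sites$site_class == "SNP")
  if (!length(idx)) {
    return(list(n_fixed = 0L, n_fixed_nonsyn = 0L, fixed_sites = integer()))
  }
  sub <- gm_subset(gm, sites = idx)
  fst <- per_site_fst(sub, labels, group, ref_pop)
  fixed <- !is.na(fst) & fst > fst_threshold
  list(n_fixed = sum(fixed),
       n_fixed_nonsyn = sum(fixed & !is.na(sub$sites$effect) &
                              sub$sites$effect == "nonsynonymous"),
       fixed_sites = idx[fixed])
}

#' HKA chi-square for one gene against the genome-wide background
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' polymorphism-versus-divergence table `[gene poly, gene fixed;
#' background poly, background fixed]`, where the background excludes the
#' focal gene. `excess_direction` is `fixed_excess` when the gene's observed
#' fixed count exceeds its expectation under the pooled ratio. Any expected
#' cell below 1 sets `low_expectation = TRUE` (the p-value is still
#' reported); a gene with no sites is untestable and gets p = 1.
#'
#' @param gene_poly,gene_fixed Focal-gene counts.
#' @param bg_poly,bg_fixed Background counts (focal gene excluded).
#' @return A tibble: `chi2`, `p`, `excess_direction`, `low_expectation`.
#' @export
hka_chi2 <- function(gene_poly, gene_fixed, bg_poly, bg_fixed) {
  if (any(c(gene_poly, gene_fixed, bg_poly, bg_fixed) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(bg_poly + bg_fixed == 0)) {
    stop("background must contain sites", call. = FALSE)
  }
  a <- as.numeric(gene_poly); b <- as.numeric(gene_fixed)
  cc <- as.numeric(bg_poly); d <- as.numeric(bg_fixed)
  n <- a + b + cc + d
  gene_tot <- a + b
  exp_fixed <- gene_tot * (b + d) / n
  exp_poly <- gene_tot * (a + cc) / n
  chi2 <- ifelse(gene_tot == 0, 0,
                 n * (a * d - b * cc)^2 /
                   pmax((a + b) * (cc + d) * (a + cc) * (b + d), 1e-300))
  # degenerate margins (all-poly or all-fixed genomes) carry no contrast
  chi2[(a + cc) == 0 | (b + d) == 0] <- 0
  p <- ifelse(gene_tot == 0, 1,
              stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  tibble::tibble(
    chi2 = chi2, p = p,
    excess_direction = dplyr::case_when(
      gene_tot == 0 ~ NA_character_,
      b > exp_fixed ~ "fixed_excess",
      TRUE ~ "poly_excess"
    ),
    low_expectation = gene_tot > 0 &
      (pmin(exp_fixed, exp_poly,
            (cc + d) * (a + cc) / n, (cc + d) * (b + d) / n) < 1)
  )
}

#' Genome-wide HKA scan
#'
#' Runs the per-gene polymorphism-versus-divergence contrast over every gene
#' with assigned SNP sites: within-group polymorphic counts, Fst-defined
#' fixed differences (with their nonsynonymous subset), the chi-square
#' against the genome-wide background (focal gene excluded) and the
#' retention flag at `p_threshold`.
#'
#' @inheritParams count_fixed_differences
#' @param p_threshold Retention threshold on the HKA p-value (default 0.01).
#' @return A tibble of class `hka_result` with one row per gene: `gene_id`,
#'   `n_poly`, `n_fixed`, `n_fixed_nonsyn`, `chi2`, `p`,
#'   `excess_direction`, `low_expectation`, `retained` and a `fixed_sites`
#'   list column of site row indices.
#' @export
hka_scan <- function(gm, labels, group = c("P1", "HYB"), ref_pop = "P2",
                     fst_threshold = 0.95, p_threshold = 0.01) {
  snp <- gm$sites$site_class == "SNP" & !is.na(gm$sites$gene_id)
  idx <- which(snp)
  if (!length(idx)) stop("no gene-assigned SNP sites", call. = FALSE)
  sub <- gm_subset(gm, sites = idx)
  cols <- pop_columns(sub, labels, group)
  g <- sub$geno[, cols, drop = FALSE]
  alt <- rowSums(g, na.rm = TRUE)
  n_hap <- 2L * rowSums(!is.na(g))
  poly <- alt > 0 & alt < n_hap
  fst <- per_site_fst(sub, labels, group, ref_pop)
  fixed <- !is.na(fst) & fst > fst_threshold
  nonsyn <- !is.na(sub$sites$effect) & sub$sites$effect == "nonsynonymous"
  per_gene <- tibble::tibble(gene_id = sub$sites$gene_id,
                             poly = poly, fixed = fixed,
                             fixed_nonsyn = fixed & nonsyn,
                             site = idx) |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(n_poly = sum(.data$poly),
                     n_fixed = sum(.data$fixed),
                     n_fixed_nonsyn = sum(.data$fixed_nonsyn),
                     fixed_sites = list(.data$site[.data$fixed]),
                     .groups = "drop")
  tot_poly <- sum(per_gene$n_poly)
  tot_fixed <- sum(per_gene$n_fixed)
  ht <- hka_chi2(per_gene$n_poly, per_gene$n_fixed,
                 tot_poly - per_gene$n_poly, tot_fixed - per_gene$n_fixed)
  out <- dplyr::bind_cols(per_gene[, c("gene_id", "n_poly", "n_fixed",
                                       "n_fixed_nonsyn")], ht)
  out$retained <- out$p < p_threshold
  out$fixed_sites <- per_gene$fixed_sites
  class(out) <- c("hka_result", class(out))
  out
}

#' Select positively selected genes
#'
#' Final PSG calling on an HKA scan: genes are ranked by their count of
#' fixed nonsynonymous differences, the top `top_fraction` (boundary ties
#' included; a gene must carry at least one fixed nonsynonymous difference)
#' is intersected with the retained genes, and each surviving gene must pass
#' the hybrid-inheritance check — more than `min_hyb_het_frac` of hybrid
#' samples are heterozygous at one or more of the gene's fixed-difference
#' sites, evidencing one allele from each parent.
#'
#' @param hka An `hka_result` tibble from [hka_scan()].
#' @param gm,labels The genotype matrix and labels the scan was run on.
#' @param top_fraction Fraction of genes kept by the fixed-nonsynonymous
#'   ranking (default 0.025).
#' @param min_hyb_het_frac Hybrid-inheritance threshold (strict;
#'   default 0.5).
#' @return `hka` with columns `in_top`, `hyb_het_frac`, `inheritance_ok`,
#'   `psg` appended.
#' @export
select_psgs <- function(hka, gm, labels, top_fraction = 0.025,
                        min_hyb_het_frac = 0.5) {
  m <- nrow(hka)
  k <- ceiling(top_fraction * m)
  ranked <- sort(hka$n_fixed_nonsyn, decreasing = TRUE)
  cutoff <- if (k >= 1) ranked[k] else Inf
  hka$in_top <- hka$n_fixed_nonsyn >= max(cutoff, 1L)
  hyb_cols <- pop_columns(gm, labels, "HYB")
  hka$hyb_het_frac <- purrr::map_dbl(hka$fixed_sites, function(sites) {
    if (!length(sites)) return(NA_real_)
    g <- gm$geno[sites, hyb_cols, drop = FALSE]
    het_any <- apply(g == 1L, 2, function(x) any(x, na.rm = TRUE))
    called <- apply(!is.na(g), 2, any)
    if (!any(called)) return(NA_real_)
    sum(het_any & called) / sum(called)
  })
  hka$inheritance_ok <- !is.na(hka$hyb_het_frac) &
    hka$hyb_het_frac > min_hyb_het_frac
  hka$psg <- hka$retained & hka$in_top & hka$inheritance_ok
  if (!any(hka$retained)) {
    message("select_psgs: no genes retained at the HKA threshold; ",
            "PSG set is empty")
  }
  hka
}

#' @export
glance.hka_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    total_poly = sum(x$n_poly),
    total_fixed = sum(x$n_fixed),
    n_retained = sum(x$retained),
    n_psg = if ("psg" %in% names(x)) sum(x$psg) else NA_integer_
  )
}
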