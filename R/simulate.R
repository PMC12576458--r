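#' Simulation configuration
#'
#' Builds the parameter set for the synthetic-data generator: a desk-scale
#' stand-in for a resequencing + allele-resolved expression study of two
#' diverged parental populations (paternal-like `P1`, maternal-like `P2`),
#' a heterozygous hybrid cohort (`HYB`), an outgroup, and planted signals
#' (diagnostic sites, sweeps, positively selected genes, inversions,
#' allelic-bias classes) with machine-readable ground truth. Unknown
#' arguments are rejected.
#'
#' Defaults give 2 chromosomes x 1 Mb with 20 000 SNPs; cohort sizes are
#' half the study scale (28 paternal, 10 maternal, 14 hybrid accessions);
#' parental divergence `F = 0.3` reproduces the parental-contrast
#' differentiation; hybrids are ancient-hybrid-like, drawing per-site
#' ancestry pairs (both-P1 / one-each / both-P2) with a paternal-dominant
#' default, while forced diagnostic sites and planted inversion genotypes
#' override the draw.
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @param n_chrom,chrom_length,n_sites Genome geometry.
#' @param n_p1,n_p2,n_hyb,n_out Samples per population.
#' @param F_div Balding-Nichols divergence between the parents.
#' @param beta_shape Symmetric Beta shape for ancestral frequencies.
#' @param diagnostic_fraction Fraction of sites forced to fixed opposite
#'   parental homozygotes.
#' @param genotype_error_rate Per-call probability of a uniform genotype
#'   re-draw.
#' @param ancestry_probs Length-3 probabilities (both-P1, one-each,
#'   both-P2) for hybrid per-site ancestry outside forced sites.
#' @param inversions Tibble (`chrom`, `start`, `end`, `label`) of planted
#'   inversion regions, or `NULL`.
#' @param inversion_genotypes Named character vector: planted class per
#'   hybrid sample (`heterozygous`, `P1_homozygous`, `P2_homozygous`);
#'   `NULL` plants a default 8/3/3 split.
#' @param sweeps Tibble (`chrom`, `start`, `end`) of swept regions, or
#'   `NULL`.
#' @param sweep_r Diversity-reduction factor r (swept-window diversity is
#'   reduced to a fraction r of its neutral value).
#' @param sweep_pop Population carrying the sweep (default `"P2"`).
#' @param n_genes Gene models per chromosome tiling (2-exon genes).
#' @param gene_length,gene_spacing Gene-model geometry in bp.
#' @param n_psg Number of planted positively selected genes.
#' @param psg_fixed_sites Fixed-difference sites planted per PSG.
#' @param psg_nonsyn_frac Fraction of planted fixed sites annotated
#'   nonsynonymous.
#' @param psg_hyb_het_prob Per-site probability that a hybrid is
#'   heterozygous (rather than P1-homozygous) at a planted PSG site.
#' @param background_nonsyn_frac Fraction of exonic SNPs annotated
#'   nonsynonymous outside planted PSG sites.
#' @param tissues,conditions,n_reps Expression design (defaults: shoot/root
#'   x 0/200/400 mM NaCl x 3 replicates).
#' @param expr_genes Genes carrying expression data (default: all).
#' @param depth Mean allele-summed read depth per gene and replicate.
#' @param expr_dispersion Negative-binomial dispersion of total counts.
#' @param theta Planted allelic bias (P1-read probability) for biased
#'   cells.
#' @param class_fractions Named fractions of expression genes planted as
#'   `consistent`, `direction_shifting`, `non_directional` (the rest are
#'   unbiased).
#' @param introgression_f Introgression fraction for the four-taxon
#'   site-pattern simulator.
#' @param d_n_sites,d_n_blocks Four-taxon simulator geometry.
#' @param d_F_internal,d_F_tip Drift intensities of the four-taxon
#'   simulator (internal branch and tips).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 1e6, n_sites = 20000L,
                       n_p1 = 28L, n_p2 = 10L, n_hyb = 14L, n_out = 4L,
                       F_div = 0.3, beta_shape = 0.8,
                       diagnostic_fraction = 0.05,
                       genotype_error_rate = 0.005,
                       ancestry_probs = c(0.75, 0.20, 0.05),
                       inversions = NULL, inversion_genotypes = NULL,
                       sweeps = NULL, sweep_r = 0.1, sweep_pop = "P2",
                       n_genes = 200L, gene_length = 2000L,
                       gene_spacing = 5000L,
                       n_psg = 10L, psg_fixed_sites = 12L,
                       psg_nonsyn_frac = 2 / 3, psg_hyb_het_prob = 0.15,
                       background_nonsyn_frac = 0.25,
                       tissues = c("shoot", "root"),
                       conditions = c("0", "200", "400"),
                       n_reps = 3L, expr_genes = NULL,
                       depth = 100, expr_dispersion = 0.1, theta = 0.8,
                       class_fractions = c(consistent = 0.10,
                                           direction_shifting = 0.10,
                                           non_directional = 0.10),
                       introgression_f = 0.2,
                       d_n_sites = 10000L, d_n_blocks = 20L,
                       d_F_internal = 0.2, d_F_tip = 0.1) {
  cfg <- as.list(environment())
  stopifnot(F_div >= 0, F_div < 1,
            diagnostic_fraction >= 0, diagnostic_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            introgression_f >= 0, introgression_f <= 1,
            theta >= 0, theta <= 1, sweep_r > 0, sweep_r <= 1,
            abs(sum(ancestry_probs) - 1) < 1e-8,
            sum(class_fractions) <= 1)
  if (is.null(cfg$inversions)) {
    cfg$inversions <- tibble::tibble(
      chrom = c("chr1", "chr2"),
      start = c(300001L, 150001L),
      end = c(500000L, 300000L),
      label = c("inv1", "inv2"))
  }
  if (is.null(cfg$inversion_genotypes)) {
    classes <- rep(c("heterozygous", "P1_homozygous", "P2_homozygous"),
                   length.out = max(n_hyb, 1))
    classes[seq_len(min(8, n_hyb))] <- "heterozygous"
    if (n_hyb >= 11) classes[9:11] <- "P1_homozygous"
    if (n_hyb >= 14) classes[12:14] <- "P2_homozygous"
    cfg$inversion_genotypes <- stats::setNames(
      classes[seq_len(n_hyb)], paste0("HYB_", seq_len(n_hyb)))
  }
  if (is.null(cfg$sweeps)) {
    cfg$sweeps <- tibble::tibble(chrom = "chr2",
                                 start = 600001L, end = 700000L)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d chrom x %g bp, %d sites; P1/P2/HYB/OUT = %d/%d/%d/%d; F = %g, f = %g\n",
    x$seed, x$n_chrom, x$chrom_length, x$n_sites,
    x$n_p1, x$n_p2, x$n_hyb, x$n_out, x$F_div, x$introgression_f))
  invisible(x)
}

# Balding-Nichols draw: subpopulation frequencies around ancestral p.
balding_nichols <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate the parental populations
#'
#' Ancestral frequencies are drawn from a symmetric Beta, parental
#' frequencies from the Balding-Nichols distribution at divergence `F_div`,
#' and diploid genotypes binomially per individual. A `diagnostic_fraction`
#' of sites is overridden to fixed opposite homozygotes (P1 reference,
#' P2 alternate), sweep regions push the swept population's frequencies
#' toward fixation so that its diversity falls to a fraction `sweep_r` of
#' neutral, and planted PSG genes receive parental fixed differences.
#' Genotype errors re-draw calls uniformly. Outgroup samples are fixed for
#' the reference allele. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `gm` (a [geno_matrix()] of P1 + P2 + OUT samples),
#'   `labels`, `genes` (gene-model tibble), `freqs` (per-site generating
#'   frequencies `p1`, `p2`), `truth` (see [simulate_dataset()]).
#' @export
simulate_parental_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  with(config, {
    chroms <- paste0("chr", seq_len(n_chrom))
    per_chrom <- diff(round(seq(0, n_sites, length.out = n_chrom + 1)))
    sites <- purrr::map2_dfr(chroms, per_chrom, function(ch, n) {
      tibble::tibble(chrom = ch,
                     pos = sort(sample.int(chrom_length - 1, n)) + 1L)
    })
    n_total <- nrow(sites)
    sites$ref <- sample(c("A", "C", "G", "T"), n_total, replace = TRUE)
    sites$alt <- vapply(sites$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))

    genes <- purrr::map_dfr(chroms, function(ch) {
      starts <- seq(1L, by = gene_spacing, length.out = n_genes)
      starts <- starts[starts + gene_length - 1 <= chrom_length]
      tibble::tibble(
        gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
        chrom = ch, start = starts, end = starts + gene_length - 1L,
        strand = "+",
        exons = purrr::map(starts, function(s) {
          third <- floor(gene_length / 3)
          cbind(start = c(s, s + 2L * third),
                end = c(s + third - 1L, s + gene_length - 1L))
        }))
    })

    anc <- stats::rbeta(n_total, beta_shape, beta_shape)
    p1 <- balding_nichols(anc, F_div)
    p2 <- balding_nichols(anc, F_div)

    in_regions <- function(regs) {
      hit <- rep(FALSE, n_total)
      if (is.null(regs)) return(hit)
      for (i in seq_len(nrow(regs))) {
        hit <- hit | (sites$chrom == regs$chrom[i] &
                        sites$pos >= regs$start[i] &
                        sites$pos <= regs$end[i])
      }
      hit
    }

    # planted diagnostic sites: P1 fixed ref, P2 fixed alt
    diag_sites <- which(stats::runif(n_total) < diagnostic_fraction)
    p1[diag_sites] <- 0
    p2[diag_sites] <- 1

    # sweep: with probability 1 - r the swept population's frequency
    # collapses to the nearer boundary, scaling its heterozygosity by r
    swept <- which(in_regions(sweeps))
    if (length(swept)) {
      collapse <- stats::runif(length(swept)) > sweep_r
      tgt <- if (sweep_pop == "P1") "p1" else "p2"
      pv <- get(tgt)
      pv[swept][collapse] <- round(
        stats::rbinom(sum(collapse), 1, pv[swept][collapse]))
      assign(tgt, pv)
    }

    # annotate sites to genes, then plant PSG fixed differences
    gm0 <- geno_matrix(sites, matrix(integer(), n_total, 0), character())
    gm0 <- assign_sites_to_genes(gm0, genes)
    sites <- gm0$sites
    exonic <- which(sites$region == "exon" & !(seq_len(n_total) %in%
                                                 diag_sites))
    psg_genes <- character()
    psg_site_idx <- integer()
    if (n_psg > 0) {
      cand <- sites$gene_id[exonic]
      counts <- table(cand)
      eligible <- names(counts)[counts >= psg_fixed_sites]
      psg_genes <- sort(sample(eligible, min(n_psg, length(eligible))))
      for (gid in psg_genes) {
        gsites <- exonic[cand == gid]
        pick <- sort(sample(gsites, psg_fixed_sites))
        p1[pick] <- 1   # group allele = alternate
        p2[pick] <- 0
        psg_site_idx <- c(psg_site_idx, pick)
      }
    }

    # coding-effect annotation: planted PSG sites mostly nonsynonymous,
    # other exonic SNPs at the background rate
    effect <- rep(NA_character_, n_total)
    effect[sites$region == "exon"] <- ifelse(
      stats::runif(sum(sites$region == "exon")) < background_nonsyn_frac,
      "nonsynonymous", "synonymous")
    effect[sites$region == "intron"] <- "noncoding"
    if (length(psg_site_idx)) {
      effect[psg_site_idx] <- ifelse(
        stats::runif(length(psg_site_idx)) < psg_nonsyn_frac,
        "nonsynonymous", "synonymous")
    }
    sites$effect <- effect

    draw_geno <- function(p, n_ind) {
      matrix(stats::rbinom(length(p) * n_ind, 2, rep(p, n_ind)),
             nrow = length(p), ncol = n_ind)
    }
    g1 <- draw_geno(p1, n_p1)
    g2 <- draw_geno(p2, n_p2)
    go <- matrix(0L, n_total, n_out)
    geno <- cbind(g1, g2, go)
    samples <- c(paste0("P1_", seq_len(n_p1)), paste0("P2_", seq_len(n_p2)),
                 if (n_out > 0) paste0("OUT_", seq_len(n_out)))
    geno <- apply_genotype_errors(geno, genotype_error_rate)
    gm <- geno_matrix(sites, geno, samples)
    labels <- tibble::tibble(
      sample = samples,
      population = c(rep("P1", n_p1), rep("P2", n_p2), rep("OUT", n_out)),
      source = "genome")
    truth <- list(
      diagnostic_sites = diag_sites,
      psg_genes = psg_genes,
      psg_sites = sort(psg_site_idx),
      sweeps = sweeps,
      sweep_r = sweep_r,
      sweep_pop = sweep_pop,
      inversions = inversions,
      inversion_genotypes = inversion_genotypes
    )
    list(gm = gm, labels = labels, genes = genes,
         freqs = tibble::tibble(p1 = p1, p2 = p2), truth = truth)
  })
}

# Uniform re-draw genotype error.
apply_genotype_errors <- function(geno, rate) {
  if (rate <= 0) return(geno)
  err <- which(stats::runif(length(geno)) < rate)
  if (length(err)) geno[err] <- sample(0:2, length(err), replace = TRUE)
  geno
}

#' Add hybrid samples to a simulated parental matrix
#'
#' Each hybrid draws, per site, an ancestry pair — both alleles from P1,
#' one from each parent, or both from P2 — with the config's
#' `ancestry_probs` (paternal-dominant by default, emulating an ancient
#' paternal-backcrossed hybrid). Forced exceptions: planted diagnostic
#' sites are one-from-each-parent (heterozygous up to genotype error);
#' inside planted inversion regions the per-sample planted class fixes the
#' ancestry pair; at planted PSG fixed-difference sites hybrids are
#' heterozygous with probability `psg_hyb_het_prob` and P1-homozygous
#' otherwise (occasional retained maternal alleles on a paternal
#' background).
#'
#' @param config A [sim_config()].
#' @param parental Output of [simulate_parental_populations()].
#' @return `parental` with hybrid columns appended to `gm` and `labels`.
#' @export
simulate_hybrids <- function(config, parental) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gm <- parental$gm
  n_total <- nrow(gm$sites)
  p1 <- parental$freqs$p1
  p2 <- parental$freqs$p2
  truth <- parental$truth
  hyb_names <- names(config$inversion_genotypes)
  if (is.null(hyb_names)) hyb_names <- paste0("HYB_", seq_len(config$n_hyb))
  inv_mask <- rep(FALSE, n_total)
  if (!is.null(truth$inversions)) {
    for (i in seq_len(nrow(truth$inversions))) {
      inv_mask <- inv_mask | (gm$sites$chrom == truth$inversions$chrom[i] &
                                gm$sites$pos >= truth$inversions$start[i] &
                                gm$sites$pos <= truth$inversions$end[i])
    }
  }
  diag_mask <- rep(FALSE, n_total)
  diag_mask[truth$diagnostic_sites] <- TRUE
  psg_mask <- rep(FALSE, n_total)
  psg_mask[truth$psg_sites] <- TRUE

  geno_h <- matrix(NA_integer_, n_total, config$n_hyb)
  for (j in seq_len(config$n_hyb)) {
    anc_class <- sample.int(3, n_total, replace = TRUE,
                            prob = config$ancestry_probs)
    # forced structure overrides the ancestry draw
    anc_class[diag_mask] <- 2L
    anc_class[psg_mask] <- ifelse(
      stats::runif(sum(psg_mask)) < config$psg_hyb_het_prob, 2L, 1L)
    planted <- truth$inversion_genotypes[[hyb_names[j]]]
    if (!is.null(planted) && any(inv_mask)) {
      anc_class[inv_mask] <- switch(planted,
                                    heterozygous = 2L,
                                    P1_homozygous = 1L,
                                    P2_homozygous = 3L)
      # diagnostic sites inside the inversion follow the planted class too,
      # except that the het class is exactly the one-from-each draw
    }
    a1 <- stats::rbinom(n_total, 1,
                        ifelse(anc_class == 3L, p2, p1))
    a2 <- stats::rbinom(n_total, 1,
                        ifelse(anc_class == 1L, p1, p2))
    geno_h[, j] <- a1 + a2
  }
  geno_h <- apply_genotype_errors(geno_h, config$genotype_error_rate)
  gm2 <- geno_matrix(gm$sites, cbind(gm$geno, geno_h),
                     c(gm$samples, hyb_names))
  labels2 <- dplyr::bind_rows(
    parental$labels,
    tibble::tibble(sample = hyb_names, population = "HYB",
                   source = "genome"))
  parental$gm <- gm2
  parental$labels <- labels2
  parental
}

#' Simulate four-taxon site frequencies for the D statistic
#'
#' Generates per-site alternate-allele frequencies for (P1, P2, P3,
#' outgroup) by drawing Balding-Nichols drift around a species topology
#' (((P1, P2), P3), O); with probability `introgression_f` a site's
#' genealogy instead groups P2 with P3 (a shared drifted frequency),
#' producing an ABBA excess. Expected D is 0 at `f = 0` and increases
#' with `f`. Blocks are contiguous runs of sites.
#'
#' @param config A [sim_config()]; uses `introgression_f`, `d_n_sites`,
#'   `d_n_blocks`, `d_F_internal`, `d_F_tip`, `beta_shape` and `seed`.
#' @param seed_offset Added to the config seed (lets replicate studies
#'   re-draw independently).
#' @return A tibble with columns `p1`, `p2`, `p3`, `p4`, `block`.
#' @export
simulate_four_taxon_sites <- function(config, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L + seed_offset)
  n <- config$d_n_sites
  f <- config$introgression_f
  Fi <- config$d_F_internal
  Ft <- config$d_F_tip
  anc <- stats::rbeta(n, config$beta_shape, config$beta_shape)
  internal12 <- balding_nichols(anc, Fi)
  p1 <- balding_nichols(internal12, Ft)
  p2 <- balding_nichols(internal12, Ft)
  p3 <- balding_nichols(anc, Ft)
  p4 <- balding_nichols(anc, Ft / 2)
  intro <- stats::runif(n) < f
  if (any(intro)) {
    donor <- balding_nichols(anc[intro], Fi)
    p2[intro] <- balding_nichols(donor, Ft)
    p3[intro] <- balding_nichols(donor, Ft)
  }
  tibble::tibble(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 block = rep(seq_len(config$d_n_blocks),
                             each = ceiling(n / config$d_n_blocks))[
                               seq_len(n)])
}

#' Simulate allele-resolved expression counts with planted ASE classes
#'
#' For every gene x hybrid replicate x tissue x condition cell, the total
#' allele-summed read count is negative-binomial with the configured mean
#' and dispersion and the P1-allele count is binomial with the cell's
#' planted P1-read probability theta. Planted classes realise the
#' classifier's definitions: `consistent` genes hold one biased theta in
#' every cell, `direction_shifting` genes cross 0.5 between cells,
#' `non_directional` genes are biased in a strict subset of cells, and the
#' remainder are balanced.
#'
#' @param config A [sim_config()].
#' @param genes Optional character vector of gene ids (default: the
#'   config's `expr_genes`, else gene ids generated by the genome
#'   simulator are supplied by [simulate_dataset()]).
#' @return A list: `counts` (allele-count tibble), `truth` (tibble
#'   `gene_id`, `class`, `direction`).
#' @export
simulate_allele_counts <- function(config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(genes)) genes <- config$expr_genes
  stopifnot(length(genes) > 0)
  n_g <- length(genes)
  fr <- config$class_fractions
  n_cons <- round(fr[["consistent"]] * n_g)
  n_shift <- round(fr[["direction_shifting"]] * n_g)
  n_nd <- round(fr[["non_directional"]] * n_g)
  class <- rep("none", n_g)
  class[seq_len(n_cons)] <- "consistent"
  class[n_cons + seq_len(n_shift)] <- "direction_shifting"
  class[n_cons + n_shift + seq_len(n_nd)] <- "non_directional"
  class <- sample(class)  # shuffle over gene ids
  direction <- sample(c("P1", "P2"), n_g, replace = TRUE)
  theta_hi <- config$theta
  theta_lo <- 1 - config$theta
  cells <- tidyr::expand_grid(tissue = config$tissues,
                              condition = config$conditions)
  n_cells <- nrow(cells)
  theta_tab <- purrr::map_dfr(seq_len(n_g), function(i) {
    th <- rep(0.5, n_cells)
    base <- if (direction[i] == "P1") theta_hi else theta_lo
    if (class[i] == "consistent") {
      th[] <- base
    } else if (class[i] == "direction_shifting") {
      half <- seq_len(ceiling(n_cells / 2))
      th[half] <- base
      th[-half] <- 1 - base
    } else if (class[i] == "non_directional") {
      k <- max(1, floor(n_cells / 3))
      th[seq_len(k)] <- base
    }
    dplyr::mutate(cells, gene_id = genes[i], theta = th)
  })
  design <- tidyr::expand_grid(
    gene_id = genes,
    sample = paste0("HYBrep_", seq_len(config$n_reps)),
    cells)
  design <- dplyr::left_join(design, theta_tab,
                             by = c("gene_id", "tissue", "condition"))
  n_rec <- nrow(design)
  total <- stats::rnbinom(n_rec, mu = config$depth,
                          size = 1 / config$expr_dispersion)
  design$count_p1 <- stats::rbinom(n_rec, total, design$theta)
  design$count_p2 <- total - design$count_p1
  counts <- design[, c("gene_id", "sample", "tissue", "condition",
                       "count_p1", "count_p2")]
  list(counts = counts,
       truth = tibble::tibble(gene_id = genes, class = class,
                              direction = ifelse(class == "none",
                                                 NA_character_, direction)))
}

#' Simulate a complete study dataset
#'
#' Chains the genome-level generators (parents with planted diagnostics,
#' sweeps and PSG fixed differences; hybrids with planted inversion
#' genotypes), the expression generator and the four-taxon frequency
#' simulator, and assembles the ground truth for recovery evaluation.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `gm`, `labels`, `genes`,
#'   `counts`, `four_taxon`, `freqs`, `truth` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  parental <- simulate_parental_populations(config)
  full <- simulate_hybrids(config, parental)
  expr_genes <- config$expr_genes
  if (is.null(expr_genes)) expr_genes <- full$genes$gene_id
  expr <- simulate_allele_counts(config, genes = expr_genes)
  four <- simulate_four_taxon_sites(config)
  truth <- full$truth
  truth$ase <- expr$truth
  # sites effectively fixed-discordant between the parents in the generating
  # frequencies (planted sites plus near-fixed drift); the reference set for
  # diagnostic-site precision
  truth$discordant_sites <- which(
    (full$freqs$p1 <= 0.05 & full$freqs$p2 >= 0.95) |
      (full$freqs$p1 >= 0.95 & full$freqs$p2 <= 0.05))
  structure(list(gm = full$gm, labels = full$labels, genes = full$genes,
                 counts = expr$counts, four_taxon = four,
                 freqs = full$freqs, truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  print(x$config)
  print(x$gm)
  cat(sprintf("  %d gene models, %d expression records, %d four-taxon sites\n",
              nrow(x$genes), nrow(x$counts), nrow(x$four_taxon)))
  invisible(x)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `variants.vcf` (with INFO annotations), `genes.gff3`,
#' `labels.tsv`, `allele_counts.tsv`, `inversions.bed`, `sweeps.bed` and
#' `truth.json` into `dir`. Files parse back through the package readers to
#' the in-memory objects; regeneration under the same config is
#' byte-identical.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    gff = file.path(dir, "genes.gff3"),
    labels = file.path(dir, "labels.tsv"),
    counts = file.path(dir, "allele_counts.tsv"),
    inversions = file.path(dir, "inversions.bed"),
    sweeps = file.path(dir, "sweeps.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(dataset$gm, paths[["vcf"]])
  g <- dataset$genes
  gff <- c("##gff-version 3",
           unlist(purrr::map(seq_len(nrow(g)), function(i) {
             ex <- g$exons[[i]]
             c(sprintf("%s\thybridpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i],
                       g$gene_id[i]),
               sprintf("%s\thybridpop\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                       g$chrom[i], ex[, "start"], ex[, "end"], g$strand[i],
                       g$gene_id[i], seq_len(nrow(ex)), g$gene_id[i]))
           })))
  writeLines(gff, paths[["gff"]])
  readr::write_tsv(dataset$labels, paths[["labels"]])
  readr::write_tsv(dataset$counts, paths[["counts"]])
  write_bed <- function(regs, path) {
    if (is.null(regs) || nrow(regs) == 0) {
      writeLines(character(), path)
    } else {
      lab <- if (!is.null(regs$label)) regs$label else
        paste0("region", seq_len(nrow(regs)))
      writeLines(sprintf("%s\t%d\t%d\t%s", regs$chrom, regs$start - 1L,
                         regs$end, lab), path)
    }
  }
  write_bed(dataset$truth$inversions, paths[["inversions"]])
  write_bed(dataset$truth$sweeps, paths[["sweeps"]])
  truth <- dataset$truth
  truth_json <- list(
    diagnostic_sites = truth$diagnostic_sites,
    psg_genes = truth$psg_genes,
    psg_sites = truth$psg_sites,
    sweep_r = truth$sweep_r,
    sweep_pop = truth$sweep_pop,
    sweeps = truth$sweeps,
    inversions = truth$inversions,
    inversion_genotypes = as.list(truth$inversion_genotypes),
    ase = truth$ase,
    seed = dataset$config$seed
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a ground-truth JSON written by [write_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return A list mirroring the dataset's `truth` element.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$diagnostic_sites <- as.integer(x$diagnostic_sites)
  x$psg_genes <- as.character(unlist(x$psg_genes))
  x$psg_sites <- as.integer(x$psg_sites)
  x$sweeps <- tibble::as_tibble(x$sweeps)
  x$inversions <- tibble::as_tibble(x$inversions)
  x$inversion_genotypes <- unlist(x$inversion_genotypes)
  x$ase <- tibble::as_tibble(x$ase)
  x
}
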