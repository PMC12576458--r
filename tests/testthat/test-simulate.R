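# Small geometries keep the generator tests quick.
small_cfg <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_chrom = 1L, chrom_length = 2e5,
                   n_sites = 2000L, n_p1 = 12L, n_p2 = 8L, n_hyb = 6L,
                   n_out = 2L, n_genes = 30L, n_psg = 2L,
                   inversions = tibble::tibble(chrom = "chr1",
                                               start = 50001L,
                                               end = 100000L,
                                               label = "inv1"),
                   sweeps = tibble::tibble(chrom = character(),
                                           start = integer(),
                                           end = integer()))
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(a$gm$geno, b$gm$geno)
  expect_identical(a$counts, b$counts)
  expect_identical(a$four_taxon, b$four_taxon)
  expect_identical(a$truth$psg_genes, b$truth$psg_genes)
  c <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$gm$geno, c$gm$geno))
})

test_that("zero divergence gives undifferentiated parents", {
  cfg <- small_cfg(seed = 11, F_div = 0, diagnostic_fraction = 0,
                   genotype_error_rate = 0, n_psg = 0L)
  ds <- simulate_dataset(cfg)
  w <- make_windows(c(chr1 = 2e5), 2e5, 2e5)
  fst <- hudson_fst(ds$gm, ds$labels, "P1", "P2", w)$fst
  expect_lt(abs(fst), 0.02)
})

test_that("windowed Fst recovers the generating divergence", {
  cfg <- sim_config(seed = 12, n_chrom = 1L, chrom_length = 1e6,
                    n_sites = 20000L, n_p1 = 20L, n_p2 = 20L, n_hyb = 2L,
                    n_out = 0L, F_div = 0.3, diagnostic_fraction = 0,
                    genotype_error_rate = 0, n_psg = 0L,
                    sweeps = tibble::tibble(chrom = character(),
                                            start = integer(),
                                            end = integer()))
  ds <- simulate_dataset(cfg)
  w <- make_windows(c(chr1 = 1e6), 20000, 20000)
  fst <- hudson_fst(ds$gm, ds$labels, "P1", "P2", w)
  expect_equal(mean(fst$fst, na.rm = TRUE), 0.3, tolerance = 0.05 / 0.3)
})

test_that("diagnostic sites are heterozygous in error-free hybrids", {
  cfg <- small_cfg(seed = 13, genotype_error_rate = 0)
  ds <- simulate_dataset(cfg)
  hyb <- ds$labels$sample[ds$labels$population == "HYB"]
  g <- ds$gm$geno[ds$truth$diagnostic_sites,
                  match(hyb, ds$gm$samples), drop = FALSE]
  # outside the inversion every hybrid is het; inside, the planted class
  outside <- ds$gm$sites$pos[ds$truth$diagnostic_sites] < 50001 |
    ds$gm$sites$pos[ds$truth$diagnostic_sites] > 100000
  expect_true(all(g[outside, ] == 1L))
  p1 <- ds$gm$geno[ds$truth$diagnostic_sites,
                   ds$labels$population == "P1", drop = FALSE]
  p2 <- ds$gm$geno[ds$truth$diagnostic_sites,
                   ds$labels$population == "P2", drop = FALSE]
  expect_true(all(p1 == 0L))
  expect_true(all(p2 == 2L))
})

test_that("F1-style hybrids conserve the mean parental frequency", {
  cfg <- small_cfg(seed = 14, genotype_error_rate = 0,
                   ancestry_probs = c(0, 1, 0), n_hyb = 40L)
  ds <- simulate_dataset(cfg)
  hyb_cols <- which(ds$labels$population[match(ds$gm$samples,
                                               ds$labels$sample)] == "HYB")
  outside <- rep(TRUE, nrow(ds$gm$sites))
  inv <- ds$truth$inversions
  outside[ds$gm$sites$pos >= inv$start & ds$gm$sites$pos <= inv$end] <- FALSE
  outside[ds$truth$psg_sites] <- FALSE
  hyb_freq <- rowMeans(ds$gm$geno[outside, hyb_cols]) / 2
  expected <- (ds$freqs$p1[outside] + ds$freqs$p2[outside]) / 2
  # per-site binomial noise averages out across sites
  expect_equal(mean(hyb_freq), mean(expected), tolerance = 0.01)
  expect_gt(stats::cor(hyb_freq, expected), 0.95)
})

test_that("hybrid diversity exceeds both parents under the default design", {
  cfg <- small_cfg(seed = 15, n_sites = 4000L)
  ds <- simulate_dataset(cfg)
  w <- make_windows(c(chr1 = 2e5), 2e5, 2e5)
  pis <- vapply(c("P1", "P2", "HYB"), function(p)
    window_pi(ds$gm, ds$labels, p, w)$pi, numeric(1))
  expect_gt(pis[["HYB"]], pis[["P1"]])
  expect_gt(pis[["HYB"]], pis[["P2"]])
})

test_that("four-taxon frequencies behave at the introgression limits", {
  cfg0 <- small_cfg(seed = 16, introgression_f = 0, d_n_sites = 4000L)
  d0 <- mean(vapply(1:30, function(i)
    d_statistic(simulate_four_taxon_sites(cfg0, seed_offset = i))$D,
    numeric(1)))
  expect_lt(abs(d0), 0.02)

  cfg1 <- small_cfg(seed = 16, introgression_f = 1, d_n_sites = 4000L)
  d1 <- d_statistic(simulate_four_taxon_sites(cfg1))$D
  expect_gt(d1, 0.2)

  cfg_mid <- small_cfg(seed = 16, introgression_f = 0.3, d_n_sites = 4000L)
  d_mid <- d_statistic(simulate_four_taxon_sites(cfg_mid))$D
  expect_gt(d1, d_mid)
  expect_gt(d_mid, 0.02)
})

test_that("planted allelic-bias classes realise their definitions", {
  cfg <- small_cfg(seed = 17, depth = 200)
  expr <- simulate_allele_counts(cfg, genes = sprintf("g%03d", 1:200))
  expect_equal(nrow(expr$truth), 200)
  expect_equal(sort(unique(expr$truth$class)),
               sort(c("consistent", "direction_shifting",
                      "non_directional", "none")))
  by_gene <- dplyr::summarise(
    dplyr::group_by(expr$counts, gene_id = .data$gene_id,
                    tissue = .data$tissue, condition = .data$condition),
    frac = sum(.data$count_p1) / sum(.data$count_p1 + .data$count_p2),
    .groups = "drop")
  merged <- dplyr::inner_join(by_gene, expr$truth, by = "gene_id")
  cons <- merged[merged$class == "consistent" & merged$direction == "P1", ]
  expect_equal(mean(cons$frac), 0.8, tolerance = 0.02)
  null <- merged[merged$class == "none", ]
  expect_equal(mean(null$frac), 0.5, tolerance = 0.01)
  shift <- merged[merged$class == "direction_shifting", ]
  spread <- dplyr::summarise(dplyr::group_by(shift, gene_id = .data$gene_id),
                             lo = min(.data$frac), hi = max(.data$frac))
  expect_true(all(spread$lo < 0.5 & spread$hi > 0.5))
})

test_that("written datasets round-trip and regenerate byte-identically", {
  cfg <- small_cfg(seed = 18, n_sites = 500L, n_genes = 10L, n_psg = 1L,
                   psg_fixed_sites = 3L)
  ds <- simulate_dataset(cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_dataset(ds, dir1)
  gm_back <- read_vcf(paths[["vcf"]])
  expect_equal(gm_back$geno, ds$gm$geno)
  expect_equal(gm_back$sites$effect, ds$gm$sites$effect)
  labs_back <- read_labels(paths[["labels"]])
  expect_equal(labs_back$population, ds$labels$population)
  counts_back <- read_allele_counts(paths[["counts"]])
  expect_equal(counts_back$count_p1, ds$counts$count_p1)
  genes_back <- read_gene_models(paths[["gff"]])
  expect_equal(genes_back$gene_id, ds$genes$gene_id)
  expect_equal(genes_back$exons, ds$genes$exons)
  truth_back <- read_truth(paths[["truth"]])
  expect_equal(truth_back$psg_genes, ds$truth$psg_genes)
  expect_equal(truth_back$diagnostic_sites, ds$truth$diagnostic_sites)
  inv_back <- read_regions_bed(paths[["inversions"]])
  expect_equal(inv_back$start, ds$truth$inversions$start)

  dir2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), dir2)
  for (f in basename(paths)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(F_div = 1.2))
  expect_error(sim_config(theta = 2))
  expect_error(sim_config(bogus_key = 1), "unused argument")
})
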