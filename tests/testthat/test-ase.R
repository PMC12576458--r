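# A compact parental panel: 10 P1 + 10 P2 + 5 HYB samples.
ase_fixture <- function(rows, pos = NULL, ...) {
  gm <- make_gm(rows, pos = pos, ...)
  labs <- make_labels(n_p1 = 10, n_p2 = 10, n_hyb = 5)
  list(gm = gm, labs = labs)
}

test_that("diagnostic sites require fixed discordance and 80% consistency", {
  r_fixed <- c(rep(0L, 10), rep(2L, 9), 1L, rep(1L, 5))     # (1.0, 0.9)
  r_weak <- c(rep(0L, 10), rep(2L, 7), rep(1L, 3), rep(1L, 5))  # (1.0, 0.7)
  r_same <- c(rep(0L, 10), rep(0L, 10), rep(0L, 5))          # no discordance
  fx <- ase_fixture(rbind(r_fixed, r_weak, r_same))
  diag <- find_diagnostic_sites(fx$gm, fx$labs)
  expect_equal(diag$qualifies, c(TRUE, FALSE, FALSE))
  expect_equal(diag$p1_consistency[1], 1.0)
  expect_equal(diag$p2_consistency[1], 0.9)
  expect_equal(diag$p1_allele[1], "ref")
  expect_equal(diag$p2_allele[1], "alt")

  # consistency exactly at the threshold is rejected (strict >)
  r_80 <- c(rep(0L, 10), rep(2L, 8), rep(1L, 2), rep(1L, 5))
  fx2 <- ase_fixture(rbind(r_80))
  expect_false(find_diagnostic_sites(fx2$gm, fx2$labs)$qualifies)
})

test_that("hybrid genotyping keeps sites with enough heterozygotes", {
  base <- c(rep(0L, 10), rep(2L, 10))
  rows <- rbind(c(base, 1L, 1L, 1L, 0L, 0L),   # 3 het -> retained
                c(base, 1L, 1L, 0L, 0L, 0L),   # 2 het -> dropped
                c(base, rep(NA_integer_, 5)))  # all missing -> dropped
  fx <- ase_fixture(rows)
  diag <- find_diagnostic_sites(fx$gm, fx$labs)
  expect_true(all(diag$qualifies))
  diag <- genotype_hybrids(diag, fx$gm, fx$labs, min_het = 3)
  expect_equal(diag$n_hyb_het, c(3, 2, 0))
  expect_equal(diag$qualifies, c(TRUE, FALSE, FALSE))
  expect_equal(diag$n_hyb_called[3], 0)
})

test_that("gene diagnoses enforce the exon and direction criteria", {
  diag <- tibble::tibble(
    site = 1:6,
    gene_id = c("gA", "gA", "gB", "gC", "gC", NA),
    region = c("exon", "exon", "intron", "exon", "intron", "exon"),
    qualifies = TRUE,
    chrom = "chr1", pos = 1:6
  )
  ratios <- tibble::tibble(site = 1:6,
                           p1_fraction = c(0.7, 0.8, 0.6, 0.7, 0.3, 0.5))
  gd <- assemble_gene_diagnoses(diag, ratios)
  gd <- gd[order(gd$gene_id), ]
  expect_equal(gd$gene_id, c("gA", "gB", "gC"))
  expect_equal(gd$usable, c(TRUE, FALSE, FALSE))
  expect_equal(gd$reason, c("ok", "no_exonic_site", "opposing_directions"))

  # an exactly balanced site is concordant with anything
  gd2 <- assemble_gene_diagnoses(
    diag[diag$gene_id %in% "gA", ],
    tibble::tibble(site = 1:2, p1_fraction = c(0.5, 0.9)))
  expect_true(gd2$usable)

  # a gene with no qualifying site is reported, not dropped
  diag3 <- diag[3, ]
  diag3$qualifies <- FALSE
  gd3 <- assemble_gene_diagnoses(diag3)
  expect_false(gd3$usable)
  expect_equal(gd3$reason, "no_diagnostic_sites")
})

test_that("the allelic-imbalance test applies both thresholds", {
  counts <- tibble::tibble(
    gene_id = rep(c("hi", "even", "weak"), each = 2),
    sample = rep(c("r1", "r2"), 3),
    tissue = "shoot", condition = "0",
    count_p1 = c(200L, 200L, 25L, 25L, 60L, 60L),
    count_p2 = c(50L, 50L, 25L, 25L, 50L, 50L)
  )
  res <- ase_test(counts)
  res <- res[order(res$gene_id), ]
  hi <- res[res$gene_id == "hi", ]
  expect_equal(hi$total_p1, 400)
  expect_equal(hi$log2fc, log2(400.5 / 100.5))
  expect_gt(hi$log2fc, 1.99)
  # oracle: exact two-sided binomial tail for k = 400 of n = 500 at 0.5
  oracle <- min(1, 2 * sum(stats::dbinom(400:500, 500, 0.5)))
  expect_equal(hi$p, oracle, tolerance = 1e-12)
  expect_lt(hi$p, 1e-15)
  expect_equal(hi$bias, "P1")

  even <- res[res$gene_id == "even", ]
  expect_equal(even$log2fc, 0)
  expect_equal(even$bias, "none")

  # |log2fc| below 1 is never ASE regardless of p
  weak <- res[res$gene_id == "weak", ]
  expect_lt(abs(weak$log2fc), 1)
  expect_equal(weak$bias, "none")

  # zero-count cells are untested
  z <- ase_test(tibble::tibble(gene_id = "z", sample = "r1",
                               tissue = "shoot", condition = "0",
                               count_p1 = 0L, count_p2 = 0L))
  expect_true(is.na(z$p))
  expect_true(is.na(z$bias))
})

test_that("overdispersed replicates trigger the beta-binomial fallback", {
  # wildly divergent replicate fractions: binomial p would be tiny,
  # the beta-binomial acknowledges the replicate variance
  counts <- tibble::tibble(
    gene_id = "g", sample = paste0("r", 1:3),
    tissue = "shoot", condition = "0",
    count_p1 = c(190L, 10L, 110L), count_p2 = c(10L, 190L, 90L)
  )
  res <- ase_test(counts)
  expect_gt(res$rho, 0)
  binom_p <- min(1, 2 * stats::pbinom(sum(counts$count_p1) - 1, 600, 0.5,
                                      lower.tail = FALSE))
  expect_gt(res$p, binom_p)
})

test_that("BH adjustment matches the step-up oracle and handles NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  out <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ASEG classification partitions genes by the four-way rule", {
  make_res <- function(gene, biases) {
    cells <- tidyr::expand_grid(tissue = c("shoot", "root"),
                                condition = c("0", "200", "400"))
    tibble::tibble(gene_id = gene, tissue = cells$tissue,
                   condition = cells$condition, bias = biases)
  }
  res <- dplyr::bind_rows(
    make_res("gCons", rep("P1", 6)),
    make_res("gShift", c("P1", "none", "P2", "none", "none", "none")),
    make_res("gNonDir", c("P1", rep("none", 5))),
    make_res("gNull", rep("none", 6))
  )
  cl <- classify_asegs(res)
  got <- stats::setNames(cl$genes$class, cl$genes$gene_id)
  expect_equal(got[["gCons"]], "consistent")
  expect_equal(got[["gShift"]], "direction_shifting")
  expect_equal(got[["gNonDir"]], "non_directional")
  expect_equal(got[["gNull"]], "not_aseg")
  expect_equal(sum(cl$summary$n), 4)  # the partition is exhaustive
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("swapping the parental count columns mirrors every result", {
  set.seed(21)
  counts <- tidyr::expand_grid(
    gene_id = paste0("g", 1:30), sample = paste0("r", 1:3),
    tissue = c("shoot", "root"), condition = c("0", "200", "400"))
  counts$count_p1 <- stats::rnbinom(nrow(counts), mu = 60, size = 10)
  counts$count_p2 <- stats::rbinom(nrow(counts), counts$count_p1 + 40L, 0.5)
  swapped <- dplyr::rename(counts, count_p1 = count_p2,
                           count_p2 = count_p1)
  a <- ase_test(counts)
  b <- ase_test(swapped)
  ord <- order(a$gene_id, a$tissue, a$condition)
  a <- a[ord, ]; b <- b[order(b$gene_id, b$tissue, b$condition), ]
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  flip <- c(P1 = "P2", P2 = "P1", none = "none")
  expect_equal(b$bias, unname(flip[a$bias]))
  ca <- classify_asegs(a)$summary
  cb <- classify_asegs(b)$summary
  expect_equal(ca, cb)
})

test_that("the genome-wide bias test is a one-tailed exact binomial", {
  expect_gt(bias_binomial_test(10, 10), 0.4)
  expect_equal(bias_binomial_test(3, 0), 0.125)
  expect_equal(bias_binomial_test(0, 3), 0.125)
  # the dominant-direction tail for a heavily skewed ortholog split
  expect_lt(bias_binomial_test(4968, 2274), 1e-100)
  expect_error(bias_binomial_test(0, 0), "zero")
})
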